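test_that("alpha/beta/gamma closed forms and degenerate flagging", {
  # a tree has alpha = 0 for any V >= 3
  for (V in c(3, 5, 12)) {
    abg <- alpha_beta_gamma(L = V - 1, V = V)
    expect_equal(abg$alpha, 0)
  }
  k4 <- alpha_beta_gamma(L = 6, V = 4)
  expect_equal(k4$alpha, 1)
  expect_equal(k4$beta, 1.5)
  expect_equal(k4$gamma, 1)
  few <- alpha_beta_gamma(L = 1, V = 2)
  expect_false(few$defined)
  expect_true(is.na(few$alpha) && is.na(few$gamma))
  expect_equal(few$beta, 0.5)
  expect_equal(recover_node_count(2133, 0.832), 2564L)
})

test_that("decay constant: closed forms and inverse identity", {
  expect_equal(decay_alpha(0.5, 1), log(2))
  expect_equal(decay_alpha(0.05, 30000), -log(0.05) / 30000)
  expect_equal(decay_alpha(0.05, 30000), 9.986e-5, tolerance = 1e-3)
  set.seed(2)
  for (k in 1:20) {
    p <- runif(1, 0.01, 0.99); d <- runif(1, 0.1, 1e5)
    expect_equal(exp(-decay_alpha(p, d) * d), p, tolerance = 1e-12)
  }
  expect_error(decay_alpha(0, 10), "\\(0, 1\\)")
  expect_error(decay_alpha(1.2, 10), "\\(0, 1\\)")
  expect_error(decay_alpha(0.5, 0), "> 0")
  dd <- distance_decay(0.05, 3000)
  expect_equal(dd$decay_alpha, -log(0.05) / 3000)
})

test_that("PC: self-term, isolated patches, exhaustive-path oracle", {
  dec <- distance_decay(0.5, 1)
  one <- make_network(data.frame(id = 1, a = 10),
                      data.frame(i = integer(0), j = integer(0),
                                 lcd = numeric(0)), landscape_area_ha = 100)
  expect_equal(probability_of_connectivity(one, dec), 10^2 / 100^2)
  two <- make_network(data.frame(id = 1:2, a = c(3, 4)),
                      data.frame(i = integer(0), j = integer(0),
                                 lcd = numeric(0)), landscape_area_ha = 50)
  expect_equal(probability_of_connectivity(two, dec), (9 + 16) / 2500)
  empty <- make_network(data.frame(id = integer(0), a = numeric(0)),
                        data.frame(i = integer(0), j = integer(0),
                                   lcd = numeric(0)), landscape_area_ha = 10)
  expect_equal(probability_of_connectivity(empty, dec), 0)
  set.seed(14)
  for (k in 1:6) {
    net <- random_graph_network(4, p = 0.6)
    nodes <- net_nodes(net)
    lam <- runif(1, 0.3, 1.5)
    d <- structure(list(p = NA, d_ref = NA, decay_alpha = lam),
                   class = "distance_decay")
    expect_equal(probability_of_connectivity(net, d),
                 oracle_pc(nodes, net$edges, lam, net$landscape_area_ha),
                 tolerance = 1e-12)
  }
})

test_that("dPC: total loss for a single patch, brute-force leave-one-out", {
  dec <- distance_decay(0.5, 1)
  one <- make_network(data.frame(id = 1, a = 10),
                      data.frame(i = integer(0), j = integer(0),
                                 lcd = numeric(0)), landscape_area_ha = 100)
  expect_equal(unname(delta_pc(one, dec)), 100)
  # 5-node chain: compare against recomputing PC with the path oracle
  chain <- make_network(data.frame(id = 1:5, a = c(2, 1, 3, 1, 2)),
                        data.frame(i = 1:4, j = 2:5, lcd = c(.5, .8, .3, 1)),
                        landscape_area_ha = 20)
  lam <- 0.7
  d <- structure(list(p = NA, d_ref = NA, decay_alpha = lam),
                 class = "distance_decay")
  dpc <- delta_pc(chain, d)
  pc_full <- oracle_pc(net_nodes(chain), chain$edges, lam, 20)
  for (i in 1:5) {
    nodes_i <- net_nodes(chain)[-i, ]
    edges_i <- chain$edges[chain$edges$i != i & chain$edges$j != i, ]
    pc_i <- oracle_pc(nodes_i, edges_i, lam, 20)
    expect_equal(unname(dpc[as.character(i)]),
                 100 * (pc_full - pc_i) / pc_full, tolerance = 1e-10)
  }
  expect_true(all(dpc >= 0 & dpc <= 100))
})

test_that("dPC of a vanishing leaf patch tends to zero", {
  d <- structure(list(p = NA, d_ref = NA, decay_alpha = 1),
                 class = "distance_decay")
  net <- make_network(data.frame(id = 1:3, a = c(5, 5, 1e-6)),
                      data.frame(i = c(1, 2), j = c(2, 3), lcd = c(1, 1)),
                      landscape_area_ha = 20)
  dpc <- delta_pc(net, d)
  expect_lt(dpc[["3"]], 1e-4)
})

test_that("BCPC: three-node chain, leaves, exhaustive oracle on small graphs", {
  d1 <- structure(list(p = NA, d_ref = NA, decay_alpha = 1),
                  class = "distance_decay")
  chain <- make_network(data.frame(id = 1:3, a = c(1, 1, 1)),
                        data.frame(i = c(1, 2), j = c(2, 3), lcd = c(1, 1)),
                        landscape_area_ha = 10)
  b <- bc_pc(chain, d1)
  expect_equal(unname(b["2"]), exp(-2))
  expect_equal(unname(b["1"]), 0)
  expect_equal(unname(b["3"]), 0)
  set.seed(77)
  for (k in 1:10) {
    n <- sample(4:7, 1)
    net <- random_graph_network(n, p = 0.5)
    lam <- runif(1, 0.2, 1.2)
    d <- structure(list(p = NA, d_ref = NA, decay_alpha = lam),
                   class = "distance_decay")
    expect_equal(bc_pc(net, d),
                 oracle_bcpc(net_nodes(net), net$edges, lam),
                 tolerance = 1e-12)
  }
})

test_that("current flow: single resistor, series circuit, invariances", {
  # two nodes, one edge: every grounding pushes the unit current through both
  two <- make_network(data.frame(id = 1:2, a = c(1, 1)),
                      data.frame(i = 1, j = 2, lcd = 2),
                      landscape_area_ha = 10)
  cf2 <- current_flow(two)
  expect_equal(unname(cf2), c(2, 2))

  # series 1 -2- 3 with conductances 2 and 1: hand-solved Kirchhoff
  ser <- make_network(data.frame(id = 1:3, a = c(1, 1, 1)),
                      data.frame(i = c(1, 2), j = c(2, 3), lcd = c(0.5, 1)),
                      landscape_area_ha = 10)
  cf <- current_flow(ser)
  expect_equal(unname(cf), c(4, 6, 4), tolerance = 1e-10)

  # uniform conductance scaling leaves node currents unchanged
  ser2 <- make_network(data.frame(id = 1:3, a = c(1, 1, 1)),
                       data.frame(i = c(1, 2), j = c(2, 3),
                                  lcd = 10 * c(0.5, 1)),
                       landscape_area_ha = 10)
  expect_equal(current_flow(ser2), cf, tolerance = 1e-10)

  # isolated node gets zero
  iso <- make_network(data.frame(id = 1:3, a = c(1, 1, 1)),
                      data.frame(i = 1, j = 2, lcd = 1),
                      landscape_area_ha = 10)
  expect_equal(unname(current_flow(iso))[3], 0)
})

test_that("adding a corridor never decreases PC", {
  set.seed(9)
  for (k in 1:5) {
    net <- random_graph_network(5, p = 0.4)
    d <- structure(list(p = NA, d_ref = NA, decay_alpha = 0.8),
                   class = "distance_decay")
    pc0 <- probability_of_connectivity(net, d)
    # add one absent edge
    have <- paste(net$edges$i, net$edges$j)
    pairs <- t(utils::combn(5, 2))
    absent <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% have), , drop = FALSE]
    if (nrow(absent) == 0) next
    e2 <- rbind(net$edges, data.frame(i = absent[1, 1], j = absent[1, 2],
                                      lcd = 1))
    net2 <- make_network(net_nodes(net), e2, net$landscape_area_ha)
    expect_gte(probability_of_connectivity(net2, d), pc0 - 1e-12)
  }
})

test_that("connectivity report carries the documented tables", {
  set.seed(4)
  net <- random_graph_network(5, p = 0.7)
  net$scale <- dispersal_scale("small")
  rep <- connectivity_report(net, decay = distance_decay(0.05, 3000))
  expect_named(rep$network_level,
               c("scale", "year", "V", "L", "alpha", "beta", "gamma", "pc"))
  expect_named(rep$node_level, c("id", "area_ha", "dpc", "bcpc", "cf"))
  expect_equal(rep$network_level$beta, net$L / net$V)
  expect_true(all(rep$node_level$cf >= 0))
})
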