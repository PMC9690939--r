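lam1 <- structure(list(p = NA, d_ref = NA, decay_alpha = 1),
                  class = "distance_decay")

triangles_graph <- function() {
  # two disjoint unit-weight triangles (nodes 1-3 and 4-6)
  net <- make_network(
    data.frame(id = 1:6, a = rep(1, 6)),
    data.frame(i = c(1, 1, 2, 4, 4, 5), j = c(2, 3, 3, 5, 6, 6),
               lcd = rep(0, 6)),
    landscape_area_ha = 10)
  build_weighted_graph(net, lam1)   # d = 0 -> every weight exactly 1
}

test_that("edge weights follow the area-product distance-decay kernel", {
  net <- make_network(data.frame(id = 1:2, a = c(1, 1)),
                      data.frame(i = 1, j = 2, lcd = 0),
                      landscape_area_ha = 10)
  expect_equal(build_weighted_graph(net, lam1)$edges$weight, 1)
  net2 <- make_network(data.frame(id = 1:2, a = c(2, 2)),
                       data.frame(i = 1, j = 2, lcd = 0),
                       landscape_area_ha = 10)
  expect_equal(build_weighted_graph(net2, lam1)$edges$weight, 4)  # bilinear
  set.seed(3)
  net3 <- random_graph_network(6, p = 0.6)
  wg <- build_weighted_graph(net3, lam1)
  nodes <- net_nodes(net3)
  manual <- nodes$a[wg$edges$i] * nodes$a[wg$edges$j] * exp(-wg$edges$d)
  expect_equal(wg$edges$weight, manual, tolerance = 1e-12)
})

test_that("modularity: single cluster, two triangles, per-node clusters", {
  wg <- triangles_graph()
  expect_equal(modularity_score(wg, rep(1, 6)), 0)
  expect_equal(modularity_score(wg, c(1, 1, 1, 2, 2, 2)), 0.5)
  # fully split complete graph has negative modularity
  k4 <- make_network(data.frame(id = 1:4, a = rep(1, 4)),
                     data.frame(i = c(1, 1, 1, 2, 2, 3), j = c(2, 3, 4, 3, 4, 4),
                                lcd = rep(0, 6)), landscape_area_ha = 10)
  wk4 <- build_weighted_graph(k4, lam1)
  expect_lt(modularity_score(wk4, 1:4), 0)
  # exhaustive check: the component split is optimal over all 6-node partitions
  best <- max(vapply(all_partitions(6),
                     function(m) modularity_score(wg, m), numeric(1)))
  expect_equal(best, 0.5)
})

test_that("modularity agrees with the igraph implementation on random graphs", {
  set.seed(10)
  for (k in 1:6) {
    net <- random_graph_network(6, p = 0.5)
    wg <- build_weighted_graph(net, lam1)
    g <- igraph::graph_from_data_frame(wg$edges[, c("i", "j")],
                                       directed = FALSE,
                                       vertices = data.frame(name = 1:6))
    mem <- sample(1:3, 6, replace = TRUE)
    expect_equal(modularity_score(wg, mem),
                 igraph::modularity(g, mem[as.integer(igraph::V(g)$name)],
                                    weights = wg$edges$weight),
                 tolerance = 1e-12)
  }
})

test_that("greedy agglomeration recovers components and handles no edges", {
  wg <- triangles_graph()
  part <- greedy_modularity(wg)
  expect_equal(part$q, 0.5)
  expect_equal(part$n_groups, 2)
  expect_equal(unname(part$membership[1:3]), rep(1, 3))
  expect_equal(unname(part$membership[4:6]), rep(2, 3))

  lone <- build_weighted_graph(
    make_network(data.frame(id = 1:3, a = rep(1, 3)),
                 data.frame(i = integer(0), j = integer(0), lcd = numeric(0)),
                 landscape_area_ha = 10), lam1)
  p0 <- greedy_modularity(lone)
  expect_equal(p0$n_groups, 3)
  expect_true(is.na(p0$q))
  expect_true(isTRUE(attr(p0$q, "undefined")))
})

test_that("greedy modularity is near-optimal on small random graphs", {
  set.seed(20)
  for (k in 1:10) {
    n <- sample(5:7, 1)
    net <- random_graph_network(n, p = 0.5)
    wg <- build_weighted_graph(net, lam1)
    if (wg$m <= 0) next
    greedy <- greedy_modularity(wg)
    opt <- max(vapply(all_partitions(n),
                      function(m) modularity_score(wg, m), numeric(1)))
    if (opt > 0) expect_gte(greedy$q, 0.95 * opt)
  }
})

test_that("greedy agglomeration matches the reference CNM implementation", {
  set.seed(33)
  for (k in 1:8) {
    n <- sample(5:9, 1)
    net <- random_graph_network(n, p = 0.5)
    wg <- build_weighted_graph(net, lam1)
    if (wg$m <= 0) next
    mine <- greedy_modularity(wg)
    g <- igraph::graph_from_data_frame(wg$edges[, c("i", "j")],
                                       directed = FALSE,
                                       vertices = data.frame(name = seq_len(n)))
    ref <- igraph::cluster_fast_greedy(g, weights = wg$edges$weight)
    expect_equal(mine$q, max(ref$modularity), tolerance = 1e-9)
  }
})

test_that("node importance normalises and combines as stated", {
  rep4 <- list(node_level = data.frame(
    id = 1:4, area_ha = c(10, 40, 20, 10), bcpc = c(0, 6, 3, 2)))
  imp <- node_importance(rep4)
  expect_equal(imp$pni[2], 1)                      # max bcpc and max area
  expect_equal(imp$pni[1], 0)                      # min bcpc and min area
  expect_equal(imp$cpi, c(0, 1, .5, 2 / 6))
  expect_equal(imp$hfi, c(0, 1, 1 / 3, 0))
  expect_equal(imp$pni, 0.5 * imp$cpi + 0.5 * imp$hfi)
  # degenerate component collapses to zero
  repd <- list(node_level = data.frame(id = 1:3, area_ha = c(1, 2, 3),
                                       bcpc = c(5, 5, 5)))
  impd <- node_importance(repd)
  expect_equal(impd$cpi, rep(0, 3))
  # affine rescaling of bcpc leaves pni unchanged
  repa <- rep4
  repa$node_level$bcpc <- 3 * repa$node_level$bcpc + 7
  expect_equal(node_importance(repa)$pni, imp$pni)
})

test_that("core nodes follow the weight-dominance rule without parameters", {
  path <- list(nodes = data.frame(id = 1:3, a = 1),
               edges = data.frame(i = c(1, 2), j = c(2, 3)))
  W <- c("1" = 0.5, "2" = 0.9, "3" = 0.3)
  cn <- core_nodes(path, W)
  expect_equal(cn$cen, c(-0.4, (0.9 - 0.5) + (0.9 - 0.3), -0.6))
  expect_equal(cn$is_core, c(FALSE, TRUE, FALSE))
  # isolated node: empty sum, not core
  iso <- list(nodes = data.frame(id = 1:2, a = 1),
              edges = data.frame(i = integer(0), j = integer(0)))
  cni <- core_nodes(iso, c("1" = 0.7, "2" = 0.2))
  expect_equal(cni$cen, c(0, 0))
  expect_false(any(cni$is_core))
  # all weights equal: no node dominates
  cne <- core_nodes(path, c("1" = 0.4, "2" = 0.4, "3" = 0.4))
  expect_false(any(cne$is_core))
})

test_that("patch matching requires a majority overlap", {
  ps_t <- make_patch_set(list(1:100, 201:260), c(30, 30))
  ps_t1 <- make_patch_set(list(4:103, 500:520), c(30, 30))
  nm <- match_patches(ps_t, ps_t1)
  expect_equal(nm[1], 1L)       # 97% of patch 1 carried over
  expect_true(is.na(nm[2]))     # patch 2 vanished
  ps_bad <- make_patch_set(list(1:10), c(10, 10))
  expect_error(match_patches(ps_t, ps_bad), "different grids")
})

test_that("evolution relation follows core nodes across the identity map", {
  mem_t <- c("1" = 1, "2" = 1, "3" = 2, "4" = 2)
  mem_t1 <- c("1" = 1, "2" = 1, "3" = 2, "4" = 2)
  part_t <- make_partition(mem_t); part_t1 <- make_partition(mem_t1)
  cores <- data.frame(id = 1:4, cen = c(1, -1, 1, -1),
                      is_core = c(TRUE, FALSE, TRUE, FALSE))
  rel <- track_evolution(part_t, cores, part_t1)
  expect_equal(rel, data.frame(group_t = c(1, 2), group_t1 = c(1, 2)))
  # a group's two cores landing in two successor groups relates it to both
  part_s <- make_partition(c("1" = 1, "2" = 1, "3" = 1, "4" = 2))
  cores2 <- data.frame(id = 1:4, cen = c(1, 0, 1, 0),
                       is_core = c(TRUE, FALSE, TRUE, FALSE))
  split_t1 <- make_partition(c("1" = 5, "2" = 5, "3" = 6, "4" = 6))
  rel2 <- track_evolution(part_s, cores2, split_t1)
  expect_setequal(paste(rel2$group_t, rel2$group_t1), c("1 5", "1 6"))
  # a group without core nodes relates to nothing
  nocore <- data.frame(id = 1:4, cen = 0, is_core = FALSE)
  expect_equal(nrow(track_evolution(part_t, nocore, part_t1)), 0)
})

test_that("the classifier emits each of the seven life-cycle events", {
  # identical groups -> stability
  pt <- make_partition(c("1" = 1, "2" = 1, "3" = 2, "4" = 2))
  cores <- data.frame(id = 1:4, cen = c(1, -1, 1, -1),
                      is_core = c(TRUE, FALSE, TRUE, FALSE))
  rel <- track_evolution(pt, cores, pt)
  ev <- classify_events(rel, pt, pt)
  expect_equal(ev$type, c("stability", "stability"))

  # expansion / shrinkage via size changes beyond tau
  big <- make_partition(c("1" = 1, "2" = 1, "5" = 1, "3" = 2, "4" = 2))
  rel2 <- track_evolution(pt, cores, big)
  ev2 <- classify_events(rel2, pt, big)
  expect_setequal(ev2$type, c("expansion", "stability"))
  shr <- make_partition(c("1" = 1, "3" = 2, "4" = 2))
  rel3 <- track_evolution(pt, cores, shr)
  ev3 <- classify_events(rel3, pt, shr)
  expect_true("shrinkage" %in% ev3$type)

  # split: one predecessor's cores in two successors
  cores2 <- data.frame(id = 1:4, cen = 1, is_core = c(TRUE, TRUE, TRUE, FALSE))
  one <- make_partition(c("1" = 1, "2" = 1, "3" = 1, "4" = 1))
  two <- make_partition(c("1" = 7, "2" = 7, "3" = 8, "4" = 8))
  ev4 <- classify_events(track_evolution(one, cores2, two), one, two)
  expect_equal(ev4$type, "split")
  expect_equal(ev4$groups_t1, "7;8")

  # merger: two predecessors' cores in one successor
  ev5 <- classify_events(track_evolution(two, cores2, one), two, one)
  expect_equal(ev5$type, "merger")

  # formation and disappearance
  only_t <- make_partition(c("1" = 1, "2" = 1))
  only_t1 <- make_partition(c("9" = 3, "10" = 3))
  coret <- data.frame(id = 1:2, cen = 1, is_core = TRUE)
  relx <- track_evolution(only_t, coret, only_t1)
  evx <- classify_events(relx, only_t, only_t1)
  expect_setequal(evx$type, c("disappearance", "formation"))
})

test_that("every group lands in exactly one event (accounting property)", {
  set.seed(6)
  for (k in 1:10) {
    n_t <- sample(4:8, 1); n_t1 <- sample(4:8, 1)
    ids_t <- as.character(seq_len(n_t))
    ids_t1 <- as.character(sample(20, n_t1))
    pt <- make_partition(stats::setNames(sample(1:3, n_t, TRUE), ids_t))
    p1 <- make_partition(stats::setNames(sample(1:3, n_t1, TRUE), ids_t1))
    nm <- sample(c(ids_t1, rep(NA, 3)), n_t, replace = TRUE)
    cores <- data.frame(id = ids_t, cen = 1,
                        is_core = sample(c(TRUE, FALSE), n_t, TRUE))
    rel <- track_evolution(pt, cores, p1, nm)
    ev <- classify_events(rel, pt, p1, nm)
    seen_t <- unlist(strsplit(ev$groups_t[ev$groups_t != ""], ";"))
    seen_t1 <- unlist(strsplit(ev$groups_t1[ev$groups_t1 != ""], ";"))
    expect_setequal(seen_t, as.character(unique(unname(pt$membership))))
    expect_setequal(seen_t1, as.character(unique(unname(p1$membership))))
    expect_equal(anyDuplicated(seen_t), 0)
    expect_equal(anyDuplicated(seen_t1), 0)
  }
})
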