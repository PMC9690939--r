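# node table of an eco_network (works for raster-built and abstract networks)
net_nodes <- function(network) {
  stopifnot(inherits(network, "eco_network"))
  network$patches$patches
}

# igraph over patch ids with edge attribute lcd
patch_graph <- function(network) {
  nodes <- net_nodes(network)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(network$edges) > 0) {
    ii <- match(network$edges$i, nodes$id)
    jj <- match(network$edges$j, nodes$id)
    g <- igraph::add_edges(g, as.vector(rbind(ii, jj)),
                           lcd = network$edges$lcd)
  }
  igraph::set_vertex_attr(g, "name", value = as.character(nodes$id))
}

#' Network-structure indices: closure, line-point rate, connectivity
#'
#' With L corridors and V sources: alpha = (L - V + 1) / (2V - 5) measures
#' network closure (how many independent loops exist), beta = L / V is the
#' mean number of corridors per source, gamma = L / (3 (V - 2)) compares the
#' corridor count to the maximum possible in a planar network. alpha and
#' gamma need V >= 3; with fewer sources they are returned as `NA` and
#' `defined` is `FALSE`.
#'
#' @param L corridor count, or an `eco_network` (then `V` is ignored).
#' @param V source count.
#' @return list with `alpha`, `beta`, `gamma`, `L`, `V`, `defined`.
#' @export
alpha_beta_gamma <- function(L, V = NULL) {
  if (inherits(L, "eco_network")) { V <- L$V; L <- L$L }
  if (is.null(V)) stop("`V` is required when `L` is a count")
  defined <- V >= 3
  list(
    alpha = if (defined) (L - V + 1) / (2 * V - 5) else NA_real_,
    beta = L / V,
    gamma = if (defined) L / (3 * (V - 2)) else NA_real_,
    L = L, V = V, defined = defined
  )
}

#' Recover the source count from a corridor count and line-point rate
#'
#' Since beta = L / V, the node count is V = round(L / beta); used to
#' cross-check published index tables that print L and beta but not V.
#'
#' @param L corridor count.
#' @param beta line-point rate.
#' @return integer V.
#' @export
recover_node_count <- function(L, beta) as.integer(round(L / beta))

#' Distance-decay constant of the movement-probability kernel
#'
#' Movement probability decays as `exp(-alpha * d)`; the decay constant is
#' fixed by one anchor point: `alpha = -log(p) / d`, with `p` the movement
#' probability at distance `d`. The species' maximum dispersal distance is
#' conventionally anchored at p = 0.05.
#'
#' @param p probability in (0, 1).
#' @param d anchor distance (> 0), in the same (cost) units as the
#'   inter-patch distances.
#' @return the decay constant.
#' @export
decay_alpha <- function(p, d) {
  if (!is.numeric(p) || p <= 0 || p >= 1) stop("`p` must be in (0, 1)")
  if (!is.numeric(d) || d <= 0) stop("`d` must be > 0")
  -log(p) / d
}

#' Distance-decay specification
#'
#' @param p movement probability at the reference distance.
#' @param d_ref reference distance in cost units.
#' @return a `distance_decay`: list with `p`, `d_ref`, `decay_alpha`.
#' @export
distance_decay <- function(p = 0.05, d_ref) {
  structure(list(p = p, d_ref = d_ref, decay_alpha = decay_alpha(p, d_ref)),
            class = "distance_decay")
}

#' Distance decay for one dispersal scale
#'
#' Anchors p at the scale's maximum dispersal distance expressed in cost
#' units (`max_dispersal_km * 1000 * r_ref`).
#'
#' @param scale a [dispersal_scale()].
#' @param p anchor probability (default 0.05).
#' @param r_ref reference resistance (default 1).
#' @return a [distance_decay()].
#' @export
scale_decay <- function(scale, p = 0.05, r_ref = 1) {
  distance_decay(p, scale$max_dispersal_km * 1000 * r_ref)
}

# max-product movement probabilities between all node pairs:
# p*_ij = exp(-lambda * D_ij) with D the shortest-path distance over edge lcd
pstar_matrix <- function(network, decay) {
  g <- patch_graph(network)
  n <- igraph::vcount(g)
  if (n == 0) return(matrix(0, 0, 0))
  D <- igraph::distances(g, weights = igraph::E(g)$lcd)
  P <- exp(-decay$decay_alpha * D)
  P[!is.finite(D)] <- 0
  diag(P) <- 1
  P
}

#' Probability of connectivity (PC)
#'
#' `PC = sum_i sum_j a_i a_j p*_ij / A_L^2`, where `p*_ij` is the
#' maximum-product path probability between patches i and j (step
#' probability `exp(-alpha * lcd)` along corridors, so the optimal path
#' minimises the summed least-cost distance), `a` the patch attribute and
#' `A_L` the total landscape area. Self-pairs contribute `a_i^2`
#' (`p*_ii = 1`); unreachable pairs contribute nothing.
#'
#' @param network an `eco_network`.
#' @param decay a [distance_decay()].
#' @return PC in `[0, 1]`; 0 for an empty network.
#' @export
probability_of_connectivity <- function(network, decay) {
  nodes <- net_nodes(network)
  if (nrow(nodes) == 0) return(0)
  if (any(nodes$a <= 0)) stop("patch attributes must be positive")
  P <- pstar_matrix(network, decay)
  a <- nodes$a
  sum(outer(a, a) * P) / network$landscape_area_ha^2
}

# network with one patch (and incident corridors) removed
drop_patch <- function(network, id) {
  nodes <- net_nodes(network)
  keep <- nodes$id != id
  edges <- network$edges
  if (nrow(edges) > 0) edges <- edges[edges$i != id & edges$j != id, , drop = FALSE]
  make_network(nodes[keep, , drop = FALSE], edges, network$landscape_area_ha,
               scale = network$scale, year = network$year)
}

#' Patch importance by connectivity loss (dPC)
#'
#' `dPC_i = 100 (PC - PC_remove_i) / PC`: the percentage of the probability
#' of connectivity lost when patch i and its corridors are removed.
#'
#' @param network an `eco_network`.
#' @param id patch id to remove; omit to get all patches.
#' @param decay a [distance_decay()].
#' @return named numeric vector of dPC values in `[0, 100]` (`NA` with a
#'   warning when PC is zero).
#' @export
delta_pc <- function(network, decay, id = NULL) {
  nodes <- net_nodes(network)
  ids <- id %||% nodes$id
  pc <- probability_of_connectivity(network, decay)
  out <- stats::setNames(rep(NA_real_, length(ids)), ids)
  if (pc <= 0) {
    warning("PC is zero; dPC undefined")
    return(out)
  }
  for (k in seq_along(ids)) {
    pc_rm <- probability_of_connectivity(drop_patch(network, ids[k]), decay)
    out[k] <- 100 * (pc - pc_rm) / pc
  }
  out
}

#' Area- and decay-weighted betweenness centrality (BCPC)
#'
#' For every unordered patch pair (j, k), the maximum-product-probability
#' path (the corridor path minimising total least-cost distance) is found;
#' each of its interior patches accumulates
#' `a_j a_k exp(-alpha d_jk)`, with `d_jk` the optimal path's total cost.
#' Endpoints are excluded; unreachable pairs contribute nothing.
#'
#' @param network an `eco_network`.
#' @param decay a [distance_decay()].
#' @return named numeric vector of BCPC values per patch.
#' @export
bc_pc <- function(network, decay) {
  nodes <- net_nodes(network)
  n <- nrow(nodes)
  out <- stats::setNames(rep(0, n), nodes$id)
  if (n < 3 || nrow(network$edges) == 0) return(out)
  g <- patch_graph(network)
  wts <- igraph::E(g)$lcd
  D <- igraph::distances(g, weights = wts)
  a <- nodes$a
  for (j in seq_len(n - 1)) {
    ks <- (j + 1):n
    reach <- ks[is.finite(D[j, ks])]
    if (length(reach) == 0) next
    sp <- igraph::shortest_paths(g, from = j, to = reach, weights = wts,
                                 output = "vpath")
    for (q in seq_along(reach)) {
      k <- reach[q]
      vp <- as.integer(sp$vpath[[q]])
      interior <- setdiff(vp, c(j, k))
      if (length(interior))
        out[interior] <- out[interior] +
          a[j] * a[k] * exp(-decay$decay_alpha * D[j, k])
    }
  }
  out
}

#' Circuit-theory current flow through each patch (CF)
#'
#' The corridor network is read as a resistor network (edge conductance
#' `1 / lcd`). For every focal patch j, a unit current is injected at every
#' other patch of j's component while j is grounded; Kirchhoff's equations
#' give the potentials, and the current through patch i is half the sum of
#' the absolute currents on its incident edges plus half its net injection.
#' `CF_i` sums these through-currents over all groundings. Isolated patches
#' get 0.
#'
#' @param network an `eco_network`.
#' @return named numeric vector of CF values per patch.
#' @export
current_flow <- function(network) {
  nodes <- net_nodes(network)
  n <- nrow(nodes)
  out <- stats::setNames(rep(0, n), nodes$id)
  if (n == 0 || nrow(network$edges) == 0) return(out)
  g <- patch_graph(network)
  comp <- igraph::components(g)$membership
  edges_idx <- cbind(match(network$edges$i, nodes$id),
                     match(network$edges$j, nodes$id))
  cond <- 1 / network$edges$lcd
  for (cm in unique(comp)) {
    S <- which(comp == cm)
    m <- length(S)
    if (m < 2) next
    pos <- match(seq_len(n), S)  # node -> position in S
    Lap <- matrix(0, m, m)
    in_comp <- which(comp[edges_idx[, 1]] == cm)
    for (e in in_comp) {
      u <- pos[edges_idx[e, 1]]; v <- pos[edges_idx[e, 2]]
      Lap[u, v] <- Lap[u, v] - cond[e]; Lap[v, u] <- Lap[v, u] - cond[e]
      Lap[u, u] <- Lap[u, u] + cond[e]; Lap[v, v] <- Lap[v, v] + cond[e]
    }
    for (jg in seq_len(m)) {
      b <- rep(1, m); b[jg] <- -(m - 1)
      v_pot <- rep(0, m)
      v_pot[-jg] <- solve(Lap[-jg, -jg, drop = FALSE], b[-jg])
      flow <- rep(0, m)
      for (e in in_comp) {
        u <- pos[edges_idx[e, 1]]; vv <- pos[edges_idx[e, 2]]
        I <- abs((v_pot[u] - v_pot[vv]) * cond[e])
        flow[u] <- flow[u] + I; flow[vv] <- flow[vv] + I
      }
      out[S] <- out[S] + 0.5 * (flow + abs(b))
    }
  }
  out
}

#' Full connectivity report for one network
#'
#' Network level: V, L, alpha, beta, gamma, PC. Node level: area, dPC, BCPC,
#' CF. Edge level: lcd, cwd_lcpl, width. The decay defaults to the network
#' scale's maximum dispersal distance at p = 0.05.
#'
#' @param network an `eco_network`.
#' @param decay a [distance_decay()]; default derived from the network scale.
#' @param p anchor probability used when deriving the default decay.
#' @param r_ref reference resistance for the default decay.
#' @return a `connectivity_report`: list of data.frames `network_level`,
#'   `node_level`, `edge_level`.
#' @export
connectivity_report <- function(network, decay = NULL, p = 0.05, r_ref = 1) {
  if (is.null(decay)) {
    if (is.null(network$scale))
      stop("no decay given and network has no scale to derive one from")
    decay <- scale_decay(network$scale, p = p, r_ref = r_ref)
  }
  abg <- alpha_beta_gamma(network)
  pc <- probability_of_connectivity(network, decay)
  dpc <- if (pc > 0) delta_pc(network, decay) else
    stats::setNames(rep(NA_real_, network$V), net_nodes(network)$id)
  bcpc <- bc_pc(network, decay)
  cf <- current_flow(network)
  nodes <- net_nodes(network)
  structure(list(
    network_level = data.frame(
      scale = if (!is.null(network$scale$name)) network$scale$name else NA,
      year = network$year, V = network$V, L = network$L,
      alpha = abg$alpha, beta = abg$beta, gamma = abg$gamma, pc = pc),
    node_level = data.frame(
      id = nodes$id, area_ha = nodes$area_ha, dpc = as.numeric(dpc),
      bcpc = as.numeric(bcpc), cf = as.numeric(cf)),
    edge_level = if (nrow(network$edges) > 0)
      network$edges[, intersect(c("i", "j", "lcd", "cwd_lcpl", "width_m"),
                                names(network$edges)), drop = FALSE]
    else data.frame(i = integer(0), j = integer(0), lcd = numeric(0)),
    decay = decay
  ), class = "connectivity_report")
}
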