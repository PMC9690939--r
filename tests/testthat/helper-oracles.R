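# Independent oracles used by the tests. These deliberately share no code
# with the package implementations they check.

# Plain O(V^2) Dijkstra over the 8-connected cell graph with step cost
# step_length * (R(u) + R(v)) / 2. Returns the full cost raster from a
# source cell set.
oracle_cost_distance <- function(R, h, source_cells) {
  nr <- nrow(R); nc <- ncol(R); n <- nr * nc
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  dist <- rep(Inf, n); dist[source_cells] <- 0
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (length(cand) == 0) break
    u <- cand[which.min(dist[cand])]
    done[u] <- TRUE
    ru <- (u - 1) %% nr + 1; cu <- (u - 1) %/% nr + 1
    for (k in 1:8) {
      r2 <- ru + dr[k]; c2 <- cu + dc[k]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v <- (c2 - 1) * nr + r2
      step <- if (dr[k] != 0 && dc[k] != 0) h * sqrt(2) else h
      w <- dist[u] + step * (R[u] + R[v]) / 2
      if (w < dist[v]) dist[v] <- w
    }
  }
  matrix(dist, nr, nc)
}

# Brute-force Euclidean distance (in cells) to the nearest TRUE cell.
oracle_edt <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  out <- matrix(Inf, nrow(mask), ncol(mask))
  if (nrow(idx) == 0) return(out)
  for (r in seq_len(nrow(mask))) for (c in seq_len(ncol(mask)))
    out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
  out
}

# Count connected components of a logical matrix by BFS flood fill.
oracle_n_components <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 0, 0, 1), c(0, -1, 1, 0))
  count <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      ru <- (u - 1) %% nr + 1; cu <- (u - 1) %/% nr + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- ru + offs[k, 1]; c2 <- cu + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        v <- (c2 - 1) * nr + r2
        if (mask[v] && !seen[v]) { seen[v] <- TRUE; queue <- c(queue, v) }
      }
    }
  }
  count
}

# ---- abstract-graph oracles -------------------------------------------------

# All simple paths between two nodes of an undirected graph given as an
# edge list (data.frame i, j, lcd). Returns list of node-id vectors.
oracle_simple_paths <- function(edges, from, to, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$j[edges$i == v], edges$i[edges$j == v])
  })
  paths <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == to) { paths[[length(paths) + 1]] <<- path; return(invisible()) }
    for (w in adj[[as.character(v)]])
      if (!(w %in% path)) walk(c(path, w))
  }
  walk(from)
  paths
}

edge_lcd <- function(edges, u, v) {
  hit <- (edges$i == u & edges$j == v) | (edges$i == v & edges$j == u)
  min(edges$lcd[hit])
}

path_cost <- function(edges, path) {
  if (length(path) < 2) return(0)
  sum(vapply(seq_len(length(path) - 1),
             function(k) edge_lcd(edges, path[k], path[k + 1]), numeric(1)))
}

# Max-product movement probability by exhaustive path enumeration.
oracle_pstar <- function(nodes, edges, from, to, lambda) {
  if (from == to) return(1)
  paths <- oracle_simple_paths(edges, from, to, nodes$id)
  if (length(paths) == 0) return(0)
  max(vapply(paths, function(p) exp(-lambda * path_cost(edges, p)), numeric(1)))
}

oracle_pc <- function(nodes, edges, lambda, area) {
  tot <- 0
  for (i in nodes$id) for (j in nodes$id)
    tot <- tot + nodes$a[nodes$id == i] * nodes$a[nodes$id == j] *
      oracle_pstar(nodes, edges, i, j, lambda)
  tot / area^2
}

# BCPC by exhaustive search: for every unordered pair, the best (minimum
# total cost) simple path; interior nodes accumulate the weighted kernel.
oracle_bcpc <- function(nodes, edges, lambda) {
  out <- stats::setNames(rep(0, nrow(nodes)), nodes$id)
  ids <- nodes$id
  n <- length(ids)
  if (n < 3) return(out)
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    paths <- oracle_simple_paths(edges, ids[a], ids[b], ids)
    if (length(paths) == 0) next
    costs <- vapply(paths, function(p) path_cost(edges, p), numeric(1))
    best <- paths[[which.min(costs)]]
    interior <- setdiff(best, c(ids[a], ids[b]))
    if (length(interior))
      out[as.character(interior)] <- out[as.character(interior)] +
        nodes$a[a] * nodes$a[b] * exp(-lambda * min(costs))
  }
  out
}

# ---- modularity oracles -----------------------------------------------------

# Weighted modularity from the adjacency matrix (independent formulation).
oracle_modularity <- function(W, membership) {
  m <- sum(W) / 2
  q <- 0
  for (cl in unique(membership)) {
    sel <- membership == cl
    q <- q + sum(W[sel, sel]) / (2 * m) - (sum(W[sel, ]) / (2 * m))^2
  }
  q
}

# All set partitions of 1..n (Bell(8) = 4140), as membership vectors.
all_partitions <- function(n) {
  grow <- function(parts, k) {
    if (k > n) return(parts)
    out <- list()
    for (p in parts) {
      for (b in seq_along(p)) {
        q <- p; q[[b]] <- c(q[[b]], k)
        out[[length(out) + 1]] <- q
      }
      out[[length(out) + 1]] <- c(p, list(k))
    }
    grow(out, k + 1)
  }
  parts <- grow(list(list(1L)), 2L)
  lapply(parts, function(p) {
    mem <- integer(n)
    for (b in seq_along(p)) mem[p[[b]]] <- b
    mem
  })
}

# ---- random fixtures --------------------------------------------------------

random_graph_network <- function(n, p = 0.5, area = 100, connected_bias = TRUE) {
  nodes <- data.frame(id = seq_len(n), a = stats::runif(n, 0.5, 3))
  pairs <- t(utils::combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  if (connected_bias && !any(keep)) keep[sample.int(length(keep), 1)] <- TRUE
  edges <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                      lcd = stats::runif(sum(keep), 0.2, 2))
  make_network(nodes, edges, landscape_area_ha = area)
}

make_partition <- function(membership) {
  structure(list(membership = membership, q = NA_real_,
                 n_groups = length(unique(membership)), q_trace = NULL),
            class = "group_partition")
}

# hand-built patch_set on a grid (cells: list of column-major index vectors)
make_patch_set <- function(cells, shape, cell_size = 30, year = NA) {
  area <- vapply(cells, length, integer(1)) * cell_size^2 / 1e4
  structure(
    list(patches = data.frame(id = seq_along(cells),
                              n_cells = vapply(cells, length, integer(1)),
                              area_ha = area, a = area),
         cells = cells, shape = shape, cell_size = cell_size, year = year,
         scale_name = NA),
    class = "patch_set")
}

unlimited_scale <- function() {
  structure(list(name = "test", max_dispersal_km = 1e9, min_habitat_ha = 0),
            class = "dispersal_scale")
}
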