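#' Build the 8-connected movement graph of a resistance surface
#'
#' Cells are vertices; every pair of 8-neighbours is joined by an edge whose
#' weight is the step length (cell size, or cell size times sqrt(2) on
#' diagonals) times the mean of the two cells' resistance values — the
#' standard raster cost-distance convention.
#'
#' @param resistance a resistance [eco_raster].
#' @return a `cost_graph`: list with the `igraph` object and grid metadata.
#' @export
cost_graph <- function(resistance) {
  stopifnot(inherits(resistance, "eco_raster"))
  R <- resistance$grid
  nr <- nrow(R); nc <- ncol(R); h <- resistance$cell_size
  cellv <- as.numeric(R)
  from <- integer(0); to <- integer(0); len <- numeric(0)
  all_cells <- seq_len(nr * nc)
  r <- ((all_cells - 1L) %% nr) + 1L
  c <- ((all_cells - 1L) %/% nr) + 1L
  add <- function(mask, off, step) {
    f <- all_cells[mask]
    from <<- c(from, f); to <<- c(to, f + off)
    len <<- c(len, rep(step, length(f)))
  }
  add(c < nc, nr, h)                      # east
  add(r < nr, 1L, h)                      # south
  add(r < nr & c < nc, nr + 1L, h * sqrt(2))  # south-east
  add(r > 1L & c < nc, nr - 1L, h * sqrt(2))  # north-east
  w <- len * (cellv[from] + cellv[to]) / 2
  g <- igraph::make_empty_graph(n = nr * nc, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(from, to)), weight = w)
  structure(list(graph = g, nr = nr, nc = nc, cell_size = h, ncell = nr * nc),
            class = "cost_graph")
}

# Attach one zero-cost virtual vertex per patch, wired to all its cells.
graph_with_patches <- function(cg, cells_list) {
  n <- length(cells_list)
  g2 <- igraph::add_vertices(cg$graph, n)
  virt <- cg$ncell + seq_len(n)
  for (i in seq_len(n)) {
    cells <- cells_list[[i]]
    g2 <- igraph::add_edges(g2, as.vector(rbind(rep(virt[i], length(cells)),
                                                cells)),
                            weight = rep(0, length(cells)))
  }
  list(graph = g2, virt = virt)
}

#' Cumulative cost distance from a source patch
#'
#' Per-cell minimal accumulated traversal cost from any source cell, under
#' 8-neighbour moves costing step length times mean resistance.
#'
#' @param resistance resistance [eco_raster].
#' @param source integer vector of source cell indices (column-major), or a
#'   `patch_set` plus `id`.
#' @param id patch id when `source` is a `patch_set`.
#' @param graph optional prebuilt [cost_graph()] to reuse.
#' @return an [eco_raster] of cumulative costs (kind `"cost_distance"`).
#' @export
cost_distance <- function(resistance, source, id = NULL, graph = NULL) {
  if (inherits(source, "patch_set")) {
    stopifnot(!is.null(id))
    source <- source$cells[[id]]
  }
  source <- as.integer(source)
  cg <- graph %||% cost_graph(resistance)
  if (any(source < 1 | source > cg$ncell)) stop("source cells outside raster")
  gp <- graph_with_patches(cg, list(source))
  d <- igraph::distances(gp$graph, v = gp$virt, to = seq_len(cg$ncell),
                         algorithm = "dijkstra")
  eco_raster(matrix(as.numeric(d), cg$nr, cg$nc),
             cell_size = resistance$cell_size, origin = resistance$origin,
             year = resistance$year, kind = "cost_distance")
}

# Geometric length (metres) of a path of cell indices.
path_length_m <- function(path, nr, h) {
  if (length(path) < 2) return(0)
  r <- ((path - 1L) %% nr) + 1L
  c <- ((path - 1L) %/% nr) + 1L
  steps <- ifelse(abs(diff(r)) + abs(diff(c)) == 2, h * sqrt(2), h)
  sum(steps)
}

#' Least-cost corridor between two source patches
#'
#' @param resistance resistance [eco_raster].
#' @param a,b integer cell-index vectors of the two patches (or a
#'   `patch_set` with `ids = c(i, j)`).
#' @param ids pair of patch ids when `a` is a `patch_set`.
#' @param graph optional prebuilt [cost_graph()].
#' @return a `corridor` (list with `i`, `j`, `path`, `cwd`, `length_m`,
#'   `cwd_lcpl`), or `NULL` when the patches are mutually unreachable.
#' @export
least_cost_path <- function(resistance, a, b = NULL, ids = NULL, graph = NULL) {
  if (inherits(a, "patch_set")) {
    stopifnot(length(ids) == 2)
    b <- a$cells[[ids[2]]]; a <- a$cells[[ids[1]]]
  } else ids <- c(1L, 2L)
  if (length(intersect(a, b)) > 0 || identical(sort(a), sort(b)))
    stop("the two patches must be distinct and disjoint")
  cg <- graph %||% cost_graph(resistance)
  gp <- graph_with_patches(cg, list(a, b))
  sp <- igraph::shortest_paths(gp$graph, from = gp$virt[1], to = gp$virt[2],
                               output = "vpath")
  vp <- as.integer(sp$vpath[[1]])
  vp <- vp[vp <= cg$ncell]
  if (length(vp) == 0) return(NULL)
  cwd <- igraph::distances(gp$graph, v = gp$virt[1], to = gp$virt[2])[1, 1]
  len <- path_length_m(vp, cg$nr, cg$cell_size)
  new_corridor(ids[1], ids[2], vp, cwd, len)
}

new_corridor <- function(i, j, path, cwd, length_m) {
  structure(list(i = i, j = j, path = path, cwd = cwd, length_m = length_m,
                 cwd_lcpl = if (length_m > 0) cwd / length_m else NA_real_),
            class = "corridor")
}

#' All-pairs least-cost distances, paths and cost rasters for a patch set
#'
#' One Dijkstra sweep per patch (through a zero-cost virtual vertex wired to
#' all patch cells, so distances are boundary-to-boundary). Heavy stages of
#' the pipeline reuse this across dispersal scales.
#'
#' @param resistance resistance [eco_raster].
#' @param patches a `patch_set`.
#' @param graph optional prebuilt [cost_graph()].
#' @return list with `D` (n x n least-cost distance matrix), `cost`
#'   (n x ncell matrix of per-patch cumulative-cost rasters), `paths`
#'   (`paths[[i]][[j]]`, i < j, cell-index vectors) and the `cost_graph`.
#' @export
pairwise_cost_paths <- function(resistance, patches, graph = NULL) {
  stopifnot(inherits(patches, "patch_set"))
  cg <- graph %||% cost_graph(resistance)
  n <- nrow(patches$patches)
  D <- matrix(0, n, n)
  cost <- matrix(NA_real_, n, cg$ncell)
  paths <- rep(list(list()), n)
  if (n == 0) return(list(D = D, cost = cost, paths = paths, graph = cg))
  gp <- graph_with_patches(cg, patches$cells)
  dall <- igraph::distances(gp$graph, v = gp$virt,
                            to = c(seq_len(cg$ncell), gp$virt),
                            algorithm = "dijkstra")
  cost <- dall[, seq_len(cg$ncell), drop = FALSE]
  D <- dall[, cg$ncell + seq_len(n), drop = FALSE]
  dimnames(D) <- NULL
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      js <- (i + 1):n
      reach <- js[is.finite(D[i, js])]
      if (length(reach) == 0) next
      sp <- igraph::shortest_paths(gp$graph, from = gp$virt[i],
                                   to = gp$virt[reach], output = "vpath")
      for (k in seq_along(reach)) {
        vp <- as.integer(sp$vpath[[k]])
        paths[[i]][[as.character(reach[k])]] <- vp[vp <= cg$ncell]
      }
    }
  }
  list(D = D, cost = cost, paths = paths, graph = cg)
}

#' Corridor quality: relative resistance and corridor width
#'
#' `cwd_lcpl` is the cumulative cost divided by the geometric path length
#' (1 on a uniform unit-resistance surface; larger values mean a worse
#' corridor). The corridor band collects every cell whose summed cost
#' distances to the two endpoint patches stay within `band_cost_budget` of
#' the optimum; the width is the band area divided by the path length.
#'
#' @param corridor a `corridor`.
#' @param cost_a,cost_b cumulative-cost rasters (matrices or [eco_raster]s)
#'   from the two endpoint patches.
#' @param cell_size cell edge length in metres.
#' @param band_cost_budget extra cost allowed in the band; default 10% of the
#'   corridor's `cwd`.
#' @return the corridor with `width_m` and `band_cells` filled in.
#' @export
corridor_quality <- function(corridor, cost_a, cost_b, cell_size = 30,
                             band_cost_budget = NULL) {
  stopifnot(inherits(corridor, "corridor"))
  if (length(corridor$path) < 2 || corridor$length_m <= 0)
    stop("zero-length corridor path")
  if (inherits(cost_a, "eco_raster")) cost_a <- cost_a$grid
  if (inherits(cost_b, "eco_raster")) cost_b <- cost_b$grid
  budget <- band_cost_budget %||% (0.1 * corridor$cwd)
  band <- which(cost_a + cost_b <= corridor$cwd + budget)
  corridor$width_m <- length(band) * cell_size^2 / corridor$length_m
  corridor$band_cells <- band
  corridor
}

#' Build the ecological network for one dispersal scale
#'
#' Candidate corridors are all unordered patch pairs. A pair is kept when
#' (i) its least-cost path does not cross any third source patch (corridors
#' across intermediate sources are ignored) and (ii) its least-cost distance
#' does not exceed the scale's dispersal threshold, taken as
#' `max_dispersal_km * 1000 * r_ref` cost units — the cost of covering the
#' maximum dispersal distance over ideal habitat of resistance `r_ref`.
#'
#' @param patches a `patch_set` (>= 1 patch).
#' @param resistance resistance [eco_raster].
#' @param scale a [dispersal_scale()].
#' @param pairwise optional precomputed [pairwise_cost_paths()] result.
#' @param graph optional prebuilt [cost_graph()].
#' @param r_ref reference resistance converting the dispersal distance into
#'   cost units (default 1).
#' @param band_frac corridor-band budget as a fraction of each corridor's
#'   cwd (default 0.1); used for the width metric.
#' @return an `eco_network`: list with `patches`, `edges` (data.frame `i`,
#'   `j`, `lcd`, `cwd`, `length_m`, `cwd_lcpl`, `width_m`), `paths`, `lcd`
#'   (full pairwise matrix), `V`, `L`, `scale`, `year`,
#'   `landscape_area_ha`.
#' @export
build_network <- function(patches, resistance, scale, pairwise = NULL,
                          graph = NULL, r_ref = 1, band_frac = 0.1) {
  stopifnot(inherits(patches, "patch_set"))
  n <- nrow(patches$patches)
  if (n < 1) stop("need at least one source patch")
  pw <- pairwise %||% pairwise_cost_paths(resistance, patches, graph = graph)
  nr <- patches$shape[1]; h <- patches$cell_size
  ncell <- prod(patches$shape)
  threshold <- scale$max_dispersal_km * 1000 * r_ref
  patch_of <- integer(ncell)
  for (i in seq_len(n)) patch_of[patches$cells[[i]]] <- i
  rows <- list()
  paths_kept <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      lcd <- pw$D[i, j]
      if (!is.finite(lcd) || lcd > threshold) next
      vp <- pw$paths[[i]][[as.character(j)]]
      if (is.null(vp) || length(vp) < 2) next
      hit <- patch_of[vp]
      if (any(hit != 0 & hit != i & hit != j)) next  # crosses a third source
      corr <- new_corridor(i, j, vp, lcd, path_length_m(vp, nr, h))
      corr <- corridor_quality(corr, pw$cost[i, ], pw$cost[j, ],
                               cell_size = h,
                               band_cost_budget = band_frac * lcd)
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, lcd = lcd, cwd = corr$cwd, length_m = corr$length_m,
        cwd_lcpl = corr$cwd_lcpl, width_m = corr$width_m)
      paths_kept[[paste(i, j)]] <- vp
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(i = integer(0), j = integer(0), lcd = numeric(0),
               cwd = numeric(0), length_m = numeric(0), cwd_lcpl = numeric(0),
               width_m = numeric(0))
  structure(
    list(patches = patches, edges = edges, paths = paths_kept, lcd = pw$D,
         V = n, L = nrow(edges), scale = scale, year = patches$year,
         landscape_area_ha = ncell * cell_area_ha(h), cell_size = h),
    class = "eco_network"
  )
}

#' @export
print.eco_network <- function(x, ...) {
  cat(sprintf("<eco_network> scale %s, year %s: V = %d, L = %d\n",
              if (!is.null(x$scale$name)) x$scale$name else "-",
              ifelse(is.na(x$year), "-", x$year), x$V, x$L))
  invisible(x)
}

#' Assemble an abstract ecological network from node and edge tables
#'
#' For analyses that start from an existing patch graph rather than rasters
#' (and for oracle-style testing): nodes carry the patch attribute `a`,
#' edges the least-cost distance `lcd`.
#'
#' @param nodes data.frame with `id` and `a` (patch attribute, e.g. area in
#'   hectares); `area_ha` taken equal to `a` unless supplied.
#' @param edges data.frame with `i`, `j`, `lcd`.
#' @param landscape_area_ha total landscape area normalising PC.
#' @param scale,year optional labels.
#' @return an `eco_network` without raster-derived fields.
#' @export
make_network <- function(nodes, edges, landscape_area_ha,
                         scale = NULL, year = NA) {
  stopifnot(all(c("id", "a") %in% names(nodes)))
  if (nrow(edges) > 0) stopifnot(all(c("i", "j", "lcd") %in% names(edges)))
  if (is.null(nodes$area_ha)) nodes$area_ha <- nodes$a
  n <- nrow(nodes)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (k in seq_len(nrow(edges))) {
    i <- match(edges$i[k], nodes$id); j <- match(edges$j[k], nodes$id)
    D[i, j] <- D[j, i] <- min(D[i, j], edges$lcd[k])
  }
  structure(
    list(patches = list(patches = nodes), edges = edges, paths = list(),
         lcd = D, V = n, L = nrow(edges), scale = scale, year = year,
         landscape_area_ha = landscape_area_ha, cell_size = NA),
    class = "eco_network"
  )
}
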