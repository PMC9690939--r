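#' Configure a synthetic multi-temporal landscape scenario
#'
#' Describes a seeded synthetic scene: a correlated-relief DEM plus a series
#' of 7-class land-cover rasters in which natural vegetation forms separated
#' clusters (a main forest block with shrub-linked satellite patches and a
#' grassland fringe), a river occupies a connected low-elevation band, urban
#' cores sit in the landscape border and construction land grows by a fixed
#' fraction of the landscape at every time step.
#'
#' @param shape integer length-2, rows and columns of the grid.
#' @param years strictly increasing integer labels, one raster per year.
#' @param n_forest_blocks number of separated vegetation clusters.
#' @param n_urban_seeds number of initial construction cores.
#' @param urban_growth_per_step fraction of the landscape converted to
#'   construction at each step, in `[0, 1)`.
#' @param relief_amplitude total relief (max - min elevation) in metres.
#' @param seed RNG seed (integer below 2^31 - 2).
#' @param cell_size cell edge length in metres.
#' @param origin x/y of the top-left grid corner.
#' @param block_fractions optional numeric vector, target main-block area of
#'   each cluster as a fraction of its macro-region; defaults to a geometric
#'   ladder spanning the five dispersal-scale habitat thresholds.
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(shape = c(360, 360),
                            years = c(1990, 2000, 2010, 2020),
                            n_forest_blocks = 6,
                            n_urban_seeds = 3,
                            urban_growth_per_step = 0.02,
                            relief_amplitude = 600,
                            seed = 42L,
                            cell_size = 30,
                            origin = c(0, 0),
                            block_fractions = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(is.na(shape)) || any(shape <= 0))
    stop("configuration error: `shape` must be two positive integers")
  if (length(years) < 1 || is.unsorted(years, strictly = TRUE))
    stop("configuration error: `years` must be strictly increasing")
  if (urban_growth_per_step < 0 || urban_growth_per_step >= 1)
    stop("configuration error: `urban_growth_per_step` must be in [0, 1)")
  if (n_forest_blocks < 0 || n_urban_seeds < 0)
    stop("configuration error: counts must be >= 0")
  if (relief_amplitude < 0)
    stop("configuration error: `relief_amplitude` must be >= 0")
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0 || seed > .Machine$integer.max - 2L)
    stop("configuration error: `seed` out of range")
  structure(
    list(shape = shape, years = as.integer(years),
         n_forest_blocks = as.integer(n_forest_blocks),
         n_urban_seeds = as.integer(n_urban_seeds),
         urban_growth_per_step = urban_growth_per_step,
         relief_amplitude = relief_amplitude, seed = seed,
         cell_size = cell_size, origin = as.numeric(origin),
         block_fractions = block_fractions),
    class = "scenario_config"
  )
}

#' Default multi-scale demonstration scenario
#'
#' A 360 x 360 grid of 30 m cells (11,664 ha) over four decades with six
#' vegetation clusters whose main blocks span roughly 1150 to 14 ha, so that
#' the five dispersal scales yield nested, shrinking source sets.
#'
#' @param seed RNG seed.
#' @return a [scenario_config].
#' @export
default_scenario <- function(seed = 42L) scenario_config(seed = seed)

# Default geometric ladder of main-block areas (fractions of a macro-region).
# On the default 360 x 360 grid these give roughly 1150, 1060, 550, 330, 75
# and 14 ha, covering all five minimum-habitat thresholds.
.block_fraction_ladder <- c(0.74, 0.68, 0.35, 0.21, 0.048, 0.009)

#' Generate a correlated synthetic DEM
#'
#' Sums four octaves of bilinearly upsampled white noise (amplitude halving
#' with each frequency doubling) and rescales the field linearly to
#' `[0, relief_amplitude]` metres, giving a smooth surface with realistic
#' spatial autocorrelation. Deterministic for a fixed seed.
#'
#' @param config a [scenario_config].
#' @return an [eco_raster] of kind `"dem"`.
#' @export
generate_dem <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  nr <- config$shape[1]; nc <- config$shape[2]
  if (config$relief_amplitude == 0)
    return(eco_raster(matrix(0, nr, nc), cell_size = config$cell_size,
                      origin = config$origin, kind = "dem"))
  set.seed(config$seed)
  z <- matrix(0, nr, nc)
  for (o in 1:4) {
    cr <- max(2L, ceiling(nr / 2^(7 - o)))
    cc <- max(2L, ceiling(nc / 2^(7 - o)))
    noise <- matrix(stats::rnorm(cr * cc), cr, cc)
    z <- z + resize_bilinear(noise, nr, nc) * 2^(1 - o)
  }
  z <- (z - min(z)) / (max(z) - min(z))
  # right-skewed hypsometry: broad lowland plain, localised uplands
  z <- z^3 * config$relief_amplitude
  eco_raster(z, cell_size = config$cell_size, origin = config$origin,
             kind = "dem")
}

# ---- internal geometry helpers ----------------------------------------------

# 8-neighbourhood of a set of linear (column-major) cell indices.
neighbours8 <- function(cells, nr, nc) {
  r <- ((cells - 1L) %% nr) + 1L
  c <- ((cells - 1L) %/% nr) + 1L
  out <- integer(0)
  for (k in seq_len(8)) {
    r2 <- r + NEIGH8[k, 1]; c2 <- c + NEIGH8[k, 2]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    out <- c(out, (c2[ok] - 1L) * nr + r2[ok])
  }
  unique(out)
}

# Randomised accretion of a connected blob of ~n cells inside `allowed`.
grow_blob <- function(allowed, seed_cell, n, batch_frac = 0.3) {
  nr <- nrow(allowed); nc <- ncol(allowed)
  blob <- logical(nr * nc)
  if (n <= 0 || !allowed[seed_cell]) return(matrix(blob, nr, nc))
  blob[seed_cell] <- TRUE
  frontier <- setdiff(neighbours8(seed_cell, nr, nc), seed_cell)
  frontier <- frontier[allowed[frontier]]
  remaining <- n - 1L
  while (remaining > 0L && length(frontier) > 0L) {
    take <- min(remaining, max(1L, ceiling(length(frontier) * batch_frac)))
    chosen <- frontier[sample.int(length(frontier), take)]
    blob[chosen] <- TRUE
    remaining <- remaining - take
    grown <- neighbours8(chosen, nr, nc)
    grown <- grown[allowed[grown] & !blob[grown]]
    frontier <- unique(c(setdiff(frontier, chosen), grown))
    frontier <- frontier[!blob[frontier]]
  }
  matrix(blob, nr, nc)
}

# Integer line between two cells (Bresenham); returns linear indices.
line_cells <- function(r0, c0, r1, c1, nr) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- sign(r1 - r0); sc <- sign(c1 - c0)
  err <- dc - dr
  r <- r0; c <- c0
  cells <- integer(0)
  repeat {
    cells <- c(cells, (c - 1L) * nr + r)
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc)  { err <- err + dc; r <- r + sr }
  }
  cells
}

# Macro-region layout: split the interior (inside a border band) into an
# nr_m x nc_m grid of regions separated by margins; the horizontal inter-row
# margin hosts the river.
plan_layout <- function(config) {
  nr <- config$shape[1]; nc <- config$shape[2]
  k <- config$n_forest_blocks
  border <- max(3L, round(min(nr, nc) * 0.045))
  col_margin <- 6L; row_margin <- 10L
  nr_m <- max(1L, floor(sqrt(k))); nc_m <- max(1L, ceiling(k / nr_m))
  rows_avail <- nr - 2L * border - (nr_m - 1L) * row_margin
  cols_avail <- nc - 2L * border - (nc_m - 1L) * col_margin
  if (k > 0 && (rows_avail < 4L * nr_m || cols_avail < 4L * nc_m))
    stop("generation error at step layout: grid too small for ",
         k, " vegetation clusters")
  rh <- if (nr_m > 0) floor(rows_avail / nr_m) else 0L
  cw <- if (nc_m > 0) floor(cols_avail / nc_m) else 0L
  regions <- vector("list", k)
  for (i in seq_len(k)) {
    ri <- (i - 1L) %/% nc_m; ci <- (i - 1L) %% nc_m
    r0 <- border + 1L + ri * (rh + row_margin)
    c0 <- border + 1L + ci * (cw + col_margin)
    regions[[i]] <- c(r0 = r0, r1 = r0 + rh - 1L, c0 = c0, c1 = c0 + cw - 1L)
  }
  river_rows <- if (nr_m >= 2) {
    top <- border + rh  # last row of first macro-row band
    (top + 1L):(top + row_margin)
  } else {
    (nr - border + 1L):nr
  }
  list(border = border, regions = regions, river_rows = river_rows,
       nr_m = nr_m, nc_m = nc_m)
}

#' Generate the multi-temporal land-use series
#'
#' Builds the year-0 land cover (farmland matrix, vegetation clusters with
#' grassland fringes and shrub connector strips, a connected river band
#' following low elevation, unused-land patches and urban seed cores), then
#' advances construction land by seeded edge accretion: at every step exactly
#' `round(urban_growth_per_step * ncells)` non-water cells adjacent to
#' existing construction are converted.
#'
#' @param config a [scenario_config].
#' @param dem the paired [eco_raster] DEM (same shape).
#' @return list of land-use [eco_raster]s, one per year.
#' @export
generate_landuse_series <- function(config, dem) {
  stopifnot(inherits(config, "scenario_config"), inherits(dem, "eco_raster"))
  nr <- config$shape[1]; nc <- config$shape[2]
  if (!all(dim(dem$grid) == config$shape))
    stop("DEM shape does not match configuration shape")
  codes <- landuse_codes()
  set.seed(config$seed + 1L)
  lay <- plan_layout(config)
  g <- matrix(codes[["farmland"]], nr, nc)

  # river: connected band of width 3 following minimum elevation within the
  # designated margin rows
  rr <- lay$river_rows
  if (length(rr) >= 3 && nc >= 2) {
    band <- rr[2:(length(rr) - 1)]
    path <- integer(nc)
    path[1] <- band[which.min(dem$grid[band, 1])]
    for (j in 2:nc) {
      cand <- intersect(path[j - 1] + (-1L:1L), band)
      path[j] <- cand[which.min(dem$grid[cand, j])]
    }
    for (j in seq_len(nc)) {
      rows <- pmax(1L, pmin(nr, path[j] + (-1L:1L)))
      g[rows, j] <- codes[["water"]]
    }
  }

  # vegetation clusters
  fr <- config$block_fractions
  if (is.null(fr)) fr <- .block_fraction_ladder
  k <- config$n_forest_blocks
  if (k > 0) fr <- rep_len(fr, k)
  for (i in seq_len(k)) {
    rg <- lay$regions[[i]]
    region <- matrix(FALSE, nr, nc)
    region[rg["r0"]:rg["r1"], rg["c0"]:rg["c1"]] <- TRUE
    region <- region & g == codes[["farmland"]]
    allowed <- region & !dilate_mask(!region, 1)  # keep 1 cell for the fringe
    region_cells <- sum(region)
    target <- min(round(fr[i] * region_cells), floor(sum(allowed) * 0.85))
    ctr <- round(c(mean(c(rg["r0"], rg["r1"])), mean(c(rg["c0"], rg["c1"]))))
    seed_cell <- (ctr[2] - 1L) * nr + ctr[1]
    if (!allowed[seed_cell]) {
      ok <- which(allowed)
      if (length(ok) == 0) next
      seed_cell <- ok[which.min(abs(ok - seed_cell))]
    }
    main <- grow_blob(allowed, seed_cell, target)
    blobs <- main
    sat_frac <- c(0.013, 0.010)
    sats <- list()
    for (s in seq_along(sat_frac)) {
      keepout <- dilate_mask(blobs, 3)
      ring <- dilate_mask(blobs, 12) & !keepout & allowed
      cand <- which(ring)
      if (length(cand) == 0) break
      sseed <- cand[sample.int(length(cand), 1)]
      sallow <- allowed & !keepout
      sat <- grow_blob(sallow, sseed, max(4L, round(sat_frac[s] * region_cells)))
      if (sum(sat) == 0) next
      sats[[length(sats) + 1]] <- sat
      blobs <- blobs | sat
    }
    fringe <- dilate_mask(blobs, 1) & !blobs & region
    g[blobs] <- codes[["forest"]]
    g[fringe] <- codes[["grassland"]]
    # shrub strips from each satellite to the main block
    main_cells <- which(main)
    mr <- ((main_cells - 1L) %% nr) + 1L; mc <- ((main_cells - 1L) %/% nr) + 1L
    for (sat in sats) {
      sc_cells <- which(sat)
      r0 <- round(mean(((sc_cells - 1L) %% nr) + 1L))
      c0 <- round(mean(((sc_cells - 1L) %/% nr) + 1L))
      nearest <- which.min((mr - r0)^2 + (mc - c0)^2)
      strip <- line_cells(r0, c0, mr[nearest], mc[nearest], nr)
      strip <- strip[g[strip] %in% codes[c("farmland", "grassland")]]
      g[strip] <- codes[["shrub"]]
    }
  }

  # unused land: two small patches in remaining farmland, clear of vegetation
  veg <- g == codes[["forest"]] | g == codes[["shrub"]] | g == codes[["grassland"]]
  for (u in 1:2) {
    far <- g == codes[["farmland"]] & !dilate_mask(veg, 3)
    cand <- which(far)
    if (length(cand) == 0) break
    useed <- cand[sample.int(length(cand), 1)]
    blob <- grow_blob(far, useed, min(30L, length(cand)))
    g[blob] <- codes[["unused"]]
  }

  # urban seed cores in the border band
  if (config$n_urban_seeds > 0) {
    border_band <- matrix(FALSE, nr, nc)
    b <- lay$border
    border_band[c(1:b, (nr - b + 1L):nr), ] <- TRUE
    border_band[, c(1:b, (nc - b + 1L):nc)] <- TRUE
    for (s in seq_len(config$n_urban_seeds)) {
      far <- border_band & g == codes[["farmland"]]
      cand <- which(far)
      if (length(cand) == 0)
        stop("generation error at step urban-seeds: no farmland left in border")
      useed <- cand[sample.int(length(cand), 1)]
      blob <- grow_blob(far, useed, min(40L, length(cand)))
      g[blob] <- codes[["construction"]]
    }
  }

  out <- vector("list", length(config$years))
  out[[1]] <- eco_raster(g, cell_size = config$cell_size,
                         origin = config$origin, year = config$years[1],
                         kind = "landuse")
  n_new <- round(config$urban_growth_per_step * nr * nc)
  if (length(config$years) > 1) {
    for (t in 2:length(config$years)) {
      g <- grow_urban(g, n_new, codes,
                      step = paste(config$years[t - 1], "->", config$years[t]))
      out[[t]] <- eco_raster(g, cell_size = config$cell_size,
                             origin = config$origin, year = config$years[t],
                             kind = "landuse")
    }
  }
  out
}

# Accrete exactly n_new construction cells onto the existing urban frontier.
grow_urban <- function(g, n_new, codes, step) {
  nr <- nrow(g); nc <- ncol(g)
  remaining <- n_new
  while (remaining > 0L) {
    urban <- g == codes[["construction"]]
    frontier_mask <- dilate_mask(urban, 1) & !urban & g != codes[["water"]]
    frontier <- which(frontier_mask)
    if (length(frontier) == 0L)
      stop("generation error at step ", step,
           ": urban growth frontier exhausted with ", remaining,
           " cells still to convert")
    take <- min(remaining, max(1L, ceiling(length(frontier) * 0.5)))
    chosen <- frontier[sample.int(length(frontier), take)]
    g[chosen] <- codes[["construction"]]
    remaining <- remaining - take
  }
  g
}

#' Generate a full landscape bundle (DEM + land-use series)
#'
#' @param config a [scenario_config].
#' @return a `landscape_bundle`: list with elements `dem`, `landuse` (list of
#'   rasters, one per year) and `config`.
#' @export
generate_scenario <- function(config) {
  dem <- generate_dem(config)
  lu <- generate_landuse_series(config, dem)
  structure(list(dem = dem, landuse = lu, config = config),
            class = "landscape_bundle")
}
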