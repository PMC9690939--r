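#' Default resistance factor tables
#'
#' The four movement-resistance factors with their class assignments and
#' weights (weights 0.32 / 0.27 / 0.22 / 0.19 sum to 1): land-use type
#' (construction 1000, water 900, unused 600, farmland 500, grassland 100,
#' shrub 1, forest 1), distance to construction land in metres (<=200: 900,
#' 200-500: 700, 500-1000: 500, 1000-2000: 300, >2000: 1), slope in degrees
#' (0-15: 1, 15-30: 200, 30-45: 400, >45: 800) and elevation in metres
#' (<=100: 1, 100-200: 200, 200-400: 400, >400: 600).
#'
#' Numeric class intervals are closed on their upper bound, so a value
#' exactly on a printed break (e.g. slope 15) falls in the lower class.
#'
#' @return named list of four `factor_table` objects, each a list with
#'   `factor`, `weight` and `classes` (data.frame `lower`, `upper`, `value`
#'   for interval factors; `code`, `value` for the categorical land-use
#'   factor).
#' @export
default_factor_tables <- function() {
  codes <- landuse_codes()
  lu <- data.frame(
    code = codes[c("construction", "water", "unused", "farmland",
                   "grassland", "shrub", "forest")],
    value = c(1000, 900, 600, 500, 100, 1, 1)
  )
  list(
    land_use = factor_table("land_use", 0.32, lu),
    dist_construction = factor_table(
      "dist_construction", 0.27,
      data.frame(lower = c(-Inf, 200, 500, 1000, 2000),
                 upper = c(200, 500, 1000, 2000, Inf),
                 value = c(900, 700, 500, 300, 1))),
    slope = factor_table(
      "slope", 0.22,
      data.frame(lower = c(-Inf, 15, 30, 45), upper = c(15, 30, 45, Inf),
                 value = c(1, 200, 400, 800))),
    elevation = factor_table(
      "elevation", 0.19,
      data.frame(lower = c(-Inf, 100, 200, 400), upper = c(100, 200, 400, Inf),
                 value = c(1, 200, 400, 600)))
  )
}

#' Build a resistance factor table
#'
#' @param factor one of `"land_use"`, `"slope"`, `"elevation"`,
#'   `"dist_construction"`.
#' @param weight the factor's weight in the comprehensive surface.
#' @param classes data.frame of classes: either `code`/`value` (categorical)
#'   or `lower`/`upper`/`value` (intervals `(lower, upper]`, exhaustive and
#'   non-overlapping).
#' @return a `factor_table`.
#' @export
factor_table <- function(factor, weight, classes) {
  if (!all(classes$value >= 1 & classes$value <= 1000))
    stop("resistance values must lie in [1, 1000]")
  if (!is.null(classes$lower)) {
    o <- order(classes$upper)
    classes <- classes[o, , drop = FALSE]
    if (any(classes$lower[-1] != classes$upper[-nrow(classes)]))
      stop("interval classes must tile the domain without overlap")
  }
  structure(list(factor = factor, weight = weight, classes = classes),
            class = "factor_table")
}

#' Slope in degrees from a DEM
#'
#' Central-difference gradient over the cell size (one-sided differences on
#' the grid border), slope = atan(sqrt((dz/dx)^2 + (dz/dy)^2)) in degrees.
#'
#' @param dem an [eco_raster] DEM with at least 2 rows and 2 columns.
#' @return an [eco_raster] of kind `"slope"` with values in `[0, 90)`.
#' @export
slope_from_dem <- function(dem) {
  stopifnot(inherits(dem, "eco_raster"))
  z <- dem$grid
  nr <- nrow(z); nc <- ncol(z)
  if (nr < 2) stop("DEM degenerate along rows: need >= 2 rows")
  if (nc < 2) stop("DEM degenerate along columns: need >= 2 columns")
  h <- dem$cell_size
  dzdx <- matrix(0, nr, nc); dzdy <- matrix(0, nr, nc)
  if (nc >= 3) dzdx[, 2:(nc - 1)] <- (z[, 3:nc] - z[, 1:(nc - 2)]) / (2 * h)
  dzdx[, 1] <- (z[, 2] - z[, 1]) / h
  dzdx[, nc] <- (z[, nc] - z[, nc - 1]) / h
  if (nr >= 3) dzdy[2:(nr - 1), ] <- (z[3:nr, ] - z[1:(nr - 2), ]) / (2 * h)
  dzdy[1, ] <- (z[2, ] - z[1, ]) / h
  dzdy[nr, ] <- (z[nr, ] - z[nr - 1, ]) / h
  slope <- atan(sqrt(dzdx^2 + dzdy^2)) * 180 / pi
  eco_raster(slope, cell_size = dem$cell_size, origin = dem$origin,
             year = dem$year, kind = "slope")
}

#' Euclidean distance to the nearest construction cell
#'
#' Exact Euclidean distance between cell centres, in metres; 0 on
#' construction cells. When the raster holds no construction at all, every
#' cell is `Inf` (which the distance factor table maps to its ">2000 m"
#' class) and attribute `no_construction = TRUE` is set.
#'
#' @param landuse a land-use [eco_raster].
#' @return an [eco_raster] of kind `"dist_construction"`.
#' @export
distance_to_construction <- function(landuse) {
  stopifnot(inherits(landuse, "eco_raster"))
  codes <- landuse_codes()
  urban <- landuse$grid == codes[["construction"]]
  nr <- nrow(urban); nc <- ncol(urban)
  if (!any(urban)) {
    out <- eco_raster(matrix(Inf, nr, nc), cell_size = landuse$cell_size,
                      origin = landuse$origin, year = landuse$year,
                      kind = "dist_construction")
    attr(out, "no_construction") <- TRUE
    return(out)
  }
  if (all(urban)) {
    d <- matrix(0, nr, nc)
  } else {
    # distmap: per foreground pixel, distance to nearest background pixel
    d <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - urban),
                                             metric = "euclidean"))
    d <- matrix(d, nr, nc) * landuse$cell_size
  }
  eco_raster(d, cell_size = landuse$cell_size, origin = landuse$origin,
             year = landuse$year, kind = "dist_construction")
}

#' Reclassify a raster into factor resistance values
#'
#' @param raster an [eco_raster] (land-use codes or a continuous factor).
#' @param table the matching `factor_table`.
#' @return an [eco_raster] of per-cell resistance values.
#' @export
reclassify_factor <- function(raster, table) {
  stopifnot(inherits(raster, "eco_raster"), inherits(table, "factor_table"))
  g <- raster$grid
  cl <- table$classes
  if (!is.null(cl$code)) {
    i <- match(g, cl$code)
  } else {
    # intervals (lower, upper]; findInterval on the upper bounds
    i <- findInterval(g, cl$upper, left.open = TRUE) + 1L
    i[g > cl$upper[nrow(cl)]] <- NA
  }
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop(sprintf(
      "factor %s: value %s at cell (%d, %d) is not covered by any class",
      table$factor, format(g[bad]), ((bad - 1) %% nrow(g)) + 1,
      ((bad - 1) %/% nrow(g)) + 1))
  }
  out <- matrix(cl$value[i], nrow(g), ncol(g))
  eco_raster(out, cell_size = raster$cell_size, origin = raster$origin,
             year = raster$year, kind = paste0("R_", table$factor))
}

#' Combine the four factor rasters into the comprehensive resistance surface
#'
#' Weighted overlay: the per-cell resistance is the sum of each factor's
#' reclassified value times its weight (0.32 land use + 0.27 distance to
#' construction + 0.22 slope + 0.19 elevation with the default tables).
#'
#' @param factors named list of the four reclassified [eco_raster]s
#'   (`land_use`, `dist_construction`, `slope`, `elevation`).
#' @param tables the factor tables providing the weights (default tables if
#'   omitted).
#' @return an [eco_raster] of kind `"resistance"`, with the four factor grids
#'   attached as attribute `provenance`.
#' @export
combine_resistance <- function(factors, tables = default_factor_tables()) {
  need <- names(tables)
  if (!all(need %in% names(factors)))
    stop("`factors` must contain: ", paste(need, collapse = ", "))
  dims <- lapply(factors[need], function(f) dim(f$grid))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("factor raster shapes differ: ",
         paste(vapply(dims, paste, character(1), collapse = "x"),
               collapse = " vs "))
  w <- vapply(tables, function(t) t$weight, numeric(1))
  acc <- 0
  for (nm in need) acc <- acc + factors[[nm]]$grid * w[[nm]]
  ref <- factors[[need[1]]]
  out <- eco_raster(acc, cell_size = ref$cell_size, origin = ref$origin,
                    year = ref$year, kind = "resistance")
  attr(out, "provenance") <- factors[need]
  out
}

#' Build the comprehensive resistance surface for one year
#'
#' Convenience wrapper: derives slope from the DEM, the distance transform
#' from the land use, reclassifies all four factors and combines them.
#'
#' @param landuse land-use [eco_raster].
#' @param dem matching DEM [eco_raster].
#' @param tables factor tables (defaults to [default_factor_tables()]).
#' @return resistance [eco_raster].
#' @export
resistance_surface <- function(landuse, dem, tables = default_factor_tables()) {
  if (!all(dim(landuse$grid) == dim(dem$grid)))
    stop("land-use and DEM shapes differ")
  factors <- list(
    land_use = reclassify_factor(landuse, tables$land_use),
    dist_construction = reclassify_factor(distance_to_construction(landuse),
                                          tables$dist_construction),
    slope = reclassify_factor(slope_from_dem(dem), tables$slope),
    elevation = reclassify_factor(dem, tables$elevation)
  )
  combine_resistance(factors, tables)
}
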