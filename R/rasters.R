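#' Raster container for landscape layers
#'
#' A minimal in-memory raster: a numeric or integer matrix plus the grid
#' metadata every module shares. Row 1 is the northernmost row; the centre of
#' cell `(r, c)` sits at `(origin[1] + (c - 0.5) * cell_size,
#' origin[2] - (r - 0.5) * cell_size)`, with `origin` the top-left corner of
#' the top-left cell.
#'
#' @param grid matrix of cell values (land-cover codes, metres, resistance...).
#' @param cell_size cell edge length in metres (default 30).
#' @param origin numeric length-2, x/y of the top-left corner.
#' @param year integer time label, or `NA` for layers without one.
#' @param kind free-text layer kind, e.g. `"landuse"`, `"dem"`, `"resistance"`.
#' @return an object of class `eco_raster`.
#' @export
eco_raster <- function(grid, cell_size = 30, origin = c(0, 0), year = NA_integer_,
                       kind = "layer") {
  if (!is.matrix(grid) || nrow(grid) < 1 || ncol(grid) < 1)
    stop("`grid` must be a non-empty matrix")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("`cell_size` must be a single positive number")
  structure(
    list(grid = grid, cell_size = cell_size, origin = as.numeric(origin),
         year = year, kind = kind),
    class = "eco_raster"
  )
}

#' @export
print.eco_raster <- function(x, ...) {
  cat(sprintf("<eco_raster %s> %d x %d cells, %g m, year %s\n",
              x$kind, nrow(x$grid), ncol(x$grid), x$cell_size,
              ifelse(is.na(x$year), "-", x$year)))
  invisible(x)
}

#' @export
dim.eco_raster <- function(x) dim(x$grid)

#' Land-cover category codes
#'
#' The seven land-cover categories and their integer codes as stored in a
#' land-use raster. Natural vegetation (forest, shrub, grassland) is the MSPA
#' foreground.
#'
#' @return named integer vector.
#' @export
landuse_codes <- function() {
  c(construction = 1L, water = 2L, unused = 3L, farmland = 4L,
    grassland = 5L, shrub = 6L, forest = 7L)
}

#' Cell area in hectares
#' @param cell_size cell edge length in metres.
#' @return hectares covered by one cell (0.09 ha for 30 m cells).
#' @export
cell_area_ha <- function(cell_size) cell_size^2 / 1e4

# ---- plain-text raster I/O (ESRI ASCII grid) --------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text raster interchange: a six-line header (ncols, nrows, xllcorner,
#' yllcorner, cellsize, NODATA_value) followed by rows of values, north first.
#'
#' @param raster an [eco_raster].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @export
write_asc <- function(raster, path, nodata = -9999) {
  stopifnot(inherits(raster, "eco_raster"))
  g <- raster$grid
  yll <- raster$origin[2] - nrow(g) * raster$cell_size
  hdr <- c(
    sprintf("ncols %d", ncol(g)),
    sprintf("nrows %d", nrow(g)),
    sprintf("xllcorner %.10g", raster$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", raster$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  g[is.na(g)] <- nodata
  rows <- apply(g, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_asc()] or any GIS.
#' @param year,kind metadata attached to the returned raster.
#' @return an [eco_raster].
#' @export
read_asc <- function(path, year = NA_integer_, kind = "layer") {
  lines <- readLines(path)
  hdr <- lines[1:6]
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  vals <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  ncols <- as.integer(vals[["ncols"]]); nrows <- as.integer(vals[["nrows"]])
  cellsize <- vals[["cellsize"]]
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nrows * ncols)
    stop("ASCII grid body does not match header dimensions")
  g <- matrix(body, nrow = nrows, ncol = ncols, byrow = TRUE)
  g[g == vals[["nodata_value"]]] <- NA
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + nrows * cellsize)
  eco_raster(g, cell_size = cellsize, origin = origin, year = year, kind = kind)
}

# ---- shared grid helpers ----------------------------------------------------

# Shift a matrix by (dr, dc), padding with `fill`.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

NEIGH8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
NEIGH4 <- cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))

# Binary erosion by a (2w+1)-square structuring element (Chebyshev ball).
erode_mask <- function(mask, w = 1L) {
  m <- mask
  storage.mode(m) <- "logical"
  for (i in seq_len(w)) {
    acc <- m
    for (k in seq_len(8)) {
      acc <- acc & shift_mat(m, NEIGH8[k, 1], NEIGH8[k, 2], fill = FALSE)
    }
    m <- acc
  }
  m
}

# Binary dilation by a (2w+1)-square structuring element.
dilate_mask <- function(mask, w = 1L) {
  m <- mask
  storage.mode(m) <- "logical"
  for (i in seq_len(w)) {
    acc <- m
    for (k in seq_len(8)) {
      acc <- acc | shift_mat(m, NEIGH8[k, 1], NEIGH8[k, 2], fill = FALSE)
    }
    m <- acc
  }
  m
}

# Label connected components of a logical matrix. Returns an integer matrix
# (0 = background); labels are ordered by each component's smallest linear
# (column-major) cell index, so labelling is deterministic.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  cells <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(cells) == 0) return(out)
  offs <- if (connectivity == 8) {
    cbind(dr = c(0, 1, 1, 1), dc = c(1, -1, 0, 1))
  } else {
    cbind(dr = c(0, 1), dc = c(1, 0))
  }
  r <- ((cells - 1) %% nr) + 1
  c <- ((cells - 1) %/% nr) + 1
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r2 <- r + offs[k, 1]; c2 <- c + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    idx2 <- (c2[ok] - 1) * nr + r2[ok]
    keep <- mask[idx2]
    from <- c(from, cells[ok][keep]); to <- c(to, idx2[keep])
  }
  vid <- match(cells, cells)  # identity, vertices 1..n in cell order
  g <- igraph::make_empty_graph(n = length(cells), directed = FALSE)
  if (length(from) > 0) {
    e <- rbind(match(from, cells), match(to, cells))
    g <- igraph::add_edges(g, as.vector(e))
  }
  comp <- igraph::components(g)$membership
  # relabel by first occurrence in cell (linear-index) order
  lab <- match(comp, unique(comp))
  out[cells] <- lab
  out
}

# Bilinear upsampling of a matrix to (nr, nc); used by the terrain generator.
resize_bilinear <- function(m, nr, nc) {
  snr <- nrow(m); snc <- ncol(m)
  # map target cell centres onto source cell-centre coordinates
  sr <- pmin(pmax((seq_len(nr) - 0.5) / nr * (snr - 1) + 1, 1), snr)
  sc <- pmin(pmax((seq_len(nc) - 0.5) / nc * (snc - 1) + 1, 1), snc)
  r0 <- pmin(floor(sr), snr - 1); c0 <- pmin(floor(sc), snc - 1)
  fr <- sr - r0; fc <- sc - c0
  m00 <- m[r0, c0, drop = FALSE]; m10 <- m[r0 + 1, c0, drop = FALSE]
  m01 <- m[r0, c0 + 1, drop = FALSE]; m11 <- m[r0 + 1, c0 + 1, drop = FALSE]
  FR <- matrix(fr, nr, nc); FC <- matrix(fc, nr, nc, byrow = TRUE)
  m00 * (1 - FR) * (1 - FC) + m10 * FR * (1 - FC) +
    m01 * (1 - FR) * FC + m11 * FR * FC
}
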