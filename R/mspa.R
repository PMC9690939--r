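#' The five species dispersal scales
#'
#' Paired minimum habitat area and maximum dispersal distance for the five
#' terrestrial-mammal dispersal groups: small (10 ha / 3 km), meso
#' (60 ha / 10 km), large (300 ha / 30 km), extra-large (500 ha / 60 km) and
#' ultra-large (1000 ha / 100 km).
#'
#' @return data.frame with columns `name`, `max_dispersal_km`,
#'   `min_habitat_ha`.
#' @export
dispersal_scales <- function() {
  data.frame(
    name = c("small", "meso", "large", "extra_large", "ultra_large"),
    max_dispersal_km = c(3, 10, 30, 60, 100),
    min_habitat_ha = c(10, 60, 300, 500, 1000),
    stringsAsFactors = FALSE
  )
}

#' Look up one dispersal scale by name
#' @param name one of `"small"`, `"meso"`, `"large"`, `"extra_large"`,
#'   `"ultra_large"`.
#' @return a one-row list with `name`, `max_dispersal_km`, `min_habitat_ha`.
#' @export
dispersal_scale <- function(name) {
  tab <- dispersal_scales()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown dispersal scale: ", name)
  structure(as.list(tab[i, ]), class = "dispersal_scale")
}

#' MSPA class codes
#'
#' Integer codes used in classified MSPA grids: 0 background, 1 core,
#' 2 islet, 3 perforation, 4 edge, 5 loop, 6 bridge, 7 branch.
#' @return named integer vector.
#' @export
mspa_classes <- function() {
  c(background = 0L, core = 1L, islet = 2L, perforation = 3L, edge = 4L,
    loop = 5L, bridge = 6L, branch = 7L)
}

#' Extract the natural-vegetation foreground
#'
#' Foreground cells are those whose land-cover code is forest, shrub or
#' grassland; everything else is background.
#'
#' @param landuse a land-use [eco_raster].
#' @return logical matrix (attributes `cell_size` and `year` carried along).
#' @export
binarize_foreground <- function(landuse) {
  stopifnot(inherits(landuse, "eco_raster"))
  codes <- landuse_codes()
  if (!all(landuse$grid %in% codes))
    stop("land-use raster contains codes outside the 7 categories")
  mask <- landuse$grid %in% codes[c("forest", "shrub", "grassland")]
  mask <- matrix(mask, nrow(landuse$grid), ncol(landuse$grid))
  attr(mask, "cell_size") <- landuse$cell_size
  attr(mask, "year") <- landuse$year
  mask
}

#' Morphological spatial pattern analysis of a binary foreground
#'
#' Partitions every foreground cell into one of the seven MSPA classes using
#' box (Chebyshev) morphology:
#' core cells survive erosion by `edge_width_cells`; whole foreground
#' components without core are islets; the non-core rind within
#' `edge_width_cells` of core is split into perforation (bordering a hole
#' enclosed by foreground) and edge (bordering the exterior), with
#' perforation taking precedence; the remaining non-core cells of
#' core-bearing components are connectors, subclassed by the core components
#' their geodesic neighbourhood touches: two or more distinct cores make a
#' bridge, re-attachment to a single core at separate contact sites makes a
#' loop, a single contact site makes a branch.
#'
#' Foreground connectivity is 8 by default; holes are detected with the dual
#' 4-connectivity.
#'
#' @param mask logical matrix (from [binarize_foreground()]).
#' @param edge_width_cells positive integer erosion/rind width.
#' @param connectivity foreground connectivity, 4 or 8.
#' @return an object of class `mspa_map`: list with `grid` (integer codes,
#'   see [mspa_classes()]), `edge_width_cells`, `connectivity`, `cell_size`.
#' @export
classify_mspa <- function(mask, edge_width_cells = 1L, connectivity = 8) {
  if (!is.matrix(mask)) stop("`mask` must be a matrix")
  if (edge_width_cells < 1) stop("`edge_width_cells` must be >= 1")
  stopifnot(connectivity %in% c(4, 8))
  cls <- mspa_classes()
  nr <- nrow(mask); nc <- ncol(mask)
  m <- matrix(as.logical(mask), nr, nc)
  out <- matrix(cls[["background"]], nr, nc)
  if (!any(m)) {
    return(new_mspa_map(out, edge_width_cells, connectivity, mask))
  }
  w <- as.integer(edge_width_cells)
  core <- erode_mask(m, w)
  fg_lab <- label_components(m, connectivity)
  core_comps <- unique(fg_lab[core])
  core_bearing <- fg_lab > 0 & fg_lab %in% core_comps
  islet <- m & !core_bearing
  # holes: background components (4-connectivity) not touching the border
  bg_lab <- label_components(!m, 4)
  border_labs <- unique(c(bg_lab[1, ], bg_lab[nr, ], bg_lab[, 1], bg_lab[, nc]))
  hole <- bg_lab > 0 & !(bg_lab %in% border_labs)
  rind <- dilate_mask(core, w) & m & !core & core_bearing
  perforation <- rind & dilate_mask(hole, w)
  edge <- rind & !perforation
  connector <- m & core_bearing & !core & !rind
  out[core] <- cls[["core"]]
  out[islet] <- cls[["islet"]]
  out[perforation] <- cls[["perforation"]]
  out[edge] <- cls[["edge"]]
  if (any(connector)) {
    core_lab <- label_components(core, connectivity)
    thick <- core | rind
    thick_lab <- label_components(thick, connectivity)
    # map each thick region to the core components it contains
    thick_to_core <- split(core_lab[core], thick_lab[core])
    conn_lab <- label_components(connector, connectivity)
    for (cc in seq_len(max(conn_lab))) {
      cells <- which(conn_lab == cc)
      nb <- neighbours8(cells, nr, nc)
      touch_thick <- nb[thick[nb]]
      tregs <- unique(thick_lab[touch_thick])
      cores_touched <- unique(unlist(thick_to_core[as.character(tregs)]))
      if (length(cores_touched) >= 2) {
        out[cells] <- cls[["bridge"]]
      } else {
        # contact sites: thick cells adjacent to this connector, clustered
        site_mask <- matrix(FALSE, nr, nc)
        site_mask[touch_thick] <- TRUE
        n_sites <- max(label_components(site_mask, 8))
        out[cells] <- if (n_sites >= 2) cls[["loop"]] else cls[["branch"]]
      }
    }
  }
  new_mspa_map(out, edge_width_cells, connectivity, mask)
}

new_mspa_map <- function(grid, edge_width_cells, connectivity, mask) {
  structure(
    list(grid = grid, edge_width_cells = as.integer(edge_width_cells),
         connectivity = connectivity,
         cell_size = attr(mask, "cell_size") %||% 30,
         year = attr(mask, "year") %||% NA_integer_),
    class = "mspa_map"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mspa_map <- function(x, ...) {
  cat(sprintf("<mspa_map> %d x %d, edge width %d cell(s)\n",
              nrow(x$grid), ncol(x$grid), x$edge_width_cells))
  print(class_proportions(x))
  invisible(x)
}

#' Per-class share of the foreground
#'
#' @param mspa an `mspa_map`.
#' @return data.frame with columns `class`, `cells`, `hectares`, `fraction`;
#'   fractions sum to 1 over a non-empty foreground. An empty foreground
#'   yields all-zero fractions and attribute `empty_foreground = TRUE`.
#' @export
class_proportions <- function(mspa) {
  stopifnot(inherits(mspa, "mspa_map"))
  cls <- mspa_classes()
  fg_classes <- cls[names(cls) != "background"]
  counts <- vapply(fg_classes, function(k) sum(mspa$grid == k), integer(1))
  total <- sum(counts)
  out <- data.frame(
    class = names(fg_classes),
    cells = as.integer(counts),
    hectares = counts * cell_area_ha(mspa$cell_size),
    fraction = if (total > 0) counts / total else rep(0, length(counts)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  if (total == 0) attr(out, "empty_foreground") <- TRUE
  out
}

#' Extract ecological source patches for one dispersal scale
#'
#' Connected components of MSPA core cells whose area reaches the scale's
#' minimum habitat area become source patches. Ids are assigned
#' deterministically: descending area, ties broken by the topmost-leftmost
#' cell.
#'
#' @param mspa an `mspa_map`.
#' @param scale a [dispersal_scale()] (or any list with `min_habitat_ha`).
#' @return a `patch_set`: list with `patches` (data.frame `id`, `n_cells`,
#'   `area_ha`, `a` — the patch attribute used by the connectivity indices,
#'   set to the area in hectares), `cells` (list of column-major cell
#'   indices), `shape`, `cell_size`, `year`, `scale_name`.
#' @export
extract_sources <- function(mspa, scale) {
  stopifnot(inherits(mspa, "mspa_map"))
  cls <- mspa_classes()
  core <- mspa$grid == cls[["core"]]
  lab <- label_components(core, mspa$connectivity)
  nr <- nrow(core); nc <- ncol(core)
  ids <- seq_len(max(lab, 0L))
  cells_list <- if (length(ids)) split(which(lab > 0), lab[lab > 0]) else list()
  area <- vapply(cells_list, length, integer(1)) * cell_area_ha(mspa$cell_size)
  keep <- which(area >= scale$min_habitat_ha)
  cells_list <- cells_list[keep]; area <- area[keep]
  if (length(keep)) {
    # row-major rank of each component's topmost-leftmost cell
    first_rm <- vapply(cells_list, function(cells) {
      r <- ((cells - 1L) %% nr) + 1L; c <- ((cells - 1L) %/% nr) + 1L
      min((r - 1L) * nc + c)
    }, numeric(1))
    o <- order(-area, first_rm)
    cells_list <- cells_list[o]; area <- area[o]
  }
  n <- length(cells_list)
  structure(
    list(
      patches = data.frame(id = seq_len(n),
                           n_cells = vapply(cells_list, length, integer(1)),
                           area_ha = as.numeric(area), a = as.numeric(area),
                           row.names = NULL),
      cells = unname(cells_list),
      shape = c(nr, nc), cell_size = mspa$cell_size,
      year = mspa$year, scale_name = if (!is.null(scale$name)) scale$name else NA
    ),
    class = "patch_set"
  )
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d source patch(es), scale %s, year %s\n",
              nrow(x$patches), x$scale_name %||% "-",
              ifelse(is.na(x$year), "-", x$year)))
  invisible(x)
}
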