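# subset a patch_set to the patches flagged in `keep` (order preserved,
# ids renumbered 1..k)
subset_patches <- function(patches, keep) {
  idx <- which(keep)
  out <- patches
  out$patches <- patches$patches[idx, , drop = FALSE]
  out$patches$id <- seq_along(idx)
  rownames(out$patches) <- NULL
  out$cells <- patches$cells[idx]
  out
}

subset_pairwise <- function(pw, keep) {
  idx <- which(keep)
  paths <- rep(list(list()), length(idx))
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      p <- pw$paths[[idx[a]]][[as.character(idx[b])]]
      if (!is.null(p)) paths[[a]][[as.character(b)]] <- p
    }
  }
  list(D = pw$D[idx, idx, drop = FALSE],
       cost = pw$cost[idx, , drop = FALSE],
       paths = paths, graph = pw$graph)
}

#' Run the full multi-scale, multi-year network analysis
#'
#' Pipeline order: MSPA classification of the vegetation foreground,
#' resistance surface, per-scale source extraction and least-cost corridor
#' networks, connectivity indices, ecological-group detection with node
#' importance and core nodes, and group-evolution tracking between
#' consecutive years. Least-cost distances and paths are computed once per
#' year on the union source set (the smallest habitat threshold) and reused
#' across scales, whose source sets are nested.
#'
#' @param x a [scenario_config()] (the landscape is generated) or a
#'   `landscape_bundle` from [generate_scenario()].
#' @param scales character vector of dispersal-scale names to analyse.
#' @param years optional subset of the bundle's years.
#' @param edge_width MSPA edge width in cells.
#' @param p decay anchor probability (default 0.05 at the maximum dispersal
#'   distance).
#' @param r_ref reference resistance converting dispersal distances to cost
#'   units.
#' @param tau relative size-change tolerance for the stability event.
#' @param band_frac corridor-band cost budget as a fraction of cwd.
#' @param out_dir optional directory; when given, CSV reports and a run
#'   manifest are written there.
#' @param write_rasters also write land-use/DEM/resistance ASCII grids to
#'   `out_dir`.
#' @return a `multiscale_run`: list with `results[[year]][[scale]]` (each
#'   holding `patches`, `network`, `report`, `partition`, `importance`,
#'   `cores`), `mspa[[year]]`, `events`, and the summary data.frames
#'   `network_summary`, `group_summary`, `event_summary`.
#' @export
run_multiscale <- function(x, scales = dispersal_scales()$name, years = NULL,
                           edge_width = 1L, p = 0.05, r_ref = 1, tau = 0.2,
                           band_frac = 0.1, out_dir = NULL,
                           write_rasters = FALSE) {
  bundle <- if (inherits(x, "scenario_config")) generate_scenario(x) else x
  if (!inherits(bundle, "landscape_bundle"))
    stop("`x` must be a scenario_config or landscape_bundle")
  if (length(scales) == 0) stop("`scales` must name at least one scale")
  all_years <- vapply(bundle$landuse, function(r) r$year, integer(1))
  years <- years %||% all_years
  if (!all(years %in% all_years))
    stop("year(s) missing from bundle: ",
         paste(setdiff(years, all_years), collapse = ", "))
  sc_tab <- dispersal_scales()
  if (!all(scales %in% sc_tab$name))
    stop("unknown scale(s): ", paste(setdiff(scales, sc_tab$name), collapse = ", "))
  scales <- sc_tab$name[sc_tab$name %in% scales]  # canonical order
  union_scale <- dispersal_scale(scales[which.min(
    sc_tab$min_habitat_ha[match(scales, sc_tab$name)])])

  results <- list(); mspa_maps <- list()
  for (yr in years) {
    lu <- bundle$landuse[[match(yr, all_years)]]
    message(sprintf("[%s] resistance + MSPA", yr))
    resist <- resistance_surface(lu, bundle$dem)
    msp <- classify_mspa(binarize_foreground(lu), edge_width_cells = edge_width)
    mspa_maps[[as.character(yr)]] <- msp
    union_patches <- extract_sources(msp, union_scale)
    message(sprintf("[%s] %d union source(s); least-cost sweep", yr,
                    nrow(union_patches$patches)))
    cg <- cost_graph(resist)
    pw <- pairwise_cost_paths(resist, union_patches, graph = cg)
    per_scale <- list()
    for (sn in scales) {
      sc <- dispersal_scale(sn)
      keep <- union_patches$patches$area_ha >= sc$min_habitat_ha
      patches <- subset_patches(union_patches, keep)
      patches$scale_name <- sn
      if (nrow(patches$patches) == 0) {
        per_scale[[sn]] <- list(patches = patches, network = NULL,
                                report = NULL, partition = NULL,
                                importance = NULL, cores = NULL)
        next
      }
      net <- build_network(patches, resist, sc,
                           pairwise = subset_pairwise(pw, keep),
                           r_ref = r_ref, band_frac = band_frac)
      rep <- connectivity_report(net, p = p, r_ref = r_ref)
      decay <- scale_decay(sc, p = p, r_ref = r_ref)
      wg <- build_weighted_graph(net, decay)
      part <- greedy_modularity(wg)
      imp <- node_importance(rep)
      cores <- core_nodes(wg, stats::setNames(imp$pni, imp$id))
      per_scale[[sn]] <- list(patches = patches, network = net, report = rep,
                              partition = part, importance = imp,
                              cores = cores)
      message(sprintf("[%s] %-12s V=%3d L=%3d groups=%d", yr, sn, net$V,
                      net$L, part$n_groups))
    }
    results[[as.character(yr)]] <- per_scale
  }

  # evolution between consecutive analysed years, per scale
  events <- list()
  if (length(years) >= 2) {
    for (t in seq_len(length(years) - 1)) {
      y0 <- as.character(years[t]); y1 <- as.character(years[t + 1])
      for (sn in scales) {
        r0 <- results[[y0]][[sn]]; r1 <- results[[y1]][[sn]]
        if (is.null(r0$partition) || is.null(r1$partition)) next
        nm <- match_patches(r0$patches, r1$patches)
        rel <- track_evolution(r0$partition, r0$cores, r1$partition, nm)
        ev <- classify_events(rel, r0$partition, r1$partition, nm, tau = tau)
        if (!is.null(ev) && nrow(ev) > 0) {
          ev <- cbind(year_t = years[t], year_t1 = years[t + 1], scale = sn,
                      ev)
          events[[length(events) + 1]] <- ev
        }
      }
    }
  }
  event_summary <- if (length(events)) do.call(rbind, events) else
    data.frame(year_t = integer(0), year_t1 = integer(0),
               scale = character(0), type = character(0),
               groups_t = character(0), groups_t1 = character(0),
               size_t = integer(0), size_t1 = integer(0))

  network_summary <- do.call(rbind, lapply(names(results), function(yr) {
    do.call(rbind, lapply(scales, function(sn) {
      r <- results[[yr]][[sn]]
      if (is.null(r$network)) {
        return(data.frame(scale = sn, year = as.integer(yr), V = 0L, L = 0L,
                          alpha = NA, beta = NA, gamma = NA, pc = NA,
                          cwd_lcpl_mean = NA, width_mean_m = NA,
                          cf_mean = NA, n_groups = 0L, n_core = 0L))
      }
      nl <- r$report$network_level; e <- r$network$edges
      data.frame(
        scale = sn, year = as.integer(yr), V = nl$V, L = nl$L,
        alpha = nl$alpha, beta = nl$beta, gamma = nl$gamma, pc = nl$pc,
        cwd_lcpl_mean = if (nrow(e)) mean(e$cwd_lcpl) else NA,
        width_mean_m = if (nrow(e)) mean(e$width_m) else NA,
        cf_mean = mean(r$report$node_level$cf),
        n_groups = r$partition$n_groups, n_core = sum(r$cores$is_core))
    }))
  }))
  group_summary <- network_summary[, c("scale", "year", "n_groups", "n_core")]

  run <- structure(
    list(results = results, mspa = mspa_maps, events = event_summary,
         network_summary = network_summary, group_summary = group_summary,
         config = if (inherits(x, "scenario_config")) x else bundle$config,
         scales = scales, years = years,
         params = list(edge_width = edge_width, p = p, r_ref = r_ref,
                       tau = tau, band_frac = band_frac)),
    class = "multiscale_run")

  if (!is.null(out_dir)) write_run_reports(run, bundle, out_dir,
                                           write_rasters = write_rasters)
  run
}

#' Write the CSV reports (and optional rasters) of a pipeline run
#'
#' Files: `network_summary.csv` (one row per scale and year),
#' `node_report.csv` (id, area_ha, dpc, bcpc, cf, pni, group_id, is_core),
#' `edge_report.csv` (i, j, lcd, cwd, length_m, cwd_lcpl, width_m),
#' `mspa_proportions.csv`, `events.csv` and `manifest.txt`.
#'
#' @param run a `multiscale_run`.
#' @param bundle the analysed `landscape_bundle` (for raster export).
#' @param out_dir output directory (created if missing).
#' @param write_rasters also export land-use, DEM and MSPA grids as ASCII.
#' @return the output directory, invisibly.
#' @export
write_run_reports <- function(run, bundle = NULL, out_dir,
                              write_rasters = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(run$network_summary, "network_summary.csv")
  nodes <- do.call(rbind, lapply(names(run$results), function(yr) {
    do.call(rbind, lapply(names(run$results[[yr]]), function(sn) {
      r <- run$results[[yr]][[sn]]
      if (is.null(r$report)) return(NULL)
      nl <- r$report$node_level
      cbind(scale = sn, year = as.integer(yr), nl,
            pni = r$importance$pni,
            group_id = unname(r$partition$membership[as.character(nl$id)]),
            is_core = r$cores$is_core)
    }))
  }))
  if (!is.null(nodes)) wcsv(nodes, "node_report.csv")
  edges <- do.call(rbind, lapply(names(run$results), function(yr) {
    do.call(rbind, lapply(names(run$results[[yr]]), function(sn) {
      r <- run$results[[yr]][[sn]]
      if (is.null(r$network) || nrow(r$network$edges) == 0) return(NULL)
      cbind(scale = sn, year = as.integer(yr), r$network$edges)
    }))
  }))
  if (!is.null(edges)) wcsv(edges, "edge_report.csv")
  props <- do.call(rbind, lapply(names(run$mspa), function(yr)
    cbind(year = as.integer(yr), class_proportions(run$mspa[[yr]]))))
  if (!is.null(props)) wcsv(props, "mspa_proportions.csv")
  wcsv(run$events, "events.csv")
  cfg <- run$config
  manifest <- c(
    paste0("package = ecoscapenet ",
           as.character(utils::packageVersion("ecoscapenet"))),
    paste0("generated = synthetic scenario, seed ", cfg$seed),
    paste0("shape = ", paste(cfg$shape, collapse = " x ")),
    paste0("years = ", paste(run$years, collapse = ", ")),
    paste0("scales = ", paste(run$scales, collapse = ", ")),
    paste0("edge_width = ", run$params$edge_width),
    paste0("p = ", run$params$p),
    paste0("r_ref = ", run$params$r_ref),
    paste0("tau = ", run$params$tau),
    paste0("band_frac = ", run$params$band_frac)
  )
  writeLines(manifest, file.path(out_dir, "manifest.txt"))
  if (write_rasters && !is.null(bundle)) {
    write_asc(bundle$dem, file.path(out_dir, "dem.asc"))
    for (lu in bundle$landuse)
      write_asc(lu, file.path(out_dir, sprintf("landuse_%s.asc", lu$year)))
    for (yr in names(run$mspa)) {
      m <- run$mspa[[yr]]
      write_asc(eco_raster(m$grid, cell_size = m$cell_size),
                file.path(out_dir, sprintf("mspa_%s.asc", yr)))
    }
  }
  invisible(out_dir)
}

#' Export a network's corridors as GeoJSON line features
#'
#' One LineString per corridor (cell-centre coordinates in the raster's
#' coordinate system) with properties i, j, lcd, cwd, length_m, cwd_lcpl,
#' width_m.
#'
#' @param network an `eco_network` built from rasters.
#' @param path output file.
#' @param origin,cell_size grid geotransform (defaults from the network).
#' @return the path, invisibly.
#' @export
write_network_geojson <- function(network, path, origin = c(0, 0),
                                  cell_size = network$cell_size) {
  stopifnot(inherits(network, "eco_network"))
  nr <- network$patches$shape[1]
  feats <- lapply(seq_len(nrow(network$edges)), function(k) {
    e <- network$edges[k, ]
    cells <- network$paths[[paste(e$i, e$j)]]
    r <- ((cells - 1L) %% nr) + 1L
    c <- ((cells - 1L) %/% nr) + 1L
    coords <- lapply(seq_along(cells), function(t)
      c(origin[1] + (c[t] - 0.5) * cell_size,
        origin[2] - (r[t] - 0.5) * cell_size))
    list(type = "Feature",
         geometry = list(type = "LineString", coordinates = coords),
         properties = as.list(e))
  })
  json <- jsonlite::toJSON(list(type = "FeatureCollection", features = feats),
                           auto_unbox = TRUE, digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry `area_ha`, edges carry `lcd`; readable by igraph, Gephi, etc.
#'
#' @param network an `eco_network`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_network_graphml <- function(network, path) {
  g <- patch_graph(network)
  g <- igraph::set_vertex_attr(g, "area_ha", value = net_nodes(network)$area_ha)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
print.multiscale_run <- function(x, ...) {
  cat("<multiscale_run>\n")
  print(x$network_summary, row.names = FALSE)
  invisible(x)
}
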