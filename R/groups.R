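#' Weighted patch graph for ecological-group detection
#'
#' Every corridor becomes a weighted edge
#' `E_ij = a_i * a_j * exp(-alpha * d_ij)` with `d_ij` the corridor's
#' least-cost distance, so edges between large, close patches dominate.
#'
#' @param network an `eco_network`.
#' @param decay a [distance_decay()].
#' @return a `weighted_graph`: list with `nodes` (data.frame `id`, `a`),
#'   `edges` (data.frame `i`, `j`, `d`, `weight`) and `m` (total edge
#'   weight).
#' @export
build_weighted_graph <- function(network, decay) {
  nodes <- net_nodes(network)
  e <- network$edges
  if (nrow(e) > 0) {
    ai <- nodes$a[match(e$i, nodes$id)]
    aj <- nodes$a[match(e$j, nodes$id)]
    edges <- data.frame(i = e$i, j = e$j, d = e$lcd,
                        weight = ai * aj * exp(-decay$decay_alpha * e$lcd))
  } else {
    edges <- data.frame(i = integer(0), j = integer(0), d = numeric(0),
                        weight = numeric(0))
  }
  structure(list(nodes = nodes[, c("id", "a")], edges = edges,
                 m = sum(edges$weight)),
            class = "weighted_graph")
}

#' Weighted modularity of a partition
#'
#' `q = sum_C [ w_in(C) / m - (deg(C) / (2m))^2 ]` with `w_in(C)` the total
#' intra-group edge weight, `deg(C)` the summed weighted degree of the
#' group's members and `m` the total edge weight. Dense within-group links
#' and sparse between-group links give large q.
#'
#' @param graph a `weighted_graph`.
#' @param membership vector of group labels, one per node (in `graph$nodes`
#'   order, or named by node id).
#' @return modularity q (`NA` with attribute `undefined` when the graph has
#'   no edge weight).
#' @export
modularity_score <- function(graph, membership) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- nrow(graph$nodes)
  if (length(membership) != n) stop("membership length must equal node count")
  if (!is.null(names(membership)))
    membership <- membership[as.character(graph$nodes$id)]
  if (graph$m <= 0) {
    out <- NA_real_; attr(out, "undefined") <- TRUE
    return(out)
  }
  m <- graph$m
  gi <- membership[match(graph$edges$i, graph$nodes$id)]
  gj <- membership[match(graph$edges$j, graph$nodes$id)]
  w <- graph$edges$weight
  w_in <- tapply(w[gi == gj], gi[gi == gj], sum)
  deg <- stats::setNames(rep(0, length(unique(membership))), unique(membership))
  for (k in seq_along(w)) {
    deg[as.character(gi[k])] <- deg[as.character(gi[k])] + w[k]
    deg[as.character(gj[k])] <- deg[as.character(gj[k])] + w[k]
  }
  q <- 0
  for (cl in names(deg)) {
    wi <- if (cl %in% names(w_in)) w_in[[cl]] else 0
    q <- q + wi / m - (deg[[cl]] / (2 * m))^2
  }
  q
}

#' Greedy agglomerative modularity maximisation
#'
#' Starts from singleton groups and iteratively merges the pair of groups
#' with the best modularity change (largest increase or smallest decrease;
#' ties broken towards the smallest pair of group indices), recording all
#' n..1 levels and returning the level with maximum modularity. With no
#' edges, the singleton partition is returned and q is flagged undefined.
#'
#' @param graph a `weighted_graph`.
#' @return a `group_partition`: list with `membership` (named by node id,
#'   groups numbered by first occurrence), `q`, `n_groups`, `q_trace`.
#' @export
greedy_modularity <- function(graph) {
  stopifnot(inherits(graph, "weighted_graph"))
  n <- nrow(graph$nodes)
  if (n < 1) stop("graph needs at least one node")
  ids <- graph$nodes$id
  singleton <- stats::setNames(seq_len(n), ids)
  if (graph$m <= 0 || n == 1) {
    q <- NA_real_; attr(q, "undefined") <- TRUE
    return(new_group_partition(singleton, q, graph))
  }
  m <- graph$m
  # cluster-level aggregates
  B <- matrix(0, n, n)   # between-cluster weights
  ei <- match(graph$edges$i, ids); ej <- match(graph$edges$j, ids)
  for (k in seq_along(ei)) {
    B[ei[k], ej[k]] <- B[ei[k], ej[k]] + graph$edges$weight[k]
    B[ej[k], ei[k]] <- B[ej[k], ei[k]] + graph$edges$weight[k]
  }
  win <- rep(0, n)
  deg <- rowSums(B)
  active <- rep(TRUE, n)
  member <- seq_len(n)                   # node -> cluster
  q <- sum(win / m) - sum((deg / (2 * m))^2)
  best_q <- q; best_member <- member
  levels_q <- numeric(n); levels_q[1] <- q
  for (step in seq_len(n - 1)) {
    act <- which(active)
    # delta-q for merging every active pair
    dq_edge <- B[act, act, drop = FALSE] / m
    dq_deg <- 2 * outer(deg[act], deg[act]) / (2 * m)^2
    dq <- dq_edge - dq_deg
    diag(dq) <- -Inf
    best <- which(dq == max(dq), arr.ind = TRUE)
    # deterministic: smallest (i, j) cluster-index pair
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    o <- order(act[best[, 1]], act[best[, 2]])
    bi <- act[best[o[1], 1]]; bj <- act[best[o[1], 2]]
    q <- q + dq[best[o[1], 1], best[o[1], 2]]
    # merge bj into bi
    win[bi] <- win[bi] + win[bj] + B[bi, bj]
    B[bi, ] <- B[bi, ] + B[bj, ]
    B[, bi] <- B[, bi] + B[, bj]
    B[bi, bi] <- 0
    B[bj, ] <- 0; B[, bj] <- 0
    deg[bi] <- deg[bi] + deg[bj]
    active[bj] <- FALSE
    member[member == bj] <- bi
    levels_q[step + 1] <- q
    if (q > best_q + 1e-12) { best_q <- q; best_member <- member }
  }
  membership <- stats::setNames(match(best_member, unique(best_member)), ids)
  new_group_partition(membership, best_q, graph, q_trace = levels_q)
}

new_group_partition <- function(membership, q, graph, q_trace = NULL) {
  structure(list(membership = membership, q = q,
                 n_groups = length(unique(membership)), q_trace = q_trace),
            class = "group_partition")
}

#' @export
print.group_partition <- function(x, ...) {
  cat(sprintf("<group_partition> %d group(s), q = %s\n", x$n_groups,
              ifelse(is.na(x$q), "undefined", format(x$q, digits = 4))))
  invisible(x)
}

#' Ecological node importance (PNI)
#'
#' Patch-location importance CPI is the min-max-normalised BCPC; habitat
#' function importance HFI is the min-max-normalised patch area;
#' `PNI = 0.5 CPI + 0.5 HFI`. A degenerate component (all values equal) is
#' set to 0 for every node.
#'
#' @param report a `connectivity_report` (or any list with `node_level`
#'   holding `id`, `area_ha`, `bcpc`).
#' @return data.frame with `id`, `cpi`, `hfi`, `pni`.
#' @export
node_importance <- function(report) {
  nl <- report$node_level
  minmax <- function(x) {
    rng <- range(x)
    if (diff(rng) == 0) rep(0, length(x)) else (x - rng[1]) / diff(rng)
  }
  cpi <- minmax(nl$bcpc)
  hfi <- minmax(nl$area_ha)
  data.frame(id = nl$id, cpi = cpi, hfi = hfi, pni = 0.5 * cpi + 0.5 * hfi)
}

#' Identify core nodes by local weight dominance
#'
#' `Cen(v) = sum over neighbours v_i of (W_v - W_vi)`; a node is core when
#' `Cen(v) > 0`. Weights are the PNI values; neighbours are taken in the
#' whole corridor graph by default (`scope = "group"` restricts them to the
#' node's own group). No further parameters. An isolated node has an empty
#' sum, `Cen = 0`, and is therefore not core.
#'
#' @param graph a `weighted_graph` (or `eco_network`).
#' @param weights named numeric vector of node weights (e.g. `pni`).
#' @param partition optional `group_partition`, required for
#'   `scope = "group"`.
#' @param scope `"graph"` (default) or `"group"`.
#' @return data.frame with `id`, `cen`, `is_core`.
#' @export
core_nodes <- function(graph, weights, partition = NULL,
                       scope = c("graph", "group")) {
  scope <- match.arg(scope)
  if (inherits(graph, "eco_network"))
    graph <- list(nodes = net_nodes(graph), edges = graph$edges)
  ids <- graph$nodes$id
  W <- weights[as.character(ids)]
  if (anyNA(W)) stop("`weights` must be named by node id and cover all nodes")
  cen <- stats::setNames(rep(0, length(ids)), ids)
  e <- graph$edges
  if (nrow(e) > 0) {
    keep <- rep(TRUE, nrow(e))
    if (scope == "group") {
      if (is.null(partition)) stop("scope = \"group\" needs a partition")
      mem <- partition$membership
      keep <- mem[as.character(e$i)] == mem[as.character(e$j)]
    }
    for (k in which(keep)) {
      i <- as.character(e$i[k]); j <- as.character(e$j[k])
      cen[i] <- cen[i] + (W[i] - W[j])
      cen[j] <- cen[j] + (W[j] - W[i])
    }
  }
  data.frame(id = ids, cen = as.numeric(cen), is_core = as.numeric(cen) > 0)
}

#' Match patches between two years by cell overlap
#'
#' Patch identity across time steps: patch p at year t is matched to the
#' year-t+1 patch sharing the most cells with it, provided the overlap
#' covers at least `min_overlap` of p's cells (ties towards the smaller id).
#'
#' @param patches_t,patches_t1 `patch_set`s on the same grid.
#' @param min_overlap minimum shared fraction of the year-t patch.
#' @return integer vector: for each year-t patch id, the matched year-t+1
#'   patch id or `NA`.
#' @export
match_patches <- function(patches_t, patches_t1, min_overlap = 0.5) {
  stopifnot(inherits(patches_t, "patch_set"), inherits(patches_t1, "patch_set"))
  if (!all(patches_t$shape == patches_t1$shape))
    stop("patch sets live on different grids")
  ncell <- prod(patches_t$shape)
  owner <- integer(ncell)
  for (q in seq_along(patches_t1$cells)) owner[patches_t1$cells[[q]]] <- q
  n <- length(patches_t$cells)
  out <- rep(NA_integer_, n)
  for (p in seq_len(n)) {
    hits <- owner[patches_t$cells[[p]]]
    hits <- hits[hits > 0]
    if (length(hits) == 0) next
    tab <- sort(table(hits), decreasing = TRUE)
    best <- as.integer(names(tab)[1])
    if (tab[1] >= min_overlap * length(patches_t$cells[[p]])) out[p] <- best
  }
  out
}

#' Evolution relation between two years' group partitions
#'
#' Groups C (year t) and C' (year t+1) are related when some core node of C
#' appears — via the patch identity map — as a member of C'. Groups without
#' core nodes relate to nothing.
#'
#' @param partition_t,partition_t1 `group_partition`s.
#' @param cores_t data.frame from [core_nodes()] for year t.
#' @param node_map integer vector mapping year-t node ids to year-t+1 node
#'   ids (`NA` = no identity), e.g. from [match_patches()]; identity by
#'   shared id when omitted.
#' @return data.frame `group_t`, `group_t1` (the relation R).
#' @export
track_evolution <- function(partition_t, cores_t, partition_t1,
                            node_map = NULL) {
  mem_t <- partition_t$membership
  mem_t1 <- partition_t1$membership
  ids_t <- names(mem_t)
  if (is.null(node_map)) {
    node_map <- stats::setNames(ids_t, ids_t)
    node_map[!(ids_t %in% names(mem_t1))] <- NA
  } else {
    node_map <- stats::setNames(as.character(node_map), ids_t)
  }
  core_ids <- as.character(cores_t$id[cores_t$is_core])
  rel <- unique(do.call(rbind, lapply(core_ids, function(v) {
    tgt <- node_map[[v]]
    if (is.na(tgt) || !(tgt %in% names(mem_t1))) return(NULL)
    data.frame(group_t = unname(mem_t[[v]]), group_t1 = unname(mem_t1[[tgt]]))
  })))
  if (is.null(rel))
    rel <- data.frame(group_t = integer(0), group_t1 = integer(0))
  rel
}

#' Classify group life-cycle events between two years
#'
#' The bipartite evolution relation is decomposed into events covering every
#' group exactly once: a year-t+1 group with no predecessor forms; a year-t
#' group with no successor disappears; a one-to-one pair is stable when the
#' member-count change stays within `tau` of the old size, expansion when it
#' grows more, shrinkage when it shrinks more; one-to-many is a split,
#' many-to-one a merger; many-to-many tangles are resolved by
#' strongest-overlap pairing (shared mapped members) and the pairs
#' re-classified, leftovers becoming disappearance/formation.
#'
#' @param relation data.frame from [track_evolution()].
#' @param partition_t,partition_t1 the two `group_partition`s.
#' @param node_map optional patch identity map (as in [track_evolution()]).
#' @param tau relative size-change tolerance for stability (default 0.2).
#' @return data.frame with `type`, `groups_t`, `groups_t1` (ids joined by
#'   `";"`), `size_t`, `size_t1`.
#' @export
classify_events <- function(relation, partition_t, partition_t1,
                            node_map = NULL, tau = 0.2) {
  mem_t <- partition_t$membership
  mem_t1 <- partition_t1$membership
  ids_t <- names(mem_t)
  if (is.null(node_map)) {
    node_map <- stats::setNames(ids_t, ids_t)
    node_map[!(ids_t %in% names(mem_t1))] <- NA
  } else {
    node_map <- stats::setNames(as.character(node_map), ids_t)
  }
  size_t <- table(mem_t); size_t1 <- table(mem_t1)
  groups_t <- sort(unique(unname(mem_t)))
  groups_t1 <- sort(unique(unname(mem_t1)))
  # overlap (shared mapped members) between a t group and a t1 group
  overlap <- function(ct, ct1) {
    v <- ids_t[mem_t == ct]
    tgt <- node_map[v]
    tgt <- tgt[!is.na(tgt) & tgt %in% names(mem_t1)]
    sum(mem_t1[tgt] == ct1)
  }
  one_to_one <- function(ct, ct1) {
    st <- size_t[[as.character(ct)]]; s1 <- size_t1[[as.character(ct1)]]
    type <- if (s1 > st * (1 + tau)) "expansion"
    else if (s1 < st * (1 - tau)) "shrinkage"
    else "stability"
    ev(type, ct, ct1, st, s1)
  }
  ev <- function(type, gt, g1, st, s1) {
    data.frame(type = type,
               groups_t = paste(gt, collapse = ";"),
               groups_t1 = paste(g1, collapse = ";"),
               size_t = st, size_t1 = s1, stringsAsFactors = FALSE)
  }
  events <- list()
  # connected components of the bipartite relation
  all_t <- paste0("t", groups_t); all_t1 <- paste0("s", groups_t1)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(all_t, all_t1))
  if (nrow(relation) > 0)
    g <- igraph::add_edges(g, as.vector(rbind(paste0("t", relation$group_t),
                                              paste0("s", relation$group_t1))))
  comp <- igraph::components(g)$membership
  for (cm in unique(comp)) {
    vs <- names(comp)[comp == cm]
    Tg <- as.integer(sub("^t", "", vs[startsWith(vs, "t")]))
    Sg <- as.integer(sub("^s", "", vs[startsWith(vs, "s")]))
    if (length(Tg) == 0) {
      for (s in Sg) events[[length(events) + 1]] <-
          ev("formation", integer(0), s, 0L, size_t1[[as.character(s)]])
    } else if (length(Sg) == 0) {
      for (t in Tg) events[[length(events) + 1]] <-
          ev("disappearance", t, integer(0), size_t[[as.character(t)]], 0L)
    } else if (length(Tg) == 1 && length(Sg) == 1) {
      events[[length(events) + 1]] <- one_to_one(Tg, Sg)
    } else if (length(Tg) == 1) {
      events[[length(events) + 1]] <-
        ev("split", Tg, sort(Sg), size_t[[as.character(Tg)]],
           sum(unlist(lapply(Sg, function(s) size_t1[[as.character(s)]]))))
    } else if (length(Sg) == 1) {
      events[[length(events) + 1]] <-
        ev("merger", sort(Tg), Sg,
           sum(unlist(lapply(Tg, function(t) size_t[[as.character(t)]]))),
           size_t1[[as.character(Sg)]])
    } else {
      # many-to-many: strongest-overlap pairing, then re-classify
      ov <- outer(Tg, Sg, Vectorize(overlap))
      Tleft <- seq_along(Tg); Sleft <- seq_along(Sg)
      while (length(Tleft) > 0 && length(Sleft) > 0 &&
             max(ov[Tleft, Sleft]) > 0) {
        sub <- ov[Tleft, Sleft, drop = FALSE]
        hit <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        ti <- Tleft[hit[1]]; si <- Sleft[hit[2]]
        events[[length(events) + 1]] <- one_to_one(Tg[ti], Sg[si])
        Tleft <- setdiff(Tleft, ti); Sleft <- setdiff(Sleft, si)
      }
      for (ti in Tleft) events[[length(events) + 1]] <-
          ev("disappearance", Tg[ti], integer(0),
             size_t[[as.character(Tg[ti])]], 0L)
      for (si in Sleft) events[[length(events) + 1]] <-
          ev("formation", integer(0), Sg[si], 0L,
             size_t1[[as.character(Sg[si])]])
    }
  }
  do.call(rbind, events)
}
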