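#' Probability distribution of a state label over shape-graph nodes
#'
#' For each node v the raw weight is the within-node proportion of label-l
#' frames, `count_l(v) / size(v)` (the pie-chart semantics); the weights are
#' then normalized to sum to 1. The count-based alternative
#' (`count_l(v) / total_l`) is available via `mode = "count"` for sensitivity
#' analysis.
#'
#' @param graph a `shape_graph` built with labels.
#' @param label state label.
#' @param mode `"proportion"` (default) or `"count"`.
#' @return numeric vector over nodes summing to 1, with attribute `label`.
#' @export
label_distribution <- function(graph, label, mode = c("proportion", "count")) {
  mode <- match.arg(mode)
  stopifnot(inherits(graph, "shape_graph"))
  if (is.null(graph$label_counts))
    .stop2("statemapper_validation_error", "graph has no label counts")
  if (!label %in% colnames(graph$label_counts))
    .stop2("statemapper_empty_label_error", "label '%s' unknown", label)
  cnt <- graph$label_counts[, label]
  if (sum(cnt) == 0)
    .stop2("statemapper_empty_label_error",
           "label '%s' occurs in no node", label)
  raw <- if (mode == "proportion") cnt / graph$node_size else cnt
  mu <- raw / sum(raw)
  attr(mu, "label") <- label
  mu
}

#' All-pairs geodesic (hop-count) distance matrix of a shape graph
#'
#' Unit edge weights; unreachable pairs carry `Inf`.
#' @param graph a `shape_graph`.
#' @return node x node numeric matrix.
#' @export
geodesic_matrix <- function(graph) {
  stopifnot(inherits(graph, "shape_graph"))
  D <- igraph::distances(as_igraph(graph), algorithm = "unweighted")
  dimnames(D) <- NULL
  D
}

#' Exact 1-Wasserstein optimal-transport distance between node distributions
#'
#' Solves `min_{mu in Pi(p, q)} sum_ij D_ij mu_ij` exactly with a
#' transportation-simplex (network) solver restricted to the supports of p
#' and q. Errors (rather than returning infinity) if the two supports lie in
#' different graph components.
#'
#' @param D geodesic cost matrix (from [geodesic_matrix()]).
#' @param p,q probability vectors over nodes (must each sum to 1).
#' @return list with `cost` and `plan` (a data.frame of `from` node, `to`
#'   node, `mass` for the optimal coupling's support).
#' @export
ot_distance <- function(D, p, q) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (length(p) != n || length(q) != n)
    .stop2("statemapper_validation_error",
           "'p' and 'q' must have one entry per node")
  for (v in list(p, q))
    if (any(v < -1e-12) || abs(sum(v) - 1) > 1e-8)
      .stop2("statemapper_validation_error",
             "distributions must be non-negative and sum to 1")
  sp <- which(p > 0)
  sq <- which(q > 0)
  subC <- D[sp, sq, drop = FALSE]
  if (any(!is.finite(subC)))
    .stop2("statemapper_infeasible_transport_error",
           "supports lie in different graph components")
  sol <- transport_simplex_cpp(subC, p[sp], q[sq])
  keep <- sol$mass > 1e-15
  plan <- data.frame(from = sp[sol$i[keep]], to = sq[sol$j[keep]],
                     mass = sol$mass[keep])
  list(cost = sol$cost, plan = plan)
}

# Exact OT on the graph itself (min-cost flow with supply p - q).
# Agrees with ot_distance() -- property-tested.
.ot_distance_graph <- function(graph, p, q) {
  ot_flow_cpp(graph$edges, length(graph$members), p - q)
}

# support-restricted dense transportation simplex, cost only
.ot_cost_dense <- function(D, p, q) {
  sp <- which(p > 0)
  sq <- which(q > 0)
  transport_simplex_cpp(D[sp, sq, drop = FALSE], p[sp], q[sq])$cost
}

# per-node closeness: (number of reachable other nodes) / (sum of distances)
.node_closeness <- function(D) {
  n <- nrow(D)
  if (n == 1L) return(0)
  fin <- is.finite(D)
  diag(fin) <- FALSE
  Dz <- D
  Dz[!fin] <- 0
  reach <- rowSums(fin)
  tot <- rowSums(Dz)
  ifelse(reach > 0, reach / pmax(tot, .Machine$double.eps), 0)
}

#' Label-weighted closeness centrality
#'
#' Closeness of node v is the reciprocal of the average geodesic distance
#' from v to the nodes it can reach (isolated nodes score 0, no
#' small-component rescaling). Returns the mu_l-weighted arithmetic mean.
#'
#' @param graph a `shape_graph`.
#' @param mu_l node distribution from [label_distribution()].
#' @param D optional precomputed geodesic matrix.
#' @return scalar in `[0, 1]`.
#' @export
closeness_centrality <- function(graph, mu_l, D = NULL) {
  if (is.null(D)) D <- geodesic_matrix(graph)
  sum(mu_l * .node_closeness(D))
}

#' Label-weighted degree centrality
#'
#' Degree of node v normalized by the maximum possible degree `N - 1`,
#' averaged with weights mu_l. Errors on a single-node graph (undefined
#' normalization).
#'
#' @inheritParams closeness_centrality
#' @return scalar in `[0, 1]`.
#' @export
degree_centrality <- function(graph, mu_l) {
  n <- length(graph$members)
  if (n < 2L)
    .stop2("statemapper_undefined_normalization_error",
           "degree centrality undefined on a single-node graph")
  deg <- tabulate(graph$edges, nbins = n)
  sum(mu_l * deg / (n - 1L))
}

#' Diameter of a state label's node set
#'
#' The longest geodesic distance between any two nodes containing label l
#' (paths may traverse non-l nodes). A single l-node gives 0; l-nodes in
#' different components raise an infeasible error.
#'
#' @param graph a `shape_graph`.
#' @param label state label.
#' @param D optional precomputed geodesic matrix.
#' @return non-negative scalar.
#' @export
label_diameter <- function(graph, label, D = NULL) {
  if (is.null(graph$label_counts) || !label %in% colnames(graph$label_counts))
    .stop2("statemapper_empty_label_error", "label '%s' unknown", label)
  lnodes <- which(graph$label_counts[, label] > 0)
  if (length(lnodes) == 0L)
    .stop2("statemapper_empty_label_error",
           "label '%s' occurs in no node", label)
  if (length(lnodes) == 1L) return(0)
  if (is.null(D)) D <- geodesic_matrix(graph)
  sub <- D[lnodes, lnodes]
  if (any(!is.finite(sub)))
    .stop2("statemapper_infeasible_transport_error",
           "label '%s' nodes lie in different components", label)
  max(sub)
}

# restrict a shape graph to a node subset, re-indexed; frames outside are
# discarded (their mass fraction is reported by the caller)
.subset_graph <- function(graph, nodes) {
  keep <- sort(nodes)
  remap <- integer(length(graph$members))
  remap[keep] <- seq_along(keep)
  e <- graph$edges
  e <- e[e[, 1L] %in% keep & e[, 2L] %in% keep, , drop = FALSE]
  structure(list(members = graph$members[keep],
                 edges = matrix(remap[e], ncol = 2L),
                 node_size = graph$node_size[keep],
                 label_counts = graph$label_counts[keep, , drop = FALSE],
                 labels = graph$labels, levels = graph$levels,
                 n_frames = graph$n_frames),
            class = "shape_graph")
}

#' All topological descriptors of one subject's shape graph
#'
#' Computes, for every state label, the weighted degree centrality, weighted
#' closeness centrality and label diameter, and the nine OT distances
#' (three within-session condition pairs per session plus three pre/post
#' pairs of the same condition). If the graph is disconnected the analysis is
#' restricted to the component carrying the largest number of frame
#' memberships and the discarded mass fraction is recorded. Measures whose
#' label is absent (or absent after restriction) are reported as `NA`.
#'
#' @param graph a `shape_graph` with labels from [MS_LEVELS].
#' @param subject_id,group metadata echoed into the row.
#' @param ot_solver `"flow"` (default; sparse min-cost flow on the graph) or
#'   `"dense"` (transportation simplex on the precomputed geodesic matrix);
#'   the two are exactly equivalent (property-tested) and differ only in
#'   speed profile.
#' @return one-row data.frame (a MeasureTable row).
#' @export
compute_all_measures <- function(graph, subject_id = NA_character_,
                                 group = NA_character_,
                                 ot_solver = c("flow", "dense")) {
  flow_solver <- match.arg(ot_solver)
  stopifnot(inherits(graph, "shape_graph"))
  ig <- as_igraph(graph)
  comp <- igraph::components(ig)
  discarded <- 0
  if (comp$no > 1L) {
    mass <- vapply(seq_len(comp$no), function(cc)
      sum(graph$node_size[comp$membership == cc]), numeric(1))
    main <- which.max(mass)
    discarded <- 1 - mass[main] / sum(graph$node_size)
    graph <- .subset_graph(graph, which(comp$membership == main))
    ig <- as_igraph(graph)
  }
  D <- igraph::distances(ig, algorithm = "unweighted")
  dimnames(D) <- NULL
  levels <- graph$levels
  present <- vapply(levels, function(l)
    sum(graph$label_counts[, l]) > 0, logical(1))
  mus <- setNames(vector("list", length(levels)), levels)
  for (l in levels[present]) mus[[l]] <- label_distribution(graph, l)

  row <- list(subject_id = subject_id, group = group,
              n_nodes = length(graph$members), n_edges = nrow(graph$edges),
              n_components = comp$no, discarded_mass = discarded)
  n_nodes <- length(graph$members)
  deg <- tabulate(graph$edges, nbins = n_nodes)
  ccv <- .node_closeness(D)
  for (l in levels) {
    row[[paste0("dc_", l)]] <- if (present[l] && n_nodes >= 2L)
      sum(mus[[l]] * deg / (n_nodes - 1L)) else NA_real_
    row[[paste0("cc_", l)]] <- if (present[l])
      sum(mus[[l]] * ccv) else NA_real_
    row[[paste0("diam_", l)]] <- if (present[l])
      label_diameter(graph, l, D = D) else NA_real_
  }
  pairs <- rbind(c("FA1", "OM1"), c("FA1", "RS1"), c("OM1", "RS1"),
                 c("FA2", "OM2"), c("FA2", "RS2"), c("OM2", "RS2"),
                 c("FA1", "FA2"), c("OM1", "OM2"), c("RS1", "RS2"))
  doable <- present[pairs[, 1L]] & present[pairs[, 2L]]
  costs <- rep(NA_real_, nrow(pairs))
  if (any(doable)) {
    if (flow_solver == "dense") {
      costs[doable] <- vapply(which(doable), function(t)
        .ot_cost_dense(D, mus[[pairs[t, 1L]]], mus[[pairs[t, 2L]]]),
        numeric(1))
    } else {
      sup <- vapply(which(doable), function(t)
        mus[[pairs[t, 1L]]] - mus[[pairs[t, 2L]]],
        numeric(length(graph$members)))
      costs[doable] <- ot_flow_batch_cpp(graph$edges, length(graph$members),
                                         sup)
    }
  }
  for (t in seq_len(nrow(pairs)))
    row[[paste0("d_", pairs[t, 1L], "_", pairs[t, 2L])]] <- costs[t]
  as.data.frame(row, stringsAsFactors = FALSE)
}
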