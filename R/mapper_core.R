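#' Fit a 2-D filter (lens) embedding
#'
#' The filter only slices the data: clustering happens later in the original
#' feature space. Three pluggable methods share one contract:
#' \describe{
#'   \item{`linear-projection`}{top-2 variance-maximizing projection
#'     (principal components), deterministic; the default.}
#'   \item{`identity`}{requires 2-D input, returns it unchanged.}
#'   \item{`nonlinear-manifold`}{neighbour-graph spectral embedding (Laplacian
#'     eigenmaps on the kNN graph, with a minimum-spanning-tree union so the
#'     graph is connected); deterministic given `seed`.}
#' }
#' Principal-axis and eigenvector signs are fixed canonically (largest-loading
#' entry positive) so identical inputs give bitwise-identical embeddings.
#'
#' @param data frames x features numeric matrix, >= 10 rows, finite.
#' @param method filter method, see above.
#' @param seed integer seed (recorded; the spectral method is deterministic).
#' @param n_neighbors neighbourhood size for `nonlinear-manifold`.
#' @return object of class `filter_embedding` with `coords` (frames x 2).
#' @export
fit_filter <- function(data,
                       method = c("linear-projection", "identity",
                                  "nonlinear-manifold"),
                       seed = 1L, n_neighbors = 15L) {
  method <- match.arg(method)
  data <- as.matrix(data)
  if (nrow(data) < 10L)
    .stop2("statemapper_validation_error", "need at least 10 frames")
  if (!all(is.finite(data)))
    .stop2("statemapper_validation_error", "input contains non-finite values")

  coords <- switch(method,
    "identity" = {
      if (ncol(data) != 2L)
        .stop2("statemapper_dimension_error",
               "identity filter requires 2-D input (got %d columns)", ncol(data))
      data
    },
    "linear-projection" = {
      xc <- sweep(data, 2L, colMeans(data))
      # top-2 principal axes via the (features x features) Gram spectrum
      ev <- eigen(crossprod(xc), symmetric = TRUE)
      v <- ev$vectors[, 1:2, drop = FALSE]
      for (k in seq_len(ncol(v))) {
        piv <- which.max(abs(v[, k]))
        if (v[piv, k] < 0) v[, k] <- -v[, k]
      }
      xc %*% v
    },
    "nonlinear-manifold" = .spectral_embedding(data, n_neighbors, seed))

  colnames(coords) <- c("f1", "f2")
  structure(list(coords = coords, method = method, seed = as.integer(seed)),
            class = "filter_embedding")
}

# Laplacian-eigenmaps embedding of the kNN-union-MST graph.
.spectral_embedding <- function(data, n_neighbors, seed) {
  n <- nrow(data)
  k <- max(2L, min(as.integer(n_neighbors), n - 1L))
  dmat <- as.matrix(dist(data))
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1L)]
    A[i, nb] <- 1
  }
  A <- pmax(A, t(A)) # symmetric union kNN
  g_full <- igraph::graph_from_adjacency_matrix(dmat, mode = "undirected",
                                                weighted = TRUE, diag = FALSE)
  mst <- igraph::mst(g_full, algorithm = "prim")
  A[igraph::as_edgelist(mst, names = FALSE)] <- 1
  A <- pmax(A, t(A))
  dg <- rowSums(A)
  dhalf <- 1 / sqrt(pmax(dg, 1e-12))
  L <- diag(n) - (A * dhalf) * rep(dhalf, each = n)
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(ev$values)
  z <- ev$vectors[, ord[2:3], drop = FALSE]
  coords <- z * dhalf
  for (j in 1:2) {
    piv <- which.max(abs(coords[, j]))
    if (coords[piv, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Build an overlapping 2-D rectangular cover of a filter embedding
#'
#' Per dimension the observed range is split into `b` equal base intervals;
#' interval i is centred at `min + (i + 1/2) * base` with half-width
#' `base * (1 + p) / 2`, so adjacent intervals overlap by fraction `p` of the
#' base width.
#'
#' @param embedding a [fit_filter()] result (or a 2-column matrix).
#' @param b divisions per dimension (>= 2).
#' @param p overlap fraction in `[0, 1)`.
#' @return object of class `mapper_cover`.
#' @export
build_cover <- function(embedding, b = 30L, p = 0.5) {
  coords <- if (inherits(embedding, "filter_embedding")) embedding$coords
            else as.matrix(embedding)
  if (length(b) != 1L || b < 2L || b != round(b))
    .stop2("statemapper_param_error", "'b' must be an integer >= 2")
  if (length(p) != 1L || !is.finite(p) || p < 0 || p >= 1)
    .stop2("statemapper_param_error", "'p' must lie in [0, 1)")
  b <- as.integer(b)
  rng <- apply(coords, 2L, range)
  if (any(rng[2L, ] - rng[1L, ] <= 0))
    .stop2("statemapper_validation_error",
           "degenerate filter dimension: max equals min")
  base <- (rng[2L, ] - rng[1L, ]) / b
  centers <- lapply(1:2, function(d) rng[1L, d] + (seq_len(b) - 0.5) * base[d])
  structure(list(b = b, p = p, centers = centers,
                 half_width = base * (1 + p) / 2, range = rng),
            class = "mapper_cover")
}

#' Assign frames to cover bins
#'
#' Frame f belongs to bin (i, j) iff both filter coordinates lie within the
#' respective closed intervals. Empty bins are retained (with no members).
#'
#' @param embedding the [fit_filter()] result the cover was built on.
#' @param cover a [build_cover()] result.
#' @return object of class `bin_assignment`: `bins` (list of integer member
#'   vectors for the non-empty bins), `index` (matrix of their (i, j) cover
#'   coordinates), `n_bins_total`, `memberships` (per-frame bin count).
#' @export
assign_bins <- function(embedding, cover) {
  coords <- if (inherits(embedding, "filter_embedding")) embedding$coords
            else as.matrix(embedding)
  M <- lapply(1:2, function(d) {
    ctr <- cover$centers[[d]]
    # closed intervals with a relative tolerance so range endpoints stay
    # covered under floating-point rounding
    hw <- cover$half_width[d] * (1 + 1e-12) + 1e-12
    matrix(vapply(ctr, function(cc) abs(coords[, d] - cc) <= hw,
                  logical(nrow(coords))),
           nrow = nrow(coords))
  })
  memberships <- as.integer(rowSums(M[[1L]]) * rowSums(M[[2L]]))
  if (any(memberships < 1L))
    .stop2("statemapper_validation_error",
           "cover does not span the embedding: uncovered frame")
  # enumerate (frame, interval-i, interval-j) triples and split by bin id
  w1 <- which(M[[1L]], arr.ind = TRUE)
  w2 <- which(M[[2L]], arr.ind = TRUE)
  n1 <- tabulate(w1[, 1L], nbins = nrow(coords))
  n2 <- tabulate(w2[, 1L], nbins = nrow(coords))
  o1 <- w1[order(w1[, 1L]), 2L]
  o2 <- w2[order(w2[, 1L]), 2L]
  # frame f contributes n1[f] * n2[f] (i, j) interval pairs
  f_rep <- rep.int(seq_len(nrow(coords)), n1 * n2)
  idx1 <- split(o1, rep.int(seq_len(nrow(coords)), n1))
  idx2 <- split(o2, rep.int(seq_len(nrow(coords)), n2))
  pairs_i <- unlist(mapply(function(a, b) rep(a, each = length(b)),
                           idx1, idx2, SIMPLIFY = FALSE), use.names = FALSE)
  pairs_j <- unlist(mapply(function(a, b) rep(b, times = length(a)),
                           idx1, idx2, SIMPLIFY = FALSE), use.names = FALSE)
  bin_id <- (pairs_i - 1L) * cover$b + pairs_j
  bins <- split(f_rep, bin_id)
  ids <- as.integer(names(bins))
  ord <- order(ids)
  bins <- unname(bins[ord])
  ids <- ids[ord]
  nz <- cbind((ids - 1L) %/% cover$b + 1L, (ids - 1L) %% cover$b + 1L)
  structure(list(bins = bins, index = nz,
                 n_bins_total = cover$b^2, memberships = memberships),
            class = "bin_assignment")
}

#' Global epsilon rule for density clustering
#'
#' The smallest epsilon such that every point has at least `k` neighbours
#' within epsilon, i.e. the maximum over points of the distance to the k-th
#' nearest neighbour (Euclidean, computed on the full cloud).
#'
#' @param data point set (matrix) or a precomputed full distance matrix
#'   passed via `dist_matrix`.
#' @param k neighbour count (default 3).
#' @param dist_matrix optional precomputed `as.matrix(dist(data))`.
#' @return positive scalar epsilon.
#' @export
select_epsilon <- function(data, k = 3L, dist_matrix = NULL) {
  if (is.null(dist_matrix)) dist_matrix <- as.matrix(dist(as.matrix(data)))
  n <- nrow(dist_matrix)
  if (n < k + 1L)
    .stop2("statemapper_param_error",
           "need at least k + 1 = %d points, got %d", k + 1L, n)
  max(kth_nn_dist_cpp(dist_matrix, as.integer(k)))
}

#' Density-based clustering of one bin's points
#'
#' DBSCAN-flavoured clustering in the original feature space: a core point has
#' at least `min_neighbors` other points within `epsilon`; clusters are
#' connected components of core points plus border points attached to their
#' nearest core. Points that are neither (per-bin noise) are returned as
#' singleton clusters so that no frame is ever dropped.
#'
#' @param bin_points matrix of points (rows) in the original feature space.
#' @param epsilon neighbourhood radius (> 0).
#' @param min_neighbors core-point threshold: a core point needs at least
#'   this many other points within `epsilon` (default 2, matching the
#'   minPts-counting-self convention of common DBSCAN implementations).
#' @return list of integer row-index vectors, one per cluster (empty list for
#'   an empty bin).
#' @export
cluster_bin <- function(bin_points, epsilon, min_neighbors = 2L) {
  if (!is.finite(epsilon) || epsilon <= 0)
    .stop2("statemapper_param_error", "'epsilon' must be > 0")
  bin_points <- as.matrix(bin_points)
  n <- nrow(bin_points)
  if (n == 0L) return(list())
  dmat <- as.matrix(dist(bin_points))
  cluster_bins_cpp(dmat, list(seq_len(n)), epsilon, as.integer(min_neighbors))
}

#' Build the shape graph from per-bin clusters
#'
#' One node per cluster; an edge joins two distinct nodes iff their member
#' sets intersect (shared frames from overlapping bins). Per-node label counts
#' are tallied from the frame labels.
#'
#' @param clusters list of integer frame-index vectors (collectively covering
#'   all frames).
#' @param labels per-frame state labels (character or factor), or `NULL`.
#' @param n_frames total number of frames (default: max index seen).
#' @param levels label levels for the count matrix columns.
#' @return object of class `shape_graph`.
#' @export
build_graph <- function(clusters, labels = NULL, n_frames = NULL,
                        levels = NULL) {
  if (length(clusters) == 0L)
    .stop2("statemapper_validation_error", "no clusters supplied")
  if (is.null(n_frames)) n_frames <- max(unlist(clusters))
  covered <- sort(unique(unlist(clusters)))
  if (!identical(covered, seq_len(n_frames)))
    .stop2("statemapper_validation_error",
           "clusters do not cover all %d frames", n_frames)
  nn <- length(clusters)
  sizes <- lengths(clusters)
  edges <- overlap_edges_cpp(clusters, n_frames)

  label_counts <- NULL
  if (!is.null(labels)) {
    if (length(labels) != n_frames)
      .stop2("statemapper_validation_error",
             "'labels' length must equal the number of frames")
    if (is.null(levels)) levels <- unique(labels)
    lab <- as.integer(factor(labels, levels = levels))
    label_counts <- t(vapply(clusters, function(m)
      tabulate(lab[m], nbins = length(levels)), integer(length(levels))))
    colnames(label_counts) <- levels
  }
  structure(list(members = lapply(clusters, as.integer),
                 edges = matrix(as.integer(edges), ncol = 2L),
                 node_size = as.integer(sizes),
                 label_counts = label_counts,
                 labels = if (is.null(labels)) NULL else as.character(labels),
                 levels = levels, n_frames = as.integer(n_frames)),
            class = "shape_graph")
}

#' @export
print.shape_graph <- function(x, ...) {
  cat(sprintf("<shape_graph> %d nodes, %d edges, %d frames\n",
              length(x$members), nrow(x$edges), x$n_frames))
  if (!is.null(x$label_counts)) {
    tot <- colSums(x$label_counts)
    cat("  label frame-memberships:",
        paste(sprintf("%s=%d", colnames(x$label_counts), as.integer(tot)),
              collapse = " "), "\n")
  }
  invisible(x)
}

#' Convert a shape graph to an igraph object
#'
#' Node attributes: `size` (member count) and one `n_<label>` count per label.
#' @param graph a `shape_graph`.
#' @return an igraph graph.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "shape_graph"))
  g <- igraph::make_empty_graph(n = length(graph$members), directed = FALSE)
  if (nrow(graph$edges) > 0L)
    g <- igraph::add_edges(g, t(graph$edges))
  g <- igraph::set_vertex_attr(g, "size", value = graph$node_size)
  if (!is.null(graph$label_counts))
    for (l in colnames(graph$label_counts))
      g <- igraph::set_vertex_attr(g, paste0("n_", l),
                                   value = graph$label_counts[, l])
  g
}

#' Expected data points per non-empty cover bin
#'
#' Closed-form bin-density estimate for an n-point cloud under a 2-D cover
#' with b divisions per dimension and overlap p, of which a fraction
#' `f_empty` of bins are empty:
#' `n / ((b + p - b p)^2 * (1 - f_empty))`.
#'
#' @param n number of data points.
#' @param b divisions per dimension.
#' @param p overlap fraction in `[0, 1)`.
#' @param f_empty fraction of empty bins in `[0, 1)`.
#' @return expected number of points per non-empty bin.
#' @examples
#' expected_points_per_nonempty_bin(600, 30, 0.5, 0.4) # ~4.16
#' @export
expected_points_per_nonempty_bin <- function(n, b, p, f_empty = 0) {
  if (!is.finite(f_empty) || f_empty < 0 || f_empty >= 1)
    .stop2("statemapper_param_error", "'f_empty' must lie in [0, 1)")
  if (!is.finite(b) || b < 1) .stop2("statemapper_param_error", "'b' must be >= 1")
  if (!is.finite(p) || p < 0 || p >= 1)
    .stop2("statemapper_param_error", "'p' must lie in [0, 1)")
  n / ((b + p - b * p)^2 * (1 - f_empty))
}

#' Construct a Mapper shape graph from a labeled point cloud
#'
#' End-to-end Mapper construction: filter embedding, overlapping rectangular
#' cover, per-bin density clustering in the original space with a single
#' global epsilon (smallest epsilon giving every point at least `k`
#' neighbours), and cluster-overlap graph construction.
#'
#' @param values frames x features matrix.
#' @param labels optional per-frame labels.
#' @param filter_method passed to [fit_filter()].
#' @param seed filter seed.
#' @param bins cover divisions per dimension.
#' @param overlap cover overlap fraction.
#' @param k neighbour count for the epsilon rule.
#' @param min_neighbors DBSCAN core threshold.
#' @param levels label levels.
#' @return a `shape_graph`.
#' @export
mapper_graph <- function(values, labels = NULL,
                         filter_method = "linear-projection", seed = 1L,
                         bins = 30L, overlap = 0.5, k = 3L,
                         min_neighbors = 2L, levels = NULL) {
  values <- as.matrix(values)
  emb <- fit_filter(values, method = filter_method, seed = seed)
  cov <- build_cover(emb, b = bins, p = overlap)
  ba <- assign_bins(emb, cov)
  dmat <- .fast_euclidean(values)
  eps <- select_epsilon(values, k = k, dist_matrix = dmat)
  clusters <- cluster_bins_cpp(dmat, ba$bins, eps, as.integer(min_neighbors))
  g <- build_graph(clusters, labels = labels, n_frames = nrow(values),
                   levels = levels)
  attr(g, "epsilon") <- eps
  attr(g, "cover") <- list(b = cov$b, p = cov$p)
  g
}
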