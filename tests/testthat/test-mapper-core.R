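# Mapper construction: filter, cover, binning, epsilon rule, density
# clustering, nerve graph, bin-density formula

test_that("identity filter passes 2-D input through and validates", {
  xy <- cbind(1:20, 21:40)
  emb <- fit_filter(xy, method = "identity")
  expect_equal(unname(emb$coords), unname(xy))
  expect_error(fit_filter(cbind(xy, 1), method = "identity"),
               class = "statemapper_dimension_error")
  expect_error(fit_filter(xy[1:5, ]), class = "statemapper_validation_error")
  xy[3, 1] <- NA
  expect_error(fit_filter(xy), class = "statemapper_validation_error")
})

test_that("linear projection captures a rank-1 cloud in one coordinate", {
  set.seed(4)
  u <- rnorm(50); u <- u / sqrt(sum(u^2))
  X <- outer(1:100, u)
  emb <- fit_filter(X, method = "linear-projection")
  v <- apply(emb$coords, 2L, var)
  expect_lt(v[2L], 1e-10 * v[1L])
  # determinism
  expect_identical(emb$coords,
                   fit_filter(X, method = "linear-projection")$coords)
})

test_that("nonlinear-manifold filter is deterministic given a seed", {
  set.seed(8)
  X <- matrix(rnorm(60 * 5), 60)
  a <- fit_filter(X, method = "nonlinear-manifold", seed = 2L)
  b <- fit_filter(X, method = "nonlinear-manifold", seed = 2L)
  expect_identical(a$coords, b$coords)
  expect_equal(dim(a$coords), c(60L, 2L))
})

test_that("cover follows the centred-interval convention", {
  # both dims spanning [0, 10]
  xy <- cbind(c(0, 10, seq(1, 9, length.out = 18)),
              c(0, 10, seq(1, 9, length.out = 18)))
  cov <- build_cover(xy, b = 5L, p = 0.5)
  expect_equal(cov$centers[[1L]], c(1, 3, 5, 7, 9))
  expect_equal(unname(cov$half_width), c(1.5, 1.5))
  # membership geometry: x = 2.2 lies in intervals centred 1 and 3, x = 0
  # only in the first
  inside <- function(x, c) abs(x - c) <= 1.5
  expect_equal(which(inside(2.2, cov$centers[[1L]])), c(1L, 2L))
  expect_equal(which(inside(0, cov$centers[[1L]])), 1L)
  # p = 0 tiles the range: interior points fall in exactly one interval
  cov0 <- build_cover(xy, b = 5L, p = 0)
  hits <- vapply(c(0.3, 2.2, 6.7, 9.9), function(x)
    sum(abs(x - cov0$centers[[1L]]) <= cov0$half_width[1L]), numeric(1))
  expect_true(all(hits == 1))
  expect_error(build_cover(cbind(rep(1, 20), 1:20), b = 5L),
               class = "statemapper_validation_error")
  expect_error(build_cover(xy, b = 1L), class = "statemapper_param_error")
  expect_error(build_cover(xy, b = 5L, p = 1), class = "statemapper_param_error")
})

test_that("bin assignment covers all frames with bounded multiplicity", {
  span <- cbind(c(0, 10), c(0, 10))
  cov <- build_cover(span, b = 2L, p = 0)
  # a frame at a bin centre belongs to exactly one bin
  ba1 <- assign_bins(rbind(c(2.5, 2.5)), cov)
  expect_equal(ba1$memberships, 1L)
  # a frame in the overlap region of both dimensions hits 4 bins at p = 0.5
  cov5 <- build_cover(span, b = 5L, p = 0.5)
  ba4 <- assign_bins(rbind(c(2.2, 2.2)), cov5)
  expect_equal(ba4$memberships, 4L)
  # uniform cloud, b = 30, p = 0.5: mean memberships per point in [1, 4]
  set.seed(21)
  xy <- cbind(runif(600), runif(600))
  cov30 <- build_cover(xy, b = 30L, p = 0.5)
  ba <- assign_bins(xy, cov30)
  expect_true(all(ba$memberships >= 1L))
  expect_true(all(ba$memberships <= 4L))
  expect_true(mean(ba$memberships) >= 1 && mean(ba$memberships) <= 4)
  # bin lists are consistent with membership counts
  expect_equal(sum(lengths(ba$bins)), sum(ba$memberships))
})

test_that("raising the overlap cannot decrease total memberships", {
  set.seed(31)
  xy <- cbind(runif(200), runif(200))
  tot <- vapply(c(0, 0.2, 0.5, 0.8), function(p)
    sum(assign_bins(xy, build_cover(xy, b = 10L, p = p))$memberships),
    numeric(1))
  expect_true(all(diff(tot) >= 0))
})

test_that("epsilon rule returns the max kth-nearest-neighbour distance", {
  # collinear points 0..4, k = 3: endpoint's 3rd neighbour sits at distance 3
  pts <- matrix(0:4, ncol = 1L)
  expect_equal(select_epsilon(pts, k = 3L), 3)
  # brute-force oracle on a random cloud
  set.seed(12)
  X <- matrix(rnorm(40), 20L)
  d <- as.matrix(dist(X))
  kth <- max(apply(d, 1L, function(r) sort(r)[4L])) # self at rank 1
  expect_equal(select_epsilon(X, k = 3L), kth, tolerance = 1e-12)
  # equilateral triangle plus centroid: epsilon equals the side length
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(select_epsilon(rbind(tri, colMeans(tri)), k = 3L), 1,
               tolerance = 1e-12)
  expect_error(select_epsilon(matrix(0, 2L, 1L), k = 3L),
               class = "statemapper_param_error")
})

test_that("per-bin density clustering follows the core/border/noise rules", {
  # all points identical -> one cluster
  same <- matrix(1, 6L, 2L)
  cl <- cluster_bin(same, epsilon = 0.5, min_neighbors = 3L)
  expect_length(cl, 1L)
  expect_setequal(cl[[1L]], 1:6)
  # two tight groups far apart -> exactly two clusters
  set.seed(3)
  g1 <- matrix(runif(10, 0, 0.2), 5L)
  g2 <- matrix(runif(10, 100, 100.2), 5L)
  cl2 <- cluster_bin(rbind(g1, g2), epsilon = 0.5, min_neighbors = 3L)
  expect_length(cl2, 2L)
  expect_setequal(unlist(cl2), 1:10)
  # isolated points are retained as singletons, never dropped
  iso <- rbind(c(0, 0), c(10, 10))
  cl3 <- cluster_bin(iso, epsilon = 1, min_neighbors = 3L)
  expect_length(cl3, 2L)
  expect_true(all(lengths(cl3) == 1L))
  expect_error(cluster_bin(iso, epsilon = 0), class = "statemapper_param_error")
  expect_length(cluster_bin(matrix(0, 0L, 2L), 1), 0L)
})

test_that("the nerve graph links clusters exactly when they share frames", {
  g <- build_graph(list(c(1L, 2L, 3L), c(3L, 4L, 5L), 6L),
                   labels = rep(c("a", "b"), 3L))
  expect_equal(length(g$members), 3L)
  expect_equal(g$edges, matrix(c(1L, 2L), 1L))
  expect_equal(g$node_size, c(3L, 3L, 1L))
  expect_equal(rowSums(g$label_counts), as.double(g$node_size),
               ignore_attr = TRUE)
  # disjoint clusters -> edgeless
  g0 <- build_graph(list(1:2, 3:4, 5:6))
  expect_equal(nrow(g0$edges), 0L)
  # chain sharing one frame with the next -> path with n - 1 edges
  chain <- lapply(1:9, function(i) c(i, i + 1L))
  gp <- build_graph(chain)
  expect_equal(nrow(gp$edges), 8L)
  ig <- as_igraph(gp)
  expect_true(igraph::is_connected(ig))
  expect_equal(max(igraph::degree(ig)), 2L)
  expect_error(build_graph(list(1:2, 4:5)),
               class = "statemapper_validation_error")
})

test_that("mapper_graph conserves frames and label counts", {
  set.seed(17)
  X <- matrix(rnorm(300 * 5), 300L)
  labs <- rep(c("u", "v", "w"), each = 100L)
  g <- mapper_graph(X, labels = labs, bins = 8L, overlap = 0.5)
  expect_setequal(unlist(g$members), 1:300)
  expect_equal(rowSums(g$label_counts), as.double(g$node_size),
               ignore_attr = TRUE)
  for (l in c("u", "v", "w"))
    expect_gte(sum(g$label_counts[, l]), 100)
  # with p = 0 every frame lands in exactly one node: counts are exact
  g0 <- mapper_graph(X, labels = labs, bins = 8L, overlap = 0)
  expect_equal(unname(colSums(g0$label_counts)), rep(100, 3L))
  expect_equal(sum(g0$node_size), 300L)
})

test_that("the bin-density formula reproduces its worked examples", {
  expect_equal(round(expected_points_per_nonempty_bin(600, 30, 0.5, 0.4), 2),
               4.16)
  expect_equal(expected_points_per_nonempty_bin(900, 30, 0, 0), 1.0)
  expect_equal(expected_points_per_nonempty_bin(600, 15, 0.5, 0.4), 15.625)
  expect_error(expected_points_per_nonempty_bin(600, 30, 0.5, 1),
               class = "statemapper_param_error")
})
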