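# statistical battery: ANOVA, t tests, correlations, M_eff, BY-FDR, mixed
# models, median split, insightfulness model

make_long <- function(n_per_group = 6L, seed = 1L, g_eff = 0, s_eff = 0,
                      i_eff = 0, subj_sd = 1, noise_sd = 1) {
  set.seed(seed)
  n <- 2L * n_per_group
  grp <- rep(c("a", "b"), each = n_per_group)
  u <- rnorm(n, 0, subj_sd)
  d <- expand.grid(subject = seq_len(n), session = c("s1", "s2"),
                   stringsAsFactors = FALSE)
  d$group <- grp[d$subject]
  d$value <- u[d$subject] + g_eff * (d$group == "b") +
    s_eff * (d$session == "s2") +
    i_eff * (d$group == "b") * (d$session == "s2") + rnorm(nrow(d), 0, noise_sd)
  d
}

test_that("mixed ANOVA matches textbook sums of squares", {
  d <- make_long(5L, seed = 2L, g_eff = 0.5, s_eff = 0.4, i_eff = 0.3)
  res <- mixed_anova(d, "value")
  # closed-form oracle for the balanced 2 x 2 mixed design
  y <- xtabs(value ~ subject + session, d)
  grp <- d$group[match(rownames(y), d$subject)]
  n <- nrow(y); npg <- n / 2
  gm <- mean(y)
  subj_m <- rowMeans(y)
  sess_m <- colMeans(y)
  grp_m <- tapply(subj_m, grp, mean)
  cell_m <- rbind(a = colMeans(y[grp == "a", ]), b = colMeans(y[grp == "b", ]))
  ss_group <- 2 * npg * sum((grp_m - gm)^2)
  ss_subj <- 2 * sum((subj_m - grp_m[grp])^2)
  ss_sess <- n * sum((sess_m - gm)^2)
  ss_cells <- npg * sum((cell_m - gm)^2)
  ss_int <- ss_cells - ss_group - ss_sess
  ss_tot <- sum((y - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj - ss_sess - ss_int
  df_err <- n - 2
  expect_equal(res$group$statistic, ss_group / (ss_subj / (n - 2)),
               tolerance = 1e-8)
  expect_equal(res$session$statistic, ss_sess / (ss_err / df_err),
               tolerance = 1e-8)
  expect_equal(res$interaction$statistic, ss_int / (ss_err / df_err),
               tolerance = 1e-8)
  expect_equal(res$group$df, c(1, n - 2))
  expect_equal(res$session$df, c(1, n - 2))
  expect_true(all(vapply(res, function(t) t$p >= 0 && t$p <= 1, logical(1))))
})

test_that("mixed ANOVA validates its design", {
  d <- make_long(4L)
  d$value <- 1
  expect_error(mixed_anova(d, "value"), class = "statemapper_degenerate_error")
  d2 <- make_long(4L)[-1L, ]
  expect_error(mixed_anova(d2, "value"), class = "statemapper_design_error")
})

test_that("Welch t matches a from-first-principles evaluation", {
  x <- c(1, 2, 3, 4, 5); y <- c(3, 4, 5, 6, 10)
  r <- welch_t(x, y)
  vx <- var(x) / 5; vy <- var(y) / 5
  t_ref <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df_ref <- (vx + vy)^2 / (vx^2 / 4 + vy^2 / 4)
  p_ref <- 2 * pt(-abs(t_ref), df_ref)
  expect_equal(r$statistic, t_ref, tolerance = 1e-12)
  expect_equal(r$df, df_ref, tolerance = 1e-12)
  expect_equal(r$p, p_ref, tolerance = 1e-12)
  expect_error(welch_t(rep(1, 4), rep(2, 4)),
               class = "statemapper_degenerate_error")
  expect_error(welch_t(1, 1:4), class = "statemapper_param_error")
})

test_that("paired t handles the degenerate cases the contract states", {
  x <- c(1, 2, 3, 4)
  r0 <- paired_t(x, x)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  expect_error(paired_t(x, x + 1), class = "statemapper_degenerate_error")
  expect_error(paired_t(1:3, 1:4), class = "statemapper_param_error")
  r <- paired_t(c(1, 2, 3, 4, 6), c(2, 3, 5, 4, 9))
  expect_equal(r$df, 4)
  expect_gt(r$p, 0)
})

test_that("Kendall correlations and the M_eff correction behave", {
  tab <- data.frame(a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1),
                    c = c(1, 3, 2, 5, 4), k = c(2, 3, 1, 5, 7))
  r <- correlation_matrix(tab, c("a", "b"), c("c", "k"), method = "kendall")
  expect_equal(unname(r$r["a", "c"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(r$r["b", "c"]), -0.6, tolerance = 1e-12)
  expect_true(all(r$p_corrected >= r$p_raw - 1e-15, na.rm = TRUE))
  expect_true(all(r$p_corrected <= 1, na.rm = TRUE))
  # perfectly concordant / discordant pairs
  rs <- correlation_matrix(tab, c("a", "b"), method = "kendall")
  expect_equal(unname(rs$r["a", "b"]), -1)
  expect_equal(diag(rs$r), c(a = 1, b = 1))
  expect_equal(rs$r, t(rs$r))
  # constant column flagged, not crashed
  tab$z <- 1
  rc <- correlation_matrix(tab, c("a", "z"), c("c"), method = "kendall")
  expect_true(is.na(rc$r["z", "c"]))
  expect_true("z" %in% rc$undefined)
  expect_error(correlation_matrix(tab[1:3, ], c("a", "b"), c("c")),
               class = "statemapper_validation_error")
})

test_that("M_eff reproduces the eigenvalue-variance closed forms", {
  expect_equal(estimate_m_eff(diag(10)), 10)
  expect_equal(estimate_m_eff(matrix(1, 10, 10)), 1)
  eq <- matrix(0.5, 4, 4); diag(eq) <- 1
  expect_equal(estimate_m_eff(eq), 3.25)
  # Li-Ji variant: identity still gives M
  expect_equal(estimate_m_eff(diag(10), method = "liji"), 10)
  expect_error(estimate_m_eff(matrix(c(1, .2, .6, 1), 2)),
               class = "statemapper_validation_error")
  # clamped to [1, M] on arbitrary PSD correlation matrices
  set.seed(5)
  for (i in 1:20) {
    X <- matrix(rnorm(80), 20L)
    R <- cor(X)
    m <- estimate_m_eff(R)
    expect_true(m >= 1 && m <= 4)
  }
})

test_that("BY adjustment matches the harmonic step-up worked examples", {
  expect_equal(by_fdr(0.2), 0.2)
  expect_equal(by_fdr(c(0.01, 0.02, 0.03)), rep(0.055, 3L), tolerance = 1e-12)
  expect_equal(by_fdr(rep(1, 5L)), rep(1, 5L))
  expect_error(by_fdr(c(0.5, 1.2)), class = "statemapper_validation_error")
  # monotone in sorted order and permutation-invariant
  set.seed(9)
  p <- runif(20)
  adj <- by_fdr(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(20L)
  expect_equal(by_fdr(p[perm]), adj[perm])
  expect_true(all(adj >= p))
})

test_that("the mixed linear model recovers a planted interaction", {
  set.seed(12)
  n <- 36L
  x <- rnorm(n)
  beta <- c(int = 1, x = 0.5, s = -0.8, xs = 0.9)
  ests <- replicate(20, {
    u <- rnorm(n, 0, 0.7)
    d <- data.frame(subject = rep(seq_len(n), 2L),
                    session = rep(c("s1", "s2"), each = n),
                    positive_derealization = rep(x, 2L))
    s2 <- d$session == "s2"
    d$value <- beta["int"] + beta["x"] * d$positive_derealization +
      beta["s"] * s2 + beta["xs"] * d$positive_derealization * s2 +
      u[d$subject] + rnorm(2L * n, 0, 0.45)
    f <- fit_mixed_lm(d, "value", ~ positive_derealization * session)
    expect_false(f$singular)
    expect_true(f$r2_conditional >= f$r2_marginal)
    f$coefficients$estimate[grepl(":", f$coefficients$term)]
  })
  expect_lt(abs(mean(ests) - beta["xs"]) / beta["xs"], 0.1)
})

test_that("zero random-effect variance gives conditional ~ marginal R2", {
  set.seed(3)
  n <- 36L
  deltas <- replicate(200, {
    d <- data.frame(subject = rep(seq_len(n), 2L),
                    session = rep(c("s1", "s2"), each = n),
                    positive_derealization = rep(rnorm(n), 2L))
    d$value <- 0.8 * d$positive_derealization + rnorm(2L * n)
    f <- fit_mixed_lm(d, "value", ~ positive_derealization * session)
    f$r2_conditional - f$r2_marginal
  })
  expect_lt(median(deltas), 0.02)
})

test_that("median split puts ties in the lower group and flags tiny groups", {
  tab <- data.frame(subject = 1:7, split = c(3, 1, 4, 1, 5, 9, 2),
                    pre = c(5, 6, 7, 8, 9, 10, 11),
                    post = c(4, 5, 6, 8, 9, 10, 11))
  r <- median_split_test(tab, "split", "pre", "post")
  expect_equal(r$median, 3)
  expect_equal(r$n_low, 4L) # median element in the lower group
  expect_equal(r$n_high, 3L)
  expect_equal(abs(r$n_low - r$n_high), 1L)
  expect_s3_class(r$low, "test_result")
  # constant split variable -> one empty group flagged
  tab$flat <- 1
  rf <- median_split_test(tab, "flat", "pre", "post")
  expect_identical(rf$high, "insufficient-data")
  # planted decrease only in the low subgroup is detected
  set.seed(33)
  hits <- 0L
  for (i in 1:50) {
    n <- 18L
    sv <- rnorm(n)
    low <- sv <= median(sv)
    pre <- rnorm(n)
    post <- pre - 1.2 * low + rnorm(n, 0, 0.5)
    t2 <- data.frame(split = sv, pre = pre, post = post)
    rr <- median_split_test(t2, "split", "pre", "post")
    if (rr$low$p < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 40L)
})

test_that("insightfulness model recovers exact and planted structure", {
  set.seed(8)
  n <- 36L
  tab <- data.frame(positive_derealization = rnorm(n), d_OM1_OM2 = rnorm(n))
  # noise-free outcome: exact linear recovery
  tab$insightfulness <- 2 + 0.7 * tab$positive_derealization +
    0.4 * tab$d_OM1_OM2
  # noise-free fit: lm warns about an essentially perfect fit, by design here
  r <- suppressWarnings(insightfulness_model(tab))
  expect_gt(r$full$adj_r2, 0.999)
  expect_false(r$rank_deficient)
  # with a real distance contribution the full model beats the reduced one
  diffs <- replicate(30, {
    t2 <- data.frame(positive_derealization = rnorm(n),
                     d_OM1_OM2 = rnorm(n))
    t2$insightfulness <- 0.7 * t2$positive_derealization +
      0.8 * t2$d_OM1_OM2 + rnorm(n, 0, 0.8)
    m <- insightfulness_model(t2)
    m$full$adj_r2 - m$reduced$adj_r2
  })
  expect_gt(median(diffs), 0)
})
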