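#' @title Statistical battery for topological descriptors
#' @description Constructors and tests mirroring the analysis design: mixed
#'   two-way ANOVA (group between, session within), Welch and paired t tests,
#'   Kendall/Pearson correlation matrices with an effective-number-of-tests
#'   correction, Benjamini-Yekutieli FDR, random-intercept mixed linear
#'   models, a median-split test, and the insightfulness linear model.
#' @name stats_harness
NULL

.test_result <- function(statistic, df, p, effect = NA_character_,
                         correction = "none") {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p = unname(p), effect = effect, correction = correction),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  dfs <- paste(signif(x$df, 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g (%s)\n",
              x$effect, x$statistic, dfs, x$p, x$correction))
  invisible(x)
}

#' Two-way mixed ANOVA (between-subject group, within-subject session)
#'
#' Fits `dv ~ group * session + Error(subject)` on a long-format table and
#' returns the F tests for the group main effect (between stratum), the
#' session main effect and the group-by-session interaction (within stratum).
#'
#' @param table long-format data.frame.
#' @param dv name of the dependent-variable column.
#' @param between,within,subject names of the factor columns.
#' @return list of three `test_result`s: `group`, `session`, `interaction`.
#' @export
mixed_anova <- function(table, dv, between = "group", within = "session",
                        subject = "subject") {
  d <- data.frame(y = table[[dv]],
                  g = factor(table[[between]]),
                  s = factor(table[[within]]),
                  id = factor(table[[subject]]))
  if (any(is.na(d$y)))
    .stop2("statemapper_design_error", "missing values in '%s'", dv)
  tab <- table(d$id, d$s)
  if (any(tab != 1L))
    .stop2("statemapper_design_error",
           "every subject must be observed exactly once per session")
  if (var(d$y) == 0)
    .stop2("statemapper_degenerate_error", "'%s' is constant", dv)
  fit <- aov(y ~ g * s + Error(id), data = d)
  sm <- summary(fit)
  betw <- as.data.frame(sm[["Error: id"]][[1L]])
  with_ <- as.data.frame(sm[["Error: Within"]][[1L]])
  rn_b <- trimws(rownames(betw)); rn_w <- trimws(rownames(with_))
  pick <- function(df, rn, term) {
    k <- match(term, rn)
    res <- match("Residuals", rn)
    if (is.na(k) || !is.finite(df[k, "F value"]))
      .stop2("statemapper_degenerate_error",
             "F undefined for term '%s' (degenerate variance)", term)
    .test_result(df[k, "F value"], c(df[k, "Df"], df[res, "Df"]),
                 df[k, "Pr(>F)"], effect = term)
  }
  list(group = pick(betw, rn_b, "g"),
       session = pick(with_, rn_w, "s"),
       interaction = pick(with_, rn_w, "g:s"))
}

#' Welch's unequal-variance t test
#'
#' Two-sided independent-samples t test with Welch-Satterthwaite (fractional)
#' degrees of freedom -- the safer default when group variances may differ,
#' as they do for the drug-affected distance measures.
#' Missing values are dropped per sample.
#' @param x,y numeric samples (each >= 2 non-missing observations).
#' @return a `test_result`.
#' @export
welch_t <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    .stop2("statemapper_param_error", "need >= 2 observations per sample")
  if (var(x) == 0 && var(y) == 0)
    .stop2("statemapper_degenerate_error", "zero variance in both samples")
  tt <- t.test(x, y, var.equal = FALSE)
  .test_result(tt$statistic, tt$parameter, tt$p.value, effect = "welch_t")
}

#' Paired t test
#'
#' Pairs with a missing value in either member are dropped.
#' @param x,y numeric samples of equal length (>= 2 complete pairs).
#' @return a `test_result`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y))
    .stop2("statemapper_param_error", "paired samples must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 2L)
    .stop2("statemapper_param_error", "need >= 2 pairs")
  d <- x - y
  if (sd(d) == 0 && any(d != 0))
    .stop2("statemapper_degenerate_error",
           "differences are constant and nonzero: t undefined")
  if (all(d == 0)) return(.test_result(0, length(x) - 1L, 1, effect = "paired_t"))
  tt <- t.test(x, y, paired = TRUE)
  .test_result(tt$statistic, tt$parameter, tt$p.value, effect = "paired_t")
}

#' Effective number of independent tests from a correlation matrix
#'
#' Nyholt's eigenvalue-variance estimator (default):
#' `M_eff = 1 + (M - 1) * (1 - Var(lambda) / M)` with the sample variance
#' (denominator M - 1) of the eigenvalues, clamped to `[1, M]`. The Li-Ji
#' variant (`sum over eigenvalues of I(lambda >= 1) + (lambda - floor(lambda))`)
#' is available behind `method = "liji"`.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param method `"nyholt"` (default) or `"liji"`.
#' @return scalar effective number of tests.
#' @export
estimate_m_eff <- function(corr, method = c("nyholt", "liji")) {
  method <- match.arg(method)
  corr <- as.matrix(corr)
  if (nrow(corr) != ncol(corr) || max(abs(corr - t(corr))) > 1e-8)
    .stop2("statemapper_validation_error", "correlation matrix must be symmetric")
  if (max(abs(diag(corr) - 1)) > 1e-8)
    .stop2("statemapper_validation_error", "diagonal must be 1")
  M <- nrow(corr)
  if (M == 1L) return(1)
  lam <- eigen((corr + t(corr)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-6)
    .stop2("statemapper_validation_error",
           "matrix is not positive semi-definite within tolerance")
  if (method == "nyholt") {
    m_eff <- 1 + (M - 1) * (1 - var(lam) / M)
  } else {
    lam <- abs(lam)
    m_eff <- sum(ifelse(lam >= 1, 1, 0) + (lam - floor(lam)))
  }
  min(max(m_eff, 1), M)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment with the harmonic-sum factor `c(m) = sum_{i<=m} 1/i`,
#' monotone in the sorted order and capped at 1.
#' @param pvals numeric p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
by_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    .stop2("statemapper_validation_error", "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BY")
}

#' Correlation matrix with effective-number-of-tests correction
#'
#' Pairwise correlations (and two-sided p-values) of the `measures` columns
#' with the `scales` columns; if `scales` is `NULL`, the symmetric
#' self-correlation of `measures`. Corrected p-values are
#' `min(1, p * M_eff)` where `M_eff` is Nyholt's estimate computed from the
#' correlation matrix of the scales battery (of the measures themselves when
#' `scales` is `NULL`). Constant columns yield `NA` entries and are listed in
#' `$undefined`.
#'
#' @param table data.frame holding all columns.
#' @param measures character vector of measure column names.
#' @param scales optional character vector of psychometric column names.
#' @param method `"kendall"` or `"pearson"`.
#' @param m_eff optional externally supplied effective number of tests.
#' @return object of class `correlation_result` with fields `r`, `p_raw`,
#'   `p_corrected`, `m_eff`, `method`, `undefined`.
#' @export
correlation_matrix <- function(table, measures, scales = NULL,
                               method = c("kendall", "pearson"),
                               m_eff = NULL) {
  method <- match.arg(method)
  symmetric <- is.null(scales)
  if (symmetric) scales <- measures
  X <- as.matrix(table[, measures, drop = FALSE])
  Y <- as.matrix(table[, scales, drop = FALSE])
  cc <- stats::complete.cases(cbind(X, Y))
  if (sum(cc) < 4L)
    .stop2("statemapper_validation_error",
           "need >= 4 complete observations")
  X <- X[cc, , drop = FALSE]; Y <- Y[cc, , drop = FALSE]
  const_x <- apply(X, 2L, function(v) var(v) == 0)
  const_y <- apply(Y, 2L, function(v) var(v) == 0)

  r <- matrix(NA_real_, ncol(X), ncol(Y), dimnames = list(measures, scales))
  p <- r
  for (i in seq_len(ncol(X))) {
    for (j in seq_len(ncol(Y))) {
      if (symmetric && i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
      if (const_x[i] || const_y[j]) next
      ct <- suppressWarnings(cor.test(X[, i], Y[, j], method = method))
      r[i, j] <- unname(ct$estimate)
      p[i, j] <- ct$p.value
    }
  }
  if (is.null(m_eff)) {
    B <- Y[, !const_y, drop = FALSE]
    m_eff <- if (ncol(B) >= 2L)
      estimate_m_eff(suppressWarnings(cor(B, method = method)))
    else 1
  }
  p_corr <- pmin(1, p * m_eff)
  undefined <- c(measures[const_x], setdiff(scales[const_y], measures[const_x]))
  structure(list(r = r, p_raw = p, p_corrected = p_corr, m_eff = m_eff,
                 method = method, undefined = undefined,
                 n = sum(cc)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s, %d obs, M_eff = %.3f\n",
              x$method, x$n, x$m_eff))
  print(round(x$r, 3))
  invisible(x)
}

#' Random-intercept mixed linear model
#'
#' Fits `outcome ~ fixed` with a random intercept per subject (REML via
#' `nlme::lme`), returning the fixed-effect table (estimate, t, p with
#' containment degrees of freedom) and Nakagawa-style marginal and
#' conditional R-squared values. A singular or non-converging fit is flagged
#' and refitted as a plain linear model (`singular = TRUE`).
#'
#' @param table data.frame in long format.
#' @param outcome outcome column name.
#' @param fixed one-sided formula of fixed effects,
#'   e.g. `~ positive_derealization * session`.
#' @param subject subject-id column name.
#' @return object of class `mixed_model_fit`.
#' @export
fit_mixed_lm <- function(table, outcome, fixed, subject = "subject") {
  d <- as.data.frame(table)
  d$.subj <- factor(d[[subject]])
  if (min(table(d$.subj)) < 2L)
    .stop2("statemapper_design_error",
           "need >= 2 observations per subject for a within-subject model")
  form <- stats::as.formula(paste(outcome, "~", deparse(fixed[[2L]])))
  fit <- tryCatch(
    nlme::lme(form, random = ~ 1 | .subj, data = d, method = "REML"),
    error = function(e) NULL)
  singular <- FALSE
  if (!is.null(fit)) {
    vc <- suppressWarnings(nlme::VarCorr(fit))
    sd_b <- suppressWarnings(as.numeric(vc["(Intercept)", "StdDev"]))
    sd_e <- fit$sigma
    if (!is.finite(sd_b) || sd_b < 1e-8 * max(sd_e, 1e-12)) singular <- TRUE
  }
  if (is.null(fit)) {
    singular <- TRUE
    lmfit <- stats::lm(form, data = d)
    smc <- summary(lmfit)$coefficients
    coefs <- data.frame(term = rownames(smc), estimate = smc[, 1L],
                        t = smc[, 3L], p = smc[, 4L], row.names = NULL)
    fixed_pred <- predict(lmfit)
    var_f <- var(fixed_pred); var_b <- 0
    var_e <- summary(lmfit)$sigma^2
  } else {
    tt <- summary(fit)$tTable
    coefs <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                        t = tt[, "t-value"], p = tt[, "p-value"],
                        row.names = NULL)
    fixed_pred <- predict(fit, level = 0)
    var_f <- var(fixed_pred)
    vc <- suppressWarnings(nlme::VarCorr(fit))
    var_b <- suppressWarnings(as.numeric(vc["(Intercept)", "Variance"]))
    if (!is.finite(var_b)) var_b <- 0
    var_e <- fit$sigma^2
  }
  tot <- var_f + var_b + var_e
  structure(list(coefficients = coefs,
                 r2_marginal = var_f / tot,
                 r2_conditional = (var_f + var_b) / tot,
                 var_fixed = var_f, var_subject = var_b, var_residual = var_e,
                 singular = singular, outcome = outcome, fixed = fixed),
            class = "mixed_model_fit")
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> %s ~ %s  (R2 marginal %.3f, conditional %.3f%s)\n",
              x$outcome, deparse(x$fixed[[2L]]), x$r2_marginal,
              x$r2_conditional, if (x$singular) ", SINGULAR" else ""))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Median-split paired test
#'
#' Splits subjects at the median of `split_var` (ties, including the median
#' element itself, go to the lower group) and runs a paired t test of the
#' pre/post pair within each subgroup. Subgroups smaller than 3 are flagged
#' as insufficient rather than tested.
#'
#' @param table per-subject data.frame.
#' @param split_var column to split on.
#' @param dv_pre,dv_post pre- and post-session dependent-variable columns.
#' @return list with `median`, and per subgroup (`low`, `high`) either a
#'   `test_result` or the string `"insufficient-data"`, plus group sizes.
#' @export
median_split_test <- function(table, split_var, dv_pre, dv_post) {
  sv <- table[[split_var]]
  if (any(is.na(sv)))
    .stop2("statemapper_validation_error", "'%s' has missing values", split_var)
  med <- median(sv)
  low <- sv <= med
  run <- function(sel) {
    if (sum(sel) < 3L) return("insufficient-data")
    paired_t(table[[dv_pre]][sel], table[[dv_post]][sel])
  }
  list(median = med, n_low = sum(low), n_high = sum(!low),
       low = run(low), high = run(!low))
}

#' Linear model of insightfulness on derealization and d(OM1, OM2)
#'
#' Fits `insightfulness ~ positive_derealization * d(OM1, OM2)` (full model)
#' and the derealization-only reduced model, returning coefficients, overall
#' F and its p, and multiple/adjusted R-squared for both.
#'
#' @param table per-subject data.frame.
#' @param outcome,derealization,distance column names.
#' @return object of class `insight_model`.
#' @export
insightfulness_model <- function(table, outcome = "insightfulness",
                                 derealization = "positive_derealization",
                                 distance = "d_OM1_OM2") {
  d <- data.frame(y = table[[outcome]], x1 = table[[derealization]],
                  x2 = table[[distance]])
  d <- d[stats::complete.cases(d), , drop = FALSE]
  full <- stats::lm(y ~ x1 * x2, data = d)
  reduced <- stats::lm(y ~ x1, data = d)
  rank_deficient <- any(is.na(coef(full)))
  pack <- function(fit) {
    sm <- summary(fit)
    fstat <- sm$fstatistic
    list(coefficients = sm$coefficients,
         f = unname(fstat[1L]), df = unname(fstat[2:3]),
         p = unname(stats::pf(fstat[1L], fstat[2L], fstat[3L],
                              lower.tail = FALSE)),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared)
  }
  structure(list(full = pack(full), reduced = pack(reduced),
                 rank_deficient = rank_deficient, n = nrow(d)),
            class = "insight_model")
}

#' @export
print.insight_model <- function(x, ...) {
  cat(sprintf("<insight_model> n = %d; full adj R2 = %.3f (F = %.3g, p = %.3g); reduced adj R2 = %.3f\n",
              x$n, x$full$adj_r2, x$full$f, x$full$p, x$reduced$adj_r2))
  invisible(x)
}
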