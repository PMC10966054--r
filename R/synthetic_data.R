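#' Parameters for the synthetic multi-state cohort generator
#'
#' Bundles and validates the knobs of the synthetic world: a two-group
#' (active/control) cohort, six concatenated state blocks per subject
#' (RS, FA, OM per session, two sessions), state-specific mean activity
#' patterns, a global post-retreat shift, a group-specific extra displacement
#' of the post-retreat OM/RS states, temporally autocorrelated noise, and
#' psychometric scores generated from the planted subject latents.
#'
#' Geometry: the six state means are mutually orthogonal directions scaled so
#' that the Euclidean distance between any two state means equals
#' `state_separation`. The retreat shift acts along a further orthogonal unit
#' direction `u`; the drug shift acts along an eighth orthogonal direction `w`,
#' displacing OM2 along `+w` and RS2 along `-w` (a common displacement of both
#' states would leave their mutual distance unchanged and could not plant the
#' group effect the pipeline is meant to recover).
#'
#' @param n_per_group subjects per group (default 18).
#' @param n_features voxel-surrogate dimension (default 200).
#' @param frames_per_state frames per state block (default 100).
#' @param state_separation Euclidean distance between condition mean patterns
#'   (default 1.5, about 1.4 dominant-mode stationary noise sds: heavily
#'   overlapping states, as in real recordings).
#' @param retreat_shift displacement added to all session-2 states along `u`
#'   (default 1, comparable to the local noise scale so that pre/post clouds
#'   still overlap and the shape graph stays connected).
#' @param drug_shift_scale extra OM2/RS2 displacement per unit of subject
#'   latent, active group only (default 1.5).
#' @param noise_sd innovation standard deviation of the AR(1) noise (scale of
#'   the total per-frame innovation energy, `n_features * noise_sd^2`).
#' @param ar_coeff AR(1) coefficient in `[0, 1)`.
#' @param n_noise_modes number of orthonormal spatial noise modes the AR(1)
#'   noise is confined to (low-rank spatially correlated noise, emulating the
#'   strong spatial correlation of BOLD recordings; `n_features` recovers
#'   isotropic noise).
#' @param retreat_gain_sd sd of the per-subject multiplicative retreat gain.
#' @param psy_noise_sd measurement noise sd of the psychometric scores.
#' @param seed integer master seed.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_per_group = 18L, n_features = 200L,
                          frames_per_state = 100L, state_separation = 1.5,
                          retreat_shift = 1, drug_shift_scale = 1.5,
                          noise_sd = 1, ar_coeff = 0.4, n_noise_modes = 10L,
                          retreat_gain_sd = 0.2, psy_noise_sd = 0.3,
                          seed = 1L) {
  chk_count <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x < 1 || x != round(x))
      .stop2("statemapper_param_error", "'%s' must be a single count >= 1", nm)
  }
  chk_count(n_per_group, "n_per_group")
  chk_count(n_features, "n_features")
  chk_count(frames_per_state, "frames_per_state")
  if (n_features < 8L)
    .stop2("statemapper_param_error",
           "'n_features' must be >= 8 (six state directions plus u and w)")
  if (!is.finite(state_separation) || state_separation < 0)
    .stop2("statemapper_param_error", "'state_separation' must be >= 0")
  if (!is.finite(retreat_shift) || retreat_shift < 0)
    .stop2("statemapper_param_error", "'retreat_shift' must be >= 0")
  if (!is.finite(drug_shift_scale) || drug_shift_scale < 0)
    .stop2("statemapper_param_error", "'drug_shift_scale' must be >= 0")
  if (!is.finite(noise_sd) || noise_sd <= 0)
    .stop2("statemapper_param_error", "'noise_sd' must be > 0")
  if (!is.finite(ar_coeff) || ar_coeff < 0 || ar_coeff >= 1)
    .stop2("statemapper_param_error", "'ar_coeff' must lie in [0, 1)")
  chk_count(n_noise_modes, "n_noise_modes")
  if (n_noise_modes > n_features)
    .stop2("statemapper_param_error",
           "'n_noise_modes' cannot exceed 'n_features'")
  if (!is.finite(retreat_gain_sd) || retreat_gain_sd < 0)
    .stop2("statemapper_param_error", "'retreat_gain_sd' must be >= 0")
  if (!is.finite(psy_noise_sd) || psy_noise_sd <= 0)
    .stop2("statemapper_param_error", "'psy_noise_sd' must be > 0")
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed))
    .stop2("statemapper_param_error", "'seed' must be a single integer")
  structure(list(n_per_group = as.integer(n_per_group),
                 n_features = as.integer(n_features),
                 frames_per_state = as.integer(frames_per_state),
                 state_separation = state_separation,
                 retreat_shift = retreat_shift,
                 drug_shift_scale = drug_shift_scale,
                 noise_sd = noise_sd, ar_coeff = ar_coeff,
                 n_noise_modes = as.integer(n_noise_modes),
                 retreat_gain_sd = retreat_gain_sd,
                 psy_noise_sd = psy_noise_sd, seed = as.integer(seed)),
            class = "cohort_params")
}

# Shared cohort geometry, deterministic in params$seed. The generative
# structure lives in a low-dimensional latent subspace embedded in feature
# space by an orthonormal map Q: condition means (FA, OM, RS) at the vertices
# of an equilateral triangle of side state_separation in latent dims 1-2, the
# retreat axis u = dim 3, the drug axis w = dim 4, and n_noise_modes AR(1)
# noise modes with geometrically decaying innovation scales
# (noise_sd * 0.7^(k-1)) along latent dims 1..r. Low intrinsic dimension is
# what lets the bin-wise density clustering form mixed-label clusters, as in
# real BOLD recordings.
.noise_decay <- 0.7

.state_space <- function(params) {
  .with_seed(.derive_seed(params$seed, 1L), {
    r <- params$n_noise_modes
    L <- max(4L, r)
    G <- matrix(rnorm(params$n_features * L), params$n_features, L)
    Q <- qr.Q(qr(G))
    # canonical signs so the frame is reproducible across BLAS variants
    for (k in seq_len(L)) {
      piv <- which.max(abs(Q[, k]))
      if (Q[piv, k] < 0) Q[, k] <- -Q[, k]
    }
    tri <- rbind(FA = c(0, 1 / sqrt(3)),
                 OM = c(-0.5, -1 / (2 * sqrt(3))),
                 RS = c(0.5, -1 / (2 * sqrt(3)))) * params$state_separation
    cond_means <- Q[, 1:2, drop = FALSE] %*% t(tri) # n_features x 3
    colnames(cond_means) <- rownames(tri)
    list(cond_means = cond_means, u = Q[, 3], w = Q[, 4],
         noise_modes = Q[, seq_len(r), drop = FALSE],
         mode_sds = params$noise_sd * .noise_decay^(seq_len(r) - 1L))
  })
}

# per-subject ground-truth latents, deterministic in (seed, index, group)
.subject_latents <- function(params, subject_index, group) {
  .with_seed(.derive_seed(params$seed, 2L, subject_index,
                          ifelse(group == "active", 1L, 0L)), {
    latent <- if (group == "active") rnorm(1L, 1, 0.35) else rnorm(1L, 0, 0.10)
    gain <- rnorm(1L, 1, params$retreat_gain_sd)
    list(latent = latent, retreat_gain = gain)
  })
}

.block_states <- function() {
  paste0(rep(.session_block_order, 2L), rep(1:2, each = 3L))
}

#' Generate one synthetic labeled multi-state time series
#'
#' Produces six contiguous blocks of `frames_per_state` frames in scan order
#' RS1, FA1, OM1, RS2, FA2, OM2. Each frame is the state mean pattern, plus
#' the retreat shift (session 2, scaled by the subject's retreat gain), plus
#' the drug displacement of OM2/RS2 (active group only, `+w` for OM2 and `-w`
#' for RS2, scaled by `drug_shift_scale` times the subject latent), plus AR(1)
#' noise that runs continuously within each session and restarts from its
#' stationary distribution at the session boundary.
#'
#' @param params a [cohort_params()] object.
#' @param subject_index positive integer index within the group.
#' @param group `"active"` or `"control"`.
#' @return an object of class `labeled_ts` with fields `values`
#'   (frames x features), `labels`, `subject_id`, `group` and the planted
#'   ground truth in `latent` / `retreat_gain`.
#' @export
generate_subject <- function(params, subject_index, group = c("active", "control")) {
  if (!inherits(params, "cohort_params"))
    .stop2("statemapper_param_error", "'params' must be a cohort_params object")
  group <- match.arg(group)
  if (length(subject_index) != 1L || !is.finite(subject_index) ||
      subject_index < 1 || subject_index != round(subject_index))
    .stop2("statemapper_param_error", "'subject_index' must be a count >= 1")

  space <- .state_space(params)
  lat <- .subject_latents(params, subject_index, group)
  fps <- params$frames_per_state
  block_states <- .block_states()
  n_frames <- 6L * fps
  labels <- rep(block_states, each = fps)

  cond <- sub("[12]$", "", block_states)
  means <- matrix(0, 6L, params$n_features)
  for (bl in seq_len(6L)) {
    session2 <- bl > 3L
    mu <- space$cond_means[, cond[bl]]
    if (session2)
      mu <- mu + params$retreat_shift * lat$retreat_gain * space$u
    st <- block_states[bl]
    if (group == "active" && st %in% c("OM2", "RS2")) {
      sgn <- if (st == "OM2") 1 else -1
      mu <- mu + sgn * params$drug_shift_scale * lat$latent * space$w
    }
    means[bl, ] <- mu
  }

  # AR(1) noise per spatial mode (innovation sd mode_sds[k]), run
  # continuously within each session and restarted from the stationary
  # distribution at the session boundary
  noise <- .with_seed(.derive_seed(params$seed, 3L, subject_index,
                                   ifelse(group == "active", 1L, 0L)), {
    r <- params$n_noise_modes
    z <- matrix(0, n_frames, r)
    rho <- params$ar_coeff
    stat_sds <- space$mode_sds / sqrt(1 - rho^2)
    for (sess in 0:1) {
      off <- sess * 3L * fps
      x <- rnorm(r, 0, stat_sds)
      z[off + 1L, ] <- x
      if (3L * fps > 1L) {
        innov <- matrix(rnorm((3L * fps - 1L) * r), 3L * fps - 1L) *
          rep(space$mode_sds, each = 3L * fps - 1L)
        for (k in seq_len(r))
          z[off + 2:(3L * fps), k] <- stats::filter(innov[, k], rho,
                                                    "recursive",
                                                    init = x[k])
      }
    }
    z %*% t(space$noise_modes)
  })

  values <- noise + means[rep(seq_len(6L), each = fps), , drop = FALSE]
  structure(list(values = values, labels = labels,
                 subject_id = sprintf("%s%02d",
                                      ifelse(group == "active", "A", "C"),
                                      subject_index),
                 group = group, latent = lat$latent,
                 retreat_gain = lat$retreat_gain),
            class = "labeled_ts")
}

#' @export
print.labeled_ts <- function(x, ...) {
  cat(sprintf("<labeled_ts> subject %s (%s): %d frames x %d features, states: %s\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values),
              paste(rle(x$labels)$values, collapse = " ")))
  invisible(x)
}

#' Generate a full synthetic cohort with psychometric scores
#'
#' Generates `n_per_group` subjects per group via [generate_subject()] and a
#' psychometric table. Positive derealization is a noisy linear readout of the
#' planted subject latent; insightfulness is a noisy linear combination of
#' positive derealization and the subject's realized retreat-response
#' magnitude. The generative coefficients are recorded in
#' `attr(psychometrics, "coefficients")` for parameter-recovery tests.
#'
#' @param params a [cohort_params()] object.
#' @return list with `subjects` (list of `labeled_ts`) and `psychometrics`
#'   (data.frame: subject_id, group, positive_derealization, insightfulness,
#'   latent_shift, retreat_gain).
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "cohort_params"))
    .stop2("statemapper_param_error", "'params' must be a cohort_params object")
  subjects <- c(lapply(seq_len(params$n_per_group), generate_subject,
                       params = params, group = "active"),
                lapply(seq_len(params$n_per_group), generate_subject,
                       params = params, group = "control"))
  coefs <- list(a = 1, b = 0.8, c = 0.5)
  psy <- .with_seed(.derive_seed(params$seed, 4L), {
    lat <- vapply(subjects, `[[`, numeric(1), "latent")
    gain <- vapply(subjects, `[[`, numeric(1), "retreat_gain")
    n <- length(subjects)
    pd <- coefs$a * lat + rnorm(n, 0, params$psy_noise_sd)
    ins <- coefs$b * pd + coefs$c * params$retreat_shift * gain +
      rnorm(n, 0, params$psy_noise_sd)
    data.frame(subject_id = vapply(subjects, `[[`, character(1), "subject_id"),
               group = vapply(subjects, `[[`, character(1), "group"),
               positive_derealization = pd, insightfulness = ins,
               latent_shift = lat, retreat_gain = gain,
               stringsAsFactors = FALSE)
  })
  attr(psy, "coefficients") <- coefs
  list(subjects = subjects, psychometrics = psy)
}

#' Noisy circle point cloud
#'
#' Standard topology fixture for Mapper: points on a circle of the given
#' radius with Gaussian radial noise.
#'
#' @param n number of points (>= 8).
#' @param radius circle radius.
#' @param noise_sd radial noise sd (0 for an exact circle).
#' @param seed integer seed.
#' @param equal_spacing if `TRUE`, angles are equally spaced instead of
#'   uniformly random (useful for closed-form nearest-neighbour checks).
#' @return an `n x 2` matrix.
#' @export
generate_circle_cloud <- function(n, radius = 1, noise_sd = 0, seed = 1L,
                                  equal_spacing = FALSE) {
  if (length(n) != 1L || !is.finite(n) || n < 8L || n != round(n))
    .stop2("statemapper_param_error", "'n' must be a count >= 8")
  if (!is.finite(radius) || radius <= 0)
    .stop2("statemapper_param_error", "'radius' must be > 0")
  if (!is.finite(noise_sd) || noise_sd < 0)
    .stop2("statemapper_param_error", "'noise_sd' must be >= 0")
  .with_seed(.derive_seed(seed, 5L), {
    theta <- if (equal_spacing) seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
             else runif(n, 0, 2 * pi)
    r <- radius + rnorm(n, 0, noise_sd)
    cbind(x = r * cos(theta), y = r * sin(theta))
  })
}
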