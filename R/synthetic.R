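# Behavioral score models: intercept (control level), slope per unit latent
# severity, and residual sd. Levels and group directions follow the published
# demographic summaries of large autism/control cohorts: higher ADOS/ADI/SRS
# and lower verbal IQ / Vineland composite with increasing severity.
BEHAVIOR_MODEL <- list(
  ados_social_comm    = c(intercept = 1.25, slope = 10.6, sd = 1.4),
  adi_r_social        = c(intercept = 0,    slope = 19.7, sd = 5.7),
  adi_r_verbal        = c(intercept = 0,    slope = 15.9, sd = 4.6),
  verbal_iq           = c(intercept = 112,  slope = -7,   sd = 13.3),
  performance_iq      = c(intercept = 108,  slope = -2,   sd = 13.3),
  srs_total           = c(intercept = 21,   slope = 70,   sd = 16.2),
  vineland_composite  = c(intercept = 105,  slope = -30,  sd = 11.6)
)

#' Simulation parameters for a synthetic multisite cohort
#'
#' Bundles and validates the knobs of [simulate_cohort()]. Defaults describe a
#' mid-sized multisite resting-state study: 5 sites of 24 subjects (12 autism,
#' 12 control), 100 lattice ROIs, 150 volumes at TR = 2 s, a group effect of
#' 0.5 Fisher-z units concentrated on 2% of connections, per-site additive
#' offsets (sd 0.1 z), weak age and age-squared trends, subject-level noise of
#' 0.2 z, and Fisher-z sampling noise of sd 1/sqrt(T_retained - 3) emulating
#' finite scan length.
#'
#' @param n_roi ROI count.
#' @param n_sites Number of sites.
#' @param subjects_per_site Subjects per site (scalar or length `n_sites`).
#' @param autism_per_site Autism subjects per site (scalar or vector); the
#'   rest are controls. At least 2 per diagnosis per site are required.
#' @param volumes_per_site Acquired BOLD volumes per site (scalar or vector).
#' @param tr Repetition time, seconds.
#' @param effect_fraction Fraction of connections carrying the group effect.
#' @param delta Group effect size at unit severity, Fisher-z units.
#' @param site_offset_sd SD of per-(site, connection) additive offsets, z.
#' @param age_slope,age_curvature Linear and quadratic age trend, z/year and
#'   z/year^2, common to all connections.
#' @param subject_noise_sd Subject-level noise sd, z units.
#' @param baseline_range Range of per-connection baseline strength, z units.
#' @param measurement_noise If TRUE (default) add Fisher-z sampling noise with
#'   sd 1/sqrt(T_retained - 3), tying connectivity precision to scan length.
#' @param motion_spike_rate Per-volume probability of a motion spike; autism
#'   subjects use 1.5x this rate (more in-scanner motion), which induces the
#'   group difference in retained volumes.
#' @param age_range Age range sampled uniformly per site, years.
#' @param behavior_noise_scale Multiplier on the behavioral residual sds.
#' @param behavior_missing_rate Fraction of behavioral scores masked missing.
#' @param male_fraction,handedness_probs,eyes_probs Demographic composition.
#' @param missing_handedness_rate Fraction of subjects with missing handedness
#'   (downstream imputation exercises the nearest-neighbor rule).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated list of class `fcloo_sim_params`.
#' @export
sim_params <- function(n_roi = 100L, n_sites = 5L, subjects_per_site = 24L,
                       autism_per_site = 12L, volumes_per_site = 150L, tr = 2,
                       effect_fraction = 0.02, delta = 0.5,
                       site_offset_sd = 0.1,
                       age_slope = -0.002, age_curvature = 2e-5,
                       subject_noise_sd = 0.2,
                       baseline_range = c(-0.2, 0.6),
                       measurement_noise = TRUE,
                       motion_spike_rate = 0.02,
                       age_range = c(6, 60),
                       behavior_noise_scale = 1,
                       behavior_missing_rate = 0.15,
                       male_fraction = 0.85,
                       handedness_probs = c(right = 0.894, left = 0.099,
                                            ambidextrous = 0.007),
                       eyes_probs = c(open = 0.7, closed = 0.25, unknown = 0.05),
                       missing_handedness_rate = 0,
                       seed = 1L) {
  p <- list(
    n_roi = as.integer(n_roi), n_sites = as.integer(n_sites),
    subjects_per_site = rep_len(as.integer(subjects_per_site), n_sites),
    autism_per_site = rep_len(as.integer(autism_per_site), n_sites),
    volumes_per_site = rep_len(as.integer(volumes_per_site), n_sites),
    tr = tr, effect_fraction = effect_fraction, delta = delta,
    site_offset_sd = site_offset_sd, age_slope = age_slope,
    age_curvature = age_curvature, subject_noise_sd = subject_noise_sd,
    baseline_range = baseline_range, measurement_noise = measurement_noise,
    motion_spike_rate = motion_spike_rate, age_range = age_range,
    behavior_noise_scale = behavior_noise_scale,
    behavior_missing_rate = behavior_missing_rate,
    male_fraction = male_fraction,
    handedness_probs = handedness_probs, eyes_probs = eyes_probs,
    missing_handedness_rate = missing_handedness_rate,
    seed = as.integer(seed))
  stopifnot(p$n_roi >= 2, p$n_sites >= 1,
            p$effect_fraction >= 0, p$effect_fraction <= 1,
            p$site_offset_sd >= 0, p$subject_noise_sd >= 0,
            p$motion_spike_rate >= 0, p$motion_spike_rate <= 1,
            all(p$subjects_per_site >= p$autism_per_site),
            diff(p$baseline_range) >= 0, diff(p$age_range) >= 0)
  if (any(p$autism_per_site < 2) || any(p$subjects_per_site - p$autism_per_site < 2)) {
    warning("some site has fewer than 2 subjects of a diagnosis; ",
            "classifier runs need >= 2 per diagnosis")
  }
  structure(p, class = "fcloo_sim_params")
}

# deterministic lattice of >= n_roi centroids (5-mm spacing, compact box)
lattice_centroids <- function(n_roi, spacing = 5) {
  side <- ceiling(n_roi^(1 / 3))
  grid <- expand.grid(x = 0:(side), y = 0:(side), z = 0:(side))
  grid <- grid[order(grid$z, grid$y, grid$x), ]
  grid <- grid[seq_len(n_roi), ] * spacing
  data.frame(roi_id = seq_len(n_roi) - 1L,
             x = grid$x, y = grid$y, z = grid$z,
             n_voxels = rep(5L, n_roi))
}

# retained volume count after scrubbing a Bernoulli spike train with a
# one-frame guard band on each side
simulate_retained <- function(n_volumes, spike_rate) {
  spikes <- stats::rbinom(n_volumes, 1L, spike_rate) == 1L
  flagged <- spikes
  flagged[which(spikes) + 1L] <- TRUE
  flagged <- flagged[seq_len(n_volumes)]
  flagged[pmax(which(spikes) - 1L, 1L)] <- TRUE
  flagged[1L] <- spikes[1L] | (length(spikes) > 1L && spikes[2L])
  sum(!flagged, na.rm = TRUE)
}

#' Simulate a multisite cohort with planted group effects
#'
#' Generates a cohort whose statistical structure matches what the
#' leave-one-out classifier assumes: per-connection values are
#' \deqn{x = baseline_c + \beta_{age} age + \beta_{age^2} age^2 +
#'       site_{s,c} + severity \cdot \delta \cdot 1[c \in affected] +
#'       \epsilon,}
#' with \eqn{\epsilon \sim N(0, \sigma_e^2)} plus (optionally) Fisher-z
#' sampling noise of sd \eqn{1/\sqrt{T_{ret} - 3}}. Latent severity is
#' \eqn{|N(1, 0.3^2)|} for autism subjects and 0 for controls; behavioral
#' scores are linear maps of severity plus noise with group directions
#' matching published cohort summaries (higher SRS/ADOS, lower Vineland and
#' verbal IQ in autism). Identical seeds give identical datasets.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `cohort` (an `fcloo_cohort`) and `truth`
#'   (affected connection pairs and indices, per-site offsets, per-subject
#'   severity, and the generating coefficients).
#' @export
simulate_cohort <- function(params) {
  stopifnot(inherits(params, "fcloo_sim_params"))
  p <- params
  set.seed(p$seed)
  R <- p$n_roi
  C <- n_connections(R)
  rois <- lattice_centroids(R)
  pairs <- connection_pairs(R)

  n_affected <- round(p$effect_fraction * C)
  affected <- sort(sample.int(C, n_affected))
  baseline <- stats::runif(C, p$baseline_range[1L], p$baseline_range[2L])
  site_offsets <- matrix(stats::rnorm(p$n_sites * C, 0, p$site_offset_sd),
                         nrow = p$n_sites)

  n <- sum(p$subjects_per_site)
  site <- rep(paste0("site", seq_len(p$n_sites)), p$subjects_per_site)
  diagnosis <- unlist(lapply(seq_len(p$n_sites), function(s) {
    rep(c("autism", "control"),
        c(p$autism_per_site[s], p$subjects_per_site[s] - p$autism_per_site[s]))
  }))
  site_idx <- rep(seq_len(p$n_sites), p$subjects_per_site)

  age <- stats::runif(n, p$age_range[1L], p$age_range[2L])
  gender <- ifelse(stats::runif(n) < p$male_fraction, "male", "female")
  handedness <- sample(names(p$handedness_probs), n, replace = TRUE,
                       prob = p$handedness_probs)
  if (p$missing_handedness_rate > 0) {
    handedness[stats::runif(n) < p$missing_handedness_rate] <- NA_character_
  }
  eyes <- sample(names(p$eyes_probs), n, replace = TRUE, prob = p$eyes_probs)

  severity <- ifelse(diagnosis == "autism", abs(stats::rnorm(n, 1, 0.3)), 0)

  acquired <- p$volumes_per_site[site_idx]
  spike_rate <- p$motion_spike_rate * ifelse(diagnosis == "autism", 1.5, 1)
  retained <- vapply(seq_len(n),
                     function(i) simulate_retained(acquired[i], spike_rate[i]),
                     integer(1L))
  retained <- pmax(retained, 10L)  # never fewer than 10 usable volumes

  behaviors <- matrix(NA_real_, n, length(BEHAVIOR_MODEL),
                      dimnames = list(NULL, names(BEHAVIOR_MODEL)))
  for (m in names(BEHAVIOR_MODEL)) {
    bm <- BEHAVIOR_MODEL[[m]]
    v <- bm[["intercept"]] + bm[["slope"]] * severity +
      stats::rnorm(n, 0, bm[["sd"]] * p$behavior_noise_scale)
    if (startsWith(m, "adi_")) v[diagnosis == "control"] <- NA_real_
    drop <- stats::runif(n) < p$behavior_missing_rate
    v[drop] <- NA_real_
    behaviors[, m] <- v
  }

  values <- matrix(0, n, C)
  for (i in seq_len(n)) {
    mu <- baseline + p$age_slope * age[i] + p$age_curvature * age[i]^2 +
      site_offsets[site_idx[i], ]
    mu[affected] <- mu[affected] + severity[i] * p$delta
    x <- mu + stats::rnorm(C, 0, p$subject_noise_sd)
    if (p$measurement_noise) {
      x <- x + stats::rnorm(C, 0, 1 / sqrt(retained[i] - 3))
    }
    values[i, ] <- x
  }

  phen <- data.frame(
    subject_id = sprintf("sub%04d", seq_len(n)),
    site = site, diagnosis = diagnosis, age = age, gender = gender,
    handedness = handedness, eyes = eyes,
    n_volumes_acquired = acquired, n_volumes_retained = retained,
    stringsAsFactors = FALSE)
  phen <- cbind(phen, as.data.frame(behaviors))

  cohort <- cohort_dataset(phen, values, rois)
  truth <- list(
    affected_idx = affected,
    affected_pairs = cbind(i = pairs$i[affected], j = pairs$j[affected]),
    site_offsets = site_offsets,
    severity = severity,
    baseline = baseline,
    coefficients = c(age_slope = p$age_slope, age_curvature = p$age_curvature,
                     delta = p$delta),
    params = p)
  list(cohort = cohort, truth = truth)
}

#' Simulate ROI time series with a prescribed association structure
#'
#' Draws `n_volumes` samples from a zero-mean multivariate normal whose
#' correlation matrix is `tanh` of the target Fisher-z matrix, so the
#' empirical Fisher-z association matrix converges to the target as the
#' series lengthens (standard error 1/sqrt(T - 3) per connection).
#'
#' @param target_z Symmetric R x R Fisher-z matrix (diagonal ignored).
#' @param n_volumes Number of time points T.
#' @param seed Integer seed.
#' @param ridge Diagonal load added (and renormalized) if the correlation
#'   matrix is not positive definite (default 1e-8); if it remains
#'   non-positive-definite after loading, an error is raised.
#' @return R x T numeric matrix of time courses.
#' @export
simulate_timeseries <- function(target_z, n_volumes, seed = 1L, ridge = 1e-8) {
  stopifnot(is.matrix(target_z), nrow(target_z) == ncol(target_z),
            n_volumes >= 2)
  R <- nrow(target_z)
  cmat <- tanh(target_z)
  diag(cmat) <- 1
  ch <- tryCatch(chol(cmat), error = function(e) NULL)
  if (is.null(ch)) {
    cmat <- cmat + diag(ridge, R)
    cmat <- stats::cov2cor(cmat)
    ch <- tryCatch(chol(cmat), error = function(e) NULL)
    if (is.null(ch)) {
      stop("target matrix is not positive definite after diagonal loading")
    }
  }
  set.seed(seed)
  z <- matrix(stats::rnorm(n_volumes * R), n_volumes, R)
  t(z %*% ch)
}

#' Simulate rigid-body motion parameters
#'
#' Produces a 6 x T trace (3 translations in mm, 3 rotations in radians) made
#' of a slow low-amplitude drift plus motion spikes at Bernoulli(`spike_rate`)
#' frames. Spike amplitude (1.2 mm, alternating sign and cycling translation
#' axis) guarantees a root-mean-square framewise displacement above the 0.2 mm
#' scrubbing threshold at every spike frame, while the drift alone stays well
#' below it.
#'
#' @param n_volumes Number of frames T (>= 2).
#' @param spike_rate Per-frame spike probability.
#' @param seed Integer seed.
#' @return 6 x T numeric matrix.
#' @export
simulate_motion <- function(n_volumes, spike_rate, seed = 1L) {
  stopifnot(n_volumes >= 2, spike_rate >= 0, spike_rate <= 1)
  set.seed(seed)
  t_idx <- seq_len(n_volumes)
  motion <- matrix(0, 6L, n_volumes)
  for (r in 1:6) {
    amp <- if (r <= 3) 0.05 else 5e-4
    phase <- stats::runif(1, 0, 2 * pi)
    motion[r, ] <- amp * sin(2 * pi * 2 * t_idx / n_volumes + phase) +
      stats::rnorm(n_volumes, 0, amp / 20)
  }
  spikes <- which(stats::rbinom(n_volumes, 1L, spike_rate) == 1L)
  for (k in seq_along(spikes)) {
    axis <- (k - 1L) %% 3L + 1L
    motion[axis, spikes[k]] <- motion[axis, spikes[k]] + 1.2 * (-1)^(k - 1L)
  }
  motion
}
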