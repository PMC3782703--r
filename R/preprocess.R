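#' Bandpass parameters
#'
#' @param low,high Passband edges in Hz (defaults 0.001 and 0.1, the
#'   conventional resting-state band).
#' @param tr Repetition time in seconds.
#' @return Validated list of class `fcloo_bandpass_params`.
#' @export
bandpass_params <- function(low = 0.001, high = 0.1, tr = 2) {
  nyquist <- 1 / (2 * tr)
  if (!(low >= 0 && low < high && high < nyquist)) {
    stop("invalid band [", low, ", ", high, "] Hz: need 0 <= low < high < ",
         "Nyquist = ", nyquist, " Hz for TR = ", tr, " s")
  }
  structure(list(low = low, high = high, tr = tr),
            class = "fcloo_bandpass_params")
}

#' Scrubbing parameters
#'
#' @param threshold Displacement threshold in mm (default 0.2) applied to both
#'   framewise displacement and (normalized) DVARS.
#' @param rotation_radius Radius in mm at which rotations are converted to arc
#'   length (default 50).
#' @param drop_before,drop_after Number of neighboring frames removed on each
#'   side of a flagged frame (default 1 each).
#' @return Validated list of class `fcloo_scrub_params`.
#' @export
scrub_params <- function(threshold = 0.2, rotation_radius = 50,
                         drop_before = 1L, drop_after = 1L) {
  stopifnot(threshold > 0, rotation_radius > 0,
            drop_before >= 0, drop_after >= 0)
  structure(list(threshold = threshold, rotation_radius = rotation_radius,
                 drop_before = as.integer(drop_before),
                 drop_after = as.integer(drop_after)),
            class = "fcloo_scrub_params")
}

#' Linear detrend and bandpass filter
#'
#' Removes the per-channel linear trend (which absorbs most very-low-frequency
#' drift in short series), applies an ideal FFT-domain band mask keeping
#' frequencies in `[low, high]` Hz, and finally removes the band-limited
#' component of the linear ramp, making the whole operation an exact
#' orthogonal projection: linear ramps are annihilated, in-band sinusoids pass
#' essentially unattenuated, and applying the filter twice equals applying it
#' once to machine precision. The DC bin is excluded whenever `low > 0`, so
#' output channels have (numerically) zero mean.
#'
#' @param series channels x T numeric matrix.
#' @param params A [bandpass_params()] object.
#' @return Filtered channels x T matrix.
#' @export
temporal_filter <- function(series, params = bandpass_params()) {
  stopifnot(inherits(params, "fcloo_bandpass_params"), is.matrix(series))
  T <- ncol(series)
  if (T < 8L) stop("need at least 8 time points")
  tt <- seq_len(T)
  xm <- tt - mean(tt)
  # linear detrend per channel
  slope <- (series %*% xm) / sum(xm^2)
  detr <- series - rowMeans(series) - slope %*% t(xm)
  # ideal FFT mask; bins at k/(T*tr), folded to [0, Nyquist]
  freqs <- (seq_len(T) - 1L) / (T * params$tr)
  freqs <- pmin(freqs, 1 / params$tr - freqs)
  keep <- freqs >= params$low & freqs <= params$high
  mask <- function(m) {
    ft <- t(stats::mvfft(t(m)))
    ft[, !keep] <- 0
    Re(t(stats::mvfft(t(ft), inverse = TRUE))) / T
  }
  out <- mask(detr)
  # remove the in-band image of the ramp so the operator is a projection
  u <- drop(mask(matrix(xm, 1L)))
  uu <- sum(u^2)
  if (uu > .Machine$double.eps * sum(xm^2)) {
    out <- out - ((out %*% u) / uu) %*% t(u)
  }
  out
}

#' Nuisance regression
#'
#' Replaces each channel by the residuals of a least-squares fit on the
#' nuisance regressors plus an intercept (the voxelwise regression of CSF,
#' white-matter, soft-tissue and motion time courses). Rank-deficient
#' regressor sets have their dependent columns dropped with a warning.
#'
#' @param series channels x T matrix.
#' @param nuisance K x T matrix of nuisance time courses.
#' @return channels x T residual matrix, orthogonal to every regressor.
#' @export
nuisance_regression <- function(series, nuisance) {
  stopifnot(is.matrix(series), is.matrix(nuisance),
            ncol(series) == ncol(nuisance))
  T <- ncol(series)
  if (nrow(nuisance) >= T) stop("need fewer regressors than time points")
  if (any(!is.finite(nuisance))) stop("non-finite nuisance regressors")
  X <- cbind(1, t(nuisance))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    warning("dropping ", ncol(X) - qx$rank, " linearly dependent nuisance column(s)")
  }
  t(qr.resid(qx, t(series)))
}

#' Framewise displacement
#'
#' Per-frame head-motion magnitude from the six rigid-body parameters: the
#' root-mean-square of the six frame-to-frame parameter differences, with
#' rotations converted to arc length at `rotation_radius` mm. FD of the first
#' frame is 0 by definition. `variant = "power"` instead returns the L1 sum of
#' absolute differences (the convention of the scrubbing literature).
#'
#' @param motion 6 x T matrix: rows 1-3 translations (mm), rows 4-6 rotations
#'   (radians).
#' @param rotation_radius Sphere radius in mm for the rotation-to-arc
#'   conversion (default 50).
#' @param variant "rms" (default) or "power" (L1).
#' @return Numeric vector of length T.
#' @export
framewise_displacement <- function(motion, rotation_radius = 50,
                                   variant = c("rms", "power")) {
  variant <- match.arg(variant)
  stopifnot(is.matrix(motion), nrow(motion) == 6L)
  T <- ncol(motion)
  if (T < 2L) stop("need at least 2 frames")
  conv <- motion
  conv[4:6, ] <- conv[4:6, ] * rotation_radius
  d <- conv[, -1L, drop = FALSE] - conv[, -T, drop = FALSE]
  fd <- switch(variant,
               rms = sqrt(colMeans(d^2)),
               power = colSums(abs(d)))
  c(0, fd)
}

#' DVARS
#'
#' Root-mean-square over channels of the temporal signal derivative,
#' optionally divided by the global standard deviation of the series so that a
#' single mm-scale threshold remains meaningful on normalized data.
#' DVARS of the first frame is 0 by definition.
#'
#' @param series channels x T matrix.
#' @param scale Divisor applied to the raw RMS; `"global_sd"` (default) uses
#'   the standard deviation of all samples, a number disables scaling when set
#'   to 1.
#' @return Numeric vector of length T.
#' @export
dvars <- function(series, scale = "global_sd") {
  stopifnot(is.matrix(series))
  T <- ncol(series)
  if (T < 2L) stop("need at least 2 frames")
  d <- series[, -1L, drop = FALSE] - series[, -T, drop = FALSE]
  dv <- sqrt(colMeans(d^2))
  div <- if (identical(scale, "global_sd")) {
    s <- stats::sd(as.vector(series))
    if (s > 0) s else 1
  } else as.numeric(scale)
  c(0, dv / div)
}

#' Motion scrubbing
#'
#' Removes every frame whose framewise displacement or DVARS exceeds the
#' threshold, together with `drop_before`/`drop_after` neighbors, and
#' concatenates the survivors.
#'
#' @param series channels x T matrix.
#' @param fd Framewise displacement, length T.
#' @param dv DVARS, length T (optional; `NULL` scrubs on FD alone).
#' @param params A [scrub_params()] object.
#' @return List with `series` (channels x T'), `mask` (logical length T,
#'   TRUE = retained) and `n_retained`.
#' @export
scrub <- function(series, fd, dv = NULL, params = scrub_params()) {
  stopifnot(inherits(params, "fcloo_scrub_params"), is.matrix(series))
  T <- ncol(series)
  stopifnot(length(fd) == T, is.null(dv) || length(dv) == T)
  bad <- fd > params$threshold
  if (!is.null(dv)) bad <- bad | dv > params$threshold
  flag <- bad
  for (t in which(bad)) {
    lo <- max(1L, t - params$drop_before)
    hi <- min(T, t + params$drop_after)
    flag[lo:hi] <- TRUE
  }
  if (all(flag)) stop("all frames removed by scrubbing (retained count 0)")
  list(series = series[, !flag, drop = FALSE],
       mask = !flag,
       n_retained = sum(!flag))
}

#' Retained-volume summary statistics
#'
#' Summarizes motion scrubbing over a cohort: the fraction of subjects
#' retaining more than 50% of acquired volumes (overall and per diagnosis,
#' with a two-proportion z-test), and a pooled two-sample t-test on the
#' retained counts by diagnosis. A zero-variance degenerate case is flagged
#' rather than producing infinite statistics.
#'
#' @param phenotypes Phenotype data.frame with `diagnosis`,
#'   `n_volumes_acquired`, and `n_volumes_retained`.
#' @return List with `fraction_over_half`, `fraction_by_group`,
#'   `proportion_test` (z, p), `count_test` (t, df, p, degenerate flag).
#' @export
retained_volume_stats <- function(phenotypes) {
  ph <- phenotypes
  stopifnot(all(c("diagnosis", "n_volumes_acquired", "n_volumes_retained")
                %in% names(ph)))
  if (any(is.na(ph$n_volumes_retained)) || any(is.na(ph$n_volumes_acquired))) {
    stop("retained and acquired volume counts must be present")
  }
  aut <- ph$diagnosis == "autism"
  if (!any(aut) || all(aut)) stop("both diagnosis groups must be non-empty")
  over <- ph$n_volumes_retained / ph$n_volumes_acquired > 0.5
  k1 <- sum(over[aut]); n1 <- sum(aut)
  k2 <- sum(over[!aut]); n2 <- sum(!aut)
  prop <- two_proportion_z(k1, n1, k2, n2)

  ra <- ph$n_volumes_retained[aut]
  rc <- ph$n_volumes_retained[!aut]
  df <- n1 + n2 - 2L
  sp2 <- (sum((ra - mean(ra))^2) + sum((rc - mean(rc))^2)) / df
  degenerate <- sp2 <= 0
  tt <- if (degenerate && mean(ra) == mean(rc)) 0 else if (degenerate) NA_real_ else {
    (mean(ra) - mean(rc)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  pt_ <- if (is.na(tt)) NA_real_ else 2 * stats::pt(-abs(tt), df)
  list(fraction_over_half = mean(over),
       fraction_by_group = c(autism = k1 / n1, control = k2 / n2),
       proportion_test = prop,
       count_test = list(t = tt, df = df, p = pt_, degenerate = degenerate))
}
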