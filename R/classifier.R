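# Leave-one-out dual-group GLM classifier.
#
# For each left-out subject and each connection: fit a general linear model
# (intercept + age + age^2 + gender + handedness) separately to the remaining
# autism and control subjects, predict the left-out subject's value from each
# fit, shift both estimates by the site mean offset, and score the connection
# as (|x - est_control| - |x - est_autism|) * F with F = t^2 from the pooled
# two-sample t-test between the remaining groups. Connection scores are
# averaged over the connections incident to each ROI and the per-ROI averages
# summed into the classification score: positive predicts autism, negative
# control. No connectivity value of the left-out subject enters any fit,
# F statistic, selection p-value or site mean — only its own x in the score.

#' Covariate design matrix
#'
#' Builds the classifier design: intercept, age, age-squared, a female
#' indicator, and left/ambidextrous handedness indicators (right-handed is the
#' reference level).
#'
#' @param phenotypes Phenotype data.frame with non-missing age, gender and
#'   handedness (impute handedness first, see [impute_handedness()]).
#' @return n x 6 numeric matrix.
#' @export
covariate_matrix <- function(phenotypes) {
  ph <- phenotypes
  if (any(is.na(ph$age) | is.na(ph$gender) | is.na(ph$handedness))) {
    stop("missing covariate values; impute handedness before classification")
  }
  cbind(intercept = 1,
        age = ph$age,
        age_sq = ph$age^2,
        female = as.numeric(ph$gender == "female"),
        hand_left = as.numeric(ph$handedness == "left"),
        hand_ambi = as.numeric(ph$handedness == "ambidextrous"))
}

# QR of a group design with rank bookkeeping. Rank-deficient columns (e.g. a
# single-gender group) are dropped by pivoting; a group smaller than its
# retained column count + 1 falls back to the intercept-only mean model.
design_qr <- function(X) {
  qx <- qr(X)
  dropped <- if (qx$rank < ncol(X)) sort(qx$pivot[-seq_len(qx$rank)]) else integer(0)
  degenerate <- nrow(X) < qx$rank + 1L
  if (degenerate) {
    qx <- qr(X[, 1L, drop = FALSE])
    dropped <- 2:ncol(X)
  }
  list(qr = qx, dropped = dropped, degenerate = degenerate, p = ncol(X))
}

# multivariate coefficients from a design_qr; rows = design columns (dropped
# or degenerate columns contribute 0 to predictions)
fit_coef <- function(dq, Y) {
  B <- qr.coef(dq$qr, Y)
  if (!is.matrix(B)) B <- matrix(B, ncol = NCOL(Y))
  if (dq$degenerate && dq$p > 1L) {
    B <- rbind(B, matrix(0, dq$p - 1L, ncol(B)))
  }
  B[is.na(B)] <- 0
  B
}

#' Fit a single-connection group model
#'
#' Least-squares fit of one group's connection values on the classifier
#' covariates. Rank-deficient columns are dropped (recorded in `dropped`);
#' a group with fewer subjects than retained columns + 1 is flagged degenerate
#' and falls back to the group-mean model.
#'
#' @param values Numeric vector of the group's values for one connection.
#' @param covariates Covariate matrix for the same subjects
#'   (see [covariate_matrix()]).
#' @return List of class `fcloo_group_fit`: `coefficients` (named, NA for
#'   dropped columns), `dropped`, `degenerate`, `n_fit`, `residual_df`.
#' @export
fit_group_model <- function(values, covariates) {
  stopifnot(length(values) >= 2L, all(is.finite(values)),
            nrow(covariates) == length(values))
  dq <- design_qr(covariates)
  B <- qr.coef(dq$qr, values)
  coefs <- rep(NA_real_, ncol(covariates))
  names(coefs) <- colnames(covariates)
  if (dq$degenerate) {
    coefs[1L] <- mean(values)
  } else {
    coefs[seq_along(B)] <- B
  }
  structure(list(coefficients = coefs, dropped = dq$dropped,
                 degenerate = dq$degenerate, n_fit = length(values),
                 residual_df = length(values) - dq$qr$rank),
            class = "fcloo_group_fit")
}

#' Predict a left-out subject's value from a group fit
#'
#' Linear combination of fitted coefficients and the subject's covariates;
#' dropped (NA) coefficients contribute 0. Degenerate fits return the group
#' mean.
#'
#' @param fit A `fcloo_group_fit`.
#' @param covariates Numeric covariate vector (same columns as the fit).
#' @return Scalar estimate.
#' @export
predict_group_model <- function(fit, covariates) {
  stopifnot(inherits(fit, "fcloo_group_fit"))
  b <- fit$coefficients
  if (any(is.na(covariates))) stop("missing covariate for prediction")
  b[is.na(b)] <- 0
  sum(b * covariates)
}

#' Site mean offset for one connection
#'
#' The difference between the target site's mean value (excluding the left-out
#' subject) and the mean over subjects at all other sites. Both group
#' estimates for the left-out subject are shifted by this offset, so
#' systematic per-site shifts in connectivity do not bias the comparison with
#' the subject's own (site-shifted) value.
#'
#' @param values Per-subject values for one connection.
#' @param sites Site labels, same length.
#' @param target_site Site of the left-out subject.
#' @param exclude Index of the left-out subject in `values`.
#' @return Scalar offset; 0 with a warning for a single-site dataset.
#' @export
site_offset <- function(values, sites, target_site, exclude) {
  in_site <- sites == target_site
  other <- !in_site
  if (!any(other)) {
    warning("single-site dataset: site offset defined as 0")
    return(0)
  }
  keep <- in_site
  keep[exclude] <- FALSE
  if (!any(keep)) stop("target site needs >= 2 subjects")
  mean(values[keep]) - mean(values[other])
}

#' Two-sample connection statistics
#'
#' Pooled-variance two-sample t statistic (df = n1 + n2 - 2), two-tailed
#' p-value, and the weighting statistic F = t^2. A zero pooled variance is
#' flagged degenerate: the connection gets F = 0 and is excluded from
#' p-value-based selection.
#'
#' @param values_aut,values_ctl Group value vectors (each length >= 2).
#' @return List: `t`, `F`, `p`, `df`, `degenerate`.
#' @export
connection_stats <- function(values_aut, values_ctl) {
  n1 <- length(values_aut); n2 <- length(values_ctl)
  stopifnot(n1 >= 2L, n2 >= 2L)
  df <- n1 + n2 - 2L
  m1 <- mean(values_aut); m2 <- mean(values_ctl)
  sp2 <- (sum((values_aut - m1)^2) + sum((values_ctl - m2)^2)) / df
  if (sp2 <= 0) {
    return(list(t = NA_real_, F = 0, p = NA_real_, df = df, degenerate = TRUE))
  }
  tt <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, F = tt^2, p = 2 * stats::pt(-abs(tt), df), df = df,
       degenerate = FALSE)
}

#' F-weighted connection score
#'
#' `(|x - est_ctl| - |x - est_aut|) * F`: proximity of the subject's value to
#' the autism estimate yields a positive contribution, so more negative
#' classification scores predict control and more positive predict autism.
#'
#' @param x The left-out subject's value for the connection.
#' @param est_aut,est_ctl Site-adjusted group estimates.
#' @param F Weighting statistic (`t^2`).
#' @return Scalar score.
#' @export
score_connection <- function(x, est_aut, est_ctl, F) {
  (abs(x - est_ctl) - abs(x - est_aut)) * F
}

# ---- leave-one-out engine ---------------------------------------------------

# Per-cohort precomputation shared across left-out subjects.
loo_prepare <- function(cohort) {
  ph <- cohort$phenotypes
  V <- cohort$values
  n <- nrow(V)
  aut <- which(ph$diagnosis == "autism")
  ctl <- which(ph$diagnosis == "control")
  if (length(aut) < 3L || length(ctl) < 3L) {
    stop("need >= 2 autism and >= 2 control subjects after leaving one out")
  }
  X <- covariate_matrix(ph)
  sites <- ph$site
  site_levels <- unique(sites)
  site_sum <- rowsum(V, sites, reorder = FALSE)   # per-site column sums
  site_n <- as.vector(table(sites)[rownames(site_sum)])
  list(V = V, X = X, n = n, aut = aut, ctl = ctl,
       sites = sites, site_levels = rownames(site_sum),
       site_sum = site_sum, site_n = site_n,
       total_sum = colSums(V),
       # full-group fits and moments, reused when the left-out subject is in
       # the other group
       qr_aut = design_qr(X[aut, , drop = FALSE]),
       qr_ctl = design_qr(X[ctl, , drop = FALSE]),
       B_aut = NULL, B_ctl = NULL,
       sum_aut = colSums(V[aut, , drop = FALSE]),
       sum_ctl = colSums(V[ctl, , drop = FALSE]),
       ssq_aut = colSums(V[aut, , drop = FALSE]^2),
       ssq_ctl = colSums(V[ctl, , drop = FALSE]^2))
}

# group moments with one subject removed (or not, if the subject is not in
# the group)
group_moments <- function(sum_g, ssq_g, n_g, v_s = NULL) {
  if (!is.null(v_s)) {
    sum_g <- sum_g - v_s
    ssq_g <- ssq_g - v_s^2
    n_g <- n_g - 1L
  }
  mean_g <- sum_g / n_g
  css_g <- ssq_g - n_g * mean_g^2
  list(mean = mean_g, css = css_g, n = n_g)
}

# Per-connection scores, F, and p for one left-out subject. Only the left-out
# subject's own x enters the score; fits, moments and site means exclude it.
loo_subject <- function(prep, s) {
  V <- prep$V; X <- prep$X
  in_aut <- s %in% prep$aut
  x <- V[s, ]
  x0 <- X[s, ]

  if (in_aut) {
    own <- setdiff(prep$aut, s)
    dq_own <- design_qr(X[own, , drop = FALSE])
    B_aut <- fit_coef(dq_own, V[own, , drop = FALSE])
    if (is.null(prep$B_ctl)) {
      prep$B_ctl <- fit_coef(prep$qr_ctl, V[prep$ctl, , drop = FALSE])
    }
    B_ctl <- prep$B_ctl
    ma <- group_moments(prep$sum_aut, prep$ssq_aut, length(prep$aut), x)
    mc <- group_moments(prep$sum_ctl, prep$ssq_ctl, length(prep$ctl))
  } else {
    own <- setdiff(prep$ctl, s)
    dq_own <- design_qr(X[own, , drop = FALSE])
    B_ctl <- fit_coef(dq_own, V[own, , drop = FALSE])
    if (is.null(prep$B_aut)) {
      prep$B_aut <- fit_coef(prep$qr_aut, V[prep$aut, , drop = FALSE])
    }
    B_aut <- prep$B_aut
    mc <- group_moments(prep$sum_ctl, prep$ssq_ctl, length(prep$ctl), x)
    ma <- group_moments(prep$sum_aut, prep$ssq_aut, length(prep$aut))
  }

  est_aut <- drop(x0 %*% B_aut)
  est_ctl <- drop(x0 %*% B_ctl)

  # site mean offset (excluding the left-out subject from its own site mean)
  si <- match(prep$sites[s], prep$site_levels)
  if (length(prep$site_levels) > 1L) {
    if (prep$site_n[si] < 2L) {
      stop("site ", prep$site_levels[si],
           " has a single subject; cannot form its leave-one-out site mean")
    }
    own_mean <- (prep$site_sum[si, ] - x) / (prep$site_n[si] - 1L)
    other_mean <- (prep$total_sum - prep$site_sum[si, ]) /
      (prep$n - prep$site_n[si])
    offset <- own_mean - other_mean
  } else {
    offset <- 0
  }
  est_aut <- est_aut + offset
  est_ctl <- est_ctl + offset

  df <- ma$n + mc$n - 2L
  sp2 <- (ma$css + mc$css) / df
  degenerate <- sp2 <= 0
  se <- sqrt(sp2 * (1 / ma$n + 1 / mc$n))
  tt <- (ma$mean - mc$mean) / se
  tt[degenerate] <- NA_real_
  Fstat <- tt^2
  Fstat[degenerate] <- 0
  p <- 2 * stats::pt(-abs(tt), df)

  score <- (abs(x - est_ctl) - abs(x - est_aut)) * Fstat
  score[degenerate] <- 0
  list(score = score, F = Fstat, p = p, prep = prep)
}

# Mean of scores over the incident connections of each ROI (ROIs with no
# incident connection in the subset contribute 0), summed over ROIs.
aggregate_roi_scores <- function(score, subset, pairs, n_roi) {
  if (!length(subset)) return(0)
  g <- c(pairs$i[subset], pairs$j[subset]) + 1L
  v <- c(score[subset], score[subset])
  sums <- rowsum(v, g, reorder = FALSE)
  cnts <- rowsum(rep(1, length(g)), g, reorder = FALSE)
  sum(sums / cnts)
}

#' Select discriminative connections for one left-out subject
#'
#' The subset of connections whose two-tailed pooled t-test between the
#' remaining autism and control subjects has p < `alpha`. The subset is
#' computed on the remaining subjects only and is therefore (slightly)
#' different for every left-out subject.
#'
#' @param cohort An `fcloo_cohort`.
#' @param left_out Subject id or row index.
#' @param alpha Selection threshold in (0, 1).
#' @return Integer vector of connection indices (canonical order).
#' @export
select_connections <- function(cohort, left_out, alpha) {
  stopifnot(alpha > 0, alpha <= 1)
  s <- subject_row(cohort, left_out)
  prep <- loo_prepare(cohort)
  res <- loo_subject(prep, s)
  if (alpha == 1) which(!is.na(res$p)) else which(!is.na(res$p) & res$p < alpha)
}

subject_row <- function(cohort, subject) {
  i <- if (is.character(subject)) {
    match(subject, cohort$phenotypes$subject_id)
  } else as.integer(subject)
  if (is.na(i) || i < 1L || i > nrow(cohort$values)) stop("unknown subject")
  i
}

#' Classification score for one left-out subject
#'
#' Runs the full scoring chain for a single subject: dual-group GLM fits and
#' F statistics on the remaining subjects, site-adjusted estimates, F-weighted
#' connection scores, per-ROI averaging and the ROI sum.
#'
#' @param cohort An `fcloo_cohort`.
#' @param left_out Subject id or row index.
#' @param subset Connection indices to use (default all), e.g. from
#'   [select_connections()].
#' @return List: `score`, `n_connections_used`, `empty_subset` flag.
#' @export
classify_left_out <- function(cohort, left_out, subset = NULL) {
  s <- subject_row(cohort, left_out)
  prep <- loo_prepare(cohort)
  res <- loo_subject(prep, s)
  pairs <- connection_pairs(nrow(cohort$rois))
  if (is.null(subset)) subset <- seq_along(res$score)
  if (!length(subset)) {
    return(list(score = 0, n_connections_used = 0L, empty_subset = TRUE))
  }
  list(score = aggregate_roi_scores(res$score, subset, pairs, nrow(cohort$rois)),
       n_connections_used = length(subset),
       empty_subset = FALSE)
}

#' Leave-one-out classification scores for a cohort
#'
#' One score per subject, each computed with that subject fully held out of
#' the group fits, F statistics, connection selection and site means; the
#' subject's own connectivity enters only as the value x being scored.
#'
#' @param cohort An `fcloo_cohort`.
#' @param subset_rule `"all"` (default), `"alpha"` (connections with selection
#'   p < `alpha`), or `"fixed"` (the connection set in `subset`).
#' @param alpha Selection threshold for `subset_rule = "alpha"`.
#' @param subset Connection index vector for `subset_rule = "fixed"`.
#' @param threshold_mode `"zero"` (predict autism iff score > 0, default) or
#'   `"roc"` (Youden-optimal threshold on the score vector).
#' @param keep_connection_level If TRUE, attach the per-subject connection
#'   score/p matrices as attributes (`connection_scores`, `connection_p`) for
#'   downstream per-ROI and per-bin analyses.
#' @return data.frame of class `fcloo_loo_result` with columns subject_id,
#'   site, actual, score, predicted, n_connections_used, empty_subset;
#'   attribute `threshold` holds the threshold used.
#' @export
loo_scores <- function(cohort, subset_rule = c("all", "alpha", "fixed"),
                       alpha = NULL, subset = NULL,
                       threshold_mode = c("zero", "roc"),
                       keep_connection_level = FALSE) {
  subset_rule <- match.arg(subset_rule)
  threshold_mode <- match.arg(threshold_mode)
  if (subset_rule == "alpha") stopifnot(!is.null(alpha), alpha > 0, alpha <= 1)
  if (subset_rule == "fixed") stopifnot(!is.null(subset))
  ph <- cohort$phenotypes
  n <- nrow(ph)
  R <- nrow(cohort$rois)
  pairs <- connection_pairs(R)
  prep <- loo_prepare(cohort)

  scores <- numeric(n)
  used <- integer(n)
  empty <- logical(n)
  conn_scores <- if (keep_connection_level) {
    matrix(NA_real_, n, ncol(cohort$values))
  }
  conn_p <- if (keep_connection_level) matrix(NA_real_, n, ncol(cohort$values))

  for (s in seq_len(n)) {
    res <- loo_subject(prep, s)
    prep <- res$prep  # caches the full-group fit after first use
    sel <- switch(subset_rule,
                  all = seq_along(res$score),
                  alpha = which(!is.na(res$p) & res$p < alpha),
                  fixed = subset)
    if (length(sel)) {
      scores[s] <- aggregate_roi_scores(res$score, sel, pairs, R)
    } else {
      empty[s] <- TRUE
    }
    used[s] <- length(sel)
    if (keep_connection_level) {
      conn_scores[s, ] <- res$score
      conn_p[s, ] <- res$p
    }
  }

  thr <- threshold_scores(scores, ph$diagnosis, mode = threshold_mode)
  predicted <- thr$predicted
  # empty-subset fallback: score 0, predict the majority class of the others
  if (any(empty)) {
    for (s in which(empty)) {
      others <- ph$diagnosis[-s]
      predicted[s] <- names(sort(table(others), decreasing = TRUE))[1L]
    }
  }
  out <- data.frame(subject_id = ph$subject_id, site = ph$site,
                    actual = ph$diagnosis, score = scores,
                    predicted = predicted, n_connections_used = used,
                    empty_subset = empty, stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr$threshold
  attr(out, "threshold_mode") <- threshold_mode
  if (keep_connection_level) {
    attr(out, "connection_scores") <- conn_scores
    attr(out, "connection_p") <- conn_p
  }
  class(out) <- c("fcloo_loo_result", "data.frame")
  out
}

#' Naive per-connection reference implementation
#'
#' A deliberately slow, connection-by-connection re-implementation of
#' [loo_scores()] used as an independent correctness oracle: every fit,
#' statistic, site mean and aggregation is recomputed from scratch with
#' scalar operations. Intended for small cohorts (R <= 20, n <= 40).
#'
#' @inheritParams loo_scores
#' @return data.frame with subject_id, actual, score.
#' @export
loo_scores_reference <- function(cohort, subset_rule = c("all", "alpha"),
                                 alpha = NULL) {
  subset_rule <- match.arg(subset_rule)
  ph <- cohort$phenotypes
  V <- cohort$values
  n <- nrow(ph)
  R <- nrow(cohort$rois)
  C <- ncol(V)
  pairs <- connection_pairs(R)
  X <- covariate_matrix(ph)
  scores <- numeric(n)
  for (s in seq_len(n)) {
    rest <- setdiff(seq_len(n), s)
    aut <- rest[ph$diagnosis[rest] == "autism"]
    ctl <- rest[ph$diagnosis[rest] == "control"]
    sc <- numeric(C)
    pv <- rep(NA_real_, C)
    for (c_ in seq_len(C)) {
      fa <- fit_group_model(V[aut, c_], X[aut, , drop = FALSE])
      fc <- fit_group_model(V[ctl, c_], X[ctl, , drop = FALSE])
      ea <- predict_group_model(fa, X[s, ])
      ec <- predict_group_model(fc, X[s, ])
      o <- if (length(unique(ph$site)) > 1L) {
        site_offset(V[, c_], ph$site, ph$site[s], s)
      } else 0
      st <- connection_stats(V[aut, c_], V[ctl, c_])
      pv[c_] <- st$p
      sc[c_] <- if (st$degenerate) 0 else {
        score_connection(V[s, c_], ea + o, ec + o, st$F)
      }
    }
    sel <- if (subset_rule == "all") seq_len(C) else which(!is.na(pv) & pv < alpha)
    roi_vals <- numeric(R)
    for (r in seq_len(R)) {
      inc <- sel[pairs$i[sel] == r - 1L | pairs$j[sel] == r - 1L]
      if (length(inc)) roi_vals[r] <- mean(sc[inc])
    }
    scores[s] <- sum(roi_vals)
  }
  data.frame(subject_id = ph$subject_id, actual = ph$diagnosis, score = scores,
             stringsAsFactors = FALSE)
}

#' Per-ROI leave-one-out accuracy
#'
#' Accuracy of the classifier when, for each ROI, only the connections
#' incident to that ROI are used (no p-value threshold), with the score
#' thresholded at 0 — the region-level map of where discriminative
#' information lives. Also reports a conservative multiple-comparison display
#' floor: the smallest accuracy whose exact binomial tail p-value, Bonferroni
#' corrected across the R ROIs, is below `q`.
#'
#' @param cohort An `fcloo_cohort`.
#' @param q Level for the display floor (default 0.05).
#' @return List: `accuracy` (data.frame roi_id, accuracy, n_correct),
#'   `display_floor`.
#' @export
per_roi_accuracy <- function(cohort, q = 0.05) {
  res <- loo_scores(cohort, subset_rule = "all", keep_connection_level = TRUE)
  sc <- attr(res, "connection_scores")
  R <- nrow(cohort$rois)
  n <- nrow(sc)
  pairs <- connection_pairs(R)
  acc <- numeric(R)
  ncor <- integer(R)
  for (r in seq_len(R)) {
    inc <- which(pairs$i == r - 1L | pairs$j == r - 1L)
    s_r <- vapply(seq_len(n), function(s) {
      aggregate_roi_scores(sc[s, ], inc, pairs, R)
    }, numeric(1L))
    pred <- ifelse(s_r > 0, "autism", "control")
    ncor[r] <- sum(pred == res$actual)
    acc[r] <- ncor[r] / n
  }
  floor_k <- binomial_critical_count(n, q / R)
  list(accuracy = data.frame(roi_id = seq_len(R) - 1L, accuracy = acc,
                             n_correct = ncor),
       display_floor = floor_k / n)
}

#' Per-bin leave-one-out accuracy
#'
#' Classification accuracy within each strength-by-distance bin: the score of
#' each subject is recomputed using only the connections of the bin
#' (thresholded at 0). Bins with no connections are absent from the output.
#'
#' @param cohort An `fcloo_cohort`.
#' @param bins data.frame from [assign_strength_distance_bins()], one row per
#'   connection.
#' @return data.frame: z_bin, d_bin, n_connections, n_correct, accuracy.
#' @export
per_bin_accuracy <- function(cohort, bins) {
  stopifnot(nrow(bins) == ncol(cohort$values))
  res <- loo_scores(cohort, subset_rule = "all", keep_connection_level = TRUE)
  sc <- attr(res, "connection_scores")
  R <- nrow(cohort$rois)
  pairs <- connection_pairs(R)
  key <- paste(bins$z_bin, bins$d_bin)
  groups <- split(seq_len(nrow(bins)), key)
  out <- lapply(groups, function(sel) {
    s_b <- vapply(seq_len(nrow(sc)), function(s) {
      aggregate_roi_scores(sc[s, ], sel, pairs, R)
    }, numeric(1L))
    pred <- ifelse(s_b > 0, "autism", "control")
    data.frame(z_bin = bins$z_bin[sel[1L]], d_bin = bins$d_bin[sel[1L]],
               n_connections = length(sel),
               n_correct = sum(pred == res$actual),
               accuracy = mean(pred == res$actual))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$z_bin, out$d_bin), ]
}
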