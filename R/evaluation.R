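#' Threshold classification scores
#'
#' `mode = "zero"` predicts autism for scores strictly above 0. `mode = "roc"`
#' scans all candidate thresholds (midpoints between adjacent sorted scores,
#' plus the extremes) and picks the one maximizing sensitivity + specificity
#' (the Youden-optimal operating point of the ROC curve), breaking ties toward
#' the smaller threshold.
#'
#' @param scores Numeric classification scores.
#' @param labels Actual diagnosis, values "autism"/"control".
#' @param mode `"zero"` or `"roc"`.
#' @return List: `predicted` (character vector), `threshold`, `degenerate`
#'   (TRUE when all scores are equal under roc).
#' @export
threshold_scores <- function(scores, labels, mode = c("zero", "roc")) {
  mode <- match.arg(mode)
  if (mode == "zero") {
    thr <- 0
    degenerate <- FALSE
  } else {
    stopifnot(all(c("autism", "control") %in% labels))
    u <- sort(unique(scores))
    if (length(u) == 1L) {
      thr <- u
      degenerate <- TRUE
    } else {
      degenerate <- FALSE
      cand <- c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
      best <- -Inf
      thr <- cand[1L]
      for (tc in cand) {
        pred <- scores > tc
        sens <- mean(pred[labels == "autism"])
        spec <- mean(!pred[labels == "control"])
        if (sens + spec > best + 1e-12) {
          best <- sens + spec
          thr <- tc
        }
      }
    }
  }
  list(predicted = ifelse(scores > thr, "autism", "control"),
       threshold = thr, degenerate = degenerate)
}

#' Evaluate predictions against diagnoses
#'
#' Accuracy, sensitivity (autism correctly identified), specificity (controls
#' correctly identified), and the exact one-sided binomial tail probability
#' P(X >= n_correct | n, 1/2) measuring whether accuracy beats chance.
#'
#' @param predictions,labels Character vectors ("autism"/"control") of equal
#'   length.
#' @return List of class `fcloo_evaluation`: n, n_correct, accuracy,
#'   sensitivity, specificity, binomial_p.
#' @export
evaluate_classification <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  n <- length(labels)
  correct <- predictions == labels
  aut <- labels == "autism"
  ctl <- labels == "control"
  out <- list(
    n = n,
    n_correct = sum(correct),
    accuracy = mean(correct),
    sensitivity = if (any(aut)) mean(correct[aut]) else NA_real_,
    specificity = if (any(ctl)) mean(correct[ctl]) else NA_real_,
    binomial_p = stats::pbinom(sum(correct) - 1L, n, 0.5, lower.tail = FALSE))
  class(out) <- "fcloo_evaluation"
  out
}

#' @export
print.fcloo_evaluation <- function(x, ...) {
  cat(sprintf(
    "accuracy %.1f%% (%d/%d), sensitivity %.1f%%, specificity %.1f%%, binomial p = %.3g\n",
    100 * x$accuracy, x$n_correct, x$n, 100 * x$sensitivity,
    100 * x$specificity, x$binomial_p))
  invisible(x)
}

#' Critical correct-count for significant accuracy
#'
#' The smallest number of correct predictions k such that the exact binomial
#' tail P(X >= k | n, 1/2) falls below `alpha` — e.g. 509 of 964 subjects
#' (52.8%) for alpha = 0.05 and 531 (55.1%) for alpha = 0.001.
#'
#' @param n Number of subjects.
#' @param alpha Significance level in (0, 0.5).
#' @return Integer count.
#' @export
binomial_critical_count <- function(n, alpha) {
  stopifnot(n >= 1, alpha > 0, alpha < 0.5)
  k <- seq(ceiling(n / 2), n)
  tail <- stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
  k[which(tail < alpha)[1L]]
}

#' Two-proportion z-test
#'
#' Pooled-proportion z statistic for k1/n1 vs k2/n2 with a two-tailed normal
#' p-value. A pooled proportion of exactly 0 or 1 is degenerate (z = 0,
#' flagged).
#'
#' @param k1,n1,k2,n2 Successes and totals of the two groups.
#' @return List: `z`, `p`, `degenerate`.
#' @export
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  pp <- (k1 + k2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    return(list(z = 0, p = 1, degenerate = TRUE))
  }
  z <- (k1 / n1 - k2 / n2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Correlations between classifier scores and behavioral measures
#'
#' Pearson correlation (pairwise-complete) of the per-subject classification
#' score with each behavioral measure, with the usual t-transform p-value on
#' n - 2 degrees of freedom. Measures with fewer than 3 complete pairs are
#' reported missing.
#'
#' @param scores Per-subject classification scores.
#' @param phenotypes Phenotype data.frame aligned with `scores`.
#' @param measures Behavioral columns to test (default all seven).
#' @return data.frame: measure, r, p, n.
#' @export
behavior_correlations <- function(scores, phenotypes,
                                  measures = BEHAVIOR_MEASURES) {
  stopifnot(length(scores) == nrow(phenotypes))
  rows <- lapply(measures, function(m) {
    y <- phenotypes[[m]]
    ok <- !is.na(y) & !is.na(scores)
    if (sum(ok) < 3L || stats::sd(y[ok]) == 0 || stats::sd(scores[ok]) == 0) {
      return(data.frame(measure = m, r = NA_real_, p = NA_real_, n = sum(ok)))
    }
    r <- stats::cor(scores[ok], y[ok])
    nn <- sum(ok)
    tt <- r * sqrt((nn - 2) / (1 - r^2))
    data.frame(measure = m, r = r, p = 2 * stats::pt(-abs(tt), nn - 2), n = nn)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg pass mask
#'
#' Step-up false-discovery-rate control at level `q`.
#'
#' @param pvalues Numeric p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return Logical vector: TRUE where the hypothesis is rejected.
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  stopifnot(all(pvalues > 0 & pvalues <= 1))
  stats::p.adjust(pvalues, method = "BH") <= q
}

#' Site-level accuracy correlates
#'
#' Pearson correlations of per-site classification accuracy with the number
#' of imaging volumes and with site sample size — the site-level analysis of
#' what drives multisite accuracy.
#'
#' @param site_accuracy Per-site accuracy.
#' @param site_volumes Per-site acquired volume count.
#' @param site_n Per-site subject count.
#' @return List with `volumes` and `sample_size`, each (r, p), plus a
#'   `degenerate` flag when accuracies are constant.
#' @export
site_accuracy_analysis <- function(site_accuracy, site_volumes, site_n) {
  stopifnot(length(site_accuracy) >= 3L,
            length(site_volumes) == length(site_accuracy),
            length(site_n) == length(site_accuracy))
  if (stats::sd(site_accuracy) == 0) {
    return(list(volumes = c(r = NA_real_, p = NA_real_),
                sample_size = c(r = NA_real_, p = NA_real_),
                degenerate = TRUE))
  }
  one <- function(x) {
    if (stats::sd(x) == 0) return(c(r = NA_real_, p = NA_real_))
    ct <- stats::cor.test(site_accuracy, x)
    c(r = unname(ct$estimate), p = ct$p.value)
  }
  list(volumes = one(site_volumes), sample_size = one(site_n),
       degenerate = FALSE)
}

#' Per-site accuracy table from a leave-one-out result
#'
#' @param loo_result Result of [loo_scores()].
#' @return data.frame: site, n, n_correct, accuracy.
#' @export
site_accuracy <- function(loo_result) {
  stopifnot(inherits(loo_result, "fcloo_loo_result"))
  correct <- loo_result$predicted == loo_result$actual
  agg <- stats::aggregate(correct, by = list(site = loo_result$site),
                          FUN = function(x) c(n = length(x), k = sum(x)))
  data.frame(site = agg$site, n = agg$x[, "n"], n_correct = agg$x[, "k"],
             accuracy = agg$x[, "k"] / agg$x[, "n"])
}
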