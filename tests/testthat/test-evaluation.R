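test_that("zero and ROC thresholds behave on separable scores", {
  scores <- c(-1, -2, 1, 2)
  labels <- c("control", "control", "autism", "autism")
  z <- threshold_scores(scores, labels, mode = "zero")
  expect_equal(z$predicted, labels)
  expect_equal(z$threshold, 0)
  r <- threshold_scores(scores, labels, mode = "roc")
  expect_equal(r$predicted, labels)   # same predictions when 0 separates
  # constant scores flagged degenerate under roc
  d <- threshold_scores(rep(1, 4), labels, mode = "roc")
  expect_true(d$degenerate)
})

test_that("ROC threshold equals an exhaustive midpoint scan", {
  set.seed(9)
  for (rep_ in 1:5) {
    scores <- rnorm(20)
    labels <- sample(c("autism", "control"), 20, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    got <- threshold_scores(scores, labels, mode = "roc")
    # oracle: brute-force over all candidate cuts
    u <- sort(unique(scores))
    cand <- c(u[1] - 1, (u[-1] + u[-length(u)]) / 2, u[length(u)] + 1)
    j <- sapply(cand, function(th) {
      pred <- scores > th
      mean(pred[labels == "autism"]) + mean(!pred[labels == "control"])
    })
    expect_equal(got$threshold, cand[which.max(j)])
  }
})

test_that("evaluation computes rates and the exact binomial tail", {
  labels <- rep(c("autism", "control"), 5)
  ev <- evaluate_classification(labels, labels)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$binomial_p, 2^-10, tolerance = 1e-12)
  flipped <- ifelse(labels == "autism", "control", "autism")
  ev2 <- evaluate_classification(flipped, labels)
  expect_equal(ev2$accuracy, 0)
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$specificity, 0)
  # accuracy identity
  set.seed(10)
  pred <- sample(c("autism", "control"), 10, replace = TRUE)
  ev3 <- evaluate_classification(pred, labels)
  nA <- sum(labels == "autism"); nC <- sum(labels == "control")
  expect_equal(ev3$accuracy,
               (ev3$sensitivity * nA + ev3$specificity * nC) / 10)
})

test_that("critical counts reproduce the published 964-subject boundaries", {
  expect_equal(binomial_critical_count(964, 0.05), 509)
  expect_equal(round(100 * 509 / 964, 1), 52.8)
  expect_equal(binomial_critical_count(964, 0.001), 531)
  expect_equal(round(100 * 531 / 964, 1), 55.1)
  # boundary behavior of the evaluation p-value
  pred509 <- rep(c("autism", "control"), c(509, 455))
  lab <- rep("autism", 964)
  expect_lt(evaluate_classification(pred509, lab)$binomial_p, 0.05)
  pred508 <- rep(c("autism", "control"), c(508, 456))
  expect_gte(evaluate_classification(pred508, lab)$binomial_p, 0.05)
})

test_that("critical counts match a log-space summation oracle", {
  # independent oracle: exact tail by stable log-space accumulation
  log_tail <- function(k, n) {
    lp <- lchoose(n, k:n) - n * log(2)
    m <- max(lp)
    m + log(sum(exp(lp - m)))
  }
  oracle <- function(n, alpha) {
    for (k in ceiling(n / 2):n) {
      if (log_tail(k, n) < log(alpha)) return(k)
    }
  }
  for (case in list(c(100, 0.05), c(100, 0.001), c(250, 0.01))) {
    expect_equal(binomial_critical_count(case[1], case[2]),
                 oracle(case[1], case[2]))
  }
  expect_equal(binomial_critical_count(100, 0.05), 59)
})

test_that("critical fraction is monotone and tends to one half", {
  expect_true(binomial_critical_count(964, 0.001) >=
                binomial_critical_count(964, 0.01))
  expect_true(binomial_critical_count(964, 0.01) >=
                binomial_critical_count(964, 0.05))
  fr <- sapply(c(100, 964, 10000), function(n) {
    binomial_critical_count(n, 0.05) / n
  })
  expect_true(all(diff(fr) < 0))
  expect_lt(fr[3] - 0.5, 0.01)
})

test_that("two-proportion z-test matches hand evaluation", {
  eq <- two_proportion_z(5, 10, 10, 20)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  t1 <- two_proportion_z(8, 10, 2, 10)
  expect_equal(t1$z, 2.683282, tolerance = 1e-6)
  expect_equal(t1$p, 0.0072904, tolerance = 1e-5)
  # antisymmetry
  t2 <- two_proportion_z(2, 10, 8, 10)
  expect_equal(t2$z, -t1$z)
  expect_equal(t2$p, t1$p)
  # degenerate pooled proportion
  expect_true(two_proportion_z(0, 5, 0, 5)$degenerate)
})

test_that("behavior correlations are pairwise-complete Pearson tests", {
  set.seed(11)
  n <- 40
  scores <- rnorm(n)
  ph <- data.frame(srs_total = scores,
                   verbal_iq = rnorm(n),
                   vineland_composite = c(rep(NA, 38), 1, 2))
  ph[, setdiff(fcloo:::BEHAVIOR_MEASURES, names(ph))] <- NA_real_
  out <- behavior_correlations(scores, ph)
  expect_equal(out$r[out$measure == "srs_total"], 1)
  # insufficient pairs reported missing
  expect_true(is.na(out$r[out$measure == "vineland_composite"]))
  expect_true(is.na(out$r[out$measure == "ados_social_comm"]))
  # p matches cor.test
  ct <- cor.test(scores, ph$verbal_iq)
  expect_equal(out$p[out$measure == "verbal_iq"], ct$p.value, tolerance = 1e-10)
})

test_that("null behavior correlations have uniform p-values", {
  set.seed(12)
  ps <- replicate(200, {
    s <- rnorm(50); y <- rnorm(50)
    ph <- data.frame(srs_total = y)
    ph[, setdiff(fcloo:::BEHAVIOR_MEASURES, names(ph))] <- NA_real_
    b <- behavior_correlations(s, ph)
    b$p[b$measure == "srs_total"]
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("Benjamini-Hochberg step-up passes the hand-traced set", {
  expect_equal(fdr_bh(c(0.001, 0.02, 0.03, 0.5), 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_true(all(fdr_bh(rep(0.001, 10), 0.05)))
  expect_false(any(fdr_bh(rep(1, 5), 0.05)))
  # BH pass set contains the Bonferroni pass set
  set.seed(13)
  p <- runif(50)^2
  bh <- fdr_bh(p, 0.05)
  bonf <- p <= 0.05 / length(p)
  expect_true(all(bh[bonf]))
})

test_that("site accuracy correlates behave and ignore site order", {
  acc <- c(0.5, 0.6, 0.7, 0.8)
  vols <- c(100, 150, 200, 250)
  n <- c(30, 25, 40, 20)
  out <- site_accuracy_analysis(acc, vols, n)
  expect_equal(unname(out$volumes["r"]), 1)
  perm <- c(3, 1, 4, 2)
  out2 <- site_accuracy_analysis(acc[perm], vols[perm], n[perm])
  expect_equal(out$volumes, out2$volumes)
  expect_equal(out$sample_size, out2$sample_size)
  expect_true(site_accuracy_analysis(rep(0.5, 3), vols[1:3], n[1:3])$degenerate)
})
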