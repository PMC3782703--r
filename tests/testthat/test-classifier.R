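make_design <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", 1:n),
    site = sample(c("A", "B"), n, replace = TRUE),
    diagnosis = sample(c("autism", "control"), n, replace = TRUE),
    age = runif(n, 6, 60),
    gender = sample(c("male", "female"), n, replace = TRUE),
    handedness = sample(c("right", "left", "ambidextrous"), n,
                        replace = TRUE, prob = c(0.8, 0.15, 0.05)),
    stringsAsFactors = FALSE)
}

test_that("group model fits recover exact and degenerate structure", {
  ph <- make_design(12)
  X <- covariate_matrix(ph)
  # constant values: intercept only
  f <- fit_group_model(rep(2.5, 12), X)
  expect_equal(unname(f$coefficients["intercept"]), 2.5)
  expect_equal(unname(f$coefficients[c("age", "age_sq", "female")]),
               rep(0, 3), tolerance = 1e-10)
  expect_equal(predict_group_model(f, X[3, ]), 2.5, tolerance = 1e-10)
  # exact linear signal in age
  f2 <- fit_group_model(2 * ph$age, X)
  expect_equal(unname(f2$coefficients["age"]), 2, tolerance = 1e-10)
  expect_equal(predict_group_model(f2, X[5, ]), 2 * ph$age[5],
               tolerance = 1e-8)
  # degenerate group: fewer subjects than columns -> mean model
  f3 <- fit_group_model(c(1, 3), X[1:2, ])
  expect_true(f3$degenerate)
  expect_equal(predict_group_model(f3, X[4, ]), 2)
})

test_that("fit coefficients equal the explicit normal-equations solution", {
  ph <- make_design(40, seed = 2)
  X <- covariate_matrix(ph)
  set.seed(3)
  y <- rnorm(40)
  f <- fit_group_model(y, X)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(f$coefficients), as.vector(beta), tolerance = 1e-8)
  # prediction is the dot product
  expect_equal(predict_group_model(f, X[7, ]),
               sum(f$coefficients * X[7, ]), tolerance = 1e-12)
})

test_that("rank-deficient covariate columns are dropped, not fatal", {
  ph <- make_design(15, seed = 4)
  ph$gender <- "male"          # constant column collides with intercept
  ph$handedness <- "right"
  X <- covariate_matrix(ph)
  set.seed(5)
  f <- fit_group_model(rnorm(15), X)
  expect_true(length(f$dropped) >= 3)
  expect_true(all(is.na(f$coefficients[f$dropped])))
  expect_true(is.finite(predict_group_model(f, X[2, ])))
})

test_that("site offsets exclude the left-out subject and other sites", {
  values <- c(1, 1, 1, 99, 0.4, 0.4, 0.4)
  sites <- c("A", "A", "A", "A", "B", "B", "C")
  expect_equal(site_offset(values, sites, "A", exclude = 4), 1 - 0.4)
  # invariant to the excluded subject's own value
  values2 <- values; values2[4] <- -123
  expect_equal(site_offset(values2, sites, "A", 4),
               site_offset(values, sites, "A", 4))
  # equal site means give zero offset
  expect_equal(site_offset(rep(2, 7), sites, "A", 1), 0)
  # single-site data: zero with a warning
  expect_warning(o <- site_offset(values, rep("A", 7), "A", 1), "single-site")
  expect_equal(o, 0)
})

test_that("connection statistics match the pooled two-sample t-test", {
  st <- connection_stats(c(1, 2, 3), c(4, 5, 6))
  expect_equal(st$t, -3.6742346, tolerance = 1e-6)
  expect_equal(st$p, 0.0213116, tolerance = 1e-5)
  expect_equal(st$F, st$t^2)
  expect_equal(st$df, 4L)
  # identical groups
  st0 <- connection_stats(c(1, 2), c(1, 2))
  expect_equal(st0$t, 0)
  expect_equal(st0$p, 1)
  # scale invariance of t and p
  st2 <- connection_stats(2 * c(1, 2, 3), 2 * c(4, 5, 6))
  expect_equal(st2$t, st$t)
  expect_equal(st2$p, st$p)
  # zero pooled variance flagged with F = 0
  stz <- connection_stats(c(1, 1), c(1, 1))
  expect_true(stz$degenerate)
  expect_equal(stz$F, 0)
})

test_that("connection scores follow the sign convention", {
  # proximity to the autism estimate is positive
  expect_gt(score_connection(x = 0.5, est_aut = 0.5, est_ctl = 0.1, F = 2), 0)
  expect_equal(score_connection(0.3, 0.7, 0.7, F = 5), 0)
  expect_equal(score_connection(0.1, 0, 0.3, F = 4), (0.2 - 0.1) * 4)
})

test_that("connection selection calibrates on null data and finds planted effects", {
  null <- small_cohort(seed = 31, n_roi = 30, delta = 0, site_offset_sd = 0,
                       n_sites = 2, subjects_per_site = 30, autism_per_site = 15)
  sel <- select_connections(null$cohort, 1, alpha = 0.01)
  C <- n_connections(30)
  band <- qbinom(c(0.005, 0.995), C, 0.01)
  expect_gte(length(sel), band[1])
  expect_lte(length(sel), band[2])
  # alpha = 1 keeps every testable connection
  expect_equal(length(select_connections(null$cohort, 1, alpha = 1)), C)
  # planted effects are enriched among selected connections
  pl <- small_cohort(seed = 32, n_roi = 30, delta = 0.8,
                     subject_noise_sd = 0.15, n_sites = 2,
                     subjects_per_site = 30, autism_per_site = 15)
  sel2 <- select_connections(pl$cohort, 5, alpha = 0.01)
  aff <- pl$truth$affected_idx
  tab <- matrix(c(sum(sel2 %in% aff), sum(!(aff %in% sel2)),
                  sum(!(sel2 %in% aff)), C - length(union(sel2, aff))), 2)
  expect_lt(fisher.test(tab)$p.value, 0.01)
})

test_that("leave-one-out hygiene: the left-out subject's values touch only x", {
  sc <- small_cohort(seed = 33)
  co <- sc$cohort
  s <- 4L
  r1 <- loo_scores(co, subset_rule = "all", keep_connection_level = TRUE)
  # replace the left-out subject's connectivity with arbitrary numbers
  co2 <- co
  set.seed(99)
  co2$values[s, ] <- rnorm(ncol(co2$values), 5, 3)
  r2 <- loo_scores(co2, subset_rule = "all", keep_connection_level = TRUE)
  # selection p-values for subject s are untouched (fits, F, site means too)
  expect_equal(attr(r1, "connection_p")[s, ], attr(r2, "connection_p")[s, ])
  # and its score changes only through the x term of score_connection:
  # score difference per connection is bounded by F * |x1 - x2|
  expect_equal(select_connections(co, s, 0.05), select_connections(co2, s, 0.05))
})

test_that("scores are invariant to subject order", {
  sc <- small_cohort(seed = 34)
  co <- sc$cohort
  r1 <- loo_scores(co, subset_rule = "all")
  set.seed(1)
  perm <- sample(nrow(co$values))
  co2 <- cohort_dataset(co$phenotypes[perm, ], co$values[perm, ], co$rois)
  r2 <- loo_scores(co2, subset_rule = "all")
  expect_equal(r2$score[match(r1$subject_id, r2$subject_id)], r1$score,
               tolerance = 1e-10)
})

test_that("production classifier equals the naive per-connection reference", {
  sc <- small_cohort(seed = 35, n_roi = 10, n_sites = 3,
                     subjects_per_site = 10, autism_per_site = 5)
  co <- sc$cohort
  for (rule in list(list(r = "all", a = NULL), list(r = "alpha", a = 0.05))) {
    prod <- loo_scores(co, subset_rule = rule$r, alpha = rule$a)
    ref <- loo_scores_reference(co, subset_rule = rule$r, alpha = rule$a)
    expect_lt(max(abs(prod$score - ref$score)),
              1e-10 * max(1, max(abs(ref$score))))
  }
})

test_that("empty connection subsets fall back to the majority class", {
  sc <- small_cohort(seed = 36, n_sites = 2, subjects_per_site = 12,
                     autism_per_site = 5)  # controls are the majority
  r <- loo_scores(sc$cohort, subset_rule = "fixed", subset = integer(0))
  expect_true(all(r$empty_subset))
  expect_true(all(r$score == 0))
  expect_true(all(r$predicted == "control"))
  cl <- classify_left_out(sc$cohort, 1, subset = integer(0))
  expect_true(cl$empty_subset)
  expect_equal(cl$score, 0)
})

test_that("classify_left_out agrees with loo_scores row by row", {
  sc <- small_cohort(seed = 37)
  co <- sc$cohort
  r <- loo_scores(co, subset_rule = "all")
  for (s in c(1L, 7L, 20L)) {
    expect_equal(classify_left_out(co, s)$score, r$score[s], tolerance = 1e-12)
  }
})

test_that("per-ROI accuracy equals rerunning on incident connection subsets", {
  sc <- small_cohort(seed = 38, n_roi = 5, n_sites = 2,
                     subjects_per_site = 12, autism_per_site = 6)
  co <- sc$cohort
  out <- per_roi_accuracy(co)
  pairs <- connection_pairs(5)
  for (r in 0:4) {
    inc <- which(pairs$i == r | pairs$j == r)
    ref <- loo_scores(co, subset_rule = "fixed", subset = inc)
    acc <- mean(ref$predicted == ref$actual)
    expect_equal(out$accuracy$accuracy[r + 1], acc)
  }
  expect_true(out$display_floor > 0.5 && out$display_floor <= 1)
})

test_that("per-bin accuracy partitions connections and matches the whole", {
  sc <- small_cohort(seed = 39, n_roi = 8, n_sites = 2,
                     subjects_per_site = 12, autism_per_site = 6)
  co <- sc$cohort
  C <- ncol(co$values)
  # single bin: equals whole-matrix accuracy
  one <- data.frame(z_bin = rep(0L, C), d_bin = rep(0L, C))
  pb <- per_bin_accuracy(co, one)
  whole <- loo_scores(co, subset_rule = "all")
  expect_equal(pb$accuracy, mean(whole$predicted == whole$actual))
  expect_equal(pb$n_connections, C)
  # a real binning partitions the connections disjointly
  set.seed(2)
  ref_z <- rnorm(C, 0.2, 0.2)
  bins <- assign_strength_distance_bins(ref_z, connection_distances(co$rois))
  pb2 <- per_bin_accuracy(co, bins)
  expect_equal(sum(pb2$n_connections), C)
})

test_that("accuracy rises with effect size on planted cohorts", {
  accs <- sapply(c(0, 1.5), function(d) {
    sc <- small_cohort(seed = 40, n_roi = 20, n_sites = 2,
                       subjects_per_site = 20, autism_per_site = 10,
                       delta = d, subject_noise_sd = 0.15)
    r <- loo_scores(sc$cohort, subset_rule = "all")
    mean(r$predicted == r$actual)
  })
  expect_gt(accs[2], accs[1])
  expect_gt(accs[2], 0.9)
})
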