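#' Pipeline configuration
#'
#' Assembles and validates the configuration of [run_pipeline()]: simulation
#' parameters, preprocessing and binning settings, the connection-subset rule,
#' threshold mode, significance levels and the master seed. Printing the
#' object shows every default.
#'
#' @param sim A [sim_params()] object (its seed is overridden by `seed`).
#' @param bandpass A [bandpass_params()] object.
#' @param scrub A [scrub_params()] object.
#' @param bins A [bin_spec()] object.
#' @param subset_rule `"all"` or `"alpha"`.
#' @param alpha_sweep Selection thresholds evaluated when
#'   `subset_rule = "alpha"` (default the conventional four:
#'   0.01, 0.001, 1e-4, 1e-5).
#' @param threshold_mode `"zero"` or `"roc"`.
#' @param q FDR level for multiple-comparison corrections.
#' @param seed Master seed; all stage randomness derives from it.
#' @param out Output directory for artifacts (`NULL` = no files written).
#' @param write_matrices If TRUE, write every subject's association matrix in
#'   the binary container (off by default to keep runs light).
#' @return List of class `fcloo_config`.
#' @export
pipeline_config <- function(sim = sim_params(),
                            bandpass = bandpass_params(),
                            scrub = scrub_params(),
                            bins = bin_spec(),
                            subset_rule = c("alpha", "all"),
                            alpha_sweep = c(0.01, 0.001, 1e-4, 1e-5),
                            threshold_mode = c("zero", "roc"),
                            q = 0.05,
                            seed = 1L,
                            out = NULL,
                            write_matrices = FALSE) {
  subset_rule <- match.arg(subset_rule)
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(all(alpha_sweep > 0), all(alpha_sweep <= 1), q > 0, q < 1)
  structure(list(sim = sim, bandpass = bandpass, scrub = scrub, bins = bins,
                 subset_rule = subset_rule, alpha_sweep = alpha_sweep,
                 threshold_mode = threshold_mode, q = q,
                 seed = as.integer(seed), out = out,
                 write_matrices = write_matrices),
            class = "fcloo_config")
}

#' @export
print.fcloo_config <- function(x, ...) {
  cat("fcloo pipeline configuration\n")
  cat("  seed:", x$seed, "\n")
  cat("  subset rule:", x$subset_rule,
      if (x$subset_rule == "alpha") paste0("(alpha sweep: ",
                                           paste(x$alpha_sweep, collapse = ", "), ")"),
      "\n")
  cat("  threshold mode:", x$threshold_mode, ", FDR q:", x$q, "\n")
  s <- x$sim
  cat("  cohort: R =", s$n_roi, ",", s$n_sites, "site(s) x",
      paste(unique(s$subjects_per_site), collapse = "/"), "subjects, delta =",
      s$delta, ", effect fraction =", s$effect_fraction, "\n")
  cat("  bandpass:", x$bandpass$low, "-", x$bandpass$high, "Hz, TR",
      x$bandpass$tr, "s; scrub threshold:", x$scrub$threshold, "mm\n")
  invisible(x)
}

log_line <- function(log, stage, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", stage, "] ",
                paste0(..., collapse = ""))
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
  invisible(msg)
}

#' Run the end-to-end pipeline
#'
#' simulate -> classify -> evaluate on a synthetic multisite cohort, with
#' fixed-seed reproducibility: the same configuration and seed produce
#' byte-identical artifacts. Stages write their outputs (phenotypes, ground
#' truth, score tables, evaluation summaries, site and behavior analyses) and
#' a manifest recording parameters and md5 hashes of every artifact.
#'
#' @param config A [pipeline_config()] object.
#' @return Invisibly, a list with the cohort, per-alpha leave-one-out results
#'   and evaluations, site accuracy analysis, behavior correlations and
#'   retained-volume statistics.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "fcloo_config"))
  out_dir <- config$out
  log <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    log <- file.path(out_dir, "pipeline.log")
    cat("", file = log)
  }
  artifacts <- character(0)

  # -- simulate ---------------------------------------------------------------
  sim <- config$sim
  sim$seed <- config$seed
  stage <- "simulate"
  t0 <- Sys.time()
  simres <- simulate_cohort(sim)
  cohort <- simres$cohort
  if (any(is.na(cohort$phenotypes$handedness))) {
    cohort$phenotypes <- impute_handedness(cohort$phenotypes)
  }
  log_line(log, stage, "cohort of ", nrow(cohort$phenotypes), " subjects, ",
           ncol(cohort$values), " connections, ",
           length(simres$truth$affected_idx), " affected (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s)")
  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "phenotypes.tsv")
    write_phenotypes(cohort$phenotypes, f)
    artifacts <- c(artifacts, f)
    f <- file.path(out_dir, "rois.tsv")
    write_roi_set(cohort$rois, f)
    artifacts <- c(artifacts, f)
    f <- file.path(out_dir, "ground_truth_connections.tsv")
    utils::write.table(
      data.frame(i = simres$truth$affected_pairs[, "i"],
                 j = simres$truth$affected_pairs[, "j"]),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
    if (config$write_matrices) {
      mdir <- file.path(out_dir, "matrices")
      dir.create(mdir, showWarnings = FALSE)
      for (i in seq_len(nrow(cohort$values))) {
        write_assoc_matrix(assoc_matrix(cohort, i),
                           file.path(mdir, paste0(cohort$phenotypes$subject_id[i],
                                                  ".fcz")))
      }
    }
  }

  # -- preprocess accounting --------------------------------------------------
  retained <- retained_volume_stats(cohort$phenotypes)
  log_line(log, "preprocess",
           sprintf("%.1f%% of subjects retain >50%% of volumes",
                   100 * retained$fraction_over_half))

  # -- classify ---------------------------------------------------------------
  stage <- "classify"
  t0 <- Sys.time()
  runs <- list()
  if (config$subset_rule == "all") {
    runs[["all"]] <- loo_scores(cohort, subset_rule = "all",
                                threshold_mode = config$threshold_mode)
  } else {
    runs[["all"]] <- loo_scores(cohort, subset_rule = "all",
                                threshold_mode = config$threshold_mode)
    for (a in config$alpha_sweep) {
      runs[[paste0("p", a)]] <- loo_scores(cohort, subset_rule = "alpha",
                                           alpha = a,
                                           threshold_mode = config$threshold_mode)
    }
  }
  log_line(log, stage, length(runs), " subset rule(s) scored (",
           round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s); ",
           "mean selected connections: ",
           paste(vapply(runs, function(r) round(mean(r$n_connections_used)),
                        numeric(1L)), collapse = ", "))
  if (!is.null(out_dir)) {
    for (nm in names(runs)) {
      f <- file.path(out_dir, paste0("scores_", nm, ".tsv"))
      df <- runs[[nm]]
      df$score <- sprintf("%.12g", df$score)
      utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, f)
    }
  }

  # -- evaluate ---------------------------------------------------------------
  stage <- "evaluate"
  evals <- lapply(runs, function(r) {
    evaluate_classification(r$predicted, r$actual)
  })
  eval_table <- data.frame(
    subset = names(evals),
    n = vapply(evals, `[[`, numeric(1L), "n"),
    n_correct = vapply(evals, `[[`, numeric(1L), "n_correct"),
    accuracy = vapply(evals, `[[`, numeric(1L), "accuracy"),
    sensitivity = vapply(evals, `[[`, numeric(1L), "sensitivity"),
    specificity = vapply(evals, `[[`, numeric(1L), "specificity"),
    binomial_p = vapply(evals, `[[`, numeric(1L), "binomial_p"))
  best <- runs[[length(runs)]]
  sa <- site_accuracy(best)
  ph <- cohort$phenotypes
  site_vol <- stats::aggregate(ph$n_volumes_acquired,
                               by = list(site = ph$site), FUN = mean)
  sa <- merge(sa, site_vol, by = "site")
  names(sa)[names(sa) == "x"] <- "mean_volumes"
  site_corr <- if (nrow(sa) >= 3L) {
    site_accuracy_analysis(sa$accuracy, sa$mean_volumes, sa$n)
  }
  behav <- behavior_correlations(best$score, ph)
  behav$fdr_pass <- FALSE
  ok <- !is.na(behav$p)
  if (any(ok)) behav$fdr_pass[ok] <- fdr_bh(behav$p[ok], config$q)
  log_line(log, stage, "best-rule accuracy ",
           sprintf("%.1f%%", 100 * eval_table$accuracy[nrow(eval_table)]),
           " (binomial p = ",
           format(eval_table$binomial_p[nrow(eval_table)], digits = 3), ")")

  if (!is.null(out_dir)) {
    f <- file.path(out_dir, "evaluation.tsv")
    ev <- eval_table
    for (cn in c("accuracy", "sensitivity", "specificity", "binomial_p")) {
      ev[[cn]] <- sprintf("%.10g", ev[[cn]])
    }
    utils::write.table(ev, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
    f <- file.path(out_dir, "site_accuracy.tsv")
    utils::write.table(sa, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
    f <- file.path(out_dir, "behavior_correlations.tsv")
    utils::write.table(behav, f, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, f)
    manifest <- list(
      seed = config$seed,
      subset_rule = config$subset_rule,
      alpha_sweep = config$alpha_sweep,
      threshold_mode = config$threshold_mode,
      sim = unclass(sim),
      artifacts = as.list(stats::setNames(
        unname(tools::md5sum(artifacts)), basename(artifacts))))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    } else {
      dput(manifest, file.path(out_dir, "manifest.txt"))
    }
  }

  invisible(list(cohort = cohort, truth = simres$truth, runs = runs,
                 evaluation = eval_table, site_accuracy = sa,
                 site_analysis = site_corr, behavior = behav,
                 retained = retained))
}
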