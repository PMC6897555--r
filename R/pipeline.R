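# End-to-end orchestration: generate stimuli, simulate a cohort, run the
# behavioral, CP and ERP analyses, optionally sweep the net model, and
# assemble cohort-level tables plus a reproducibility manifest.

#' Pipeline configuration
#'
#' Every analysis constant is surfaced here with its study default: the 80%
#' criterion over 20-trial windows sustained for at least 60 trials, the
#' +/-100 uV extreme-value limit, the 2/6 SD probability-filter limits, the
#' N1 (150-220 ms, occipital) and LPC (600-800 ms, parietal) windows, and
#' the 20% per-condition artifact exclusion rule.
#'
#' @param n_subjects Cohort size (default 12).
#' @param mix Archetype mix (see [gen_cohort()]).
#' @param k Covariant feature pairs for the stimulus set (default 4).
#' @param n_stimuli Stimulus-set size (default 180).
#' @param n_trials Trials per subject (default 400).
#' @param seed Master seed.
#' @param with_epochs Generate and analyze EEG epochs (default TRUE).
#' @param window_width,criterion,min_remaining_trials Learning-curve rule.
#' @param extreme_limit,single_sd,global_sd Artifact-rejection limits.
#' @param max_reject_frac Per-condition rejected-trial fraction above which
#'   a subject is excluded from ERP averages (default 0.2).
#' @param n1,lpc `"component_window"` definitions; defaults use the
#'   synthetic montage's occipital and parietal clusters.
#' @param net_sweep Optional list with `k_values` and `seeds` to also run
#'   [sweep_k()]; `NULL` (default) skips it.
#' @param out_dir Optional directory for CSV/JSON outputs.
#' @return A `"pipeline_config"` list.
#' @export
pipeline_config <- function(n_subjects = 12,
                            mix = c(Learner = 0.5, NonLearner = 0.4,
                                    Borderline = 0.1),
                            k = 4, n_stimuli = 180, n_trials = 400, seed = 1,
                            with_epochs = TRUE, window_width = 20,
                            criterion = 0.80, min_remaining_trials = 60,
                            extreme_limit = 100, single_sd = 2, global_sd = 6,
                            max_reject_frac = 0.2,
                            n1 = component_window("N1", c(150, 220),
                                                  occipital_cluster()),
                            lpc = component_window("LPC", c(600, 800),
                                                   parietal_cluster()),
                            net_sweep = NULL, out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Generates a stimulus set, schedule and rating pairs, simulates the cohort,
#' classifies every learning curve, computes per-subject CP statistics and
#' (when epochs are on) the baseline-corrected, artifact-filtered
#' before/after N1 and LPC cluster means, then assembles cohort tables and
#' the learning/ERP correlations. Per-subject failures are logged in the
#' manifest and skipped; the run continues.
#'
#' @param config A `"pipeline_config"`.
#' @return A `"pipeline_report"` list: `assessments`, `cp`, `erp`,
#'   `correlations` (data frames), optional `net_sweep`, and `manifest`.
#'   With `out_dir` set, the tables are also written as CSV plus a JSON
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(config$out_dir) && !dir.exists(config$out_dir)) {
    stop("missing output directory: ", config$out_dir)
  }
  seed <- config$seed
  scheme <- make_scheme(config$k, seed = derive_seed(seed, "scheme"))
  set <- make_set(scheme, n = config$n_stimuli,
                  seed = derive_seed(seed, "set"))
  schedule <- build_schedule(set, n_trials = config$n_trials,
                             seed = derive_seed(seed, "sched"))
  pairs <- sample_rating_pairs(set, seed = derive_seed(seed, "pairs"))
  cohort <- gen_cohort(config$n_subjects, mix = config$mix, seed = seed,
                       pairs = pairs, with_epochs = config$with_epochs,
                       n_trials = config$n_trials)

  assess_rows <- list(); cp_rows <- list(); erp_rows <- list()
  failures <- character(0); reject_log <- list()
  for (subj in cohort) {
    res <- tryCatch({
      acc <- window_accuracy(subj$log, width = config$window_width)
      assessment <- classify_learner(
        acc, width = config$window_width, criterion = config$criterion,
        min_remaining_trials = config$min_remaining_trials)
      blocks <- block_summaries(subj$log)
      stats_cp <- cp_stats(subj$ratings)
      arow <- data.frame(
        subject_id = subj$subject_id, archetype = subj$archetype,
        status = assessment$status, learning_point = assessment$learning_point,
        accuracy_last_block = blocks$accuracy[nrow(blocks)],
        mean_rt_last_block = blocks$mean_rt[nrow(blocks)]
      )
      crow <- data.frame(
        subject_id = subj$subject_id, status = assessment$status,
        Wpre = stats_cp$Wpre, Wpost = stats_cp$Wpost,
        Bpre = stats_cp$Bpre, Bpost = stats_cp$Bpost,
        diffW = stats_cp$diffW, diffB = stats_cp$diffB,
        global_cp = stats_cp$global_cp
      )
      erow <- NULL
      if (config$with_epochs && !is.null(subj$epochs)) {
        split <- split_trials(assessment, config$n_trials)
        if (!split$excluded) {
          ep <- baseline_correct(subj$epochs)
          r1 <- reject_extreme(ep, limit = config$extreme_limit)
          r2 <- reject_probability(r1$epochs, single_sd = config$single_sd,
                                   global_sd = config$global_sd)
          rejected <- union(r1$rejected,
                            r1$epochs$trials$trial[r2$rejected])
          reject_log[[subj$subject_id]] <- length(rejected)
          frac <- function(idx) mean(idx %in% rejected)
          if (frac(split$before) <= config$max_reject_frac &&
              frac(split$after) <= config$max_reject_frac) {
            erps <- split_and_average(r2$epochs, split$before, split$after)
            m <- function(erp, cw) component_mean(erp, cw)$mean_voltage
            erow <- data.frame(
              subject_id = subj$subject_id, status = assessment$status,
              n1_before = m(erps$before, config$n1),
              n1_after = m(erps$after, config$n1),
              lpc_before = m(erps$before, config$lpc),
              lpc_after = m(erps$after, config$lpc),
              n_rejected = length(rejected)
            )
            erow$n1_change <- erow$n1_after - erow$n1_before
            erow$lpc_change <- erow$lpc_after - erow$lpc_before
          }
        }
      }
      list(arow = arow, crow = crow, erow = erow)
    }, error = function(e) {
      failures <<- c(failures, paste0(subj$subject_id, ": ",
                                      conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    assess_rows[[length(assess_rows) + 1]] <- res$arow
    cp_rows[[length(cp_rows) + 1]] <- res$crow
    if (!is.null(res$erow)) erp_rows[[length(erp_rows) + 1]] <- res$erow
  }
  assessments <- do.call(rbind, assess_rows)
  cp <- do.call(rbind, cp_rows)
  erp <- if (length(erp_rows) > 0) do.call(rbind, erp_rows) else NULL

  correlations <- NULL
  if (!is.null(erp) && nrow(erp) >= 4) {
    acc_last <- assessments$accuracy_last_block[
      match(erp$subject_id, assessments$subject_id)]
    corr_row <- function(label, x, y) {
      r <- tryCatch(spearman_fisher(x, y), error = function(e) NULL)
      if (is.null(r)) return(NULL)
      data.frame(contrast = label, rho = r$rho, n = r$n,
                 fisher_z = r$fisher_z, ci_low = r$ci95[1],
                 ci_high = r$ci95[2], p = r$p)
    }
    correlations <- rbind(
      corr_row("n1_change_vs_last_block_accuracy", erp$n1_change, acc_last),
      corr_row("lpc_change_vs_last_block_accuracy", erp$lpc_change, acc_last)
    )
  }

  net <- NULL
  if (!is.null(config$net_sweep)) {
    net <- sweep_k(config$net_sweep$k_values, config$net_sweep$seeds,
                   cfg = config$net_sweep$cfg %||% net_config())
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("catperc")),
    seed = seed, n_subjects = config$n_subjects, k = config$k,
    n_stimuli = config$n_stimuli, n_trials = config$n_trials,
    rejected_trials = reject_log, failures = failures
  )
  report <- structure(list(assessments = assessments, cp = cp, erp = erp,
                           correlations = correlations, net_sweep = net,
                           manifest = manifest),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    wr <- function(df, name) {
      if (!is.null(df)) {
        utils::write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
                         row.names = FALSE)
      }
    }
    wr(assessments, "assessments"); wr(cp, "cp_stats")
    wr(erp, "erp_measures"); wr(correlations, "correlations")
    wr(net, "net_sweep")
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", nrow(x$assessments), "subjects analyzed\n")
  print(table(x$assessments$status))
  if (!is.null(x$erp)) cat(nrow(x$erp), "subjects with ERP measures\n")
  if (length(x$manifest$failures) > 0) {
    cat("failures:\n "); cat(x$manifest$failures, sep = "\n ")
  }
  invisible(x)
}
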