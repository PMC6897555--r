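# Reported cohort outcomes of the two texture category-learning EEG
# experiments the toolkit models, shipped as plain-text tables. These are
# inputs for worked-example checks (effect sizes from printed t statistics,
# learner tallies per difficulty level), not outputs of this package.

#' Reported cohort outcome tables
#'
#' Loads the shipped plain-text summaries of the two category-learning
#' experiments: per-difficulty learner tallies for both cohorts
#' (`exp1_outcomes`, `exp2_outcomes`), the replication cohort's
#' dissimilarity-change statistics by group (`exp2_dissimilarity`), and the
#' exploratory cohort's ERP change statistics (`exp1_erp`). The t statistics
#' and degrees of freedom in the latter two feed the worked-example
#' effect-size computations (`d = t / sqrt(df + 1)`).
#'
#' @return Named list of data frames: `exp1_outcomes`, `exp2_outcomes`,
#'   `exp2_dissimilarity`, `exp1_erp`.
#' @export
#' @examples
#' tabs <- reference_outcomes()
#' sum(tabs$exp1_outcomes$learners)  # 28 learners across the four levels
reference_outcomes <- function() {
  rd <- function(name) {
    utils::read.csv(system.file("extdata", name, package = "catperc",
                                mustWork = TRUE),
                    stringsAsFactors = FALSE)
  }
  list(exp1_outcomes = rd("exp1_outcomes.csv"),
       exp2_outcomes = rd("exp2_outcomes.csv"),
       exp2_dissimilarity = rd("exp2_dissimilarity.csv"),
       exp1_erp = rd("exp1_erp.csv"))
}
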