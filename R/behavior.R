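# Behavioral analysis: learning-curve classification against the sustained
# 80% criterion, block summaries, dissimilarity-judgement CP statistics,
# effect sizes and rank correlations with Fisher-z intervals.

#' Per-window accuracy of a trial log
#'
#' Percentage correct in each consecutive, non-overlapping run of `width`
#' trials (20 by default), the unit in which learning curves are assessed.
#'
#' @param log A trial-log data frame with a logical/0-1 `correct` column
#'   (e.g. from [gen_trial_log()]).
#' @param width Window width in trials; `nrow(log)` must be divisible by it.
#' @return Numeric vector of per-window proportions in `[0, 1]`.
#' @export
window_accuracy <- function(log, width = 20) {
  correct <- as.numeric(log$correct)
  if (length(correct) == 0 || length(correct) %% width != 0) {
    stop("malformed log: trial count must be a positive multiple of width")
  }
  unname(colMeans(matrix(correct, nrow = width)))
}

#' Classify a learning curve
#'
#' A subject is a Learner if there is a first window `b` from which accuracy
#' stays at or above `criterion` through the end of training, with the
#' sustained run covering at least `min_remaining_trials` trials. The
#' learning point is the first trial of that window; a run starting at the
#' very first window makes the subject an Immediate Learner (learning point
#' 1). Subjects who touch the criterion in some window but do not sustain it
#' are Borderline; subjects who never reach it are Non-Learners.
#'
#' @param acc Per-window accuracies from [window_accuracy()].
#' @param width Window width in trials used to compute `acc`.
#' @param criterion Accuracy criterion (default 0.80).
#' @param min_remaining_trials Minimum trials the sustained run must cover
#'   (default 60, i.e. the run must begin at least 60 trials before the end).
#' @return A `"learning_assessment"`: list with `status` (one of
#'   `"Immediate"`, `"Learner"`, `"Borderline"`, `"NonLearner"`),
#'   `learning_point` (trial index, `NA` unless Immediate/Learner) and
#'   `window_accuracy`.
#' @export
classify_learner <- function(acc, width = 20, criterion = 0.80,
                             min_remaining_trials = 60) {
  if (length(acc) == 0) stop("malformed input: empty accuracy series")
  nb <- length(acc)
  sustained_from <- NA_integer_
  for (b in seq_len(nb)) {
    if (all(acc[b:nb] >= criterion) &&
        (nb - b + 1) * width >= min_remaining_trials) {
      sustained_from <- b
      break
    }
  }
  if (!is.na(sustained_from)) {
    status <- if (sustained_from == 1L) "Immediate" else "Learner"
    lp <- (sustained_from - 1L) * as.integer(width) + 1L
  } else {
    status <- if (any(acc >= criterion)) "Borderline" else "NonLearner"
    lp <- NA_integer_
  }
  structure(list(status = status, learning_point = lp,
                 window_accuracy = acc, width = as.integer(width),
                 criterion = criterion,
                 min_remaining_trials = min_remaining_trials),
            class = "learning_assessment")
}

#' @export
print.learning_assessment <- function(x, ...) {
  cat("Learning assessment:", x$status)
  if (!is.na(x$learning_point)) cat(" (learning point: trial", x$learning_point, ")")
  cat("\n", length(x$window_accuracy), "windows of", x$width, "trials; criterion",
      x$criterion, "\n")
  invisible(x)
}

#' Block-level accuracy and mean reaction time
#'
#' @param log Trial-log data frame with `correct` and `rt` columns.
#' @param block Block size in trials (default 100: four blocks of a
#'   400-trial session).
#' @return Data frame with one row per block: `block`, `accuracy`,
#'   `mean_rt`.
#' @export
block_summaries <- function(log, block = 100) {
  n <- nrow(log)
  if (n == 0 || n %% block != 0) {
    stop("malformed log: trial count must be a positive multiple of block")
  }
  idx <- rep(seq_len(n / block), each = block)
  data.frame(
    block = seq_len(n / block),
    accuracy = as.numeric(tapply(as.numeric(log$correct), idx, mean)),
    mean_rt = as.numeric(tapply(log$rt, idx, mean))
  )
}

#' Categorical-perception statistics from a rating table
#'
#' Averages the 1-9 dissimilarity ratings by pair type and phase and derives
#' the three CP variables: within-category change `diffW = Wpost - Wpre`,
#' between-category change `diffB = Bpost - Bpre`, and the composite
#' `global_cp = diffB - diffW`, which is amplified when between-category
#' separation and within-category compression co-occur.
#'
#' @param ratings Rating-table data frame with columns `pair_type`
#'   (`"within"`/`"between"`), `phase` (`"pre"`/`"post"`) and `rating`
#'   (integers 1-9), e.g. from [gen_ratings()].
#' @return A `"cp_stats"` list: `Wpre`, `Wpost`, `Bpre`, `Bpost`, `diffW`,
#'   `diffB`, `global_cp`.
#' @export
cp_stats <- function(ratings) {
  need <- expand.grid(pair_type = c("within", "between"),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  have <- unique(ratings[, c("pair_type", "phase")])
  for (i in seq_len(nrow(need))) {
    if (!any(have$pair_type == need$pair_type[i] & have$phase == need$phase[i])) {
      stop("incomplete table: missing ", need$pair_type[i], "/", need$phase[i],
           " ratings")
    }
  }
  m <- function(pt, ph) {
    mean(ratings$rating[ratings$pair_type == pt & ratings$phase == ph])
  }
  Wpre <- m("within", "pre"); Wpost <- m("within", "post")
  Bpre <- m("between", "pre"); Bpost <- m("between", "post")
  structure(list(Wpre = Wpre, Wpost = Wpost, Bpre = Bpre, Bpost = Bpost,
                 diffW = Wpost - Wpre, diffB = Bpost - Bpre,
                 global_cp = (Bpost - Bpre) - (Wpost - Wpre)),
            class = "cp_stats")
}

#' @export
print.cp_stats <- function(x, ...) {
  cat(sprintf("CP stats: Wpre=%.3f Wpost=%.3f Bpre=%.3f Bpost=%.3f\n",
              x$Wpre, x$Wpost, x$Bpre, x$Bpost))
  cat(sprintf("  diffW=%.3f diffB=%.3f GlobalCP=%.3f\n",
              x$diffW, x$diffB, x$global_cp))
  invisible(x)
}

#' Cohen's d from a paired t statistic
#'
#' For a paired design with `df` degrees of freedom (`n = df + 1` pairs),
#' `d = t / sqrt(n)`.
#'
#' @param t Paired t statistic.
#' @param df Degrees of freedom (`n - 1`), at least 1.
#' @param kind Design label carried on the result (`"paired"` default).
#' @return An `"effect_size"` list: `d`, `t`, `df`, `kind`.
#' @export
#' @examples
#' cohens_d_from_t(6.453, 17)$d  # 1.521...
cohens_d_from_t <- function(t, df, kind = "paired") {
  if (!is.numeric(df) || df < 1) stop("invalid input: df must be >= 1")
  structure(list(d = t / sqrt(df + 1), t = t, df = df, kind = kind),
            class = "effect_size")
}

#' Paired t test and effect size from raw samples
#'
#' Computes the paired t statistic and two algebraically identical paths to
#' Cohen's d: `mean(diff) / sd(diff)` and `t / sqrt(n)`.
#'
#' @param x,y Paired numeric samples of equal length (n >= 2).
#' @return An `"effect_size"` list with `d`, `t`, `df`, `mean_diff`,
#'   `sd_diff`, `kind = "paired"`.
#' @export
paired_effect <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  out <- cohens_d_from_t(t, n - 1)
  out$mean_diff <- mean(d)
  out$sd_diff <- stats::sd(d)
  out
}

#' Spearman correlation with a Fisher-z confidence interval
#'
#' Rank-order correlation with mid-rank ties; the 95% interval is formed on
#' the Fisher scale, `z = atanh(rho)`, as `z +/- 1.96 / sqrt(n - 3)`, and
#' back-transformed.
#'
#' @param x,y Numeric vectors of equal length, n >= 4, neither constant.
#' @return A `"correlation_result"` list: `rho`, `n`, `fisher_z`, `ci95`
#'   (length-2 vector), `p` (two-sided, via the t approximation).
#' @export
spearman_fisher <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant series")
  }
  rho <- stats::cor(rank(x), rank(y))
  z <- atanh(rho)
  ci <- tanh(z + c(-1, 1) * 1.96 / sqrt(n - 3))
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- if (abs(rho) >= 1) 0 else 2 * stats::pt(-abs(tstat), n - 2)
  structure(list(rho = rho, n = n, fisher_z = z, ci95 = ci, p = p),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho(%d) = %.3f, p = %.3g, Fisher z = %.4f, 95%% CI = [%.3f, %.3f]\n",
              x$n - 2, x$rho, x$p, x$fisher_z, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Split trials into before- and after-learning parts
#'
#' Learners are split at their learning point (before = trials strictly
#' before it); Non-Learners and Borderlines are split in half, so that their
#' first/second-half contrast controls for mere exposure. Immediate Learners
#' have an empty "before" part and are flagged for exclusion from
#' before/after ERP contrasts.
#'
#' @param assessment A `"learning_assessment"`.
#' @param n_trials Total number of trials in the session.
#' @return List with integer vectors `before` and `after` (a disjoint
#'   partition of `1:n_trials`) and logical `excluded`.
#' @export
split_trials <- function(assessment, n_trials) {
  stopifnot(inherits(assessment, "learning_assessment"))
  st <- assessment$status
  if (st %in% c("Immediate", "Learner")) {
    lp <- assessment$learning_point
    before <- seq_len(lp - 1)
    after <- if (lp <= n_trials) lp:n_trials else integer(0)
  } else {
    half <- floor(n_trials / 2)
    before <- seq_len(half)
    after <- (half + 1):n_trials
  }
  list(before = before, after = after,
       excluded = length(before) == 0 || length(after) == 0)
}
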