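# Independent oracles used across the suite. These deliberately use the
# dumbest possible formulation (exhaustive enumeration, double loops) so
# they stay independent of the implementation paths they check.

# Learning-curve classification by exhaustive enumeration of sustain runs.
oracle_classify <- function(acc, width = 20, criterion = 0.80,
                            min_remaining = 60) {
  nb <- length(acc)
  candidates <- integer(0)
  for (b in seq_len(nb)) {
    run_ok <- TRUE
    for (j in b:nb) if (acc[j] < criterion) { run_ok <- FALSE; break }
    if (run_ok && (nb - b + 1) * width >= min_remaining) {
      candidates <- c(candidates, b)
    }
  }
  if (length(candidates) > 0) {
    b <- min(candidates)
    list(status = if (b == 1) "Immediate" else "Learner",
         learning_point = (b - 1) * width + 1)
  } else if (any(acc >= criterion)) {
    list(status = "Borderline", learning_point = NA)
  } else {
    list(status = "NonLearner", learning_point = NA)
  }
}

# Mean pairwise Euclidean distances by pair type, as a double loop.
oracle_category_distances <- function(h, labels) {
  nb <- 0; nw <- 0; sb <- 0; sw <- 0
  for (i in seq_len(nrow(h) - 1)) {
    for (j in (i + 1):nrow(h)) {
      d <- sqrt(sum((h[i, ] - h[j, ])^2))
      if (labels[i] == labels[j]) { sw <- sw + d; nw <- nw + 1 }
      else { sb <- sb + d; nb <- nb + 1 }
    }
  }
  list(between = sb / nb, within = sw / nw)
}

# Spearman's coefficient by the textbook no-ties formula 1 - 6*sum(d^2)/(n(n^2-1)).
oracle_spearman_no_ties <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# A small deterministic epoch array with hand-controllable content.
toy_epochs <- function(n_chan = 4, n_samp = 100, n_trials = 8, srate = 100,
                       window = c(-0.5, 0.5), fill = 0,
                       channels = paste0("ch", seq_len(n_chan))) {
  epoch_array(array(fill, c(n_chan, n_samp, n_trials)), channels = channels,
              srate = srate, window = window)
}

# A trial log data frame from a plain correctness vector.
log_from_correct <- function(correct, rt = 1) {
  n <- length(correct)
  cat_seq <- rep(c("K", "L"), length.out = n)
  data.frame(trial = seq_len(n), stimulus_id = paste0("s", seq_len(n)),
             category = cat_seq,
             response = ifelse(correct, cat_seq,
                               ifelse(cat_seq == "K", "L", "K")),
             correct = as.logical(correct), rt = rep_len(rt, n))
}
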