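# Two-phase neural-network model of learned categorical perception:
# an unsupervised autoencoding phase over binary N-dimensional stimuli,
# then a supervised categorization phase with corrective feedback.
# CP is measured as the change in mean pairwise Euclidean distance between
# hidden-unit representations, between- vs within-category; dimensional
# reduction is tracked through per-input-dimension encoder weight norms.

#' Network configuration
#'
#' Architecture and training hyperparameters: `n_dims` binary input
#' dimensions of which `k_cov` covary with the category; a single layer of
#' `h` tanh hidden units whose activations lie strictly in (-1, 1); linear
#' reconstruction and category heads; full-batch gradient descent with
#' momentum and an L2 penalty on non-bias weights. A net counts as a
#' Learner when its final regularized mean squared error on the last layer
#' is at or below `success_threshold` (default 1e-3).
#'
#' @param n_dims Input dimensionality N (default 12).
#' @param k_cov Number of category-covariant dimensions, 1..n_dims.
#' @param h Hidden-unit count (default 8).
#' @param learning_rate Gradient-descent step size (default 0.1).
#' @param momentum Momentum coefficient (default 0.9).
#' @param epochs_unsup Autoencoding epochs (default 500).
#' @param epochs_sup Supervised epochs (default 3000).
#' @param l2_penalty L2 weight-decay coefficient (default 1e-5).
#' @param success_threshold Learner criterion on the last-layer regularized
#'   MSE (default 1e-3, inclusive).
#' @param freeze_encoder If TRUE the supervised phase trains only the
#'   category head; by default the encoder is fine-tuned.
#' @param seed Seed for weight initialization.
#' @return A `"net_config"` list.
#' @export
net_config <- function(n_dims = 12, k_cov = 4, h = 8, learning_rate = 0.1,
                       momentum = 0.9, epochs_unsup = 500, epochs_sup = 3000,
                       l2_penalty = 1e-5, success_threshold = 1e-3,
                       freeze_encoder = FALSE, seed = 1) {
  stopifnot(k_cov >= 1, k_cov <= n_dims, h >= 1, success_threshold > 0)
  structure(list(n_dims = as.integer(n_dims), k_cov = as.integer(k_cov),
                 h = as.integer(h), learning_rate = learning_rate,
                 momentum = momentum, epochs_unsup = as.integer(epochs_unsup),
                 epochs_sup = as.integer(epochs_sup), l2_penalty = l2_penalty,
                 success_threshold = success_threshold,
                 freeze_encoder = freeze_encoder, seed = seed),
            class = "net_config")
}

#' Generate binary category stimuli for the net
#'
#' A balanced two-category set of binary vectors: `k_cov` covariant
#' dimensions are fully determined by the category label (category 0 takes
#' value 0, category 1 takes value 1 on those dimensions) while the
#' remaining dimensions are independent fair draws.
#'
#' @param cfg A `"net_config"`.
#' @param n_per_category Items per category (default 40, >= 2).
#' @param seed Seed.
#' @return A `"binary_stimulus_set"`: list with `vectors`
#'   (2n x n_dims 0/1 matrix), `labels` (0/1), `covariant_dims` (indices).
#' @export
gen_binary_stimuli <- function(cfg, n_per_category = 40, seed = 1) {
  stopifnot(inherits(cfg, "net_config"), n_per_category >= 2)
  # the covariant-dimension set is part of the category structure, so it is
  # fixed by the config seed; `seed` only drives the item-level randomness
  cov_dims <- with_seed(derive_seed(cfg$seed, "covdims"),
                        sort(sample(cfg$n_dims, cfg$k_cov)))
  with_seed(derive_seed(seed, "binstim"), {
    n <- 2L * n_per_category
    labels <- rep(0:1, each = n_per_category)
    x <- matrix(stats::rbinom(n * cfg$n_dims, 1, 0.5), n, cfg$n_dims)
    x[, cov_dims] <- matrix(labels, n, cfg$k_cov)
    structure(list(vectors = x, labels = labels, covariant_dims = cov_dims),
              class = "binary_stimulus_set")
  })
}

# +/-1 input coding with a bias column
net_inputs <- function(x) cbind(1, 2 * x - 1)

init_state <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "init"), {
    r <- function(nr, nc) matrix(stats::runif(nr * nc, -0.3, 0.3), nr, nc)
    structure(list(
      We = r(cfg$n_dims + 1, cfg$h),   # input (+bias) -> hidden
      Wd = r(cfg$h + 1, cfg$n_dims),   # hidden (+bias) -> reconstruction
      Wc = r(cfg$h + 1, 1),            # hidden (+bias) -> category
      phase = "initialized", final_mse = NA_real_, cfg = cfg
    ), class = "net_state")
  })
}

no_bias <- function(w) { w[1, ] <- 0; w }

#' Hidden-unit representations of a stimulus set
#'
#' @param state A `"net_state"`.
#' @param stimuli A `"binary_stimulus_set"` (or a 0/1 matrix).
#' @return Items x h matrix of tanh activations, all strictly in (-1, 1).
#' @export
hidden_activations <- function(state, stimuli) {
  x <- if (inherits(stimuli, "binary_stimulus_set")) stimuli$vectors else stimuli
  tanh(net_inputs(x) %*% state$We)
}

#' Train the unsupervised (autoencoding) phase
#'
#' Full-batch gradient descent on the reconstruction mean squared error of
#' the +/-1-coded inputs, with L2 weight decay on non-bias weights. This
#' phase models mere passive exposure: the net learns the lay of the land
#' (feature frequencies and correlations) without any category feedback.
#'
#' @param cfg A `"net_config"`.
#' @param stimuli A `"binary_stimulus_set"`; labels are not used.
#' @return A `"net_state"` tagged `"post-unsupervised"`, with
#'   `recon_mse` (final reconstruction MSE) and the per-epoch `loss_trace`.
#' @export
train_autoencoder <- function(cfg, stimuli) {
  stopifnot(inherits(cfg, "net_config"),
            inherits(stimuli, "binary_stimulus_set"))
  state <- init_state(cfg)
  xb <- net_inputs(stimuli$vectors)
  target <- 2 * stimuli$vectors - 1
  n <- nrow(xb); d <- cfg$n_dims
  vWe <- state$We * 0; vWd <- state$Wd * 0
  trace <- numeric(cfg$epochs_unsup)
  for (ep in seq_len(cfg$epochs_unsup)) {
    z <- tanh(xb %*% state$We)
    zb <- cbind(1, z)
    xhat <- zb %*% state$Wd
    err <- xhat - target
    loss <- mean(err^2) + cfg$l2_penalty *
      (sum(no_bias(state$We)^2) + sum(no_bias(state$Wd)^2))
    if (!is.finite(loss)) stop("divergence: autoencoder loss is not finite")
    trace[ep] <- loss
    g <- 2 * err / (n * d)
    gWd <- crossprod(zb, g) + 2 * cfg$l2_penalty * no_bias(state$Wd)
    dz <- g %*% t(state$Wd[-1, , drop = FALSE]) * (1 - z^2)
    gWe <- crossprod(xb, dz) + 2 * cfg$l2_penalty * no_bias(state$We)
    vWd <- cfg$momentum * vWd - cfg$learning_rate * gWd
    vWe <- cfg$momentum * vWe - cfg$learning_rate * gWe
    state$Wd <- state$Wd + vWd
    state$We <- state$We + vWe
  }
  z <- tanh(xb %*% state$We)
  state$recon_mse <- mean((cbind(1, z) %*% state$Wd - target)^2)
  state$loss_trace <- trace
  state$phase <- "post-unsupervised"
  state
}

#' Train the supervised (categorization) phase
#'
#' Starting from the post-unsupervised state, trains the linear category
#' head (+/-1-coded single output) on the regularized mean squared error,
#' fine-tuning the encoder unless `cfg$freeze_encoder`. The recorded
#' `final_mse` is the regularized MSE on the last layer: the output MSE
#' plus the L2 penalty on the head's non-bias weights.
#'
#' @param state A `"net_state"` tagged `"post-unsupervised"`.
#' @param stimuli A `"binary_stimulus_set"` with labels.
#' @param cfg Optional `"net_config"` override; defaults to the state's.
#' @return A `"net_state"` tagged `"post-supervised"` with `final_mse` set.
#' @export
train_supervised <- function(state, stimuli, cfg = NULL) {
  stopifnot(inherits(state, "net_state"),
            inherits(stimuli, "binary_stimulus_set"))
  if (!identical(state$phase, "post-unsupervised")) {
    stop("supervised phase requires a post-unsupervised state")
  }
  cfg <- cfg %||% state$cfg
  xb <- net_inputs(stimuli$vectors)
  tgt <- matrix(2 * stimuli$labels - 1, ncol = 1)
  n <- nrow(xb)
  vWe <- state$We * 0; vWc <- state$Wc * 0
  trace <- numeric(cfg$epochs_sup)
  for (ep in seq_len(cfg$epochs_sup)) {
    z <- tanh(xb %*% state$We)
    zb <- cbind(1, z)
    y <- zb %*% state$Wc
    err <- y - tgt
    loss <- mean(err^2) + cfg$l2_penalty *
      (sum(no_bias(state$Wc)^2) + sum(no_bias(state$We)^2))
    if (!is.finite(loss)) stop("divergence: supervised loss is not finite")
    trace[ep] <- loss
    g <- 2 * err / n
    gWc <- crossprod(zb, g) + 2 * cfg$l2_penalty * no_bias(state$Wc)
    vWc <- cfg$momentum * vWc - cfg$learning_rate * gWc
    state$Wc <- state$Wc + vWc
    if (!cfg$freeze_encoder) {
      dz <- g %*% t(state$Wc[-1, , drop = FALSE]) * (1 - z^2)
      gWe <- crossprod(xb, dz) + 2 * cfg$l2_penalty * no_bias(state$We)
      vWe <- cfg$momentum * vWe - cfg$learning_rate * gWe
      state$We <- state$We + vWe
    }
  }
  z <- tanh(xb %*% state$We)
  y <- cbind(1, z) %*% state$Wc
  state$final_mse <- mean((y - tgt)^2) +
    cfg$l2_penalty * sum(no_bias(state$Wc)^2)
  state$loss_trace <- trace
  state$phase <- "post-supervised"
  state
}

#' Learner / Non-Learner classification of a trained net
#'
#' @param state A post-supervised `"net_state"`.
#' @param threshold Success threshold on the last-layer regularized MSE
#'   (default the config's, 1e-3); the bound is inclusive.
#' @return Logical: TRUE for a Learner net.
#' @export
classify_net <- function(state, threshold = NULL) {
  stopifnot(inherits(state, "net_state"))
  if (!identical(state$phase, "post-supervised")) {
    stop("classification requires a post-supervised state")
  }
  threshold <- threshold %||% state$cfg$success_threshold
  state$final_mse <= threshold
}

#' Mean pairwise hidden distances by pair type
#'
#' Brute-force-equivalent mean Euclidean distances among hidden
#' representations, separately over between-category and within-category
#' pairs.
#'
#' @param h Items x h matrix of hidden activations.
#' @param labels 0/1 category labels, one per row; both categories must be
#'   present.
#' @return List with `between` and `within` mean distances.
#' @export
category_distances <- function(h, labels) {
  if (length(unique(labels)) < 2) {
    stop("invalid probe: both categories must be present")
  }
  d <- as.matrix(stats::dist(h))
  same <- outer(labels, labels, "==")
  ut <- upper.tri(d)
  list(between = mean(d[ut & !same]), within = mean(d[ut & same]))
}

#' Hidden-space CP effect of supervised learning
#'
#' Measures mean pairwise hidden distances for a probe set under the
#' pre-learning (post-unsupervised) and post-learning (post-supervised)
#' states. Separation is the increase in between-category distance,
#' compression the decrease in within-category distance. Per-dimension
#' salience (the dimensional-reduction readout) is the Euclidean norm of
#' each input dimension's encoder weight column in each state.
#'
#' @param state_pre `"net_state"` before supervised learning.
#' @param state_post `"net_state"` after supervised learning.
#' @param probe A balanced `"binary_stimulus_set"`.
#' @return A `"net_cp_result"` list: `between_pre`, `between_post`,
#'   `within_pre`, `within_post`, `separation`, `compression`, `learner`,
#'   `salience_pre`, `salience_post`, `covariant_dims`.
#' @export
cp_effect <- function(state_pre, state_post, probe) {
  stopifnot(inherits(state_pre, "net_state"), inherits(state_post, "net_state"),
            inherits(probe, "binary_stimulus_set"))
  if (!identical(dim(state_pre$We), dim(state_post$We))) {
    stop("states do not share an architecture")
  }
  d_pre <- category_distances(hidden_activations(state_pre, probe),
                              probe$labels)
  d_post <- category_distances(hidden_activations(state_post, probe),
                               probe$labels)
  salience <- function(s) sqrt(rowSums(s$We[-1, , drop = FALSE]^2))
  learner <- if (identical(state_post$phase, "post-supervised")) {
    classify_net(state_post)
  } else NA
  structure(list(
    between_pre = d_pre$between, between_post = d_post$between,
    within_pre = d_pre$within, within_post = d_post$within,
    separation = d_post$between - d_pre$between,
    compression = d_pre$within - d_post$within,
    learner = learner,
    salience_pre = salience(state_pre), salience_post = salience(state_post),
    covariant_dims = probe$covariant_dims
  ), class = "net_cp_result")
}

#' @export
print.net_cp_result <- function(x, ...) {
  cat(sprintf("Net CP effect (%s net):\n",
              if (isTRUE(x$learner)) "Learner" else "Non-Learner"))
  cat(sprintf("  between: %.3f -> %.3f (separation %+.3f)\n",
              x$between_pre, x$between_post, x$separation))
  cat(sprintf("  within : %.3f -> %.3f (compression %+.3f)\n",
              x$within_pre, x$within_post, x$compression))
  invisible(x)
}

#' Sweep difficulty (covariant proportion) over seeds
#'
#' Runs the full two-phase model for every combination of `k_cov` values
#' and seeds, measuring the hidden-space CP effect of each net on a fresh
#' probe set, and returns one row per net.
#'
#' @param k_values Integer vector of covariant-dimension counts.
#' @param seeds Integer vector of seeds (one net per seed per k).
#' @param cfg Base `"net_config"`; `k_cov` and `seed` are overridden per
#'   cell.
#' @param n_per_category Training and probe items per category (default 40).
#' @return Data frame with columns `k_cov`, `n_dims`, `seed`, `final_mse`,
#'   `learner`, `between_pre`, `between_post`, `within_pre`, `within_post`,
#'   `separation`, `compression`, `salience_gap` (mean covariant minus mean
#'   non-covariant post-supervised salience).
#' @export
sweep_k <- function(k_values, seeds, cfg = net_config(),
                    n_per_category = 40) {
  stopifnot(length(k_values) >= 1, length(seeds) >= 1)
  rows <- list()
  for (k in k_values) {
    for (s in seeds) {
      cell <- net_config(n_dims = cfg$n_dims, k_cov = k, h = cfg$h,
                         learning_rate = cfg$learning_rate,
                         momentum = cfg$momentum,
                         epochs_unsup = cfg$epochs_unsup,
                         epochs_sup = cfg$epochs_sup,
                         l2_penalty = cfg$l2_penalty,
                         success_threshold = cfg$success_threshold,
                         freeze_encoder = cfg$freeze_encoder,
                         seed = derive_seed(s, "net", k))
      train <- gen_binary_stimuli(cell, n_per_category,
                                  seed = derive_seed(s, "train", k))
      probe <- gen_binary_stimuli(cell, n_per_category,
                                  seed = derive_seed(s, "probe", k))
      pre <- train_autoencoder(cell, train)
      post <- train_supervised(pre, train)
      eff <- cp_effect(pre, post, probe)
      cov <- probe$covariant_dims
      noncov <- setdiff(seq_len(cell$n_dims), cov)
      gap <- if (length(noncov) > 0) {
        mean(eff$salience_post[cov]) - mean(eff$salience_post[noncov])
      } else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        k_cov = k, n_dims = cell$n_dims, seed = s, final_mse = post$final_mse,
        learner = eff$learner, between_pre = eff$between_pre,
        between_post = eff$between_post, within_pre = eff$within_pre,
        within_post = eff$within_post, separation = eff$separation,
        compression = eff$compression, salience_gap = gap
      )
    }
  }
  do.call(rbind, rows)
}
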