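# Synthetic cohorts with known injected effects: logistic learning curves,
# pre/post dissimilarity ratings with injected separation/compression, and
# stimulus-locked epochs carrying N1/LPC-like templates plus Gaussian noise.
# Every generator is a pure function of (profile, seed), and ground-truth
# parameters travel with every generated object.

#' Default synthetic channel montage
#'
#' Ten 10-20 labels covering the occipital N1 cluster (Iz, Oz, O1, O2, POz),
#' a parietal LPC cluster (Pz, P1, P2, CPz) and one frontal control channel,
#' chosen for desk-scale speed rather than a full 64-channel montage.
#'
#' @return Character vector of channel labels.
#' @export
default_channels <- function() {
  c("Iz", "Oz", "O1", "O2", "POz", "Pz", "P1", "P2", "CPz", "Fz")
}

occipital_cluster <- function() c("Iz", "Oz", "O1", "O2", "POz")
parietal_cluster <- function() c("Pz", "P1", "P2", "CPz")

#' Subject archetype profile
#'
#' Bundles the generative parameters of one simulated subject. Accuracy
#' follows a logistic learning curve
#' `p(t) = 0.5 + (a - 0.5) / (1 + exp(-(t - t0)/s))`; ratings are base
#' dissimilarities plus injected post-training effects (`sigma_b` on
#' between-category pairs, signed `sigma_w` on within-category pairs) and
#' Gaussian rating noise; epochs carry an occipital N1 template and a
#' parietal LPC template whose amplitudes switch from pre to post values at
#' the learning point.
#'
#' Archetype defaults mirror the observed regimes of the study the toolkit
#' models: Learners inject a between-category separation of about +1.8
#' rating units, a weak (non-significant) compression, an N1 attenuation of
#' about +1.1 uV and an LPC boost of about +0.5 uV; Non-Learners inject the
#' small same-direction drifts (+0.776 between, +0.376 within) and flat ERP
#' components.
#'
#' @param archetype One of `"Learner"`, `"Immediate"`, `"Borderline"`,
#'   `"NonLearner"`.
#' @param ... Named overrides of any profile field (`t0`, `s`, `asymptote`,
#'   `rt_base`, `rt_decline`, `base_between`, `base_within`, `sigma_b`,
#'   `sigma_w`, `rating_noise`, `n1_pre`, `n1_change`, `lpc_pre`,
#'   `lpc_change`, `noise_sd`, `artifact_rate`, `osc_amp`).
#' @return A `"subject_profile"` list.
#' @export
subject_profile <- function(archetype = c("Learner", "Immediate",
                                          "Borderline", "NonLearner"), ...) {
  archetype <- match.arg(archetype)
  base <- list(
    archetype = archetype,
    t0 = 150, s = 10, asymptote = 0.95,  # learning-curve asymptotic accuracy
    osc_amp = 0,                          # accuracy oscillation (Borderline)
    rt_base = 1.1, rt_decline = 0.3,      # seconds; decline tied to learning
    base_between = 5.0, base_within = 4.3,
    sigma_b = 1.8, sigma_w = -0.43, rating_noise = 1.0,
    n1_pre = -4.0, n1_change = 1.1,       # uV; positive change = attenuation
    lpc_pre = 2.0, lpc_change = 0.5,
    noise_sd = 8, artifact_rate = 0.06,
    drift_sd = 2                          # per-trial DC offset, removed by baseline
  )
  tweak <- switch(archetype,
    Learner = list(),
    Immediate = list(t0 = -50, s = 10, asymptote = 0.95),
    Borderline = list(t0 = 120, asymptote = 0.80, osc_amp = 0.06,
                      sigma_b = 1.0, sigma_w = 0.1,
                      n1_change = 0.4, lpc_change = 0.2),
    NonLearner = list(asymptote = 0.55, rt_decline = 0,
                      sigma_b = 0.776, sigma_w = 0.376,
                      n1_change = 0, lpc_change = 0)
  )
  prof <- utils::modifyList(base, tweak)
  prof <- utils::modifyList(prof, list(...))
  if (prof$asymptote < 0.5 || prof$asymptote > 1) {
    stop("asymptotic accuracy must be in [0.5, 1]")
  }
  if (archetype == "NonLearner" && prof$asymptote >= 0.8) {
    stop("NonLearner archetype requires asymptotic accuracy < 0.8")
  }
  structure(prof, class = "subject_profile")
}

#' Trial-success probability of a profile
#'
#' The logistic learning curve (plus any Borderline oscillation term),
#' clipped to `[0, 1]`.
#'
#' @param profile A `"subject_profile"`.
#' @param t Trial indices (1-based).
#' @return Success probabilities.
#' @export
success_prob <- function(profile, t) {
  p <- 0.5 + (profile$asymptote - 0.5) / (1 + exp(-(t - profile$t0) / profile$s))
  if (profile$osc_amp > 0) {
    ramp <- 1 / (1 + exp(-(t - profile$t0) / profile$s))
    p <- p + profile$osc_amp * sin(2 * pi * t / 100) * ramp
  }
  pmin(pmax(p, 0), 1)
}

#' Generate a synthetic trial log
#'
#' Per-trial correctness is Bernoulli in the profile's logistic learning
#' curve; reaction times are lognormal with a mean that declines as the
#' curve rises (scaled by `rt_decline`). Stimulus ids and true categories
#' come from `schedule` when given, otherwise categories alternate.
#'
#' @param profile A `"subject_profile"`.
#' @param n_trials Number of trials (default 400).
#' @param seed Seed.
#' @param schedule Optional `"trial_schedule"` supplying stimulus ids and
#'   categories.
#' @param subject_id Optional label.
#' @return A trial-log data frame: `trial`, `stimulus_id`, `category`,
#'   `response`, `correct`, `rt`; the generating profile is attached as the
#'   `"profile"` attribute.
#' @export
gen_trial_log <- function(profile, n_trials = 400, seed = 1, schedule = NULL,
                          subject_id = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  if (!is.null(schedule)) {
    stopifnot(inherits(schedule, "trial_schedule"))
    n_trials <- schedule$n_trials
  }
  with_seed(derive_seed(seed, "triallog"), {
    t <- seq_len(n_trials)
    p <- success_prob(profile, t)
    correct <- stats::rbinom(n_trials, 1, p) == 1
    learned_frac <- (p - 0.5) / max(profile$asymptote - 0.5, 1e-9)
    rt_mean <- pmax(profile$rt_base - profile$rt_decline * learned_frac, 0.2)
    rt <- stats::rlnorm(n_trials, meanlog = log(rt_mean) - 0.02, sdlog = 0.2)
    category <- if (!is.null(schedule)) schedule$category else
      rep(c("K", "L"), length.out = n_trials)
    stimulus_id <- if (!is.null(schedule)) schedule$stimulus_id else
      paste0(tolower(category), t)
    response <- ifelse(correct, category, ifelse(category == "K", "L", "K"))
    log <- data.frame(trial = t, stimulus_id = stimulus_id,
                      category = category, response = response,
                      correct = correct, rt = rt,
                      stringsAsFactors = FALSE)
    attr(log, "profile") <- profile
    attr(log, "subject_id") <- subject_id
    log
  })
}

#' Generate a synthetic rating table
#'
#' Pre-training ratings are `round(clip(base + noise, 1, 9))` with the base
#' depending on pair type; post-training ratings add the injected
#' between-category shift `sigma_b` and the signed within-category shift
#' `sigma_w` before rounding. Both phases use the same pairs in the same
#' order.
#'
#' @param profile A `"subject_profile"`.
#' @param pairs A `"rating_pair_set"` from [sample_rating_pairs()].
#' @param seed Seed.
#' @return A rating-table data frame: `pair_index`, `pair_type`, `phase`,
#'   `rating`, with the profile attached as `"profile"`.
#' @export
gen_ratings <- function(profile, pairs, seed = 1) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(pairs, "rating_pair_set") || is.data.frame(pairs))
  with_seed(derive_seed(seed, "ratings"), {
    base <- ifelse(pairs$pair_type == "between",
                   profile$base_between, profile$base_within)
    shift <- ifelse(pairs$pair_type == "between",
                    profile$sigma_b, profile$sigma_w)
    n <- nrow(pairs)
    draw <- function(mu) {
      as.integer(round(pmin(pmax(mu + stats::rnorm(n, 0, profile$rating_noise),
                                 1), 9)))
    }
    out <- rbind(
      data.frame(pair_index = pairs$pair_index, pair_type = pairs$pair_type,
                 phase = "pre", rating = draw(base)),
      data.frame(pair_index = pairs$pair_index, pair_type = pairs$pair_type,
                 phase = "post", rating = draw(base + shift))
    )
    attr(out, "profile") <- profile
    out
  })
}

#' Window-mean attenuation of a Gaussian component template
#'
#' The mean over a measurement window `[a, b]` of a unit-amplitude Gaussian
#' bump centred at `center` with width `sd`, in closed form:
#' `sd * sqrt(2*pi) / (b - a) * (pnorm((b-center)/sd) - pnorm((a-center)/sd))`.
#' Multiplying an injected peak amplitude by this factor gives the expected
#' window-mean voltage, the ground truth for recovery tests.
#'
#' @param center Template peak latency (seconds).
#' @param sd Template width (seconds).
#' @param window Length-2 measurement window (seconds).
#' @return The attenuation factor in (0, 1].
#' @export
template_window_factor <- function(center, sd, window) {
  sd * sqrt(2 * pi) / (window[2] - window[1]) *
    (stats::pnorm((window[2] - center) / sd) -
       stats::pnorm((window[1] - center) / sd))
}

# template parameters shared by the generator and the recovery oracles
n1_template_params <- function() list(center = 0.185, sd = 0.025)
lpc_template_params <- function() list(center = 0.700, sd = 0.080)

#' Generate synthetic stimulus-locked epochs
#'
#' Epochs at 500 Hz spanning -1000 to +2000 ms around onset. Every trial is
#' the sum of (a) a negative Gaussian N1 bump centred at 185 ms on the
#' occipital channels, (b) a positive slow LPC wave centred at 700 ms on the
#' parietal channels, (c) a per-trial, per-channel DC offset (removed by
#' baseline correction), and (d) white Gaussian noise. Component amplitudes
#' switch from their pre to post values at `learning_point`. Artifact trials
#' (rate `artifact_rate`) carry a >100 uV excursion on one random channel.
#'
#' @param profile A `"subject_profile"`.
#' @param n_trials Number of trials (default 400).
#' @param learning_point Trial index at which amplitudes switch; `NA` (the
#'   Non-Learner case) keeps the pre amplitudes throughout.
#' @param seed Seed.
#' @param channels Channel labels (default [default_channels()]).
#' @param srate Sampling rate in Hz (default 500).
#' @param window Epoch window in seconds (default `c(-1, 2)`).
#' @param subject_id Optional label.
#' @return An `"epoch_array"` with per-trial metadata columns `trial`,
#'   `condition` (`"pre"`/`"post"`), `artifact`; ground truth is attached as
#'   the `"truth"` attribute.
#' @export
gen_epochs <- function(profile, n_trials = 400, learning_point = NA, seed = 1,
                       channels = default_channels(), srate = 500,
                       window = c(-1, 2), subject_id = NULL) {
  stopifnot(inherits(profile, "subject_profile"))
  with_seed(derive_seed(seed, "epochs"), {
    n_chan <- length(channels)
    n_samp <- as.integer(round((window[2] - window[1]) * srate))
    tt <- window[1] + (seq_len(n_samp) - 1) / srate
    n1p <- n1_template_params(); lpcp <- lpc_template_params()
    n1_shape <- exp(-(tt - n1p$center)^2 / (2 * n1p$sd^2))
    lpc_shape <- exp(-(tt - lpcp$center)^2 / (2 * lpcp$sd^2))
    occ <- which(channels %in% occipital_cluster())
    par <- which(channels %in% parietal_cluster())
    post <- if (is.na(learning_point)) rep(FALSE, n_trials) else
      seq_len(n_trials) >= learning_point
    n1_amp <- profile$n1_pre + ifelse(post, profile$n1_change, 0)
    lpc_amp <- profile$lpc_pre + ifelse(post, profile$lpc_change, 0)
    artifact <- stats::rbinom(n_trials, 1, profile$artifact_rate) == 1
    data <- array(stats::rnorm(n_chan * n_samp * n_trials, 0, profile$noise_sd),
                  dim = c(n_chan, n_samp, n_trials))
    add_template <- function(rows, shape, amp) {
      m <- shape %o% amp                       # samples x trials
      data[rows, , ] <<- data[rows, , , drop = FALSE] +
        aperm(array(m, c(n_samp, n_trials, length(rows))), c(3, 1, 2))
    }
    add_template(occ, n1_shape, n1_amp)
    add_template(par, lpc_shape, lpc_amp)
    drift <- matrix(stats::rnorm(n_chan * n_trials, 0, profile$drift_sd),
                    n_chan, n_trials)
    data <- sweep(data, c(1, 3), drift, "+")
    span <- which(tt >= 0.3 & tt <= 0.5)
    for (i in which(artifact)) {
      ch <- sample(n_chan, 1)
      data[ch, span, i] <- data[ch, span, i] + sample(c(-150, 150), 1)
    }
    ep <- epoch_array(data, channels, srate, window,
                      trials = data.frame(trial = seq_len(n_trials),
                                          condition = ifelse(post, "post", "pre"),
                                          artifact = artifact),
                      subject_id = subject_id)
    attr(ep, "truth") <- list(
      profile = profile, learning_point = learning_point,
      n1_window_pre = profile$n1_pre *
        template_window_factor(n1p$center, n1p$sd, c(0.15, 0.22)),
      n1_window_change = profile$n1_change *
        template_window_factor(n1p$center, n1p$sd, c(0.15, 0.22)),
      lpc_window_pre = profile$lpc_pre *
        template_window_factor(lpcp$center, lpcp$sd, c(0.6, 0.8)),
      lpc_window_change = profile$lpc_change *
        template_window_factor(lpcp$center, lpcp$sd, c(0.6, 0.8))
    )
    ep
  })
}

#' Generate a synthetic cohort
#'
#' Draws an archetype for each subject from the mix, builds the
#' subject's profile (with mild between-subject jitter around the archetype
#' means), and generates a trial log and a rating table — plus, optionally,
#' stimulus-locked epochs keyed to the profile's generative learning point.
#'
#' @param n_subjects Number of subjects (0 gives an empty cohort).
#' @param mix Named numeric vector of archetype proportions over
#'   `Learner`, `Immediate`, `Borderline`, `NonLearner` (must sum to 1).
#' @param seed Seed.
#' @param pairs A `"rating_pair_set"`; by default a self-contained one is
#'   built from a small internal stimulus set.
#' @param with_epochs If TRUE (default FALSE), also generate epochs per
#'   subject (memory-heavy: ~48 MB per 400-trial subject at 10 channels).
#' @param n_trials Trials per subject (default 400).
#' @param jitter Relative SD of between-subject parameter jitter
#'   (default 0.1; 0 disables it).
#' @return A `"cohort"` list of subjects, each a list with `subject_id`,
#'   `archetype`, `profile`, `log`, `ratings` and (optionally) `epochs`.
#' @export
gen_cohort <- function(n_subjects, mix = c(Learner = 0.5, NonLearner = 0.4,
                                           Borderline = 0.1),
                       seed = 1, pairs = NULL, with_epochs = FALSE,
                       n_trials = 400, jitter = 0.1) {
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  bad <- setdiff(names(mix), c("Learner", "Immediate", "Borderline",
                               "NonLearner"))
  if (length(bad) > 0) stop("unknown archetype(s): ", paste(bad, collapse = ", "))
  if (n_subjects == 0) return(structure(list(), class = "cohort"))
  if (is.null(pairs)) {
    scheme <- make_scheme(4, seed = derive_seed(seed, "cohort-scheme"))
    set <- make_set(scheme, n = 20, seed = derive_seed(seed, "cohort-set"))
    pairs <- sample_rating_pairs(set, seed = derive_seed(seed, "cohort-pairs"))
  }
  archetypes <- with_seed(derive_seed(seed, "mix"), {
    sample(names(mix), n_subjects, replace = TRUE, prob = mix)
  })
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("sub%03d", i)
    prof <- with_seed(derive_seed(seed, "profile", i), {
      p <- subject_profile(archetypes[i])
      if (jitter > 0) {
        jit <- function(v, lo = -Inf, hi = Inf) {
          pmin(pmax(v * (1 + stats::rnorm(1, 0, jitter)), lo), hi)
        }
        p$t0 <- jit(p$t0)
        p$asymptote <- jit(p$asymptote, 0.5, if (archetypes[i] == "NonLearner") 0.79 else 1)
        p$sigma_b <- jit(p$sigma_b)
        p$sigma_w <- jit(p$sigma_w)
        p$n1_change <- jit(p$n1_change)
        p$lpc_change <- jit(p$lpc_change)
      }
      p
    })
    log <- gen_trial_log(prof, n_trials = n_trials,
                         seed = derive_seed(seed, "log", i), subject_id = sid)
    ratings <- gen_ratings(prof, pairs, seed = derive_seed(seed, "rate", i))
    subj <- list(subject_id = sid, archetype = archetypes[i], profile = prof,
                 log = log, ratings = ratings)
    if (with_epochs) {
      # the generative learning point: where the curve crosses 80%
      lp <- if (archetypes[i] %in% c("Learner", "Immediate")) {
        cross <- which(success_prob(prof, seq_len(n_trials)) >= 0.8)
        if (length(cross) > 0) cross[1] else NA
      } else NA
      subj$epochs <- gen_epochs(prof, n_trials = n_trials, learning_point = lp,
                                seed = derive_seed(seed, "epoch", i),
                                subject_id = sid)
    }
    subjects[[i]] <- subj
  }
  structure(subjects, class = "cohort", seed = seed, pairs = pairs)
}
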