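test_that("archetype profiles respect their accuracy constraints", {
  expect_error(subject_profile("NonLearner", asymptote = 0.9), "NonLearner")
  expect_error(subject_profile("Learner", asymptote = 1.2), "accuracy")
  imm <- subject_profile("Immediate")
  expect_gt(success_prob(imm, 1), 0.8)   # above criterion from trial 1
  non <- subject_profile("NonLearner")
  expect_lt(max(success_prob(non, 1:400)), 0.8)
})

test_that("trial logs are deterministic and follow the logistic curve downstream", {
  prof <- subject_profile("Learner")
  expect_identical(gen_trial_log(prof, seed = 5), gen_trial_log(prof, seed = 5))
  expect_false(identical(gen_trial_log(prof, seed = 5),
                         gen_trial_log(prof, seed = 6)))

  # chance-level subjects never classify as Learners, and the NonLearner
  # fraction matches the binomial oracle: a 20-trial window hits 16/20 at
  # chance with p = 1 - pbinom(15, 20, 0.5) = 0.0059, so P(no window does,
  # in 20 windows) = (1 - 0.0059)^20 = 0.888 (the rest are Borderline)
  flat <- subject_profile("NonLearner", asymptote = 0.5)
  status <- vapply(1:30, function(s) {
    classify_learner(window_accuracy(gen_trial_log(flat, seed = s)))$status
  }, "")
  expect_false(any(status %in% c("Learner", "Immediate")))
  p_non <- (pbinom(15, 20, 0.5))^20
  half_width <- 1.96 * sqrt(p_non * (1 - p_non) / 30)
  expect_gt(mean(status == "NonLearner"), p_non - half_width - 0.05)

  # a steep learner's detected learning point recovers the injected onset
  steep <- subject_profile("Learner", asymptote = 0.98, t0 = 100, s = 10)
  lps <- vapply(1:20, function(s) {
    a <- classify_learner(window_accuracy(gen_trial_log(steep, seed = s)))
    if (a$status %in% c("Learner", "Immediate")) a$learning_point else NA_integer_
  }, integer(1))
  expect_true(mean(!is.na(lps)) >= 0.9)
  expect_true(mean(abs(lps[!is.na(lps)] - 120) <= 40) >= 0.9)

  # an early onset makes performance criterial from the outset
  early <- subject_profile("Immediate", asymptote = 0.95, t0 = -50)
  st <- classify_learner(window_accuracy(gen_trial_log(early, seed = 2)))$status
  expect_equal(st, "Immediate")
})

test_that("reaction times are positive and decline only with learning", {
  lrn <- gen_trial_log(subject_profile("Learner"), seed = 1)
  expect_true(all(lrn$rt > 0))
  expect_lt(mean(lrn$rt[301:400]), mean(lrn$rt[1:100]))
  non <- gen_trial_log(subject_profile("NonLearner"), seed = 1)
  expect_lt(abs(mean(non$rt[301:400]) - mean(non$rt[1:100])), 0.1)
})

test_that("rating generator injects recoverable separation and compression", {
  set <- make_set(make_scheme(4, 1), 20, 1)
  pairs <- sample_rating_pairs(set, 1)

  silent <- subject_profile("Learner", sigma_b = 0, sigma_w = 0,
                            rating_noise = 0)
  s0 <- cp_stats(gen_ratings(silent, pairs, seed = 1))
  expect_equal(s0$diffW, 0)
  expect_equal(s0$diffB, 0)
  expect_equal(s0$global_cp, 0)

  # cohort-level recovery of the injected effects (Monte-Carlo)
  inj <- subject_profile("Learner", sigma_b = 1.8, sigma_w = -0.4)
  diffs <- vapply(1:50, function(s) {
    st <- cp_stats(gen_ratings(inj, pairs, seed = s))
    c(st$diffB, st$diffW)
  }, numeric(2))
  expect_lt(abs(mean(diffs[1, ]) - 1.8), 0.1)
  expect_lt(abs(mean(diffs[2, ]) + 0.4), 0.1)

  # Non-Learner same-direction drifts leave Global CP near zero
  non <- subject_profile("NonLearner")
  g <- vapply(1:50, function(s) {
    cp_stats(gen_ratings(non, pairs, seed = s))$global_cp
  }, numeric(1))
  expect_lt(abs(mean(g) - 0.4), 0.25)
  ratings <- gen_ratings(inj, pairs, seed = 1)
  expect_true(all(ratings$rating %in% 1:9))
})

test_that("epoch generator places exact component means when noise is off", {
  quiet <- subject_profile("Learner", noise_sd = 0, artifact_rate = 0,
                           drift_sd = 0, n1_pre = -4, n1_change = 1.1,
                           lpc_pre = 2, lpc_change = 0.5)
  ep <- gen_epochs(quiet, n_trials = 20, learning_point = 11, seed = 1)
  truth <- attr(ep, "truth")
  sp <- split_and_average(ep, 1:10, 11:20)
  n1 <- component_window("N1", c(150, 220), c("Iz", "Oz", "O1", "O2", "POz"))
  lpc <- component_window("LPC", c(600, 800), c("Pz", "P1", "P2", "CPz"))
  m <- function(e, cw) component_mean(e, cw)$mean_voltage
  # the closed-form factor integrates the continuous template; the measured
  # mean samples it at 500 Hz, so agreement is to discretization error (<1%)
  expect_equal(m(sp$before, n1), truth$n1_window_pre, tolerance = 0.01)
  expect_equal(m(sp$after, n1) - m(sp$before, n1), truth$n1_window_change,
               tolerance = 0.01)
  expect_equal(m(sp$before, lpc), truth$lpc_window_pre, tolerance = 0.01)
  expect_equal(m(sp$after, lpc) - m(sp$before, lpc), truth$lpc_window_change,
               tolerance = 0.01)
  # closed-form template attenuation is itself correct: numeric quadrature
  f <- integrate(function(t) exp(-(t - 0.185)^2 / (2 * 0.025^2)), 0.15, 0.22)
  expect_equal(template_window_factor(0.185, 0.025, c(0.15, 0.22)),
               f$value / 0.07, tolerance = 1e-6)
})

test_that("artifact injection matches the requested rate through the extreme filter", {
  prof <- subject_profile("Learner", artifact_rate = 0.06)
  ep <- gen_epochs(prof, n_trials = 400, learning_point = 150, seed = 3)
  out <- reject_extreme(baseline_correct(ep))
  rate <- length(out$rejected) / 400
  # binomial 95% band around 0.06 at n = 400
  expect_gt(rate, 0.06 - 1.96 * sqrt(0.06 * 0.94 / 400) - 0.01)
  expect_lt(rate, 0.06 + 1.96 * sqrt(0.06 * 0.94 / 400) + 0.01)
  expect_identical(gen_epochs(prof, n_trials = 20, learning_point = 5, seed = 9)$data,
                   gen_epochs(prof, n_trials = 20, learning_point = 5, seed = 9)$data)
})

test_that("cohorts honour the archetype mix, determinism and the empty case", {
  expect_length(gen_cohort(0, seed = 1), 0)
  all_non <- gen_cohort(8, mix = c(NonLearner = 1), seed = 2)
  status <- vapply(all_non, function(s) {
    classify_learner(window_accuracy(s$log))$status
  }, "")
  expect_true(all(status %in% c("NonLearner", "Borderline")))
  expect_false(any(status %in% c("Learner", "Immediate")))

  a <- gen_cohort(3, seed = 5)
  b <- gen_cohort(3, seed = 5)
  expect_identical(a, b)
  expect_error(gen_cohort(3, mix = c(Learner = 0.6)), "sum to 1")
  expect_error(gen_cohort(3, mix = c(Wizard = 1)), "unknown archetype")
})
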