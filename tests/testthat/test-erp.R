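test_that("epoch arrays validate their geometry", {
  expect_error(epoch_array(array(0, c(2, 50, 3)), c("a", "b"), 100, c(-1, 2)),
               "samples")
  expect_error(epoch_array(array(0, c(2, 100, 3)), c("a", "a"), 100, c(-0.5, 0.5)),
               "unique")
  expect_error(epoch_array(array(0, c(2, 100, 3)), c("a", "b"), 100, c(0.5, 1.5)),
               "onset")
  ep <- toy_epochs()
  expect_equal(epoch_times(ep)[1], -0.5)
  expect_equal(length(epoch_times(ep)), 100)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  ep <- toy_epochs(fill = 5)
  out <- baseline_correct(ep)
  expect_true(all(out$data == 0))
  # already-zero-baseline input is unchanged (idempotence)
  expect_identical(baseline_correct(out)$data, out$data)

  set.seed(31)
  ep2 <- toy_epochs()
  ep2$data[] <- rnorm(length(ep2$data))
  out2 <- baseline_correct(ep2)
  tt <- epoch_times(out2)
  idx <- which(tt >= -0.2 & tt < 0)
  bl_means <- apply(out2$data[, idx, , drop = FALSE], c(1, 3), mean)
  expect_true(all(abs(bl_means) < 1e-9))
  expect_error(baseline_correct(ep2, c(-2, 0)), "configuration")
})

test_that("extreme-value rejection removes exactly the over-limit trials", {
  ep <- toy_epochs(n_trials = 10)
  ep$data[] <- rnorm(length(ep$data), 0, 10)
  ep$data[pmin(abs(ep$data), 99) != abs(ep$data)] <- 50  # clamp inside +/-100
  ep$data[2, 17, 4] <- 150
  out <- reject_extreme(ep)
  expect_equal(out$rejected, 4)
  expect_equal(dim(out$epochs$data)[3], 9)
  expect_equal(out$epochs$trials$trial, setdiff(1:10, 4))

  calm <- toy_epochs(n_trials = 5)
  calm$data[] <- rnorm(length(calm$data), 0, 10)
  calm$data[abs(calm$data) > 50] <- 50
  out2 <- reject_extreme(calm)
  expect_length(out2$rejected, 0)

  # brute-force scan oracle on a mixed set
  set.seed(8)
  mix <- toy_epochs(n_trials = 30)
  mix$data[] <- rnorm(length(mix$data), 0, 30)
  out3 <- reject_extreme(mix)
  brute <- which(vapply(1:30, function(i) any(abs(mix$data[, , i]) > 100),
                        logical(1)))
  expect_equal(out3$rejected, brute)

  all_bad <- toy_epochs(n_trials = 3, fill = 200)
  expect_error(reject_extreme(all_bad), "unusable")
})

test_that("probability filter rejects constructed outliers but few clean trials", {
  set.seed(77)
  ep <- toy_epochs(n_chan = 6, n_samp = 200, n_trials = 100, srate = 200,
                   window = c(-0.5, 0.5))
  ep$data[] <- rnorm(length(ep$data), 0, 10)
  # one trial drawn from a 10x variance distribution on one channel
  ep$data[3, , 42] <- rnorm(200, 0, 100)
  out <- reject_probability(ep)
  expect_true(42 %in% out$rejected)
  # homogeneous-Gaussian null: small rejection fraction
  clean <- toy_epochs(n_chan = 6, n_samp = 200, n_trials = 100, srate = 200,
                      window = c(-0.5, 0.5))
  clean$data[] <- rnorm(length(clean$data), 0, 10)
  out2 <- reject_probability(clean)
  expect_lt(length(out2$rejected) / 100, 0.10)
  # infinite limits reject nothing
  out3 <- reject_probability(clean, single_sd = Inf, global_sd = Inf)
  expect_length(out3$rejected, 0)
  expect_error(reject_probability(toy_epochs(n_trials = 5)), "fewer than 10")
})

test_that("rejection composes in the documented order on a constructed fixture", {
  set.seed(5)
  ep <- toy_epochs(n_chan = 4, n_samp = 100, n_trials = 40)
  ep$data[] <- rnorm(length(ep$data), 0, 10)
  ep$data[1, 10, 7] <- 180              # extreme-value casualty
  ep$data[2, , 21] <- rnorm(100, 0, 90) # improbable but mostly under 100 uV
  ep$data[2, , 21][abs(ep$data[2, , 21]) > 95] <- 95
  r1 <- reject_extreme(ep)
  expect_equal(r1$rejected, 7)
  r2 <- reject_probability(r1$epochs)
  expect_true(21 %in% r1$epochs$trials$trial[r2$rejected])
  expect_false(7 %in% r2$epochs$trials$trial)
})

test_that("split averages reproduce identical trials and shrink noise as 1/sqrt(n)", {
  ep <- toy_epochs(n_trials = 6)
  wave <- matrix(rnorm(4 * 100), 4, 100)
  for (i in 1:6) ep$data[, , i] <- wave
  sp <- split_and_average(ep, 1:3, 4:6)
  expect_equal(sp$before$data, wave)
  expect_equal(sp$after$data, wave)
  expect_equal(sp$before$n_trials, 3)

  set.seed(13)
  n <- 64
  ep2 <- toy_epochs(n_trials = n)
  for (i in seq_len(n)) ep2$data[, , i] <- wave + rnorm(400, 0, 5)
  sp2 <- split_and_average(ep2, 1:(n / 2), (n / 2 + 1):n)
  rmse <- sqrt(mean((sp2$before$data - wave)^2))
  expect_lt(rmse, 3 * 5 / sqrt(n / 2))   # error of a mean of n/2 trials
  sp_small <- split_and_average(ep2, 1:4, 5:n)
  rmse_small <- sqrt(mean((sp_small$before$data - wave)^2))
  expect_gt(rmse_small, rmse)            # fewer trials, larger error

  expect_error(split_and_average(ep, 1:3, 3:6), "disjoint")
  ep$trials$trial <- 101:106
  expect_error(split_and_average(ep, 1:3, 4:6), "exclusion")
})

test_that("component means average the window-by-cluster block and are linear", {
  ep <- toy_epochs(n_chan = 3, n_samp = 100, n_trials = 4, fill = 1,
                   channels = c("Oz", "Pz", "Fz"))
  sp <- split_and_average(ep, 1:2, 3:4)
  cw <- component_window("N1", c(0, 200), c("Oz", "Pz"))
  expect_equal(component_mean(sp$before, cw)$mean_voltage, 1)

  set.seed(21)
  a <- sp$before; b <- sp$after
  a$data[] <- rnorm(300); b$data[] <- rnorm(300)
  ma <- component_mean(a, cw)$mean_voltage
  mb <- component_mean(b, cw)$mean_voltage
  combo <- a; combo$data <- 2 * a$data + 3 * b$data
  expect_equal(component_mean(combo, cw)$mean_voltage, 2 * ma + 3 * mb)

  expect_error(component_mean(a, component_window("N1", c(0, 100), "Cz")),
               "unknown channel")
})

test_that("a-priori component presets carry the published windows and clusters", {
  p <- component_presets()
  expect_equal(p$exp1_n1$window, c(150, 220))
  expect_equal(p$exp2_lpc$window, c(600, 800))
  expect_setequal(p$exp1_n1$cluster, c("Iz", "Oz", "O1", "O2", "POz"))
  expect_setequal(p$exp2_lpc$cluster, c("Pz", "P1", "P2", "CPz", "CP1", "CP2"))
})

test_that("difference waves subtract pointwise", {
  ep <- toy_epochs(n_trials = 4)
  set.seed(3)
  ep$data[] <- rnorm(length(ep$data))
  sp <- split_and_average(ep, 1:2, 3:4)
  d <- difference_wave(sp$after, sp$before)
  expect_equal(d$data, sp$after$data - sp$before$data)
  expect_true(all(difference_wave(sp$after, sp$after)$data == 0))
  zero <- sp$before; zero$data[] <- 0
  expect_equal(difference_wave(sp$after, zero)$data, sp$after$data)
  bad <- sp$before; bad$channels <- rev(bad$channels)
  expect_error(difference_wave(sp$after, bad), "mismatch")
})
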