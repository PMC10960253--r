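test_that("EMG envelope chain handles degenerate inputs", {
  n <- 5000
  expect_equal(emg_envelope(rep(0, n), 2500, 1), rep(0, n))
  # constant (DC) input vanishes after demeaning (up to the residual of the
  # slowly decaying narrow-notch transient)
  expect_lt(max(emg_envelope(rep(3.7, n), 2500, 1)), 1e-4)
  expect_error(emg_envelope(rnorm(n), 2500, mvc_max = 0), "mvc_max")
})

test_that("the notch removes a pure 60 Hz interference", {
  fs <- 2500
  t <- (0:(4 * fs - 1)) / fs
  x <- sin(2 * pi * 60 * t)
  env <- emg_envelope(x, fs, mvc_max = 1)
  # rectified-smoothed amplitude of a unit sine without filtering is 2/pi
  expect_lt(mean(env[1000:9000]), 0.05 * 2 / pi)
})

test_that("a seeded noisy envelope reproduces its frozen golden values", {
  env_prof <- rep(0.2, 200)
  raw <- synth_raw_emg(env_prof, fs_env = 100, fs_out = 2500,
                       powerline_amp = 0.3, seed = 42)
  env <- emg_envelope(raw, 2500, mvc_max = 2)
  idx <- c(500, 1500, 2500, 3500, 4500)
  golden <- c(0.0775215209423235, 0.0768909894126666, 0.0787349181327867,
              0.0805421148710589, 0.0855543780934978)
  expect_equal(env[idx], golden, tolerance = 1e-12)
})

test_that("decimation preserves slow content and sample bookkeeping", {
  fs <- 2500
  x <- rep(1.5, fs * 2)
  y <- decimate_all(x, fs)
  expect_length(y, 200)
  expect_lt(max(abs(y - 1.5)), 1e-6)
  t <- (0:(fs * 4 - 1)) / fs
  s <- sin(2 * pi * 1 * t)
  sd_ <- decimate_all(s, fs)
  expect_lt(abs((max(sd_) - 1)), 0.01)   # 1 Hz amplitude kept within 1 percent
  df <- data.frame(a = s, b = 2 * s)
  dd <- decimate_all(df, fs)
  expect_named(dd, c("a", "b"))
  expect_equal(nrow(dd), 400)
  expect_error(decimate_all(x, 2510), "integer multiple")
})

test_that("segmentation yields overlapping three-period windows", {
  tr40 <- fix_trial(duration_s = 40)
  reals <- segment_realizations(tr40, period_s = 2)
  expect_length(reals, 18)
  expect_length(reals[[1]]$trial$time, 600)
  # stride of one period: window k starts at sample (k-1)*200 + 1
  expect_equal(reals[[2]]$trial$angle, tr40$angle[201:800])
  expect_equal(reals[[1]]$period_index, 1)
  expect_length(segment_realizations(fix_trial(duration_s = 6)), 1)
  expect_length(segment_realizations(fix_trial(duration_s = 5.9)), 0)
  # references are cut alongside
  ref <- reference_set(seq_len(4000), seq_len(4000), seq_len(4000) - 2000.5,
                       seq_len(4000), seq_len(4000))
  reals_r <- segment_realizations(tr40, ref, period_s = 2)
  expect_equal(reals_r[[3]]$reference$tau_a, 401:1000)
})

test_that("the TA filter drops any-sample exceedance with a strict threshold", {
  r_quiet <- fake_realization(0.2, "t1", 1, ta = 0)
  r_border <- fake_realization(0.2, "t1", 2, ta = 0.05)
  r_active <- fake_realization(0.2, "t1", 3, ta = 0.01)
  r_active$trial$excitations$ta[17] <- 0.06
  kept <- filter_ta_active(list(r_quiet, r_border, r_active))
  expect_length(kept, 2)
  expect_equal(vapply(kept, function(r) r$period_index, numeric(1)), c(1, 2))
})

test_that("selection keeps the n realizations closest to the target", {
  levels <- c(0.20, 0.26, 0.21, 0.24, 0.22, 0.25, 0.23)
  reals <- lapply(seq_along(levels), function(i)
    fake_realization(levels[i], sprintf("t%02d", i), i))
  sel <- select_realizations(reals, n = 3)
  got <- vapply(sel, function(r) r$trial$excitations$gm[1], numeric(1))
  expect_equal(sort(got), c(0.20, 0.21, 0.22))
  # an exact-target candidate is always selected
  expect_true(0.20 %in% got)
  expect_error(select_realizations(reals, n = 10), "shortfall")
  # ties broken by trial id then period: selection invariant under permutation
  reals_t <- list(fake_realization(0.20, "a", 1),
                  fake_realization(0.21, "b", 2),
                  fake_realization(0.21, "a", 2),
                  fake_realization(0.21, "a", 9))
  s1 <- select_realizations(reals_t, n = 2)
  s2 <- select_realizations(rev(reals_t), n = 2)
  key <- function(s) vapply(s, function(r)
    paste(r$trial_id, r$period_index), character(1))
  expect_identical(key(s1), key(s2))
  expect_identical(key(s1), c("a 1", "a 2"))
})

test_that("set building averages pointwise and is seeded", {
  reals <- lapply(1:12, function(i) fake_realization(0.2, "t1", i))
  sets <- build_sets(reals, n_val_subsets = 3, subset_size = 5, seed = 2)
  # identical realizations: the calibration mean is any one of them
  expect_equal(sets$calibration$trial$excitations$gm,
               reals[[1]]$trial$excitations$gm)
  expect_equal(sets$calibration$reference$k_att, reals[[1]]$reference$k_att)
  # averaged displacement is re-centered
  expect_equal(mean(sets$calibration$reference$delta_gm), 0, tolerance = 1e-15)
  sets2 <- build_sets(reals, n_val_subsets = 3, subset_size = 5, seed = 2)
  expect_identical(sets$validation[[2]]$reference, sets2$validation[[2]]$reference)
  expect_length(sets$validation, 3)
})

test_that("a full synthetic session survives the segmentation-selection pipeline", {
  # 3 trials of 16 s (8 periods): 6 realizations each, TA bursts disabled
  trials <- lapply(1:3, function(i) {
    ang <- make_movement_profile(duration_s = 16, seed = i)
    exc <- make_excitations(duration_s = 16, ta_burst_rate = 0, seed = 10 + i)
    new_trial((seq_along(ang) - 1) / 100, ang, exc, sprintf("t%d", i))
  })
  reals <- unlist(lapply(trials, segment_realizations), recursive = FALSE)
  expect_length(reals, 18)
  kept <- filter_ta_active(reals)
  expect_length(kept, 18)
  sel <- select_realizations(kept, n = 10)
  expect_length(sel, 10)
})
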