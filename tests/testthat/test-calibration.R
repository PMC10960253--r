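cf <- curve_coefficients()

test_that("variance-normalized error has its closed-form values", {
  set.seed(42)
  ref <- sin(seq(0, 10, by = 0.1)) + rnorm(101, 0, 0.2)
  expect_equal(normalized_error(ref, ref), 0)
  cc <- 0.7
  expect_equal(normalized_error(ref + cc, ref),
               cc^2 / mean((ref - mean(ref))^2), tolerance = 1e-12)
  expect_equal(normalized_error(rep(mean(ref), 101), ref), 1, tolerance = 1e-12)
  expect_error(normalized_error(ref, rep(1, 101)), "variance")
})

test_that("nRMSE has its closed-form values", {
  x <- c(1, -2, 3, 0.5)
  expect_equal(nrmse(x, x), 0)
  expect_equal(nrmse(2 * x, x), 100)
  expect_equal(nrmse(rep(0, 4), x), 100)
  expect_error(nrmse(x, rep(0, 4)), "RMS")
})

test_that("penalty factor is 1 when physiological and follows the quadratic hinge", {
  ok <- list(data.frame(lnorm = runif(50, 0.7, 1.3), eps_t = runif(50, 0, 0.05)))
  expect_equal(penalty_factor(ok), 1)
  # single MTU at lnorm 1.45 throughout: violation 0.1^2 -> p = 2 at gamma 100
  bad <- list(data.frame(lnorm = rep(1.45, 50), eps_t = rep(0.01, 50)))
  expect_equal(penalty_factor(bad, gamma = 100), 2)
  expect_equal(penalty_factor(bad, gamma = 200), 3)   # p - 1 scales with gamma
  # non-decreasing in the violation magnitude
  worse <- list(data.frame(lnorm = rep(1.55, 50), eps_t = rep(0.01, 50)))
  expect_gt(penalty_factor(worse), penalty_factor(bad))
  slack <- list(data.frame(lnorm = rep(1, 50), eps_t = rep(-0.1, 50)))
  expect_equal(penalty_factor(slack, gamma = 100), 2)
})

test_that("objective is zero for the generating model and type 1 ignores stiffness", {
  setup <- fix_cal_setup()
  spec1 <- calibration_spec(cal_type = 1)
  spec4 <- calibration_spec(cal_type = 4)
  expect_lt(objective(setup$subject$truth, setup$trial, setup$reference, spec4),
            1e-10)
  # perturbing the stiffness references leaves a type 1 objective unchanged
  ref2 <- setup$reference
  ref2$k_att <- ref2$k_att * 3
  ref2$k_tsm <- ref2$k_tsm * 3
  ref2$k_a <- ref2$k_a + 50
  ref2$delta_gm <- ref2$delta_gm + rev(ref2$delta_gm) * 0.5
  m0 <- make_uncalibrated_model()
  expect_equal(objective(m0, setup$trial, setup$reference, spec1),
               objective(m0, setup$trial, ref2, spec1))
  expect_false(isTRUE(all.equal(
    objective(m0, setup$trial, setup$reference, spec4),
    objective(m0, setup$trial, ref2, spec4))))
})

test_that("uncalibrated model scaling acts on lengths only", {
  m1 <- make_uncalibrated_model(1)
  m2 <- make_uncalibrated_model(1.1)
  expect_equal(m2$GM$lo_m, 1.1 * m1$GM$lo_m)
  expect_equal(m2$SO$ls_t, 1.1 * m1$SO$ls_t)
  expect_equal(m2$GL$lmtu_ref, 1.1 * m1$GL$lmtu_ref)
  expect_equal(m2$GM$f_max, m1$GM$f_max)
  for (p in m2) expect_s3_class(p, "mtu_parameters")
})

test_that("calibration respects bounds, is seeded-reproducible, and tracks the best", {
  setup <- fix_cal_setup()
  spec <- calibration_spec(cal_type = 2, tendon_prior = "compliant",
                           budget = 400, n_probe = 30, seed = 5)
  m0 <- make_uncalibrated_model()
  r1 <- calibrate(m0, setup$trial, setup$reference, spec)
  r2 <- calibrate(m0, setup$trial, setup$reference, spec)
  expect_identical(r1$model, r2$model)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best) <= 0))
  expect_lte(r1$best_objective, r1$initial_objective)
  b <- emgstiff:::calibration_bounds(m0, spec)
  for (j in seq_along(r1$model)) {
    for (nm in emgstiff:::FREE_PARAMS) {
      expect_gte(r1$model[[j]][[nm]], b[[j]][[nm]][1])
      expect_lte(r1$model[[j]][[nm]], b[[j]][[nm]][2])
    }
    # compliant prior constrains the tendon scale to 0.278 +/- 30 percent
    expect_gte(r1$model[[j]]$gt, 0.278 * 0.7)
    expect_lte(r1$model[[j]]$gt, 0.278 * 1.3)
  }
})

test_that("model evaluation reports per-variable nRMSE", {
  setup <- fix_cal_setup()
  nr <- evaluate_model(setup$subject$truth, setup$trial, setup$reference)
  expect_named(nr, c("tau_a", "k_a", "delta_gm", "k_att", "k_tsm"))
  expect_true(all(nr < 1e-6))   # reference generated by this very model
  nr0 <- evaluate_model(make_uncalibrated_model(), setup$trial, setup$reference)
  expect_true(all(nr0 > 0))
})
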