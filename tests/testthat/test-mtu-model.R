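cf <- curve_coefficients()
model <- make_uncalibrated_model()
gm <- model$GM

test_that("activation dynamics fixes endpoints and matches the closed form", {
  expect_equal(activation_from_excitation(0, -1.5), 0)
  expect_equal(activation_from_excitation(1, -1.5), 1)
  expect_equal(activation_from_excitation(0.5, -3 + 1e-12),
               (exp(-1.5) - 1) / (exp(-3) - 1), tolerance = 1e-9)
  u <- seq(0, 1, by = 0.05)
  expect_true(all(diff(activation_from_excitation(u, -2)) > 0))
  # shape factor near zero degenerates to the identity (series branch)
  expect_equal(activation_from_excitation(u, -1e-8), u, tolerance = 1e-8)
  expect_error(activation_from_excitation(1.2, -1.5), "excitation")
})

test_that("MTU kinematics are linear and anchored at the reference posture", {
  expect_equal(mtu_length_from_angle(gm$theta_ref, gm), gm$lmtu_ref)
  expect_equal(mtu_length_from_angle(gm$theta_ref + 0.1, gm),
               gm$lmtu_ref + 0.1 * 0.0513)
  th <- seq(-0.5, 0.2, by = 0.05)
  expect_equal(diff(mtu_length_from_angle(th, gm)),
               rep(0.05 * gm$r, length(th) - 1))
  # plantarflexors lengthen with dorsiflexion
  expect_true(all(diff(mtu_length_from_angle(th, gm)) > 0))
})

test_that("pennation angle preserves muscle thickness", {
  expect_equal(pennation_angle(1, 0.3), 0.3)
  expect_equal(pennation_angle(2, pi / 6), asin(0.25))
  expect_equal(pennation_angle(c(0.8, 1, 1.4), 0), rep(0, 3))
  l <- seq(0.7, 1.5, by = 0.1)
  expect_true(all(diff(pennation_angle(l, 0.4)) < 0))
  expect_error(pennation_angle(0.3, 0.4), "infeasible")
})

test_that("equilibrium solve matches the bisection oracle and meets the residual bound", {
  for (a in c(0, 0.2, 0.7)) {
    for (dl in c(-0.005, 0, 0.008)) {
      l_mtu <- gm$lmtu_ref + dl
      st <- solve_fiber_equilibrium(a, l_mtu, 0, gm, cf)
      lm_oracle <- o_solve_lm(a, l_mtu, 0, gm)
      expect_lt(abs(st$l_m - lm_oracle), 1e-8)
      expect_lt(abs(st$f_t - st$f_m * cos(st$phi)), 1e-6 * gm$f_max)
    }
  }
  # passive-only solution sits near the passive-curve root of the residual
  st0 <- solve_fiber_equilibrium(0, gm$lmtu_ref - 0.004, 0, gm, cf)
  expect_lt(abs(o_residual(st0$l_m, 0, 0, gm$lmtu_ref - 0.004, gm)), 1e-6)
})

test_that("stiffness composition follows the series arrangement", {
  st <- solve_fiber_equilibrium(0.3, gm$lmtu_ref + 0.003, 0.02, gm, cf)
  ks <- mtu_stiffness(st, gm, cf)
  expect_equal(ks$k_mtu, 1 / (1 / ks$k_t + 1 / ks$k_eqm), tolerance = 1e-12)
  expect_equal(ks$k_eqm,
               ks$k_m * cos(st$phi)^2 + (st$f_m / st$l_m) * sin(st$phi)^2,
               tolerance = 1e-12)
  expect_lte(ks$k_mtu, min(ks$k_t, ks$k_eqm))
  # matches what the solver itself reported
  expect_equal(ks$k_mtu, st$k_mtu, tolerance = 1e-9)
  # zero pennation collapses the geometric term
  so_flat <- mtu_parameters("SO", lo_m = 0.044, ls_t = 0.268, f_max = 3549,
                            shape_a = -1.5, phi_o = 0)
  stf <- solve_fiber_equilibrium(0.3, so_flat$lmtu_ref + 0.002, 0, so_flat, cf)
  ksf <- mtu_stiffness(stf, so_flat, cf)
  expect_equal(ksf$k_eqm, ksf$k_m, tolerance = 1e-12)
})

test_that("MTU stiffness equals the finite difference of equilibrium MTU force", {
  h <- 1e-6
  for (a in c(0.1, 0.4)) {
    for (dl in c(-0.003, 0.002, 0.006)) {
      l_mtu <- gm$lmtu_ref + dl
      st <- solve_fiber_equilibrium(a, l_mtu, 0.01, gm, cf)
      fp <- solve_fiber_equilibrium(a, l_mtu + h, 0.01, gm, cf)$f_mtu
      fm <- solve_fiber_equilibrium(a, l_mtu - h, 0.01, gm, cf)$f_mtu
      expect_equal(st$k_mtu, (fp - fm) / (2 * h), tolerance = 0.01)
    }
  }
})

test_that("fiber velocity series uses backward differences, shortening-positive", {
  p <- gm
  lm <- rep(0.05, 5)
  expect_equal(fiber_velocity_series(lm, 0.01, p), rep(0, 5))
  # shortening at 0.1 * lo_m per second gives vnorm = +0.01
  lm2 <- 0.05 - (0:4) * 0.001 * p$lo_m   # dt = 0.01 s, rate 0.1 lo_m / s
  v <- fiber_velocity_series(lm2, 0.01, p)
  expect_equal(v[-1], rep(0.01, 4), tolerance = 1e-12)
  expect_equal(fiber_velocity_series(rev(lm2), 0.01, p)[-1],
               -rep(0.01, 4), tolerance = 1e-12)
})

test_that("joint projection and GM displacement identities hold", {
  expect_equal(joint_torque(100, 0.0513), 5.13)
  expect_equal(joint_stiffness(1000, 0.0513), 0.0513^2 * 1000)
  expect_equal(joint_torque(matrix(c(1, 2, 3, 4), 2), 0.1), c(0.4, 0.6))
  expect_equal(joint_torque(c(0, 0, 0), 0.0513), 0)
  expect_equal(gm_displacement(rep(0.05, 10), rep(0.2, 10)), rep(0, 10))
  dg <- gm_displacement(seq(0.04, 0.05, length.out = 11), rep(0.1, 11))
  expect_equal(mean(dg), 0, tolerance = 1e-15)
  expect_equal(diff(dg), rep(0.001 * cos(0.1), 10), tolerance = 1e-12)
})

test_that("trial simulation is steady under constant inputs and sums exactly", {
  n <- 50
  tr <- new_trial((0:(n - 1)) / 100, rep(gm$theta_ref, n),
                  data.frame(gm = rep(0, n), gl = rep(0, n), so = rep(0, n),
                             ta = rep(0, n)), "const")
  est <- simulate_trial(model, tr, cf)
  expect_lt(diff(range(est$estimates$tau_a[-1])), 1e-9)
  expect_lt(diff(range(est$estimates$k_a[-1])), 1e-9)
  # exact aggregation identities at every sample
  km <- sapply(est$states, `[[`, "k_mtu")
  fm <- sapply(est$states, `[[`, "f_mtu")
  expect_equal(est$estimates$k_a, 0.0513^2 * rowSums(km), tolerance = 1e-12)
  expect_equal(est$estimates$tau_a, 0.0513 * rowSums(fm), tolerance = 1e-12)
  expect_equal(est$estimates$k_att, rowSums(sapply(est$states, `[[`, "k_t")),
               tolerance = 1e-12)
})

test_that("simulated fiber lengths match a per-sample oracle re-solve", {
  tr <- fix_trial(duration_s = 1.5, exc = 0.25)
  est <- simulate_trial(model["GM"], tr, cf)
  s <- est$states$GM
  a <- activation_from_excitation(tr$excitations$gm, gm$shape_a)
  lmtu <- mtu_length_from_angle(tr$angle, gm)
  for (k in c(2, 30, 80, 120, 150)) {
    # velocity is implicit: at the solution it equals the backward difference,
    # so the fixed-velocity oracle at the recorded vnorm has the same root
    lm_oracle <- o_solve_lm(a[k], lmtu[k], s$vnorm[k], gm)
    expect_lt(abs(s$l_m[k] - lm_oracle), 1e-8)
  }
  expect_equal(s$vnorm, fiber_velocity_series(s$l_m, tr$dt, gm),
               tolerance = 1e-12)
})

test_that("equilibrium residual stays below 1e-6 f_max across a full trial", {
  tr <- fix_trial(duration_s = 4, exc = 0.2, prbs = TRUE)
  est <- simulate_trial(model, tr, cf)
  for (nm in names(model)) {
    s <- est$states[[nm]]
    expect_lt(max(abs(s$f_t - s$f_m * cos(s$phi))),
              1e-6 * model[[nm]]$f_max)
  }
})

test_that("increasing activation never decreases MTU force", {
  tr_lo <- fix_trial(duration_s = 2, exc = 0.15)
  tr_hi <- fix_trial(duration_s = 2, exc = 0.30)
  f_lo <- simulate_trial(model, tr_lo, cf)$estimates$tau_a
  f_hi <- simulate_trial(model, tr_hi, cf)$estimates$tau_a
  expect_true(all(f_hi >= f_lo - 1e-9))
})

test_that("parameter container enforces invariants", {
  expect_error(mtu_parameters("x", lo_m = -1, ls_t = 0.2, f_max = 100), "positive")
  expect_error(mtu_parameters("x", lo_m = 0.05, ls_t = 0.2, f_max = 100,
                              shape_a = 0.5), "shape_a")
  expect_error(mtu_parameters("x", lo_m = 0.05, ls_t = 0.2, f_max = 100,
                              gt = 2), "gt")
  expect_error(mtu_parameters("x", lo_m = 0.05, ls_t = 0.2, f_max = 100,
                              gp = 1.4), "gp")
  p <- mtu_parameters("x", lo_m = 0.05, ls_t = 0.2, f_max = 100, phi_o = 0.1)
  expect_equal(p$v_max, 0.5)
  expect_equal(p$lmtu_ref, 0.05 * cos(0.1) + 0.2)
})
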