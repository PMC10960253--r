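cf <- curve_coefficients()

test_that("tendon force-strain curve matches direct evaluation and is linear in gt", {
  eps <- c(-0.01, 0, 0.02, 0.047, 0.1)
  expect_equal(tendon_force_norm(eps, 1, cf), o_ft(eps), tolerance = 1e-12)
  expect_equal(tendon_force_norm(0, 1, cf), 0.200 * exp(0.175) - 0.238,
               tolerance = 1e-12)
  expect_equal(tendon_force_norm(eps, 0.5, cf),
               0.5 * tendon_force_norm(eps, 1, cf), tolerance = 1e-14)
  expect_equal(tendon_stiffness_norm(eps, 0.278, cf),
               0.278 * tendon_stiffness_norm(eps, 1, cf), tolerance = 1e-15)
  # strain at which the gt = 1 curve reaches unit normalized force
  eps_star <- bisect_root(function(e) o_ft(e) - 1, 0, 0.2)
  expect_equal(eps_star, 0.0471, tolerance = 1e-3)
  expect_equal(tendon_force_norm(eps_star, 1, cf), 1, tolerance = 1e-9)
  # strictly increasing in strain
  grid <- seq(-0.01, 0.1, by = 1e-3)
  expect_true(all(diff(tendon_force_norm(grid, 1, cf)) > 0))
})

test_that("active force-length curve matches the gaussian-sum oracle", {
  l <- c(0.65, 0.8, 1, 1.2, 1.35)
  expect_equal(active_force_length(l, cf), o_fa(l), tolerance = 1e-12)
  expect_true(abs(active_force_length(1, cf) - 1) <= 0.01)
  expect_lt(active_force_length(5, cf), 1e-6)   # gaussian decay
  # derivative changes sign across the plateau
  expect_gt(active_stiffness_length(0.8, cf), 0)
  expect_lt(active_stiffness_length(1.2, cf), 0)
  # degenerate width is rejected
  expect_error(active_force_length(0.266 / 0.025, cf), "degenerate")
})

test_that("force-velocity curve is shortening-positive, decreasing and bounded", {
  expect_equal(force_velocity(0, cf), o_fv(0), tolerance = 1e-12)
  expect_equal(force_velocity(0, cf), 1.0057, tolerance = 1e-4)
  expect_lt(force_velocity(1, cf), 1e-4)            # max shortening
  expect_equal(force_velocity(-1, cf), 1.739, tolerance = 1e-4)
  v <- seq(-1.5, 1.5, by = 0.01)
  fv <- force_velocity(v, cf)
  expect_true(all(diff(fv) < 0))
  expect_true(all(fv > 0 & fv < 1.739))
})

test_that("passive force-length curve matches the power law and is linear in gp", {
  expect_equal(passive_force_length(1, 1, cf), 0.014, tolerance = 1e-14)
  expect_equal(passive_force_length(1.35, 1, cf), 0.014 * 1.35^11,
               tolerance = 1e-12)
  expect_identical(passive_force_length(0, 1, cf), 0)
  expect_equal(passive_stiffness_length(1, 1, cf), 11 * 0.014,
               tolerance = 1e-14)
  l <- seq(0.5, 1.5, by = 0.1)
  expect_equal(passive_force_length(l, 1.3, cf),
               1.3 * passive_force_length(l, 1, cf), tolerance = 1e-14)
  expect_true(all(diff(passive_force_length(l, 1, cf)) > 0))
})

test_that("every analytic stiffness curve equals the finite difference of its force curve", {
  h <- 1e-6
  rel_err <- function(analytic, fd) max(abs(analytic - fd) / pmax(abs(analytic), 1e-8))
  eps <- seq(-0.01, 0.10, by = 0.002)
  fd <- (tendon_force_norm(eps + h, 1, cf) - tendon_force_norm(eps - h, 1, cf)) / (2 * h)
  expect_lt(rel_err(tendon_stiffness_norm(eps, 1, cf), fd), 1e-6)

  l <- seq(0.5, 1.5, by = 0.01)
  fd <- (active_force_length(l + h, cf) - active_force_length(l - h, cf)) / (2 * h)
  expect_lt(rel_err(active_stiffness_length(l, cf), fd), 1e-6)

  fd <- (passive_force_length(l + h, 1, cf) - passive_force_length(l - h, 1, cf)) / (2 * h)
  expect_lt(max(abs(passive_stiffness_length(l, 1, cf) - fd)), 1e-8)
})

test_that("coefficient container validates invariants and curve tabulation works", {
  expect_error(curve_coefficients(a1 = -1), "a1")
  expect_error(curve_coefficients(c3 = 0))
  expect_error(tendon_force_norm(0, gt = -1, cf))
  tab <- tabulate_curve("tendon", from = -0.01, to = 0.05, by = 0.01)
  expect_named(tab, c("x", "value", "derivative"))
  expect_equal(tab$value, tendon_force_norm(tab$x, 1, cf))
  tab_v <- tabulate_curve("velocity", from = -1, to = 1, by = 0.5)
  expect_equal(tab_v$value, force_velocity(tab_v$x, cf))
})
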