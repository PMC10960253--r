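#' Construct a trial of synchronized angle and excitation time series
#'
#' A trial bundles the model inputs: a uniformly sampled ankle angle series
#' (rad, dorsiflexion-positive) and one normalized EMG envelope per muscle
#' (fraction of MVC), on a common time grid.
#'
#' @param time Time vector, s, uniformly sampled.
#' @param angle Ankle angle, rad, dorsiflexion-positive; same length as
#'   `time`.
#' @param excitations Data frame of per-muscle envelopes (columns typically
#'   `gm`, `gl`, `so`, `ta`), values in \[0, 1\].
#' @param id Optional trial identifier.
#' @return An object of class `mtu_trial`: a list with elements `time`,
#'   `dt`, `fs`, `angle`, `excitations`, `id`.
#' @export
new_trial <- function(time, angle, excitations, id = NA_character_) {
  stopifnot(is.numeric(time), length(time) >= 2,
            length(angle) == length(time),
            is.data.frame(excitations), nrow(excitations) == length(time))
  dts <- diff(time)
  if (any(abs(dts - dts[1]) > 1e-9))
    stop("trial time grid is not uniform (tolerance 1e-9 s)", call. = FALSE)
  if (anyNA(angle) || anyNA(excitations))
    stop("trial contains missing values", call. = FALSE)
  structure(list(time = as.numeric(time), dt = dts[1], fs = 1 / dts[1],
                 angle = as.numeric(angle),
                 excitations = as.data.frame(excitations),
                 id = id),
            class = "mtu_trial")
}

#' @export
print.mtu_trial <- function(x, ...) {
  cat(sprintf("mtu_trial '%s': %d samples at %.6g Hz (%.6g s), channels: %s\n",
              x$id, length(x$time), x$fs, length(x$time) * x$dt,
              paste(names(x$excitations), collapse = ", ")))
  invisible(x)
}

#' Activation dynamics: nonlinear excitation-to-activation map
#'
#' Maps a normalized EMG envelope `u` into muscle activation through
#' `(exp(A * u) - 1) / (exp(A) - 1)`, where the shape factor `A` in (-3, 0)
#' controls the curvature (more negative = stronger amplification of low
#' excitations). Endpoints are fixed: u = 0 maps to 0 and u = 1 to 1. As A
#' approaches 0 the map tends to the identity; for |A| < 1e-6 a second-order
#' series expansion is used to avoid 0/0.
#'
#' @param u Normalized excitation in \[0, 1\], vectorized.
#' @param shape_a Shape factor A in (-3, 0).
#' @return Activation in \[0, 1\], same length as `u`.
#' @export
activation_from_excitation <- function(u, shape_a) {
  stopifnot(is.numeric(u), all(is.finite(u)),
            shape_a > -3, shape_a < 0 || abs(shape_a) < 1e-6)
  if (any(u < 0 | u > 1))
    stop("excitation must lie in [0, 1]", call. = FALSE)
  if (abs(shape_a) < 1e-6) {
    u + shape_a * u * (u - 1) / 2
  } else {
    (exp(shape_a * u) - 1) / (exp(shape_a) - 1)
  }
}

#' Linear constant-moment-arm MTU kinematics
#'
#' Maps ankle angle to MTU length with a constant moment arm anchored at the
#' reference posture: `l_mtu = lmtu_ref + r * (theta - theta_ref)`. With a
#' positive moment arm and dorsiflexion-positive angles, the plantarflexor
#' MTUs lengthen as the ankle dorsiflexes.
#'
#' @param theta Ankle angle, rad, dorsiflexion-positive, vectorized.
#' @param params An [mtu_parameters()] object.
#' @return MTU length, m, same length as `theta`.
#' @export
mtu_length_from_angle <- function(theta, params) {
  params$lmtu_ref + params$r * (theta - params$theta_ref)
}

#' Pennation angle at constant muscle thickness
#'
#' `phi = asin(sin(phi_o) / lnorm)`: as the fiber shortens the pennation
#' angle grows so that the muscle thickness `lo_m * sin(phi_o)` stays
#' constant.
#'
#' @param lnorm Normalized fiber length (>= sin(phi_o)), vectorized.
#' @param phi_o Pennation angle at optimal fiber length, rad.
#' @return Pennation angle, rad.
#' @export
pennation_angle <- function(lnorm, phi_o) {
  s <- sin(phi_o) / lnorm
  if (any(s > 1))
    stop("infeasible geometry: fiber shorter than muscle thickness (sin(phi_o)/lnorm > 1)",
         call. = FALSE)
  asin(s)
}

#' Normalized fiber velocity by backward differences
#'
#' `vnorm[k] = -(l_m[k] - l_m[k-1]) / dt / v_max`, shortening-positive, with
#' `vnorm[1] = 0`. During trial simulation the same backward difference is
#' evaluated implicitly inside the equilibrium residual (against the
#' previously solved fiber length), so the velocities stored in a simulated
#' state series satisfy exactly this relation; an explicit lagged velocity
#' would oscillate whenever the tendon is much stiffer than the fiber.
#'
#' @param l_m Fiber length series, m.
#' @param dt Sampling interval, s (> 0).
#' @param params An [mtu_parameters()] object (supplies `v_max`).
#' @return Normalized velocity series, same length as `l_m`.
#' @export
fiber_velocity_series <- function(l_m, dt, params) {
  stopifnot(dt > 0, length(l_m) >= 1)
  c(0, -diff(l_m) / dt / params$v_max)
}

#' Solve the fiber-tendon force equilibrium of one MTU
#'
#' Finds the fiber length at which the tendon force balances the fiber force
#' projected on the tendon's line of action,
#' `ft(eps_t) = (a * fa * fv + fp) * cos(phi)`, by Brent's method on the
#' normalized residual. The search bracket is `lnorm` in
#' `[max(0.3, sin(phi_o) + 1e-6), 1.8]`, widened by factors of 1.5 (first
#' upward up to three times, then downward to the pennation geometry
#' limit) if the residual does not change sign; fiber-length tolerance is
#' 1e-12 m, which leaves the force residual below 1e-6 * f_max. A slack
#' tendon (negative strain at the solution) is solved as written but
#' flagged.
#'
#' @param a Activation in \[0, 1\].
#' @param l_mtu MTU length, m.
#' @param vnorm Normalized fiber velocity (shortening-positive).
#' @param params An [mtu_parameters()] object.
#' @param coeffs A [curve_coefficients()] object.
#' @return A one-sample MTU state: a named list with fiber length `l_m`,
#'   `lnorm`, pennation `phi`, `vnorm`, tendon strain `eps_t`, forces `f_t`,
#'   `f_m`, `f_mtu` (N), stiffnesses `k_t`, `k_m`, `k_eqm`, `k_mtu` (N/m),
#'   the activation `a`, and a bit-coded `flag` (1 = slack tendon, 2 = fiber
#'   outside \[0.65, 1.35\], 4 = non-physical stiffness).
#' @export
solve_fiber_equilibrium <- function(a, l_mtu, vnorm = 0, params,
                                    coeffs = curve_coefficients()) {
  stopifnot(a >= 0, a <= 1, is.finite(l_mtu), is.finite(vnorm))
  st <- cpp_solve_equilibrium(a, l_mtu, vnorm, unclass(params),
                              as_coeff_list(coeffs))
  st$a <- a
  st
}

#' Analytic MTU stiffness composition
#'
#' Composes tendon, fiber, and unit stiffness from a converged equilibrium
#' state: `k_t = (f_max / ls_t) * kt(eps_t)`,
#' `k_m = (f_max / lo_m) * (a * ka * fv + kp)`,
#' `k_eqm = k_m * cos(phi)^2 + (f_m / l_m) * sin(phi)^2` (the fiber
#' stiffness seen along the tendon's line of action, including the geometric
#' pennation term), and the series combination
#' `k_mtu = 1 / (1 / k_t + 1 / k_eqm)`. If `k_t` or `k_eqm` is not
#' positive, `k_mtu` is reported as 0 with a warning.
#'
#' @param state A state as returned by [solve_fiber_equilibrium()] (must
#'   carry the activation `a`).
#' @inheritParams solve_fiber_equilibrium
#' @return A list with `k_t`, `k_m`, `k_eqm`, `k_mtu` (N/m).
#' @export
mtu_stiffness <- function(state, params, coeffs = curve_coefficients()) {
  fv <- force_velocity(state$vnorm, coeffs)
  k_t <- (params$f_max / params$ls_t) *
    tendon_stiffness_norm(state$eps_t, params$gt, coeffs)
  k_m <- (params$f_max / params$lo_m) *
    (state$a * active_stiffness_length(state$lnorm, coeffs) * fv +
       passive_stiffness_length(state$lnorm, params$gp, coeffs))
  k_eqm <- k_m * cos(state$phi)^2 + (state$f_m / state$l_m) * sin(state$phi)^2
  if (k_t <= 0 || k_eqm <= 0) {
    warning("non-positive tendon or fiber stiffness; k_mtu reported as 0")
    k_mtu <- 0
  } else {
    k_mtu <- 1 / (1 / k_t + 1 / k_eqm)
  }
  list(k_t = k_t, k_m = k_m, k_eqm = k_eqm, k_mtu = k_mtu)
}

#' Joint-level projection of MTU forces and stiffness
#'
#' With a common constant moment arm `r`, ankle torque is
#' `tau_a = sum(r * f_mtu_j)` and rotational ankle stiffness is
#' `k_a = sum(r^2 * k_mtu_j)`.
#'
#' @param f_mtu,k_mtu Numeric vectors (or matrices with one column per MTU)
#'   of MTU forces (N) and stiffnesses (N/m).
#' @param r Moment arm, m.
#' @return Torque in N m (`joint_torque`) or rotational stiffness in
#'   N m/rad (`joint_stiffness`); per-sample if matrices are supplied.
#' @export
joint_torque <- function(f_mtu, r) {
  if (is.matrix(f_mtu)) r * rowSums(f_mtu) else r * sum(f_mtu)
}

#' @rdname joint_torque
#' @export
joint_stiffness <- function(k_mtu, r) {
  if (is.matrix(k_mtu)) r^2 * rowSums(k_mtu) else r^2 * sum(k_mtu)
}

#' Centered GM fiber displacement along the tendon's line of action
#'
#' `l_m * cos(phi)` centered to zero mean over the trial; the model's proxy
#' for the measured displacement of the GM muscle-tendon junction.
#'
#' @param l_m Fiber length series, m.
#' @param phi Pennation angle series, rad.
#' @return Zero-mean displacement series, m.
#' @export
gm_displacement <- function(l_m, phi) {
  stopifnot(length(l_m) >= 1, length(phi) == length(l_m))
  proj <- l_m * cos(phi)
  proj - mean(proj)
}

#' Simulate a trial through the EMG-driven model
#'
#' Runs the full per-sample pipeline for every MTU: activation dynamics,
#' linear MTU kinematics, lagged fiber-velocity estimate, fiber-tendon
#' equilibrium, and stiffness composition; then aggregates to the joint
#' level. Excitation channels are matched to MTUs by name
#' (case-insensitive); the GM displacement proxy uses the model's first MTU.
#'
#' @param model Named list of [mtu_parameters()] (one per modeled MTU, GM
#'   first); all MTUs must share the same moment arm.
#' @param trial An [new_trial()] object with one excitation channel per
#'   modeled MTU.
#' @param coeffs A [curve_coefficients()] object.
#' @return An object of class `trial_estimates`: a list with `estimates`
#'   (data frame: `time`, `tau_a` N m, `k_a` N m/rad, `k_att` N/m summed
#'   tendon stiffness, `k_tsm` N/m summed muscle stiffness, `delta_gm` m)
#'   and `states` (named list of per-MTU state data frames).
#' @export
simulate_trial <- function(model, trial, coeffs = curve_coefficients()) {
  stopifnot(inherits(trial, "mtu_trial"), length(model) >= 1)
  rs <- vapply(model, `[[`, numeric(1), "r")
  if (any(abs(rs - rs[1]) > 1e-12))
    stop("all MTUs must share the same moment arm", call. = FALSE)
  io <- model_trial_inputs(model, trial)
  res <- cpp_simulate_trial(io$act, io$lmtu, trial$dt,
                            lapply(model, unclass), as_coeff_list(coeffs),
                            full = TRUE)
  r <- rs[1]
  est <- data.frame(
    time = trial$time,
    tau_a = r * res$f_mtu_sum,
    k_a = r^2 * res$k_mtu_sum,
    k_att = res$k_t_sum,
    k_tsm = res$k_m_sum,
    delta_gm = res$gm_proj - mean(res$gm_proj)
  )
  states <- lapply(seq_along(model), function(j) {
    df <- as.data.frame(res$states[[j]])
    df$a <- io$act[, j]
    df$time <- trial$time
    df
  })
  names(states) <- names(model)
  structure(list(estimates = est, states = states,
                 mean_violation = res$mean_violation, r = r),
            class = "trial_estimates")
}

# Shared input assembly: activation and MTU-length matrices (n x m).
model_trial_inputs <- function(model, trial) {
  exc_names <- tolower(names(trial$excitations))
  act <- matrix(0, length(trial$time), length(model))
  lmtu <- matrix(0, length(trial$time), length(model))
  for (j in seq_along(model)) {
    ch <- match(tolower(model[[j]]$name), exc_names)
    if (is.na(ch))
      stop(sprintf("trial has no excitation channel for MTU '%s'",
                   model[[j]]$name), call. = FALSE)
    act[, j] <- activation_from_excitation(trial$excitations[[ch]],
                                           model[[j]]$shape_a)
    lmtu[, j] <- mtu_length_from_angle(trial$angle, model[[j]])
  }
  list(act = act, lmtu = lmtu)
}

#' @export
print.trial_estimates <- function(x, ...) {
  e <- x$estimates
  cat(sprintf(
    "trial_estimates: %d samples, %d MTUs\n  tau_a  [%.2f, %.2f] N m\n  k_a    [%.1f, %.1f] N m/rad\n  k_att  [%.0f, %.0f] N/m\n  k_tsm  [%.0f, %.0f] N/m\n",
    nrow(e), length(x$states), min(e$tau_a), max(e$tau_a),
    min(e$k_a), max(e$k_a), min(e$k_att), max(e$k_att),
    min(e$k_tsm), max(e$k_tsm)))
  invisible(x)
}
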