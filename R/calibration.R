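#' Variance-normalized mean squared error
#'
#' `mean((est - ref)^2) / var(ref)` with the population variance of the
#' reference, so a constant estimate equal to `mean(ref)` scores exactly 1.
#' This is the error functional combined across biomechanical variables by
#' the calibration objective.
#'
#' @param est,ref Numeric series of equal length (>= 2).
#' @return Dimensionless error (scalar).
#' @export
normalized_error <- function(est, ref) {
  stopifnot(length(est) == length(ref), length(ref) >= 2,
            all(is.finite(est)), all(is.finite(ref)))
  v <- mean((ref - mean(ref))^2)
  if (v <= 0) stop("reference signal has zero variance", call. = FALSE)
  mean((est - ref)^2) / v
}

#' Percent root-mean-square error normalized by reference RMS
#'
#' `100 * rms(est - ref) / rms(ref)`: the accuracy metric reported for every
#' estimated biomechanical variable.
#'
#' @inheritParams normalized_error
#' @return Error in percent.
#' @export
nrmse <- function(est, ref) {
  stopifnot(length(est) == length(ref), length(ref) >= 1,
            all(is.finite(est)), all(is.finite(ref)))
  r <- sqrt(mean(ref^2))
  if (r <= 0) stop("reference signal has zero RMS", call. = FALSE)
  100 * sqrt(mean((est - ref)^2)) / r
}

#' Physiological penalty factor
#'
#' Quadratic-hinge penalty on non-physiological MTU states: normalized fiber
#' lengths outside \[0.65, 1.35\] and negative tendon strain (slack tendon).
#' `p = 1 + gamma * mean(violation)` where the violation at each sample of
#' each MTU is `max(0, 0.65 - lnorm)^2 + max(0, lnorm - 1.35)^2 +
#' max(0, -eps_t)^2`. `p = 1` when every sample is physiological; the
#' functional form is a package choice (only what is penalized is dictated
#' by the model), and `gamma` is configurable.
#'
#' @param states List of per-MTU state data frames (columns `lnorm`,
#'   `eps_t`), e.g. the `states` element of [simulate_trial()] output.
#' @param gamma Penalty gain (default 100).
#' @return Penalty factor `p >= 1`.
#' @export
penalty_factor <- function(states, gamma = 100) {
  stopifnot(length(states) >= 1, gamma >= 0)
  v <- vapply(states, function(s) {
    mean(pmax(0, 0.65 - s$lnorm)^2 + pmax(0, s$lnorm - 1.35)^2 +
           pmax(0, -s$eps_t)^2)
  }, numeric(1))
  1 + gamma * mean(v)
}

#' Multi-level reference signal set
#'
#' The five reference series a calibration can be informed by: ankle torque,
#' ankle stiffness, centered GM displacement, summed Achilles tendon
#' stiffness, and summed triceps surae muscle stiffness, on a common time
#' grid.
#'
#' @param tau_a Ankle torque, N m.
#' @param k_a Ankle rotational stiffness, N m/rad.
#' @param delta_gm Centered GM fiber displacement along the tendon, m.
#' @param k_att Summed tendon stiffness, N/m.
#' @param k_tsm Summed muscle stiffness, N/m.
#' @return An object of class `reference_set` (a data frame).
#' @export
reference_set <- function(tau_a, k_a, delta_gm, k_att, k_tsm) {
  n <- length(tau_a)
  stopifnot(n >= 2, length(k_a) == n, length(delta_gm) == n,
            length(k_att) == n, length(k_tsm) == n)
  df <- data.frame(tau_a = tau_a, k_a = k_a, delta_gm = delta_gm,
                   k_att = k_att, k_tsm = k_tsm)
  if (!all(vapply(df, function(x) all(is.finite(x)), logical(1))))
    stop("reference signals must be finite", call. = FALSE)
  structure(df, class = c("reference_set", "data.frame"))
}

#' Calibration specification
#'
#' Defines which reference signals inform the calibration (types 1-4), the
#' tendon-stiffness prior, the physiological penalty gain, and the
#' simulated-annealing settings.
#'
#' Calibration types activate reference signals cumulatively: type 1 uses
#' ankle torque only; type 2 adds ankle stiffness; type 3 adds GM
#' displacement; type 4 adds tendon and muscle stiffness (two further error
#' terms). The tendon prior fixes the starting value and calibration bounds
#' of `gt`: `"degroote"` starts at the generic stiff tendon (`gt = 1`,
#' bounds (0.05, 1.5)); `"compliant"` starts at `gt = 0.278` with bounds
#' +/- 30 percent (0.195, 0.362). The remaining bounds are relative to the
#' initial model: `lo_m`, `ls_t`, `phi_o` +/- 50 percent; `f_max` from 30
#' to 250 percent; `shape_a` in (-3, 0); `gp` in (0.7, 1.3).
#'
#' @param cal_type Integer 1-4.
#' @param tendon_prior `"degroote"` or `"compliant"`.
#' @param gamma Penalty gain (default 100).
#' @param budget Maximum number of objective evaluations (default 15000).
#' @param t0 Initial annealing temperature; `NULL` (default) sets it to the
#'   spread (standard deviation) of the objective over `n_probe` random
#'   probes of the search box.
#' @param cooling Geometric cooling factor per temperature level.
#' @param steps_per_temp Randomized coordinate sweeps per temperature level
#'   (each sweep proposes one move per parameter).
#' @param n_probe Random probes used to set `t0` (counted in the budget).
#' @param step0,step_min Initial and minimum per-coordinate proposal width
#'   on the unit-scaled parameters; each coordinate's width adapts toward a
#'   40-60 percent acceptance rate.
#' @param seed RNG seed; the same seed and inputs reproduce the calibration
#'   bit-identically.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(cal_type = 4,
                             tendon_prior = c("degroote", "compliant"),
                             gamma = 100, budget = 15000, t0 = NULL,
                             cooling = 0.9, steps_per_temp = 3,
                             n_probe = 100, step0 = 0.25, step_min = 1e-3,
                             seed = 1) {
  tendon_prior <- match.arg(tendon_prior)
  stopifnot(cal_type %in% 1:4, gamma >= 0, budget > n_probe,
            cooling > 0, cooling < 1, steps_per_temp >= 1,
            step0 > 0, step_min > 0, step_min <= step0)
  structure(list(cal_type = as.integer(cal_type), tendon_prior = tendon_prior,
                 gamma = gamma, budget = as.integer(budget), t0 = t0,
                 cooling = cooling, steps_per_temp = as.integer(steps_per_temp),
                 n_probe = as.integer(n_probe), step0 = step0,
                 step_min = step_min, seed = as.integer(seed)),
            class = "calibration_spec")
}

# Per-parameter calibration bounds, relative to the initial model.
calibration_bounds <- function(model, spec) {
  gt_b <- if (spec$tendon_prior == "compliant") c(0.278 * 0.7, 0.278 * 1.3)
          else c(0.05 + 1e-4, 1.5 - 1e-4)
  lapply(model, function(p) {
    phi_lo <- 0.5 * p$phi_o
    phi_hi <- min(1.5 * p$phi_o, pi / 2 - 1e-6)
    if (p$phi_o == 0) { phi_lo <- 0; phi_hi <- 1e-9 }
    list(lo_m = c(0.5, 1.5) * p$lo_m,
         ls_t = c(0.5, 1.5) * p$ls_t,
         f_max = c(0.3, 2.5) * p$f_max,
         shape_a = c(-3 + 1e-4, -1e-4),
         phi_o = c(phi_lo, phi_hi),
         gt = gt_b,
         gp = c(0.7 + 1e-4, 1.3 - 1e-4))
  })
}

FREE_PARAMS <- c("lo_m", "ls_t", "f_max", "shape_a", "phi_o", "gt", "gp")

# Encode a model as unit-scaled free parameters (clipped into bounds).
encode_model <- function(model, bounds) {
  unlist(lapply(seq_along(model), function(j) {
    vapply(FREE_PARAMS, function(nm) {
      b <- bounds[[j]][[nm]]
      if (diff(b) <= 0) return(0)
      min(1, max(0, (model[[j]][[nm]] - b[1]) / (b[2] - b[1])))
    }, numeric(1))
  }))
}

# Decode unit-scaled parameters into plain MTU parameter lists. Geometry
# (moment arm, reference MTU length and angle) is the subject's and is not
# calibrated; v_max tracks the decoded optimal fiber length.
decode_model <- function(x, model, bounds) {
  np <- length(FREE_PARAMS)
  out <- lapply(seq_along(model), function(j) {
    p <- unclass(model[[j]])
    for (i in seq_len(np)) {
      b <- bounds[[j]][[FREE_PARAMS[i]]]
      p[[FREE_PARAMS[i]]] <- b[1] + x[(j - 1) * np + i] * max(0, diff(b))
    }
    p$v_max <- 10 * p$lo_m
    p
  })
  names(out) <- names(model)
  out
}

# Precomputed context for fast objective evaluation: fixed MTU-length
# matrix, raw excitation matrix, reference moments, active error terms.
objective_context <- function(model, trial, reference, spec,
                              coeffs = curve_coefficients()) {
  stopifnot(inherits(trial, "mtu_trial"), inherits(reference, "reference_set"),
            nrow(reference) == length(trial$time))
  exc_names <- tolower(names(trial$excitations))
  u <- sapply(model, function(p) {
    ch <- match(tolower(p$name), exc_names)
    if (is.na(ch)) stop(sprintf("no excitation channel for MTU '%s'", p$name),
                        call. = FALSE)
    trial$excitations[[ch]]
  })
  lmtu <- sapply(model, function(p) mtu_length_from_angle(trial$angle, p))
  active <- c(tau_a = TRUE, k_a = spec$cal_type >= 2,
              delta_gm = spec$cal_type >= 3,
              k_att = spec$cal_type == 4, k_tsm = spec$cal_type == 4)
  varp <- vapply(reference, function(x) mean((x - mean(x))^2), numeric(1))
  if (any(varp[active] <= 0))
    stop("active reference signal has zero variance", call. = FALSE)
  list(u = u, lmtu = lmtu, dt = trial$dt, r = model[[1]]$r,
       ref = reference, varp = varp, active = active,
       gamma = spec$gamma, cf = as_coeff_list(coeffs))
}

objective_eval <- function(pars, ctx) {
  act <- ctx$u
  for (j in seq_along(pars))
    act[, j] <- activation_from_excitation(ctx$u[, j], pars[[j]]$shape_a)
  sim <- tryCatch(
    cpp_simulate_trial(act, ctx$lmtu, ctx$dt, pars, ctx$cf, FALSE),
    error = function(e) NULL)
  if (is.null(sim)) return(1e6)   # sentinel: keep the optimizer total
  p <- 1 + ctx$gamma * sim$mean_violation
  est <- list(tau_a = ctx$r * sim$f_mtu_sum,
              k_a = ctx$r^2 * sim$k_mtu_sum,
              delta_gm = sim$gm_proj - mean(sim$gm_proj),
              k_att = sim$k_t_sum, k_tsm = sim$k_m_sum)
  terms <- vapply(names(est)[ctx$active], function(nm) {
    mean((est[[nm]] - ctx$ref[[nm]])^2) / ctx$varp[[nm]]
  }, numeric(1))
  p * mean(terms)
}

#' Multi-level calibration objective
#'
#' The penalized average of the variance-normalized errors of the active
#' reference signals: `Fobj = p * mean(E_active)`, where the active terms
#' are selected by the calibration type (type 4 contributes tendon and
#' muscle stiffness as two separate terms) and `p` is the
#' [penalty_factor()]. A model that fails to simulate scores a large finite
#' sentinel (1e6) so the optimizer stays total.
#'
#' @param model Named list of [mtu_parameters()].
#' @param trial An [new_trial()] with the calibration inputs.
#' @param reference A [reference_set()] on the trial's time grid.
#' @param spec A [calibration_spec()].
#' @param coeffs A [curve_coefficients()] object.
#' @return The objective value (scalar).
#' @export
objective <- function(model, trial, reference, spec = calibration_spec(),
                      coeffs = curve_coefficients()) {
  ctx <- objective_context(model, trial, reference, spec, coeffs)
  objective_eval(lapply(model, unclass), ctx)
}

#' Evaluate a model's nRMSE against a reference set
#'
#' Simulates the model on the trial and reports the percent nRMSE of each of
#' the five biomechanical variables against the reference.
#'
#' @inheritParams objective
#' @return Named numeric vector of nRMSE (percent) for `tau_a`, `k_a`,
#'   `delta_gm`, `k_att`, `k_tsm`.
#' @export
evaluate_model <- function(model, trial, reference,
                           coeffs = curve_coefficients()) {
  stopifnot(inherits(reference, "reference_set"))
  est <- simulate_trial(model, trial, coeffs)$estimates
  vapply(c("tau_a", "k_a", "delta_gm", "k_att", "k_tsm"),
         function(nm) nrmse(est[[nm]], reference[[nm]]), numeric(1))
}

#' Calibrate MTU parameters by bounded simulated annealing
#'
#' Adjusts the seven free parameters of every MTU (21 parameters for the
#' three-muscle model) to minimize the multi-level [objective()]. Parameters
#' are scaled to the unit box of their calibration bounds; proposals perturb
#' a random small subset of coordinates with gaussian steps clipped to the
#' box, acceptance is by the Metropolis rule, cooling is geometric, and the
#' proposal step adapts toward a moderate acceptance rate. Each temperature
#' level restarts from the best-ever point, which is also the returned
#' solution. The run is fully reproducible from `spec$seed`.
#'
#' @param model Initial (e.g. uncalibrated) model: named list of
#'   [mtu_parameters()]. Its values anchor the relative bounds; under the
#'   compliant prior the starting `gt` is reset to 0.278.
#' @inheritParams objective
#' @param validation Optional list with elements `trial` and `reference`:
#'   held-out data on which the fitted model is also scored.
#' @return An object of class `calibration_result`: list with `model`
#'   (fitted [mtu_parameters()]), `best_objective`, `initial_objective`,
#'   `trace` (data frame: `eval`, `value`, `accepted`, `best`), `nrmse_cal`
#'   and optionally `nrmse_val`, `evals`, `seed`, and `improved` (FALSE with
#'   a warning if no proposal ever improved on the start).
#' @export
calibrate <- function(model, trial, reference, spec = calibration_spec(),
                      validation = NULL, coeffs = curve_coefficients()) {
  stopifnot(inherits(spec, "calibration_spec"))
  bounds <- calibration_bounds(model, spec)
  start <- model
  if (spec$tendon_prior == "compliant")
    for (j in seq_along(start)) start[[j]]$gt <- 0.278
  ctx <- objective_context(model, trial, reference, spec, coeffs)
  f_of <- function(x) {
    v <- objective_eval(decode_model(x, model, bounds), ctx)
    if (!is.finite(v)) 1e6 else v
  }

  set.seed(spec$seed)
  npar <- length(FREE_PARAMS) * length(model)
  x0 <- encode_model(start, bounds)
  f0 <- f_of(x0)

  # Temperature from the objective spread over random probes of the box.
  probes <- matrix(runif(spec$n_probe * npar), spec$n_probe, npar)
  fp <- apply(probes, 1, f_of)
  t0 <- spec$t0
  if (is.null(t0)) {
    ok <- fp[is.finite(fp) & fp < 1e6]
    t0 <- if (length(ok) >= 2) max(stats::sd(ok), 1e-8) else max(abs(f0), 1)
  }
  evals <- spec$n_probe + 1L

  x <- x0; f <- f0
  if (min(fp) < f0) { x <- probes[which.min(fp), ]; f <- min(fp) }
  xbest <- x; fbest <- f
  temp <- t0
  v <- rep(spec$step0, npar)   # per-coordinate step widths
  ncap <- spec$budget
  tr_val <- tr_best <- numeric(ncap); tr_acc <- logical(ncap); ntr <- 0L
  accn <- tryn <- numeric(npar)

  while (evals < spec$budget) {
    for (sweep in seq_len(spec$steps_per_temp)) {
      for (i in sample.int(npar)) {   # randomized coordinate sweep
        if (evals >= spec$budget) break
        x2 <- x
        x2[i] <- min(1, max(0, x[i] + runif(1, -1, 1) * v[i]))
        f2 <- f_of(x2)
        evals <- evals + 1L
        accepted <- f2 < f || runif(1) < exp(-(f2 - f) / temp)
        tryn[i] <- tryn[i] + 1
        if (accepted) { x <- x2; f <- f2; accn[i] <- accn[i] + 1 }
        if (f2 < fbest) { xbest <- x2; fbest <- f2 }
        ntr <- ntr + 1L
        tr_val[ntr] <- f2; tr_best[ntr] <- fbest; tr_acc[ntr] <- accepted
      }
      if (sweep %% 5L == 0L || sweep == spec$steps_per_temp) {
        # steer each coordinate's width toward ~50 percent acceptance
        rate <- accn / pmax(1, tryn)
        up <- rate > 0.6; dn <- rate < 0.4
        v[up] <- v[up] * (1 + 2 * (rate[up] - 0.6) / 0.4)
        v[dn] <- v[dn] / (1 + 2 * (0.4 - rate[dn]) / 0.4)
        v <- pmin(1, pmax(spec$step_min, v))
        accn[] <- 0; tryn[] <- 0
      }
    }
    temp <- temp * spec$cooling
    x <- xbest; f <- fbest   # elitist restart each temperature level
  }

  improved <- fbest < f0
  if (!improved)
    warning("annealing budget exhausted without improving on the initial model")
  fitted_raw <- decode_model(xbest, model, bounds)
  fitted <- lapply(fitted_raw, function(p) {
    q <- structure(p, class = "mtu_parameters"); validate_mtu_parameters(q); q
  })
  res <- list(model = fitted, best_objective = fbest, initial_objective = f0,
              trace = data.frame(eval = seq_len(ntr) + spec$n_probe + 1L,
                                 value = tr_val[seq_len(ntr)],
                                 accepted = tr_acc[seq_len(ntr)],
                                 best = tr_best[seq_len(ntr)]),
              nrmse_cal = evaluate_model(fitted, trial, reference, coeffs),
              evals = evals, seed = spec$seed, spec = spec,
              improved = improved)
  if (!is.null(validation))
    res$nrmse_val <- evaluate_model(fitted, validation$trial,
                                    validation$reference, coeffs)
  structure(res, class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "calibration_result: type %d, %s prior, %d evaluations (seed %d)\n  Fobj %.3g -> %.3g\n",
    x$spec$cal_type, x$spec$tendon_prior, x$evals, x$seed,
    x$initial_objective, x$best_objective))
  cat("  calibration nRMSE (%):",
      paste(sprintf("%s %.1f", names(x$nrmse_cal), x$nrmse_cal), collapse = ", "),
      "\n")
  if (!is.null(x$nrmse_val))
    cat("  validation nRMSE (%): ",
        paste(sprintf("%s %.1f", names(x$nrmse_val), x$nrmse_val),
              collapse = ", "), "\n")
  invisible(x)
}
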