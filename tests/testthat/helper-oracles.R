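# Independent oracles and shared fixtures. The oracle curve formulas are
# written out in plain R, independently of the package's compiled path.

fixenv <- new.env(parent = emptyenv())

# --- pure-R constitutive curves (generic default coefficients) -------------
o_ft <- function(eps, gt = 1) gt * (0.200 * exp(35 * (eps + 0.005)) - 0.238)
o_fa <- function(l) {
  b1 <- c(0.813, 0.509, 0.095); b2 <- c(1.070, 0.701, 1.004)
  b3 <- c(0.266, 0.018, 0.309); b4 <- c(-0.025, 0.162, -0.042)
  out <- 0
  for (i in 1:3)
    out <- out + b1[i] * exp(-0.5 * (l - b2[i])^2 / (b3[i] + b4[i] * l)^2)
  out
}
o_fv <- function(v) 1.739 - 1.739 / (1 + exp((0.030 - v) / 0.095))
o_fp <- function(l, gp = 1) gp * 0.014 * l^11

# Equilibrium residual in units of f_max, from the oracle curves only.
o_residual <- function(l_m, a, vnorm, l_mtu, p) {
  lnorm <- l_m / p$lo_m
  sinphi <- sin(p$phi_o) / lnorm
  cphi <- sqrt(1 - sinphi^2)
  eps <- (l_mtu - l_m * cphi) / p$ls_t - 1
  o_ft(eps, p$gt) - (a * o_fa(lnorm) * o_fv(vnorm) + o_fp(lnorm, p$gp)) * cphi
}

# Plain bisection to a fixed interval tolerance.
bisect_root <- function(f, lo, hi, tol = 1e-12, maxit = 300) {
  flo <- f(lo); fhi <- f(hi)
  stopifnot(flo * fhi <= 0)
  for (i in seq_len(maxit)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (fm == 0 || (hi - lo) / 2 < tol) return(mid)
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}

# Oracle fiber length at fixed activation and velocity (bisection, 1e-12 m).
o_solve_lm <- function(a, l_mtu, vnorm, p) {
  lo <- p$lo_m * max(0.3, sin(p$phi_o) + 1e-6)
  hi <- p$lo_m * 1.8
  bisect_root(function(lm) o_residual(lm, a, vnorm, l_mtu, p), lo, hi)
}

# --- fixtures ---------------------------------------------------------------

# Deterministic sinusoidal trial with constant plantarflexor excitation.
fix_trial <- function(duration_s = 6, fs = 100, exc = 0.2, prbs = FALSE,
                      seed = 1) {
  ang <- make_movement_profile(duration_s, fs, with_prbs = prbs, seed = seed)
  n <- length(ang)
  excdf <- data.frame(gm = rep(exc, n), gl = rep(exc, n), so = rep(exc, n),
                      ta = rep(0.01, n))
  new_trial((seq_len(n) - 1) / fs, ang, excdf, "fixture")
}

# Small synthetic subject + processed calibration/validation sets, built once
# per test run (shared across test files through fixenv).
fix_cal_setup <- function() {
  if (!is.null(fixenv$cal)) return(fixenv$cal)
  sub <- make_subject(seed = 7, n_trials = 2)
  reals <- unlist(lapply(seq_along(sub$trials), function(i)
    segment_realizations(sub$trials[[i]], sub$references$noiseless[[i]])),
    recursive = FALSE)
  reals <- filter_ta_active(reals)
  sets <- build_sets(reals, n_val_subsets = 2, subset_size = 10, seed = 1)
  cal_trial <- sets$calibration$trial
  val_trial <- sets$validation[[1]]$trial
  fixenv$cal <- list(
    subject = sub,
    trial = cal_trial,
    reference = make_reference(sub$truth, cal_trial),
    validation = list(trial = val_trial,
                      reference = make_reference(sub$truth, val_trial)))
  fixenv$cal
}

# Minimal hand-built realization for selection/set-building tests.
fake_realization <- function(pf_level, trial_id, period_index, n = 60,
                             ta = 0.01, with_ref = TRUE) {
  excdf <- data.frame(gm = rep(pf_level, n), gl = rep(pf_level, n),
                      so = rep(pf_level, n), ta = rep(ta, n))
  tr <- new_trial((seq_len(n) - 1) / 100, rep(-0.17, n), excdf, trial_id)
  ref <- if (with_ref)
    reference_set(rep(pf_level * 100, n), seq_len(n) + 0,
                  seq_len(n) / n - mean(seq_len(n) / n),
                  rep(1e5, n), rep(5e4, n))
  structure(list(trial = tr, reference = ref, trial_id = trial_id,
                 period_index = period_index), class = "realization")
}
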