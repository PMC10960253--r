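#' Synthetic ankle movement profile
#'
#' Generates the study-style large sinusoidal ankle rotation (amplitude =
#' half peak-to-peak, default 20 degrees at 0.5 Hz, centered at 10 degrees
#' of plantarflexion) with optional superimposed pseudo-random binary
#' (PRBS) position perturbations: a two-level sequence (levels symmetric at
#' +/- half the perturbation amplitude by default) held for the switching
#' time, with linear velocity-saturated transitions so the perturbation's
#' angular velocity never exceeds `vmax_rad_s`.
#'
#' @param duration_s Trial duration, s (default 40).
#' @param fs Sampling rate, Hz (default 100).
#' @param amplitude_deg Sinusoid amplitude (half peak-to-peak), degrees.
#' @param freq_hz Sinusoid frequency, Hz (default 0.5).
#' @param center_deg_pf Movement center, degrees of plantarflexion.
#' @param with_prbs Superimpose PRBS perturbations?
#' @param prbs_amplitude_rad PRBS amplitude (level separation), rad.
#' @param switching_s PRBS switching time, s (default 0.153).
#' @param vmax_rad_s Maximum perturbation velocity, rad/s (default 1.75).
#' @param symmetric Center the two PRBS levels about zero (default TRUE);
#'   otherwise levels are `{0, prbs_amplitude_rad}`.
#' @param seed RNG seed for the switch pattern.
#' @return Ankle angle series, rad dorsiflexion-positive, of length
#'   `duration_s * fs` on the grid `t = (0:(n-1)) / fs`.
#' @export
make_movement_profile <- function(duration_s = 40, fs = 100,
                                  amplitude_deg = 20, freq_hz = 0.5,
                                  center_deg_pf = 10, with_prbs = TRUE,
                                  prbs_amplitude_rad = 0.14,
                                  switching_s = 0.153, vmax_rad_s = 1.75,
                                  symmetric = TRUE, seed = 1) {
  stopifnot(duration_s > 0, fs > 0, freq_hz >= 0, switching_s > 0,
            vmax_rad_s > 0)
  if (fs * switching_s < 1)
    stop("switching time must span at least one sample", call. = FALSE)
  n <- as.integer(round(duration_s * fs))
  t <- (seq_len(n) - 1) / fs
  ang <- angle_from_pf_deg(center_deg_pf) +
    (amplitude_deg * pi / 180) * sin(2 * pi * freq_hz * t)
  if (with_prbs)
    ang <- ang + prbs_perturbation(n, fs, prbs_amplitude_rad, switching_s,
                                   vmax_rad_s, symmetric, seed)
  ang
}

# Velocity-limited two-level PRBS position perturbation.
prbs_perturbation <- function(n, fs, amplitude, switching_s, vmax, symmetric,
                              seed) {
  t <- (seq_len(n) - 1) / fs
  iv <- floor(t / switching_s)
  set.seed(seed)
  lev <- sample(c(0, 1), max(iv) + 1L, replace = TRUE) * amplitude
  if (symmetric) lev <- lev - amplitude / 2
  target <- lev[iv + 1L]
  dmax <- vmax / fs
  p <- numeric(n)
  p[1] <- target[1]
  for (k in 2:n)
    p[k] <- p[k - 1] + min(dmax, max(-dmax, target[k] - p[k - 1]))
  p
}

#' Synthetic per-muscle excitation envelopes
#'
#' Emulates a subject sustaining plantarflexor activity at a target level
#' (default 20 percent MVC): the GM, GL and SO envelopes are the target
#' plus independent low-pass-filtered gaussian noise (rescaled to the
#' requested standard deviation and clipped to \[0, 1\]), while the TA stays
#' near-silent at a small baseline with seeded occasional smooth bursts
#' (exceeding the 5 percent activity threshold) to exercise the TA filter.
#'
#' @param duration_s Trial duration, s.
#' @param fs Sampling rate, Hz.
#' @param pf_target Plantarflexor target level, fraction of MVC (0.20).
#' @param noise_sigma Envelope noise standard deviation, fraction of MVC.
#' @param noise_cutoff_hz Low-pass cutoff of the envelope noise, Hz.
#' @param ta_base TA baseline, fraction of MVC.
#' @param ta_burst_rate Expected TA bursts per trial (0 disables bursts).
#' @param ta_burst_amp Burst peak amplitude above baseline, fraction of MVC.
#' @param ta_burst_dur_s Burst duration scale, s.
#' @param seed RNG seed.
#' @return Data frame with columns `gm`, `gl`, `so`, `ta`.
#' @export
make_excitations <- function(duration_s = 40, fs = 100, pf_target = 0.20,
                             noise_sigma = 0.03, noise_cutoff_hz = 2,
                             ta_base = 0.01, ta_burst_rate = 0.5,
                             ta_burst_amp = 0.08, ta_burst_dur_s = 1,
                             seed = 1) {
  stopifnot(pf_target > 0, pf_target < 1, noise_sigma >= 0, ta_base >= 0)
  n <- as.integer(round(duration_s * fs))
  set.seed(seed)
  smooth_noise <- function() {
    if (noise_sigma == 0) return(numeric(n))
    w <- rnorm(n)
    bf <- signal::butter(2, noise_cutoff_hz / (fs / 2), type = "low")
    y <- signal::filtfilt(bf, w)
    y / stats::sd(y) * noise_sigma
  }
  pf <- function() pmin(1, pmax(0, pf_target + smooth_noise()))
  gm <- pf(); gl <- pf(); so <- pf()
  ta <- rep(ta_base, n)
  if (ta_burst_rate > 0) {
    nb <- stats::rpois(1, ta_burst_rate)
    if (nb > 0) {
      t <- (seq_len(n) - 1) / fs
      centers <- runif(nb, 0, duration_s)
      for (ct in centers)
        ta <- ta + ta_burst_amp * exp(-0.5 * ((t - ct) / (ta_burst_dur_s / 4))^2)
    }
  }
  data.frame(gm = gm, gl = gl, so = so, ta = pmin(1, ta))
}

#' Ground-truth reference signals for a trial
#'
#' Runs a ground-truth model through [simulate_trial()] and packages the
#' five reference signals; optionally degraded with multiplicative gaussian
#' noise (emulating measurement and identification noise on experimental
#' references).
#'
#' @param model Ground-truth model (named list of [mtu_parameters()]).
#' @param trial An [new_trial()].
#' @param noise_sigma Relative noise standard deviation (0 = noiseless).
#' @param seed RNG seed for the noise.
#' @param coeffs A [curve_coefficients()] object.
#' @return A [reference_set()].
#' @export
make_reference <- function(model, trial, noise_sigma = 0, seed = 1,
                           coeffs = curve_coefficients()) {
  est <- simulate_trial(model, trial, coeffs)$estimates
  sig <- est[c("tau_a", "k_a", "delta_gm", "k_att", "k_tsm")]
  if (noise_sigma > 0) {
    set.seed(seed)
    sig <- lapply(sig, function(x) x * (1 + rnorm(length(x), 0, noise_sigma)))
    sig$delta_gm <- sig$delta_gm - mean(sig$delta_gm)
  }
  reference_set(sig$tau_a, sig$k_a, sig$delta_gm, sig$k_att, sig$k_tsm)
}

#' Generate a complete synthetic subject
#'
#' Draws a plausible ground-truth parameter set around the nominal model
#' (lengths, maximum force and pennation uniform within +/- 20 percent;
#' shape factor uniform in (-2.5, -0.5); `gp` uniform in (0.9, 1.1); `gt`
#' fixed by the chosen truth prior, 0.278 for the compliant tendon), then
#' builds a session of `n_trials` 40 s trials (sinusoid + PRBS movement,
#' noisy 20 percent-MVC plantarflexor excitations, near-silent TA) and, if
#' requested, per-trial noiseless and noisy ground-truth reference sets.
#' Regenerating with the same seed is bit-identical, and the ground truth
#' is returned alongside the data for parameter-recovery experiments.
#'
#' @param seed Master RNG seed; per-trial seeds are derived from it.
#' @param n_trials Number of trials in the session (default 21).
#' @param duration_s Trial duration, s (default 40).
#' @param gt_truth Ground-truth tendon-stiffness scale (default 0.278, the
#'   compliant tendon; use 1 for the generic stiff tendon).
#' @param ref_noise_sigma Relative noise on the noisy reference variant.
#' @param ta_burst_rate Expected TA bursts per trial (0 disables).
#' @param movement,excitation Optional named lists of overrides passed on
#'   to [make_movement_profile()] and [make_excitations()].
#' @param make_references Generate ground-truth references (default TRUE)?
#' @return An object of class `synthetic_subject`: list with `truth`,
#'   `trials`, `references` (each with `noiseless` and `noisy`), `seed`,
#'   and the generator `settings`.
#' @export
make_subject <- function(seed = 1, n_trials = 21, duration_s = 40,
                         gt_truth = 0.278, ref_noise_sigma = 0.01,
                         ta_burst_rate = 0.5, movement = list(),
                         excitation = list(), make_references = TRUE) {
  set.seed(seed)
  truth <- lapply(names(NOMINAL_MTUS), function(nm) {
    nom <- NOMINAL_MTUS[[nm]]
    mtu_parameters(nm,
                   lo_m = nom$lo_m * runif(1, 0.8, 1.2),
                   ls_t = nom$ls_t * runif(1, 0.8, 1.2),
                   f_max = nom$f_max * runif(1, 0.8, 1.2),
                   shape_a = runif(1, -2.5, -0.5),
                   phi_o = nom$phi_o * runif(1, 0.8, 1.2),
                   gt = gt_truth, gp = runif(1, 0.9, 1.1))
  })
  names(truth) <- names(NOMINAL_MTUS)

  trials <- vector("list", n_trials)
  refs_clean <- refs_noisy <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    si <- seed * 1000L + i
    mv <- utils::modifyList(list(duration_s = duration_s, seed = si),
                            movement)
    ex <- utils::modifyList(list(duration_s = duration_s,
                                 ta_burst_rate = ta_burst_rate,
                                 seed = si + 500L),
                            excitation)
    ang <- do.call(make_movement_profile, mv)
    exc <- do.call(make_excitations, ex)
    n <- length(ang)
    fs <- mv$fs %||% 100
    trials[[i]] <- new_trial((seq_len(n) - 1) / fs, ang, exc,
                             id = sprintf("trial%02d", i))
    if (make_references) {
      refs_clean[[i]] <- make_reference(truth, trials[[i]], 0)
      refs_noisy[[i]] <- make_reference(truth, trials[[i]], ref_noise_sigma,
                                        seed = si + 900L)
    }
  }
  structure(list(truth = truth, trials = trials,
                 references = if (make_references)
                   list(noiseless = refs_clean, noisy = refs_noisy),
                 seed = seed,
                 settings = list(n_trials = n_trials, duration_s = duration_s,
                                 gt_truth = gt_truth,
                                 ref_noise_sigma = ref_noise_sigma,
                                 ta_burst_rate = ta_burst_rate,
                                 movement = movement, excitation = excitation)),
            class = "synthetic_subject")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf(
    "synthetic_subject (seed %d): %d trials x %g s, truth gt = %.3f%s\n",
    x$seed, length(x$trials), x$settings$duration_s, x$truth[[1]]$gt,
    if (is.null(x$references)) ", no references" else ""))
  invisible(x)
}

#' Synthetic raw EMG at the acquisition rate
#'
#' Amplitude-modulated band-limited noise emulating a raw surface EMG
#' recording whose rectified-smoothed envelope tracks a prescribed profile;
#' used to exercise the envelope-extraction chain (including a powerline
#' component at 60 Hz if requested).
#'
#' @param envelope Target envelope profile (fraction of MVC) at `fs_env`.
#' @param fs_env Sampling rate of `envelope`, Hz.
#' @param fs_out Output raw rate, Hz (default 2500).
#' @param powerline_amp Amplitude of an additive 60 Hz component.
#' @param seed RNG seed.
#' @return Numeric vector of length `length(envelope) * fs_out / fs_env`.
#' @export
synth_raw_emg <- function(envelope, fs_env = 100, fs_out = 2500,
                          powerline_amp = 0, seed = 1) {
  stopifnot(fs_out %% fs_env == 0)
  q <- fs_out / fs_env
  n <- length(envelope) * q
  t <- (seq_len(n) - 1) / fs_out
  env_hi <- approx(seq_along(envelope) / fs_env, envelope, xout = t,
                   rule = 2)$y
  set.seed(seed)
  carrier <- rnorm(n)
  bf <- signal::butter(2, c(20, 450) / (fs_out / 2), type = "pass")
  carrier <- signal::filtfilt(bf, carrier)
  carrier <- carrier / stats::sd(carrier)
  env_hi * carrier + powerline_amp * sin(2 * pi * 60 * t)
}
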