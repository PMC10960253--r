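#' EMG envelope extraction
#'
#' The envelope chain, applied in this exact order: band-stop Butterworth
#' filter at \[59, 61\] Hz (4th order, applied forward-backward so the
#' envelope is not lagged) to remove powerline interference, demean,
#' rectify, smooth with a centered moving mean of 250 ms (the window
#' shrinks symmetrically at the edges), and normalize by the MVC maximum.
#'
#' @param x Raw EMG channel (arbitrary units).
#' @param fs Sampling rate, Hz (>= 500).
#' @param mvc_max Maximum of the MVC recording in the same units (> 0).
#' @param window_s Moving-mean window, s (default 0.25).
#' @param band Stop-band edges, Hz (default `c(59, 61)`).
#' @return Normalized envelope, same length as `x`.
#' @export
emg_envelope <- function(x, fs, mvc_max, window_s = 0.25, band = c(59, 61)) {
  stopifnot(is.numeric(x), length(x) > 24, fs >= 500)
  if (!is.numeric(mvc_max) || mvc_max <= 0)
    stop("mvc_max must be positive", call. = FALSE)
  bf <- signal::butter(2, band / (fs / 2), type = "stop")  # 4th-order bandstop
  y <- filtfilt_padded(bf, x, pad = min(length(x) - 1L, as.integer(2 * fs)))
  y <- y - mean(y)
  y <- abs(y)
  y <- moving_mean(y, odd_window(window_s * fs))
  y / mvc_max
}

odd_window <- function(w) 2L * as.integer(floor(w / 2)) + 1L

# Zero-phase filtering with odd-reflection end padding: extends the signal
# by point-reflected copies at both ends before the forward-backward pass,
# which suppresses the startup transients of an unpadded filtfilt (a
# constant input comes back exactly constant).
filtfilt_padded <- function(filt, x, pad) {
  n <- length(x)
  pad <- max(1L, min(as.integer(pad), n - 1L))
  head_pad <- 2 * x[1] - x[(pad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(filt, c(head_pad, x, tail_pad))
  y[(pad + 1L):(pad + n)]
}

# Centered moving mean with symmetric edge truncation, O(n) via cumsum.
moving_mean <- function(x, w) {
  n <- length(x)
  half <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Decimate signals to a common low rate
#'
#' Anti-alias filtered downsampling of one or several channels from `fs_in`
#' to `fs_out` (default 100 Hz). The input rate must be an integer multiple
#' of the output rate; large factors are applied in stages of at most 10.
#' The output grid starts at the first input sample (t = 0).
#'
#' @param signals A numeric vector, or a data frame / named list of numeric
#'   channels of equal length.
#' @param fs_in Input sampling rate, Hz.
#' @param fs_out Output sampling rate, Hz (default 100).
#' @return Same shape as `signals`, decimated.
#' @export
decimate_all <- function(signals, fs_in, fs_out = 100) {
  q <- fs_in / fs_out
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop(sprintf("input rate %g Hz is not an integer multiple of %g Hz",
                 fs_in, fs_out), call. = FALSE)
  q <- as.integer(round(q))
  dec1 <- function(x) {
    for (qi in stage_factors(q)) {
      bf <- signal::butter(4, 0.8 / qi, type = "low")
      x <- filtfilt_padded(bf, x, pad = min(length(x) - 1L, 30L * qi))
      x <- x[seq(1L, length(x), by = qi)]
    }
    x
  }
  if (is.data.frame(signals)) as.data.frame(lapply(signals, dec1))
  else if (is.list(signals)) lapply(signals, dec1)
  else dec1(signals)
}

# Split a decimation factor into stages <= 10 (filter stability).
stage_factors <- function(q) {
  out <- integer(0)
  while (q > 10L) {
    f <- max(Filter(function(d) q %% d == 0L, 2:10))
    if (length(f) == 0) stop("decimation factor has a prime factor > 10")
    out <- c(out, f)
    q <- q %/% f
  }
  c(out, q[q > 1L])
}

#' Segment a trial into overlapping three-period realizations
#'
#' Cuts a processed trial (and optionally its reference signals) into
#' segments three movement periods long, each starting one period after the
#' previous one. A 40 s trial at a 2 s period yields 18 realizations; a
#' trial shorter than three periods yields none.
#'
#' @param trial An [new_trial()] at the processed rate.
#' @param reference Optional [reference_set()] (or data frame) on the same
#'   grid, segmented alongside.
#' @param period_s Movement period, s (default 2, i.e. 0.5 Hz).
#' @return List of `realization` objects: each a list with `trial` (times
#'   rebased to 0), `reference` (or `NULL`), `trial_id`, `period_index`.
#' @export
segment_realizations <- function(trial, reference = NULL, period_s = 2) {
  stopifnot(inherits(trial, "mtu_trial"), period_s > 0)
  n_per <- as.integer(round(period_s / trial$dt))
  n_seg <- 3L * n_per
  n <- length(trial$time)
  if (!is.null(reference)) stopifnot(nrow(reference) == n)
  n_real <- if (n < n_seg) 0L else (n - n_seg) %/% n_per + 1L
  lapply(seq_len(n_real), function(k) {
    i0 <- (k - 1L) * n_per + 1L
    idx <- i0:(i0 + n_seg - 1L)
    seg <- new_trial(time = (seq_len(n_seg) - 1) * trial$dt,
                     angle = trial$angle[idx],
                     excitations = trial$excitations[idx, , drop = FALSE],
                     id = trial$id)
    ref <- if (is.null(reference)) NULL else reference[idx, , drop = FALSE]
    structure(list(trial = seg, reference = ref, trial_id = trial$id,
                   period_index = k), class = "realization")
  })
}

#' Drop realizations with tibialis anterior activity
#'
#' A realization is discarded when its TA envelope exceeds the threshold
#' (default 5 percent MVC) at any sample; exactly reaching the threshold is
#' kept (strict inequality).
#'
#' @param realizations List of realizations from [segment_realizations()].
#' @param threshold TA activity threshold, fraction of MVC (default 0.05).
#' @param channel Name of the TA envelope column (default `"ta"`).
#' @return The surviving realizations.
#' @export
filter_ta_active <- function(realizations, threshold = 0.05, channel = "ta") {
  keep <- vapply(realizations, function(r) {
    ta <- r$trial$excitations[[channel]]
    if (is.null(ta)) stop("realizations carry no TA channel", call. = FALSE)
    !any(ta > threshold)
  }, logical(1))
  realizations[keep]
}

#' Select the realizations closest to the target activity level
#'
#' Scores each realization by the mean over samples of the squared
#' deviation of the mean plantarflexor envelope (GM, GL, SO) from the
#' target (default 20 percent MVC), and keeps the `n` lowest-scoring ones.
#' Ties are broken by trial id, then period index, so the selection is
#' invariant under reordering of equal-score candidates.
#'
#' @inheritParams filter_ta_active
#' @param n Number of realizations to keep (default 200).
#' @param target Target plantarflexor activity, fraction of MVC (0.20).
#' @param channels Plantarflexor envelope column names.
#' @return A list of exactly `n` realizations.
#' @export
select_realizations <- function(realizations, n = 200, target = 0.20,
                                channels = c("gm", "gl", "so")) {
  if (length(realizations) < n)
    stop(sprintf("only %d realizations available, %d required (shortfall %d)",
                 length(realizations), n, n - length(realizations)),
         call. = FALSE)
  score <- vapply(realizations, function(r) {
    pf <- rowMeans(r$trial$excitations[, channels, drop = FALSE])
    mean((pf - target)^2)
  }, numeric(1))
  tid <- vapply(realizations, function(r) as.character(r$trial_id), character(1))
  pidx <- vapply(realizations, function(r) r$period_index, numeric(1))
  realizations[order(score, tid, pidx)[seq_len(n)]]
}

#' Build calibration and validation reference sets from an ensemble
#'
#' The calibration set is the pointwise mean over all selected realizations
#' of both the model inputs (angle, excitations) and the reference signals;
#' each validation set is the pointwise mean of a seeded random subset
#' (sampled without replacement within a subset, independently across
#' subsets). Averaged GM displacement is re-centered to zero mean.
#'
#' @param ensemble List of realizations (each carrying a `reference`).
#' @param n_val_subsets Number of validation subsets (default 15).
#' @param subset_size Realizations per validation subset (default 100).
#' @param seed RNG seed for the subset draws.
#' @return List with `calibration` and `validation` (a list of
#'   `n_val_subsets`); each element is a list with `trial` ([new_trial()])
#'   and `reference` ([reference_set()]).
#' @export
build_sets <- function(ensemble, n_val_subsets = 15, subset_size = 100,
                       seed = 1) {
  stopifnot(length(ensemble) >= subset_size, length(ensemble) >= 1)
  if (any(vapply(ensemble, function(r) is.null(r$reference), logical(1))))
    stop("every realization must carry reference signals", call. = FALSE)
  set.seed(seed)
  cal <- average_realizations(ensemble)
  val <- lapply(seq_len(n_val_subsets), function(s) {
    idx <- sample.int(length(ensemble), subset_size, replace = FALSE)
    average_realizations(ensemble[idx])
  })
  list(calibration = cal, validation = val)
}

average_realizations <- function(reals) {
  tr1 <- reals[[1]]$trial
  ang <- rowMeans(sapply(reals, function(r) r$trial$angle))
  exc <- as.data.frame(lapply(names(tr1$excitations), function(ch) {
    rowMeans(sapply(reals, function(r) r$trial$excitations[[ch]]))
  }))
  names(exc) <- names(tr1$excitations)
  ref_cols <- lapply(names(reals[[1]]$reference), function(ch) {
    rowMeans(sapply(reals, function(r) r$reference[[ch]]))
  })
  names(ref_cols) <- names(reals[[1]]$reference)
  ref_cols$delta_gm <- ref_cols$delta_gm - mean(ref_cols$delta_gm)
  list(trial = new_trial(tr1$time, ang, exc, id = "ensemble-mean"),
       reference = reference_set(ref_cols$tau_a, ref_cols$k_a,
                                 ref_cols$delta_gm, ref_cols$k_att,
                                 ref_cols$k_tsm))
}
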