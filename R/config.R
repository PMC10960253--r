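#' Default configuration
#'
#' The package's tunable settings, grouped by pipeline stage. `generator`
#' holds the synthetic-protocol constants (trial count and duration,
#' sinusoid, PRBS, plantarflexor target and noise); `model` the initial
#' model scaling and stiffness scale factors; `processing` the envelope /
#' segmentation / selection settings; `calibration` the objective and
#' annealing settings.
#'
#' @return Nested named list of defaults.
#' @export
default_config <- function() {
  list(
    generator = list(
      n_trials = 21, duration_s = 40, fs = 100,
      amplitude_deg = 20, freq_hz = 0.5, center_deg_pf = 10,
      prbs_amplitude_rad = 0.14, switching_s = 0.153, vmax_rad_s = 1.75,
      pf_target = 0.20, noise_sigma = 0.03, noise_cutoff_hz = 2,
      ta_base = 0.01, ta_burst_rate = 0.5, gt_truth = 0.278,
      ref_noise_sigma = 0.01
    ),
    model = list(scale = 1, gt = 1, gp = 1, shape_a = -1.5),
    processing = list(
      envelope_window_s = 0.25, notch_low_hz = 59, notch_high_hz = 61,
      fs_out = 100, period_s = 2, ta_threshold = 0.05,
      n_select = 200, pf_target = 0.20, n_val_subsets = 15,
      subset_size = 100
    ),
    calibration = list(
      cal_type = 4, tendon_prior = "degroote", gamma = 100,
      budget = 15000, cooling = 0.9, steps_per_temp = 3,
      n_probe = 100, step0 = 0.25, step_min = 1e-3
    )
  )
}

# field -> c(lower, upper), open bounds checked strictly
CONFIG_BOUNDS <- list(
  "model.gt" = c(0.05, 1.5),
  "model.gp" = c(0.7, 1.3),
  "model.shape_a" = c(-3, 0)
)

#' Load and validate a configuration file
#'
#' Reads a YAML configuration, fills unset fields with the defaults of
#' [default_config()], rejects unknown keys, and checks bounded fields
#' (e.g. `model.gp` must lie in (0.7, 1.3)).
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Optional nested list merged over the file (highest
#'   precedence); validated the same way.
#' @return The validated, fully populated configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                                 call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
  }
  if (!is.null(overrides)) user <- modifyList(user, overrides)
  check_unknown_keys(user, cfg, prefix = "")
  cfg <- modifyList(cfg, user)
  validate_config(cfg)
  cfg
}

check_unknown_keys <- function(user, ref, prefix) {
  unknown <- setdiff(names(user), names(ref))
  if (length(unknown) > 0)
    stop(sprintf("unknown configuration key(s): %s",
                 paste0(prefix, unknown, collapse = ", ")), call. = FALSE)
  for (k in names(user))
    if (is.list(ref[[k]]) && is.list(user[[k]]))
      check_unknown_keys(user[[k]], ref[[k]], paste0(prefix, k, "."))
}

validate_config <- function(cfg) {
  for (key in names(CONFIG_BOUNDS)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- cfg[[parts[1]]][[parts[2]]]
    b <- CONFIG_BOUNDS[[key]]
    if (!is.numeric(val) || val <= b[1] || val >= b[2])
      stop(sprintf("configuration field %s = %s outside bounds (%g, %g)",
                   key, format(val), b[1], b[2]), call. = FALSE)
  }
  g <- cfg$generator
  pos <- c("n_trials", "duration_s", "fs", "freq_hz", "prbs_amplitude_rad",
           "switching_s", "vmax_rad_s")
  for (f in pos)
    if (!is.numeric(g[[f]]) || g[[f]] <= 0)
      stop(sprintf("configuration field generator.%s must be positive", f),
           call. = FALSE)
  if (g$pf_target <= 0 || g$pf_target >= 1)
    stop("configuration field generator.pf_target outside bounds (0, 1)",
         call. = FALSE)
  cal <- cfg$calibration
  if (!cal$cal_type %in% 1:4)
    stop("configuration field calibration.cal_type must be 1, 2, 3 or 4",
         call. = FALSE)
  if (!cal$tendon_prior %in% c("degroote", "compliant"))
    stop("configuration field calibration.tendon_prior must be 'degroote' or 'compliant'",
         call. = FALSE)
  invisible(cfg)
}
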