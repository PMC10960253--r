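#' Read and write trials as CSV
#'
#' Trials are stored as CSV with a header row `time_s, angle_rad`, then one
#' column per excitation channel with an MVC unit suffix (e.g.
#' `exc_gm_mvc`). Numbers are written with 17 significant digits so a
#' write-read round trip is bit-identical. Angles are radians,
#' dorsiflexion-positive (see [angle_from_pf_deg()] for the experimental
#' convention).
#'
#' @param trial An [new_trial()] object.
#' @param path File path.
#' @return `read_trial()` returns an [new_trial()]; `write_trial()` returns
#'   `path` invisibly.
#' @export
write_trial <- function(trial, path) {
  stopifnot(inherits(trial, "mtu_trial"))
  df <- data.frame(time_s = trial$time, angle_rad = trial$angle)
  for (ch in names(trial$excitations))
    df[[paste0("exc_", ch, "_mvc")]] <- trial$excitations[[ch]]
  write_csv17(df, path)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  df <- read_csv_checked(path)
  need <- c("time_s", "angle_rad")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("trial file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  exc_cols <- grep("^exc_.*_mvc$", names(df), value = TRUE)
  if (length(exc_cols) == 0)
    stop(sprintf("trial file %s has no excitation columns (exc_*_mvc)", path),
         call. = FALSE)
  dts <- diff(df$time_s)
  bad <- which(abs(dts - dts[1]) > 1e-9)
  if (length(bad) > 0)
    stop(sprintf("non-uniform time grid in %s: first offending row %d", path,
                 bad[1] + 2L), call. = FALSE)
  exc <- df[exc_cols]
  names(exc) <- sub("^exc_(.*)_mvc$", "\\1", exc_cols)
  new_trial(df$time_s, df$angle_rad, exc, id = basename(path))
}

# Full-precision CSV writer (17 significant digits round-trips doubles).
write_csv17 <- function(df, path) {
  chr <- as.data.frame(lapply(df, function(x)
    if (is.numeric(x)) sprintf("%.17g", x) else as.character(x)),
    check.names = FALSE)
  names(chr) <- names(df)
  utils::write.table(chr, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_csv_checked <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(utils::read.csv(path), error = function(e)
    stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (nrow(df) == 0)
    stop(sprintf("file %s is empty", path), call. = FALSE)
  na_row <- which(!stats::complete.cases(df))
  if (length(na_row) > 0)
    stop(sprintf("missing value in %s: first offending row %d", path,
                 na_row[1] + 1L), call. = FALSE)
  df
}

#' Read and write reference sets as CSV
#'
#' Columns: `time_s, tau_a_Nm, k_a_Nm_per_rad, delta_gm_m, k_att_N_per_m,
#' k_tsm_N_per_m`, full precision.
#'
#' @param reference A [reference_set()].
#' @param time Time vector matching the reference rows.
#' @param path File path.
#' @return `read_reference_set()` returns a list with `time` and
#'   `reference`; the writer returns `path` invisibly.
#' @export
write_reference_set <- function(reference, time, path) {
  stopifnot(inherits(reference, "reference_set"),
            length(time) == nrow(reference))
  df <- data.frame(time_s = time, tau_a_Nm = reference$tau_a,
                   k_a_Nm_per_rad = reference$k_a,
                   delta_gm_m = reference$delta_gm,
                   k_att_N_per_m = reference$k_att,
                   k_tsm_N_per_m = reference$k_tsm)
  write_csv17(df, path)
  invisible(path)
}

#' @rdname write_reference_set
#' @export
read_reference_set <- function(path) {
  df <- read_csv_checked(path)
  need <- c("time_s", "tau_a_Nm", "k_a_Nm_per_rad", "delta_gm_m",
            "k_att_N_per_m", "k_tsm_N_per_m")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop(sprintf("reference file %s is missing column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  list(time = df$time_s,
       reference = reference_set(df$tau_a_Nm, df$k_a_Nm_per_rad,
                                 df$delta_gm_m, df$k_att_N_per_m,
                                 df$k_tsm_N_per_m))
}

#' Read and write model parameter files (JSON)
#'
#' A model file stores every MTU's parameters (including geometry and the
#' derived `v_max`), optional curve-coefficient overrides, the tendon prior
#' identifier, and a format version. Files round-trip losslessly and are
#' validated against the parameter invariants on load.
#'
#' @param model Named list of [mtu_parameters()].
#' @param path File path.
#' @param prior Optional tendon-prior label stored with the file.
#' @param coeffs Optional non-default [curve_coefficients()] to store.
#' @return `read_model()` returns a list with `model`, `coeffs`, `prior`;
#'   `write_model()` returns `path` invisibly.
#' @export
write_model <- function(model, path, prior = NULL, coeffs = NULL) {
  obj <- list(format_version = 1L,
              prior = prior,
              mtus = lapply(model, unclass),
              coefficients = if (!is.null(coeffs)) unclass(coeffs))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L)
    stop(sprintf("unsupported model file version in %s", path), call. = FALSE)
  model <- lapply(obj$mtus, function(p)
    mtu_parameters(p$name, lo_m = p$lo_m, ls_t = p$ls_t, f_max = p$f_max,
                   shape_a = p$shape_a, phi_o = p$phi_o, gt = p$gt,
                   gp = p$gp, r = p$r, lmtu_ref = p$lmtu_ref,
                   theta_ref = p$theta_ref))
  names(model) <- names(obj$mtus)
  cfs <- if (!is.null(obj$coefficients))
    do.call(curve_coefficients, obj$coefficients)
  else curve_coefficients()
  list(model = model, coeffs = cfs, prior = obj$prior)
}

#' Write a reproducibility record for a command run
#'
#' Every stochastic pipeline step can emit a JSON record carrying the
#' command, its configuration snapshot, all seeds, and the package version,
#' sufficient to reproduce the run exactly.
#'
#' @param command Command name.
#' @param config Configuration list (snapshot).
#' @param seeds Named list/vector of seeds used.
#' @param extra Optional further fields (e.g. nRMSE table, fitted values).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_record <- function(command, config, seeds, extra = list(),
                                path) {
  rec <- c(list(command = command,
                package_version = as.character(utils::packageVersion("emgstiff")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seeds = seeds, config = config), extra)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
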