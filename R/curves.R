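#' Dimensionless muscle-tendon constitutive-curve coefficients
#'
#' Immutable container for the coefficients of the normalized tendon
#' force-strain curve (exponential), the active force-length curve (sum of
#' three gaussians), the force-velocity curve (sigmoid), and the passive
#' force-length curve (11th-power law), together with their analytic
#' derivatives. The defaults are the generic dimensionless coefficients used
#' throughout the package; all curves are evaluated as written, also outside
#' the physiological range, so that equilibrium residuals stay continuous.
#'
#' @param a1,a2,a3,a4 Tendon force-strain coefficients (dimensionless).
#' @param b1,b2,b3,b4 Length-3 numeric vectors: gaussian amplitudes, centers,
#'   base widths and length-proportional widths of the active force-length
#'   curve.
#' @param c1,c2,c3 Force-velocity coefficients; `c1` is the eccentric force
#'   asymptote.
#' @param d1 Passive force-length scale.
#'
#' @return An object of class `curve_coefficients` (a named list).
#' @examples
#' cf <- curve_coefficients()
#' tendon_force_norm(0.02, gt = 1, coeffs = cf)
#' @export
curve_coefficients <- function(a1 = 0.200, a2 = 35, a3 = 0.005, a4 = 0.238,
                               b1 = c(0.813, 0.509, 0.095),
                               b2 = c(1.070, 0.701, 1.004),
                               b3 = c(0.266, 0.018, 0.309),
                               b4 = c(-0.025, 0.162, -0.042),
                               c1 = 1.739, c2 = 0.030, c3 = 0.095,
                               d1 = 0.014) {
  cf <- list(a1 = a1, a2 = a2, a3 = a3, a4 = a4,
             b1 = b1, b2 = b2, b3 = b3, b4 = b4,
             c1 = c1, c2 = c2, c3 = c3, d1 = d1)
  stopifnot(
    all(vapply(cf, function(x) all(is.finite(x)), logical(1))),
    length(b1) == 3, length(b2) == 3, length(b3) == 3, length(b4) == 3,
    a1 > 0, a2 > 0, c1 > 1, c3 > 0, d1 > 0
  )
  structure(cf, class = "curve_coefficients")
}

as_coeff_list <- function(coeffs) {
  if (!inherits(coeffs, "curve_coefficients"))
    stop("`coeffs` must be a curve_coefficients object", call. = FALSE)
  unclass(coeffs)
}

#' Normalized tendon force-strain curve and its derivative
#'
#' `tendon_force_norm()` evaluates the dimensionless tendon force
#' `Gt * (a1 * exp(a2 * (strain + a3)) - a4)`; `tendon_stiffness_norm()` is
#' its analytic derivative with respect to strain. `gt` linearly scales
#' tendon stiffness: `gt = 1` is the generic (stiff) tendon, values near
#' 0.278 describe a markedly more compliant Achilles tendon. Negative strain
#' (slack tendon) is evaluated as written and yields a small negative force;
#' callers that care flag it separately.
#'
#' @param strain Tendon strain, `l_t / ls_t - 1` (dimensionless), vectorized.
#' @param gt Tendon-stiffness scale factor (> 0).
#' @param coeffs A [curve_coefficients()] object.
#' @return Dimensionless force (or stiffness), same length as `strain`.
#' @export
tendon_force_norm <- function(strain, gt = 1, coeffs = curve_coefficients()) {
  stopifnot(is.numeric(strain), all(is.finite(strain)), gt > 0)
  cpp_tendon_force(as.numeric(strain), gt, as_coeff_list(coeffs))
}

#' @rdname tendon_force_norm
#' @export
tendon_stiffness_norm <- function(strain, gt = 1, coeffs = curve_coefficients()) {
  stopifnot(is.numeric(strain), all(is.finite(strain)), gt > 0)
  cpp_tendon_stiffness(as.numeric(strain), gt, as_coeff_list(coeffs))
}

#' Active force-length curve and its derivative
#'
#' Sum of three gaussians in normalized fiber length, with widths that grow
#' linearly with fiber length (`b3 + b4 * lnorm`); the derivative therefore
#' carries the chain rule through both the numerator and the denominator of
#' each gaussian argument.
#'
#' @param lnorm Normalized fiber length `l_m / lo_m` (> 0), vectorized.
#' @inheritParams tendon_force_norm
#' @return Dimensionless force (or its slope), same length as `lnorm`.
#' @export
active_force_length <- function(lnorm, coeffs = curve_coefficients()) {
  check_lnorm_domain(lnorm, coeffs)
  cpp_active_force(as.numeric(lnorm), as_coeff_list(coeffs))
}

#' @rdname active_force_length
#' @export
active_stiffness_length <- function(lnorm, coeffs = curve_coefficients()) {
  check_lnorm_domain(lnorm, coeffs)
  cpp_active_stiffness(as.numeric(lnorm), as_coeff_list(coeffs))
}

check_lnorm_domain <- function(lnorm, coeffs) {
  stopifnot(is.numeric(lnorm), all(is.finite(lnorm)), all(lnorm > 0))
  for (i in 1:3) {
    w <- coeffs$b3[i] + coeffs$b4[i] * lnorm
    if (any(abs(w) < 1e-12))
      stop("degenerate gaussian width b3 + b4 * lnorm = 0 in active curve",
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Force-velocity curve
#'
#' Sigmoidal normalized force-velocity relationship. The sign convention is
#' shortening-positive: `vnorm = +1` is maximum-velocity shortening (force
#' near 0) and negative `vnorm` is lengthening (force approaching the
#' eccentric asymptote `c1`). The curve is strictly decreasing in `vnorm` and
#' bounded in (0, c1).
#'
#' @param vnorm Normalized fiber contraction velocity `v_m / v_max`,
#'   positive during shortening, vectorized.
#' @inheritParams tendon_force_norm
#' @return Dimensionless force, same length as `vnorm`.
#' @export
force_velocity <- function(vnorm, coeffs = curve_coefficients()) {
  stopifnot(is.numeric(vnorm), all(is.finite(vnorm)))
  cpp_force_velocity(as.numeric(vnorm), as_coeff_list(coeffs))
}

#' Passive force-length curve and its derivative
#'
#' Power-law normalized passive fiber force `Gp * d1 * lnorm^11`. `gp`
#' linearly scales the muscle's passive stiffness.
#'
#' @inheritParams active_force_length
#' @param gp Passive-stiffness scale factor (> 0).
#' @return Dimensionless force (or its slope), same length as `lnorm`.
#' @export
passive_force_length <- function(lnorm, gp = 1, coeffs = curve_coefficients()) {
  stopifnot(is.numeric(lnorm), all(is.finite(lnorm)), all(lnorm >= 0), gp > 0)
  cpp_passive_force(as.numeric(lnorm), gp, as_coeff_list(coeffs))
}

#' @rdname passive_force_length
#' @export
passive_stiffness_length <- function(lnorm, gp = 1, coeffs = curve_coefficients()) {
  stopifnot(is.numeric(lnorm), all(is.finite(lnorm)), all(lnorm >= 0), gp > 0)
  cpp_passive_stiffness(as.numeric(lnorm), gp, as_coeff_list(coeffs))
}

#' Tabulate a constitutive curve over a grid
#'
#' Convenience used by the command-line `curves` subcommand: evaluates one of
#' the normalized curves and its derivative over a grid, returning a
#' data frame suitable for plotting or regression tests.
#'
#' @param curve One of `"tendon"`, `"active"`, `"velocity"`, `"passive"`.
#' @param from,to,by Grid specification for the abscissa (strain, normalized
#'   length, or normalized velocity depending on `curve`).
#' @param gt,gp Scale factors passed to the tendon and passive curves.
#' @inheritParams tendon_force_norm
#' @return A data frame with columns `x`, `value`, `derivative`.
#' @export
tabulate_curve <- function(curve = c("tendon", "active", "velocity", "passive"),
                           from, to, by, gt = 1, gp = 1,
                           coeffs = curve_coefficients()) {
  curve <- match.arg(curve)
  x <- seq(from, to, by = by)
  res <- switch(curve,
    tendon = list(tendon_force_norm(x, gt, coeffs),
                  tendon_stiffness_norm(x, gt, coeffs)),
    active = list(active_force_length(x, coeffs),
                  active_stiffness_length(x, coeffs)),
    velocity = {
      fv <- force_velocity(x, coeffs)
      h <- 1e-6
      list(fv, (force_velocity(x + h, coeffs) - force_velocity(x - h, coeffs)) / (2 * h))
    },
    passive = list(passive_force_length(x, gp, coeffs),
                   passive_stiffness_length(x, gp, coeffs))
  )
  data.frame(x = x, value = res[[1]], derivative = res[[2]])
}
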