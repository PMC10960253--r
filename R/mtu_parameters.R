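#' Angle conventions
#'
#' Internally all ankle angles are in radians, dorsiflexion-positive. The
#' experimental convention (degrees, plantarflexion-positive) is converted at
#' the I/O boundary with these helpers.
#'
#' @param deg_pf Angle in degrees, plantarflexion-positive.
#' @param rad_df Angle in radians, dorsiflexion-positive.
#' @return The converted angle.
#' @export
angle_from_pf_deg <- function(deg_pf) -deg_pf * pi / 180

#' @rdname angle_from_pf_deg
#' @export
angle_to_pf_deg <- function(rad_df) -rad_df * 180 / pi

# Reference posture: 10 degrees of plantarflexion (the movement center),
# where the kinematic map and moment arm are anchored.
REF_ANGLE_RAD <- -10 * pi / 180

#' Muscle-tendon unit parameters
#'
#' The seven calibrated parameters of one Hill-type muscle-tendon unit
#' (optimal fiber length, tendon slack length, maximum isometric force,
#' activation shape factor, pennation angle at optimal fiber length, and the
#' tendon- and passive-stiffness scale factors), plus the constant Achilles
#' tendon moment arm and the MTU length at the reference posture that anchor
#' the linear kinematic map. Maximum contraction velocity is derived as
#' `10 * lo_m` per second.
#'
#' @param name MTU label (e.g. `"GM"`).
#' @param lo_m Optimal fiber length, m.
#' @param ls_t Tendon slack length, m.
#' @param f_max Maximum isometric force, N.
#' @param shape_a Activation nonlinearity shape factor, in (-3, 0).
#' @param phi_o Pennation angle at optimal fiber length, rad, in \[0, pi/2).
#' @param gt Tendon-stiffness scale, in (0.05, 1.5); 1 is the generic stiff
#'   tendon, ~0.278 a compliant Achilles tendon.
#' @param gp Muscle passive-stiffness scale, in (0.7, 1.3).
#' @param r Constant moment arm, m (default 0.0513, the Achilles tendon
#'   moment arm at 10 degrees of plantarflexion).
#' @param lmtu_ref MTU length at the reference ankle angle, m. Defaults to
#'   `lo_m * cos(phi_o) + ls_t`, i.e. fiber at optimal length and tendon at
#'   slack length in the reference posture (near-zero passive force at rest).
#' @param theta_ref Reference ankle angle, rad dorsiflexion-positive
#'   (default: 10 degrees plantarflexion).
#'
#' @return An object of class `mtu_parameters` (a named list, including the
#'   derived `v_max`).
#' @examples
#' gm <- mtu_parameters("GM", lo_m = 0.051, ls_t = 0.399, f_max = 1558,
#'                      shape_a = -1.5, phi_o = 0.17)
#' gm$v_max  # 10 * lo_m
#' @export
mtu_parameters <- function(name, lo_m, ls_t, f_max, shape_a = -1.5,
                           phi_o = 0, gt = 1, gp = 1, r = 0.0513,
                           lmtu_ref = NULL, theta_ref = REF_ANGLE_RAD) {
  if (is.null(lmtu_ref)) lmtu_ref <- lo_m * cos(phi_o) + ls_t
  p <- list(name = as.character(name), lo_m = lo_m, ls_t = ls_t,
            f_max = f_max, shape_a = shape_a, phi_o = phi_o, gt = gt,
            gp = gp, r = r, lmtu_ref = lmtu_ref, theta_ref = theta_ref,
            v_max = 10 * lo_m)
  validate_mtu_parameters(p)
  structure(p, class = "mtu_parameters")
}

validate_mtu_parameters <- function(p) {
  num <- p[setdiff(names(p), "name")]
  if (!all(vapply(num, function(x) is.numeric(x) && is.finite(x), logical(1))))
    stop("all MTU parameters must be finite numbers", call. = FALSE)
  if (p$lo_m <= 0 || p$ls_t <= 0 || p$f_max <= 0)
    stop("lo_m, ls_t and f_max must be positive", call. = FALSE)
  if (p$shape_a <= -3 || p$shape_a >= 0)
    stop("shape_a must lie in (-3, 0)", call. = FALSE)
  if (p$phi_o < 0 || p$phi_o >= pi / 2)
    stop("phi_o must lie in [0, pi/2)", call. = FALSE)
  if (p$gt <= 0.05 || p$gt >= 1.5)
    stop("gt must lie in (0.05, 1.5)", call. = FALSE)
  if (p$gp <= 0.7 || p$gp >= 1.3)
    stop("gp must lie in (0.7, 1.3)", call. = FALSE)
  if (abs(p$v_max - 10 * p$lo_m) > 1e-12)
    stop("v_max must equal 10 * lo_m", call. = FALSE)
  invisible(p)
}

#' @export
print.mtu_parameters <- function(x, ...) {
  cat(sprintf(
    "MTU '%s': lo_m=%.4f m, ls_t=%.4f m, f_max=%.0f N, A=%.3f, phi_o=%.3f rad, gt=%.3f, gp=%.3f\n",
    x$name, x$lo_m, x$ls_t, x$f_max, x$shape_a, x$phi_o, x$gt, x$gp))
  invisible(x)
}

# Nominal triceps-surae parameters (generic adult lower-limb values): medial
# gastrocnemius, lateral gastrocnemius, soleus. These seed the uncalibrated
# model and the synthetic ground-truth draws.
NOMINAL_MTUS <- list(
  GM = list(lo_m = 0.051, ls_t = 0.399, f_max = 1558, phi_o = 0.17),
  GL = list(lo_m = 0.059, ls_t = 0.365, f_max = 683,  phi_o = 0.14),
  SO = list(lo_m = 0.044, ls_t = 0.268, f_max = 3549, phi_o = 0.44)
)

#' Build the nominal three-MTU ankle plantarflexor model
#'
#' Returns the shipped generic GM/GL/SO parameter set, optionally with
#' lengths linearly scaled to a subject's stature. This is the
#' "uncalibrated" starting model for calibration.
#'
#' @param scale Positive length scale factor: multiplies `lo_m`, `ls_t` and
#'   `lmtu_ref`; forces are left unchanged.
#' @param gt,gp Stiffness scale factors applied to every MTU (defaults: the
#'   generic stiff tendon `gt = 1` and neutral passive scaling `gp = 1`).
#' @param shape_a Activation shape factor applied to every MTU.
#' @return A named list of three [mtu_parameters()] objects (GM, GL, SO).
#' @export
make_uncalibrated_model <- function(scale = 1, gt = 1, gp = 1, shape_a = -1.5) {
  stopifnot(is.numeric(scale), scale > 0)
  out <- lapply(names(NOMINAL_MTUS), function(nm) {
    n <- NOMINAL_MTUS[[nm]]
    mtu_parameters(nm, lo_m = n$lo_m * scale, ls_t = n$ls_t * scale,
                   f_max = n$f_max, shape_a = shape_a, phi_o = n$phi_o,
                   gt = gt, gp = gp)
  })
  names(out) <- names(NOMINAL_MTUS)
  out
}
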