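#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Dimensionless constitutive-curve coefficients (tendon exponential, triple
// gaussian active force-length, sigmoidal force-velocity, power-law passive).
struct Coefs {
  double a1, a2, a3, a4;
  double b1[3], b2[3], b3[3], b4[3];
  double c1, c2, c3;
  double d1;
};

static Coefs as_coefs(const List& cf) {
  Coefs c;
  c.a1 = as<double>(cf["a1"]); c.a2 = as<double>(cf["a2"]);
  c.a3 = as<double>(cf["a3"]); c.a4 = as<double>(cf["a4"]);
  NumericVector b1 = cf["b1"], b2 = cf["b2"], b3 = cf["b3"], b4 = cf["b4"];
  for (int i = 0; i < 3; ++i) {
    c.b1[i] = b1[i]; c.b2[i] = b2[i]; c.b3[i] = b3[i]; c.b4[i] = b4[i];
  }
  c.c1 = as<double>(cf["c1"]); c.c2 = as<double>(cf["c2"]);
  c.c3 = as<double>(cf["c3"]);
  c.d1 = as<double>(cf["d1"]);
  return c;
}

static inline double ft_curve(double eps, double gt, const Coefs& c) {
  return gt * (c.a1 * std::exp(c.a2 * (eps + c.a3)) - c.a4);
}
static inline double kt_curve(double eps, double gt, const Coefs& c) {
  return gt * c.a1 * c.a2 * std::exp(c.a2 * (eps + c.a3));
}
static inline double fa_curve(double l, const Coefs& c) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = c.b3[i] + c.b4[i] * l;
    if (std::fabs(den) < 1e-12)
      stop("active force-length curve: degenerate gaussian width at lnorm = %g", l);
    double u = (l - c.b2[i]) / den;
    s += c.b1[i] * std::exp(-0.5 * u * u);
  }
  return s;
}
// d fa / d lnorm; the gaussian width b3 + b4*lnorm depends on lnorm, so the
// chain rule runs through both the numerator and denominator of the argument.
static inline double ka_curve(double l, const Coefs& c) {
  double s = 0.0;
  for (int i = 0; i < 3; ++i) {
    double den = c.b3[i] + c.b4[i] * l;
    if (std::fabs(den) < 1e-12)
      stop("active stiffness-length curve: degenerate gaussian width at lnorm = %g", l);
    double u = (l - c.b2[i]) / den;
    double du = (c.b3[i] + c.b4[i] * c.b2[i]) / (den * den);
    s += -c.b1[i] * std::exp(-0.5 * u * u) * u * du;
  }
  return s;
}
static inline double fv_curve(double v, const Coefs& c) {
  return c.c1 - c.c1 / (1.0 + std::exp((c.c2 - v) / c.c3));
}
static inline double fp_curve(double l, double gp, const Coefs& c) {
  return gp * c.d1 * std::pow(l, 11.0);
}
static inline double kp_curve(double l, double gp, const Coefs& c) {
  return gp * 11.0 * c.d1 * std::pow(l, 10.0);
}

// [[Rcpp::export]]
NumericVector cpp_tendon_force(NumericVector strain, double gt, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(strain.size());
  for (R_xlen_t i = 0; i < strain.size(); ++i) out[i] = ft_curve(strain[i], gt, c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_tendon_stiffness(NumericVector strain, double gt, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(strain.size());
  for (R_xlen_t i = 0; i < strain.size(); ++i) out[i] = kt_curve(strain[i], gt, c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_active_force(NumericVector lnorm, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(lnorm.size());
  for (R_xlen_t i = 0; i < lnorm.size(); ++i) out[i] = fa_curve(lnorm[i], c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_active_stiffness(NumericVector lnorm, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(lnorm.size());
  for (R_xlen_t i = 0; i < lnorm.size(); ++i) out[i] = ka_curve(lnorm[i], c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_force_velocity(NumericVector vnorm, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(vnorm.size());
  for (R_xlen_t i = 0; i < vnorm.size(); ++i) out[i] = fv_curve(vnorm[i], c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_passive_force(NumericVector lnorm, double gp, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(lnorm.size());
  for (R_xlen_t i = 0; i < lnorm.size(); ++i) out[i] = fp_curve(lnorm[i], gp, c);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_passive_stiffness(NumericVector lnorm, double gp, List cf) {
  Coefs c = as_coefs(cf);
  NumericVector out(lnorm.size());
  for (R_xlen_t i = 0; i < lnorm.size(); ++i) out[i] = kp_curve(lnorm[i], gp, c);
  return out;
}

// ---------------------------------------------------------------------------
// Fiber-tendon equilibrium
// ---------------------------------------------------------------------------

struct MtuPar {
  double lo_m, ls_t, f_max, phi_o, gt, gp;
  double w;        // muscle thickness lo_m * sin(phi_o), constant
  std::string name;
};

static MtuPar as_par(const List& p) {
  MtuPar m;
  m.lo_m  = as<double>(p["lo_m"]);
  m.ls_t  = as<double>(p["ls_t"]);
  m.f_max = as<double>(p["f_max"]);
  m.phi_o = as<double>(p["phi_o"]);
  m.gt    = as<double>(p["gt"]);
  m.gp    = as<double>(p["gp"]);
  m.w     = m.lo_m * std::sin(m.phi_o);
  m.name  = p.containsElementNamed("name") ? as<std::string>(p["name"]) : "mtu";
  return m;
}

// Velocity rule during the solve.  With vel_implicit, the normalized fiber
// velocity is the backward difference of the candidate fiber length against
// the previously solved one, evaluated inside the residual; this makes the
// per-sample solve implicit in velocity and unconditionally stable (an
// explicit lagged velocity oscillates when the tendon is much stiffer than
// the fiber).  Otherwise vnorm is held fixed at v_fixed.
struct VelRule {
  bool implicit_v;
  double v_fixed;   // used when !implicit_v
  double lm_prev;   // previous solved fiber length (m), implicit mode
  double inv_dt_vmax;
};

static inline double vel_of(double lm, const VelRule& v) {
  if (!v.implicit_v) return v.v_fixed;
  return -(lm - v.lm_prev) * v.inv_dt_vmax;   // shortening positive
}

// Normalized equilibrium residual g(l_m) = ft(eps_t) - (a*fa*fv + fp)*cos(phi),
// in units of f_max.  a held fixed during the solve.
static inline double eq_residual(double lm, double a, const VelRule& vr,
                                 double lmtu, const MtuPar& p, const Coefs& c) {
  double lnorm = lm / p.lo_m;
  double sinphi = p.w / lm;              // constant-thickness pennation
  double cosphi = std::sqrt(1.0 - sinphi * sinphi);
  double lt = lmtu - lm * cosphi;
  double eps = lt / p.ls_t - 1.0;
  double fv = fv_curve(vel_of(lm, vr), c);
  double fm = a * fa_curve(lnorm, c) * fv + fp_curve(lnorm, p.gp, c);
  return ft_curve(eps, p.gt, c) - fm * cosphi;
}

// Brent root bracketing + refinement on fiber length (m).  Tolerance 1e-12 m.
static double brent_fiber(double a, const VelRule& fv, double lmtu,
                          const MtuPar& p, const Coefs& c, int sample) {
  double floor_lm = p.lo_m * (std::sin(p.phi_o) + 1e-6);
  double lo = std::max(p.lo_m * 0.3, floor_lm);
  double hi = p.lo_m * 1.8;
  double fa_ = eq_residual(lo, a, fv, lmtu, p, c);
  double fb_ = eq_residual(hi, a, fv, lmtu, p, c);
  int tries = 0;
  while (fa_ * fb_ > 0.0 && tries < 3) {  // widen upward first
    hi *= 1.5;
    fb_ = eq_residual(hi, a, fv, lmtu, p, c);
    ++tries;
  }
  tries = 0;                // then downward, to the pennation geometry limit
  while (fa_ * fb_ > 0.0 && tries < 3 && lo > floor_lm) {
    lo = std::max(lo / 1.5, floor_lm);
    fa_ = eq_residual(lo, a, fv, lmtu, p, c);
    ++tries;
  }
  if (fa_ * fb_ > 0.0)
    stop("fiber-tendon equilibrium: no sign change for MTU '%s' at sample %d "
         "(residual %g at l_m = %g m, %g at l_m = %g m)",
         p.name.c_str(), sample + 1, fa_, lo, fb_, hi);

  // Brent's method (van Wijngaarden-Dekker-Brent)
  double xa = lo, xb = hi, xc = lo, fc = fa_;
  double d = xb - xa, e = d;
  const double tol0 = 1e-12, eps_m = 2.2204460492503131e-16;
  for (int it = 0; it < 200; ++it) {
    if (std::fabs(fc) < std::fabs(fb_)) {
      xa = xb; xb = xc; xc = xa;
      fa_ = fb_; fb_ = fc; fc = fa_;
    }
    double tol = 2.0 * eps_m * std::fabs(xb) + tol0;
    double xm = 0.5 * (xc - xb);
    if (std::fabs(xm) <= tol || fb_ == 0.0) return xb;
    if (std::fabs(e) >= tol && std::fabs(fa_) > std::fabs(fb_)) {
      double s = fb_ / fa_, pq, q;
      if (xa == xc) {               // secant
        pq = 2.0 * xm * s; q = 1.0 - s;
      } else {                       // inverse quadratic
        double r = fb_ / fc, t = fa_ / fc;
        pq = s * (2.0 * xm * t * (t - r) - (xb - xa) * (r - 1.0));
        q = (t - 1.0) * (r - 1.0) * (s - 1.0);
      }
      if (pq > 0.0) q = -q;
      pq = std::fabs(pq);
      if (2.0 * pq < std::min(3.0 * xm * q - std::fabs(tol * q), std::fabs(e * q))) {
        e = d; d = pq / q;
      } else { d = xm; e = d; }
    } else { d = xm; e = d; }
    xa = xb; fa_ = fb_;
    xb += (std::fabs(d) > tol) ? d : (xm > 0 ? tol : -tol);
    fb_ = eq_residual(xb, a, fv, lmtu, p, c);
    if ((fb_ > 0) == (fc > 0)) { xc = xa; fc = fa_; d = xb - xa; e = d; }
  }
  return xb;
}

// Populate one converged sample's mechanics into the row `k` of `out`.
// Columns: lm lnorm phi vnorm eps ft fm fmtu kt km keqm kmtu flag
static void fill_state(double* row, int n, int k, double lm, double a, double v,
                       double lmtu, const MtuPar& p, const Coefs& c) {
  double lnorm = lm / p.lo_m;
  double sinphi = p.w / lm;
  double phi = std::asin(sinphi);
  double cosphi = std::cos(phi);
  double lt = lmtu - lm * cosphi;
  double eps = lt / p.ls_t - 1.0;
  double fv = fv_curve(v, c);
  double ftn = ft_curve(eps, p.gt, c);
  double fmn = a * fa_curve(lnorm, c) * fv + fp_curve(lnorm, p.gp, c);
  double f_t = p.f_max * ftn;
  double f_m = p.f_max * fmn;
  double k_t = (p.f_max / p.ls_t) * kt_curve(eps, p.gt, c);
  double k_m = (p.f_max / p.lo_m) *
               (a * ka_curve(lnorm, c) * fv + kp_curve(lnorm, p.gp, c));
  double k_eqm = k_m * cosphi * cosphi + (f_m / lm) * sinphi * sinphi;
  double k_mtu;
  double flag = 0.0;
  if (eps < 0.0) flag += 1.0;                       // slack tendon
  if (lnorm < 0.65 || lnorm > 1.35) flag += 2.0;    // fiber out of range
  if (k_t > 0.0 && k_eqm > 0.0) {
    k_mtu = 1.0 / (1.0 / k_t + 1.0 / k_eqm);
  } else {
    k_mtu = 0.0; flag += 4.0;                       // non-physical stiffness
  }
  row[0 * n + k] = lm;     row[1 * n + k] = lnorm;  row[2 * n + k] = phi;
  row[3 * n + k] = v;      row[4 * n + k] = eps;    row[5 * n + k] = f_t;
  row[6 * n + k] = f_m;    row[7 * n + k] = f_t;    row[8 * n + k] = k_t;
  row[9 * n + k] = k_m;    row[10 * n + k] = k_eqm; row[11 * n + k] = k_mtu;
  row[12 * n + k] = flag;
}

// [[Rcpp::export]]
List cpp_solve_equilibrium(double a, double l_mtu, double vnorm, List params,
                           List cf) {
  Coefs c = as_coefs(cf);
  MtuPar p = as_par(params);
  VelRule vr; vr.implicit_v = false; vr.v_fixed = vnorm;
  vr.lm_prev = 0.0; vr.inv_dt_vmax = 0.0;
  double lm = brent_fiber(a, vr, l_mtu, p, c, 0);
  NumericMatrix st(1, 13);
  fill_state(REAL(st), 1, 0, lm, a, vnorm, l_mtu, p, c);
  return List::create(
    _["l_m"] = st(0, 0), _["lnorm"] = st(0, 1), _["phi"] = st(0, 2),
    _["vnorm"] = st(0, 3), _["eps_t"] = st(0, 4), _["f_t"] = st(0, 5),
    _["f_m"] = st(0, 6), _["f_mtu"] = st(0, 7), _["k_t"] = st(0, 8),
    _["k_m"] = st(0, 9), _["k_eqm"] = st(0, 10), _["k_mtu"] = st(0, 11),
    _["flag"] = st(0, 12));
}

// Per-sample loop over all MTUs.  Activation and MTU length are n x m
// matrices; fiber velocity at sample k is the backward difference against
// the previously solved fiber length, evaluated implicitly inside the
// equilibrium residual (first sample: static solve with vnorm = 0).
// Returns joint-level aggregates; per-MTU state matrices when full = true.
// [[Rcpp::export]]
List cpp_simulate_trial(NumericMatrix act, NumericMatrix lmtu, double dt,
                        List params_list, List cf, bool full) {
  Coefs c = as_coefs(cf);
  int n = act.nrow(), m = act.ncol();
  std::vector<MtuPar> pars(m);
  for (int j = 0; j < m; ++j) pars[j] = as_par(params_list[j]);

  NumericVector f_sum(n), kmtu_sum(n), kt_sum(n), km_sum(n);
  NumericVector gm_proj(n);  // first MTU's l_m * cos(phi), for GM displacement
  double viol = 0.0;
  List states(m);

  for (int j = 0; j < m; ++j) {
    const MtuPar& p = pars[j];
    double vmax = 10.0 * p.lo_m;
    NumericMatrix st(n, 13);
    double* s = REAL(st);
    for (int k = 0; k < n; ++k) {
      VelRule vr;
      if (k == 0) {           // no history yet: static solve
        vr.implicit_v = false; vr.v_fixed = 0.0;
        vr.lm_prev = 0.0; vr.inv_dt_vmax = 0.0;
      } else {
        vr.implicit_v = true; vr.v_fixed = 0.0;
        vr.lm_prev = s[0 * n + (k - 1)];
        vr.inv_dt_vmax = 1.0 / (dt * vmax);
      }
      double lm = brent_fiber(act(k, j), vr, lmtu(k, j), p, c, k);
      double v = vel_of(lm, vr);
      fill_state(s, n, k, lm, act(k, j), v, lmtu(k, j), p, c);
      f_sum[k] += s[7 * n + k];
      kmtu_sum[k] += s[11 * n + k];
      kt_sum[k] += s[8 * n + k];
      km_sum[k] += s[9 * n + k];
      if (j == 0) gm_proj[k] = lm * std::cos(s[2 * n + k]);
      double lnorm = s[1 * n + k], eps = s[4 * n + k];
      double d1 = std::max(0.0, 0.65 - lnorm), d2 = std::max(0.0, lnorm - 1.35);
      double d3 = std::max(0.0, -eps);
      viol += d1 * d1 + d2 * d2 + d3 * d3;
    }
    if (full) {
      colnames(st) = CharacterVector::create(
        "l_m", "lnorm", "phi", "vnorm", "eps_t", "f_t", "f_m", "f_mtu",
        "k_t", "k_m", "k_eqm", "k_mtu", "flag");
      states[j] = st;
    }
  }
  List out = List::create(
    _["f_mtu_sum"] = f_sum, _["k_mtu_sum"] = kmtu_sum,
    _["k_t_sum"] = kt_sum, _["k_m_sum"] = km_sum,
    _["gm_proj"] = gm_proj, _["mean_violation"] = viol / (double)(n * m));
  if (full) out["states"] = states;
  return out;
}
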