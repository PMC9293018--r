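#include <Rcpp.h>
#include <cmath>

// Four-variable co-culture right-hand side.
//
// State y = (B, D, DOM_E, DOM_B): bacterial and diatom cell concentrations
// (cells ml^-1) and the exudate / dead-biomass dissolved-organic-matter
// pools (bacterial cell equivalents ml^-1).
//
// Parameter vector layout (fixed, mirrored by .cc_par_vec() on the R side):
//   0 nu_mu_D   1 nu_delta_D  2 nu_mu_B  3 nu_delta_B  4 lam
//   5 CC_D      6 K_DOME      7 K_DOMB   8 delta_DOME  9 delta_DOMB
//  10 yield
// Option vector (integers): 0 split(1)/literal(0) consumption,
//   1 exudation costs diatom biomass (1/0), 2 quadratic fixed-point mu_B (1/0).
//
// Negative state components are clamped to zero before rate evaluation so
// adaptive-step overshoot cannot feed negative concentrations into the
// Monod fractions; the mathematical solution is unchanged because every
// sink flux vanishes with its state variable.
static void cc_rhs_core(const double *y, const double *p, const int *o,
                        double *dy) {
  const double B = y[0] > 0.0 ? y[0] : 0.0;
  const double D = y[1] > 0.0 ? y[1] : 0.0;
  const double E = y[2] > 0.0 ? y[2] : 0.0;
  const double M = y[3] > 0.0 ? y[3] : 0.0; /* DOM_B */

  const double mu_D = p[0] * (1.0 - D / p[5]);
  double den_D = 1.0 + mu_D;
  if (den_D < 1e-12) den_D = 1e-12; /* guard: mu_D <= -1 only when D >> CC_D */
  const double delta_D = p[1] / den_D;

  const double SE = E > 0.0 ? E / (E + p[6]) : 0.0;
  const double SB = M > 0.0 ? M / (M + p[7]) : 0.0;
  const double S = SE + SB;

  double mu_B = 0.0;
  if (S > 0.0) {
    if (o[2] == 1) /* exact nonnegative root of mu(1+mu) = nu_mu_B * S */
      mu_B = 0.5 * (-1.0 + std::sqrt(1.0 + 4.0 * p[2] * S));
    else
      mu_B = p[2] * S;
  }
  const double mu_B_E = S > 0.0 ? mu_B * SE / S : 0.0;
  const double mu_B_B = S > 0.0 ? mu_B * SB / S : 0.0;
  const double delta_B = p[3] / (1.0 + mu_B);

  const double cE = o[0] == 1 ? mu_B_E : mu_B;
  const double cB = o[0] == 1 ? mu_B_B : mu_B;
  const double exu = o[1] == 1 ? p[4] : 0.0;
  const double inv_yield = 1.0 / p[10];

  dy[0] = (mu_B - delta_B) * B;
  dy[1] = (mu_D - delta_D - exu) * D;
  dy[2] = p[4] * D - cE * B * inv_yield - p[8] * E;
  dy[3] = delta_D * D - cB * B * inv_yield - p[9] * M;
}

// [[Rcpp::export(name = ".cc_rhs_cpp")]]
Rcpp::NumericVector cc_rhs_cpp(double t, Rcpp::NumericVector y,
                               Rcpp::NumericVector pars,
                               Rcpp::IntegerVector opts) {
  (void)t; /* autonomous system */
  Rcpp::NumericVector dy(4);
  cc_rhs_core(y.begin(), pars.begin(), opts.begin(), dy.begin());
  return dy;
}

/* Dormand-Prince 5(4) coefficients */
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 71.0 / 57600, e3 = -71.0 / 16695, e4 = 71.0 / 1920,
                    e5 = -17253.0 / 339200, e6 = 22.0 / 525, e7 = -1.0 / 40;

// Adaptive RK4(5) integration of the co-culture system, reporting the state
// on the supplied (strictly increasing) output grid. Steps are shortened to
// land exactly on each output time; no interpolation.
// [[Rcpp::export(name = ".cc_integrate_cpp")]]
Rcpp::NumericMatrix cc_integrate_cpp(Rcpp::NumericVector times,
                                     Rcpp::NumericVector y0,
                                     Rcpp::NumericVector pars,
                                     Rcpp::IntegerVector opts, double rtol,
                                     double atol) {
  const int nt = times.size();
  Rcpp::NumericMatrix out(nt, 4);
  const double *p = pars.begin();
  const int *o = opts.begin();

  double y[4], k1[4], k2[4], k3[4], k4[4], k5[4], k6[4], k7[4], ytmp[4],
      ynew[4];
  for (int j = 0; j < 4; ++j) {
    y[j] = y0[j];
    out(0, j) = y0[j];
  }

  double t = times[0];
  cc_rhs_core(y, p, o, k1); /* FSAL seed */
  double h = 1e-2;
  const double hmin = 1e-12;

  for (int i = 1; i < nt; ++i) {
    const double tend = times[i];
    while (t < tend) {
      if (h > tend - t) h = tend - t;
      /* stages */
      for (int j = 0; j < 4; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      cc_rhs_core(ytmp, p, o, k2);
      for (int j = 0; j < 4; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      cc_rhs_core(ytmp, p, o, k3);
      for (int j = 0; j < 4; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      cc_rhs_core(ytmp, p, o, k4);
      for (int j = 0; j < 4; ++j)
        ytmp[j] =
            y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
      cc_rhs_core(ytmp, p, o, k5);
      for (int j = 0; j < 4; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      cc_rhs_core(ytmp, p, o, k6);
      for (int j = 0; j < 4; ++j)
        ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                              b5 * k5[j] + b6 * k6[j]);
      cc_rhs_core(ynew, p, o, k7);

      /* embedded 4th-order error estimate */
      double errnorm = 0.0;
      for (int j = 0; j < 4; ++j) {
        const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] +
                               e5 * k5[j] + e6 * k6[j] + e7 * k7[j]);
        const double ay = std::fabs(y[j]), an = std::fabs(ynew[j]);
        const double sc = atol + rtol * (ay > an ? ay : an);
        const double r = ej / sc;
        errnorm += r * r;
      }
      errnorm = std::sqrt(errnorm / 4.0);

      bool finite = true;
      for (int j = 0; j < 4; ++j)
        if (!std::isfinite(ynew[j])) finite = false;

      if (finite && errnorm <= 1.0) {
        t += h;
        for (int j = 0; j < 4; ++j) {
          y[j] = ynew[j];
          k1[j] = k7[j]; /* FSAL */
        }
      }
      double fac = finite ? 0.9 * std::pow(errnorm > 1e-10 ? errnorm : 1e-10,
                                           -0.2)
                          : 0.1;
      if (fac > 5.0) fac = 5.0;
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      if (h < hmin)
        Rcpp::stop("integration failure (step underflow) at t = %g days", t);
      if (!finite && h < 1e-10)
        Rcpp::stop("integration failure (non-finite state) at t = %g days", t);
    }
    for (int j = 0; j < 4; ++j) out(i, j) = y[j];
  }
  return out;
}
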