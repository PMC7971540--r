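// Adaptive per-cell integration of the nine-species reaction kinetics.
//
// The reaction term of the polarization model is pointwise: each grid cell
// is an independent 9-dimensional ODE system between diffusion half-steps.
// Pinned fronts drive the activation rates on a few front cells to
// O(10^2) s^-1 while the bulk stays mild, so each cell is advanced with
// its own embedded Cash-Karp 4(5) step controller: stiff cells take many
// small local substeps, calm cells a handful, and no cell pays for
// another's stiffness.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// parameter vector layout (kept in sync with .reactParVector in R/solver.R)
enum Par {
  P_CTOT, P_RTOT, P_RHOTOT, P_IR, P_IRHO, P_A1, P_A2, P_N, P_F,
  P_ALPHA, P_BETA, P_DC, P_DR, P_DRHO, P_RB, P_RHOB,
  P_IP1, P_DELP1, P_K12, P_K21, P_K23, P_K32, P_P3B, NPAR
};

static inline double hillpow(double x, double n) {
  int ni = (int)n;
  if (n == (double)ni && ni >= 1 && ni <= 12) {
    double out = x;
    for (int k = 1; k < ni; k++) out *= x;
    return out;
  }
  return std::pow(x, n);
}

static inline void rhs(const double *y, double Ic, const double *p,
                       double *dy) {
  const double C = y[0], Ci = y[1], R = y[2], Ri = y[3];
  const double rho = y[4], rhoi = y[5], P1 = y[6], P2 = y[7], P3 = y[8];
  const double fb = (1.0 - p[P_F]) + p[P_F] / p[P_P3B] * P3;
  const double QC = Ic / (1.0 + hillpow(rho / p[P_A1], p[P_N])) * fb;
  const double QR = (p[P_IR] + p[P_ALPHA] * C) * fb;
  const double Qr = (p[P_IRHO] + p[P_BETA] * R) /
                    (1.0 + hillpow(C / p[P_A2], p[P_N]));
  const double dC = QC * (Ci / p[P_CTOT]) - p[P_DC] * C;
  const double dR = QR * (Ri / p[P_RTOT]) - p[P_DR] * R;
  const double dr = Qr * (rhoi / p[P_RHOTOT]) - p[P_DRHO] * rho;
  const double gR = 0.5 * (1.0 + R / p[P_RB]);
  const double gr = 0.5 * (1.0 + rho / p[P_RHOB]);
  const double to2 = p[P_K12] * gR * P1;
  const double to1 = p[P_K21] * P2;
  const double to3 = p[P_K23] * gR * P2;
  const double back2 = p[P_K32] * gr * P3;
  dy[0] = dC; dy[1] = -dC;
  dy[2] = dR; dy[3] = -dR;
  dy[4] = dr; dy[5] = -dr;
  dy[6] = p[P_IP1] - p[P_DELP1] * P1 + to1 - to2;
  dy[7] = -to1 + to2 - to3 + back2;
  dy[8] = to3 - back2;
}

// Cash-Karp 4(5) coefficients
static const double b21 = 1.0 / 5.0;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0,
                    b53 = -70.0 / 27.0, b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
static const double d1 = 2825.0 / 27648.0, d3 = 18575.0 / 48384.0,
                    d4 = 13525.0 / 55296.0, d5 = 277.0 / 14336.0,
                    d6 = 1.0 / 4.0;

// [[Rcpp::export(name = ".reactCellsCpp")]]
List reactCells(NumericMatrix Y, NumericVector Ic, NumericVector par,
                double dt, double absTol, double relTol, NumericVector h0) {
  const int n = Y.nrow();
  if (Y.ncol() != 9) stop("state matrix must have 9 columns");
  if (par.size() != NPAR) stop("bad parameter vector");
  NumericMatrix out(clone(Y));
  NumericVector hNext(n);
  double p[NPAR];
  for (int j = 0; j < NPAR; j++) p[j] = par[j];
  long long evals = 0;
  double y[9], y5[9], ytmp[9], errv[9];
  double k1[9], k2[9], k3[9], k4[9], k5[9], k6[9];

  for (int i = 0; i < n; i++) {
    for (int j = 0; j < 9; j++) y[j] = out(i, j);
    const double ic = Ic[i % Ic.size()];
    double t = 0.0, h = std::min(h0[i], dt);
    if (!(h > 0)) h = dt;
    bool justRejected = false;
    long iter = 0;
    while (t < dt * (1.0 - 1e-12)) {
      double hTry = std::min(h, dt - t);
      rhs(y, ic, p, k1);
      for (int j = 0; j < 9; j++) ytmp[j] = y[j] + hTry * b21 * k1[j];
      rhs(ytmp, ic, p, k2);
      for (int j = 0; j < 9; j++)
        ytmp[j] = y[j] + hTry * (b31 * k1[j] + b32 * k2[j]);
      rhs(ytmp, ic, p, k3);
      for (int j = 0; j < 9; j++)
        ytmp[j] = y[j] + hTry * (b41 * k1[j] + b42 * k2[j] + b43 * k3[j]);
      rhs(ytmp, ic, p, k4);
      for (int j = 0; j < 9; j++)
        ytmp[j] = y[j] + hTry * (b51 * k1[j] + b52 * k2[j] + b53 * k3[j] +
                                 b54 * k4[j]);
      rhs(ytmp, ic, p, k5);
      for (int j = 0; j < 9; j++)
        ytmp[j] = y[j] + hTry * (b61 * k1[j] + b62 * k2[j] + b63 * k3[j] +
                                 b64 * k4[j] + b65 * k5[j]);
      rhs(ytmp, ic, p, k6);
      evals += 6;
      double err = 0.0;
      for (int j = 0; j < 9; j++) {
        y5[j] = y[j] + hTry * (c1 * k1[j] + c3 * k3[j] + c4 * k4[j] +
                               c6 * k6[j]);
        errv[j] = hTry * ((c1 - d1) * k1[j] + (c3 - d3) * k3[j] +
                          (c4 - d4) * k4[j] - d5 * k5[j] +
                          (c6 - d6) * k6[j]);
        double sc = absTol +
          relTol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
        double e = std::fabs(errv[j]) / sc;
        if (!(e <= err)) err = e;   // propagates NaN as err = NaN
      }
      if (std::isfinite(err) && err <= 1.0) {
        for (int j = 0; j < 9; j++) y[j] = y5[j];
        t += hTry;
        if (hTry >= h * 0.999) {
          double grow = justRejected
            ? 1.0
            : std::min(2.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
          h = hTry * grow;
        }
        justRejected = false;
      } else {
        h = hTry * (std::isfinite(err)
                      ? std::max(0.2, std::min(0.7, 0.9 * std::pow(err, -0.25)))
                      : 0.5);
        justRejected = true;
        if (h < dt * 1e-12)
          stop("reaction step-size underflow in cell %d at t + %g s", i + 1, t);
      }
      if (++iter > 2000000) stop("reaction substep budget exceeded in cell %d", i + 1);
    }
    for (int j = 0; j < 9; j++) out(i, j) = y[j];
    hNext[i] = h;
  }
  return List::create(_["Y"] = out, _["hNext"] = hNext,
                      _["nEval"] = (double)evals);
}
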