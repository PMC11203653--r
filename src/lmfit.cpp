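#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Three-parameter inversion-recovery model: f(ti) = A - B * exp(-ti / T1).
// Fitted per voxel by damped Gauss-Newton (Levenberg-Marquardt) with the
// analytic Jacobian. Magnitude data lose the sign of f near the null point,
// so the fit is repeated over all n+1 monotone polarity-restoration
// candidates (negate the first k samples) and the lowest-RSS fit wins.

struct FitOut {
  double A, B, t1, rss;
  int polarity, iter;
  bool converged;
};

static inline double rss_of(const std::vector<double>& y,
                            const std::vector<double>& ti,
                            double A, double B, double T1) {
  double s = 0.0;
  for (size_t i = 0; i < y.size(); ++i) {
    double r = y[i] - (A - B * std::exp(-ti[i] / T1));
    s += r * r;
  }
  return s;
}

// Solve a symmetric 3x3 system by Gaussian elimination with partial pivoting.
static bool solve3(double M[3][3], double b[3], double x[3]) {
  int idx[3] = {0, 1, 2};
  for (int c = 0; c < 3; ++c) {
    int piv = c;
    for (int r = c + 1; r < 3; ++r)
      if (std::fabs(M[idx[r]][c]) > std::fabs(M[idx[piv]][c])) piv = r;
    std::swap(idx[c], idx[piv]);
    double d = M[idx[c]][c];
    if (std::fabs(d) < 1e-300) return false;
    for (int r = c + 1; r < 3; ++r) {
      double f = M[idx[r]][c] / d;
      for (int k = c; k < 3; ++k) M[idx[r]][k] -= f * M[idx[c]][k];
      b[idx[r]] -= f * b[idx[c]];
    }
  }
  for (int c = 2; c >= 0; --c) {
    double s = b[idx[c]];
    for (int k = c + 1; k < 3; ++k) s -= M[idx[c]][k] * x[k];
    x[c] = s / M[idx[c]][c];
  }
  return std::isfinite(x[0]) && std::isfinite(x[1]) && std::isfinite(x[2]);
}

// One LM run from a given start; T1 clamped to [t1min, t1max].
static FitOut lm_run(const std::vector<double>& y, const std::vector<double>& ti,
                     double A, double B, double T1,
                     double t1min, double t1max, double tol, int maxit) {
  const int n = (int)y.size();
  if (T1 < t1min) T1 = t1min;
  if (T1 > t1max) T1 = t1max;
  double rss = rss_of(y, ti, A, B, T1);
  double lambda = 1e-3;
  bool converged = false;
  int it = 0;
  std::vector<double> e(n);
  for (; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) e[i] = std::exp(-ti[i] / T1);
    // J columns: d f / d(A, B, T1) = (1, -e_i, -B e_i ti_i / T1^2)
    double JtJ[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
    double Jtr[3] = {0, 0, 0};
    for (int i = 0; i < n; ++i) {
      double j0 = 1.0;
      double j1 = -e[i];
      double j2 = -B * e[i] * ti[i] / (T1 * T1);
      double r = y[i] - (A - B * e[i]);
      JtJ[0][0] += j0 * j0; JtJ[0][1] += j0 * j1; JtJ[0][2] += j0 * j2;
      JtJ[1][1] += j1 * j1; JtJ[1][2] += j1 * j2; JtJ[2][2] += j2 * j2;
      Jtr[0] += j0 * r; Jtr[1] += j1 * r; Jtr[2] += j2 * r;
    }
    JtJ[1][0] = JtJ[0][1]; JtJ[2][0] = JtJ[0][2]; JtJ[2][1] = JtJ[1][2];
    bool accepted = false;
    for (int attempt = 0; attempt < 30; ++attempt) {
      double M[3][3], b[3], d[3];
      for (int r = 0; r < 3; ++r) {
        for (int c = 0; c < 3; ++c) M[r][c] = JtJ[r][c];
        M[r][r] += lambda * (JtJ[r][r] > 1e-300 ? JtJ[r][r] : 1e-300);
        b[r] = Jtr[r];
      }
      if (!solve3(M, b, d)) { lambda *= 8.0; continue; }
      double An = A + d[0], Bn = B + d[1], T1n = T1 + d[2];
      if (T1n < t1min) T1n = t1min;
      if (T1n > t1max) T1n = t1max;
      double rss_new = rss_of(y, ti, An, Bn, T1n);
      if (std::isfinite(rss_new) && rss_new <= rss) {
        double scale = std::fabs(A) + std::fabs(B) + T1 + 1e-12;
        double step = (std::fabs(An - A) + std::fabs(Bn - B) + std::fabs(T1n - T1)) / scale;
        double drop = rss - rss_new;
        A = An; B = Bn; T1 = T1n; rss = rss_new;
        lambda = std::max(lambda / 3.0, 1e-14);
        accepted = true;
        if (step < tol || drop <= 1e-20 * (rss + 1e-300)) converged = true;
        break;
      }
      lambda *= 8.0;
      if (lambda > 1e14) break;
    }
    if (!accepted) { converged = true; break; }  // stuck at a (local) minimum
    if (converged) break;
  }
  FitOut out;
  out.A = A; out.B = B; out.t1 = T1; out.rss = rss;
  out.polarity = 0; out.iter = it + 1; out.converged = converged;
  return out;
}

// Coarse profile init: for T1 on a log grid, (A, B) solve a 2x2 linear LS.
static void profile_init(const std::vector<double>& y, const std::vector<double>& ti,
                         double t1min, double t1max,
                         double& A0, double& B0, double& T10) {
  const int n = (int)y.size();
  const int ng = 24;
  double lo = std::max(t1min, 20.0), hi = std::min(t1max, 12000.0);
  if (hi <= lo) { hi = t1max; lo = t1min; }
  double best = std::numeric_limits<double>::infinity();
  for (int g = 0; g < ng; ++g) {
    double T1 = lo * std::pow(hi / lo, (double)g / (ng - 1));
    double s11 = n, s12 = 0, s22 = 0, b1 = 0, b2 = 0;
    for (int i = 0; i < n; ++i) {
      double e = std::exp(-ti[i] / T1);
      s12 += -e; s22 += e * e;
      b1 += y[i]; b2 += -y[i] * e;
    }
    double det = s11 * s22 - s12 * s12;
    if (std::fabs(det) < 1e-300) continue;
    double A = (b1 * s22 - b2 * s12) / det;
    double B = (s11 * b2 - s12 * b1) / det;
    double r = rss_of(y, ti, A, B, T1);
    if (r < best) { best = r; A0 = A; B0 = B; T10 = T1; }
  }
}

static FitOut fit_candidate(const std::vector<double>& y, const std::vector<double>& ti,
                            const std::vector<double>& ymag,
                            double t1min, double t1max, double tol, int maxit) {
  const int n = (int)y.size();
  // Heuristic start: A0 = max(y), B0 = 2 A0, T10 = TI at minimum magnitude.
  double A0 = y[0];
  for (int i = 1; i < n; ++i) if (y[i] > A0) A0 = y[i];
  double B0 = 2.0 * A0;
  int imin = 0;
  for (int i = 1; i < n; ++i) if (ymag[i] < ymag[imin]) imin = i;
  double T10 = ti[imin];
  if (T10 < t1min) T10 = t1min;
  if (T10 > t1max) T10 = t1max;
  FitOut a = lm_run(y, ti, A0, B0, T10, t1min, t1max, tol, maxit);
  // Profile-likelihood start (guarantees basin capture).
  double Ap = A0, Bp = B0, Tp = T10;
  profile_init(y, ti, t1min, t1max, Ap, Bp, Tp);
  FitOut b = lm_run(y, ti, Ap, Bp, Tp, t1min, t1max, tol, maxit);
  return (b.rss < a.rss) ? b : a;
}

static FitOut fit_voxel(const std::vector<double>& sig, const std::vector<double>& ti,
                        bool magnitude, double t1min, double t1max,
                        double tol, int maxit) {
  const int n = (int)sig.size();
  std::vector<double> ymag(n);
  for (int i = 0; i < n; ++i) ymag[i] = std::fabs(sig[i]);
  FitOut best;
  best.rss = std::numeric_limits<double>::infinity();
  best.converged = false;
  best.A = NA_REAL; best.B = NA_REAL; best.t1 = NA_REAL;
  best.polarity = 0; best.iter = 0;
  int kmax = magnitude ? n : 0;
  std::vector<double> y(sig);
  for (int k = 0; k <= kmax; ++k) {
    if (magnitude) {
      for (int i = 0; i < n; ++i) y[i] = (i < k) ? -ymag[i] : ymag[i];
    }
    FitOut f = fit_candidate(y, ti, ymag, t1min, t1max, tol, maxit);
    f.polarity = k;
    if (f.rss < best.rss) best = f;
  }
  return best;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_fit_stack")]]
List cpp_fit_stack(NumericMatrix Y, NumericVector ti, bool magnitude,
                   double t1min, double t1max, double tol, int maxit) {
  const int n = Y.nrow(), m = Y.ncol();
  std::vector<double> tiv(ti.begin(), ti.end());
  NumericVector A(m), B(m), T1(m), RSS(m);
  IntegerVector POL(m), ITER(m);
  LogicalVector CONV(m);
  std::vector<double> sig(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) sig[i] = Y(i, j);
    FitOut f = fit_voxel(sig, tiv, magnitude, t1min, t1max, tol, maxit);
    A[j] = f.A; B[j] = f.B; T1[j] = f.t1; RSS[j] = f.rss;
    POL[j] = f.polarity; ITER[j] = f.iter; CONV[j] = f.converged;
  }
  return List::create(_["A"] = A, _["B"] = B, _["t1"] = T1, _["rss"] = RSS,
                      _["polarity"] = POL, _["iter"] = ITER,
                      _["converged"] = CONV);
}
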