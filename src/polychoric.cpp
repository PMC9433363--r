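#include <Rcpp.h>
using namespace Rcpp;

// 10-point Gauss-Legendre rule on [-1, 1] (symmetric half)
static const double GLX[5] = {0.1488743389816312, 0.4333953941292472,
                              0.6794095682990244, 0.8650633666889845,
                              0.9739065285171717};
static const double GLW[5] = {0.2955242247147529, 0.2692667193099963,
                              0.2190863625159820, 0.1494513491505806,
                              0.0666713443086881};

static inline double dnorm0(double x) {
  return M_1_SQRT_2PI * std::exp(-0.5 * x * x);
}

// Cell probabilities of the contingency table implied by a standard
// bivariate normal with correlation rho, cut at interior thresholds
// ta (rows) and tb (columns).  Each row strip is integrated by composite
// Gauss-Legendre quadrature; the column dimension is reduced to
// univariate normal cdf differences conditional on the row variable.
// [[Rcpp::export]]
NumericMatrix cpp_bvn_cell_probs(NumericVector ta, NumericVector tb,
                                 double rho) {
  const double LIM = 8.25;
  const int Ka = ta.size() + 1, Kb = tb.size() + 1;
  double s = std::sqrt(std::max(1.0 - rho * rho, 1e-14));

  NumericMatrix P(Ka, Kb);
  std::vector<double> cdf(Kb + 1);
  cdf[0] = 0.0;
  cdf[Kb] = 1.0;

  // narrower panels when |rho| is close to 1 and the conditional cdf is steep
  const double panw = std::min(1.0, std::max(0.15, 2.0 * s));

  for (int i = 0; i < Ka; i++) {
    double lo = (i == 0) ? -LIM : std::min(std::max(ta[i - 1], -LIM), LIM);
    double hi = (i == Ka - 1) ? LIM : std::min(std::max(ta[i], -LIM), LIM);
    if (hi <= lo) continue;
    int npan = (int)std::ceil((hi - lo) / panw);
    double h = (hi - lo) / npan;
    for (int p = 0; p < npan; p++) {
      double mid = lo + (p + 0.5) * h, half = 0.5 * h;
      for (int q = 0; q < 10; q++) {
        int k = q % 5;
        double x = mid + (q < 5 ? -1.0 : 1.0) * half * GLX[k];
        double w = half * GLW[k] * dnorm0(x);
        for (int j = 0; j < Kb - 1; j++)
          cdf[j + 1] = R::pnorm((tb[j] - rho * x) / s, 0.0, 1.0, 1, 0);
        for (int j = 0; j < Kb; j++)
          P(i, j) += w * (cdf[j + 1] - cdf[j]);
      }
    }
  }
  return P;
}

// Contingency-table log likelihood of the polychoric model at fixed
// thresholds; cell probabilities are floored to keep near-empty cells
// from producing -Inf under extreme asymmetry.
// [[Rcpp::export]]
double cpp_polychoric_loglik(NumericMatrix tab, NumericVector ta,
                             NumericVector tb, double rho) {
  NumericMatrix P = cpp_bvn_cell_probs(ta, tb, rho);
  double ll = 0.0;
  for (int i = 0; i < tab.nrow(); i++)
    for (int j = 0; j < tab.ncol(); j++)
      if (tab(i, j) > 0)
        ll += tab(i, j) * std::log(std::max(P(i, j), 1e-30));
  return ll;
}

// Standard bivariate normal density, vectorised over x and y.
// [[Rcpp::export]]
NumericVector cpp_bvn_pdf(NumericVector x, NumericVector y, double rho) {
  int n = x.size();
  double s2 = std::max(1.0 - rho * rho, 1e-14);
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    if (!R_finite(x[i]) || !R_finite(y[i])) {
      out[i] = 0.0;
    } else {
      double z = x[i] * x[i] - 2.0 * rho * x[i] * y[i] + y[i] * y[i];
      out[i] = std::exp(-0.5 * z / s2) / (2.0 * M_PI * std::sqrt(s2));
    }
  }
  return out;
}

// second differences of the bivariate normal density over the threshold
// grid: dP(i,j)/drho for every cell (derivative of the rectangle
// probability with respect to the correlation)
static void cell_dP(const std::vector<double>& A, const std::vector<double>& B,
                    double rho, int Ka, int Kb, std::vector<double>& dP) {
  double s2 = std::max(1.0 - rho * rho, 1e-14);
  double den = 2.0 * M_PI * std::sqrt(s2);
  std::vector<double> F((Ka + 1) * (Kb + 1), 0.0);
  for (int i = 0; i <= Ka; i++)
    for (int j = 0; j <= Kb; j++) {
      double x = A[i], y = B[j];
      if (R_finite(x) && R_finite(y))
        F[i + j * (Ka + 1)] =
          std::exp(-0.5 * (x * x - 2.0 * rho * x * y + y * y) / s2) / den;
    }
  for (int i = 0; i < Ka; i++)
    for (int j = 0; j < Kb; j++)
      dP[i + j * Ka] = F[(i + 1) + (j + 1) * (Ka + 1)] -
        F[i + (j + 1) * (Ka + 1)] - F[(i + 1) + j * (Ka + 1)] +
        F[i + j * (Ka + 1)];
}

// profile score d logL / d rho of the contingency-table likelihood
static double pair_score(const NumericMatrix& tab, NumericVector ta,
                         NumericVector tb, double rho) {
  int Ka = ta.size() + 1, Kb = tb.size() + 1;
  NumericMatrix P = cpp_bvn_cell_probs(ta, tb, rho);
  std::vector<double> A(Ka + 1), B(Kb + 1), dP(Ka * Kb);
  A[0] = R_NegInf; A[Ka] = R_PosInf;
  for (int i = 1; i < Ka; i++) A[i] = ta[i - 1];
  B[0] = R_NegInf; B[Kb] = R_PosInf;
  for (int j = 1; j < Kb; j++) B[j] = tb[j - 1];
  cell_dP(A, B, rho, Ka, Kb, dP);
  double g = 0.0;
  for (int i = 0; i < Ka; i++)
    for (int j = 0; j < Kb; j++)
      if (tab(i, j) > 0)
        g += tab(i, j) * dP[i + j * Ka] / std::max(P(i, j), 1e-30);
  return g;
}

// Two-step polychoric correlation at fixed thresholds: root of the
// profile score by the Illinois (modified regula falsi) method.  The
// bracket starts around the Pearson correlation of the codes and expands
// toward (lo, hi) only when the score does not change sign, so the
// expensive near-boundary evaluations are rare; returns the bound itself
// when the likelihood is monotone.
// [[Rcpp::export]]
double cpp_fit_pair(NumericMatrix tab, NumericVector ta, NumericVector tb,
                    double lo, double hi, double tol, double start) {
  double a = std::max(lo, std::min(start, hi) - 0.2);
  double b = std::min(hi, std::max(start, lo) + 0.2);
  double fa = pair_score(tab, ta, tb, a);
  double fb = pair_score(tab, ta, tb, b);
  while (fa <= 0.0 && a > lo) {          // expand left
    b = a; fb = fa;
    a = std::max(lo, a - 0.25 * (1.0 + std::fabs(a)));
    fa = pair_score(tab, ta, tb, a);
  }
  while (fb >= 0.0 && b < hi) {          // expand right
    a = b; fa = fb;
    b = std::min(hi, b + 0.25 * (1.0 + std::fabs(b)));
    fb = pair_score(tab, ta, tb, b);
  }
  if (fa <= 0.0) return a == lo ? lo : a;
  if (fb >= 0.0) return b == hi ? hi : b;
  int side = 0;
  (void)0;
  for (int it = 0; it < 100; it++) {
    double c = (a * fb - b * fa) / (fb - fa);
    if (!R_finite(c) || c <= a || c >= b) c = 0.5 * (a + b);
    double fc = pair_score(tab, ta, tb, c);
    if (std::fabs(fc) < 1e-12 || (b - a) < tol) return c;
    if (fc > 0.0) {
      a = c; fa = fc;
      if (side == 1) fb *= 0.5;
      side = 1;
    } else {
      b = c; fb = fc;
      if (side == -1) fa *= 0.5;
      side = -1;
    }
  }
  return 0.5 * (a + b);
}
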