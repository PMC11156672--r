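#include <Rcpp.h>
using namespace Rcpp;

// Ordered-probit likelihood pieces for the latent-threshold first stage:
//   P(X = k | G) = Phi(a_k - b.G) - Phi(a_{k-1} - b.G),  a_0 = -Inf, a_K = +Inf.
// Probabilities are floored at PFLOOR inside the log so the optimizer never
// sees -Inf; the unfloored log-likelihood is recomputed in R at the optimum.

static const double PFLOOR = 1e-12;

// Observation weights support aggregation of identical (G-row, X) patterns:
// the weighted likelihood over unique patterns equals the unweighted one
// over individuals exactly.
// [[Rcpp::export]]
List ordprobit_nll_gr(NumericVector b, NumericVector a,
                      NumericMatrix G, IntegerVector x, int K,
                      NumericVector w) {
  const int n = G.nrow(), J = G.ncol();
  const bool wt = w.size() == n;
  NumericVector gb(J), ga(K - 1);
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    const double wi = wt ? w[i] : 1.0;
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += b[j] * G(i, j);
    const int k = x[i];                      // 1..K
    double u = (k < K) ? a[k - 1] - s : R_PosInf;
    double l = (k > 1) ? a[k - 2] - s : R_NegInf;
    double Pu = (k < K) ? R::pnorm(u, 0.0, 1.0, 1, 0) : 1.0;
    double Pl = (k > 1) ? R::pnorm(l, 0.0, 1.0, 1, 0) : 0.0;
    double p = Pu - Pl;
    if (p < PFLOOR) p = PFLOOR;
    nll -= wi * std::log(p);

    double du = (k < K) ? R::dnorm(u, 0.0, 1.0, 0) : 0.0;
    double dl = (k > 1) ? R::dnorm(l, 0.0, 1.0, 0) : 0.0;
    // d nll / d s_i  (s enters both CDF arguments with -1)
    double ws = wi * (du - dl) / p;
    for (int j = 0; j < J; ++j) gb[j] += ws * G(i, j);
    if (k < K) ga[k - 1] -= wi * du / p;     // d nll / d a_k
    if (k > 1) ga[k - 2] += wi * dl / p;     // d nll / d a_{k-1}
  }
  return List::create(_["nll"] = nll, _["gb"] = gb, _["ga"] = ga);
}

// Negative log-likelihood with analytic gradient AND observed-information
// Hessian, parameter order (b_1..b_J, a_1..a_{K-1}). The nll is convex in
// (b, a), so Newton steps on this Hessian converge quadratically.
// [[Rcpp::export]]
List ordprobit_nll_gr_hess(NumericVector b, NumericVector a,
                           NumericMatrix G, IntegerVector x, int K,
                           NumericVector w) {
  const int n = G.nrow(), J = G.ncol(), P = J + K - 1;
  const bool wt = w.size() == n;
  NumericVector grad(P);
  NumericMatrix H(P, P);
  double nll = 0.0;

  for (int i = 0; i < n; ++i) {
    const double wi = wt ? w[i] : 1.0;
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += b[j] * G(i, j);
    const int k = x[i];                      // 1..K
    const bool hasU = k < K, hasL = k > 1;
    double u = hasU ? a[k - 1] - s : R_PosInf;
    double l = hasL ? a[k - 2] - s : R_NegInf;
    double Pu = hasU ? R::pnorm(u, 0.0, 1.0, 1, 0) : 1.0;
    double Pl = hasL ? R::pnorm(l, 0.0, 1.0, 1, 0) : 0.0;
    double p = Pu - Pl;
    if (p < PFLOOR) p = PFLOOR;
    nll -= wi * std::log(p);

    double Fu = hasU ? R::dnorm(u, 0.0, 1.0, 0) : 0.0;
    double Fl = hasL ? R::dnorm(l, 0.0, 1.0, 0) : 0.0;
    double D = Fu - Fl;
    double uFu = hasU ? u * Fu : 0.0;        // u*phi(u) -> 0 at +Inf
    double lFl = hasL ? l * Fl : 0.0;
    const double p2 = p * p;

    // gradient; a_k sits at 0-based position J + (k-1), a_{k-1} at J + (k-2)
    double gs = wi * D / p;
    for (int j = 0; j < J; ++j) grad[j] += gs * G(i, j);
    if (hasU) grad[J + k - 1] -= wi * Fu / p;
    if (hasL) grad[J + k - 2] += wi * Fl / p;

    // second derivatives of the per-observation nll
    double h_ss = wi * ((uFu - lFl) * p + D * D) / p2;
    double h_su = hasU ? wi * (-uFu * p - D * Fu) / p2 : 0.0;
    double h_sl = hasL ? wi * (lFl * p + D * Fl) / p2 : 0.0;
    double h_uu = hasU ? wi * (uFu * p + Fu * Fu) / p2 : 0.0;
    double h_ll = hasL ? wi * (-lFl * p + Fl * Fl) / p2 : 0.0;
    double h_ul = (hasU && hasL) ? -wi * Fu * Fl / p2 : 0.0;

    const int iu = J + k - 1;                // row of a_k
    const int il = J + k - 2;                // row of a_{k-1}
    for (int j = 0; j < J; ++j) {
      const double gj = G(i, j);
      for (int j2 = 0; j2 <= j; ++j2) H(j, j2) += h_ss * gj * G(i, j2);
      if (hasU) H(iu, j) += h_su * gj;
      if (hasL) H(il, j) += h_sl * gj;
    }
    if (hasU) H(iu, iu) += h_uu;
    if (hasL) H(il, il) += h_ll;
    if (hasU && hasL) H(iu, il) += h_ul;
  }
  // symmetrize from the lower triangle
  for (int r = 0; r < P; ++r)
    for (int c = r + 1; c < P; ++c) H(r, c) = H(c, r);
  return List::create(_["nll"] = nll, _["grad"] = grad, _["hess"] = H);
}

// Category probability matrix, row i col k = P(X = k | G_i).
// [[Rcpp::export]]
NumericMatrix ordprobit_probs(NumericVector b, NumericVector a,
                              NumericMatrix G, int K) {
  const int n = G.nrow(), J = G.ncol();
  NumericMatrix P(n, K);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < J; ++j) s += b[j] * G(i, j);
    double prev = 0.0;
    for (int k = 0; k < K - 1; ++k) {
      double cum = R::pnorm(a[k] - s, 0.0, 1.0, 1, 0);
      P(i, k) = cum - prev;
      prev = cum;
    }
    P(i, K - 1) = 1.0 - prev;
  }
  return P;
}
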