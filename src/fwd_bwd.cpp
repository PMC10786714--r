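#include <Rcpp.h>
using namespace Rcpp;

// Rescaled forward-backward for the 5-state IBD chain.
//
// The transition matrix between adjacent sites is parameterised by five
// numbers per interval (exploiting the symmetry of the four IBD states):
//   a = P(0->0), b = P(0->given IBD), c = P(IBD->0),
//   d = P(IBD->same), f = P(IBD->given other IBD).
// e is the L x 5 emission matrix (likelihood ratios, non-IBD column == 1),
// pi the 5-vector start distribution.  Returns the L x 5 posterior matrix
// and the per-site scaling factors (whose logs sum to the log-likelihood
// up to the constant dropped from the emissions).
// [[Rcpp::export(name = ".fwd_bwd_cpp")]]
List fwd_bwd_cpp(NumericMatrix e, NumericMatrix trans, NumericVector pi) {
  const int L = e.nrow();
  const int K = 5;
  if (e.ncol() != K) stop("emission matrix must have 5 columns");
  if (trans.nrow() != L - 1 || trans.ncol() != 5)
    stop("transition component matrix must be (L-1) x 5");

  NumericMatrix fwd(L, K), bwd(L, K), gamma(L, K);
  NumericVector scale(L);

  // forward
  double s0 = 0.0;
  for (int k = 0; k < K; ++k) {
    fwd(0, k) = pi[k] * e(0, k);
    s0 += fwd(0, k);
  }
  if (s0 <= 0.0) stop("zero forward mass at site 1");
  scale[0] = s0;
  for (int k = 0; k < K; ++k) fwd(0, k) /= s0;

  for (int t = 1; t < L; ++t) {
    const double a = trans(t - 1, 0), b = trans(t - 1, 1),
                 c = trans(t - 1, 2), d = trans(t - 1, 3),
                 f = trans(t - 1, 4);
    double S = fwd(t - 1, 1) + fwd(t - 1, 2) + fwd(t - 1, 3) + fwd(t - 1, 4);
    double v0 = a * fwd(t - 1, 0) + c * S;
    double st = 0.0;
    fwd(t, 0) = v0 * e(t, 0);
    st += fwd(t, 0);
    for (int k = 1; k < K; ++k) {
      double vk = b * fwd(t - 1, 0) + d * fwd(t - 1, k) + f * (S - fwd(t - 1, k));
      fwd(t, k) = vk * e(t, k);
      st += fwd(t, k);
    }
    if (st <= 0.0) stop("zero forward mass at site " + std::to_string(t + 1));
    scale[t] = st;
    for (int k = 0; k < K; ++k) fwd(t, k) /= st;
  }

  // backward
  for (int k = 0; k < K; ++k) bwd(L - 1, k) = 1.0;
  for (int t = L - 2; t >= 0; --t) {
    const double a = trans(t, 0), b = trans(t, 1), c = trans(t, 2),
                 d = trans(t, 3), f = trans(t, 4);
    double u[5];
    for (int k = 0; k < K; ++k) u[k] = e(t + 1, k) * bwd(t + 1, k);
    double Su = u[1] + u[2] + u[3] + u[4];
    bwd(t, 0) = (a * u[0] + b * Su) / scale[t + 1];
    for (int k = 1; k < K; ++k)
      bwd(t, k) = (c * u[0] + d * u[k] + f * (Su - u[k])) / scale[t + 1];
  }

  for (int t = 0; t < L; ++t) {
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = fwd(t, k) * bwd(t, k);
      s += gamma(t, k);
    }
    for (int k = 0; k < K; ++k) gamma(t, k) /= s;
  }

  return List::create(_["gamma"] = gamma, _["scale"] = scale);
}
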