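#include <Rcpp.h>
using namespace Rcpp;

// Log likelihood contribution of one trial under the flexible parametric
// log-cumulative-hazard model, on the ln(time) scale:
//   eta_i  = B_i.gamma + C_i.b + (C_i.a) * lnt_i - P_i.omega
//   deta_i = dB_i.gamma + C_i.a
//   event:    log(deta_i) + eta_i - exp(eta_i)
//   censored: -exp(eta_i)
// Returns -Inf (not an error) when any event row has deta <= 0, so samplers
// can reject states outside the likelihood's domain.
// [[Rcpp::export]]
double rp_trial_loglik(const NumericMatrix& B, const NumericMatrix& dB,
                       const NumericVector& lnt, const IntegerVector& event,
                       const NumericMatrix& C, const NumericMatrix& P,
                       const NumericVector& gamma, const NumericVector& b,
                       const NumericVector& a, const NumericVector& omega) {
  const int n = B.nrow(), m = B.ncol(), q = C.ncol(), L = P.ncol();
  const bool use_b = b.size() > 0, use_a = a.size() > 0, use_w = omega.size() > 0;
  double ll = 0.0;
  for (int i = 0; i < n; ++i) {
    double eta = 0.0, deta = 0.0;
    for (int k = 0; k < m; ++k) {
      eta  += B(i, k)  * gamma[k];
      deta += dB(i, k) * gamma[k];
    }
    double ca = 0.0;
    for (int k = 0; k < q; ++k) {
      const double c = C(i, k);
      if (c != 0.0) {
        if (use_b) eta += c * b[k];
        if (use_a) ca  += c * a[k];
      }
    }
    if (use_a) { eta += ca * lnt[i]; deta += ca; }
    if (use_w)
      for (int l = 0; l < L; ++l) eta -= P(i, l) * omega[l];
    if (event[i] == 1) {
      if (deta <= 0.0) return R_NegInf;
      ll += std::log(deta) + eta - std::exp(eta);
    } else {
      ll += -std::exp(eta);
    }
  }
  return ll;
}
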