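#include <Rcpp.h>
using namespace Rcpp;

// Forward-algorithm log-likelihood for pooled capture-history patterns.
//
// Hidden states: 1 alive, 2 recently dead (recoverable carcass),
// 3 long dead (absorbing). Observed codes: 1 = L (seen alive),
// 2 = D (recovered dead), 3 = U (not encountered).
//
// t0: 0-based index of the ringing year within the study years.
// age0: age at ringing (0 for nestlings, 3 for adult-trapped birds).
// obs: per-pattern integer vectors of codes for the years after marking
//      (truncated at a dead recovery).
// s1t: juvenile survival per interval, indexed by the 0-based study-year
//      index of the interval start; s2, p, r, eta scalar.
// juv_transitions: number of annual transitions at juvenile survival
//      (ages < juv_transitions use s1).
// [[Rcpp::export]]
NumericVector forward_loglik_patterns(IntegerVector t0, IntegerVector age0,
                                      List obs, NumericVector s1t,
                                      double s2, double p, double r,
                                      double eta, int juv_transitions) {
  int n = t0.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector o = obs[i];
    double a1 = 1.0, a2 = 0.0, a3 = 0.0, ll = 0.0;
    int T = o.size();
    for (int k = 0; k < T; ++k) {
      int age = age0[i] + k;                     // age entering the interval
      double s = (age >= juv_transitions) ? s2 : s1t[t0[i] + k];
      double b1 = a1 * s;                        // transition step
      double b2 = a1 * (1.0 - s) + a2 * eta;
      double b3 = a2 * (1.0 - eta) + a3;
      switch (o[k]) {                            // emission weighting
        case 1: a1 = b1 * p;         a2 = 0.0;              a3 = 0.0; break;
        case 2: a2 = b2 * r;         a1 = 0.0;              a3 = 0.0; break;
        default: a1 = b1 * (1.0 - p); a2 = b2 * (1.0 - r);  a3 = b3;
      }
      double c = a1 + a2 + a3;                   // per-step scaling
      if (!(c > 0.0)) { ll = R_NegInf; break; }
      ll += std::log(c);
      a1 /= c; a2 /= c; a3 /= c;
    }
    out[i] = ll;
  }
  return out;
}
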