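#include <Rcpp.h>
using namespace Rcpp;

// Recursive Bernoulli sampling of a spike-history GLM.
//
// drive[t] = b + sum_j k_j x_{t-j+1} (stimulus drive incl. bias; zero-padded
// at trial starts). At each bin the spike probability is
// logistic(drive[t] + h . sampled spike history); histories never cross
// trial boundaries. Uses R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
List sample_bernoulli_glm_cpp(NumericVector drive, NumericVector h,
                              IntegerVector trial_start,
                              IntegerVector trial_end) {
  const int T = drive.size();
  const int Lh = h.size();
  IntegerVector n(T);
  NumericVector p(T);
  for (int tr = 0; tr < trial_start.size(); ++tr) {
    const int t0 = trial_start[tr] - 1;   // 0-based inclusive
    const int t1 = trial_end[tr];         // 0-based exclusive
    for (int t = t0; t < t1; ++t) {
      double z = drive[t];
      for (int j = 1; j <= Lh; ++j) {
        const int s = t - j;
        if (s >= t0) z += h[j - 1] * n[s];
      }
      if (z > 30.0) z = 30.0;
      if (z < -30.0) z = -30.0;
      const double y = 1.0 / (1.0 + std::exp(-z));
      p[t] = y;
      n[t] = (unif_rand() < y) ? 1 : 0;
    }
  }
  return List::create(_["spikes"] = n, _["prob"] = p);
}
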