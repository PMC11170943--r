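#include <Rcpp.h>
using namespace Rcpp;

// Negative log-likelihood of a session's completed choices under the
// Rescorla-Wagner model with one learning rate per cue and a shared
// softmax inverse temperature.  Values reset to zero at each block
// start.  `chosen_slot` is 1 if the first cue of the pair was chosen,
// 2 otherwise; `reward` is the realized token change (0 when the
// outcome was not delivered).
// [[Rcpp::export]]
double rw_nll_cpp(NumericVector alpha, double beta,
                  IntegerVector block, IntegerVector cue1,
                  IntegerVector cue2, IntegerVector chosen_slot,
                  NumericVector reward) {
  int n = block.size();
  int ncue = alpha.size();
  std::vector<double> v(ncue, 0.0);
  double nll = 0.0;
  int cur_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      std::fill(v.begin(), v.end(), 0.0);
      cur_block = block[t];
    }
    int i = cue1[t] - 1, j = cue2[t] - 1;
    // probability of choosing option j (slot 2), Fermi form
    double dj = 1.0 / (1.0 + std::exp(beta * (v[i] - v[j])));
    double p = (chosen_slot[t] == 2) ? dj : (1.0 - dj);
    if (p < 1e-12) p = 1e-12;
    nll -= std::log(p);
    int c = (chosen_slot[t] == 2) ? j : i;
    v[c] += alpha[c] * (reward[t] - v[c]);
  }
  return nll;
}

// Replay a session's completed choices under fixed RW parameters and
// return the value of every cue *before* each trial's outcome
// (n_trials x n_cues).
// [[Rcpp::export]]
NumericMatrix rw_replay_cpp(NumericVector alpha,
                            IntegerVector block, IntegerVector cue1,
                            IntegerVector cue2, IntegerVector chosen_slot,
                            NumericVector reward) {
  int n = block.size();
  int ncue = alpha.size();
  std::vector<double> v(ncue, 0.0);
  NumericMatrix out(n, ncue);
  int cur_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (block[t] != cur_block) {
      std::fill(v.begin(), v.end(), 0.0);
      cur_block = block[t];
    }
    for (int k = 0; k < ncue; ++k) out(t, k) = v[k];
    int i = cue1[t] - 1, j = cue2[t] - 1;
    int c = (chosen_slot[t] == 2) ? j : i;
    v[c] += alpha[c] * (reward[t] - v[c]);
  }
  return out;
}
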