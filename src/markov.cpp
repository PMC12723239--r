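#include <Rcpp.h>
using namespace Rcpp;

// Sample a DNA sequence of given length from a second-order Markov chain.
// trans: 16 x 4 row-stochastic matrix; row index = 4*(prev2) + prev1
// (0-based, A=0 C=1 G=2 T=3). Uses R's RNG so set.seed() controls output.
// [[Rcpp::export(name = ".markov_sample")]]
std::string markov_sample(int len, NumericMatrix trans) {
  if (trans.nrow() != 16 || trans.ncol() != 4)
    stop("transition matrix must be 16 x 4");
  static const char bases[] = {'A', 'C', 'G', 'T'};
  std::string out(len, 'A');
  if (len <= 0) return out;
  // first two symbols from the row-averaged marginal
  double marg[4];
  double tot = 0.0;
  for (int j = 0; j < 4; ++j) {
    double s = 0.0;
    for (int i = 0; i < 16; ++i) s += trans(i, j);
    marg[j] = s;
    tot += s;
  }
  int prev2 = 0, prev1 = 0;
  for (int p = 0; p < 2 && p < len; ++p) {
    double u = unif_rand() * tot, acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += marg[j];
      if (u <= acc) { b = j; break; }
    }
    out[p] = bases[b];
    prev2 = prev1;
    prev1 = b;
  }
  for (int p = 2; p < len; ++p) {
    int row = 4 * prev2 + prev1;
    double u = unif_rand(), acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(row, j);
      if (u <= acc) { b = j; break; }
    }
    out[p] = bases[b];
    prev2 = prev1;
    prev1 = b;
  }
  return out;
}
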