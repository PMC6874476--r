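#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exhaustive search over sets of carbon-limited species, with the greedy
// nitrogen completion that yields the unique uninvadable state (if any) per
// carbon selection.
//
// State codes per species: 0 = absent, 1 = carbon-limited, 2 = nitrogen-limited.
//
// For every carbon metabolite there are (number of consumers + 1) choices of a
// carbon-limited species (the +1 is "nobody limited by this carbon"), giving
// prod_i (L_i + 1) selections in total. For each selection, species
// out-competed on their carbon (smaller lambda_c than the carbon-limited
// species of that metabolite) are eliminated; then for every nitrogen
// metabolite the surviving non-carbon-limited consumer with the largest
// lambda_n is added as nitrogen-limited, provided its lambda_n is smaller than
// the lambda_n of every carbon-limited species using that nitrogen. If that
// top candidate violates the rule, it would invade any state built on this
// carbon selection, so no uninvadable state exists for it.
// [[Rcpp::export]]
IntegerMatrix enumerate_uninvadable_cpp(int K, int M,
                                        IntegerVector ci, IntegerVector nj,
                                        NumericVector lc, NumericVector ln) {
  const int S = ci.size();
  std::vector<std::vector<int>> byC(K), byN(M);
  for (int s = 0; s < S; ++s) {
    byC[ci[s] - 1].push_back(s);
    byN[nj[s] - 1].push_back(s);
  }
  double total = 1.0;
  for (int i = 0; i < K; ++i) total *= (byC[i].size() + 1.0);
  if (total > 1e8)
    stop("too many carbon-limited selections (%.3g); pool too large for exhaustive search",
         total);

  std::vector<int> digit(K, 0);       // 0 = no carbon-limited species
  std::vector<int> climited(K, -1);
  std::vector<int> code(S, 0);
  std::vector<char> dead(S, 0);
  std::vector<int> out;               // flattened states, row-major length S
  out.reserve(1024);

  const double INF = std::numeric_limits<double>::infinity();
  bool done = false;
  while (!done) {
    for (int i = 0; i < K; ++i)
      climited[i] = digit[i] == 0 ? -1 : byC[i][digit[i] - 1];
    for (int s = 0; s < S; ++s) {
      code[s] = 0;
      int lim = climited[ci[s] - 1];
      dead[s] = (lim >= 0 && lim != s && lc[s] < lc[lim]) ? 1 : 0;
    }
    for (int i = 0; i < K; ++i)
      if (climited[i] >= 0) code[climited[i]] = 1;

    bool feas = true;
    for (int j = 0; j < M && feas; ++j) {
      double thresh = INF;
      int best = -1;
      double bestln = -INF;
      for (int idx : byN[j]) {
        if (code[idx] == 1) {                 // carbon-limited, uses nj non-limitingly
          if (ln[idx] < thresh) thresh = ln[idx];
        } else if (!dead[idx]) {
          if (ln[idx] > bestln) { bestln = ln[idx]; best = idx; }
        }
      }
      if (best >= 0) {
        if (bestln < thresh) code[best] = 2;
        else feas = false;                    // top candidate invades everything here
      }
    }
    if (feas) out.insert(out.end(), code.begin(), code.end());

    // odometer over carbon selections
    int i = 0;
    for (; i < K; ++i) {
      if (digit[i] < (int)byC[i].size()) { ++digit[i]; break; }
      digit[i] = 0;
    }
    if (i == K) done = true;
  }

  const int n = out.size() / S;
  IntegerMatrix res(n, S);
  for (int r = 0; r < n; ++r)
    for (int s = 0; s < S; ++s)
      res(r, s) = out[(size_t)r * S + s];
  return res;
}
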