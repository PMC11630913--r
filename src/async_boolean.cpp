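#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// Asynchronous Boolean simulation kernel.
//
// Each run starts from `init`, repeatedly picks one gene uniformly at random
// and updates it by its repressor-dominant rule (ON iff no activator assigned
// or >=1 activator ON, and every repressor OFF). The state is checked against
// all rules every step; a run stops at a fixed point or after max_steps
// single-gene updates. Run r uses its own std::mt19937 stream seeded
// seed + r, so runs are reproducible and order-independent.
//
// act/rep: per-gene 0-based regulator index vectors.
// [[Rcpp::export]]
List cpp_async_runs(IntegerVector init, List act, List rep,
                    int n_runs, int max_steps, double seed) {
  const int n = init.size();
  std::vector<std::vector<int> > A(n), R(n);
  for (int g = 0; g < n; ++g) {
    A[g] = as<std::vector<int> >(act[g]);
    R[g] = as<std::vector<int> >(rep[g]);
  }
  IntegerMatrix finals(n_runs, n);
  LogicalVector converged(n_runs);
  std::vector<int> s(n), f(n);

  for (int run = 0; run < n_runs; ++run) {
    std::mt19937 rng(static_cast<uint32_t>(seed) + static_cast<uint32_t>(run));
    std::uniform_int_distribution<int> pick(0, n - 1);
    for (int g = 0; g < n; ++g) s[g] = init[g];
    bool conv = false;
    for (int step = 0; step <= max_steps; ++step) {
      bool fixed = true;
      for (int g = 0; g < n; ++g) {
        bool a = A[g].empty();
        if (!a) {
          for (size_t i = 0; i < A[g].size(); ++i) {
            if (s[A[g][i]]) { a = true; break; }
          }
        }
        bool rv = false;
        for (size_t i = 0; i < R[g].size(); ++i) {
          if (s[R[g][i]]) { rv = true; break; }
        }
        f[g] = (a && !rv) ? 1 : 0;
        if (f[g] != s[g]) fixed = false;
      }
      if (fixed) { conv = true; break; }
      if (step == max_steps) break;
      int g = pick(rng);
      s[g] = f[g];
    }
    converged[run] = conv;
    for (int g = 0; g < n; ++g) finals(run, g) = s[g];
  }
  return List::create(_["finals"] = finals, _["converged"] = converged);
}
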