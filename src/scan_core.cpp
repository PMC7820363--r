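#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Grid maximization of the composite log-likelihood ratio at one test site.
//
// dist:  per-site recombination distance from the test position (cM)
// hrow:  0-based row of each site's (n, k) cell in the stacked component
//        matrix H (rows = support cells across sample-size strata,
//        cols = x-grid entries)
// gk:    per-site neutral background probability g_n(k), all > 0
// Agrid: ascending candidate decay rates (per cM)
// cutoff: minimum mixing weight alpha for a site to enter a window
//
// Returns the maximum of sum_i [ln f_i - ln g_i] over the (x, A) grid
// (0 if nothing beats the degenerate neutral model), the 1-based arg-max
// indices, the window size at the arg-max, and the largest window seen.
// Ties keep the first maximum in iteration order: A ascending outer,
// x ascending inner, strict improvement only -- i.e. smallest A, then
// lexicographically smallest x.
// [[Rcpp::export]]
List scan_core_cpp(NumericVector dist, IntegerVector hrow, NumericVector gk,
                   NumericMatrix H, NumericVector Agrid, double cutoff) {
  const int L = dist.size();
  const int nx = H.ncol();
  const int na = Agrid.size();
  std::vector<double> invgk(L);
  for (int i = 0; i < L; ++i) invgk[i] = 1.0 / gk[i];

  double best = 0.0;
  int best_x = NA_INTEGER, best_a = NA_INTEGER, best_w = NA_INTEGER;
  int max_window = 0;
  const double logcut = std::log(1.0 / cutoff);

  std::vector<int> idx;
  std::vector<double> alpha;
  idx.reserve(L);
  alpha.reserve(L);

  for (int ai = 0; ai < na; ++ai) {
    const double A = Agrid[ai];
    const double radius = logcut / A;
    idx.clear();
    alpha.clear();
    for (int i = 0; i < L; ++i) {
      if (dist[i] <= radius) {
        idx.push_back(i);
        alpha.push_back(std::exp(-A * dist[i]));
      }
    }
    const int W = (int)idx.size();
    if (W == 0) continue;
    if (W > max_window) max_window = W;
    for (int xi = 0; xi < nx; ++xi) {
      // sum of ln(f_i / g_i) accumulated as a running product of the
      // per-site likelihood ratios 1 + alpha (h/g - 1); the log is taken
      // only when the product nears the double range, which keeps the
      // result within ~L*eps relative of the direct sum of logs
      double s = 0.0, prod = 1.0;
      const double *Hcol = &H(0, xi);
      for (int w = 0; w < W; ++w) {
        const int i = idx[w];
        prod *= 1.0 + alpha[w] * (Hcol[hrow[i]] * invgk[i] - 1.0);
        if (prod < 1e-280 || prod > 1e280) {
          s += std::log(prod);
          prod = 1.0;
        }
      }
      s += std::log(prod);
      if (s > best) {
        best = s;
        best_x = xi + 1;
        best_a = ai + 1;
        best_w = W;
      }
    }
  }

  return List::create(_["best"] = best, _["x_idx"] = best_x,
                      _["a_idx"] = best_a, _["n_sites"] = best_w,
                      _["n_window"] = max_window);
}
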