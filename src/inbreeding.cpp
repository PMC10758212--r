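#include <Rcpp.h>
using namespace Rcpp;

// Meuwissen & Luo (1992) recursive inbreeding algorithm.
// sire/dam are 1-based positions into a topologically sorted pedigree
// (parents precede offspring); 0 marks an unknown parent.
// Returns F (inbreeding coefficients) and D (Mendelian sampling variance
// ratios), where diag(A) = 1 + F and |A| = prod(D).
static double msv_ratio(int s, int d, const NumericVector& F) {
  if (s == 0 && d == 0) return 1.0;
  if (s == 0) return 0.75 - 0.25 * F[d - 1];
  if (d == 0) return 0.75 - 0.25 * F[s - 1];
  return 0.5 - 0.25 * (F[s - 1] + F[d - 1]);
}

// [[Rcpp::export]]
List ml_inbreeding(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n), D(n);
  // L[j] accumulates the path coefficient from animal i to ancestor j
  std::vector<double> L(n + 1, 0.0);
  std::vector<bool> anc(n + 1, false);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree not topologically sorted at position %d", i + 1);
    if (s == 0 || d == 0) {
      F[i] = 0.0;
      D[i] = msv_ratio(s, d, F);
      continue;
    }
    double fi = -1.0;
    L[i + 1] = 1.0;
    anc[i + 1] = true;
    for (int j = i + 1; j >= 1; --j) {
      if (!anc[j]) continue;
      int js = sire[j - 1], jd = dam[j - 1];
      double Lj = L[j];
      if (js > 0) { L[js] += 0.5 * Lj; anc[js] = true; }
      if (jd > 0) { L[jd] += 0.5 * Lj; anc[jd] = true; }
      fi += Lj * Lj * msv_ratio(js, jd, F);
      L[j] = 0.0;
      anc[j] = false;
    }
    F[i] = fi;
    D[i] = msv_ratio(s, d, F);
  }
  return List::create(_["F"] = F, _["D"] = D);
}
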