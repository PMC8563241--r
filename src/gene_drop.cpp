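#include <Rcpp.h>
using namespace Rcpp;

// Gene dropping through a topologically ordered pedigree.
//
// Each founder (and each unknown-parent slot) contributes a unique allele;
// offspring receive one allele from each parent by Mendelian sampling. Per
// replicate the realized additive relationship of a pair (i,j) is half the
// number of identical-by-descent combinations among the four allele pairs,
// and the realized dominance relationship is the indicator that both of i's
// alleles can be matched to both of j's. Accumulates per-entry sums and sums
// of squares so the R wrapper can form Monte-Carlo means and standard errors.
//
// sire/dam are 1-based record indices, 0 = unknown. Uses R's RNG so results
// are reproducible under set.seed().
// [[Rcpp::export]]
List gene_drop_cpp(IntegerVector sire, IntegerVector dam, int n_reps) {
  const int q = sire.size();
  NumericMatrix add_sum(q, q), add_sumsq(q, q), dom_sum(q, q);
  std::vector<int> a1(q), a2(q);

  for (int rep = 0; rep < n_reps; ++rep) {
    int next_allele = 0;
    for (int i = 0; i < q; ++i) {
      int s = sire[i], d = dam[i];
      a1[i] = (s > 0) ? ((unif_rand() < 0.5) ? a1[s - 1] : a2[s - 1])
                      : next_allele++;
      a2[i] = (d > 0) ? ((unif_rand() < 0.5) ? a1[d - 1] : a2[d - 1])
                      : next_allele++;
    }
    for (int i = 0; i < q; ++i) {
      for (int j = i; j < q; ++j) {
        int c11 = (a1[i] == a1[j]), c12 = (a1[i] == a2[j]);
        int c21 = (a2[i] == a1[j]), c22 = (a2[i] == a2[j]);
        double add = 0.5 * (c11 + c12 + c21 + c22);
        int dom = ((c11 && c22) || (c12 && c21)) ? 1 : 0;
        add_sum(i, j) += add;
        add_sumsq(i, j) += add * add;
        dom_sum(i, j) += dom;
      }
    }
  }
  return List::create(_["add_sum"] = add_sum,
                      _["add_sumsq"] = add_sumsq,
                      _["dom_sum"] = dom_sum);
}
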