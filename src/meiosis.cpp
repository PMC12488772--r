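#include <Rcpp.h>
using namespace Rcpp;

// Meiosis under the Haldane model: crossover count per chromosome is
// Poisson(length in Morgans), crossover positions uniform, no interference.
// Uses R's RNG so set.seed() governs reproducibility.

// One gamete for each of n individuals; individual i recombines its own
// pair of haplotypes (rows i of h1 and h2, alleles coded 0/1).
// chrom_start/chrom_end: 0-based first/last marker index per chromosome.
// [[Rcpp::export]]
IntegerMatrix gametes_cpp(const IntegerMatrix& h1, const IntegerMatrix& h2,
                          const IntegerVector& chrom_start,
                          const IntegerVector& chrom_end,
                          const NumericVector& pos) {
  const int n = h1.nrow(), m = h1.ncol(), nchr = chrom_start.size();
  if (h2.nrow() != n || h2.ncol() != m)
    stop("haplotype matrices must have identical dimensions");
  IntegerMatrix g(n, m);
  std::vector<double> xo;
  for (int c = 0; c < nchr; ++c) {
    const int a = chrom_start[c], b = chrom_end[c];
    const double lo = pos[a], len = pos[b] - pos[a];
    if (len < 0) stop("map positions must be sorted within chromosome");
    for (int i = 0; i < n; ++i) {
      int k = (len > 0) ? (int) R::rpois(len) : 0;
      xo.resize(k);
      for (int t = 0; t < k; ++t) xo[t] = lo + unif_rand() * len;
      std::sort(xo.begin(), xo.end());
      int phase = (unif_rand() < 0.5) ? 0 : 1;
      int t = 0;
      for (int j = a; j <= b; ++j) {
        while (t < k && xo[t] <= pos[j]) { phase ^= 1; ++t; }
        g(i, j) = phase == 0 ? h1(i, j) : h2(i, j);
      }
    }
  }
  return g;
}

// BC1S2 dosage matrix for one cross: F1 = R x D, BC1 = gamete(F1) + gamete(R),
// then two generations of single-seed selfing. hr, hd: parental haplotypes
// (alleles 0/1, fully homozygous parents). Returns n x m donor/reference
// allele counts in {0,1,2}.
// [[Rcpp::export]]
IntegerMatrix bc1s2_cpp(const IntegerVector& hr, const IntegerVector& hd,
                        const IntegerVector& chrom_start,
                        const IntegerVector& chrom_end,
                        const NumericVector& pos, const int n) {
  const int m = hr.size();
  IntegerMatrix f1a(n, m), f1b(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) { f1a(i, j) = hr[j]; f1b(i, j) = hd[j]; }
  // BC1: one recombinant F1 gamete, the other gamete is the recipient's
  IntegerMatrix a = gametes_cpp(f1a, f1b, chrom_start, chrom_end, pos);
  IntegerMatrix b(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) b(i, j) = hr[j];
  // two rounds of selfing, single seed advanced each time
  for (int gen = 0; gen < 2; ++gen) {
    IntegerMatrix ga = gametes_cpp(a, b, chrom_start, chrom_end, pos);
    IntegerMatrix gb = gametes_cpp(a, b, chrom_start, chrom_end, pos);
    a = ga; b = gb;
  }
  IntegerMatrix dos(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) dos(i, j) = a(i, j) + b(i, j);
  return dos;
}
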