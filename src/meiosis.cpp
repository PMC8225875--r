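#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Gamete formation on a multi-chromosome genetic map.
//
// Haplotypes are raw (one byte per allele), markers-in-rows (m x n), so a
// gamete is a contiguous column and each inter-crossover stretch is a
// contiguous memcpy. Crossover counts per chromosome are Poisson(L/100)
// with positions uniform on the map interval (no interference), which for
// marker loci is exactly the Haldane model; chromosomes assort
// independently. Uses R's RNG so results follow set.seed().
//
// hap1, hap2 : m x n raw matrices (phased parental haplotypes, 0/1)
// parent     : 0-based column index of the parent for each gamete
// pos        : marker positions in cM, non-decreasing within a chromosome
// chr_begin, chr_end : 0-based first/last marker index of each chromosome
// [[Rcpp::export(name = ".gametes_cpp")]]
RawMatrix gametes_cpp(const RawMatrix& hap1,
                      const RawMatrix& hap2,
                      const IntegerVector& parent,
                      const NumericVector& pos,
                      const IntegerVector& chr_begin,
                      const IntegerVector& chr_end) {
  const int m = hap1.nrow();
  const int ng = parent.size();
  const int nchr = chr_begin.size();
  RawMatrix out(m, ng);
  const double* p0 = REAL(pos);

  for (int g = 0; g < ng; ++g) {
    const int pa = parent[g];
    const Rbyte* h[2] = { &hap1(0, pa), &hap2(0, pa) };
    Rbyte* o = &out(0, g);

    for (int c = 0; c < nchr; ++c) {
      const int b = chr_begin[c], e = chr_end[c];
      const double lo = pos[b], len = pos[e] - pos[b];
      int k = (len > 0.0) ? (int) R::rpois(len / 100.0) : 0;
      double buf[32];
      std::vector<double> big;
      double* xo = buf;
      if (k > 32) { big.resize(k); xo = big.data(); }
      for (int j = 0; j < k; ++j) xo[j] = lo + unif_rand() * len;
      std::sort(xo, xo + k);

      int cur = (unif_rand() < 0.5) ? 0 : 1;  // independent start per chrom
      int idx = b;
      for (int j = 0; j < k; ++j) {
        // markers strictly below crossover j come from the current strand
        const int nxt = (int) (std::lower_bound(p0 + idx, p0 + e + 1, xo[j])
                               - p0);
        if (nxt > idx) {
          std::memcpy(o + idx, h[cur] + idx, (size_t) (nxt - idx));
          idx = nxt;
        }
        cur = 1 - cur;
      }
      if (e + 1 > idx)
        std::memcpy(o + idx, h[cur] + idx, (size_t) (e + 1 - idx));
    }
  }
  return out;
}
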