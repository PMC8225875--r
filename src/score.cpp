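#include <Rcpp.h>
using namespace Rcpp;

// Linear genetic score per individual: for each column (individual) of the
// raw haplotype matrices, sum over the marker subset of
// (hap1 + hap2 - center) * eff. Avoids materializing a transposed dosage
// matrix for large populations (TBVs and GEBVs both reduce to this).
// idx is 0-based into the marker rows; center/eff are parallel to idx.
// [[Rcpp::export(name = ".linear_score_cpp")]]
NumericVector linear_score_cpp(const RawMatrix& hap1,
                               const RawMatrix& hap2,
                               const IntegerVector& idx,
                               const NumericVector& eff,
                               const NumericVector& center) {
  const int n = hap1.ncol();
  const int k = idx.size();
  NumericVector out(n);
  for (int j = 0; j < n; ++j) {
    const Rbyte* h1 = &hap1(0, j);
    const Rbyte* h2 = &hap2(0, j);
    double s = 0.0;
    for (int t = 0; t < k; ++t) {
      const int i = idx[t];
      s += ((int) h1[i] + (int) h2[i] - center[t]) * eff[t];
    }
    out[j] = s;
  }
  return out;
}

// Allele-1 frequency per marker over both haplotypes.
// [[Rcpp::export(name = ".allele_freq_cpp")]]
NumericVector allele_freq_cpp(const RawMatrix& hap1,
                              const RawMatrix& hap2) {
  const int m = hap1.nrow(), n = hap1.ncol();
  NumericVector out(m);
  for (int j = 0; j < n; ++j) {
    const Rbyte* h1 = &hap1(0, j);
    const Rbyte* h2 = &hap2(0, j);
    for (int i = 0; i < m; ++i) out[i] += (int) h1[i] + (int) h2[i];
  }
  const double denom = 2.0 * n;
  for (int i = 0; i < m; ++i) out[i] /= denom;
  return out;
}
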