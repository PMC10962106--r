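#include <Rcpp.h>

// Materialize a chunk of model-term columns from the dosage matrix:
// singles (j == 0) and pair products, optionally standardized in the same
// pass. Avoids the intermediate copies an R-level build would allocate per
// chunk, which dominates runtime in genome-scale scans.

// [[Rcpp::export(name = ".term_chunk_cpp")]]
Rcpp::NumericMatrix term_chunk_cpp(const Rcpp::NumericMatrix &v,
                                   const Rcpp::IntegerVector &iidx,
                                   const Rcpp::IntegerVector &jidx,
                                   const Rcpp::NumericVector &mu,
                                   const Rcpp::NumericVector &sd,
                                   bool standardize) {
  const int n = v.nrow(), k = iidx.size();
  Rcpp::NumericMatrix out(n, k);
  for (int c = 0; c < k; ++c) {
    const double *xi = &v(0, iidx[c] - 1);
    double *o = &out(0, c);
    if (jidx[c] > 0) {
      const double *xj = &v(0, jidx[c] - 1);
      for (int r = 0; r < n; ++r) o[r] = xi[r] * xj[r];
    } else {
      for (int r = 0; r < n; ++r) o[r] = xi[r];
    }
    if (standardize) {
      const double m = mu[c], s = sd[c];
      for (int r = 0; r < n; ++r) o[r] = (o[r] - m) / s;
    }
  }
  return out;
}
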