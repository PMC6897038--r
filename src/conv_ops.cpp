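// Hot inner loops of the convolution engine: the im2col gather and the
// col2im scatter-add. Indices are 1-based (as produced by the R side) and
// are trusted to be in range (they are constructed from tensor geometry,
// not user input).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector gather_idx(const NumericVector& x, const IntegerVector& idx) {
  R_xlen_t n = idx.size();
  NumericVector out(no_init(n));
  const double* xp = x.begin();
  const int* ip = idx.begin();
  double* op = out.begin();
  for (R_xlen_t i = 0; i < n; ++i) op[i] = xp[ip[i] - 1];
  return out;
}

// Row maxima of the pooling view matrix (one row = one k x k window).
// [[Rcpp::export]]
NumericVector row_max(const NumericMatrix& V) {
  R_xlen_t M = V.nrow(), kk = V.ncol();
  NumericVector out(no_init(M));
  for (R_xlen_t r = 0; r < M; ++r) {
    double m = V(r, 0);
    for (R_xlen_t j = 1; j < kk; ++j) if (V(r, j) > m) m = V(r, j);
    out[r] = m;
  }
  return out;
}

// Max-pool backward: route each window's gradient to the first position
// attaining the maximum (ties go to the earliest offset). `target` is the
// freshly allocated input-gradient array, mutated in place.
// [[Rcpp::export]]
void pool_scatter(NumericVector target, const NumericMatrix& V,
                  const NumericVector& outVec, const IntegerMatrix& idxT,
                  const NumericVector& dOut) {
  R_xlen_t M = V.nrow(), kk = V.ncol();
  if (outVec.size() != M || dOut.size() != M) stop("pool gradient size mismatch");
  double* tp = target.begin();
  for (R_xlen_t r = 0; r < M; ++r) {
    for (R_xlen_t j = 0; j < kk; ++j) {
      if (V(r, j) == outVec[r]) { tp[idxT(r, j) - 1] += dOut[r]; break; }
    }
  }
}

// Accumulates values into `target` in place; the caller owns `target`
// (a freshly allocated gradient array) so the mutation is never observable
// elsewhere. Sequential accumulation makes colliding indices (overlapping
// patches) exact.
// [[Rcpp::export]]
void scatter_add(NumericVector target, const IntegerVector& idx,
                 const NumericVector& values) {
  R_xlen_t n = idx.size();
  if (values.size() != n) stop("idx and values lengths differ");
  double* tp = target.begin();
  const int* ip = idx.begin();
  const double* vp = values.begin();
  for (R_xlen_t i = 0; i < n; ++i) tp[ip[i] - 1] += vp[i];
}
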