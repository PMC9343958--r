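// Numerical kernels: fused conv/ReLU/max-pool branch passes for the CNN,
// and the biquad-cascade IIR filter.
//
// Layout conventions: input batches are cubes (time, channel, item); branch
// features are matrices (item, pooled_time * filter) with time fastest.
// During training the forward pass stashes its im2col matrix and argmax
// indices in an external pointer that the backward pass consumes (and
// frees), so the large intermediates never cross into R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct BranchState {
  mat m;      // im2col, (n * out_len) x (klen * nch)
  umat idx;   // argmax row into the conv output, (plen * nf) x n
  uword out_len = 0, nf = 0;
};

// Batched im2col: rows = (item, output position), cols = klen * nch.
static mat im2col_batch(const cube& x, uword klen) {
  const uword len = x.n_rows, nch = x.n_cols, n = x.n_slices;
  const uword out_len = len - klen + 1;
  mat m(out_len * n, klen * nch);
  for (uword i = 0; i < n; ++i)
    for (uword c = 0; c < nch; ++c) {
      const double* src = x.slice_colptr(i, c);
      for (uword j = 0; j < klen; ++j)
        std::copy(src + j, src + j + out_len,
                  m.colptr(j + c * klen) + i * out_len);
    }
  return m;
}

// One branch forward: valid cross-correlation (as a single GEMM), ReLU,
// non-overlapping max pooling. Returns feat (n x plen*nf) and, when
// `train`, an external pointer holding the backward-pass state.
// [[Rcpp::export]]
Rcpp::List cpp_branch_forward(const arma::cube& x, const arma::cube& w,
                              const arma::vec& b, int pool_, bool train) {
  const uword klen = w.n_rows, nf = w.n_slices, n = x.n_slices;
  const uword out_len = x.n_rows - klen + 1;
  const uword pool = (uword)pool_, plen = out_len / pool;
  mat wmat(klen * w.n_cols, nf);
  for (uword f = 0; f < nf; ++f) wmat.col(f) = vectorise(w.slice(f));
  mat m = im2col_batch(x, klen);
  mat ymat = m * wmat;                     // rows (i, t), cols f
  ymat.each_row() += b.t();
  mat feat(n, plen * nf);
  umat idx;
  if (train) idx.set_size(plen * nf, n);
  for (uword i = 0; i < n; ++i) {
    const uword base = i * out_len;
    for (uword f = 0; f < nf; ++f) {
      const double* col = ymat.colptr(f) + base;
      for (uword t = 0; t < plen; ++t) {
        uword best = t * pool;
        double bv = col[best];
        for (uword j = 1; j < pool; ++j)
          if (col[t * pool + j] > bv) { bv = col[t * pool + j]; best = t * pool + j; }
        feat(i, t + f * plen) = bv > 0 ? bv : 0.0;   // ReLU after max
        if (train) idx(t + f * plen, i) = base + best;
      }
    }
  }
  if (!train) return Rcpp::List::create(Rcpp::Named("feat") = feat);
  BranchState* st = new BranchState;
  st->m = std::move(m);
  st->idx = std::move(idx);
  st->out_len = out_len;
  st->nf = nf;
  Rcpp::XPtr<BranchState> ptr(st, true);
  return Rcpp::List::create(Rcpp::Named("feat") = feat,
                            Rcpp::Named("state") = ptr);
}

// One branch backward. dfeat must already be masked by the ReLU derivative
// (zero wherever the pooled feature was clipped) and un-dropped. The state
// buffers are released afterwards: one backward per forward.
// [[Rcpp::export]]
Rcpp::List cpp_branch_backward(SEXP state_, const arma::mat& dfeat,
                               int klen_, int nch_) {
  Rcpp::XPtr<BranchState> state(state_);
  const uword klen = (uword)klen_, nch = (uword)nch_;
  const uword n = dfeat.n_rows, d = dfeat.n_cols;
  const uword out_len = state->out_len, nf = state->nf;
  mat dymat(out_len * n, nf, fill::zeros);
  const uword plen = d / nf;
  for (uword i = 0; i < n; ++i)
    for (uword f = 0; f < nf; ++f)
      for (uword t = 0; t < plen; ++t) {
        const double g = dfeat(i, t + f * plen);
        if (g != 0.0) dymat(state->idx(t + f * plen, i), f) += g;
      }
  mat dwmat = state->m.t() * dymat;
  vec db = sum(dymat, 0).t();
  cube dw(klen, nch, nf);
  for (uword f = 0; f < nf; ++f)
    dw.slice(f) = reshape(dwmat.col(f), klen, nch);
  state->m.reset();
  state->idx.reset();
  return Rcpp::List::create(Rcpp::Named("dW") = dw, Rcpp::Named("db") = db);
}

// Cascade of second-order sections, direct form II transposed, zero initial
// conditions. sos rows: b0 b1 b2 a0 a1 a2 (a0 == 1).
// [[Rcpp::export]]
arma::vec cpp_sosfilt(const arma::vec& x, const arma::mat& sos) {
  vec y = x;
  for (uword s = 0; s < sos.n_rows; ++s) {
    const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
    const double a1 = sos(s, 4), a2 = sos(s, 5);
    double z1 = 0.0, z2 = 0.0;
    for (uword n = 0; n < y.n_elem; ++n) {
      const double xn = y(n);
      const double yn = b0 * xn + z1;
      z1 = b1 * xn - a1 * yn + z2;
      z2 = b2 * xn - a2 * yn;
      y(n) = yn;
    }
  }
  return y;
}
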