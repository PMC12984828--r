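// Block-diagonal multihead attention kernels.
//
// Token sets of a minibatch are stacked row-wise; attention runs per
// sample slice and per head. Attention weights are kept in one flat
// column-major buffer (one allocation per call) laid out as
// [sample][head][n_q x n_kv]; masked (padded) tokens receive exactly
// zero weight via the -inf trick inside the softmax.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline arma::uword block_rows(bool self, int n, int nq) {
  return self ? (arma::uword)n : (arma::uword)nq;
}

// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const arma::ivec& starts,
                      const arma::ivec& ends, int H,
                      const arma::uvec& mask, bool self) {
  const int d = Q.n_cols;
  const int dk = d / H;
  const double scl = 1.0 / std::sqrt((double)dk);
  const int B = starts.n_elem;
  const int nq = self ? 0 : (int)Q.n_rows;

  arma::uvec offsets(B + 1);
  offsets[0] = 0;
  for (int s = 0; s < B; ++s) {
    const int n = ends[s] - starts[s] + 1;
    offsets[s + 1] = offsets[s] + (arma::uword)H * block_rows(self, n, nq) * n;
  }
  NumericVector alph((R_xlen_t)offsets[B]);
  double* ap = REAL(alph);

  arma::mat O(self ? K.n_rows : (arma::uword)(B * nq), d,
              arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int r0 = starts[s] - 1, r1 = ends[s] - 1;
    const int n = r1 - r0 + 1;
    const int nqs = (int)block_rows(self, n, nq);
    const int q0 = self ? r0 : s * nq;
    const int q1 = self ? r1 : (s + 1) * nq - 1;
    const arma::uvec msk = mask.subvec(r0, r1);
    const bool all_real = arma::all(msk == 1u);
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk, c1 = (h + 1) * dk - 1;
      arma::mat al(ap + offsets[s] + (arma::uword)h * nqs * n,
                   nqs, n, false, true);
      if (self)
        al = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scl;
      else
        al = Q.cols(c0, c1) * K.submat(r0, c0, r1, c1).t() * scl;
      if (!all_real) {
        for (int j = 0; j < n; ++j)
          if (msk[j] == 0u) al.col(j).fill(-arma::datum::inf);
      }
      arma::vec amax = arma::max(al, 1);
      al.each_col() -= amax;
      al = arma::exp(al);
      arma::vec rs = arma::sum(al, 1);
      al.each_col() /= rs;
      O.submat(q0, c0, q1, c1) = al * V.submat(r0, c0, r1, c1);
    }
  }
  return List::create(_["O"] = O, _["alph"] = alph,
                      _["offsets"] = IntegerVector(offsets.begin(),
                                                   offsets.end()));
}

// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& dOc, const NumericVector& alph,
                       const arma::ivec& offsets, const arma::mat& Q,
                       const arma::mat& K, const arma::mat& V,
                       const arma::ivec& starts, const arma::ivec& ends,
                       int H, bool self) {
  const int d = Q.n_cols;
  const int dk = d / H;
  const double scl = 1.0 / std::sqrt((double)dk);
  const int B = starts.n_elem;
  const int nq = self ? 0 : (int)Q.n_rows;
  const double* ap = REAL(alph);
  arma::mat dQ(Q.n_rows, d, arma::fill::zeros);
  arma::mat dK(K.n_rows, d, arma::fill::zeros);
  arma::mat dV(V.n_rows, d, arma::fill::zeros);
  for (int s = 0; s < B; ++s) {
    const int r0 = starts[s] - 1, r1 = ends[s] - 1;
    const int n = r1 - r0 + 1;
    const int nqs = self ? n : nq;
    const int q0 = self ? r0 : s * nq;
    const int q1 = self ? r1 : (s + 1) * nq - 1;
    for (int h = 0; h < H; ++h) {
      const int c0 = h * dk, c1 = (h + 1) * dk - 1;
      const arma::mat al((double*)(ap + offsets[s] +
                                   (arma::uword)h * nqs * n),
                         nqs, n, false, true);
      arma::mat dOh = dOc.submat(q0, c0, q1, c1);
      arma::mat dal = dOh * V.submat(r0, c0, r1, c1).t();
      dV.submat(r0, c0, r1, c1) += al.t() * dOh;
      arma::vec tmp = arma::sum(dal % al, 1);
      arma::mat dA = al % (dal.each_col() - tmp);
      if (self) {
        dQ.submat(r0, c0, r1, c1) += dA * K.submat(r0, c0, r1, c1) * scl;
        dK.submat(r0, c0, r1, c1) += dA.t() * Q.submat(r0, c0, r1, c1) * scl;
      } else {
        dQ.cols(c0, c1) += dA * K.submat(r0, c0, r1, c1) * scl;
        dK.submat(r0, c0, r1, c1) += dA.t() * Q.cols(c0, c1) * scl;
      }
    }
  }
  return List::create(_["dQ"] = dQ, _["dK"] = dK, _["dV"] = dV);
}

// Adds a bias row-vector to a freshly allocated matrix in place; callers
// must pass a temporary they own (results of %*%), never a shared object.
// [[Rcpp::export]]
NumericMatrix add_bias_inplace(NumericMatrix M, const NumericVector& b) {
  const int n = M.nrow(), p = M.ncol();
  double* m = REAL(M);
  const double* bb = REAL(b);
  for (int j = 0; j < p; ++j) {
    const double bj = bb[j];
    double* col = m + (R_xlen_t)j * n;
    for (int i = 0; i < n; ++i) col[i] += bj;
  }
  return M;
}
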