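// Batched multi-head scaled dot-product attention kernels.
//
// The encoder's token-wise operations (projections, feed-forward, layer
// norm) run as large BLAS calls from R; the per-sample, per-head
// attention blocks are many small matrix products, which is where R call
// overhead dominates. These kernels loop over samples and heads in C++.
// The backward kernel recomputes the softmax from Q and K instead of
// caching the attention tensors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::mat softmax_rows(arma::mat S) {
  S.each_col() -= arma::max(S, 1);
  S = arma::exp(S);
  S.each_col() /= arma::sum(S, 1);
  return S;
}

// Q, K, V: (B*L) x d stacked by sample; key_mask: B x L additive mask
// (0 for content, large negative for padding); qk_masks: optional list of
// per-sample L x L additive masks. Returns the context matrix C
// ((B*L) x d) and, if collect_cls, the per-sample [CLS] query row and key
// column of this layer's attention summed over heads (B x L each).
// [[Rcpp::export]]
List attn_forward_cpp(const arma::mat& Q, const arma::mat& K,
                      const arma::mat& V, const arma::mat& key_mask,
                      Nullable<List> qk_masks, int B, int L, int h,
                      bool collect_cls) {
  const int d = Q.n_cols;
  const int dk = d / h;
  const double scale = 1.0 / std::sqrt((double) dk);
  arma::mat C(B * L, d);
  arma::mat cls_q, cls_k;
  if (collect_cls) {
    cls_q.zeros(B, L);
    cls_k.zeros(B, L);
  }
  List qk(0);
  bool has_qk = qk_masks.isNotNull();
  if (has_qk) qk = qk_masks.get();

  for (int s = 0; s < B; s++) {
    const arma::uword r0 = (arma::uword) s * L;
    arma::rowvec km = key_mask.row(s);
    arma::mat qkm;
    if (has_qk) qkm = as<arma::mat>(qk[s]);
    for (int i = 0; i < h; i++) {
      const arma::uword c0 = (arma::uword) i * dk;
      arma::mat S = Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1) *
        K.submat(r0, c0, r0 + L - 1, c0 + dk - 1).t();
      S *= scale;
      S.each_row() += km;
      if (has_qk) S += qkm;
      arma::mat A = softmax_rows(S);
      if (collect_cls) {
        cls_q.row(s) += A.row(0);
        cls_k.row(s) += A.col(0).t();
      }
      C.submat(r0, c0, r0 + L - 1, c0 + dk - 1) =
        A * V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
    }
  }
  if (collect_cls) {
    return List::create(Named("C") = C, Named("cls_q") = cls_q,
                        Named("cls_k") = cls_k);
  }
  return List::create(Named("C") = C);
}

// Backward pass of the attention blocks; recomputes the softmax from Q
// and K. Returns gradients for Q, K and V (each (B*L) x d).
// [[Rcpp::export]]
List attn_backward_cpp(const arma::mat& Q, const arma::mat& K,
                       const arma::mat& V, const arma::mat& dC,
                       const arma::mat& key_mask, Nullable<List> qk_masks,
                       int B, int L, int h) {
  const int d = Q.n_cols;
  const int dk = d / h;
  const double scale = 1.0 / std::sqrt((double) dk);
  arma::mat dQ(B * L, d), dK(B * L, d), dV(B * L, d);
  List qk(0);
  bool has_qk = qk_masks.isNotNull();
  if (has_qk) qk = qk_masks.get();

  for (int s = 0; s < B; s++) {
    const arma::uword r0 = (arma::uword) s * L;
    arma::rowvec km = key_mask.row(s);
    arma::mat qkm;
    if (has_qk) qkm = as<arma::mat>(qk[s]);
    for (int i = 0; i < h; i++) {
      const arma::uword c0 = (arma::uword) i * dk;
      arma::mat Qh = Q.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      arma::mat Kh = K.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      arma::mat Vh = V.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      arma::mat S = Qh * Kh.t();
      S *= scale;
      S.each_row() += km;
      if (has_qk) S += qkm;
      arma::mat A = softmax_rows(S);

      arma::mat dCh = dC.submat(r0, c0, r0 + L - 1, c0 + dk - 1);
      arma::mat dA = dCh * Vh.t();
      dV.submat(r0, c0, r0 + L - 1, c0 + dk - 1) = A.t() * dCh;
      arma::mat dS = A % (dA.each_col() - arma::sum(dA % A, 1));
      dQ.submat(r0, c0, r0 + L - 1, c0 + dk - 1) = (dS * Kh) * scale;
      dK.submat(r0, c0, r0 + L - 1, c0 + dk - 1) = (dS.t() * Qh) * scale;
    }
  }
  return List::create(Named("dQ") = dQ, Named("dK") = dK,
                      Named("dV") = dV);
}
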