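// Compiled fast paths for CD-1 RBM training and supervised fine-tuning.
// All random draws (weight init, epoch shuffles, hidden-sampling uniforms)
// are generated on the R side and passed in, so these loops are exact
// replicas of the plain-R reference engines and bit-reproducible under a
// fixed R seed.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigmoid(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List cpp_train_rbm(const arma::mat& X, arma::mat W, arma::rowvec b_vis,
                         arma::rowvec b_hid, bool gaussian, double lr,
                         int epochs, int batch, double momentum,
                         double weight_decay, const arma::imat& perms,
                         const arma::mat& U) {
  const int n = X.n_rows;
  mat vW(size(W), fill::zeros);
  rowvec vbv(size(b_vis), fill::zeros), vbh(size(b_hid), fill::zeros);
  vec recon(epochs, fill::zeros);
  for (int e = 0; e < epochs; ++e) {
    // shuffled view of the data for this epoch
    uvec idx(n);
    for (int i = 0; i < n; ++i) idx(i) = perms(i, e) - 1;
    mat Xs = X.rows(idx);
    double sse = 0.0;
    for (int i0 = 0; i0 < n; i0 += batch) {
      int i1 = std::min(n, i0 + batch) - 1;
      int m = i1 - i0 + 1;
      mat Xb = Xs.rows(i0, i1);
      mat Ub = U.rows(e * n + i0, e * n + i1);
      mat h_pos = sigmoid(Xb * W.t() + repmat(b_hid, m, 1));
      mat h_state = conv_to<mat>::from(Ub < h_pos);
      mat v_recon = h_state * W + repmat(b_vis, m, 1);
      if (!gaussian) v_recon = sigmoid(v_recon);
      mat h_neg = sigmoid(v_recon * W.t() + repmat(b_hid, m, 1));
      mat gW = (h_pos.t() * Xb - h_neg.t() * v_recon) / m - weight_decay * W;
      rowvec gbv = mean(Xb - v_recon, 0);
      rowvec gbh = mean(h_pos - h_neg, 0);
      vW = momentum * vW + lr * gW;
      vbv = momentum * vbv + lr * gbv;
      vbh = momentum * vbh + lr * gbh;
      W += vW; b_vis += vbv; b_hid += vbh;
      sse += accu(square(Xb - v_recon));
    }
    recon(e) = sse / (double(n) * X.n_cols);
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("b_vis") = b_vis,
                            Rcpp::Named("b_hid") = b_hid,
                            Rcpp::Named("recon") = recon);
}

// Fine-tuning: minibatch SGD on softmax cross-entropy + L2, with Nesterov
// momentum (gradient evaluated at the lookahead point) rescaled per
// parameter by an RMSProp running second moment.
// [[Rcpp::export]]
Rcpp::List cpp_fine_tune(Rcpp::List W_in, Rcpp::List b_in, arma::mat Wout,
                         arma::rowvec bout, const arma::mat& X,
                         const arma::ivec& y, double lr, int epochs,
                         int batch, const arma::vec& mu_sched, double rho,
                         double eps, double wd, const arma::imat& perms) {
  const int n = X.n_rows;
  const int L = W_in.size();
  std::vector<mat> W(L);
  std::vector<rowvec> b(L);
  for (int l = 0; l < L; ++l) {
    W[l] = Rcpp::as<mat>(W_in[l]);
    b[l] = Rcpp::as<rowvec>(b_in[l]);
  }
  std::vector<mat> vW(L), cW(L);
  std::vector<rowvec> vb(L), cb(L);
  for (int l = 0; l < L; ++l) {
    vW[l] = zeros(size(W[l])); cW[l] = zeros(size(W[l]));
    vb[l] = zeros(size(b[l])); cb[l] = zeros(size(b[l]));
  }
  mat vWo = zeros(size(Wout)), cWo = zeros(size(Wout));
  rowvec vbo = zeros(size(bout)), cbo = zeros(size(bout));
  vec loss(epochs, fill::zeros);
  std::vector<mat> A(L + 1), Wl(L);
  std::vector<rowvec> bl(L);
  for (int e = 0; e < epochs; ++e) {
    double mu = mu_sched(e);
    uvec idx(n);
    for (int i = 0; i < n; ++i) idx(i) = perms(i, e) - 1;
    mat Xs = X.rows(idx);
    ivec ys(n);
    for (int i = 0; i < n; ++i) ys(i) = y(idx(i));
    double ce_sum = 0.0;
    int nb = 0;
    for (int i0 = 0; i0 < n; i0 += batch) {
      int i1 = std::min(n, i0 + batch) - 1;
      int m = i1 - i0 + 1;
      // lookahead parameters
      for (int l = 0; l < L; ++l) { Wl[l] = W[l] + mu * vW[l]; bl[l] = b[l] + mu * vb[l]; }
      mat Wol = Wout + mu * vWo;
      rowvec bol = bout + mu * vbo;
      // forward
      A[0] = Xs.rows(i0, i1);
      for (int l = 0; l < L; ++l)
        A[l + 1] = sigmoid(A[l] * Wl[l] + repmat(bl[l], m, 1));
      mat logits = A[L] * Wol + repmat(bol, m, 1);
      mat P = exp(logits - repmat(max(logits, 1), 1, logits.n_cols));
      P.each_col() /= sum(P, 1);
      mat T(m, 2, fill::zeros);
      for (int i = 0; i < m; ++i) {
        T(i, ys(i0 + i)) = 1.0;
        ce_sum -= std::log(std::max(P(i, ys(i0 + i)), 1e-300)) / m;
      }
      ++nb;
      // backward
      mat dlog = (P - T) / m;
      mat gWo = A[L].t() * dlog + wd * Wol;
      rowvec gbo = sum(dlog, 0);
      mat delta = dlog * Wol.t();
      for (int l = L - 1; l >= 0; --l) {
        delta %= A[l + 1] % (1.0 - A[l + 1]);
        mat gW = A[l].t() * delta + wd * Wl[l];
        rowvec gb = sum(delta, 0);
        if (l > 0) delta = delta * Wl[l].t();
        cW[l] = rho * cW[l] + (1 - rho) * square(gW);
        vW[l] = mu * vW[l] - lr * gW / (sqrt(cW[l]) + eps);
        W[l] += vW[l];
        cb[l] = rho * cb[l] + (1 - rho) * square(gb);
        vb[l] = mu * vb[l] - lr * gb / (sqrt(cb[l]) + eps);
        b[l] += vb[l];
      }
      cWo = rho * cWo + (1 - rho) * square(gWo);
      vWo = mu * vWo - lr * gWo / (sqrt(cWo) + eps);
      Wout += vWo;
      cbo = rho * cbo + (1 - rho) * square(gbo);
      vbo = mu * vbo - lr * gbo / (sqrt(cbo) + eps);
      bout += vbo;
    }
    loss(e) = ce_sum / nb;
  }
  Rcpp::List W_out_list(L), b_out_list(L);
  for (int l = 0; l < L; ++l) { W_out_list[l] = W[l]; b_out_list[l] = b[l]; }
  return Rcpp::List::create(Rcpp::Named("W") = W_out_list,
                            Rcpp::Named("b") = b_out_list,
                            Rcpp::Named("W_out") = Wout,
                            Rcpp::Named("b_out") = bout,
                            Rcpp::Named("loss") = loss);
}
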