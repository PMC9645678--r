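// Compiled core of the convolutional feature extractor: im2col gather,
// GEMM convolution, batch normalization, rectifier and max pooling for the
// whole three-block stack, forward and backward. The LSTM head and the
// optimizer stay in R (their arrays are small); these routines carry ~95% of
// the training arithmetic. Large per-batch caches (patch matrices, normalized
// activations, pooling argmax) stay on the C++ side in a session object so
// nothing big is copied across the R boundary between the forward and
// backward pass of a mini-batch.
//
// Layout contracts (match the R callers in net-math.R / net-train.R):
//  - activations At: [flat_in, n] with column-major (freq, time, channel)
//    flattening per window; block output is flattened (position, map);
//  - patch index idx: [n_pos, K], 1-based linear indices into flat_in;
//  - pool_src: [n_pool, pool^2], 1-based source positions, 0 = missing
//    (partial edge neighborhood in ceil mode).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct ConvCache {
  arma::mat G;             // [K, n_pos * n] patch matrix
  arma::mat xhat;          // [maps, n_pos * n] normalized pre-activation
  arma::vec invstd;
  std::vector<int> argmax; // winning source position per pooled cell, -1 none
  int n_pos = 0, K = 0, n_pool = 0, maps = 0, flat_in = 0;
};

struct ConvSession {
  std::vector<ConvCache> blocks;
};

// [[Rcpp::export(rng = false)]]
SEXP conv_session_new() {
  return XPtr<ConvSession>(new ConvSession(), true);
}

// forward through all conv blocks; caches stay in the session. Returns the
// final [n_pool * maps, n] activation plus per-block batch statistics.
// [[Rcpp::export(rng = false)]]
List conv_stack_forward_cpp(SEXP sess_ptr, const arma::mat& input,
                            const List& Ws, const List& gammas,
                            const List& betas, const List& idxs,
                            const List& pool_srcs, const bool training,
                            const List& run_means, const List& run_vars,
                            const double eps) {
  XPtr<ConvSession> sess(sess_ptr);
  const int n_blocks = Ws.size();
  sess->blocks.assign(n_blocks, ConvCache());
  const int n = input.n_cols;
  arma::mat At = input;
  List mus(n_blocks), vars(n_blocks);

  for (int blk = 0; blk < n_blocks; ++blk) {
    ConvCache& cc = sess->blocks[blk];
    const arma::mat W = as<arma::mat>(Ws[blk]);
    const arma::vec gamma = as<arma::vec>(gammas[blk]);
    const arma::vec beta = as<arma::vec>(betas[blk]);
    const IntegerMatrix idx = idxs[blk];
    const IntegerMatrix pool_src = pool_srcs[blk];
    const int n_pos = idx.nrow(), K = idx.ncol();
    const int maps = W.n_cols;
    const int n_pool = pool_src.nrow(), n_off = pool_src.ncol();
    cc.n_pos = n_pos; cc.K = K; cc.n_pool = n_pool; cc.maps = maps;
    cc.flat_in = At.n_rows;

    const int* ip = &idx(0, 0);
    cc.G.set_size(K, (size_t)n_pos * n);
    for (int i = 0; i < n; ++i) {
      const double* a = At.colptr(i);
      for (int pos = 0; pos < n_pos; ++pos) {
        double* g = cc.G.colptr((size_t)i * n_pos + pos);
        for (int k = 0; k < K; ++k) g[k] = a[ip[(size_t)k * n_pos + pos] - 1];
      }
    }
    arma::mat Z = W.t() * cc.G;   // [maps, n_pos * n]
    const size_t zc = Z.n_cols;

    arma::vec mu, var_;
    if (training) {
      // one fused pass for per-map mean and variance
      mu.zeros(maps); var_.zeros(maps);
      for (size_t j = 0; j < zc; ++j) {
        const double* z = Z.colptr(j);
        for (int c = 0; c < maps; ++c) { mu[c] += z[c]; var_[c] += z[c] * z[c]; }
      }
      mu /= (double)zc;
      var_ = var_ / (double)zc - arma::square(mu);
      var_.transform([](double v) { return v < 0 ? 0.0 : v; });
    } else {
      mu = as<arma::vec>(run_means[blk]);
      var_ = as<arma::vec>(run_vars[blk]);
    }
    cc.invstd = 1.0 / arma::sqrt(var_ + eps);
    mus[blk] = mu; vars[blk] = var_;

    cc.xhat = std::move(Z);
    {
      const double* mp = mu.memptr(); const double* sp_ = cc.invstd.memptr();
      for (size_t j = 0; j < zc; ++j) {
        double* x = cc.xhat.colptr(j);
        for (int c = 0; c < maps; ++c) x[c] = (x[c] - mp[c]) * sp_[c];
      }
    }

    // pool directly over the scaled + rectified activation, computed on the
    // fly per source column (each conv position feeds exactly one pooled cell)
    arma::mat At_next((size_t)n_pool * maps, n);
    cc.argmax.assign((size_t)maps * n_pool * n, -1);
    std::vector<double> best(maps), ybuf(maps);
    std::vector<int> win(maps);
    const double* gp = gamma.memptr(); const double* bp = beta.memptr();
    size_t ai = 0;
    for (int i = 0; i < n; ++i) {
      for (int pp = 0; pp < n_pool; ++pp) {
        std::fill(best.begin(), best.end(), -INFINITY);
        std::fill(win.begin(), win.end(), -1);
        for (int j = 0; j < n_off; ++j) {
          const int sp = pool_src(pp, j);
          if (sp == 0) continue;
          const double* x = cc.xhat.colptr((size_t)i * n_pos + sp - 1);
          for (int c = 0; c < maps; ++c) {
            double y = x[c] * gp[c] + bp[c];
            if (y < 0) y = 0;
            if (y > best[c]) { best[c] = y; win[c] = sp - 1; }
          }
        }
        double* o = At_next.colptr(i);
        for (int c = 0; c < maps; ++c) {
          cc.argmax[ai++] = win[c];
          o[(size_t)c * n_pool + pp] = best[c];
        }
      }
    }
    At = std::move(At_next);
  }
  return List::create(_["At_last"] = At, _["mus"] = mus, _["vars"] = vars);
}

// backward through all conv blocks using the session caches; returns
// per-block parameter gradients (small matrices/vectors only)
// [[Rcpp::export(rng = false)]]
List conv_stack_backward_cpp(SEXP sess_ptr, const arma::mat& dAt_last,
                             const List& Ws, const List& gammas,
                             const List& betas, const List& idxs) {
  XPtr<ConvSession> sess(sess_ptr);
  const int n_blocks = Ws.size();
  const int n = dAt_last.n_cols;
  List dWs(n_blocks), dgammas(n_blocks), dbetas(n_blocks);
  arma::mat dAt = dAt_last;

  for (int blk = n_blocks - 1; blk >= 0; --blk) {
    ConvCache& cc = sess->blocks[blk];
    const arma::mat W = as<arma::mat>(Ws[blk]);
    const arma::vec gamma = as<arma::vec>(gammas[blk]);
    const arma::vec beta = as<arma::vec>(betas[blk]);
    const IntegerMatrix idx = idxs[blk];
    const int n_pos = cc.n_pos, K = cc.K, maps = cc.maps, n_pool = cc.n_pool;

    // un-pool: route gradients to the argmax source positions
    arma::mat dY(maps, (size_t)n_pos * n, arma::fill::zeros);
    size_t ai = 0;
    for (int i = 0; i < n; ++i) {
      const double* d = dAt.colptr(i);
      for (int pp = 0; pp < n_pool; ++pp) {
        for (int c = 0; c < maps; ++c) {
          const int sp = cc.argmax[ai++];
          if (sp >= 0) dY(c, (size_t)i * n_pos + sp) += d[(size_t)c * n_pool + pp];
        }
      }
    }
    // fused relu mask + batch-norm gradient statistics
    const size_t ncols = dY.n_cols;
    arma::vec dgamma(maps, arma::fill::zeros), dbeta(maps, arma::fill::zeros);
    const double* gp = gamma.memptr(); const double* bp = beta.memptr();
    for (size_t j = 0; j < ncols; ++j) {
      double* d = dY.colptr(j);
      const double* x = cc.xhat.colptr(j);
      for (int c = 0; c < maps; ++c) {
        if (x[c] * gp[c] + bp[c] <= 0) { d[c] = 0.0; continue; }
        dgamma[c] += d[c] * x[c];
        dbeta[c] += d[c];
      }
    }
    // batch-norm backward; the batch means of dxhat and dxhat*xhat are
    // gamma*dbeta/m and gamma*dgamma/m, so one fused pass yields dZ
    const double m = (double)ncols;
    arma::vec scale = gamma % cc.invstd;
    for (size_t j = 0; j < ncols; ++j) {
      double* d = dY.colptr(j);
      const double* x = cc.xhat.colptr(j);
      for (int c = 0; c < maps; ++c) {
        d[c] = (d[c] - dbeta[c] / m - x[c] * dgamma[c] / m) * scale[c];
      }
    }

    dWs[blk] = cc.G * dY.t();                     // [K, maps]
    dgammas[blk] = dgamma;
    dbetas[blk] = dbeta;

    if (blk > 0) {
      arma::mat dG = W * dY;                      // [K, n_pos * n]
      arma::mat dAt_prev(cc.flat_in, n, arma::fill::zeros);
      const int* ip = &idx(0, 0);
      for (int i = 0; i < n; ++i) {
        double* a = dAt_prev.colptr(i);
        for (int pos = 0; pos < n_pos; ++pos) {
          const double* g = dG.colptr((size_t)i * n_pos + pos);
          for (int k = 0; k < K; ++k) a[ip[(size_t)k * n_pos + pos] - 1] += g[k];
        }
      }
      dAt = std::move(dAt_prev);
    }
  }
  return List::create(_["dWs"] = dWs, _["dgammas"] = dgammas,
                      _["dbetas"] = dbetas);
}
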