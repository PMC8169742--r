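// Fast training loop for the masked network. Mirrors the R reference engine
// (R/network.R) exactly: forward with elu/linear activations and inverted
// unit dropout, backprop of (1-alpha)*MSE_main + alpha*MSE_aux with the
// auxiliary gradient injected at the aggregation layer, L2 decay on unmasked
// weights, flat-state Adam, and hard re-masking after every update. Uses R's
// RNG (unif_rand) so results are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::uvec;
using arma::vec;

static void elu_inplace(mat& z) {
  z.transform([](double v) { return v > 0 ? v : std::exp(v) - 1.0; });
}

static mat elu_grad(const mat& z) {
  mat g = z;
  g.transform([](double v) { return v > 0 ? 1.0 : std::exp(v); });
  return g;
}

struct Net {
  std::vector<mat> W;
  std::vector<rowvec> b;
  std::vector<mat> mask;
  std::vector<bool> has_mask;
  std::vector<int> act;     // 1 = elu, 0 = linear
  std::vector<bool> drop;   // dropout after this layer (training only)
  int aux;                  // 0-based aggregation-layer index, -1 if none
};

// forward pass without dropout; returns main output, fills aux activations
static vec forward_eval(const Net& net, const mat& X, mat& aux_out) {
  mat A = X;
  for (size_t i = 0; i < net.W.size(); ++i) {
    mat Z = A * net.W[i];
    Z.each_row() += net.b[i];
    if (net.act[i] == 1) elu_inplace(Z);
    if ((int)i == net.aux) aux_out = Z;
    A = std::move(Z);
  }
  return vec(A.col(0));
}

// [[Rcpp::export(name = ".train_loop_cpp")]]
List train_loop_cpp(List W0, List b0, List masks, IntegerVector act,
                    LogicalVector drop_layer, int aux_index,
                    const arma::mat& X, const arma::vec& y,
                    const arma::mat& Xm, const arma::vec& ym,
                    double alpha, double lr, int batch_size, int epochs,
                    double dropout, double l2) {
  const int L = W0.size();
  Net net;
  net.aux = aux_index;
  for (int i = 0; i < L; ++i) {
    net.W.push_back(as<mat>(W0[i]));
    net.b.push_back(as<rowvec>(b0[i]));
    SEXP mk = masks[i];
    if (Rf_isNull(mk)) {
      net.mask.push_back(mat());
      net.has_mask.push_back(false);
    } else {
      net.mask.push_back(as<mat>(mk));
      net.has_mask.push_back(true);
    }
    net.act.push_back(act[i]);
    net.drop.push_back(drop_layer[i]);
  }
  const bool has_aux = aux_index >= 0;
  const double w_main = has_aux ? (1.0 - alpha) : 1.0;
  const int n = X.n_rows;
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;

  // Adam state
  std::vector<mat> mW(L), vW(L);
  std::vector<rowvec> mb(L), vb(L);
  for (int i = 0; i < L; ++i) {
    mW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    vW[i].zeros(net.W[i].n_rows, net.W[i].n_cols);
    mb[i].zeros(net.b[i].n_elem);
    vb[i].zeros(net.b[i].n_elem);
  }
  long tstep = 0;

  mat history(epochs, 3);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  std::vector<mat> A(L + 1), Z(L), D(L);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    // Fisher-Yates shuffle driven by R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(idx[i], idx[j]);
    }
    for (int s = 0; s < n; s += batch_size) {
      const int e = std::min(s + batch_size, n) - 1;
      const int nb = e - s + 1;
      uvec take(nb);
      for (int k = 0; k < nb; ++k) take[k] = idx[s + k];
      A[0] = X.rows(take);
      const vec yb = y.elem(take);

      // forward
      for (int i = 0; i < L; ++i) {
        mat Zi = A[i] * net.W[i];
        Zi.each_row() += net.b[i];
        mat Ai = Zi;
        if (net.act[i] == 1) elu_inplace(Ai);
        if (net.drop[i] && dropout > 0) {
          const double keep = 1.0 - dropout;
          mat Di(Ai.n_rows, Ai.n_cols);
          // column-major fill, matching R's matrix(runif(n), ...)
          for (arma::uword c = 0; c < Di.n_cols; ++c)
            for (arma::uword r = 0; r < Di.n_rows; ++r)
              Di(r, c) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
          Ai %= Di;
          D[i] = std::move(Di);
        } else {
          D[i].reset();
        }
        Z[i] = std::move(Zi);
        A[i + 1] = std::move(Ai);
      }
      if (!A[L].is_finite()) {
        stop("non-finite network output at epoch %d; try a lower learning rate",
             epoch + 1);
      }

      // backward
      mat dA = (A[L].col(0) - yb) * (w_main * 2.0 / nb);
      std::vector<mat> gW(L);
      std::vector<rowvec> gb(L);
      for (int i = L - 1; i >= 0; --i) {
        if (i == net.aux) {
          const mat& S = A[i + 1];
          dA += (S.each_col() - yb) * (alpha * 2.0 / (nb * (double)S.n_cols));
        }
        if (D[i].n_elem) dA %= D[i];
        mat dZ = (net.act[i] == 1) ? mat(dA % elu_grad(Z[i])) : dA;
        mat gWi = A[i].t() * dZ;
        if (l2 > 0) gWi += 2.0 * l2 * net.W[i];
        if (net.has_mask[i]) gWi %= net.mask[i];
        gW[i] = std::move(gWi);
        gb[i] = arma::sum(dZ, 0);
        if (i > 0) dA = dZ * net.W[i].t();
      }

      // Adam
      ++tstep;
      const double c1 = 1.0 - std::pow(beta1, (double)tstep);
      const double c2 = 1.0 - std::pow(beta2, (double)tstep);
      for (int i = 0; i < L; ++i) {
        mW[i] = beta1 * mW[i] + (1 - beta1) * gW[i];
        vW[i] = beta2 * vW[i] + (1 - beta2) * (gW[i] % gW[i]);
        net.W[i] -= lr * (mW[i] / c1) / (arma::sqrt(vW[i] / c2) + eps);
        if (net.has_mask[i]) net.W[i] %= net.mask[i];
        mb[i] = beta1 * mb[i] + (1 - beta1) * gb[i];
        vb[i] = beta2 * vb[i] + (1 - beta2) * (gb[i] % gb[i]);
        net.b[i] -= lr * (mb[i] / c1) / (arma::sqrt(vb[i] / c2) + eps);
      }
    }

    // monitor loss (no dropout)
    mat aux_act;
    vec pred = forward_eval(net, Xm, aux_act);
    const double mse_main = arma::mean(arma::square(pred - ym));
    double mse_aux = 0.0;
    if (has_aux) {
      mat err = aux_act.each_col() - ym;
      mse_aux = arma::accu(err % err) / err.n_elem;
    }
    const double a_eff = has_aux ? alpha : 0.0;
    const double total = (1 - a_eff) * mse_main + a_eff * mse_aux;
    if (!std::isfinite(total)) {
      stop("non-finite monitor loss at epoch %d; try a lower learning rate",
           epoch + 1);
    }
    history(epoch, 0) = mse_main;
    history(epoch, 1) = mse_aux;
    history(epoch, 2) = total;
  }

  List Wout(L), bout(L);
  for (int i = 0; i < L; ++i) {
    Wout[i] = wrap(net.W[i]);
    bout[i] = wrap(vec(net.b[i].t()));
  }
  return List::create(_["W"] = Wout, _["b"] = bout,
                      _["history"] = wrap(history));
}
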