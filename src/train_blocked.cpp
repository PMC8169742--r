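// Block-structured training loop for the pathway-masked architecture.
// Identical algorithm to the generic loop in train_loop.cpp, but exploits
// the fact that masked layers are block-diagonal by pathway: each pathway's
// sub-network (gene inputs -> hidden stack -> aggregation neuron) is trained
// as dense per-pathway blocks, which avoids multiplying the structural
// zeros. Masked positions of the full weight matrices are never written, so
// they remain exactly zero.

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

template <typename T>
struct AdamT {
  T m, v;
  void init(const T& like) {
    m.zeros(arma::size(like));
    v.zeros(arma::size(like));
  }
  void step(T& w, const T& g, double lr, double c1, double c2) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * (g % g);
    w -= lr * (m / c1) / (arma::sqrt(v / c2) + 1e-8);
  }
};

struct AdamScalar {
  double m = 0, v = 0;
  void step(double& w, double g, double lr, double c1, double c2) {
    m = 0.9 * m + 0.1 * g;
    v = 0.999 * v + 0.001 * g * g;
    w -= lr * (m / c1) / (std::sqrt(v / c2) + 1e-8);
  }
};

// [[Rcpp::export(name = ".train_loop_blk_cpp")]]
List train_loop_blk_cpp(List W0, List b0, List gene_idx0,
                        IntegerVector widths, int n_hidden,
                        const arma::mat& X, const arma::vec& y,
                        const arma::mat& Xm, const arma::vec& ym,
                        double alpha, double lr, int batch_size, int epochs,
                        double dropout, double l2) {
  const int P = widths.size();
  const int n = X.n_rows;
  // layer indexing in W0/b0: 0..n_hidden-1 hidden, n_hidden agg, n_hidden+1 out
  std::vector<mat> Wfull(W0.size());
  std::vector<rowvec> bfull(W0.size());
  for (int i = 0; i < W0.size(); ++i) {
    Wfull[i] = as<mat>(W0[i]);
    bfull[i] = as<rowvec>(b0[i]);
  }
  // neuron column ranges per pathway
  std::vector<uvec> genes(P), cols(P);
  {
    int off = 0;
    for (int p = 0; p < P; ++p) {
      genes[p] = as<uvec>(gene_idx0[p]);   // 0-based
      uvec c(widths[p]);
      for (int k = 0; k < widths[p]; ++k) c[k] = off + k;
      cols[p] = c;
      off += widths[p];
    }
  }
  // extract dense blocks: Wb[p][l] for l = 0..n_hidden-1, aggb[p] (w_p vec)
  std::vector<std::vector<mat>> Wb(P);
  std::vector<std::vector<rowvec>> bb(P);
  std::vector<vec> aggW(P);
  std::vector<double> aggB(P);
  for (int p = 0; p < P; ++p) {
    Wb[p].resize(n_hidden);
    bb[p].resize(n_hidden);
    Wb[p][0] = Wfull[0].submat(genes[p], cols[p]);
    bb[p][0] = bfull[0].cols(cols[p][0], cols[p][widths[p] - 1]);
    for (int l = 1; l < n_hidden; ++l) {
      Wb[p][l] = Wfull[l].submat(cols[p], cols[p]);
      bb[p][l] = bfull[l].cols(cols[p][0], cols[p][widths[p] - 1]);
    }
    aggW[p] = Wfull[n_hidden].submat(cols[p], uvec({(arma::uword)p}));
    aggB[p] = bfull[n_hidden][p];
  }
  mat Wout = Wfull[n_hidden + 1];            // P x 1
  double bout = bfull[n_hidden + 1][0];

  // Adam state
  std::vector<std::vector<AdamT<mat>>> aW(P);
  std::vector<std::vector<AdamT<rowvec>>> ab(P);
  std::vector<AdamT<vec>> aAgg(P);
  std::vector<AdamScalar> aAggB(P);
  for (int p = 0; p < P; ++p) {
    aW[p].resize(n_hidden); ab[p].resize(n_hidden);
    aAgg[p].init(aggW[p]);
    for (int l = 0; l < n_hidden; ++l) {
      aW[p][l].init(Wb[p][l]);
      ab[p][l].init(bb[p][l]);
    }
  }
  AdamT<mat> aOut;
  AdamScalar aOutB;
  aOut.init(Wout);
  long tstep = 0;

  const double w_main = 1.0 - alpha;
  const double keep = 1.0 - dropout;

  // scratch per pathway
  std::vector<std::vector<mat>> A(P), Z(P), D(P);
  for (int p = 0; p < P; ++p) {
    A[p].resize(n_hidden + 1);
    Z[p].resize(n_hidden);
    D[p].resize(n_hidden);
  }

  auto assemble = [&]() {
    for (int p = 0; p < P; ++p) {
      Wfull[0].submat(genes[p], cols[p]) = Wb[p][0];
      bfull[0].cols(cols[p][0], cols[p][widths[p] - 1]) = bb[p][0];
      for (int l = 1; l < n_hidden; ++l) {
        Wfull[l].submat(cols[p], cols[p]) = Wb[p][l];
        bfull[l].cols(cols[p][0], cols[p][widths[p] - 1]) = bb[p][l];
      }
      Wfull[n_hidden].submat(cols[p], uvec({(arma::uword)p})) = aggW[p];
      bfull[n_hidden][p] = aggB[p];
    }
    Wfull[n_hidden + 1] = Wout;
    bfull[n_hidden + 1][0] = bout;
  };

  auto monitor_forward = [&](const mat& Xe, mat& S_out) -> vec {
    const int ne = Xe.n_rows;
    mat S(ne, P);
    for (int p = 0; p < P; ++p) {
      mat Ael = Xe.cols(genes[p]);
      for (int l = 0; l < n_hidden; ++l) {
        mat Zl = Ael * Wb[p][l];
        Zl.each_row() += bb[p][l];
        elu_inplace(Zl);
        Ael = std::move(Zl);
      }
      S.col(p) = Ael * aggW[p] + aggB[p];
    }
    vec pred = S * Wout + bout;
    S_out = std::move(S);
    return pred;
  };

  mat history(epochs, 3);
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int epoch = 0; epoch < epochs; ++epoch) {
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
      const mat Xb = X.rows(take);
      const vec yb = y.elem(take);

      // forward per pathway into aggregation activations S
      mat S(nb, P);
      for (int p = 0; p < P; ++p) {
        A[p][0] = Xb.cols(genes[p]);
        for (int l = 0; l < n_hidden; ++l) {
          mat Zl = A[p][l] * Wb[p][l];
          Zl.each_row() += bb[p][l];
          mat Al = Zl;
          elu_inplace(Al);
          if (dropout > 0 && l < n_hidden - 1) {
            mat Dl(Al.n_rows, Al.n_cols);
            for (arma::uword c = 0; c < Dl.n_cols; ++c)
              for (arma::uword r = 0; r < Dl.n_rows; ++r)
                Dl(r, c) = (unif_rand() < keep) ? 1.0 / keep : 0.0;
            Al %= Dl;
            D[p][l] = std::move(Dl);
          } else {
            D[p][l].reset();
          }
          Z[p][l] = std::move(Zl);
          A[p][l + 1] = std::move(Al);
        }
        S.col(p) = A[p][n_hidden] * aggW[p] + aggB[p];
      }
      vec yhat = S * Wout + bout;
      if (!yhat.is_finite()) {
        stop("non-finite network output at epoch %d; try a lower learning rate",
             epoch + 1);
      }

      // output layer gradients
      vec dout = (yhat - yb) * (w_main * 2.0 / nb);
      mat gWout = S.t() * dout + 2.0 * l2 * Wout;
      double gbout = arma::accu(dout);
      // gradient into S: main path + auxiliary loss
      mat dS = dout * Wout.t();
      dS += (S.each_col() - yb) * (alpha * 2.0 / (nb * (double)P));

      ++tstep;
      const double c1 = 1.0 - std::pow(0.9, (double)tstep);
      const double c2 = 1.0 - std::pow(0.999, (double)tstep);

      for (int p = 0; p < P; ++p) {
        // aggregation neuron (linear)
        vec dzagg = dS.col(p);
        vec gAgg = A[p][n_hidden].t() * dzagg + 2.0 * l2 * aggW[p];
        double gAggB = arma::accu(dzagg);
        mat dA = dzagg * aggW[p].t();
        for (int l = n_hidden - 1; l >= 0; --l) {
          if (D[p][l].n_elem) dA %= D[p][l];
          mat dZ = dA % elu_grad(Z[p][l]);
          mat gW = A[p][l].t() * dZ + 2.0 * l2 * Wb[p][l];
          rowvec gb = arma::sum(dZ, 0);
          if (l > 0) dA = dZ * Wb[p][l].t();
          aW[p][l].step(Wb[p][l], gW, lr, c1, c2);
          ab[p][l].step(bb[p][l], gb, lr, c1, c2);
        }
        aAgg[p].step(aggW[p], gAgg, lr, c1, c2);
        aAggB[p].step(aggB[p], gAggB, lr, c1, c2);
      }
      aOut.step(Wout, gWout, lr, c1, c2);
      aOutB.step(bout, gbout, lr, c1, c2);
    }

    mat S_mon;
    vec pred = monitor_forward(Xm, S_mon);
    const double mse_main = arma::mean(arma::square(pred - ym));
    mat err = S_mon.each_col() - ym;
    const double mse_aux = arma::accu(err % err) / err.n_elem;
    const double total = (1 - alpha) * mse_main + alpha * mse_aux;
    if (!std::isfinite(total)) {
      stop("non-finite monitor loss at epoch %d; try a lower learning rate",
           epoch + 1);
    }
    history(epoch, 0) = mse_main;
    history(epoch, 1) = mse_aux;
    history(epoch, 2) = total;
  }

  assemble();
  List WoutL(Wfull.size()), boutL(Wfull.size());
  for (size_t i = 0; i < Wfull.size(); ++i) {
    WoutL[i] = wrap(Wfull[i]);
    boutL[i] = wrap(vec(bfull[i].t()));
  }
  return List::create(_["W"] = WoutL, _["b"] = boutL,
                      _["history"] = wrap(history));
}
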