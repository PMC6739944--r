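// Multi-task sequence CNN: three conv->ReLU->batchnorm->maxpool units,
// a sigmoid fully connected layer and a sigmoid multi-task output layer.
// Trained with minibatch RMSprop on binary cross entropy; L1/L2 penalties
// are applied to the fully connected layer weights only. All randomness
// (init, shuffling) is supplied by the caller, so runs are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.9;
static const double P_CLIP = 1e-12;

struct ConvLayer {
  mat W;           // (w*C_in) x C_out
  rowvec b;        // C_out
  rowvec gamma, beta, run_mean, run_var;
  int width;
  int pool;
};

struct Params {
  std::vector<ConvLayer> conv;
  mat Wfc;  rowvec bfc;
  mat Wout; rowvec bout;
};

static Params params_from_list(const Rcpp::List& pl) {
  Params p;
  Rcpp::List convs = pl["conv"];
  for (int j = 0; j < convs.size(); ++j) {
    Rcpp::List cl = convs[j];
    ConvLayer c;
    c.W = Rcpp::as<mat>(cl["W"]);
    c.b = Rcpp::as<rowvec>(cl["b"]);
    c.gamma = Rcpp::as<rowvec>(cl["gamma"]);
    c.beta = Rcpp::as<rowvec>(cl["beta"]);
    c.run_mean = Rcpp::as<rowvec>(cl["run_mean"]);
    c.run_var = Rcpp::as<rowvec>(cl["run_var"]);
    c.width = Rcpp::as<int>(cl["width"]);
    c.pool = Rcpp::as<int>(cl["pool"]);
    p.conv.push_back(c);
  }
  Rcpp::List fc = pl["fc"], out = pl["out"];
  p.Wfc = Rcpp::as<mat>(fc["W"]);  p.bfc = Rcpp::as<rowvec>(fc["b"]);
  p.Wout = Rcpp::as<mat>(out["W"]); p.bout = Rcpp::as<rowvec>(out["b"]);
  return p;
}

static Rcpp::List params_to_list(const Params& p) {
  Rcpp::List convs(p.conv.size());
  for (size_t j = 0; j < p.conv.size(); ++j) {
    const ConvLayer& c = p.conv[j];
    convs[j] = Rcpp::List::create(
      Rcpp::Named("W") = c.W, Rcpp::Named("b") = c.b,
      Rcpp::Named("gamma") = c.gamma, Rcpp::Named("beta") = c.beta,
      Rcpp::Named("run_mean") = c.run_mean,
      Rcpp::Named("run_var") = c.run_var,
      Rcpp::Named("width") = c.width, Rcpp::Named("pool") = c.pool);
  }
  return Rcpp::List::create(
    Rcpp::Named("conv") = convs,
    Rcpp::Named("fc") = Rcpp::List::create(Rcpp::Named("W") = p.Wfc,
                                           Rcpp::Named("b") = p.bfc),
    Rcpp::Named("out") = Rcpp::List::create(Rcpp::Named("W") = p.Wout,
                                            Rcpp::Named("b") = p.bout));
}

// A: L_in x C_in x B  ->  (B*L_out) x (w*C_in); column l*C_in + d holds
// A(i + l, d); row b*L_out + i is output position i of sequence b.
static mat im2col_batch(const cube& A, int w) {
  const int L = A.n_rows, C = A.n_cols, B = A.n_slices;
  const int Lout = L - w + 1;
  mat M(B * Lout, w * C);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < w; ++l) {
      M.submat(b * Lout, l * C, b * Lout + Lout - 1, l * C + C - 1) =
        A.slice(b).rows(l, l + Lout - 1);
    }
  }
  return M;
}

static cube col2im_batch(const mat& dM, int L, int C, int w, int B) {
  const int Lout = L - w + 1;
  cube dA(L, C, B, fill::zeros);
  for (int b = 0; b < B; ++b) {
    for (int l = 0; l < w; ++l) {
      dA.slice(b).rows(l, l + Lout - 1) +=
        dM.submat(b * Lout, l * C, b * Lout + Lout - 1, l * C + C - 1);
    }
  }
  return dA;
}

// rows b*L + i of Z -> slice b of an L x C x B cube
static cube mat_to_cube(const mat& Z, int L, int B) {
  const int C = Z.n_cols;
  cube A(L, C, B);
  for (int b = 0; b < B; ++b) A.slice(b) = Z.rows(b * L, b * L + L - 1);
  return A;
}

static void maxpool_fwd(const mat& Z, int Lout, int B, int pool,
                        mat& P, umat& amax) {
  const int C = Z.n_cols;
  const int Lp = Lout / pool;
  P.set_size(B * Lp, C);
  amax.set_size(B * Lp, C);
  for (int b = 0; b < B; ++b) {
    for (int q = 0; q < Lp; ++q) {
      const int r0 = b * Lout + q * pool;
      const int ro = b * Lp + q;
      for (int c = 0; c < C; ++c) {
        double best = Z(r0, c);
        int bi = r0;
        for (int k = 1; k < pool; ++k) {
          if (Z(r0 + k, c) > best) { best = Z(r0 + k, c); bi = r0 + k; }
        }
        P(ro, c) = best;
        amax(ro, c) = bi;
      }
    }
  }
}

struct LayerCache {
  mat M;        // im2col input
  mat R;        // post-ReLU pre-BN activations
  mat xhat;     // BN normalized activations
  rowvec invstd;
  umat amax;
  int Lout, Lp, B;
};

struct FwdCache {
  std::vector<LayerCache> layers;
  mat F;   // flattened pool-3 output (B x flat)
  mat H;   // FC sigmoid activations
  mat P;   // output probabilities
};

static mat sigmoid(const mat& Z) { return 1.0 / (1.0 + exp(-Z)); }

// Forward pass. training: batch BN statistics (+ running update);
// otherwise running statistics. null_idx/null_vals replace the named
// layer-1 post-ReLU activation maps with constants (inference use).
static mat forward(Params& p, const cube& X, bool training,
                   const ivec& null_idx, const vec& null_vals,
                   FwdCache* cache, cube* acts1 = nullptr) {
  const int B = X.n_slices;
  cube A = X;
  if (cache) cache->layers.resize(p.conv.size());
  for (size_t j = 0; j < p.conv.size(); ++j) {
    ConvLayer& c = p.conv[j];
    const int Lin = A.n_rows;
    const int Lout = Lin - c.width + 1;
    mat M = im2col_batch(A, c.width);
    mat Z = M * c.W;
    Z.each_row() += c.b;
    Z = clamp(Z, 0.0, datum::inf);                 // ReLU
    if (j == 0) {
      if (acts1) *acts1 = mat_to_cube(Z, Lout, B);
      for (uword k = 0; k < null_idx.n_elem; ++k) {
        Z.col(null_idx(k)).fill(null_vals(k));
      }
    }
    mat xhat;
    rowvec invstd;
    if (training) {
      rowvec mu = mean(Z, 0);
      mat Zc = Z;
      Zc.each_row() -= mu;
      rowvec va = mean(square(Zc), 0);
      invstd = 1.0 / sqrt(va + BN_EPS);
      xhat = Zc;
      xhat.each_row() %= invstd;
      c.run_mean = BN_MOMENTUM * c.run_mean + (1 - BN_MOMENTUM) * mu;
      c.run_var = BN_MOMENTUM * c.run_var + (1 - BN_MOMENTUM) * va;
    } else {
      invstd = 1.0 / sqrt(c.run_var + BN_EPS);
      xhat = Z;
      xhat.each_row() -= c.run_mean;
      xhat.each_row() %= invstd;
    }
    mat Y = xhat;
    Y.each_row() %= c.gamma;
    Y.each_row() += c.beta;
    mat Pl;
    umat amax;
    maxpool_fwd(Y, Lout, B, c.pool, Pl, amax);
    const int Lp = Lout / c.pool;
    if (cache) {
      LayerCache& lc = cache->layers[j];
      lc.M = std::move(M); lc.R = std::move(Z);
      lc.xhat = std::move(xhat); lc.invstd = invstd;
      lc.amax = amax; lc.Lout = Lout; lc.Lp = Lp; lc.B = B;
    }
    A = mat_to_cube(Pl, Lp, B);
  }
  // flatten: F(b, i*C + c) = A(i, c, b)
  const int Lf = A.n_rows, Cf = A.n_cols;
  mat F(B, Lf * Cf);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < Lf; ++i) {
      for (int c = 0; c < Cf; ++c) F(b, i * Cf + c) = A(i, c, b);
    }
  }
  mat H = sigmoid(F * p.Wfc + repmat(p.bfc, B, 1));
  mat P = sigmoid(H * p.Wout + repmat(p.bout, B, 1));
  if (cache) { cache->F = F; cache->H = H; cache->P = P; }
  return P;
}

static double bce(const mat& P, const mat& Y) {
  mat Pc = clamp(P, P_CLIP, 1.0 - P_CLIP);
  return -accu(Y % log(Pc) + (1.0 - Y) % log(1.0 - Pc)) / Pc.n_elem;
}

struct Grads {
  std::vector<mat> dW;
  std::vector<rowvec> db, dgamma, dbeta;
  mat dWfc, dWout;
  rowvec dbfc, dbout;
};

static Grads backward(const Params& p, const FwdCache& cache,
                      const cube& X, const mat& Y,
                      double l1, double l2) {
  Grads g;
  const int B = X.n_slices;
  const double scale = 1.0 / (double)(Y.n_rows * Y.n_cols);
  mat dZout = (cache.P - Y) * scale;
  g.dWout = cache.H.t() * dZout;
  g.dbout = sum(dZout, 0);
  mat dH = dZout * p.Wout.t();
  mat dF = dH % cache.H % (1.0 - cache.H);
  g.dWfc = cache.F.t() * dF + l1 * sign(p.Wfc) + 2.0 * l2 * p.Wfc;
  g.dbfc = sum(dF, 0);
  mat dFlat = dF * p.Wfc.t();

  g.dW.resize(p.conv.size());
  g.db.resize(p.conv.size());
  g.dgamma.resize(p.conv.size());
  g.dbeta.resize(p.conv.size());

  // unflatten into pooled layer-3 gradient
  const LayerCache& l3 = cache.layers.back();
  const int C3 = p.conv.back().W.n_cols;
  mat dP(B * l3.Lp, C3);
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < l3.Lp; ++i) {
      for (int c = 0; c < C3; ++c) {
        dP(b * l3.Lp + i, c) = dFlat(b, i * C3 + c);
      }
    }
  }

  for (int j = (int)p.conv.size() - 1; j >= 0; --j) {
    const ConvLayer& c = p.conv[j];
    const LayerCache& lc = cache.layers[j];
    // maxpool backward
    mat dY(B * lc.Lout, c.W.n_cols, fill::zeros);
    for (uword r = 0; r < dP.n_rows; ++r) {
      for (uword cc = 0; cc < dP.n_cols; ++cc) {
        dY(lc.amax(r, cc), cc) += dP(r, cc);
      }
    }
    // batch-norm backward (batch statistics)
    const double N = (double)dY.n_rows;
    g.dgamma[j] = sum(dY % lc.xhat, 0);
    g.dbeta[j] = sum(dY, 0);
    rowvec sd = g.dbeta[j];
    rowvec sdx = g.dgamma[j];
    mat dZ = dY * N;
    dZ.each_row() -= sd;
    mat xs = lc.xhat;
    xs.each_row() %= sdx;
    dZ -= xs;
    dZ.each_row() %= (c.gamma % lc.invstd) / N;
    // ReLU backward
    dZ.elem(find(lc.R <= 0)).zeros();
    // conv backward
    g.dW[j] = lc.M.t() * dZ;
    g.db[j] = sum(dZ, 0);
    if (j > 0) {
      mat dMin = dZ * c.W.t();
      const LayerCache& lp = cache.layers[j - 1];
      cube dA = col2im_batch(dMin, lp.Lp, p.conv[j - 1].W.n_cols,
                             c.width, B);
      // back to pooled-matrix layout of the previous layer
      dP.set_size(B * lp.Lp, dA.n_cols);
      for (int b = 0; b < B; ++b) {
        dP.rows(b * lp.Lp, b * lp.Lp + lp.Lp - 1) = dA.slice(b);
      }
    }
  }
  return g;
}

struct RmsState {
  std::vector<mat> W;
  std::vector<rowvec> b, gamma, beta;
  mat Wfc, Wout;
  rowvec bfc, bout;
  void init(const Params& p) {
    for (const ConvLayer& c : p.conv) {
      W.push_back(zeros<mat>(size(c.W)));
      b.push_back(zeros<rowvec>(c.b.n_elem));
      gamma.push_back(zeros<rowvec>(c.gamma.n_elem));
      beta.push_back(zeros<rowvec>(c.beta.n_elem));
    }
    Wfc = zeros<mat>(size(p.Wfc));   bfc = zeros<rowvec>(p.bfc.n_elem);
    Wout = zeros<mat>(size(p.Wout)); bout = zeros<rowvec>(p.bout.n_elem);
  }
};

template <typename T>
static void rms_update(T& param, const T& grad, T& cache,
                       double lr, double rho, double eps) {
  cache = rho * cache + (1.0 - rho) * (grad % grad);
  param -= lr * grad / (sqrt(cache) + eps);
}

static cube slice_cube(const cube& X, const uvec& idx) {
  cube out(X.n_rows, X.n_cols, idx.n_elem);
  for (uword k = 0; k < idx.n_elem; ++k) out.slice(k) = X.slice(idx(k));
  return out;
}

static mat predict_batched(Params& p, const cube& X, const ivec& null_idx,
                           const vec& null_vals, int batch) {
  const int N = X.n_slices;
  const int T = p.Wout.n_cols;
  mat P(N, T);
  for (int s = 0; s < N; s += batch) {
    const int e = std::min(N, s + batch);
    uvec idx = regspace<uvec>(s, e - 1);
    cube Xb = slice_cube(X, idx);
    P.rows(s, e - 1) = forward(p, Xb, false, null_idx, null_vals, nullptr);
  }
  return P;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
Rcpp::List cnn_train_cpp(Rcpp::List params_list,
                         const arma::cube& Xtr, const arma::mat& Ytr,
                         const arma::cube& Xval, const arma::mat& Yval,
                         const arma::imat& order,
                         double lr, int batch_size,
                         double l1, double l2,
                         int max_epochs, int patience,
                         double rho, double eps, bool verbose) {
  Params p = params_from_list(params_list);
  RmsState st;
  st.init(p);
  const int Ntr = Xtr.n_slices;
  ivec no_null;
  vec no_vals;

  std::vector<double> h_train, h_val, h_vacc;
  double best_val = datum::inf;
  Params best = p;
  int best_epoch = 0;
  int checks_since_best = 0;
  bool stopped = false;

  for (int epoch = 0; epoch < max_epochs && !stopped; ++epoch) {
    double epoch_loss = 0;
    int nb = 0;
    for (int s = 0; s < Ntr; s += batch_size) {
      const int e = std::min(Ntr, s + batch_size);
      uvec idx(e - s);
      for (int k = s; k < e; ++k) idx(k - s) = (uword)order(epoch, k) - 1;
      cube Xb = slice_cube(Xtr, idx);
      mat Yb = Ytr.rows(conv_to<uvec>::from(idx));
      FwdCache cache;
      forward(p, Xb, true, no_null, no_vals, &cache);
      double loss = bce(cache.P, Yb) +
        l1 * accu(abs(p.Wfc)) + l2 * accu(square(p.Wfc));
      Grads g = backward(p, cache, Xb, Yb, l1, l2);
      for (size_t j = 0; j < p.conv.size(); ++j) {
        rms_update(p.conv[j].W, g.dW[j], st.W[j], lr, rho, eps);
        rms_update(p.conv[j].b, g.db[j], st.b[j], lr, rho, eps);
        rms_update(p.conv[j].gamma, g.dgamma[j], st.gamma[j], lr, rho, eps);
        rms_update(p.conv[j].beta, g.dbeta[j], st.beta[j], lr, rho, eps);
      }
      rms_update(p.Wfc, g.dWfc, st.Wfc, lr, rho, eps);
      rms_update(p.bfc, g.dbfc, st.bfc, lr, rho, eps);
      rms_update(p.Wout, g.dWout, st.Wout, lr, rho, eps);
      rms_update(p.bout, g.dbout, st.bout, lr, rho, eps);
      epoch_loss += loss;
      ++nb;
    }
    epoch_loss /= nb;
    // validation check (one per epoch)
    mat Pv = predict_batched(p, Xval, no_null, no_vals, 256);
    double vloss = bce(Pv, Yval);
    double vacc = accu((conv_to<mat>::from(Pv >= 0.5)) == Yval) /
      (double)Yval.n_elem;
    h_train.push_back(epoch_loss);
    h_val.push_back(vloss);
    h_vacc.push_back(vacc);
    if (vloss < best_val) {
      best_val = vloss;
      best = p;
      best_epoch = epoch + 1;
      checks_since_best = 0;
    } else if (++checks_since_best >= patience) {
      stopped = true;
    }
    if (verbose) {
      Rcpp::Rcout << "epoch " << (epoch + 1) << " train_loss "
                  << epoch_loss << " val_loss " << vloss
                  << " val_acc " << vacc << std::endl;
    }
    Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
    Rcpp::Named("params") = params_to_list(best),
    Rcpp::Named("final_params") = params_to_list(p),
    Rcpp::Named("train_loss") = h_train,
    Rcpp::Named("val_loss") = h_val,
    Rcpp::Named("val_accuracy") = h_vacc,
    Rcpp::Named("best_epoch") = best_epoch,
    Rcpp::Named("best_val_loss") = best_val);
}

// Loss and gradients for one batch (training-mode forward, batch BN
// statistics); used for gradient verification.
// [[Rcpp::export(name = ".cnn_lossgrad_cpp")]]
Rcpp::List cnn_lossgrad_cpp(Rcpp::List params_list, const arma::cube& X,
                            const arma::mat& Y, double l1, double l2) {
  Params p = params_from_list(params_list);
  ivec no_null;
  vec no_vals;
  FwdCache cache;
  forward(p, X, true, no_null, no_vals, &cache);
  double loss = bce(cache.P, Y) +
    l1 * accu(abs(p.Wfc)) + l2 * accu(square(p.Wfc));
  Grads g = backward(p, cache, X, Y, l1, l2);
  Rcpp::List conv(g.dW.size());
  for (size_t j = 0; j < g.dW.size(); ++j) {
    conv[j] = Rcpp::List::create(
      Rcpp::Named("dW") = g.dW[j], Rcpp::Named("db") = g.db[j],
      Rcpp::Named("dgamma") = g.dgamma[j],
      Rcpp::Named("dbeta") = g.dbeta[j]);
  }
  return Rcpp::List::create(
    Rcpp::Named("loss") = loss, Rcpp::Named("conv") = conv,
    Rcpp::Named("dWfc") = g.dWfc, Rcpp::Named("dbfc") = g.dbfc,
    Rcpp::Named("dWout") = g.dWout, Rcpp::Named("dbout") = g.dbout);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
arma::mat cnn_predict_cpp(Rcpp::List params_list, const arma::cube& X,
                          const arma::ivec& null_idx,
                          const arma::vec& null_vals, int batch) {
  Params p = params_from_list(params_list);
  return predict_batched(p, X, null_idx, null_vals, batch);
}

// [[Rcpp::export(name = ".cnn_layer1_acts_cpp")]]
arma::cube cnn_layer1_acts_cpp(Rcpp::List params_list, const arma::cube& X) {
  Params p = params_from_list(params_list);
  const ConvLayer& c = p.conv[0];
  const int Lout = X.n_rows - c.width + 1;
  mat M = im2col_batch(X, c.width);
  mat Z = M * c.W;
  Z.each_row() += c.b;
  Z = clamp(Z, 0.0, datum::inf);
  return mat_to_cube(Z, Lout, X.n_slices);
}

// Per-filter min, max and mean of post-ReLU layer-1 activations over all
// positions of all sequences (chunked over sequences).
// [[Rcpp::export(name = ".cnn_acts_stats_cpp")]]
Rcpp::List cnn_acts_stats_cpp(Rcpp::List params_list, const arma::cube& X,
                              int batch) {
  Params p = params_from_list(params_list);
  const ConvLayer& c = p.conv[0];
  const int C = c.W.n_cols;
  rowvec amin(C), amax(C);
  amin.fill(datum::inf);
  amax.fill(-datum::inf);
  rowvec asum(C, fill::zeros);
  double npos = 0;
  const int N = X.n_slices;
  for (int s = 0; s < N; s += batch) {
    const int e = std::min(N, s + batch);
    cube Xb = slice_cube(X, regspace<uvec>(s, e - 1));
    mat M = im2col_batch(Xb, c.width);
    mat Z = M * c.W;
    Z.each_row() += c.b;
    Z = clamp(Z, 0.0, datum::inf);
    amin = min(join_cols(amin, min(Z, 0)), 0);
    amax = max(join_cols(amax, max(Z, 0)), 0);
    asum += sum(Z, 0);
    npos += Z.n_rows;
  }
  return Rcpp::List::create(Rcpp::Named("min") = amin.t(),
                            Rcpp::Named("max") = amax.t(),
                            Rcpp::Named("mean") = (asum / npos).t());
}

// For every filter and every threshold, accumulate the one-hot submatrix
// of each k-mer whose layer-1 activation exceeds the threshold.
// thresholds: n_beta x n_filters. Returns counts (w x 4 x n_beta x filter,
// flattened over filters in a list) and n_sites (n_beta x n_filters).
// [[Rcpp::export(name = ".cnn_pwm_counts_cpp")]]
Rcpp::List cnn_pwm_counts_cpp(Rcpp::List params_list, const arma::cube& X,
                              const arma::mat& thresholds, int batch) {
  Params p = params_from_list(params_list);
  const ConvLayer& c = p.conv[0];
  const int C = c.W.n_cols, w = c.width;
  const int nb = thresholds.n_rows;
  const int N = X.n_slices;
  std::vector<cube> counts(C, cube(w, 4, nb, fill::zeros));
  mat nsites(nb, C, fill::zeros);
  for (int s = 0; s < N; s += batch) {
    const int e = std::min(N, s + batch);
    cube Xb = slice_cube(X, regspace<uvec>(s, e - 1));
    const int B = Xb.n_slices;
    const int Lout = Xb.n_rows - w + 1;
    mat M = im2col_batch(Xb, w);
    mat Z = M * c.W;
    Z.each_row() += c.b;
    Z = clamp(Z, 0.0, datum::inf);
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < Lout; ++i) {
        const uword r = (uword)(b * Lout + i);
        for (int k = 0; k < C; ++k) {
          const double a = Z(r, k);
          for (int t = 0; t < nb; ++t) {
            if (a > thresholds(t, k)) {
              counts[k].slice(t) += Xb.slice(b).rows(i, i + w - 1);
              nsites(t, k) += 1;
            }
          }
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List cl(C);
  for (int k = 0; k < C; ++k) cl[k] = counts[k];
  return Rcpp::List::create(Rcpp::Named("counts") = cl,
                            Rcpp::Named("n_sites") = nsites);
}

// Predictions before nullification and after nullifying each filter set.
// null_vals holds the replacement constant for every layer-1 filter.
// Returns P_pre (N x T) and a list of P_aft matrices, one per set.
// [[Rcpp::export(name = ".cnn_nullify_predict_cpp")]]
Rcpp::List cnn_nullify_predict_cpp(Rcpp::List params_list,
                                   const arma::cube& X,
                                   const arma::vec& null_vals,
                                   Rcpp::List sets, int batch) {
  Params p = params_from_list(params_list);
  const int N = X.n_slices;
  const int T = p.Wout.n_cols;
  const int S = sets.size();
  ivec no_null;
  vec no_vals;
  mat Ppre(N, T);
  std::vector<mat> Paft(S, mat(N, T));
  for (int s = 0; s < N; s += batch) {
    const int e = std::min(N, s + batch);
    cube Xb = slice_cube(X, regspace<uvec>(s, e - 1));
    Ppre.rows(s, e - 1) = forward(p, Xb, false, no_null, no_vals, nullptr);
    for (int q = 0; q < S; ++q) {
      ivec idx = Rcpp::as<ivec>(sets[q]);
      vec vals(idx.n_elem);
      for (uword k = 0; k < idx.n_elem; ++k) vals(k) = null_vals(idx(k));
      Paft[q].rows(s, e - 1) = forward(p, Xb, false, idx, vals, nullptr);
    }
    Rcpp::checkUserInterrupt();
  }
  Rcpp::List pl(S);
  for (int q = 0; q < S; ++q) pl[q] = Paft[q];
  return Rcpp::List::create(Rcpp::Named("P_pre") = Ppre,
                            Rcpp::Named("P_aft") = pl);
}
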