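// Small CNN for image -> profile regression: four 3x3 "same" convolution
// stages (ReLU + 2x2 max pool) followed by one ReLU dense layer and a
// linear output layer. Trained with mean absolute error and RMSProp.
// All randomness (weight init, shuffling) lives on the R side so runs are
// reproducible from an R seed; this file is deterministic given its inputs.
// Arithmetic is single precision internally (weights cross the R boundary
// as doubles), which is ample for first-order training and twice as fast.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;
using arma::uvec;

static const int KK = 3; // kernel edge, "same" padding of 1

// im2col for a 3x3 kernel, zero padding 1, stride 1.
// Row index r = c*9 + kx*3 + ky maps to source (i+ky-1, j+kx-1, c);
// column index is the output position i + j*H (column-major, as in R).
static void im2col3(const fcube& a, fmat& cols) {
  const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
  cols.zeros(9 * C, H * W);
  for (int c = 0; c < C; ++c) {
    const fmat& sl = a.slice(c);
    for (int kx = 0; kx < KK; ++kx) {
      const int dx = kx - 1;
      for (int ky = 0; ky < KK; ++ky) {
        const int dy = ky - 1;
        const int r = c * 9 + kx * 3 + ky;
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          float* dst = cols.colptr(j * H) + r; // stride 9C between columns
          const float* src = sl.colptr(js);
          for (int i = i0; i < i1; ++i) dst[(size_t)i * cols.n_rows] = src[i + dy];
        }
      }
    }
  }
}

// Adjoint of im2col3: scatter-add column gradients back onto the image.
static void col2im3(const fmat& dcols, fcube& da) {
  const int H = da.n_rows, W = da.n_cols, C = da.n_slices;
  da.zeros();
  for (int c = 0; c < C; ++c) {
    fmat& sl = da.slice(c);
    for (int kx = 0; kx < KK; ++kx) {
      const int dx = kx - 1;
      for (int ky = 0; ky < KK; ++ky) {
        const int dy = ky - 1;
        const int r = c * 9 + kx * 3 + ky;
        for (int j = 0; j < W; ++j) {
          const int js = j + dx;
          if (js < 0 || js >= W) continue;
          const int i0 = std::max(0, -dy), i1 = std::min(H, H - dy);
          const float* src = dcols.colptr(j * H) + r;
          float* dst = sl.colptr(js);
          for (int i = i0; i < i1; ++i) dst[i + dy] += src[(size_t)i * dcols.n_rows];
        }
      }
    }
  }
}

// 2x2 max pool with argmax bookkeeping (linear indices into the input cube).
static void maxpool2(const fcube& a, fcube& out, uvec& arg) {
  const int H = a.n_rows, W = a.n_cols, C = a.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  out.set_size(Ho, Wo, C);
  arg.set_size((size_t)Ho * Wo * C);
  size_t q = 0;
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        float best = -arma::datum::inf;
        size_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int ii = 2 * i + di, jj = 2 * j + dj;
            const float v = a(ii, jj, c);
            if (v > best) { best = v; bidx = (size_t)ii + (size_t)jj * H + (size_t)c * H * W; }
          }
        out(i, j, c) = best;
        arg(q++) = bidx;
      }
}

struct Net {
  std::vector<fmat> Wc;  // conv weights, (Cout x 9*Cin)
  std::vector<fvec> bc;
  fmat W1, W2;           // dense, (hidden x flat), (nout x hidden)
  fvec b1, b2;
  std::vector<int> cin, cout;
};

static fvec as_fvec(SEXP x) {
  NumericVector v(x);
  fvec out(v.size());
  for (R_xlen_t i = 0; i < v.size(); ++i) out[i] = (float)v[i];
  return out;
}

static fmat as_fmat(SEXP x) {
  NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  for (R_xlen_t i = 0; i < m.size(); ++i) out[i] = (float)m[i];
  return out;
}

static Net parse_weights(const List& weights) {
  Net net;
  for (int l = 0; l < 4; ++l) {
    NumericVector Wv = weights[2 * l];
    IntegerVector d = Wv.attr("dim"); // 3,3,Cin,Cout
    const int Cin = d[2], Cout = d[3];
    fmat Wm(Cout, 9 * Cin);
    for (int o = 0; o < Cout; ++o)
      for (int r = 0; r < 9 * Cin; ++r) Wm(o, r) = (float)Wv[r + (size_t)o * 9 * Cin];
    net.Wc.push_back(Wm);
    net.bc.push_back(as_fvec(weights[2 * l + 1]));
    net.cin.push_back(Cin);
    net.cout.push_back(Cout);
  }
  net.W1 = as_fmat(weights[8]);
  net.b1 = as_fvec(weights[9]);
  net.W2 = as_fmat(weights[10]);
  net.b2 = as_fvec(weights[11]);
  return net;
}

struct FwdState {
  std::vector<fmat> cols;    // im2col inputs per conv layer
  std::vector<fcube> act;    // post-ReLU, pre-pool activations
  std::vector<uvec> argm;    // pool argmax
  std::vector<fcube> pooled; // layer inputs (pooled outputs)
  fvec flat, h1pre, h1, out;
};

static void forward_one(const Net& net, const fcube& x, FwdState& st, bool keep) {
  fcube a = x;
  if (keep) {
    st.cols.assign(4, fmat());
    st.act.assign(4, fcube());
    st.argm.assign(4, uvec());
    st.pooled.assign(4, fcube());
  }
  fmat cols;
  for (int l = 0; l < 4; ++l) {
    if (keep) st.pooled[l] = a;
    im2col3(a, cols);
    fmat z = net.Wc[l] * cols; // Cout x HW
    z.each_col() += net.bc[l];
    z.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    const int H = a.n_rows, W = a.n_cols, Cout = net.cout[l];
    fcube act(H, W, Cout);
    fmat zt = z.t(); // (HW x Cout), matches the cube's column-major layout
    std::memcpy(act.memptr(), zt.memptr(), sizeof(float) * zt.n_elem);
    fcube pooled;
    uvec arg;
    maxpool2(act, pooled, arg);
    if (keep) {
      st.cols[l] = std::move(cols);
      st.act[l] = std::move(act);
      st.argm[l] = std::move(arg);
    }
    a = std::move(pooled);
    cols.reset();
  }
  st.flat = arma::vectorise(a);
  st.h1pre = net.W1 * st.flat + net.b1;
  st.h1 = st.h1pre;
  st.h1.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  st.out = net.W2 * st.h1 + net.b2;
}

struct Grads {
  std::vector<fmat> Wc;
  std::vector<fvec> bc;
  fmat W1, W2;
  fvec b1, b2;
  void zeros_like(const Net& n) {
    Wc.clear(); bc.clear();
    for (int l = 0; l < 4; ++l) {
      Wc.push_back(arma::zeros<fmat>(n.Wc[l].n_rows, n.Wc[l].n_cols));
      bc.push_back(arma::zeros<fvec>(n.bc[l].n_elem));
    }
    W1 = arma::zeros<fmat>(n.W1.n_rows, n.W1.n_cols);
    b1 = arma::zeros<fvec>(n.b1.n_elem);
    W2 = arma::zeros<fmat>(n.W2.n_rows, n.W2.n_cols);
    b2 = arma::zeros<fvec>(n.b2.n_elem);
  }
};

static void backward_one(const Net& net, const FwdState& st, const fvec& dout, Grads& g) {
  g.W2 += dout * st.h1.t();
  g.b2 += dout;
  fvec dh1 = net.W2.t() * dout;
  for (size_t i = 0; i < dh1.n_elem; ++i) if (st.h1pre[i] <= 0.0f) dh1[i] = 0.0f;
  g.W1 += dh1 * st.flat.t();
  g.b1 += dh1;
  fvec dflat = net.W1.t() * dh1;

  // gradient w.r.t. the last pooled cube
  const fcube& last_act = st.act[3];
  fcube dpool(last_act.n_rows / 2, last_act.n_cols / 2, last_act.n_slices);
  std::memcpy(dpool.memptr(), dflat.memptr(), sizeof(float) * dflat.n_elem);

  for (int l = 3; l >= 0; --l) {
    const fcube& act = st.act[l];
    fcube dact(act.n_rows, act.n_cols, act.n_slices, arma::fill::zeros);
    const uvec& arg = st.argm[l];
    const float* dp = dpool.memptr();
    for (size_t q = 0; q < arg.n_elem; ++q) dact[arg[q]] += dp[q];
    // ReLU: act stores post-ReLU values
    for (size_t q = 0; q < dact.n_elem; ++q) if (act[q] <= 0.0f) dact[q] = 0.0f;
    // back to (Cout x HW)
    const int H = act.n_rows, W = act.n_cols, Cout = act.n_slices;
    fmat dz(Cout, (size_t)H * W);
    {
      fmat dzt((float*)dact.memptr(), (size_t)H * W, Cout, false, true);
      dz = dzt.t();
    }
    g.Wc[l] += dz * st.cols[l].t();
    g.bc[l] += arma::sum(dz, 1);
    if (l > 0) {
      fmat dcols = net.Wc[l].t() * dz;
      fcube da(st.pooled[l].n_rows, st.pooled[l].n_cols, st.pooled[l].n_slices);
      col2im3(dcols, da);
      dpool = std::move(da);
    }
  }
}

static void rms_update(fmat& w, fmat& c, const fmat& g, float lr, float rho, float eps) {
  c = rho * c + (1.0f - rho) * arma::square(g);
  w -= lr * g / (arma::sqrt(c) + eps);
}
static void rms_update(fvec& w, fvec& c, const fvec& g, float lr, float rho, float eps) {
  c = rho * c + (1.0f - rho) * arma::square(g);
  w -= lr * g / (arma::sqrt(c) + eps);
}

static fcube sample_cube(const NumericVector& tensors, int H, int W, int C, int t) {
  const size_t sz = (size_t)H * W * C;
  fcube x(H, W, C);
  const double* src = REAL(tensors) + sz * (size_t)t;
  float* dst = x.memptr();
  for (size_t i = 0; i < sz; ++i) dst[i] = (float)src[i];
  return x;
}

static List pack_weights(const Net& net) {
  List out(12);
  for (int l = 0; l < 4; ++l) {
    const int Cin = net.cin[l], Cout = net.cout[l];
    NumericVector Wv((size_t)9 * Cin * Cout);
    for (int o = 0; o < Cout; ++o)
      for (int r = 0; r < 9 * Cin; ++r) Wv[r + (size_t)o * 9 * Cin] = net.Wc[l](o, r);
    Wv.attr("dim") = IntegerVector::create(3, 3, Cin, Cout);
    out[2 * l] = Wv;
    out[2 * l + 1] = NumericVector(net.bc[l].begin(), net.bc[l].end());
  }
  NumericMatrix W1(net.W1.n_rows, net.W1.n_cols);
  for (R_xlen_t i = 0; i < W1.size(); ++i) W1[i] = net.W1[i];
  out[8] = W1;
  out[9] = NumericVector(net.b1.begin(), net.b1.end());
  NumericMatrix W2(net.W2.n_rows, net.W2.n_cols);
  for (R_xlen_t i = 0; i < W2.size(); ++i) W2[i] = net.W2[i];
  out[10] = W2;
  out[11] = NumericVector(net.b2.begin(), net.b2.end());
  return out;
}

// One training epoch over `order` (1-based pair indices). Returns updated
// weights, RMSProp cache, and the mean MAE over the epoch.
// [[Rcpp::export]]
List cpp_cnn_train_epoch(NumericVector tensors, IntegerVector tdim,
                         IntegerVector pair_tensor, NumericMatrix targets,
                         IntegerVector order, List weights, List cache,
                         double lr, double rho, double eps, int batch_size) {
  const int H = tdim[0], W = tdim[1], C = tdim[2];
  Net net = parse_weights(weights);
  Net cch = parse_weights(cache);
  const int nout = targets.nrow();
  Grads g;
  FwdState st;
  double loss_sum = 0.0;
  int in_batch = 0;
  g.zeros_like(net);
  const float flr = (float)lr, frho = (float)rho, feps = (float)eps;
  for (int q = 0; q < order.size(); ++q) {
    const int p = order[q] - 1;
    const int t = pair_tensor[p] - 1;
    fcube x = sample_cube(tensors, H, W, C, t);
    forward_one(net, x, st, true);
    fvec y(nout);
    for (int i = 0; i < nout; ++i) y[i] = (float)targets(i, p);
    fvec diff = st.out - y;
    loss_sum += arma::mean(arma::abs(diff));
    if (!diff.is_finite()) stop("NaN/Inf encountered in training loss");
    fvec dout(nout);
    for (int i = 0; i < nout; ++i)
      dout[i] = (diff[i] > 0.0f ? 1.0f : (diff[i] < 0.0f ? -1.0f : 0.0f)) / nout;
    backward_one(net, st, dout, g);
    ++in_batch;
    const bool last = (q == order.size() - 1);
    if (in_batch == batch_size || last) {
      const float inv = 1.0f / in_batch;
      for (int l = 0; l < 4; ++l) {
        rms_update(net.Wc[l], cch.Wc[l], g.Wc[l] * inv, flr, frho, feps);
        rms_update(net.bc[l], cch.bc[l], g.bc[l] * inv, flr, frho, feps);
      }
      rms_update(net.W1, cch.W1, g.W1 * inv, flr, frho, feps);
      rms_update(net.b1, cch.b1, g.b1 * inv, flr, frho, feps);
      rms_update(net.W2, cch.W2, g.W2 * inv, flr, frho, feps);
      rms_update(net.b2, cch.b2, g.b2 * inv, flr, frho, feps);
      g.zeros_like(net);
      in_batch = 0;
    }
  }
  return List::create(_["weights"] = pack_weights(net),
                      _["cache"] = pack_weights(cch),
                      _["loss"] = loss_sum / order.size());
}

// Mean-MAE loss and its gradient over the selected pairs, without any
// update. Used by tests to validate the backward pass numerically.
// [[Rcpp::export]]
List cpp_cnn_grad(NumericVector tensors, IntegerVector tdim,
                  IntegerVector pair_tensor, NumericMatrix targets,
                  IntegerVector idx, List weights) {
  const int H = tdim[0], W = tdim[1], C = tdim[2];
  Net net = parse_weights(weights);
  const int nout = targets.nrow();
  Grads g;
  g.zeros_like(net);
  FwdState st;
  double loss = 0.0;
  for (int q = 0; q < idx.size(); ++q) {
    const int p = idx[q] - 1;
    fcube x = sample_cube(tensors, H, W, C, pair_tensor[p] - 1);
    forward_one(net, x, st, true);
    fvec y(nout);
    for (int i = 0; i < nout; ++i) y[i] = (float)targets(i, p);
    fvec diff = st.out - y;
    loss += arma::mean(arma::abs(diff));
    fvec dout(nout);
    for (int i = 0; i < nout; ++i)
      dout[i] = (diff[i] > 0.0f ? 1.0f : (diff[i] < 0.0f ? -1.0f : 0.0f)) / nout;
    backward_one(net, st, dout, g);
  }
  const float inv = 1.0f / idx.size();
  Net gn;
  gn.Wc = g.Wc; gn.bc = g.bc; gn.W1 = g.W1; gn.b1 = g.b1; gn.W2 = g.W2; gn.b2 = g.b2;
  gn.cin = net.cin; gn.cout = net.cout;
  for (int l = 0; l < 4; ++l) { gn.Wc[l] *= inv; gn.bc[l] *= inv; }
  gn.W1 *= inv; gn.b1 *= inv; gn.W2 *= inv; gn.b2 *= inv;
  return List::create(_["loss"] = loss * inv, _["grads"] = pack_weights(gn));
}

// Forward pass for the tensors selected by `idx` (1-based). Returns an
// (n_out x length(idx)) matrix of predictions.
// [[Rcpp::export]]
NumericMatrix cpp_cnn_predict(NumericVector tensors, IntegerVector tdim,
                              IntegerVector idx, List weights) {
  const int H = tdim[0], W = tdim[1], C = tdim[2];
  Net net = parse_weights(weights);
  const int nout = net.b2.n_elem;
  NumericMatrix out(nout, idx.size());
  FwdState st;
  for (int q = 0; q < idx.size(); ++q) {
    fcube x = sample_cube(tensors, H, W, C, idx[q] - 1);
    forward_one(net, x, st, false);
    for (int i = 0; i < nout; ++i) out(i, q) = st.out[i];
  }
  return out;
}
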