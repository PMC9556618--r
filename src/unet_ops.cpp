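// Core numerical kernels: a small U-Net (forward + backprop), 8-connectivity
// component labelling, and a splitmix-style seed mixer.
//
// The network operates on single-channel H x W images. Parameters are a flat
// list of (W, b) pairs in a fixed architecture order (see unet_param_shapes()
// on the R side); 3x3 convolutions store W as a (9*c_in) x c_out matrix with
// patch element order c*9 + (dj+1)*3 + (di+1) (di = row offset, dj = col
// offset); 2x2 up-convolutions store W as (4*c_in) x c_out with sub-block
// s = di + 2*dj; the final 1x1 convolution stores W as c_in x 1.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct ConvParam {
  mat W;
  vec b;
};

static std::vector<ConvParam> parse_params(const List& params) {
  std::vector<ConvParam> out;
  out.reserve(params.size());
  for (int i = 0; i < params.size(); ++i) {
    List p = params[i];
    ConvParam cp;
    cp.W = as<mat>(p["W"]);
    cp.b = as<vec>(p["b"]);
    out.push_back(cp);
  }
  return out;
}

// ---- 3x3 same-padding convolution ------------------------------------------

static mat im2col3(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  mat P(H * (size_t)W, 9 * (size_t)C, fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = X.slice_colptr(c, j + dj);
          double* dst = P.colptr(col) + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + di];
        }
      }
    }
  }
  return P;
}

static void col2im3_add(const mat& dP, cube& dX) {
  const int H = dX.n_rows, W = dX.n_cols, C = dX.n_slices;
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int col = c * 9 + (dj + 1) * 3 + (di + 1);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          double* dst = dX.slice_colptr(c, j + dj);
          const double* src = dP.colptr(col) + (size_t)j * H;
          for (int i = i0; i < i1; ++i) dst[i + di] += src[i];
        }
      }
    }
  }
}

static cube mat_to_cube(const mat& Y, int H, int W) {
  cube out(H, W, Y.n_cols);
  for (uword c = 0; c < Y.n_cols; ++c)
    out.slice(c) = reshape(Y.col(c), H, W);
  return out;
}

static mat cube_to_mat(const cube& X) {
  mat out(X.n_rows * (size_t)X.n_cols, X.n_slices);
  for (uword c = 0; c < X.n_slices; ++c)
    out.col(c) = vectorise(X.slice(c));
  return out;
}

static cube conv3(const cube& X, const ConvParam& p) {
  mat P = im2col3(X);
  mat Y = P * p.W;
  Y.each_row() += p.b.t();
  return mat_to_cube(Y, X.n_rows, X.n_cols);
}

static cube conv3_back(const cube& X, const ConvParam& p, const cube& dY,
                       mat& dW, vec& db) {
  mat dYm = cube_to_mat(dY);
  mat P = im2col3(X);
  dW = P.t() * dYm;
  db = sum(dYm, 0).t();
  mat dP = dYm * p.W.t();
  cube dX(X.n_rows, X.n_cols, X.n_slices, fill::zeros);
  col2im3_add(dP, dX);
  return dX;
}

// ---- ReLU -------------------------------------------------------------------

static void relu_inplace(cube& X) {
  X.transform([](double v) { return v > 0.0 ? v : 0.0; });
}

// zero the gradient where the (post-relu) activation is zero
static void relu_back_inplace(cube& dY, const cube& act) {
  for (uword k = 0; k < dY.n_elem; ++k)
    if (act(k) <= 0.0) dY(k) = 0.0;
}

// ---- 2x2 max pooling --------------------------------------------------------

static cube maxpool2(const cube& X, ucube& idx) {
  const int H = X.n_rows / 2, W = X.n_cols / 2, C = X.n_slices;
  cube out(H, W, C);
  idx.set_size(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double best = X(2 * i, 2 * j, c);
        uword bs = 0;
        for (int s = 1; s < 4; ++s) {
          const double v = X(2 * i + s % 2, 2 * j + s / 2, c);
          if (v > best) { best = v; bs = s; }
        }
        out(i, j, c) = best;
        idx(i, j, c) = bs;
      }
    }
  }
  return out;
}

static cube maxpool2_back(const cube& dY, const ucube& idx) {
  const int H = dY.n_rows, W = dY.n_cols, C = dY.n_slices;
  cube dX(2 * H, 2 * W, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const uword s = idx(i, j, c);
        dX(2 * i + s % 2, 2 * j + s / 2, c) += dY(i, j, c);
      }
  return dX;
}

// ---- 2x2 stride-2 up-convolution -------------------------------------------

static cube up2(const cube& X, const ConvParam& p) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const int Cout = p.W.n_cols;
  mat Xm = cube_to_mat(X);
  cube Y(2 * H, 2 * W, Cout);
  for (int s = 0; s < 4; ++s) {
    const int di = s % 2, dj = s / 2;
    mat Ys = Xm * p.W.rows(s * Cin, (s + 1) * Cin - 1);
    Ys.each_row() += p.b.t();
    for (int c = 0; c < Cout; ++c) {
      const double* src = Ys.colptr(c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          Y(2 * i + di, 2 * j + dj, c) = src[(size_t)j * H + i];
    }
  }
  return Y;
}

static cube up2_back(const cube& X, const ConvParam& p, const cube& dY,
                     mat& dW, vec& db) {
  const int H = X.n_rows, W = X.n_cols, Cin = X.n_slices;
  const int Cout = p.W.n_cols;
  mat Xm = cube_to_mat(X);
  dW.set_size(4 * Cin, Cout);
  db.zeros(Cout);
  mat dXm(H * (size_t)W, Cin, fill::zeros);
  for (int s = 0; s < 4; ++s) {
    const int di = s % 2, dj = s / 2;
    mat dYs(H * (size_t)W, Cout);
    for (int c = 0; c < Cout; ++c) {
      double* dst = dYs.colptr(c);
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          dst[(size_t)j * H + i] = dY(2 * i + di, 2 * j + dj, c);
    }
    dW.rows(s * Cin, (s + 1) * Cin - 1) = Xm.t() * dYs;
    db += sum(dYs, 0).t();
    dXm += dYs * p.W.rows(s * Cin, (s + 1) * Cin - 1).t();
  }
  return mat_to_cube(dXm, H, W);
}

// ---- 1x1 convolution --------------------------------------------------------

static cube conv1(const cube& X, const ConvParam& p) {
  mat Y = cube_to_mat(X) * p.W;
  Y.each_row() += p.b.t();
  return mat_to_cube(Y, X.n_rows, X.n_cols);
}

static cube conv1_back(const cube& X, const ConvParam& p, const cube& dY,
                       mat& dW, vec& db) {
  mat dYm = cube_to_mat(dY);
  mat Xm = cube_to_mat(X);
  dW = Xm.t() * dYm;
  db = sum(dYm, 0).t();
  return mat_to_cube(dYm * p.W.t(), X.n_rows, X.n_cols);
}

// ---- forward pass (shared by predict and grad) ------------------------------

struct Caches {
  std::vector<cube> conv_in;   // input of each parameterised layer, param order
  std::vector<cube> act_out;   // post-relu output (empty cube when no relu)
  std::vector<ucube> pool_idx; // one per encoder level
  std::vector<cube> skips;     // encoder outputs kept for concatenation
  int bottleneck_h = 0, bottleneck_w = 0;
};

static cube forward_pass(const mat& x, const IntegerVector& filters,
                         const std::vector<ConvParam>& p, Caches& cc,
                         bool keep) {
  const int L = filters.size();
  cube cur(x.n_rows, x.n_cols, 1);
  cur.slice(0) = x;
  int pi = 0;
  cc.conv_in.resize(p.size());
  cc.act_out.resize(p.size());
  cc.pool_idx.resize(L - 1);

  for (int l = 0; l < L - 1; ++l) {
    for (int k = 0; k < 2; ++k, ++pi) {
      if (keep) cc.conv_in[pi] = cur;
      cur = conv3(cur, p[pi]);
      relu_inplace(cur);
      if (keep) cc.act_out[pi] = cur;
    }
    cc.skips.push_back(cur);
    ucube idx;
    cur = maxpool2(cur, idx);
    if (keep) cc.pool_idx[l] = idx;
  }
  for (int k = 0; k < 2; ++k, ++pi) {
    if (keep) cc.conv_in[pi] = cur;
    cur = conv3(cur, p[pi]);
    relu_inplace(cur);
    if (keep) cc.act_out[pi] = cur;
  }
  cc.bottleneck_h = cur.n_rows;
  cc.bottleneck_w = cur.n_cols;
  for (int l = L - 2; l >= 0; --l) {
    if (keep) cc.conv_in[pi] = cur;
    cur = up2(cur, p[pi]);
    ++pi;
    cur = join_slices(cur, cc.skips[l]);
    for (int k = 0; k < 2; ++k, ++pi) {
      if (keep) cc.conv_in[pi] = cur;
      cur = conv3(cur, p[pi]);
      relu_inplace(cur);
      if (keep) cc.act_out[pi] = cur;
    }
  }
  if (keep) cc.conv_in[pi] = cur;
  return conv1(cur, p[pi]); // logits, H x W x 1
}

// [[Rcpp::export]]
List unet_forward_cpp(const arma::mat& x, IntegerVector filters, List params) {
  std::vector<ConvParam> p = parse_params(params);
  Caches cc;
  cube z = forward_pass(x, filters, p, cc, false);
  mat prob = 1.0 / (1.0 + exp(-z.slice(0)));
  return List::create(_["prob"] = prob,
                      _["bottleneck"] = IntegerVector::create(cc.bottleneck_h,
                                                              cc.bottleneck_w));
}

// [[Rcpp::export]]
double unet_loss_cpp(const arma::mat& x, const arma::mat& y,
                     IntegerVector filters, List params) {
  std::vector<ConvParam> p = parse_params(params);
  Caches cc;
  cube zc = forward_pass(x, filters, p, cc, false);
  const mat& z = zc.slice(0);
  // stable binary cross-entropy from logits
  mat l = clamp(z, 0.0, datum::inf) - z % y + log1p(exp(-abs(z)));
  return accu(l) / l.n_elem;
}

// [[Rcpp::export]]
List unet_grad_cpp(const arma::mat& x, const arma::mat& y,
                   IntegerVector filters, List params) {
  const int L = filters.size();
  std::vector<ConvParam> p = parse_params(params);
  Caches cc;
  cube zc = forward_pass(x, filters, p, cc, true);
  const mat& z = zc.slice(0);
  const double n = (double)z.n_elem;
  mat lossm = clamp(z, 0.0, datum::inf) - z % y + log1p(exp(-abs(z)));
  const double loss = accu(lossm) / n;

  std::vector<mat> dWs(p.size());
  std::vector<vec> dbs(p.size());

  cube dcur(z.n_rows, z.n_cols, 1);
  dcur.slice(0) = (1.0 / (1.0 + exp(-z)) - y) / n;

  int pi = (int)p.size() - 1;
  dcur = conv1_back(cc.conv_in[pi], p[pi], dcur, dWs[pi], dbs[pi]);
  --pi;

  // decoder levels were built for l = L-2 .. 0; walk params backwards
  std::vector<cube> d_skip(L - 1);
  for (int l = 0; l <= L - 2; ++l) {
    for (int k = 0; k < 2; ++k, --pi) {
      relu_back_inplace(dcur, cc.act_out[pi]);
      dcur = conv3_back(cc.conv_in[pi], p[pi], dcur, dWs[pi], dbs[pi]);
    }
    const int fl = filters[l];
    d_skip[l] = dcur.slices(fl, 2 * fl - 1);
    cube d_up = dcur.slices(0, fl - 1);
    dcur = up2_back(cc.conv_in[pi], p[pi], d_up, dWs[pi], dbs[pi]);
    --pi;
  }
  for (int k = 0; k < 2; ++k, --pi) {
    relu_back_inplace(dcur, cc.act_out[pi]);
    dcur = conv3_back(cc.conv_in[pi], p[pi], dcur, dWs[pi], dbs[pi]);
  }
  for (int l = L - 2; l >= 0; --l) {
    dcur = maxpool2_back(dcur, cc.pool_idx[l]);
    dcur += d_skip[l];
    for (int k = 0; k < 2; ++k, --pi) {
      relu_back_inplace(dcur, cc.act_out[pi]);
      dcur = conv3_back(cc.conv_in[pi], p[pi], dcur, dWs[pi], dbs[pi]);
    }
  }

  List grads(p.size());
  for (size_t i = 0; i < p.size(); ++i)
    grads[i] = List::create(_["W"] = dWs[i], _["b"] = dbs[i]);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// ---- 8-connectivity component labelling -------------------------------------

// [[Rcpp::export]]
IntegerMatrix label8_cpp(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> qi, qj;
  int next = 0;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      qi.clear(); qj.clear();
      qi.push_back(i); qj.push_back(j);
      while (!qi.empty()) {
        const int ci = qi.back(), cj = qj.back();
        qi.pop_back(); qj.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            const int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
            if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              qi.push_back(ni); qj.push_back(nj);
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---- splitmix-style seed derivation -----------------------------------------

// [[Rcpp::export]]
double mix_seed_cpp(double seed, double stream) {
  uint64_t z = (uint64_t)seed * 0x9E3779B97F4A7C15ULL +
               (uint64_t)stream + 1ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  z = z ^ (z >> 31);
  return (double)(z % 2147483647ULL) + 1.0; // in [1, 2^31 - 1]
}
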