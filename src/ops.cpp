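// Low-level numerical kernels for the segmentation networks and metrics.
// Tensors are H x W x C arma::cubes (R arrays with dim c(H, W, C)).
// Convolution weights arrive flattened as (C_out x kh*kw*C_in) matrices with
// row-major-in-R flattening r = ki + kh*(kj + kw*ci); all backward passes are
// hand-derived and checked against numerical gradients in the test suite.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;

static inline int conv_out(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

static mat im2col(const cube& x, int kh, int kw, int stride, int pad,
                  int Ho, int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat out(kh * kw * C, (arma::uword)Ho * Wo, fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const mat& xs = x.slice(ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            out(r, oi + (arma::uword)Ho * oj) = xs(i, j);
          }
        }
      }
    }
  }
  return out;
}

static void col2im_acc(const mat& cols, cube& gx, int kh, int kw, int stride,
                       int pad, int Ho, int Wo) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int ci = 0; ci < C; ++ci) {
    mat& gs = gx.slice(ci);
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const int r = ki + kh * (kj + kw * ci);
        for (int oj = 0; oj < Wo; ++oj) {
          const int j = oj * stride + kj - pad;
          if (j < 0 || j >= W) continue;
          for (int oi = 0; oi < Ho; ++oi) {
            const int i = oi * stride + ki - pad;
            if (i < 0 || i >= H) continue;
            gs(i, j) += cols(r, oi + (arma::uword)Ho * oj);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
arma::cube conv2d_fwd_cpp(const arma::cube& x, const arma::mat& Wm,
                          const arma::vec& b, int kh, int kw, int stride,
                          int pad) {
  const int Ho = conv_out(x.n_rows, kh, stride, pad);
  const int Wo = conv_out(x.n_cols, kw, stride, pad);
  const int Co = Wm.n_rows;
  mat Xc = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat Y = Wm * Xc;                       // Co x Ho*Wo
  cube out(Ho, Wo, Co);
  for (int co = 0; co < Co; ++co)
    out.slice(co) = reshape(Y.row(co), Ho, Wo) + b(co);
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(const arma::cube& x, const arma::mat& Wm,
                    const arma::cube& gy, int kh, int kw, int stride,
                    int pad, bool want_params = true) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, Co = gy.n_slices;
  mat Gy(Co, (arma::uword)Ho * Wo);
  for (int co = 0; co < Co; ++co)
    Gy.row(co) = vectorise(gy.slice(co)).t();
  mat Gxc = Wm.t() * Gy;
  cube gx(x.n_rows, x.n_cols, x.n_slices, fill::zeros);
  col2im_acc(Gxc, gx, kh, kw, stride, pad, Ho, Wo);
  if (!want_params) return List::create(Rcpp::Named("gx") = gx);
  mat Xc = im2col(x, kh, kw, stride, pad, Ho, Wo);
  mat gW = Gy * Xc.t();
  vec gb = sum(Gy, 1);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gW") = gW,
                      Rcpp::Named("gb") = gb);
}

// Transposed convolution with a 2x2 kernel and stride 2 (decoder upsampling):
// output windows do not overlap, so each output pixel receives exactly one
// contribution.  M is (4*C_out x C_in), row r = di + 2*dj + 4*co.

// [[Rcpp::export]]
arma::cube tconv2_fwd_cpp(const arma::cube& x, const arma::mat& M,
                          const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Co = M.n_rows / 4;
  mat Xm(C, (arma::uword)H * W);
  for (int ci = 0; ci < C; ++ci) Xm.row(ci) = vectorise(x.slice(ci)).t();
  mat Y = M * Xm;                        // 4*Co x H*W
  cube out(2 * H, 2 * W, Co);
  for (int co = 0; co < Co; ++co) {
    mat& os = out.slice(co);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int r = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            os(2 * i + di, 2 * j + dj) = Y(r, i + (arma::uword)H * j) + b(co);
      }
  }
  return out;
}

// [[Rcpp::export]]
List tconv2_bwd_cpp(const arma::cube& x, const arma::mat& M,
                    const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Co = M.n_rows / 4;
  mat Xm(C, (arma::uword)H * W);
  for (int ci = 0; ci < C; ++ci) Xm.row(ci) = vectorise(x.slice(ci)).t();
  mat Gy(4 * Co, (arma::uword)H * W);
  vec gb(Co, fill::zeros);
  for (int co = 0; co < Co; ++co) {
    const mat& gs = gy.slice(co);
    gb(co) = accu(gs);
    for (int dj = 0; dj < 2; ++dj)
      for (int di = 0; di < 2; ++di) {
        const int r = di + 2 * dj + 4 * co;
        for (int j = 0; j < W; ++j)
          for (int i = 0; i < H; ++i)
            Gy(r, i + (arma::uword)H * j) = gs(2 * i + di, 2 * j + dj);
      }
  }
  mat gM = Gy * Xm.t();
  mat Gx = M.t() * Gy;                   // C x H*W
  cube gx(H, W, C);
  for (int ci = 0; ci < C; ++ci) gx.slice(ci) = reshape(Gx.row(ci), H, W);
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gM") = gM,
                      Rcpp::Named("gb") = gb);
}

// [[Rcpp::export]]
List maxpool2_fwd_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube y(Ho, Wo, C), idx(Ho, Wo, C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = xs(2 * i, 2 * j);
        int bi = 0;
        for (int k = 1; k < 4; ++k) {
          const double v = xs(2 * i + k % 2, 2 * j + k / 2);
          if (v > best) { best = v; bi = k; }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube maxpool2_bwd_cpp(const arma::cube& gy, const arma::cube& idx) {
  const int Ho = gy.n_rows, Wo = gy.n_cols, C = gy.n_slices;
  cube gx(2 * Ho, 2 * Wo, C, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        const int k = (int)idx(i, j, c);
        gx(2 * i + k % 2, 2 * j + k / 2, c) = gy(i, j, c);
      }
  return gx;
}

// Position-attention block.  F is the C x N flattening of the input (column n
// = feature vector at spatial index n, n = i + H*j).  Fp = Wp %*% F is the 1x1
// projection; the affinity A[m, n] = softmax_n(Fp_n . Fp_m); the attended map
// is Fp %*% t(A) (optionally expanded by We when the projection reduced C),
// scaled by delta and added back to the input.

// [[Rcpp::export]]
List attention_fwd_cpp(const arma::cube& x, const arma::mat& Wp,
                       Rcpp::Nullable<Rcpp::NumericMatrix> We_,
                       double delta) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword N = (arma::uword)H * W;
  mat F(C, N);
  for (int c = 0; c < C; ++c) F.row(c) = vectorise(x.slice(c)).t();
  mat Fp = Wp * F;
  mat A = Fp.t() * Fp;                   // energies, then softmax in place
  for (arma::uword m = 0; m < N; ++m) {
    rowvec r = A.row(m);
    r -= r.max();
    r = exp(r);
    A.row(m) = r / accu(r);
  }
  mat att = Fp * A.t();                  // Cp x N; col m = sum_n A(m,n) Fp_n
  mat att2;
  if (We_.isNotNull()) {
    mat We = Rcpp::as<mat>(We_);
    att2 = We * att;
  } else {
    att2 = att;
  }
  cube out = x;
  for (int c = 0; c < C; ++c)
    out.slice(c) += delta * reshape(att2.row(c), H, W);
  return List::create(Rcpp::Named("out") = out, Rcpp::Named("A") = A,
                      Rcpp::Named("Fp") = Fp, Rcpp::Named("att") = att,
                      Rcpp::Named("att2") = att2);
}

// [[Rcpp::export]]
List attention_bwd_cpp(const arma::cube& x, const arma::mat& Wp,
                       Rcpp::Nullable<Rcpp::NumericMatrix> We_, double delta,
                       const arma::mat& Fp, const arma::mat& A,
                       const arma::mat& att, const arma::mat& att2,
                       const arma::cube& gy) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword N = (arma::uword)H * W;
  mat F(C, N), G(C, N);
  for (int c = 0; c < C; ++c) {
    F.row(c) = vectorise(x.slice(c)).t();
    G.row(c) = vectorise(gy.slice(c)).t();
  }
  const double gdelta = accu(G % att2);
  mat Gatt2 = delta * G;
  mat Gatt, gWe;
  bool has_We = We_.isNotNull();
  if (has_We) {
    mat We = Rcpp::as<mat>(We_);
    gWe = Gatt2 * att.t();
    Gatt = We.t() * Gatt2;
  } else {
    Gatt = Gatt2;
  }
  mat GFp = Gatt * A;                    // through att = Fp %*% t(A)
  mat GA = Gatt.t() * Fp;
  // softmax rows backward
  mat GE(N, N);
  for (arma::uword m = 0; m < N; ++m) {
    const rowvec am = A.row(m);
    const rowvec gm = GA.row(m);
    GE.row(m) = am % (gm - dot(gm, am));
  }
  GFp += Fp * (GE + GE.t());             // through E = t(Fp) %*% Fp
  mat gWp = GFp * F.t();
  mat GF = Wp.t() * GFp;
  cube gx = gy;                          // identity (residual) path
  for (int c = 0; c < C; ++c)
    gx.slice(c) += reshape(GF.row(c), H, W);
  List res = List::create(Rcpp::Named("gx") = gx, Rcpp::Named("gWp") = gWp,
                          Rcpp::Named("gdelta") = gdelta);
  if (has_We) res["gWe"] = gWe;
  return res;
}

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher, squared
// distances, separable 1-D parabola envelopes).  `target` is a 0/1 matrix;
// returns the distance in pixels from each cell to the nearest 1-cell.

static void dt1d(const vec& f, vec& d) {
  const int n = f.n_elem;
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -datum::inf;
  z[1] = datum::inf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      const int p = v[k];
      s = ((f(q) + q * q) - (f(p) + p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = datum::inf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    const int p = v[k];
    d(q) = (q - p) * (double)(q - p) + f(p);
  }
}

// [[Rcpp::export]]
arma::mat edt_cpp(const arma::mat& target) {
  const int H = target.n_rows, W = target.n_cols;
  mat d(H, W);
  d.fill(1e15);                          // finite sentinel keeps dt1d NaN-free
  d.elem(find(target > 0.5)).zeros();
  vec col(H), dcol(H);
  for (int j = 0; j < W; ++j) {
    col = d.col(j);
    dt1d(col, dcol);
    d.col(j) = dcol;
  }
  vec row(W), drow(W);
  for (int i = 0; i < H; ++i) {
    row = d.row(i).t();
    dt1d(row, drow);
    d.row(i) = drow.t();
  }
  return sqrt(d);
}

// ---- optimized training-path attention (single precision, cache kept on the
// C++ side via XPtr so the N x N matrices never cross into R) ----------------

struct AttCache {
  fmat F, Fp, At, att, att2;   // At: column m holds attention row m
};

// [[Rcpp::export]]
List attention_fwd_fast_cpp(const arma::cube& x, const arma::mat& Wp,
                            Rcpp::Nullable<Rcpp::NumericMatrix> We_,
                            double delta) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const arma::uword N = (arma::uword)H * W;
  AttCache* cc = new AttCache();
  cc->F.set_size(C, N);
  for (int c = 0; c < C; ++c)
    cc->F.row(c) = conv_to<frowvec>::from(vectorise(x.slice(c)).t());
  fmat Wpf = conv_to<fmat>::from(Wp);
  cc->Fp = Wpf * cc->F;
  cc->At = cc->Fp.t() * cc->Fp;          // symmetric energies
  for (arma::uword m = 0; m < N; ++m) {  // column-wise softmax (E symmetric)
    fvec col = cc->At.col(m);
    col -= col.max();
    col = exp(col);
    cc->At.col(m) = col / accu(col);
  }
  cc->att = cc->Fp * cc->At;
  if (We_.isNotNull()) {
    fmat Wef = conv_to<fmat>::from(Rcpp::as<mat>(We_));
    cc->att2 = Wef * cc->att;
  } else {
    cc->att2 = cc->att;
  }
  cube out = x;
  for (int c = 0; c < C; ++c)
    out.slice(c) += delta * reshape(conv_to<mat>::from(cc->att2.row(c)), H, W);
  Rcpp::XPtr<AttCache> ptr(cc, true);
  return List::create(Rcpp::Named("out") = out, Rcpp::Named("cache") = ptr);
}

// [[Rcpp::export]]
List attention_bwd_fast_cpp(SEXP cache_, const arma::mat& Wp,
                            Rcpp::Nullable<Rcpp::NumericMatrix> We_,
                            double delta, const arma::cube& gy) {
  Rcpp::XPtr<AttCache> cc(cache_);
  const int H = gy.n_rows, W = gy.n_cols, C = gy.n_slices;
  const arma::uword N = (arma::uword)H * W;
  fmat G(C, N);
  for (int c = 0; c < C; ++c)
    G.row(c) = conv_to<frowvec>::from(vectorise(gy.slice(c)).t());
  const double gdelta = accu(conv_to<mat>::from(G % cc->att2));
  fmat Gatt2 = (float)delta * G;
  fmat Gatt, gWe;
  const bool has_We = We_.isNotNull();
  if (has_We) {
    fmat Wef = conv_to<fmat>::from(Rcpp::as<mat>(We_));
    gWe = Gatt2 * cc->att.t();
    Gatt = Wef.t() * Gatt2;
  } else {
    Gatt = Gatt2;
  }
  fmat GFp = Gatt * cc->At.t();
  fmat GAt = cc->Fp.t() * Gatt;          // dL/dA[m, n] at (n, m)
  for (arma::uword m = 0; m < N; ++m) {  // softmax backward, in place
    const fvec am = cc->At.col(m);
    const fvec gm = GAt.col(m);
    GAt.col(m) = am % (gm - dot(gm, am));
  }
  GFp += cc->Fp * GAt.t();               // E symmetric: GE + t(GE)
  GFp += cc->Fp * GAt;
  fmat gWp = GFp * cc->F.t();
  fmat Wpf = conv_to<fmat>::from(Wp);
  fmat GF = Wpf.t() * GFp;
  cube gx = gy;
  for (int c = 0; c < C; ++c)
    gx.slice(c) += reshape(conv_to<mat>::from(GF.row(c)), H, W);
  List res = List::create(
      Rcpp::Named("gx") = gx,
      Rcpp::Named("gWp") = conv_to<mat>::from(gWp),
      Rcpp::Named("gdelta") = gdelta);
  if (has_We) res["gWe"] = conv_to<mat>::from(gWe);
  return res;
}

// ---- in-place helpers (objects are package-internal, never aliased) --------

// [[Rcpp::export]]
void adam_step_cpp(Rcpp::NumericVector p, Rcpp::NumericVector g,
                   Rcpp::NumericVector m, Rcpp::NumericVector v,
                   double lr, double b1, double b2, int t, double eps) {
  const double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  const int n = p.size();
  for (int i = 0; i < n; ++i) {
    m[i] = b1 * m[i] + (1 - b1) * g[i];
    v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    p[i] -= lr * (m[i] / c1) / (std::sqrt(v[i] / c2) + eps);
  }
}

// [[Rcpp::export]]
void fill0_cpp(Rcpp::NumericVector x) { std::fill(x.begin(), x.end(), 0.0); }

// [[Rcpp::export]]
void axpy_cpp(Rcpp::NumericVector dst, Rcpp::NumericVector src) {
  const int n = dst.size();
  for (int i = 0; i < n; ++i) dst[i] += src[i];
}

// ---- instance normalization (per-channel over H x W; batch size is 1) ------

// [[Rcpp::export]]
List instnorm_fwd_cpp(const arma::cube& x, const arma::vec& gamma,
                      const arma::vec& beta, double eps = 1e-5) {
  const int C = x.n_slices;
  cube y(x.n_rows, x.n_cols, C), xhat(x.n_rows, x.n_cols, C);
  vec inv_sd(C);
  for (int c = 0; c < C; ++c) {
    const mat& xs = x.slice(c);
    const double mu = accu(xs) / xs.n_elem;
    const double var = accu(square(xs - mu)) / xs.n_elem;
    inv_sd(c) = 1.0 / std::sqrt(var + eps);
    xhat.slice(c) = (xs - mu) * inv_sd(c);
    y.slice(c) = gamma(c) * xhat.slice(c) + beta(c);
  }
  return List::create(Rcpp::Named("y") = y, Rcpp::Named("xhat") = xhat,
                      Rcpp::Named("inv_sd") = inv_sd);
}

// [[Rcpp::export]]
List instnorm_bwd_cpp(const arma::cube& gy, const arma::cube& xhat,
                      const arma::vec& inv_sd, const arma::vec& gamma) {
  const int C = gy.n_slices;
  cube gx(gy.n_rows, gy.n_cols, C);
  vec ggamma(C), gbeta(C);
  for (int c = 0; c < C; ++c) {
    const mat& g = gy.slice(c);
    const mat& xh = xhat.slice(c);
    const double n = g.n_elem;
    ggamma(c) = accu(g % xh);
    gbeta(c) = accu(g);
    const mat gxh = gamma(c) * g;
    gx.slice(c) = inv_sd(c) *
        (gxh - accu(gxh) / n - xh * (accu(gxh % xh) / n));
  }
  return List::create(Rcpp::Named("gx") = gx, Rcpp::Named("ggamma") = ggamma,
                      Rcpp::Named("gbeta") = gbeta);
}
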