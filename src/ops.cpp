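// Core tensor ops for the CPU runtime: same-padding convolution,
// 2x2-stride-2 transposed convolution, and max-pooling, with backward
// passes. Single-image layout is (h, w, c) column-major, matching an R
// array of dim c(h, w, c); conv weights are R arrays (kh, kw, cin, cout).
//
// Convolutions use a transposed im2col ("colsT": (h*w) x (kh*kw*cin)) so
// that both the patch-gather and the GEMM touch contiguous memory, and a
// direct GEMM fast path for 1x1 kernels.

#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;

static inline arma::cube as_cube(const NumericVector &x) {
  IntegerVector d = x.attr("dim");
  return arma::cube(const_cast<double *>(x.begin()), d[0], d[1], d[2], false);
}

static NumericVector wrap_cube_dims(NumericVector data, int h, int w, int c) {
  data.attr("dim") = IntegerVector::create(h, w, c);
  return data;
}

// colsT: (h*w) x (kh*kw*cin); column (dh + kh*(dk + kw*ci)) holds the
// patch value at offset (dh, dk) of channel ci for every output pixel.
static arma::mat im2colT(const arma::cube &x, int kh, int kw) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  arma::mat colsT((size_t)h * w, (size_t)kh * kw * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci)
    for (int dk = 0; dk < kw; ++dk)
      for (int dh = 0; dh < kh; ++dh) {
        double *dst = colsT.colptr(dh + kh * (dk + kw * ci));
        const int i0 = std::max(0, pt - dh);            // valid output rows
        const int i1 = std::min(h, h + pt - dh);
        if (i1 <= i0) continue;
        for (int j = 0; j < w; ++j) {
          const int sj = j + dk - pl;
          if (sj < 0 || sj >= w) continue;
          const double *src = &x(i0 + dh - pt, sj, ci);
          std::memcpy(dst + (size_t)j * h + i0, src,
                      (size_t)(i1 - i0) * sizeof(double));
        }
      }
  return colsT;
}

// scatter-add transpose of im2colT
static void col2imT(const arma::mat &colsT, arma::cube &gx, int kh, int kw) {
  const int h = gx.n_rows, w = gx.n_cols, cin = gx.n_slices;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  for (int ci = 0; ci < cin; ++ci)
    for (int dk = 0; dk < kw; ++dk)
      for (int dh = 0; dh < kh; ++dh) {
        const double *src = colsT.colptr(dh + kh * (dk + kw * ci));
        const int i0 = std::max(0, pt - dh);
        const int i1 = std::min(h, h + pt - dh);
        if (i1 <= i0) continue;
        for (int j = 0; j < w; ++j) {
          const int sj = j + dk - pl;
          if (sj < 0 || sj >= w) continue;
          double *dst = &gx(i0 + dh - pt, sj, ci);
          const double *s = src + (size_t)j * h + i0;
          for (int i = 0; i < i1 - i0; ++i) dst[i] += s[i];
        }
      }
}

// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x_, NumericVector w_, NumericVector b_) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int h = x.n_rows, w = x.n_cols;
  arma::mat W(const_cast<double *>(w_.begin()), (size_t)kh * kw * cin, cout,
              false);
  NumericVector out((size_t)h * w * cout);
  arma::mat Y(out.begin(), (size_t)h * w, cout, false);
  if (kh == 1 && kw == 1) {
    arma::mat X(x.memptr(), (size_t)h * w, cin, false);
    Y = X * W;
  } else {
    Y = im2colT(x, kh, kw) * W;
  }
  arma::rowvec b(const_cast<double *>(b_.begin()), cout, false);
  Y.each_row() += b;
  return wrap_cube_dims(out, h, w, cout);
}

// [[Rcpp::export]]
List conv2d_bw(NumericVector x_, NumericVector w_, NumericVector gy_) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], cin = wd[2], cout = wd[3];
  const int h = x.n_rows, w = x.n_cols;
  arma::mat W(const_cast<double *>(w_.begin()), (size_t)kh * kw * cin, cout,
              false);
  arma::mat GY(const_cast<double *>(gy_.begin()), (size_t)h * w, cout, false);
  NumericVector gWout((size_t)kh * kw * cin * cout);
  gWout.attr("dim") = wd;
  arma::mat gW(gWout.begin(), (size_t)kh * kw * cin, cout, false);
  NumericVector gxout((size_t)h * w * cin);
  arma::vec gb = arma::sum(GY, 0).t();
  if (kh == 1 && kw == 1) {
    arma::mat X(x.memptr(), (size_t)h * w, cin, false);
    gW = X.t() * GY;
    arma::mat GX(gxout.begin(), (size_t)h * w, cin, false);
    GX = GY * W.t();
  } else {
    arma::mat colsT = im2colT(x, kh, kw);
    gW = colsT.t() * GY;
    arma::mat gcolsT = GY * W.t();
    arma::cube gx(gxout.begin(), h, w, cin, false);
    col2imT(gcolsT, gx, kh, kw);
  }
  return List::create(_["gx"] = wrap_cube_dims(gxout, h, w, cin),
                      _["gw"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// transposed conv, kernel 2x2, stride 2: output (2h, 2w, cout); every
// output cell receives exactly one kernel tap, so each (di, dj) offset is
// one GEMM scattered into the strided output grid.
// [[Rcpp::export]]
NumericVector tconv2d_fw(NumericVector x_, NumericVector w_, NumericVector b_) {
  arma::cube x = as_cube(x_);
  IntegerVector wd = w_.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int h = x.n_rows, w = x.n_cols;
  const double *Wp = w_.begin();
  NumericVector out((size_t)4 * h * w * cout);
  arma::cube y(out.begin(), 2 * h, 2 * w, cout, false);
  arma::mat X(x.memptr(), (size_t)h * w, cin, false);
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = Wp[di + 2 * (dj + 2 * (ci + cin * co))];
      arma::mat Yo = X * Wo;                      // (h*w) x cout
      for (int co = 0; co < cout; ++co) {
        const double *src = Yo.colptr(co);
        for (int j = 0; j < w; ++j) {
          double *dst = &y(di, 2 * j + dj, co);
          const double *s = src + (size_t)j * h;
          for (int i = 0; i < h; ++i) dst[2 * i] = s[i];
        }
      }
    }
  arma::rowvec b(const_cast<double *>(b_.begin()), cout, false);
  arma::mat Ym(out.begin(), (size_t)4 * h * w, cout, false);
  Ym.each_row() += b;
  return wrap_cube_dims(out, 2 * h, 2 * w, cout);
}

// [[Rcpp::export]]
List tconv2d_bw(NumericVector x_, NumericVector w_, NumericVector gy_) {
  arma::cube x = as_cube(x_);
  arma::cube gy = as_cube(gy_);
  IntegerVector wd = w_.attr("dim");
  const int cin = wd[2], cout = wd[3];
  const int h = x.n_rows, w = x.n_cols;
  const double *Wp = w_.begin();
  arma::mat X(x.memptr(), (size_t)h * w, cin, false);
  NumericVector gWout(w_.size());
  gWout.attr("dim") = wd;
  NumericVector gxout((size_t)h * w * cin);
  arma::mat GX(gxout.begin(), (size_t)h * w, cin, false);
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) {
    double s = 0.0;
    const double *g = gy.slice_memptr(co);
    for (size_t k = 0; k < (size_t)4 * h * w; ++k) s += g[k];
    gb[co] = s;
  }
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      // gather strided gy into dense (h*w) x cout
      arma::mat G((size_t)h * w, cout);
      for (int co = 0; co < cout; ++co) {
        double *dst = G.colptr(co);
        for (int j = 0; j < w; ++j) {
          const double *src = &gy(di, 2 * j + dj, co);
          for (int i = 0; i < h; ++i) dst[(size_t)j * h + i] = src[2 * i];
        }
      }
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = Wp[di + 2 * (dj + 2 * (ci + cin * co))];
      GX += G * Wo.t();
      arma::mat gWo = X.t() * G;                  // cin x cout
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gWout[di + 2 * (dj + 2 * (ci + cin * co))] += gWo(ci, co);
    }
  return List::create(_["gx"] = wrap_cube_dims(gxout, h, w, cin),
                      _["gw"] = gWout, _["gb"] = gb);
}

// max pool; stride 2 halves dims (kernel 2), stride 1 keeps dims with same
// padding. Returns pooled values and 1-based argmax linear indices into x.
// [[Rcpp::export]]
List maxpool_fw(NumericVector x_, int kernel, int stride) {
  arma::cube x = as_cube(x_);
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  int oh, ow, pt = 0, pl = 0;
  if (stride == 2) { oh = h / 2; ow = w / 2; }
  else { oh = h; ow = w; pt = (kernel - 1) / 2; pl = (kernel - 1) / 2; }
  NumericVector yout((size_t)oh * ow * c);
  IntegerVector arg((size_t)oh * ow * c);
  size_t pos = 0;
  for (int ci = 0; ci < c; ++ci)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -INFINITY; int bi = 0, bj = 0;
        for (int dj = 0; dj < kernel; ++dj) {
          const int sj = j * stride + dj - pl;
          if (sj < 0 || sj >= w) continue;
          for (int di = 0; di < kernel; ++di) {
            const int si = i * stride + di - pt;
            if (si < 0 || si >= h) continue;
            const double v = x(si, sj, ci);
            if (v > best) { best = v; bi = si; bj = sj; }
          }
        }
        yout[pos] = best;
        arg[pos++] = 1 + bi + h * (bj + w * ci);
      }
  yout.attr("dim") = IntegerVector::create(oh, ow, c);
  arg.attr("dim") = IntegerVector::create(oh, ow, c);
  return List::create(_["y"] = yout, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw(IntegerVector argmax, NumericVector gy_,
                         IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2]);
  gx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < gy_.size(); ++k)
    gx[argmax[k] - 1] += gy_[k];
  return gx;
}

// batch norm statistics helper: per-channel mean and raw second moment of
// a 4-D (h, w, c, n) array without materialising a permuted copy.
// [[Rcpp::export]]
List bn_moments(NumericVector x_, int c) {
  IntegerVector d = x_.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int n = d[3];
  NumericVector mu(c), m2(c);
  const double *x = x_.begin();
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci) {
      const double *p = x + hw * ((size_t)ci + (size_t)c * s);
      double a = 0, b = 0;
      for (size_t k = 0; k < hw; ++k) { a += p[k]; b += p[k] * p[k]; }
      mu[ci] += a; m2[ci] += b;
    }
  const double denom = (double)hw * n;
  for (int ci = 0; ci < c; ++ci) { mu[ci] /= denom; m2[ci] /= denom; }
  return List::create(_["mean"] = mu, _["m2"] = m2);
}

// y = gamma * (x - mu) / sqrt(var + eps) + beta, channelwise over (h,w,c,n)
// [[Rcpp::export]]
NumericVector bn_apply(NumericVector x_, NumericVector mu, NumericVector va,
                       NumericVector gamma, NumericVector beta, double eps) {
  IntegerVector d = x_.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int c = d[2], n = d[3];
  NumericVector out(x_.size());
  out.attr("dim") = d;
  const double *x = x_.begin();
  double *y = out.begin();
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci) {
      const double sc = gamma[ci] / std::sqrt(va[ci] + eps);
      const double sh = beta[ci] - mu[ci] * sc;
      const size_t off = hw * ((size_t)ci + (size_t)c * s);
      for (size_t k = 0; k < hw; ++k) y[off + k] = x[off + k] * sc + sh;
    }
  return out;
}

// full batch-norm backward over (h, w, c, n): returns gx, ggamma, gbeta.
// training = true uses the batch-statistics Jacobian; false treats mu/va
// as constants (inference-mode gradient).
// [[Rcpp::export]]
List bn_backward(NumericVector x_, NumericVector g_, NumericVector mu,
                 NumericVector va, NumericVector gamma, double eps,
                 bool training) {
  IntegerVector d = x_.attr("dim");
  const size_t hw = (size_t)d[0] * d[1];
  const int c = d[2], n = d[3];
  const double m = (double)hw * n;
  NumericVector gxout(x_.size());
  gxout.attr("dim") = d;
  NumericVector ggamma(c), gbeta(c);
  const double *x = x_.begin(), *g = g_.begin();
  double *gx = gxout.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double inv = 1.0 / std::sqrt(va[ci] + eps);
    double sg = 0, sgx = 0;
    for (int s = 0; s < n; ++s) {
      const size_t off = hw * ((size_t)ci + (size_t)c * s);
      for (size_t k = 0; k < hw; ++k) {
        const double xhat = (x[off + k] - mu[ci]) * inv;
        sg += g[off + k];
        sgx += g[off + k] * xhat;
      }
    }
    ggamma[ci] = sgx;
    gbeta[ci] = sg;
    const double gscale = gamma[ci] * inv;
    if (training) {
      const double mg = sg / m, mgx = sgx / m;
      for (int s = 0; s < n; ++s) {
        const size_t off = hw * ((size_t)ci + (size_t)c * s);
        for (size_t k = 0; k < hw; ++k) {
          const double xhat = (x[off + k] - mu[ci]) * inv;
          gx[off + k] = gscale * (g[off + k] - mg - xhat * mgx);
        }
      }
    } else {
      for (int s = 0; s < n; ++s) {
        const size_t off = hw * ((size_t)ci + (size_t)c * s);
        for (size_t k = 0; k < hw; ++k) gx[off + k] = gscale * g[off + k];
      }
    }
  }
  return List::create(_["gx"] = gxout, _["ggamma"] = ggamma,
                      _["gbeta"] = gbeta);
}


// gather 4-D (h,w,c,n) into (n*h*w) x c, sample-major row blocks
static arma::mat gather_channels(const NumericVector &x, int h, int w, int c,
                                 int n) {
  const size_t hw = (size_t)h * w;
  arma::mat X(hw * n, c);
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci)
      std::memcpy(X.colptr(ci) + hw * s,
                  x.begin() + hw * ((size_t)ci + (size_t)c * s),
                  hw * sizeof(double));
  return X;
}

static void scatter_channels(const arma::mat &Y, double *out, int h, int w,
                             int c, int n) {
  const size_t hw = (size_t)h * w;
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < c; ++ci)
      std::memcpy(out + hw * ((size_t)ci + (size_t)c * s),
                  Y.colptr(ci) + hw * s, hw * sizeof(double));
}

// acc[i, j] += src[i + di, j + dj] within each sample block, zero outside
static void shift_add(arma::mat &acc, const arma::mat &src, int h, int w,
                      int n, int di, int dj) {
  const size_t hw = (size_t)h * w;
  const int i0 = std::max(0, -di), i1 = std::min(h, h - di);
  const int j0 = std::max(0, -dj), j1 = std::min(w, w - dj);
  if (i1 <= i0 || j1 <= j0) return;
  for (arma::uword col = 0; col < acc.n_cols; ++col) {
    double *a = acc.colptr(col);
    const double *sp = src.colptr(col);
    for (int s = 0; s < n; ++s) {
      const size_t off = hw * s;
      for (int j = j0; j < j1; ++j) {
        double *ap = a + off + (size_t)j * h + i0;
        const double *spp = sp + off + (size_t)(j + dj) * h + (i0 + di);
        for (int i = 0; i < i1 - i0; ++i) ap[i] += spp[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector relu_fw(NumericVector x_) {
  NumericVector out(x_.size());
  out.attr("dim") = x_.attr("dim");
  const double *x = x_.begin();
  double *y = out.begin();
  for (R_xlen_t k = 0; k < x_.size(); ++k) y[k] = x[k] > 0 ? x[k] : 0;
  return out;
}

// ---- batched variants over (h, w, c, n) arrays ---------------------------
// One GEMM per op across the whole mini-batch; sample s occupies row block
// [s*h*w, (s+1)*h*w) of the stacked pixel dimension.

static arma::cube sample_cube(const NumericVector &x, int s) {
  IntegerVector d = x.attr("dim");
  const size_t per = (size_t)d[0] * d[1] * d[2];
  return arma::cube(const_cast<double *>(x.begin()) + per * s,
                    d[0], d[1], d[2], false);
}

// [[Rcpp::export]]
NumericVector conv2d_fw_b(NumericVector x_, NumericVector w_,
                          NumericVector b_) {
  IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  arma::mat W(const_cast<double *>(w_.begin()), (size_t)kh * kw * cin, cout,
              false);
  const size_t hw = (size_t)h * w;
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  arma::mat X = gather_channels(x_, h, w, cin, n);   // (n*h*w) x cin
  NumericVector out(hw * n * cout);
  out.attr("dim") = IntegerVector::create(h, w, cout, n);
  if (kh == 1 && kw == 1) {
    arma::mat Y = X * W;
    Y.each_row() += arma::rowvec(const_cast<double *>(b_.begin()), cout,
                                 false);
    scatter_channels(Y, out.begin(), h, w, cout, n);
    return out;
  }
  // one GEMM per kernel tap, shifted-added into the output
  arma::mat Yacc(hw * n, cout);
  for (int co = 0; co < cout; ++co) Yacc.col(co).fill(b_[co]);
  arma::mat Wtap(cin, cout);
  for (int dk = 0; dk < kw; ++dk)
    for (int dh = 0; dh < kh; ++dh) {
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wtap(ci, co) = W(dh + kh * (dk + kw * ci), co);
      arma::mat Yt = X * Wtap;                        // value at source pixel
      // y[i, j] += Yt[i + dh - pt, j + dk - pl]
      shift_add(Yacc, Yt, h, w, n, dh - pt, dk - pl);
    }
  scatter_channels(Yacc, out.begin(), h, w, cout, n);
  return out;
}

// [[Rcpp::export]]
List conv2d_bw_b(NumericVector x_, NumericVector w_, NumericVector gy_) {
  IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  IntegerVector wd = w_.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  const size_t hw = (size_t)h * w;
  arma::mat W(const_cast<double *>(w_.begin()), (size_t)kh * kw * cin, cout,
              false);
  arma::mat GY(hw * n, cout);
  for (int s = 0; s < n; ++s)
    for (int co = 0; co < cout; ++co)
      std::memcpy(GY.colptr(co) + hw * s,
                  gy_.begin() + hw * ((size_t)co + (size_t)cout * s),
                  hw * sizeof(double));
  NumericVector gWout(w_.size());
  gWout.attr("dim") = wd;
  arma::mat gW(gWout.begin(), (size_t)kh * kw * cin, cout, false);
  arma::vec gb = arma::sum(GY, 0).t();
  NumericVector gxout(hw * n * cin);
  gxout.attr("dim") = d;
  arma::mat X = gather_channels(x_, h, w, cin, n);
  if (kh == 1 && kw == 1) {
    gW = X.t() * GY;
    arma::mat GX = GY * W.t();
    scatter_channels(GX, gxout.begin(), h, w, cin, n);
    return List::create(_["gx"] = gxout, _["gw"] = gWout,
                        _["gb"] = NumericVector(gb.begin(), gb.end()));
  }
  const int pt = (kh - 1) / 2, pl = (kw - 1) / 2;
  arma::mat GXacc(hw * n, cin, arma::fill::zeros);
  arma::mat Gshift(hw * n, cout);
  arma::mat Wtap(cin, cout);
  for (int dk = 0; dk < kw; ++dk)
    for (int dh = 0; dh < kh; ++dh) {
      // Gshift[p] = gy[p + offset]  (adjoint of the forward shift)
      Gshift.zeros();
      shift_add(Gshift, GY, h, w, n, -(dh - pt), -(dk - pl));
      arma::mat gWtap = X.t() * Gshift;               // cin x cout
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gW(dh + kh * (dk + kw * ci), co) = gWtap(ci, co);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wtap(ci, co) = W(dh + kh * (dk + kw * ci), co);
      GXacc += Gshift * Wtap.t();
    }
  scatter_channels(GXacc, gxout.begin(), h, w, cin, n);
  return List::create(_["gx"] = gxout, _["gw"] = gWout,
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// [[Rcpp::export]]
NumericVector tconv2d_fw_b(NumericVector x_, NumericVector w_,
                           NumericVector b_) {
  IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  IntegerVector wd = w_.attr("dim");
  const int cout = wd[3];
  const size_t hw = (size_t)h * w;
  const double *Wp = w_.begin();
  arma::mat X(hw * n, cin);
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < cin; ++ci)
      std::memcpy(X.colptr(ci) + hw * s,
                  x_.begin() + hw * ((size_t)ci + (size_t)cin * s),
                  hw * sizeof(double));
  NumericVector out((size_t)4 * hw * n * cout);
  out.attr("dim") = IntegerVector::create(2 * h, 2 * w, cout, n);
  double *y = out.begin();
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = Wp[di + 2 * (dj + 2 * (ci + cin * co))];
      arma::mat Yo = X * Wo;
      for (int s = 0; s < n; ++s)
        for (int co = 0; co < cout; ++co) {
          const double *src = Yo.colptr(co) + hw * s;
          double *base = y + (size_t)4 * hw * ((size_t)co + (size_t)cout * s);
          for (int j = 0; j < w; ++j) {
            double *dst = base + (size_t)(2 * j + dj) * 2 * h + di;
            const double *sv = src + (size_t)j * h;
            for (int i = 0; i < h; ++i) dst[2 * i] = sv[i];
          }
        }
    }
  for (int s = 0; s < n; ++s)
    for (int co = 0; co < cout; ++co) {
      double *base = y + (size_t)4 * hw * ((size_t)co + (size_t)cout * s);
      const double bv = b_[co];
      for (size_t k = 0; k < 4 * hw; ++k) base[k] += bv;
    }
  return out;
}

// [[Rcpp::export]]
List tconv2d_bw_b(NumericVector x_, NumericVector w_, NumericVector gy_) {
  IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], cin = d[2], n = d[3];
  IntegerVector wd = w_.attr("dim");
  const int cout = wd[3];
  const size_t hw = (size_t)h * w;
  const double *Wp = w_.begin();
  arma::mat X(hw * n, cin);
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < cin; ++ci)
      std::memcpy(X.colptr(ci) + hw * s,
                  x_.begin() + hw * ((size_t)ci + (size_t)cin * s),
                  hw * sizeof(double));
  NumericVector gWout(w_.size());
  gWout.attr("dim") = wd;
  NumericVector gxout(hw * n * cin);
  gxout.attr("dim") = d;
  arma::mat GXacc(hw * n, cin, arma::fill::zeros);
  NumericVector gb(cout);
  const double *gyp = gy_.begin();
  for (int s = 0; s < n; ++s)
    for (int co = 0; co < cout; ++co) {
      const double *g = gyp + (size_t)4 * hw * ((size_t)co + (size_t)cout * s);
      double acc = 0;
      for (size_t k = 0; k < 4 * hw; ++k) acc += g[k];
      gb[co] += acc;
    }
  for (int dj = 0; dj < 2; ++dj)
    for (int di = 0; di < 2; ++di) {
      arma::mat G(hw * n, cout);
      for (int s = 0; s < n; ++s)
        for (int co = 0; co < cout; ++co) {
          double *dst = G.colptr(co) + hw * s;
          const double *base =
              gyp + (size_t)4 * hw * ((size_t)co + (size_t)cout * s);
          for (int j = 0; j < w; ++j) {
            const double *sv = base + (size_t)(2 * j + dj) * 2 * h + di;
            for (int i = 0; i < h; ++i) dst[(size_t)j * h + i] = sv[2 * i];
          }
        }
      arma::mat Wo(cin, cout);
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          Wo(ci, co) = Wp[di + 2 * (dj + 2 * (ci + cin * co))];
      GXacc += G * Wo.t();
      arma::mat gWo = X.t() * G;
      for (int co = 0; co < cout; ++co)
        for (int ci = 0; ci < cin; ++ci)
          gWout[di + 2 * (dj + 2 * (ci + cin * co))] += gWo(ci, co);
    }
  for (int s = 0; s < n; ++s)
    for (int ci = 0; ci < cin; ++ci)
      std::memcpy(gxout.begin() + hw * ((size_t)ci + (size_t)cin * s),
                  GXacc.colptr(ci) + hw * s, hw * sizeof(double));
  return List::create(_["gx"] = gxout, _["gw"] = gWout, _["gb"] = gb);
}

// [[Rcpp::export]]
List maxpool_fw_b(NumericVector x_, int kernel, int stride) {
  IntegerVector d = x_.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  int oh, ow, pt = 0, pl = 0;
  if (stride == 2) { oh = h / 2; ow = w / 2; }
  else { oh = h; ow = w; pt = (kernel - 1) / 2; pl = (kernel - 1) / 2; }
  NumericVector yout((size_t)oh * ow * c * n);
  IntegerVector arg((size_t)oh * ow * c * n);
  yout.attr("dim") = IntegerVector::create(oh, ow, c, n);
  arg.attr("dim") = IntegerVector::create(oh, ow, c, n);
  size_t pos = 0;
  for (int s = 0; s < n; ++s) {
    arma::cube xs = sample_cube(x_, s);
    const size_t soff = (size_t)h * w * c * s;
    for (int ci = 0; ci < c; ++ci)
      for (int j = 0; j < ow; ++j)
        for (int i = 0; i < oh; ++i) {
          double best = -INFINITY; int bi = 0, bj = 0;
          for (int dj = 0; dj < kernel; ++dj) {
            const int sj = j * stride + dj - pl;
            if (sj < 0 || sj >= w) continue;
            for (int di = 0; di < kernel; ++di) {
              const int si = i * stride + di - pt;
              if (si < 0 || si >= h) continue;
              const double v = xs(si, sj, ci);
              if (v > best) { best = v; bi = si; bj = sj; }
            }
          }
          yout[pos] = best;
          arg[pos++] = 1 + (int)(soff + bi + (size_t)h * (bj + (size_t)w * ci));
        }
  }
  return List::create(_["y"] = yout, _["argmax"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool_bw_b(IntegerVector argmax, NumericVector gy_,
                           IntegerVector xdim) {
  NumericVector gx((size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  gx.attr("dim") = xdim;
  for (R_xlen_t k = 0; k < gy_.size(); ++k)
    gx[argmax[k] - 1] += gy_[k];
  return gx;
}
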