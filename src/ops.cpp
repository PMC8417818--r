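// Low-level numerical kernels for displacement estimation networks.
// Feature maps are H x W x C arma::cubes (axial, lateral, channel), matching
// R arrays of dim c(H, W, C). All indices 0-based here; R wrappers keep the
// package's 0-based sample-coordinate convention for displacements.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// im2col for stride-1 same-padding convolution: rows indexed by
// r = di + kh*(dj + kw*ci), columns by output pixel j*H + i.
static arma::mat im2col(const arma::cube& x, int kh, int kw) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int ph = kh / 2, pw = kw / 2;
  arma::mat K(kh * kw * C, H * W, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const arma::mat& sl = x.slice(ci);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * ci);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - ph;
            if (ii < 0 || ii >= H) continue;
            K(r, j * H + i) = sl(ii, jj);
          }
        }
      }
    }
  }
  return K;
}

static arma::mat weights_to_mat(const NumericVector& w, int kh, int kw,
                                int cin, int cout) {
  arma::mat Wm(cout, kh * kw * cin);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          Wm(co, di + kh * (dj + kw * ci)) =
            w[di + kh * (dj + kw * (ci + cin * co))];
  return Wm;
}

// [[Rcpp::export]]
arma::cube en_conv2d(const arma::cube& x, const NumericVector& w,
                     const NumericVector& b) {
  IntegerVector dims = w.attr("dim");
  const int kh = dims[0], kw = dims[1], cin = dims[2], cout = dims[3];
  if ((int)x.n_slices != cin) stop("conv2d: channel mismatch");
  const int H = x.n_rows, W = x.n_cols;
  arma::mat K = im2col(x, kh, kw);
  arma::mat Wm = weights_to_mat(w, kh, kw, cin, cout);
  arma::mat Y = Wm * K;  // cout x HW
  arma::cube out(H, W, cout);
  for (int co = 0; co < cout; ++co) {
    arma::mat sl(Y.row(co).t());
    sl.reshape(H, W);
    out.slice(co) = sl + b[co];
  }
  return out;
}

// [[Rcpp::export]]
List en_conv2d_bwd(const arma::cube& x, const NumericVector& w,
                   const arma::cube& gy) {
  IntegerVector dims = w.attr("dim");
  const int kh = dims[0], kw = dims[1], cin = dims[2], cout = dims[3];
  const int H = x.n_rows, W = x.n_cols;
  const int ph = kh / 2, pw = kw / 2;
  arma::mat K = im2col(x, kh, kw);
  arma::mat Gy(cout, H * W);
  for (int co = 0; co < cout; ++co)
    Gy.row(co) = arma::vectorise(gy.slice(co)).t();
  arma::mat Gw = Gy * K.t();                       // cout x (kh kw cin)
  arma::mat Wm = weights_to_mat(w, kh, kw, cin, cout);
  arma::mat Gcol = Wm.t() * Gy;                    // (kh kw cin) x HW
  // col2im scatter
  arma::cube gx(H, W, cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    arma::mat& sl = gx.slice(ci);
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di) {
        const int r = di + kh * (dj + kw * ci);
        for (int j = 0; j < W; ++j) {
          const int jj = j + dj - pw;
          if (jj < 0 || jj >= W) continue;
          for (int i = 0; i < H; ++i) {
            const int ii = i + di - ph;
            if (ii < 0 || ii >= H) continue;
            sl(ii, jj) += Gcol(r, j * H + i);
          }
        }
      }
    }
  }
  NumericVector gw(kh * kw * cin * cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      for (int dj = 0; dj < kw; ++dj)
        for (int di = 0; di < kh; ++di)
          gw[di + kh * (dj + kw * (ci + cin * co))] =
            Gw(co, di + kh * (dj + kw * ci));
  gw.attr("dim") = dims;
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(gy.slice(co));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// Transpose convolution, kernel 2x2, stride 2 (non-overlapping): each output
// pixel receives contribution from exactly one input pixel.
// [[Rcpp::export]]
arma::cube en_tconv2(const arma::cube& x, const NumericVector& w,
                     const NumericVector& b) {
  IntegerVector dims = w.attr("dim");
  const int cin = dims[2], cout = dims[3];
  if ((int)x.n_slices != cin) stop("tconv2: channel mismatch");
  const int h = x.n_rows, wd = x.n_cols;
  arma::cube out(2 * h, 2 * wd, cout);
  for (int co = 0; co < cout; ++co) out.slice(co).fill(b[co]);
  for (int co = 0; co < cout; ++co) {
    arma::mat& os = out.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      const double w00 = w[0 + 2 * (0 + 2 * (ci + cin * co))];
      const double w10 = w[1 + 2 * (0 + 2 * (ci + cin * co))];
      const double w01 = w[0 + 2 * (1 + 2 * (ci + cin * co))];
      const double w11 = w[1 + 2 * (1 + 2 * (ci + cin * co))];
      for (int j = 0; j < wd; ++j)
        for (int i = 0; i < h; ++i) {
          const double v = xs(i, j);
          os(2 * i, 2 * j) += v * w00;
          os(2 * i + 1, 2 * j) += v * w10;
          os(2 * i, 2 * j + 1) += v * w01;
          os(2 * i + 1, 2 * j + 1) += v * w11;
        }
    }
  }
  return out;
}

// [[Rcpp::export]]
List en_tconv2_bwd(const arma::cube& x, const NumericVector& w,
                   const arma::cube& gy) {
  IntegerVector dims = w.attr("dim");
  const int cin = dims[2], cout = dims[3];
  const int h = x.n_rows, wd = x.n_cols;
  arma::cube gx(h, wd, cin, arma::fill::zeros);
  NumericVector gw(4 * cin * cout);
  for (int co = 0; co < cout; ++co) {
    const arma::mat& gs = gy.slice(co);
    for (int ci = 0; ci < cin; ++ci) {
      const arma::mat& xs = x.slice(ci);
      arma::mat& gxs = gx.slice(ci);
      const double w00 = w[0 + 2 * (0 + 2 * (ci + cin * co))];
      const double w10 = w[1 + 2 * (0 + 2 * (ci + cin * co))];
      const double w01 = w[0 + 2 * (1 + 2 * (ci + cin * co))];
      const double w11 = w[1 + 2 * (1 + 2 * (ci + cin * co))];
      double g00 = 0, g10 = 0, g01 = 0, g11 = 0;
      for (int j = 0; j < wd; ++j)
        for (int i = 0; i < h; ++i) {
          const double a = gs(2 * i, 2 * j), bq = gs(2 * i + 1, 2 * j);
          const double c = gs(2 * i, 2 * j + 1), d = gs(2 * i + 1, 2 * j + 1);
          gxs(i, j) += a * w00 + bq * w10 + c * w01 + d * w11;
          const double v = xs(i, j);
          g00 += v * a; g10 += v * bq; g01 += v * c; g11 += v * d;
        }
      gw[0 + 2 * (0 + 2 * (ci + cin * co))] = g00;
      gw[1 + 2 * (0 + 2 * (ci + cin * co))] = g10;
      gw[0 + 2 * (1 + 2 * (ci + cin * co))] = g01;
      gw[1 + 2 * (1 + 2 * (ci + cin * co))] = g11;
    }
  }
  gw.attr("dim") = dims;
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(gy.slice(co));
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List en_maxpool2(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  const int h2 = h / 2, w2 = w / 2;
  arma::cube out(h2, w2, C);
  arma::ucube idx(h2, w2, C);
  for (int c = 0; c < C; ++c) {
    const arma::mat& xs = x.slice(c);
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h2; ++i) {
        int bi = 2 * i, bj = 2 * j;
        double best = xs(bi, bj); int ai = bi, aj = bj;
        if (xs(bi + 1, bj) > best) { best = xs(bi + 1, bj); ai = bi + 1; aj = bj; }
        if (xs(bi, bj + 1) > best) { best = xs(bi, bj + 1); ai = bi; aj = bj + 1; }
        if (xs(bi + 1, bj + 1) > best) { best = xs(bi + 1, bj + 1); ai = bi + 1; aj = bj + 1; }
        out(i, j, c) = best;
        idx(i, j, c) = (arma::uword)(ai + h * aj);
      }
  }
  return List::create(_["y"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube en_maxpool2_bwd(const arma::ucube& idx, const arma::cube& gy,
                           int h, int w) {
  const int C = gy.n_slices, h2 = gy.n_rows, w2 = gy.n_cols;
  arma::cube gx(h, w, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    arma::mat& gs = gx.slice(c);
    for (int j = 0; j < w2; ++j)
      for (int i = 0; i < h2; ++i) {
        arma::uword k = idx(i, j, c);
        gs((int)(k % h), (int)(k / h)) += gy(i, j, c);
      }
  }
  return gx;
}

// Bilinear resize with align-corners geometry. Forward and exact adjoint.
// [[Rcpp::export]]
arma::cube en_resize_bilinear(const arma::cube& x, int H2, int W2) {
  const int h = x.n_rows, w = x.n_cols, C = x.n_slices;
  arma::cube out(H2, W2, C);
  const double sy = (H2 > 1 && h > 1) ? (double)(h - 1) / (H2 - 1) : 0.0;
  const double sx = (W2 > 1 && w > 1) ? (double)(w - 1) / (W2 - 1) : 0.0;
  for (int j = 0; j < W2; ++j) {
    const double xs = j * sx;
    const int j0 = std::min((int)std::floor(xs), w - 1);
    const int j1 = std::min(j0 + 1, w - 1);
    const double fx = xs - j0;
    for (int i = 0; i < H2; ++i) {
      const double ys = i * sy;
      const int i0 = std::min((int)std::floor(ys), h - 1);
      const int i1 = std::min(i0 + 1, h - 1);
      const double fy = ys - i0;
      for (int c = 0; c < C; ++c) {
        out(i, j, c) =
          (1 - fy) * (1 - fx) * x(i0, j0, c) + fy * (1 - fx) * x(i1, j0, c) +
          (1 - fy) * fx * x(i0, j1, c) + fy * fx * x(i1, j1, c);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
arma::cube en_resize_bilinear_adj(const arma::cube& gy, int h, int w) {
  const int H2 = gy.n_rows, W2 = gy.n_cols, C = gy.n_slices;
  arma::cube gx(h, w, C, arma::fill::zeros);
  const double sy = (H2 > 1 && h > 1) ? (double)(h - 1) / (H2 - 1) : 0.0;
  const double sx = (W2 > 1 && w > 1) ? (double)(w - 1) / (W2 - 1) : 0.0;
  for (int j = 0; j < W2; ++j) {
    const double xs = j * sx;
    const int j0 = std::min((int)std::floor(xs), w - 1);
    const int j1 = std::min(j0 + 1, w - 1);
    const double fx = xs - j0;
    for (int i = 0; i < H2; ++i) {
      const double ys = i * sy;
      const int i0 = std::min((int)std::floor(ys), h - 1);
      const int i1 = std::min(i0 + 1, h - 1);
      const double fy = ys - i0;
      for (int c = 0; c < C; ++c) {
        const double g = gy(i, j, c);
        gx(i0, j0, c) += (1 - fy) * (1 - fx) * g;
        gx(i1, j0, c) += fy * (1 - fx) * g;
        gx(i0, j1, c) += (1 - fy) * fx * g;
        gx(i1, j1, c) += fy * fx * g;
      }
    }
  }
  return gx;
}

// Backward-mapping bilinear warp: out(i,j,c) = img(i + dy(i,j), j + dx(i,j), c)
// with clamp-to-edge; mask = 1 where the sample lies fully inside the grid.
// [[Rcpp::export]]
List en_warp(const arma::cube& img, const arma::mat& dy, const arma::mat& dx) {
  const int h = img.n_rows, w = img.n_cols, C = img.n_slices;
  arma::cube out(h, w, C);
  arma::mat mask(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double ys = i + dy(i, j), xs = j + dx(i, j);
      const bool inside = ys >= 0 && ys <= h - 1 && xs >= 0 && xs <= w - 1;
      mask(i, j) = inside ? 1.0 : 0.0;
      ys = clampd(ys, 0, h - 1); xs = clampd(xs, 0, w - 1);
      const int i0 = std::min((int)std::floor(ys), h - 2 >= 0 ? h - 2 : 0);
      const int j0 = std::min((int)std::floor(xs), w - 2 >= 0 ? w - 2 : 0);
      const int i1 = std::min(i0 + 1, h - 1), j1 = std::min(j0 + 1, w - 1);
      const double fy = ys - i0, fx = xs - j0;
      for (int c = 0; c < C; ++c)
        out(i, j, c) =
          (1 - fy) * (1 - fx) * img(i0, j0, c) + fy * (1 - fx) * img(i1, j0, c) +
          (1 - fy) * fx * img(i0, j1, c) + fy * fx * img(i1, j1, c);
    }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// [[Rcpp::export]]
List en_warp_bwd(const arma::cube& img, const arma::mat& dy, const arma::mat& dx,
                 const arma::cube& gout) {
  const int h = img.n_rows, w = img.n_cols, C = img.n_slices;
  arma::cube gimg(h, w, C, arma::fill::zeros);
  arma::mat gdy(h, w, arma::fill::zeros), gdx(h, w, arma::fill::zeros);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double ys = i + dy(i, j), xs = j + dx(i, j);
      const bool cy = ys < 0 || ys > h - 1;   // clamped => zero derivative
      const bool cx = xs < 0 || xs > w - 1;
      ys = clampd(ys, 0, h - 1); xs = clampd(xs, 0, w - 1);
      const int i0 = std::min((int)std::floor(ys), h - 2 >= 0 ? h - 2 : 0);
      const int j0 = std::min((int)std::floor(xs), w - 2 >= 0 ? w - 2 : 0);
      const int i1 = std::min(i0 + 1, h - 1), j1 = std::min(j0 + 1, w - 1);
      const double fy = ys - i0, fx = xs - j0;
      double gy_acc = 0, gx_acc = 0;
      for (int c = 0; c < C; ++c) {
        const double g = gout(i, j, c);
        gimg(i0, j0, c) += (1 - fy) * (1 - fx) * g;
        gimg(i1, j0, c) += fy * (1 - fx) * g;
        gimg(i0, j1, c) += (1 - fy) * fx * g;
        gimg(i1, j1, c) += fy * fx * g;
        // d out / d ys and d out / d xs of the bilinear form
        gy_acc += g * ((1 - fx) * (img(i1, j0, c) - img(i0, j0, c)) +
                       fx * (img(i1, j1, c) - img(i0, j1, c)));
        gx_acc += g * ((1 - fy) * (img(i0, j1, c) - img(i0, j0, c)) +
                       fy * (img(i1, j1, c) - img(i1, j0, c)));
      }
      if (!cy) gdy(i, j) = gy_acc;
      if (!cx) gdx(i, j) = gx_acc;
    }
  return List::create(_["gimg"] = gimg, _["gdy"] = gdy, _["gdx"] = gdx);
}

// Centered box (sum) filter with zero padding outside the grid; window h x w odd.
// [[Rcpp::export]]
arma::mat en_boxfilter(const arma::mat& x, int wh, int ww) {
  const int h = x.n_rows, w = x.n_cols;
  const int rh = wh / 2, rw = ww / 2;
  arma::mat tmp(h, w), out(h, w);
  // axial running sum
  for (int j = 0; j < w; ++j) {
    double s = 0;
    for (int i = 0; i <= std::min(rh, h - 1); ++i) s += x(i, j);
    for (int i = 0; i < h; ++i) {
      tmp(i, j) = s;
      const int add = i + rh + 1, rem = i - rh;
      if (add < h) s += x(add, j);
      if (rem >= 0) s -= x(rem, j);
    }
  }
  // lateral running sum
  for (int i = 0; i < h; ++i) {
    double s = 0;
    for (int j = 0; j <= std::min(rw, w - 1); ++j) s += tmp(i, j);
    for (int j = 0; j < w; ++j) {
      out(i, j) = s;
      const int add = j + rw + 1, rem = j - rw;
      if (add < w) s += tmp(i, add);
      if (rem >= 0) s -= tmp(i, rem);
    }
  }
  return out;
}

// Bilinear scatter ("splat") of point amplitudes onto a grid; positions are
// 0-based sample coordinates.
// [[Rcpp::export]]
arma::mat en_splat(const arma::vec& py, const arma::vec& px,
                   const arma::vec& amp, int h, int w) {
  arma::mat out(h, w, arma::fill::zeros);
  const int n = py.n_elem;
  for (int k = 0; k < n; ++k) {
    const double ys = py[k], xs = px[k];
    if (ys < 0 || ys > h - 1 || xs < 0 || xs > w - 1) continue;
    const int i0 = std::min((int)std::floor(ys), h - 2 >= 0 ? h - 2 : 0);
    const int j0 = std::min((int)std::floor(xs), w - 2 >= 0 ? w - 2 : 0);
    const int i1 = std::min(i0 + 1, h - 1), j1 = std::min(j0 + 1, w - 1);
    const double fy = ys - i0, fx = xs - j0, a = amp[k];
    out(i0, j0) += a * (1 - fy) * (1 - fx);
    out(i1, j0) += a * fy * (1 - fx);
    out(i0, j1) += a * (1 - fy) * fx;
    out(i1, j1) += a * fy * fx;
  }
  return out;
}
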