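// Convolution kernels for the detector's forward/backward passes.
//
// Feature maps are stored as dense arrays with dim (h, w, c, b), column-major
// (R convention), so the spatial height index varies fastest. Weights are
// (k, k, c_in/groups, c_out). All convolutions use zero padding.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad, int dil) {
  int eff = dil * (k - 1) + 1;
  return (n + 2 * pad - eff) / stride + 1;
}

// im2col for one sample and one channel group.
// col is (k*k*cg) x (ho*wo); row index r = ci*k*k + kj*k + ki.
static void im2col(const double* x, int h, int w, int cg, int c_off, int c_tot,
                   int k, int stride, int pad, int dil, int ho, int wo,
                   arma::mat& col) {
  for (int ci = 0; ci < cg; ++ci) {
    const double* xc = x + (size_t)(c_off + ci) * h * w;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ci * k * k + kj * k + ki;
        double* dst = col.colptr(0) + r;  // stride between cols = col.n_rows
        for (int oj = 0; oj < wo; ++oj) {
          int j = oj * stride - pad + kj * dil;
          bool jin = (j >= 0 && j < w);
          for (int oi = 0; oi < ho; ++oi) {
            int i = oi * stride - pad + ki * dil;
            double v = 0.0;
            if (jin && i >= 0 && i < h) v = xc[(size_t)j * h + i];
            dst[(size_t)(oj * ho + oi) * col.n_rows] = v;
          }
        }
      }
    }
  }
}

// col2im accumulation (transpose of im2col).
static void col2im(const arma::mat& col, double* x, int h, int w, int cg,
                   int c_off, int k, int stride, int pad, int dil,
                   int ho, int wo) {
  for (int ci = 0; ci < cg; ++ci) {
    double* xc = x + (size_t)(c_off + ci) * h * w;
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        int r = ci * k * k + kj * k + ki;
        const double* src = col.colptr(0) + r;
        for (int oj = 0; oj < wo; ++oj) {
          int j = oj * stride - pad + kj * dil;
          if (j < 0 || j >= w) continue;
          for (int oi = 0; oi < ho; ++oi) {
            int i = oi * stride - pad + ki * dil;
            if (i < 0 || i >= h) continue;
            xc[(size_t)j * h + i] += src[(size_t)(oj * ho + oi) * col.n_rows];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_conv2d(NumericVector x, IntegerVector xdim,
                         NumericVector wt, int k, int cout,
                         int stride, int pad, int dil, int groups,
                         Nullable<NumericVector> bias) {
  int h = xdim[0], w = xdim[1], c = xdim[2], b = xdim[3];
  int cg = c / groups, cog = cout / groups;
  int ho = out_size(h, k, stride, pad, dil);
  int wo = out_size(w, k, stride, pad, dil);
  NumericVector out((size_t)ho * wo * cout * b);
  out.attr("dim") = IntegerVector::create(ho, wo, cout, b);
  arma::mat col(k * k * cg, ho * wo);
  const double* xp = x.begin();
  double* op = out.begin();
  bool has_b = bias.isNotNull();
  NumericVector bv;
  if (has_b) bv = bias.get();
  for (int n = 0; n < b; ++n) {
    const double* xn = xp + (size_t)n * h * w * c;
    double* on = op + (size_t)n * ho * wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, h, w, cg, g * cg, c, k, stride, pad, dil, ho, wo, col);
      arma::mat W(const_cast<double*>(wt.begin()) + (size_t)g * cog * cg * k * k,
                  k * k * cg, cog, false, true);
      arma::mat O(on + (size_t)g * cog * ho * wo, ho * wo, cog, false, true);
      O = col.t() * W;
      if (has_b)
        for (int co = 0; co < cog; ++co) O.col(co) += bv[g * cog + co];
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_conv2d_backward(NumericVector x, IntegerVector xdim,
                         NumericVector wt, int k, int cout,
                         int stride, int pad, int dil, int groups,
                         NumericVector dout, bool need_dx, bool has_bias) {
  int h = xdim[0], w = xdim[1], c = xdim[2], b = xdim[3];
  int cg = c / groups, cog = cout / groups;
  int ho = out_size(h, k, stride, pad, dil);
  int wo = out_size(w, k, stride, pad, dil);
  NumericVector dx;
  if (need_dx) {
    dx = NumericVector((size_t)h * w * c * b);
    dx.attr("dim") = xdim;
  }
  NumericVector dw((size_t)k * k * cg * cout);
  dw.attr("dim") = IntegerVector::create(k, k, cg, cout);
  NumericVector db(has_bias ? cout : 0);
  arma::mat col(k * k * cg, ho * wo);
  const double* xp = x.begin();
  const double* dop = dout.begin();
  for (int n = 0; n < b; ++n) {
    const double* xn = xp + (size_t)n * h * w * c;
    const double* don = dop + (size_t)n * ho * wo * cout;
    for (int g = 0; g < groups; ++g) {
      im2col(xn, h, w, cg, g * cg, c, k, stride, pad, dil, ho, wo, col);
      arma::mat DO(const_cast<double*>(don) + (size_t)g * cog * ho * wo,
                   ho * wo, cog, false, true);
      arma::mat DW(dw.begin() + (size_t)g * cog * cg * k * k,
                   k * k * cg, cog, false, true);
      DW += col * DO;
      if (has_bias)
        for (int co = 0; co < cog; ++co) db[g * cog + co] += arma::accu(DO.col(co));
      if (need_dx) {
        arma::mat W(const_cast<double*>(wt.begin()) + (size_t)g * cog * cg * k * k,
                    k * k * cg, cog, false, true);
        arma::mat dcol = W * DO.t();
        col2im(dcol, dx.begin() + (size_t)n * h * w * c, h, w, cg, g * cg,
               k, stride, pad, dil, ho, wo);
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// Nearest-neighbour 2x upsampling, (h,w,c,b) -> (2h,2w,c,b).
// [[Rcpp::export]]
NumericVector cpp_upsample2(NumericVector x, IntegerVector xdim) {
  int h = xdim[0], w = xdim[1], c = xdim[2], b = xdim[3];
  int H = 2 * h, W = 2 * w;
  NumericVector out((size_t)H * W * c * b);
  out.attr("dim") = IntegerVector::create(H, W, c, b);
  const double* xp = x.begin();
  double* op = out.begin();
  for (size_t m = 0; m < (size_t)c * b; ++m) {
    const double* xm = xp + m * h * w;
    double* om = op + m * H * W;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        double v = xm[(size_t)j * h + i];
        size_t base = (size_t)(2 * j) * H + 2 * i;
        om[base] = v; om[base + 1] = v;
        om[base + H] = v; om[base + H + 1] = v;
      }
  }
  return out;
}

// Gradient of nearest 2x upsampling: sum each 2x2 block.
// [[Rcpp::export]]
NumericVector cpp_upsample2_backward(NumericVector g, IntegerVector gdim) {
  int H = gdim[0], W = gdim[1], c = gdim[2], b = gdim[3];
  int h = H / 2, w = W / 2;
  NumericVector out((size_t)h * w * c * b);
  out.attr("dim") = IntegerVector::create(h, w, c, b);
  const double* gp = g.begin();
  double* op = out.begin();
  for (size_t m = 0; m < (size_t)c * b; ++m) {
    const double* gm = gp + m * H * W;
    double* om = op + m * h * w;
    for (int j = 0; j < w; ++j)
      for (int i = 0; i < h; ++i) {
        size_t base = (size_t)(2 * j) * H + 2 * i;
        om[(size_t)j * h + i] =
          gm[base] + gm[base + 1] + gm[base + H] + gm[base + H + 1];
      }
  }
  return out;
}

// ---- channel-wise helpers (x laid out (h,w,c,b); hw = h*w) -----------------

// per-channel sums over (h, w, b)
// [[Rcpp::export]]
NumericVector cpp_ch_sum(NumericVector x, int hw, int c, int b) {
  NumericVector out(c);
  const double* xp = x.begin();
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch) {
      const double* p = xp + ((size_t)n * c + ch) * hw;
      double s = 0;
      for (int i = 0; i < hw; ++i) s += p[i];
      out[ch] += s;
    }
  return out;
}

// per-channel sums of x*y
// [[Rcpp::export]]
NumericVector cpp_ch_dot(NumericVector x, NumericVector y, int hw, int c, int b) {
  NumericVector out(c);
  const double* xp = x.begin();
  const double* yp = y.begin();
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)n * c + ch) * hw;
      double s = 0;
      for (int i = 0; i < hw; ++i) s += xp[off + i] * yp[off + i];
      out[ch] += s;
    }
  return out;
}

// y = x * a[ch] + bshift[ch]
// [[Rcpp::export]]
NumericVector cpp_ch_axpb(NumericVector x, NumericVector a, NumericVector bshift,
                          int hw, int c, int b) {
  NumericVector out((size_t)hw * c * b);
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)n * c + ch) * hw;
      double aa = a[ch], bb = bshift[ch];
      for (int i = 0; i < hw; ++i) op[off + i] = xp[off + i] * aa + bb;
    }
  return out;
}

// dx = gx - m1[ch] - xhat * m2[ch]
// [[Rcpp::export]]
NumericVector cpp_bn_dx(NumericVector gx, NumericVector xhat,
                        NumericVector m1, NumericVector m2,
                        int hw, int c, int b) {
  NumericVector out((size_t)hw * c * b);
  out.attr("dim") = gx.attr("dim");
  const double* gp = gx.begin();
  const double* hp = xhat.begin();
  double* op = out.begin();
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)n * c + ch) * hw;
      double a1 = m1[ch], a2 = m2[ch];
      for (int i = 0; i < hw; ++i)
        op[off + i] = gp[off + i] - a1 - hp[off + i] * a2;
    }
  return out;
}

// broadcast multiply: out = x * g where dim(g)[k] is dims[k] or 1
// [[Rcpp::export]]
NumericVector cpp_bcast_mul(NumericVector x, IntegerVector xd,
                            NumericVector g, IntegerVector gd) {
  int h = xd[0], w = xd[1], c = xd[2], b = xd[3];
  size_t sh = (gd[0] == 1) ? 0 : 1;
  size_t sw = (gd[1] == 1) ? 0 : (size_t)gd[0];
  size_t sc = (gd[2] == 1) ? 0 : (size_t)gd[0] * gd[1];
  size_t sb = (gd[3] == 1) ? 0 : (size_t)gd[0] * gd[1] * gd[2];
  NumericVector out((size_t)h * w * c * b);
  out.attr("dim") = xd;
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = out.begin();
  size_t idx = 0;
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch)
      for (int j = 0; j < w; ++j) {
        size_t gbase = n * sb + ch * sc + j * sw;
        for (int i = 0; i < h; ++i, ++idx)
          op[idx] = xp[idx] * gp[gbase + i * sh];
      }
  return out;
}

// reduce x (dims xd) to target dims gd by summing over broadcast axes
// [[Rcpp::export]]
NumericVector cpp_reduce_to(NumericVector x, IntegerVector xd, IntegerVector gd) {
  int h = xd[0], w = xd[1], c = xd[2], b = xd[3];
  size_t sh = (gd[0] == 1) ? 0 : 1;
  size_t sw = (gd[1] == 1) ? 0 : (size_t)gd[0];
  size_t sc = (gd[2] == 1) ? 0 : (size_t)gd[0] * gd[1];
  size_t sb = (gd[3] == 1) ? 0 : (size_t)gd[0] * gd[1] * gd[2];
  NumericVector out((size_t)gd[0] * gd[1] * gd[2] * gd[3]);
  out.attr("dim") = gd;
  const double* xp = x.begin();
  double* op = out.begin();
  size_t idx = 0;
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch)
      for (int j = 0; j < w; ++j) {
        size_t gbase = n * sb + ch * sc + j * sw;
        for (int i = 0; i < h; ++i, ++idx)
          op[gbase + i * sh] += xp[idx];
      }
  return out;
}

// silu forward and backward fused
// [[Rcpp::export]]
NumericVector cpp_silu(NumericVector x) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* op = out.begin();
  for (size_t i = 0; i < (size_t)x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    op[i] = xp[i] * s;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_silu_backward(NumericVector x, NumericVector g) {
  NumericVector out(x.size());
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  const double* gp = g.begin();
  double* op = out.begin();
  for (size_t i = 0; i < (size_t)x.size(); ++i) {
    double s = 1.0 / (1.0 + std::exp(-xp[i]));
    op[i] = gp[i] * s * (1.0 + xp[i] * (1.0 - s));
  }
  return out;
}

// fused batch-norm forward: xhat = (x - mu)*istd, out = xhat*gamma + beta
// [[Rcpp::export]]
List cpp_bn_fwd(NumericVector x, NumericVector mu, NumericVector istd,
                NumericVector gamma, NumericVector beta,
                int hw, int c, int b) {
  NumericVector xhat((size_t)hw * c * b), out((size_t)hw * c * b);
  xhat.attr("dim") = x.attr("dim");
  out.attr("dim") = x.attr("dim");
  const double* xp = x.begin();
  double* hp = xhat.begin();
  double* op = out.begin();
  for (int n = 0; n < b; ++n)
    for (int ch = 0; ch < c; ++ch) {
      size_t off = ((size_t)n * c + ch) * hw;
      double m = mu[ch], is = istd[ch], gg = gamma[ch], bb = beta[ch];
      for (int i = 0; i < hw; ++i) {
        double hv = (xp[off + i] - m) * is;
        hp[off + i] = hv;
        op[off + i] = hv * gg + bb;
      }
    }
  return List::create(_["xhat"] = xhat, _["out"] = out);
}
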