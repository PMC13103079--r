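// Low-level numerical kernels: 2D convolution (forward/backward) for the
// translation networks, separable valid-mode filtering for windowed SSIM,
// trilinear/nearest affine resampling for registration and grid changes,
// and boundary-distance sums for the average Hausdorff metric.
// Array layout follows R: column-major, images (H, W, C, N), volumes (X, Y, Z).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_size(int n, int k, int stride, int pad) {
  return (n + 2 * pad - k) / stride + 1;
}

// im2col for one sample: returns (Ho*Wo) x (kh*kw*Cin)
static arma::mat im2col_one(const double* x, int H, int W, int C,
                            int kh, int kw, int stride, int pad,
                            int Ho, int Wo) {
  arma::mat M(Ho * Wo, kh * kw * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)H * W * c;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        int col = dh + kh * (dw + kw * c);
        for (int wo = 0; wo < Wo; ++wo) {
          int wi = wo * stride - pad + dw;
          bool w_ok = (wi >= 0 && wi < W);
          for (int ho = 0; ho < Ho; ++ho) {
            int hi = ho * stride - pad + dh;
            double v = 0.0;
            if (w_ok && hi >= 0 && hi < H) v = xc[hi + (size_t)H * wi];
            M(ho + Ho * wo, col) = v;
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export(name = ".conv2d_fwd_cpp")]]
NumericVector conv2d_fwd_cpp(NumericVector X, NumericVector Wt,
                             NumericVector b, int stride, int pad) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  if (Cin != C) stop("conv2d: input channels (%d) != kernel channels (%d)", C, Cin);
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  if (Ho <= 0 || Wo <= 0) stop("conv2d: non-positive output size");
  arma::mat Wm(const_cast<double*>(Wt.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector out(Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(X.begin() + (size_t)H * W * C * n, H, W, C,
                             kh, kw, stride, pad, Ho, Wo);
    arma::mat Y = M * Wm;               // (Ho*Wo) x Cout
    Y.each_row() += arma::rowvec(const_cast<double*>(b.begin()), Cout, false, true);
    std::copy(Y.begin(), Y.end(), out.begin() + (size_t)Ho * Wo * Cout * n);
  }
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd_cpp")]]
List conv2d_bwd_cpp(NumericVector X, NumericVector Wt, NumericVector dY,
                    int stride, int pad, bool want_dx = true) {
  IntegerVector xd = X.attr("dim");
  IntegerVector wd = Wt.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int kh = wd[0], kw = wd[1], Cin = wd[2], Cout = wd[3];
  int Ho = out_size(H, kh, stride, pad), Wo = out_size(W, kw, stride, pad);
  arma::mat Wm(const_cast<double*>(Wt.begin()), kh * kw * Cin, Cout, false, true);
  NumericVector dX(want_dx ? X.size() : 0);
  if (want_dx) dX.attr("dim") = xd;
  arma::mat dWm(kh * kw * Cin, Cout, arma::fill::zeros);
  arma::rowvec db(Cout, arma::fill::zeros);
  // Flipped-kernel matrix for the stride-1 dX path:
  // dX = conv(dY, rot180(W) with in/out channels swapped, pad = k-1-pad).
  arma::mat Wflip;
  int pad_b = 0;
  if (want_dx && stride == 1) {
    Wflip.set_size(kh * kw * Cout, Cin);
    const double* w = Wt.begin();
    for (int ci = 0; ci < Cin; ++ci)
      for (int dw = 0; dw < kw; ++dw)
        for (int dh = 0; dh < kh; ++dh)
          for (int co = 0; co < Cout; ++co)
            Wflip(dh + kh * (dw + kw * co), ci) =
              w[(kh - 1 - dh) + kh * ((kw - 1 - dw) + kw * (ci + (size_t)Cin * co))];
    pad_b = kh - 1 - pad;
  }
  for (int n = 0; n < N; ++n) {
    arma::mat M = im2col_one(X.begin() + (size_t)H * W * C * n, H, W, C,
                             kh, kw, stride, pad, Ho, Wo);
    arma::mat G(const_cast<double*>(dY.begin()) + (size_t)Ho * Wo * Cout * n,
                Ho * Wo, Cout, false, true);
    dWm += M.t() * G;
    db += arma::sum(G, 0);
    if (!want_dx) continue;
    double* dx = dX.begin() + (size_t)H * W * C * n;
    if (stride == 1) {
      arma::mat Mg = im2col_one(dY.begin() + (size_t)Ho * Wo * Cout * n,
                                Ho, Wo, Cout, kh, kw, 1, pad_b, H, W);
      arma::mat dXn = Mg * Wflip;       // (H*W) x Cin
      std::copy(dXn.begin(), dXn.end(), dx);
    } else {
      arma::mat dM = G * Wm.t();        // (Ho*Wo) x (kh*kw*Cin), scatter back
      for (int c = 0; c < C; ++c) {
        double* dxc = dx + (size_t)H * W * c;
        for (int dw = 0; dw < kw; ++dw) {
          for (int dh = 0; dh < kh; ++dh) {
            int col = dh + kh * (dw + kw * c);
            for (int wo = 0; wo < Wo; ++wo) {
              int wi = wo * stride - pad + dw;
              if (wi < 0 || wi >= W) continue;
              for (int ho = 0; ho < Ho; ++ho) {
                int hi = ho * stride - pad + dh;
                if (hi < 0 || hi >= H) continue;
                dxc[hi + (size_t)H * wi] += dM(ho + Ho * wo, col);
              }
            }
          }
        }
      }
    }
  }
  NumericVector dWout(dWm.begin(), dWm.end());
  dWout.attr("dim") = wd;
  NumericVector dbout(db.begin(), db.end());
  return List::create(_["dX"] = dX, _["dW"] = dWout, _["db"] = dbout);
}

// Valid-mode 1D filtering of a 2D/3D array along dimension `dim` (1-based).
// [[Rcpp::export(name = ".sepfilter_valid_cpp")]]
NumericVector sepfilter_valid_cpp(NumericVector A, NumericVector kern, int dim) {
  IntegerVector ad = A.attr("dim");
  int nd = ad.size();
  if (nd < 2 || nd > 3) stop("sepfilter: 2D or 3D arrays only");
  int k = kern.size();
  std::vector<int> d(3, 1);
  for (int i = 0; i < nd; ++i) d[i] = ad[i];
  int di = dim - 1;
  int nout = d[di] - k + 1;
  if (nout <= 0) stop("sepfilter: kernel longer than dimension");
  std::vector<int> od(d);
  od[di] = nout;
  NumericVector out((size_t)od[0] * od[1] * od[2]);
  const double* a = A.begin();
  double* o = out.begin();
  const double* kv = kern.begin();
  size_t s_in[3]  = {1, (size_t)d[0], (size_t)d[0] * d[1]};
  size_t s_out[3] = {1, (size_t)od[0], (size_t)od[0] * od[1]};
  for (int z = 0; z < od[2]; ++z)
    for (int y = 0; y < od[1]; ++y)
      for (int x = 0; x < od[0]; ++x) {
        size_t base = (size_t)x * s_in[0] + (size_t)y * s_in[1] + (size_t)z * s_in[2];
        double acc = 0.0;
        for (int t = 0; t < k; ++t) acc += kv[t] * a[base + (size_t)t * s_in[di]];
        o[(size_t)x * s_out[0] + (size_t)y * s_out[1] + (size_t)z * s_out[2]] = acc;
      }
  if (nd == 2) out.attr("dim") = IntegerVector::create(od[0], od[1]);
  else out.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return out;
}

// Resample a 3D volume through an affine index map: for each output voxel
// index v (0-based), source index s = A %*% v + t; sample vol at s.
// [[Rcpp::export(name = ".resample_affine_cpp")]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector out_dim,
                                  NumericMatrix A, NumericVector t,
                                  bool nearest, double fill,
                                  bool clamp_edges = false) {
  IntegerVector vd = vol.attr("dim");
  int X = vd[0], Y = vd[1], Z = vd[2];
  int OX = out_dim[0], OY = out_dim[1], OZ = out_dim[2];
  NumericVector out((size_t)OX * OY * OZ);
  out.attr("dim") = IntegerVector::create(OX, OY, OZ);
  const double* v = vol.begin();
  double* o = out.begin();
  double a00 = A(0,0), a01 = A(0,1), a02 = A(0,2);
  double a10 = A(1,0), a11 = A(1,1), a12 = A(1,2);
  double a20 = A(2,0), a21 = A(2,1), a22 = A(2,2);
  for (int k = 0; k < OZ; ++k)
    for (int j = 0; j < OY; ++j)
      for (int i = 0; i < OX; ++i) {
        double sx = a00 * i + a01 * j + a02 * k + t[0];
        double sy = a10 * i + a11 * j + a12 * k + t[1];
        double sz = a20 * i + a21 * j + a22 * k + t[2];
        if (clamp_edges) {
          sx = std::min(std::max(sx, 0.0), (double)(X - 1));
          sy = std::min(std::max(sy, 0.0), (double)(Y - 1));
          sz = std::min(std::max(sz, 0.0), (double)(Z - 1));
        }
        double val = fill;
        if (nearest) {
          int ix = (int)std::lround(sx), iy = (int)std::lround(sy), iz = (int)std::lround(sz);
          if (ix >= 0 && ix < X && iy >= 0 && iy < Y && iz >= 0 && iz < Z)
            val = v[ix + (size_t)X * (iy + (size_t)Y * iz)];
        } else {
          int x0 = (int)std::floor(sx), y0 = (int)std::floor(sy), z0 = (int)std::floor(sz);
          double fx = sx - x0, fy = sy - y0, fz = sz - z0;
          if (x0 >= -1 && x0 < X && y0 >= -1 && y0 < Y && z0 >= -1 && z0 < Z) {
            double acc = 0.0;
            for (int dz = 0; dz <= 1; ++dz)
              for (int dy = 0; dy <= 1; ++dy)
                for (int dx = 0; dx <= 1; ++dx) {
                  int xx = x0 + dx, yy = y0 + dy, zz = z0 + dz;
                  double w = (dx ? fx : 1 - fx) * (dy ? fy : 1 - fy) * (dz ? fz : 1 - fz);
                  double s = fill;
                  if (xx >= 0 && xx < X && yy >= 0 && yy < Y && zz >= 0 && zz < Z)
                    s = v[xx + (size_t)X * (yy + (size_t)Y * zz)];
                  acc += w * s;
                }
            val = acc;
          }
        }
        o[i + (size_t)OX * (j + (size_t)OY * k)] = val;
      }
  return out;
}

// Directed mean (or max) of nearest-point distances from rows of P to rows of Q.
// [[Rcpp::export(name = ".directed_surface_dist_cpp")]]
double directed_surface_dist_cpp(NumericMatrix P, NumericMatrix Q, bool use_max) {
  int n = P.nrow(), m = Q.nrow();
  double agg = 0.0;
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double px = P(i,0), py = P(i,1), pz = P(i,2);
    for (int j = 0; j < m; ++j) {
      double dx = px - Q(j,0), dy = py - Q(j,1), dz = pz - Q(j,2);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 < best) best = d2;
    }
    best = std::sqrt(best);
    if (use_max) { if (best > agg) agg = best; } else agg += best;
  }
  return use_max ? agg : agg / n;
}

// Normalized cross-correlation between two equally sized arrays.
// [[Rcpp::export(name = ".ncc_cpp")]]
double ncc_cpp(NumericVector a, NumericVector b) {
  size_t n = a.size();
  double ma = 0, mb = 0;
  for (size_t i = 0; i < n; ++i) { ma += a[i]; mb += b[i]; }
  ma /= n; mb /= n;
  double sab = 0, saa = 0, sbb = 0;
  for (size_t i = 0; i < n; ++i) {
    double da = a[i] - ma, db = b[i] - mb;
    sab += da * db; saa += da * da; sbb += db * db;
  }
  if (saa <= 0 || sbb <= 0) return 0.0;
  return sab / std::sqrt(saa * sbb);
}

// Normalized mutual information (Studholme): (H(A)+H(B)) / H(A,B), with a
// joint histogram over `bins` equal-width bins spanning each input's range.
// [[Rcpp::export(name = ".nmi_cpp")]]
double nmi_cpp(NumericVector a, NumericVector b, int bins) {
  size_t n = a.size();
  double amin = R_PosInf, amax = R_NegInf, bmin = R_PosInf, bmax = R_NegInf;
  for (size_t i = 0; i < n; ++i) {
    if (a[i] < amin) amin = a[i];
    if (a[i] > amax) amax = a[i];
    if (b[i] < bmin) bmin = b[i];
    if (b[i] > bmax) bmax = b[i];
  }
  if (!(amax > amin) || !(bmax > bmin)) return 0.0;
  double as = bins / (amax - amin) * (1.0 - 1e-12);
  double bs = bins / (bmax - bmin) * (1.0 - 1e-12);
  std::vector<double> joint((size_t)bins * bins, 0.0);
  for (size_t i = 0; i < n; ++i) {
    int ia = (int)((a[i] - amin) * as);
    int ib = (int)((b[i] - bmin) * bs);
    joint[ia + (size_t)bins * ib] += 1.0;
  }
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  for (int ib = 0; ib < bins; ++ib)
    for (int ia = 0; ia < bins; ++ia) {
      double p = joint[ia + (size_t)bins * ib] / n;
      pa[ia] += p; pb[ib] += p;
    }
  double ha = 0, hb = 0, hab = 0;
  for (int i = 0; i < bins; ++i) {
    if (pa[i] > 0) ha -= pa[i] * std::log(pa[i]);
    if (pb[i] > 0) hb -= pb[i] * std::log(pb[i]);
  }
  for (size_t i = 0; i < joint.size(); ++i) {
    double p = joint[i] / n;
    if (p > 0) hab -= p * std::log(p);
  }
  if (hab <= 0) return 2.0;
  return (ha + hb) / hab;
}
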