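// Low-level numerical kernels: 3D convolution (im2col + GEMM), trilinear
// affine resampling, single-axis tilt projection and its exact adjoint,
// and mean-field inference for the dense binary CRF with truncated
// Gaussian neighbourhoods.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int idx3(int i, int j, int k, int H, int W) {
  return i + H * (j + W * k);
}

// im2col for a 3x3x3 kernel with zero padding 1, stride 1.
// x is laid out (H, W, D, C) column-major; col is N x (C*27), N = H*W*D,
// so every column (one kernel tap of one channel) is written as
// contiguous runs over the fastest axis. Column order within a channel
// block: t = di + 3*dj + 9*dk, offsets -1..1.
static void im2col3(const double* x, int H, int W, int D, int C,
                    arma::mat& col) {
  const int N = H * W * D;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * N;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = c * 27 + di + 3 * dj + 9 * dk;
          const int oi = di - 1, oj = dj - 1, ok = dk - 1;
          double* cr = col.colptr(r);
          for (int k = 0; k < D; ++k) {
            const int ks = k + ok;
            const bool kin = ks >= 0 && ks < D;
            for (int j = 0; j < W; ++j) {
              const int js = j + oj;
              double* dst = cr + H * (j + W * k);
              if (!kin || js < 0 || js >= W) {
                std::fill(dst, dst + H, 0.0);
                continue;
              }
              const double* src = xc + idx3(0, js, ks, H, W);
              // shifted contiguous copy along the fastest axis
              if (oi == 0) {
                std::copy(src, src + H, dst);
              } else if (oi < 0) {
                dst[0] = 0.0;
                std::copy(src, src + H - 1, dst + 1);
              } else {
                std::copy(src + 1, src + H, dst);
                dst[H - 1] = 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector dims,
                             const arma::mat& Wm, const arma::vec& b) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int N = H * W * D;
  const int Cout = Wm.n_rows;
  if ((int)Wm.n_cols != C * 27)
    stop("weight matrix has %d columns, expected %d", (int)Wm.n_cols, C * 27);
  arma::mat col(N, C * 27);
  im2col3(REAL(x), H, W, D, C, col);
  NumericVector out((size_t)N * Cout);
  arma::mat Y(REAL(out), N, Cout, false, true);
  Y = col * Wm.t();
  Y.each_row() += b.t();
  out.attr("dim") = IntegerVector::create(H, W, D, Cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bwd_cpp(NumericVector x, IntegerVector dims, NumericVector dy,
                    const arma::mat& Wm) {
  const int H = dims[0], W = dims[1], D = dims[2], C = dims[3];
  const int N = H * W * D;
  const int Cout = Wm.n_rows;
  arma::mat col(N, C * 27);
  im2col3(REAL(x), H, W, D, C, col);
  const arma::mat dY(REAL(dy), N, Cout, false, true);
  arma::mat dW = (col.t() * dY).t();      // Cout x (C*27)
  arma::vec db = arma::sum(dY, 0).t();
  arma::mat dcol = dY * Wm;               // N x (C*27)
  NumericVector dx((size_t)N * C);
  double* dxp = REAL(dx);
  for (int c = 0; c < C; ++c) {
    double* dxc = dxp + (size_t)c * N;
    for (int dk = 0; dk < 3; ++dk) {
      for (int dj = 0; dj < 3; ++dj) {
        for (int di = 0; di < 3; ++di) {
          const int r = c * 27 + di + 3 * dj + 9 * dk;
          const int oi = di - 1, oj = dj - 1, ok = dk - 1;
          const double* cr = dcol.colptr(r);
          for (int k = 0; k < D; ++k) {
            const int ks = k + ok;
            if (ks < 0 || ks >= D) continue;
            for (int j = 0; j < W; ++j) {
              const int js = j + oj;
              if (js < 0 || js >= W) continue;
              const double* src = cr + H * (j + W * k);
              double* dst = dxc + idx3(0, js, ks, H, W);
              if (oi == 0) {
                for (int i = 0; i < H; ++i) dst[i] += src[i];
              } else if (oi < 0) {
                for (int i = 1; i < H; ++i) dst[i - 1] += src[i];
              } else {
                for (int i = 0; i < H - 1; ++i) dst[i + 1] += src[i];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(H, W, D, C);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

static inline double trilinear(const double* v, int H, int W, int D,
                               double x, double y, double z) {
  // zero outside the grid
  if (x <= -1.0 || y <= -1.0 || z <= -1.0 ||
      x >= (double)H || y >= (double)W || z >= (double)D) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  double fx = x - x0, fy = y - y0, fz = z - z0;
  double out = 0.0;
  for (int dz = 0; dz < 2; ++dz) {
    int zz = z0 + dz;
    if (zz < 0 || zz >= D) continue;
    double wz = dz ? fz : 1.0 - fz;
    for (int dyy = 0; dyy < 2; ++dyy) {
      int yy = y0 + dyy;
      if (yy < 0 || yy >= W) continue;
      double wy = dyy ? fy : 1.0 - fy;
      for (int dx = 0; dx < 2; ++dx) {
        int xx = x0 + dx;
        if (xx < 0 || xx >= H) continue;
        double wx = dx ? fx : 1.0 - fx;
        out += wx * wy * wz * v[idx3(xx, yy, zz, H, W)];
      }
    }
  }
  return out;
}

// Apply pose (R, t) to a volume: out(p) = vol(R^T (p - c - t) + c),
// i.e. the object is rotated by R about the grid centre then shifted by t.
// [[Rcpp::export]]
NumericVector resample_affine_cpp(NumericVector vol, IntegerVector dims,
                                  const arma::mat& R, const arma::vec& t) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const double cx = (H - 1) / 2.0, cy = (W - 1) / 2.0, cz = (D - 1) / 2.0;
  arma::mat Rt = R.t();
  NumericVector out((size_t)H * W * D);
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int k = 0; k < D; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double px = i - cx - t[0], py = j - cy - t[1], pz = k - cz - t[2];
        double sx = Rt(0, 0) * px + Rt(0, 1) * py + Rt(0, 2) * pz + cx;
        double sy = Rt(1, 0) * px + Rt(1, 1) * py + Rt(1, 2) * pz + cy;
        double sz = Rt(2, 0) * px + Rt(2, 1) * py + Rt(2, 2) * pz + cz;
        o[idx3(i, j, k, H, W)] = trilinear(v, H, W, D, sx, sy, sz);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, D);
  return out;
}

// Single-axis tilt projection. The tilt axis is the second (y) axis; the
// beam runs along the third (z) axis at 0 degrees. For each tilt angle the
// ray through detector coordinate u is integrated with unit step over a
// parameter range long enough to cover the volume diagonal, so projections
// at any angle conserve the mass of a compact centred object. At exactly
// 0 degrees all sample points fall on grid nodes and the projection equals
// the plain z-axis sum.
// [[Rcpp::export]]
NumericVector project_tilt_cpp(NumericVector vol, IntegerVector dims,
                               NumericVector angles_deg) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const int nA = angles_deg.size();
  int Ld = (int)std::ceil(std::sqrt((double)H * H + (double)D * D)) + 2;
  if ((Ld - D) % 2 != 0) Ld += 1;  // keep integer sample points at 0 deg
  const double cx = (H - 1) / 2.0, cz = (D - 1) / 2.0, ct = (Ld - 1) / 2.0;
  NumericVector out((size_t)H * W * nA);
  double* op = REAL(out);
  const double* v = REAL(vol);
  for (int a = 0; a < nA; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ca = std::cos(th), sa = std::sin(th);
    double* img = op + (size_t)a * H * W;
    for (int tpar = 0; tpar < Ld; ++tpar) {
      const double tt = tpar - ct;
      for (int u = 0; u < H; ++u) {
        const double uu = u - cx;
        const double xs = cx + uu * ca - tt * sa;
        const double zs = cz + uu * sa + tt * ca;
        if (xs <= -1.0 || xs >= (double)H || zs <= -1.0 || zs >= (double)D)
          continue;
        int x0 = (int)std::floor(xs), z0 = (int)std::floor(zs);
        double fx = xs - x0, fz = zs - z0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= D) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dx = 0; dx < 2; ++dx) {
            int xx = x0 + dx;
            if (xx < 0 || xx >= H) continue;
            double w = wz * (dx ? fx : 1.0 - fx);
            if (w == 0.0) continue;
            const double* row = v + idx3(xx, 0, zz, H, W);
            double* irow = img + u;
            for (int y = 0; y < W; ++y)
              irow[(size_t)y * H] += w * row[(size_t)y * H];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, nA);
  return out;
}

// Exact adjoint of project_tilt_cpp: scatters each (u, y, t) ray sample of
// each projection image back into the volume with the same trilinear
// weights. Used unfiltered for adjointness checks and with ramp-filtered
// images for weighted back-projection.
// [[Rcpp::export]]
NumericVector backproject_tilt_cpp(NumericVector images, IntegerVector idims,
                                   NumericVector angles_deg, int D) {
  const int H = idims[0], W = idims[1];
  const int nA = angles_deg.size();
  int Ld = (int)std::ceil(std::sqrt((double)H * H + (double)D * D)) + 2;
  if ((Ld - D) % 2 != 0) Ld += 1;
  const double cx = (H - 1) / 2.0, cz = (D - 1) / 2.0, ct = (Ld - 1) / 2.0;
  NumericVector out((size_t)H * W * D);
  double* v = REAL(out);
  const double* ip = REAL(images);
  for (int a = 0; a < nA; ++a) {
    const double th = angles_deg[a] * M_PI / 180.0;
    const double ca = std::cos(th), sa = std::sin(th);
    const double* img = ip + (size_t)a * H * W;
    for (int tpar = 0; tpar < Ld; ++tpar) {
      const double tt = tpar - ct;
      for (int u = 0; u < H; ++u) {
        const double uu = u - cx;
        const double xs = cx + uu * ca - tt * sa;
        const double zs = cz + uu * sa + tt * ca;
        if (xs <= -1.0 || xs >= (double)H || zs <= -1.0 || zs >= (double)D)
          continue;
        int x0 = (int)std::floor(xs), z0 = (int)std::floor(zs);
        double fx = xs - x0, fz = zs - z0;
        for (int dz = 0; dz < 2; ++dz) {
          int zz = z0 + dz;
          if (zz < 0 || zz >= D) continue;
          double wz = dz ? fz : 1.0 - fz;
          for (int dx = 0; dx < 2; ++dx) {
            int xx = x0 + dx;
            if (xx < 0 || xx >= H) continue;
            double w = wz * (dx ? fx : 1.0 - fx);
            if (w == 0.0) continue;
            double* col = v + idx3(xx, 0, zz, H, W);
            const double* irow = img + u;
            for (int y = 0; y < W; ++y)
              col[(size_t)y * H] += w * irow[(size_t)y * H];
          }
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(H, W, D);
  return out;
}

// Mean-field inference for the binary dense CRF with an appearance kernel
// w1 * exp(-|p_i-p_j|^2 / (2 sa^2) - (I_i-I_j)^2 / (2 sb^2)) and a
// smoothness kernel w2 * exp(-|p_i-p_j|^2 / (2 sg^2)). Pairwise messages
// use truncated neighbourhoods of radius 3*sigma; updates are synchronous.
// Returns the converged foreground marginals Q1.
// [[Rcpp::export]]
NumericVector crf_meanfield_cpp(NumericVector prob, NumericVector intensity,
                                IntegerVector dims, double w1, double w2,
                                double sa, double sb, double sg, int iters) {
  const int H = dims[0], W = dims[1], D = dims[2];
  const int N = H * W * D;
  const double eps = 1e-8;
  std::vector<double> u1(N), u0(N), Q1(N), S(N), Ksum(N);
  const double* P = REAL(prob);
  const double* I = REAL(intensity);
  for (int n = 0; n < N; ++n) {
    double p = std::min(1.0 - eps, std::max(eps, P[n]));
    u1[n] = -std::log(p);
    u0[n] = -std::log(1.0 - p);
    Q1[n] = p;
  }
  // neighbour offsets with per-kernel spatial weights
  const int ra = (int)std::ceil(3.0 * sa);
  const int rs = (int)std::ceil(3.0 * sg);
  const int rmax = std::max(ra, rs);
  struct Nb { int di, dj, dk; double ga, gs; };
  std::vector<Nb> nbs;
  for (int dk = -rmax; dk <= rmax; ++dk)
    for (int dj = -rmax; dj <= rmax; ++dj)
      for (int di = -rmax; di <= rmax; ++di) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        double d2 = (double)di * di + (double)dj * dj + (double)dk * dk;
        double ga = 0.0, gs = 0.0;
        if (d2 <= (double)ra * ra && w1 > 0.0)
          ga = std::exp(-d2 / (2.0 * sa * sa));
        if (d2 <= (double)rs * rs && w2 > 0.0)
          gs = w2 * std::exp(-d2 / (2.0 * sg * sg));
        if (ga > 0.0 || gs > 0.0) nbs.push_back({di, dj, dk, ga, gs});
      }
  const double inv2sb2 = 1.0 / (2.0 * sb * sb);
  for (int it = 0; it < iters; ++it) {
    std::fill(S.begin(), S.end(), 0.0);
    std::fill(Ksum.begin(), Ksum.end(), 0.0);
    for (const Nb& nb : nbs) {
      const int klo = std::max(0, -nb.dk), khi = std::min(D, D - nb.dk);
      const int jlo = std::max(0, -nb.dj), jhi = std::min(W, W - nb.dj);
      const int ilo = std::max(0, -nb.di), ihi = std::min(H, H - nb.di);
      for (int k = klo; k < khi; ++k)
        for (int j = jlo; j < jhi; ++j) {
          const int base = H * (j + W * k);
          const int nbase = H * ((j + nb.dj) + W * (k + nb.dk)) + nb.di;
          for (int i = ilo; i < ihi; ++i) {
            const int n = base + i;
            const int m = nbase + i;
            double kk = nb.gs;
            if (nb.ga > 0.0) {
              const double dI = I[n] - I[m];
              kk += w1 * nb.ga * std::exp(-dI * dI * inv2sb2);
            }
            S[n] += kk * Q1[m];
            Ksum[n] += kk;
          }
        }
    }
    for (int n = 0; n < N; ++n) {
      // label 1 is penalised by neighbours' mass on label 0 and vice versa
      const double e1 = u1[n] + (Ksum[n] - S[n]);
      const double e0 = u0[n] + S[n];
      Q1[n] = 1.0 / (1.0 + std::exp(e1 - e0));
    }
  }
  NumericVector out(N);
  std::copy(Q1.begin(), Q1.end(), REAL(out));
  out.attr("dim") = IntegerVector::create(H, W, D);
  return out;
}
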