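// Dense 3D compute kernels for the segmentation networks.
//
// Feature fields are stored as (nvox x channels) matrices in voxel-major
// order, voxel index i = x + nx*(y + ny*z) for dims = (nx, ny, nz).
// Convolutions are 3x3x3, stride 1, zero padding 1; weights are
// (27*Cin x Cout) matrices with row index ci*27 + ko, where ko runs over
// kernel offsets (dx, dy, dz) with dx fastest, each in {-1, 0, 1}.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline int vox(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// Gather the 27*Cin rows of the im2col matrix for one z-slice.
static void fill_col_slice(const arma::mat& x, int nx, int ny, int nz,
                           int z, arma::mat& col) {
  const int cin = x.n_cols;
  col.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x.colptr(ci);
    int ko = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      const int zi = z + dz;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++ko) {
          if (zi < 0 || zi >= nz) continue;
          const int row = ci * 27 + ko;
          for (int y = 0; y < ny; ++y) {
            const int yi = y + dy;
            if (yi < 0 || yi >= ny) continue;
            const int x0 = (dx < 0) ? 1 : 0;
            const int x1 = (dx > 0) ? nx - 1 : nx;
            const int in_base = vox(0, yi, zi, nx, ny) + dx;
            const int out_base = y * nx;
            for (int xx = x0; xx < x1; ++xx) {
              col(row, out_base + xx) = xc[in_base + xx];
            }
          }
        }
      }
    }
  }
}

// Scatter-add a d(col)-slice back onto the input gradient.
static void scatter_col_slice(const arma::mat& dcol, int nx, int ny, int nz,
                              int z, arma::mat& gx) {
  const int cin = gx.n_cols;
  for (int ci = 0; ci < cin; ++ci) {
    double* gc = gx.colptr(ci);
    int ko = 0;
    for (int dz = -1; dz <= 1; ++dz) {
      const int zi = z + dz;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx, ++ko) {
          if (zi < 0 || zi >= nz) continue;
          const int row = ci * 27 + ko;
          for (int y = 0; y < ny; ++y) {
            const int yi = y + dy;
            if (yi < 0 || yi >= ny) continue;
            const int x0 = (dx < 0) ? 1 : 0;
            const int x1 = (dx > 0) ? nx - 1 : nx;
            const int in_base = vox(0, yi, zi, nx, ny) + dx;
            const int out_base = y * nx;
            for (int xx = x0; xx < x1; ++xx) {
              gc[in_base + xx] += dcol(row, out_base + xx);
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv3d_fw")]]
arma::mat conv3d_fw(const arma::mat& x, const arma::ivec& dims,
                    const arma::mat& w, const arma::vec& bias) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = x.n_cols, cout = w.n_cols;
  if ((int)w.n_rows != 27 * cin)
    stop("conv3d: weight rows (%d) do not match 27*Cin (%d)",
         (int)w.n_rows, 27 * cin);
  if ((int)x.n_rows != nx * ny * nz) stop("conv3d: nvox mismatch");
  arma::mat y(x.n_rows, cout);
  arma::mat col(27 * cin, nx * ny);
  for (int z = 0; z < nz; ++z) {
    fill_col_slice(x, nx, ny, nz, z, col);
    y.rows(z * nx * ny, (z + 1) * nx * ny - 1) = col.t() * w;
  }
  y.each_row() += bias.t();
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(const arma::mat& x, const arma::ivec& dims,
               const arma::mat& w, const arma::mat& gout) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int cin = x.n_cols;
  arma::mat gx(x.n_rows, cin, arma::fill::zeros);
  arma::mat gw(w.n_rows, w.n_cols, arma::fill::zeros);
  arma::mat col(27 * cin, nx * ny);
  for (int z = 0; z < nz; ++z) {
    fill_col_slice(x, nx, ny, nz, z, col);
    arma::mat gslice = gout.rows(z * nx * ny, (z + 1) * nx * ny - 1);
    gw += col * gslice;
    arma::mat dcol = w * gslice.t();
    scatter_col_slice(dcol, nx, ny, nz, z, gx);
  }
  arma::rowvec gb = arma::sum(gout, 0);
  return List::create(_["gx"] = gx, _["gw"] = gw,
                      _["gb"] = arma::vec(gb.t()));
}

// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(const arma::mat& x, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool: odd spatial dims");
  const int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  const int c = x.n_cols;
  arma::mat y(ox * oy * oz, c);
  arma::imat amax(ox * oy * oz, c);
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = x.colptr(ci);
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx) {
          double best = -std::numeric_limits<double>::infinity();
          int arg = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int i = vox(2 * xx + dx, 2 * yy + dy, 2 * z + dz,
                                  nx, ny);
                if (xc[i] > best) { best = xc[i]; arg = i; }
              }
          const int o = vox(xx, yy, z, ox, oy);
          y(o, ci) = best;
          amax(o, ci) = arg;
        }
  }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
arma::mat maxpool2_bw(const arma::mat& gout, const arma::imat& amax,
                      int nvox_in) {
  arma::mat gx(nvox_in, gout.n_cols, arma::fill::zeros);
  for (unsigned ci = 0; ci < gout.n_cols; ++ci)
    for (unsigned o = 0; o < gout.n_rows; ++o)
      gx(amax(o, ci), ci) += gout(o, ci);
  return gx;
}

// [[Rcpp::export(name = ".upsample2_fw")]]
arma::mat upsample2_fw(const arma::mat& x, const arma::ivec& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int ox = 2 * nx, oy = 2 * ny, oz = 2 * nz;
  arma::mat y(ox * oy * oz, x.n_cols);
  for (unsigned ci = 0; ci < x.n_cols; ++ci) {
    const double* xc = x.colptr(ci);
    double* yc = y.colptr(ci);
    for (int z = 0; z < oz; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          yc[vox(xx, yy, z, ox, oy)] =
            xc[vox(xx / 2, yy / 2, z / 2, nx, ny)];
  }
  return y;
}

// [[Rcpp::export(name = ".upsample2_bw")]]
arma::mat upsample2_bw(const arma::mat& gout, const arma::ivec& dims_in) {
  const int nx = dims_in[0], ny = dims_in[1], nz = dims_in[2];
  const int ox = 2 * nx, oy = 2 * ny;
  arma::mat gx(nx * ny * dims_in[2], gout.n_cols, arma::fill::zeros);
  for (unsigned ci = 0; ci < gout.n_cols; ++ci) {
    const double* gc = gout.colptr(ci);
    double* xc = gx.colptr(ci);
    for (int z = 0; z < 2 * dims_in[2]; ++z)
      for (int yy = 0; yy < oy; ++yy)
        for (int xx = 0; xx < ox; ++xx)
          xc[vox(xx / 2, yy / 2, z / 2, nx, ny)] +=
            gc[vox(xx, yy, z, ox, oy)];
  }
  return gx;
}

// Felzenszwalb & Huttenlocher 1D squared distance transform with
// anisotropic sample spacing s (parabolas at positions j*s).  Sites with
// infinite f are skipped; an all-infinite row stays infinite.
static void dt1d(const std::vector<double>& f, double s,
                 std::vector<double>& d) {
  const int n = (int)f.size();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> sites;
  sites.reserve(n);
  for (int q = 0; q < n; ++q) if (f[q] < INF) sites.push_back(q);
  if (sites.empty()) { d.assign(n, INF); return; }
  std::vector<int> v(sites.size());
  std::vector<double> zb(sites.size() + 1);
  int k = 0;
  v[0] = sites[0];
  zb[0] = -INF;
  zb[1] = INF;
  for (size_t m = 1; m < sites.size(); ++m) {
    const int q = sites[m];
    const double sq = q * s;
    double sep;
    while (true) {
      const int p = v[k];
      const double sp = p * s;
      sep = ((f[q] + sq * sq) - (f[p] + sp * sp)) / (2.0 * (sq - sp));
      if (sep <= zb[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    zb[k] = sep;
    zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double sq = q * s;
    while (zb[k + 1] < sq) ++k;
    const double sp = v[k] * s;
    d[q] = (sq - sp) * (sq - sp) + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_sq")]]
arma::vec edt_sq(const LogicalVector& mask, const arma::ivec& dims,
                 const arma::vec& spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  arma::vec d(nx * ny * nz);
  for (int i = 0; i < nx * ny * nz; ++i) d[i] = mask[i] ? 0.0 : INF;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax);
  // along x
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      f.assign(nx, INF);
      for (int x = 0; x < nx; ++x) f[x] = d[vox(x, y, z, nx, ny)];
      out.assign(nx, INF);
      dt1d(f, spacing[0], out);
      for (int x = 0; x < nx; ++x) d[vox(x, y, z, nx, ny)] = out[x];
    }
  // along y
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      f.assign(ny, INF);
      for (int y = 0; y < ny; ++y) f[y] = d[vox(x, y, z, nx, ny)];
      out.assign(ny, INF);
      dt1d(f, spacing[1], out);
      for (int y = 0; y < ny; ++y) d[vox(x, y, z, nx, ny)] = out[y];
    }
  // along z
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      f.assign(nz, INF);
      for (int z = 0; z < nz; ++z) f[z] = d[vox(x, y, z, nx, ny)];
      out.assign(nz, INF);
      dt1d(f, spacing[2], out);
      for (int z = 0; z < nz; ++z) d[vox(x, y, z, nx, ny)] = out[z];
    }
  return d;
}
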