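// Low-level volumetric primitives for the deeply supervised segmentation
// network and the evaluation metrics.  All lattices are column-major R
// arrays; feature maps are 4-D (x, y, z, channel).
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::uword vox(int ix, int iy, int iz, int nx, int ny) {
  return (arma::uword)ix + (arma::uword)nx * ((arma::uword)iy + (arma::uword)ny * (arma::uword)iz);
}

// im2col for a 3x3x3 kernel with same (zero) padding, stride 1.
// K has 27*Cin rows ordered (kx, ky, kz, cin) fastest-first to match the
// column-major flattening of a (3,3,3,Cin,Cout) weight array.
static arma::mat im2col3(const double* x, int nx, int ny, int nz, int cin) {
  arma::uword V = (arma::uword)nx * ny * nz;
  arma::mat K(27 * (arma::uword)cin, V, arma::fill::zeros);
  for (int c = 0; c < cin; ++c) {
    const double* xc = x + (arma::uword)c * V;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          arma::uword r = (arma::uword)kx + 3 * ky + 9 * kz + 27 * (arma::uword)c;
          int dx = kx - 1, dy = ky - 1, dz = kz - 1;
          int z0 = std::max(0, -dz), z1 = std::min(nz, nz - dz);
          int y0 = std::max(0, -dy), y1 = std::min(ny, ny - dy);
          int x0 = std::max(0, -dx), x1 = std::min(nx, nx - dx);
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy) {
              const double* src = xc + vox(x0 + dx, iy + dy, iz + dz, nx, ny);
              double* dst = K.colptr(vox(x0, iy, iz, nx, ny)) ; // column-major: stride over columns
              // columns are voxels; write row r across contiguous voxels
              arma::uword v0 = vox(x0, iy, iz, nx, ny);
              for (int ix = 0; ix < (x1 - x0); ++ix)
                K(r, v0 + ix) = src[ix];
              (void)dst;
            }
        }
  }
  return K;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  int cout = wd[4];
  if (wd[0] != 3 || wd[1] != 3 || wd[2] != 3 || wd[3] != cin)
    stop("conv3d: weight dims incompatible with input");
  arma::uword V = (arma::uword)nx * ny * nz;
  arma::mat K = im2col3(x.begin(), nx, ny, nz, cin);
  arma::mat W(w.begin(), 27 * (arma::uword)cin, cout, false, true);
  NumericVector out(V * (arma::uword)cout);
  arma::mat Y(out.begin(), V, cout, false, true);
  Y = K.t() * W;
  for (int c = 0; c < cout; ++c) Y.col(c) += b[c];
  out.attr("dim") = IntegerVector::create(nx, ny, nz, cout);
  return out;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], cin = xd[3];
  int cout = wd[4];
  arma::uword V = (arma::uword)nx * ny * nz;
  arma::mat K = im2col3(x.begin(), nx, ny, nz, cin);
  arma::mat W(w.begin(), 27 * (arma::uword)cin, cout, false, true);
  arma::mat dY(dy.begin(), V, cout, false, true);

  NumericVector dwv(27 * (arma::uword)cin * cout);
  arma::mat dW(dwv.begin(), 27 * (arma::uword)cin, cout, false, true);
  dW = K * dY;
  dwv.attr("dim") = IntegerVector::create(3, 3, 3, cin, cout);

  NumericVector dbv(cout);
  for (int c = 0; c < cout; ++c) dbv[c] = arma::accu(dY.col(c));

  arma::mat dK = W * dY.t();  // (27*cin) x V
  NumericVector dxv(V * (arma::uword)cin);
  double* dx = dxv.begin();
  for (int c = 0; c < cin; ++c) {
    double* dxc = dx + (arma::uword)c * V;
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          arma::uword r = (arma::uword)kx + 3 * ky + 9 * kz + 27 * (arma::uword)c;
          int dxo = kx - 1, dyo = ky - 1, dzo = kz - 1;
          int z0 = std::max(0, -dzo), z1 = std::min(nz, nz - dzo);
          int y0 = std::max(0, -dyo), y1 = std::min(ny, ny - dyo);
          int x0 = std::max(0, -dxo), x1 = std::min(nx, nx - dxo);
          for (int iz = z0; iz < z1; ++iz)
            for (int iy = y0; iy < y1; ++iy) {
              arma::uword v0 = vox(x0, iy, iz, nx, ny);
              double* dst = dxc + vox(x0 + dxo, iy + dyo, iz + dzo, nx, ny);
              for (int ix = 0; ix < (x1 - x0); ++ix)
                dst[ix] += dK(r, v0 + ix);
            }
        }
  }
  dxv.attr("dim") = IntegerVector::create(nx, ny, nz, cin);
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}

// 2x2x2 max pooling, stride 2.  Input dims must be even.
// [[Rcpp::export]]
List cpp_maxpool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2], nc = xd[3];
  if (nx % 2 || ny % 2 || nz % 2) stop("maxpool: dims must be even");
  int ox = nx / 2, oy = ny / 2, oz = nz / 2;
  arma::uword V = (arma::uword)nx * ny * nz, OV = (arma::uword)ox * oy * oz;
  NumericVector y(OV * (arma::uword)nc);
  IntegerVector idx(OV * (arma::uword)nc);
  const double* xp = x.begin();
  for (int c = 0; c < nc; ++c) {
    const double* xc = xp + (arma::uword)c * V;
    arma::uword base = (arma::uword)c * OV;
    for (int iz = 0; iz < oz; ++iz)
      for (int iy = 0; iy < oy; ++iy)
        for (int ix = 0; ix < ox; ++ix) {
          double best = -std::numeric_limits<double>::infinity();
          arma::uword bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                arma::uword v = vox(2 * ix + dx, 2 * iy + dy, 2 * iz + dz, nx, ny);
                if (xc[v] > best) { best = xc[v]; bi = v; }
              }
          arma::uword o = base + vox(ix, iy, iz, ox, oy);
          y[o] = best;
          idx[o] = (int)(bi + (arma::uword)c * V);
        }
  }
  y.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  idx.attr("dim") = IntegerVector::create(ox, oy, oz, nc);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_backward(NumericVector dy, IntegerVector idx, IntegerVector xdim) {
  arma::uword V = (arma::uword)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(V);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> axis_weights(int n_out, int n_in, int f) {
  std::vector<LinW> w(n_out);
  for (int o = 0; o < n_out; ++o) {
    double s = (o + 0.5) / f - 0.5;
    int i0 = (int)std::floor(s);
    double t = s - i0;
    int i1 = i0 + 1;
    if (i0 < 0) { i0 = 0; i1 = 0; t = 0.0; }
    if (i1 > n_in - 1) { i1 = n_in - 1; if (i0 > n_in - 1) i0 = n_in - 1; if (i0 == i1) t = 0.0; }
    w[o] = { i0, i1, 1.0 - t, t };
  }
  return w;
}

// Fixed trilinear upsampling by integer factor f (single channel).
// [[Rcpp::export]]
NumericVector cpp_upsample_forward(NumericVector x, int f) {
  IntegerVector xd = x.attr("dim");
  int nx = xd[0], ny = xd[1], nz = xd[2];
  int ox = nx * f, oy = ny * f, oz = nz * f;
  std::vector<LinW> wx = axis_weights(ox, nx, f), wy = axis_weights(oy, ny, f), wz = axis_weights(oz, nz, f);
  NumericVector out((arma::uword)ox * oy * oz);
  const double* xp = x.begin();
  double* op = out.begin();
  for (int izo = 0; izo < oz; ++izo) {
    const LinW& az = wz[izo];
    for (int iyo = 0; iyo < oy; ++iyo) {
      const LinW& ay = wy[iyo];
      for (int ixo = 0; ixo < ox; ++ixo) {
        const LinW& ax = wx[ixo];
        double v =
          az.w0 * (ay.w0 * (ax.w0 * xp[vox(ax.i0, ay.i0, az.i0, nx, ny)] + ax.w1 * xp[vox(ax.i1, ay.i0, az.i0, nx, ny)]) +
                   ay.w1 * (ax.w0 * xp[vox(ax.i0, ay.i1, az.i0, nx, ny)] + ax.w1 * xp[vox(ax.i1, ay.i1, az.i0, nx, ny)])) +
          az.w1 * (ay.w0 * (ax.w0 * xp[vox(ax.i0, ay.i0, az.i1, nx, ny)] + ax.w1 * xp[vox(ax.i1, ay.i0, az.i1, nx, ny)]) +
                   ay.w1 * (ax.w0 * xp[vox(ax.i0, ay.i1, az.i1, nx, ny)] + ax.w1 * xp[vox(ax.i1, ay.i1, az.i1, nx, ny)]));
        op[vox(ixo, iyo, izo, ox, oy)] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, oz);
  return out;
}

// Adjoint of cpp_upsample_forward.
// [[Rcpp::export]]
NumericVector cpp_upsample_backward(NumericVector dy, int f, IntegerVector xdim) {
  int nx = xdim[0], ny = xdim[1], nz = xdim[2];
  int ox = nx * f, oy = ny * f, oz = nz * f;
  std::vector<LinW> wx = axis_weights(ox, nx, f), wy = axis_weights(oy, ny, f), wz = axis_weights(oz, nz, f);
  NumericVector dx((arma::uword)nx * ny * nz);
  double* dp = dx.begin();
  const double* gp = dy.begin();
  for (int izo = 0; izo < oz; ++izo) {
    const LinW& az = wz[izo];
    for (int iyo = 0; iyo < oy; ++iyo) {
      const LinW& ay = wy[iyo];
      for (int ixo = 0; ixo < ox; ++ixo) {
        const LinW& ax = wx[ixo];
        double g = gp[vox(ixo, iyo, izo, ox, oy)];
        dp[vox(ax.i0, ay.i0, az.i0, nx, ny)] += g * az.w0 * ay.w0 * ax.w0;
        dp[vox(ax.i1, ay.i0, az.i0, nx, ny)] += g * az.w0 * ay.w0 * ax.w1;
        dp[vox(ax.i0, ay.i1, az.i0, nx, ny)] += g * az.w0 * ay.w1 * ax.w0;
        dp[vox(ax.i1, ay.i1, az.i0, nx, ny)] += g * az.w0 * ay.w1 * ax.w1;
        dp[vox(ax.i0, ay.i0, az.i1, nx, ny)] += g * az.w1 * ay.w0 * ax.w0;
        dp[vox(ax.i1, ay.i0, az.i1, nx, ny)] += g * az.w1 * ay.w0 * ax.w1;
        dp[vox(ax.i0, ay.i1, az.i1, nx, ny)] += g * az.w1 * ay.w1 * ax.w0;
        dp[vox(ax.i1, ay.i1, az.i1, nx, ny)] += g * az.w1 * ay.w1 * ax.w1;
      }
    }
  }
  dx.attr("dim") = xdim;
  return dx;
}

// "Very far" sentinel standing in for +infinity: keeps the parabola
// intersection arithmetic finite.  Any true squared distance in a scanned
// head volume is many orders of magnitude below it.
static const double DT_FAR = 1e20;

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher) with grid
// spacing s; operates in place on f (length n), using scratch arrays.
static void dt1d(std::vector<double>& f, int n, double s,
                 std::vector<int>& v, std::vector<double>& z, std::vector<double>& d) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF; z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * s;
    double sp;
    while (true) {
      double vv = (double)v[k] * s;
      sp = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2 * qq - 2 * vv);
      if (sp <= z[k] && k > 0) { --k; } else break;
    }
    if (sp <= z[k]) { // replaces the single remaining parabola
      v[0] = q; z[0] = -INF; z[1] = INF; k = 0;
    } else {
      ++k; v[k] = q; z[k] = sp; z[k + 1] = INF;
    }
  }
  int j = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * s;
    while (z[j + 1] < qq) ++j;
    double vv = (double)v[j] * s;
    d[q] = (qq - vv) * (qq - vv) + f[v[j]];
  }
  for (int q = 0; q < n; ++q) f[q] = std::min(d[q], DT_FAR);
}

// Exact squared Euclidean distance (mm^2) to the nearest foreground voxel
// centre, honouring anisotropic spacing.  Background-only input returns the
// DT_FAR sentinel (>= 1e20) everywhere; callers must reject empty masks.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, NumericVector spacing) {
  IntegerVector md = mask.attr("dim");
  int nx = md[0], ny = md[1], nz = md[2];
  NumericVector d((arma::uword)nx * ny * nz);
  for (R_xlen_t i = 0; i < mask.size(); ++i) d[i] = mask[i] ? 0.0 : DT_FAR;
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), z(nmax + 1), scratch(nmax);
  std::vector<int> v(nmax);
  // x pass
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy) {
      for (int ix = 0; ix < nx; ++ix) f[ix] = d[vox(ix, iy, iz, nx, ny)];
      dt1d(f, nx, spacing[0], v, z, scratch);
      for (int ix = 0; ix < nx; ++ix) d[vox(ix, iy, iz, nx, ny)] = f[ix];
    }
  // y pass
  for (int iz = 0; iz < nz; ++iz)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iy = 0; iy < ny; ++iy) f[iy] = d[vox(ix, iy, iz, nx, ny)];
      dt1d(f, ny, spacing[1], v, z, scratch);
      for (int iy = 0; iy < ny; ++iy) d[vox(ix, iy, iz, nx, ny)] = f[iy];
    }
  // z pass
  for (int iy = 0; iy < ny; ++iy)
    for (int ix = 0; ix < nx; ++ix) {
      for (int iz = 0; iz < nz; ++iz) f[iz] = d[vox(ix, iy, iz, nx, ny)];
      dt1d(f, nz, spacing[2], v, z, scratch);
      for (int iz = 0; iz < nz; ++iz) d[vox(ix, iy, iz, nx, ny)] = f[iz];
    }
  d.attr("dim") = md;
  return d;
}

// 6-connected component labelling of a binary lattice.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask) {
  IntegerVector md = mask.attr("dim");
  int nx = md[0], ny = md[1], nz = md[2];
  IntegerVector lab(mask.size());
  int next = 0;
  std::queue<arma::uword> q;
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        arma::uword v = vox(ix, iy, iz, nx, ny);
        if (!mask[v] || lab[v]) continue;
        lab[v] = ++next;
        q.push(v);
        while (!q.empty()) {
          arma::uword u = q.front(); q.pop();
          int ux = u % nx, uy = (u / nx) % ny, uz = u / ((arma::uword)nx * ny);
          for (int k = 0; k < 6; ++k) {
            int jx = ux + dx[k], jy = uy + dy[k], jz = uz + dz[k];
            if (jx < 0 || jy < 0 || jz < 0 || jx >= nx || jy >= ny || jz >= nz) continue;
            arma::uword w = vox(jx, jy, jz, nx, ny);
            if (mask[w] && !lab[w]) { lab[w] = next; q.push(w); }
          }
        }
      }
  lab.attr("dim") = md;
  return lab;
}

static IntegerVector box3(IntegerVector m, bool dilate) {
  IntegerVector md = m.attr("dim");
  int nx = md[0], ny = md[1], nz = md[2];
  IntegerVector out(m.size());
  for (int iz = 0; iz < nz; ++iz)
    for (int iy = 0; iy < ny; ++iy)
      for (int ix = 0; ix < nx; ++ix) {
        int acc = dilate ? 0 : 1;
        for (int dz = -1; dz <= 1 && (dilate ? !acc : acc); ++dz)
          for (int dy = -1; dy <= 1 && (dilate ? !acc : acc); ++dy)
            for (int dx = -1; dx <= 1 && (dilate ? !acc : acc); ++dx) {
              int jx = ix + dx, jy = iy + dy, jz = iz + dz;
              int val = 0; // outside lattice counts as background
              if (jx >= 0 && jy >= 0 && jz >= 0 && jx < nx && jy < ny && jz < nz)
                val = m[vox(jx, jy, jz, nx, ny)];
              if (dilate) { if (val) acc = 1; } else { if (!val) acc = 0; }
            }
        out[vox(ix, iy, iz, nx, ny)] = acc;
      }
  out.attr("dim") = md;
  return out;
}

// Morphological closing (dilate then erode) with a 3x3x3 box.
// [[Rcpp::export]]
IntegerVector cpp_boxclose(IntegerVector mask) {
  return box3(box3(mask, true), false);
}

// Morphological opening (erode then dilate) with a 3x3x3 box; removes
// isolated noise voxels.
// [[Rcpp::export]]
IntegerVector cpp_boxopen(IntegerVector mask) {
  return box3(box3(mask, false), true);
}
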