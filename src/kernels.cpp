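#include <Rcpp.h>
using namespace Rcpp;

// Even-odd (crossing number) containment test for a batch of points against
// one closed polygon ring. Points lying on an edge (within eps, in mm) count
// as inside: the boundary tie rule used throughout the package.
// [[Rcpp::export]]
LogicalVector cpp_points_in_polygon(NumericVector px, NumericVector py,
                                    NumericMatrix verts, double eps) {
  const int np = px.size();
  const int nv = verts.nrow();
  LogicalVector out(np);
  for (int i = 0; i < np; ++i) {
    const double x = px[i], y = py[i];
    bool inside = false, boundary = false;
    for (int a = 0, b = nv - 1; a < nv; b = a++) {
      const double xa = verts(a, 0), ya = verts(a, 1);
      const double xb = verts(b, 0), yb = verts(b, 1);
      // boundary check: distance from point to segment ab
      const double dx = xb - xa, dy = yb - ya;
      const double L2 = dx * dx + dy * dy;
      double t = L2 > 0 ? ((x - xa) * dx + (y - ya) * dy) / L2 : 0.0;
      t = t < 0 ? 0 : (t > 1 ? 1 : t);
      const double ex = xa + t * dx - x, ey = ya + t * dy - y;
      if (ex * ex + ey * ey <= eps * eps) { boundary = true; break; }
      // crossing number: edge straddles the horizontal ray?
      if ((ya > y) != (yb > y)) {
        const double xcross = xa + (y - ya) / (yb - ya) * (xb - xa);
        if (x < xcross) inside = !inside;
      }
    }
    out[i] = boundary || inside;
  }
  return out;
}

// Parity-accumulating variant for multi-ring slices: flips parity per ring
// so that a point inside an even number of rings ends up outside (annuli).
// `parity` is modified in place and returned.
// [[Rcpp::export]]
IntegerVector cpp_accumulate_ring(IntegerVector parity, NumericVector px,
                                  NumericVector py, NumericMatrix verts,
                                  double eps) {
  LogicalVector in_ring = cpp_points_in_polygon(px, py, verts, eps);
  for (int i = 0; i < parity.size(); ++i)
    if (in_ring[i]) parity[i] ^= 1;
  return parity;
}

static inline double catmull_rom_w(double t, int tap) {
  // Catmull-Rom cubic convolution weights, taps at offsets -1, 0, 1, 2
  switch (tap) {
    case 0: return 0.5 * (-t + 2.0 * t * t - t * t * t);
    case 1: return 0.5 * (2.0 - 5.0 * t * t + 3.0 * t * t * t);
    case 2: return 0.5 * (t + 4.0 * t * t - 3.0 * t * t * t);
    default: return 0.5 * (-t * t + t * t * t);
  }
}

// Batch interpolation of a scalar field on a regular 3-D lattice.
// method 0 = trilinear, 1 = tricubic Catmull-Rom convolution.
// Points outside the lattice hull are clamped to it; the number of clamped
// points is returned alongside the values.
// [[Rcpp::export]]
List cpp_interp3(NumericVector vals, IntegerVector dims, NumericVector origin,
                 NumericVector spacing, NumericVector px, NumericVector py,
                 NumericVector pz, int method) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = px.size();
  NumericVector out(np);
  int n_clamped = 0;
  const double *v = REAL(vals);
  for (int i = 0; i < np; ++i) {
    double gx = (px[i] - origin[0]) / spacing[0];
    double gy = (py[i] - origin[1]) / spacing[1];
    double gz = (pz[i] - origin[2]) / spacing[2];
    bool clamped = false;
    if (gx < 0) { gx = 0; clamped = true; }
    if (gy < 0) { gy = 0; clamped = true; }
    if (gz < 0) { gz = 0; clamped = true; }
    if (gx > nx - 1) { gx = nx - 1; clamped = true; }
    if (gy > ny - 1) { gy = ny - 1; clamped = true; }
    if (gz > nz - 1) { gz = nz - 1; clamped = true; }
    if (clamped) ++n_clamped;
    if (method == 0) {
      int i0 = (int)std::floor(gx); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
      int j0 = (int)std::floor(gy); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
      int k0 = (int)std::floor(gz); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
      const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
      double acc = 0.0;
      for (int a = 0; a < 2; ++a)
        for (int b = 0; b < 2; ++b)
          for (int c = 0; c < 2; ++c) {
            const double w = (a ? fx : 1 - fx) * (b ? fy : 1 - fy) * (c ? fz : 1 - fz);
            acc += w * v[(i0 + a) + (size_t)nx * ((j0 + b) + (size_t)ny * (k0 + c))];
          }
      out[i] = acc;
    } else {
      // anchor so that taps i0-1 .. i0+2 stay within the lattice
      int i0 = (int)std::floor(gx); if (i0 < 1) i0 = 1; if (i0 > nx - 3) i0 = nx - 3;
      int j0 = (int)std::floor(gy); if (j0 < 1) j0 = 1; if (j0 > ny - 3) j0 = ny - 3;
      int k0 = (int)std::floor(gz); if (k0 < 1) k0 = 1; if (k0 > nz - 3) k0 = nz - 3;
      const double fx = gx - i0, fy = gy - j0, fz = gz - k0;
      double wx[4], wy[4], wz[4];
      for (int t = 0; t < 4; ++t) {
        wx[t] = catmull_rom_w(fx, t);
        wy[t] = catmull_rom_w(fy, t);
        wz[t] = catmull_rom_w(fz, t);
      }
      double acc = 0.0;
      for (int c = 0; c < 4; ++c) {
        const size_t zoff = (size_t)ny * (k0 - 1 + c);
        for (int b = 0; b < 4; ++b) {
          const size_t yoff = (size_t)nx * ((j0 - 1 + b) + zoff);
          double row = 0.0;
          for (int a = 0; a < 4; ++a)
            row += wx[a] * v[(i0 - 1 + a) + yoff];
          acc += row * wy[b] * wz[c];
        }
      }
      out[i] = acc;
    }
  }
  return List::create(_["values"] = out, _["n_clamped"] = n_clamped);
}
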