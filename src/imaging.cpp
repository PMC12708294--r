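#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Map output voxel index v_out (0-based) through the 4x4 matrix M into the
// source grid, sample trilinearly. M acts on homogeneous 0-based indices.
// [[Rcpp::export(name = ".cpp_resample_affine")]]
NumericVector cpp_resample_affine(NumericVector src, IntegerVector src_dim,
                                  NumericMatrix M, IntegerVector out_dim,
                                  double outside, bool nearest) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int ox = out_dim[0], oy = out_dim[1], oz = out_dim[2];
  NumericVector out((R_xlen_t)ox * oy * oz);
  const double *s = src.begin();
  double m00=M(0,0),m01=M(0,1),m02=M(0,2),m03=M(0,3);
  double m10=M(1,0),m11=M(1,1),m12=M(1,2),m13=M(1,3);
  double m20=M(2,0),m21=M(2,1),m22=M(2,2),m23=M(2,3);
  R_xlen_t idx = 0;
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i, ++idx) {
        double x = m00*i + m01*j + m02*k + m03;
        double y = m10*i + m11*j + m12*k + m13;
        double z = m20*i + m21*j + m22*k + m23;
        if (nearest) {
          int xi = (int)std::lround(x), yi = (int)std::lround(y), zi = (int)std::lround(z);
          if (xi < 0 || yi < 0 || zi < 0 || xi >= sx || yi >= sy || zi >= sz) {
            out[idx] = outside;
          } else {
            out[idx] = s[(R_xlen_t)xi + (R_xlen_t)sx*(yi + (R_xlen_t)sy*zi)];
          }
          continue;
        }
        if (x < 0 || y < 0 || z < 0 || x > sx - 1 || y > sy - 1 || z > sz - 1) {
          out[idx] = outside;
          continue;
        }
        int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
        if (x0 == sx - 1) x0--;
        if (y0 == sy - 1) y0--;
        if (z0 == sz - 1) z0--;
        double fx = x - x0, fy = y - y0, fz = z - z0;
        R_xlen_t b = (R_xlen_t)x0 + (R_xlen_t)sx*(y0 + (R_xlen_t)sy*z0);
        R_xlen_t dy = sx, dz = (R_xlen_t)sx*sy;
        double c000 = s[b],          c100 = s[b+1];
        double c010 = s[b+dy],       c110 = s[b+dy+1];
        double c001 = s[b+dz],       c101 = s[b+dz+1];
        double c011 = s[b+dy+dz],    c111 = s[b+dy+dz+1];
        double c00 = c000*(1-fx) + c100*fx;
        double c10 = c010*(1-fx) + c110*fx;
        double c01 = c001*(1-fx) + c101*fx;
        double c11 = c011*(1-fx) + c111*fx;
        double c0 = c00*(1-fy) + c10*fy;
        double c1 = c01*(1-fy) + c11*fy;
        out[idx] = c0*(1-fz) + c1*fz;
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary mask; connectivity 6, 18 or 26.
// Returns integer labels 1..ncomp (0 = background), BFS flood fill.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ad = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ad == 0) continue;
        if (connectivity == 6 && ad > 1) continue;
        if (connectivity == 18 && ad > 2) continue;
        offs.push_back({dx, dy, dz});
      }
  int cur = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || lab[start]) continue;
    lab[start] = ++cur;
    q.push(start);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx*ny));
      for (auto &o : offs) {
        int ii = i + o[0], jj = j + o[1], kk = k + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) continue;
        R_xlen_t w = (R_xlen_t)ii + (R_xlen_t)nx*(jj + (R_xlen_t)ny*kk);
        if (mask[w] && !lab[w]) { lab[w] = cur; q.push(w); }
      }
    }
  }
  return lab;
}

// Trilinear sampling at scattered (continuous, 0-based) voxel coordinates.
// pts is 3 x m. Out-of-grid points get `outside`.
// [[Rcpp::export(name = ".cpp_sample_points")]]
NumericVector cpp_sample_points(NumericVector src, IntegerVector src_dim,
                                NumericMatrix pts, double outside) {
  const int sx = src_dim[0], sy = src_dim[1], sz = src_dim[2];
  const int m = pts.ncol();
  NumericVector out(m);
  const double *s = src.begin();
  for (int p = 0; p < m; ++p) {
    double x = pts(0, p), y = pts(1, p), z = pts(2, p);
    if (x < 0 || y < 0 || z < 0 || x > sx - 1 || y > sy - 1 || z > sz - 1) {
      out[p] = outside;
      continue;
    }
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 == sx - 1) x0--;
    if (y0 == sy - 1) y0--;
    if (z0 == sz - 1) z0--;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    R_xlen_t b = (R_xlen_t)x0 + (R_xlen_t)sx*(y0 + (R_xlen_t)sy*z0);
    R_xlen_t dy = sx, dz = (R_xlen_t)sx*sy;
    double c00 = s[b]*(1-fx) + s[b+1]*fx;
    double c10 = s[b+dy]*(1-fx) + s[b+dy+1]*fx;
    double c01 = s[b+dz]*(1-fx) + s[b+dz+1]*fx;
    double c11 = s[b+dy+dz]*(1-fx) + s[b+dy+dz+1]*fx;
    double c0 = c00*(1-fy) + c10*fy;
    double c1 = c01*(1-fy) + c11*fy;
    out[p] = c0*(1-fz) + c1*fz;
  }
  return out;
}

// Binary erosion/dilation with a discrete ball of radius r (voxels).
// [[Rcpp::export(name = ".cpp_morph_ball")]]
LogicalVector cpp_morph_ball(LogicalVector mask, IntegerVector dim, double r, bool erode) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  int ri = (int)std::floor(r);
  std::vector<std::array<int,3>> offs;
  for (int dz = -ri; dz <= ri; ++dz)
    for (int dy = -ri; dy <= ri; ++dy)
      for (int dx = -ri; dx <= ri; ++dx)
        if (dx*dx + dy*dy + dz*dz <= r*r) offs.push_back({dx, dy, dz});
  for (R_xlen_t v = 0; v < n; ++v) {
    int i = (int)(v % nx), j = (int)((v / nx) % ny), k = (int)(v / ((R_xlen_t)nx*ny));
    bool acc = erode;  // erode: AND over neighbourhood; dilate: OR
    for (auto &o : offs) {
      int ii = i + o[0], jj = j + o[1], kk = k + o[2];
      bool val;
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) val = false;
      else val = mask[(R_xlen_t)ii + (R_xlen_t)nx*(jj + (R_xlen_t)ny*kk)];
      if (erode) { if (!val) { acc = false; break; } }
      else       { if (val)  { acc = true;  break; } }
    }
    out[v] = acc;
  }
  return out;
}
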