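#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Amanatides-Woo / Siddon traversal of a regular voxel grid.
// Volume is an R array [nx, ny, nz] (column-major, x fastest); voxels are
// cubes of side `vs` mm; org is the world position (mm) of the corner of
// voxel (1,1,1).  Ray runs from src to dst; intersection lengths are exact
// for the segment src->dst clipped to the grid bounding box.
//
// Returns number of traversed voxels; writes 0-based linear indices into
// idx[] and lengths (mm) into len[].  Buffers must hold nx+ny+nz+4 entries.
static int trace_ray_core(const double *src, const double *dst,
                          const int *n, double vs, const double *org,
                          int *idx, double *len) {
  double d[3];
  double L2 = 0.0;
  for (int a = 0; a < 3; ++a) {
    d[a] = dst[a] - src[a];
    L2 += d[a] * d[a];
  }
  const double L = std::sqrt(L2);
  if (L == 0.0) return 0;

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    const double lo = org[a], hi = org[a] + n[a] * vs;
    if (d[a] == 0.0) {
      if (src[a] < lo || src[a] >= hi) return 0;
    } else {
      double t1 = (lo - src[a]) / d[a];
      double t2 = (hi - src[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax <= tmin) return 0;

  // start voxel from a point nudged just inside the entry face
  const double tin = tmin + 1e-12 * (tmax - tmin);
  int i[3], step[3];
  double tNext[3], tDelta[3];
  for (int a = 0; a < 3; ++a) {
    const double p = src[a] + tin * d[a];
    int ia = (int)std::floor((p - org[a]) / vs);
    if (ia < 0) ia = 0;
    if (ia >= n[a]) ia = n[a] - 1;
    i[a] = ia;
    if (d[a] > 0.0) {
      step[a] = 1;
      tDelta[a] = vs / d[a];
      tNext[a] = (org[a] + (ia + 1) * vs - src[a]) / d[a];
    } else if (d[a] < 0.0) {
      step[a] = -1;
      tDelta[a] = -vs / d[a];
      tNext[a] = (org[a] + ia * vs - src[a]) / d[a];
    } else {
      step[a] = 0;
      tDelta[a] = R_PosInf;
      tNext[a] = R_PosInf;
    }
  }

  int count = 0;
  double tcur = tmin;
  const double teps = 1e-12;
  while (tcur < tmax - teps) {
    int a = 0;
    if (tNext[1] < tNext[a]) a = 1;
    if (tNext[2] < tNext[a]) a = 2;
    const double tstop = (tNext[a] < tmax) ? tNext[a] : tmax;
    const double seg = (tstop - tcur) * L;
    if (seg > 0.0) {
      idx[count] = i[0] + n[0] * (i[1] + n[1] * i[2]);
      len[count] = seg;
      ++count;
    }
    tcur = tstop;
    if (tNext[a] >= tmax) break;
    i[a] += step[a];
    if (i[a] < 0 || i[a] >= n[a]) break;
    tNext[a] += tDelta[a];
  }
  return count;
}

// [[Rcpp::export]]
List cpp_trace_ray(NumericVector src, NumericVector dst,
                   IntegerVector dims, double voxel_size,
                   NumericVector origin) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  std::vector<int> idx(n[0] + n[1] + n[2] + 4);
  std::vector<double> len(idx.size());
  const double s[3] = {src[0], src[1], src[2]};
  const double e[3] = {dst[0], dst[1], dst[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const int m = trace_ray_core(s, e, n, voxel_size, o, idx.data(), len.data());
  IntegerVector out_idx(m);
  NumericVector out_len(m);
  for (int k = 0; k < m; ++k) {
    out_idx[k] = idx[k] + 1;  // 1-based linear index into the R array
    out_len[k] = len[k];
  }
  return List::create(_["index"] = out_idx, _["length"] = out_len);
}

// Forward projection of one view: line integral of vol along the ray from
// src to every detector pixel center given in (px, py, pz) [rows x cols].
// [[Rcpp::export]]
NumericMatrix cpp_project_view(NumericVector vol, IntegerVector dims,
                               double voxel_size, NumericVector origin,
                               NumericVector src,
                               NumericMatrix px, NumericMatrix py,
                               NumericMatrix pz) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const double s[3] = {src[0], src[1], src[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const int nr = px.nrow(), nc = px.ncol();
  NumericMatrix out(nr, nc);
  std::vector<int> idx(n[0] + n[1] + n[2] + 4);
  std::vector<double> len(idx.size());
  const double *v = REAL(vol);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const double e[3] = {px(r, c), py(r, c), pz(r, c)};
      const int m = trace_ray_core(s, e, n, voxel_size, o,
                                   idx.data(), len.data());
      double acc = 0.0;
      for (int k = 0; k < m; ++k) acc += v[idx[k]] * len[k];
      out(r, c) = acc;
    }
  }
  return out;
}

// One ART (Kaczmarz) sweep over the usable rays of a single view.
// vol is modified IN PLACE (the R wrapper passes a private copy); rays are
// visited in column-major detector order.  Rays with use[r,c] == FALSE are
// skipped, as are rays that miss the grid (sum a^2 == 0, counted).
// Returns c(sq_update, sq_residual_before, n_used, n_skipped).
// [[Rcpp::export]]
NumericVector cpp_art_view(NumericVector vol, IntegerVector dims,
                           double voxel_size, NumericVector origin,
                           NumericVector src,
                           NumericMatrix px, NumericMatrix py,
                           NumericMatrix pz,
                           NumericMatrix p, LogicalMatrix use,
                           double lambda) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const double s[3] = {src[0], src[1], src[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const int nr = px.nrow(), nc = px.ncol();
  std::vector<int> idx(n[0] + n[1] + n[2] + 4);
  std::vector<double> len(idx.size());
  double *v = REAL(vol);
  double sq_update = 0.0, sq_resid = 0.0;
  int n_used = 0, n_skipped = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!use(r, c)) continue;
      const double e[3] = {px(r, c), py(r, c), pz(r, c)};
      const int m = trace_ray_core(s, e, n, voxel_size, o,
                                   idx.data(), len.data());
      double dot = 0.0, a2 = 0.0;
      for (int k = 0; k < m; ++k) {
        dot += v[idx[k]] * len[k];
        a2 += len[k] * len[k];
      }
      if (a2 <= 0.0) {
        ++n_skipped;
        continue;
      }
      const double resid = p(r, c) - dot;
      const double scale = lambda * resid / a2;
      for (int k = 0; k < m; ++k) {
        const double du = scale * len[k];
        v[idx[k]] += du;
        sq_update += du * du;
      }
      sq_resid += resid * resid;
      ++n_used;
    }
  }
  return NumericVector::create(sq_update, sq_resid,
                               (double)n_used, (double)n_skipped);
}

// Residual (sum of squares of p - A mu over usable rays) without updating.
// [[Rcpp::export]]
NumericVector cpp_view_residual(NumericVector vol, IntegerVector dims,
                                double voxel_size, NumericVector origin,
                                NumericVector src,
                                NumericMatrix px, NumericMatrix py,
                                NumericMatrix pz,
                                NumericMatrix p, LogicalMatrix use) {
  const int n[3] = {dims[0], dims[1], dims[2]};
  const double s[3] = {src[0], src[1], src[2]};
  const double o[3] = {origin[0], origin[1], origin[2]};
  const int nr = px.nrow(), nc = px.ncol();
  std::vector<int> idx(n[0] + n[1] + n[2] + 4);
  std::vector<double> len(idx.size());
  const double *v = REAL(vol);
  double sq = 0.0;
  int n_used = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!use(r, c)) continue;
      const double e[3] = {px(r, c), py(r, c), pz(r, c)};
      const int m = trace_ray_core(s, e, n, voxel_size, o,
                                   idx.data(), len.data());
      double dot = 0.0;
      for (int k = 0; k < m; ++k) dot += v[idx[k]] * len[k];
      const double resid = p(r, c) - dot;
      sq += resid * resid;
      ++n_used;
    }
  }
  return NumericVector::create(sq, (double)n_used);
}

static inline double sq(double x) { return x * x; }

// Total variation of the volume: sum over voxels (x,y,z >= 2, 1-based) of
// sqrt(dx^2 + dy^2 + dz^2 + delta) with backward differences.
// [[Rcpp::export]]
double cpp_tv_value(NumericVector vol, IntegerVector dims, double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  double acc = 0.0;
  for (int k = 1; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        const int c = i + nx * (j + ny * k);
        const double dx = v[c] - v[c - 1];
        const double dy = v[c] - v[c - nx];
        const double dz = v[c] - v[c - nx * ny];
        acc += std::sqrt(sq(dx) + sq(dy) + sq(dz) + delta);
      }
  return acc;
}

// Gradient of cpp_tv_value with respect to every voxel.
// [[Rcpp::export]]
NumericVector cpp_tv_grad(NumericVector vol, IntegerVector dims,
                          double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *v = REAL(vol);
  NumericVector grad(vol.size());
  double *g = REAL(grad);
  for (int k = 1; k < nz; ++k)
    for (int j = 1; j < ny; ++j)
      for (int i = 1; i < nx; ++i) {
        const int c = i + nx * (j + ny * k);
        const double dx = v[c] - v[c - 1];
        const double dy = v[c] - v[c - nx];
        const double dz = v[c] - v[c - nx * ny];
        const double den = std::sqrt(sq(dx) + sq(dy) + sq(dz) + delta);
        if (den > 0.0) {
          const double inv = 1.0 / den;
          g[c] += (dx + dy + dz) * inv;
          g[c - 1] -= dx * inv;
          g[c - nx] -= dy * inv;
          g[c - nx * ny] -= dz * inv;
        }
      }
  return grad;
}
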