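#include <Rcpp.h>
using namespace Rcpp;

// Exact amortized voxel traversal (Amanatides & Woo) of rays through a
// 3D label grid. Labels: 0 background, 182 cytoplasm, 201 nucleus.
// The whole medium (background/cytoplasm/nucleus) slows the particle at the
// water rate, so the slowing path is the geometric ray parameter itself:
// segments beyond s_max (the distance from the ray origin at which the
// particle stops) are not scored, and chords are truncated at s_max.
// Returns an n x 3 matrix per ray:
//   [0] t_nuc: distance from the ray origin to the first nucleus voxel
//       (-1 when the nucleus is never reached),
//   [1] tau2: total cytoplasm path length,
//   [2] tau3: total nucleus path length,
// all in the same length unit as voxel sizes and origins (um).
//
// labels: integer vector with dim attribute (nx, ny, nz), x fastest.
// voxel:  length-3 voxel size (um). origin: world position of the corner of
// voxel (0,0,0) (um). starts/dirs: n x 3 matrices (um, unit vectors).
// [[Rcpp::export(name = ".cpp_trace_rays")]]
NumericMatrix cpp_trace_rays(IntegerVector labels, NumericVector voxel,
                             NumericVector origin, NumericMatrix starts,
                             NumericMatrix dirs, NumericVector s_max) {
  IntegerVector dim = labels.attr("dim");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = starts.nrow();
  NumericMatrix out(n, 3);
  const double vx = voxel[0], vy = voxel[1], vz = voxel[2];
  const double bx0 = origin[0], by0 = origin[1], bz0 = origin[2];
  const double bx1 = bx0 + nx * vx, by1 = by0 + ny * vy, bz1 = bz0 + nz * vz;
  const double eps = 1e-12;
  const int *lab = INTEGER(labels);

  for (int i = 0; i < n; ++i) {
    double px = starts(i, 0), py = starts(i, 1), pz = starts(i, 2);
    double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    const double smax = s_max[i];
    double tau2 = 0.0, tau3 = 0.0, t_nuc = -1.0;

    // clip ray to the grid bounding box and the stopping point: [t0, t1]
    double t0 = 0.0, t1 = smax;
    bool miss = smax <= 0;
    double lo[3] = {bx0, by0, bz0}, hi[3] = {bx1, by1, bz1};
    double p[3] = {px, py, pz}, d[3] = {dx, dy, dz};
    for (int k = 0; k < 3 && !miss; ++k) {
      if (std::fabs(d[k]) < eps) {
        if (p[k] < lo[k] || p[k] > hi[k]) miss = true;
      } else {
        double ta = (lo[k] - p[k]) / d[k];
        double tb = (hi[k] - p[k]) / d[k];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) miss = true;
      }
    }
    if (!miss && t1 > t0) {
      double t = t0 + eps;
      double cx = px + dx * t, cy = py + dy * t, cz = pz + dz * t;
      int ix = (int)std::floor((cx - bx0) / vx);
      int iy = (int)std::floor((cy - by0) / vy);
      int iz = (int)std::floor((cz - bz0) / vz);
      ix = std::min(std::max(ix, 0), nx - 1);
      iy = std::min(std::max(iy, 0), ny - 1);
      iz = std::min(std::max(iz, 0), nz - 1);
      const int stepx = dx > 0 ? 1 : (dx < 0 ? -1 : 0);
      const int stepy = dy > 0 ? 1 : (dy < 0 ? -1 : 0);
      const int stepz = dz > 0 ? 1 : (dz < 0 ? -1 : 0);
      const double inf = std::numeric_limits<double>::infinity();
      double tdx = stepx ? vx / std::fabs(dx) : inf;
      double tdy = stepy ? vy / std::fabs(dy) : inf;
      double tdz = stepz ? vz / std::fabs(dz) : inf;
      // parameter value at which the ray crosses the next voxel boundary
      double tmx = stepx ? ((bx0 + (ix + (stepx > 0)) * vx) - px) / dx : inf;
      double tmy = stepy ? ((by0 + (iy + (stepy > 0)) * vy) - py) / dy : inf;
      double tmz = stepz ? ((bz0 + (iz + (stepz > 0)) * vz) - pz) / dz : inf;
      double tcur = t0;
      while (tcur < t1) {
        double tnext = std::min(std::min(tmx, tmy), std::min(tmz, t1));
        double seg = tnext - tcur;
        if (seg > 0) {
          int v = lab[(size_t)ix + nx * ((size_t)iy + (size_t)ny * iz)];
          if (v == 201) {
            if (t_nuc < 0) t_nuc = tcur;
            tau3 += seg;
          } else if (v == 182) {
            tau2 += seg;
          }
        }
        tcur = tnext;
        if (tmx <= tmy && tmx <= tmz) { ix += stepx; tmx += tdx; }
        else if (tmy <= tmz)          { iy += stepy; tmy += tdy; }
        else                          { iz += stepz; tmz += tdz; }
        if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz)
          break;
      }
    }
    out(i, 0) = t_nuc;
    out(i, 1) = tau2;
    out(i, 2) = tau3;
  }
  return out;
}
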