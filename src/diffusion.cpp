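// Random-walk core: 3-D Gaussian steps with compartment-specific diffusivity,
// probabilistic membrane transmission/reflection on sphere surfaces, periodic
// minimum-image geometry. Positions are kept unwrapped so displacements from
// the start are exact; geometry queries wrap on the fly.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double wrap1(double x, double L) {
  double w = x - L * std::floor(x / L);
  if (w >= L) w -= L; // guard against rounding at the upper edge
  return w;
}

// minimum-image component difference
static inline double mimg(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

// Smallest t in (tmin, tmax] where |d + t*u| == r, for a ray starting at
// relative offset d from the sphere centre. Returns -1 if none.
static inline double sphere_hit(const double d[3], const double u[3],
                                double r, double tmin, double tmax) {
  // |d|^2 + 2 t d.u + t^2 = r^2  (u is unit)
  double b = d[0]*u[0] + d[1]*u[1] + d[2]*u[2];
  double c = d[0]*d[0] + d[1]*d[1] + d[2]*d[2] - r*r;
  double disc = b*b - c;
  if (disc < 0) return -1.0;
  double s = std::sqrt(disc);
  double t1 = -b - s, t2 = -b + s;
  if (t1 > tmin && t1 <= tmax) return t1;
  if (t2 > tmin && t2 <= tmax) return t2;
  return -1.0;
}

// [[Rcpp::export]]
IntegerVector mc_locate(NumericMatrix points, NumericMatrix centers,
                        NumericVector radii, NumericVector box) {
  int np = points.nrow(), nc = centers.nrow();
  IntegerVector out(np);
  for (int i = 0; i < np; ++i) {
    double w[3];
    for (int k = 0; k < 3; ++k) w[k] = wrap1(points(i, k), box[k]);
    int hit = 0;
    for (int j = 0; j < nc; ++j) {
      double dd = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = mimg(w[k] - centers(j, k), box[k]);
        dd += d * d;
      }
      if (dd <= radii[j] * radii[j]) { hit = j + 1; break; }
    }
    out[i] = hit; // 0 = extracellular, else 1-based cell index
  }
  return out;
}

struct VoxelGrid {
  int nv;
  double vx[3];
  std::vector< std::vector<int> > cand; // candidate sphere indices per voxel
  int index(const double w[3], const double box[3]) const {
    int ix[3];
    for (int k = 0; k < 3; ++k) {
      ix[k] = (int)(w[k] / vx[k]);
      if (ix[k] >= nv) ix[k] = nv - 1;
      if (ix[k] < 0) ix[k] = 0;
    }
    return (ix[2] * nv + ix[1]) * nv + ix[0];
  }
};

static void build_grid(VoxelGrid &g, const NumericMatrix &centers,
                       const NumericVector &radii, const double box[3],
                       double reach) {
  int nc = centers.nrow();
  g.nv = 6;
  for (int k = 0; k < 3; ++k) g.vx[k] = box[k] / g.nv;
  g.cand.assign(g.nv * g.nv * g.nv, std::vector<int>());
  double halfdiag = 0.5 * std::sqrt(g.vx[0]*g.vx[0] + g.vx[1]*g.vx[1] + g.vx[2]*g.vx[2]);
  for (int iz = 0; iz < g.nv; ++iz)
    for (int iy = 0; iy < g.nv; ++iy)
      for (int ix = 0; ix < g.nv; ++ix) {
        double vc[3] = { (ix + 0.5) * g.vx[0], (iy + 0.5) * g.vx[1], (iz + 0.5) * g.vx[2] };
        std::vector<int> &lst = g.cand[(iz * g.nv + iy) * g.nv + ix];
        for (int j = 0; j < nc; ++j) {
          double dd = 0.0;
          for (int k = 0; k < 3; ++k) {
            double d = mimg(vc[k] - centers(j, k), box[k]);
            dd += d * d;
          }
          double thr = radii[j] + reach + halfdiag;
          if (dd <= thr * thr) lst.push_back(j);
        }
      }
}

// Propagate walkers n_steps steps. comp: 0 = extracellular, else 1-based cell.
// p_exit / p_enter: per-cell transmission probability for inside->out and
// outside->in crossings (equal under the intracellular-reference convention).
// Uses R's RNG so set.seed() on the R side governs reproducibility.
// [[Rcpp::export]]
List mc_propagate(NumericMatrix pos, IntegerVector comp,
                  NumericMatrix centers, NumericVector radii,
                  NumericVector p_exit, NumericVector p_enter,
                  NumericVector box_in,
                  double sigma_in, double sigma_ex,
                  int n_steps, int max_crossings, bool rescale_residual) {
  RNGScope scope;
  int nw = pos.nrow(), nc = centers.nrow();
  double box[3] = { box_in[0], box_in[1], box_in[2] };
  NumericMatrix out = clone(pos);
  IntegerVector cmp = clone(comp);

  const double eps = 1e-7; // boundary nudge, μm
  double max_step = 10.0 * std::max(sigma_in, sigma_ex);
  VoxelGrid grid;
  if (nc > 0) build_grid(grid, centers, radii, box, max_step);

  for (int step = 0; step < n_steps; ++step) {
    for (int i = 0; i < nw; ++i) {
      int c = cmp[i];
      double sigma = (c > 0) ? sigma_in : sigma_ex;
      double sv[3];
      for (int k = 0; k < 3; ++k) sv[k] = sigma * norm_rand();
      double L = std::sqrt(sv[0]*sv[0] + sv[1]*sv[1] + sv[2]*sv[2]);
      if (L <= 0 || nc == 0) { // free space: take the step verbatim
        for (int k = 0; k < 3; ++k) out(i, k) += sv[k];
        continue;
      }
      double u[3] = { sv[0]/L, sv[1]/L, sv[2]/L };
      double x[3] = { out(i, 0), out(i, 1), out(i, 2) };
      int crossings = 0;
      while (L > 0) {
        double w[3];
        for (int k = 0; k < 3; ++k) w[k] = wrap1(x[k], box[k]);
        int hit_cell = -1;
        double t_hit = -1.0;
        double dh[3] = {0, 0, 0};
        if (c > 0) {
          // inside cell c-1: only its own surface can be crossed
          int j = c - 1;
          double d[3];
          for (int k = 0; k < 3; ++k) d[k] = mimg(w[k] - centers(j, k), box[k]);
          double t = sphere_hit(d, u, radii[j], 0.0, L);
          if (t > 0) { hit_cell = j; t_hit = t; for (int k = 0; k < 3; ++k) dh[k] = d[k]; }
        } else {
          const std::vector<int> &lst = grid.cand[grid.index(w, box)];
          for (size_t m = 0; m < lst.size(); ++m) {
            int j = lst[m];
            double d[3];
            for (int k = 0; k < 3; ++k) d[k] = mimg(w[k] - centers(j, k), box[k]);
            double t = sphere_hit(d, u, radii[j], 0.0, L);
            if (t > 0 && (t_hit < 0 || t < t_hit)) {
              hit_cell = j; t_hit = t; for (int k = 0; k < 3; ++k) dh[k] = d[k];
            }
          }
        }
        if (hit_cell < 0) { // no membrane encountered within remaining length
          for (int k = 0; k < 3; ++k) x[k] += L * u[k];
          break;
        }
        if (++crossings > max_crossings)
          stop("walker exceeded max_crossings membrane intersections in one step; reduce the time step tau");
        // advance to the membrane
        for (int k = 0; k < 3; ++k) x[k] += t_hit * u[k];
        L -= t_hit;
        // outward unit normal at the intersection point
        double nrm[3];
        for (int k = 0; k < 3; ++k) nrm[k] = (dh[k] + t_hit * u[k]) / radii[hit_cell];
        double p = (c > 0) ? p_exit[hit_cell] : p_enter[hit_cell];
        if (unif_rand() < p) {
          // transmit: switch compartment, rescale remaining length by the
          // ratio of step scales (sqrt(D_new/D_old))
          double s_old = (c > 0) ? sigma_in : sigma_ex;
          c = (c > 0) ? 0 : hit_cell + 1;
          double s_new = (c > 0) ? sigma_in : sigma_ex;
          if (rescale_residual) L *= s_new / s_old;
          double side = (c > 0) ? -1.0 : 1.0; // move slightly off the surface
          for (int k = 0; k < 3; ++k) x[k] += side * eps * nrm[k];
        } else {
          // specular reflection about the tangent plane
          double un = u[0]*nrm[0] + u[1]*nrm[1] + u[2]*nrm[2];
          for (int k = 0; k < 3; ++k) u[k] -= 2.0 * un * nrm[k];
          double side = (c > 0) ? -1.0 : 1.0;
          for (int k = 0; k < 3; ++k) x[k] += side * eps * nrm[k];
        }
      }
      for (int k = 0; k < 3; ++k) out(i, k) = x[k];
      cmp[i] = c;
    }
  }
  return List::create(_["positions"] = out, _["compartments"] = cmp);
}
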