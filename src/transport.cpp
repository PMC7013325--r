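// Voxel Monte Carlo photon-packet transport for interstitial PDT.
//
// Photon packets are launched from the lateral surface of a cylindrical
// fiber diffuser and propagated through a voxelized tissue model with
// per-label optical properties (mu_a, mu_s, g in cm^-1 / dimensionless).
// Absorption-weight deposition per scattering event, Henyey-Greenstein
// phase function, Russian roulette termination.  Track-length tallies are
// kept alongside the absorbed-weight tallies so that fluence can be
// estimated in non-absorbing (mu_a = 0) voxels.
//
// All geometry is in cm; the RNG is R's own (unif_rand), so set.seed()
// on the R side makes runs bit-reproducible.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Frame {
  double e1x, e1y, e1z;
  double e2x, e2y, e2z;
};

// Orthonormal basis perpendicular to a unit axis (deterministic choice).
Frame perp_frame(double ax, double ay, double az) {
  double hx, hy, hz;
  if (std::fabs(ax) <= std::fabs(ay) && std::fabs(ax) <= std::fabs(az)) {
    hx = 1.0; hy = 0.0; hz = 0.0;
  } else if (std::fabs(ay) <= std::fabs(az)) {
    hx = 0.0; hy = 1.0; hz = 0.0;
  } else {
    hx = 0.0; hy = 0.0; hz = 1.0;
  }
  // e1 = normalize(h - (h.a)a), e2 = a x e1
  double d = hx * ax + hy * ay + hz * az;
  double e1x = hx - d * ax, e1y = hy - d * ay, e1z = hz - d * az;
  double n = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
  e1x /= n; e1y /= n; e1z /= n;
  Frame f;
  f.e1x = e1x; f.e1y = e1y; f.e1z = e1z;
  f.e2x = ay * e1z - az * e1y;
  f.e2y = az * e1x - ax * e1z;
  f.e2z = ax * e1y - ay * e1x;
  return f;
}

// One emission sample: uniform along the radiation length and in azimuth on
// the lateral cylinder surface; direction uniform over the outward
// hemisphere about the local surface normal.
inline void emit_one(const double* tip, const double* axis, const Frame& f,
                     double length, double radius,
                     double* pos, double* dir) {
  double zl = length * unif_rand();
  double psi = 2.0 * M_PI * unif_rand();
  double cs = std::cos(psi), sn = std::sin(psi);
  // outward surface normal at this azimuth
  double nx = cs * f.e1x + sn * f.e2x;
  double ny = cs * f.e1y + sn * f.e2y;
  double nz = cs * f.e1z + sn * f.e2z;
  pos[0] = tip[0] + zl * axis[0] + radius * nx;
  pos[1] = tip[1] + zl * axis[1] + radius * ny;
  pos[2] = tip[2] + zl * axis[2] + radius * nz;
  // hemisphere uniform in solid angle: cos(theta) ~ U(0,1) from the normal
  double u = unif_rand();
  double st = std::sqrt(std::max(0.0, 1.0 - u * u));
  double phi = 2.0 * M_PI * unif_rand();
  double ca = std::cos(phi), sa = std::sin(phi);
  // tangent basis at the surface point: (t1 = azimuthal tangent, t2 = axis)
  double t1x = -sn * f.e1x + cs * f.e2x;
  double t1y = -sn * f.e1y + cs * f.e2y;
  double t1z = -sn * f.e1z + cs * f.e2z;
  dir[0] = u * nx + st * (ca * t1x + sa * axis[0]);
  dir[1] = u * ny + st * (ca * t1y + sa * axis[1]);
  dir[2] = u * nz + st * (ca * t1z + sa * axis[2]);
}

// Henyey-Greenstein scatter of a unit direction (MCML-style rotation).
inline void hg_scatter(double g, double* u) {
  double cost;
  if (std::fabs(g) > 1e-6) {
    double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
    cost = (1.0 + g * g - tmp * tmp) / (2.0 * g);
    if (cost > 1.0) cost = 1.0;
    if (cost < -1.0) cost = -1.0;
  } else {
    cost = 2.0 * unif_rand() - 1.0;
  }
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double phi = 2.0 * M_PI * unif_rand();
  double cosp = std::cos(phi), sinp = std::sin(phi);
  double ux = u[0], uy = u[1], uz = u[2];
  if (std::fabs(uz) > 0.99999) {
    u[0] = sint * cosp;
    u[1] = sint * sinp;
    u[2] = cost * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double tmp = std::sqrt(1.0 - uz * uz);
    u[0] = sint * (ux * uz * cosp - uy * sinp) / tmp + ux * cost;
    u[1] = sint * (uy * uz * cosp + ux * sinp) / tmp + uy * cost;
    u[2] = -sint * cosp * tmp + uz * cost;
  }
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_sample_emission(NumericVector tip, NumericVector axis,
                         double length, double radius, int n) {
  Frame f = perp_frame(axis[0], axis[1], axis[2]);
  NumericMatrix pos(n, 3), dir(n, 3);
  double p[3], d[3];
  double tp[3] = {tip[0], tip[1], tip[2]};
  double ax[3] = {axis[0], axis[1], axis[2]};
  for (int i = 0; i < n; ++i) {
    emit_one(tp, ax, f, length, radius, p, d);
    pos(i, 0) = p[0]; pos(i, 1) = p[1]; pos(i, 2) = p[2];
    dir(i, 0) = d[0]; dir(i, 1) = d[1]; dir(i, 2) = d[2];
  }
  return List::create(_["position"] = pos, _["direction"] = dir);
}

//' @noRd
// [[Rcpp::export]]
List cpp_transport(IntegerVector dims, NumericVector spacing,
                   NumericVector origin, IntegerVector labels,
                   NumericVector mua_tab, NumericVector mus_tab,
                   NumericVector g_tab,
                   NumericVector tip, NumericVector axis,
                   double length, double radius,
                   int n_photons, double w_threshold, double p_survive) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const R_xlen_t nvox = (R_xlen_t)nx * ny * nz;

  NumericVector deposited(nvox), tracklen(nvox);
  double escaped = 0.0, discarded = 0.0;

  Frame f = perp_frame(axis[0], axis[1], axis[2]);
  double tp[3] = {tip[0], tip[1], tip[2]};
  double axv[3] = {axis[0], axis[1], axis[2]};

  const double eps = 1e-12;

  for (int ph = 0; ph < n_photons; ++ph) {
    double pos[3], dir[3];
    emit_one(tp, axv, f, length, radius, pos, dir);
    double W = 1.0;

    int ix = (int)std::floor((pos[0] - ox) / sx);
    int iy = (int)std::floor((pos[1] - oy) / sy);
    int iz = (int)std::floor((pos[2] - oz) / sz);
    if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
      escaped += W;
      continue;
    }

    double s = -std::log(unif_rand()); // remaining optical depth
    bool alive = true;
    while (alive) {
      R_xlen_t v = (R_xlen_t)ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
      int lab = labels[v];
      if (lab == 0) { // void terminates the packet
        escaped += W;
        break;
      }
      double mua = mua_tab[lab], mus = mus_tab[lab];
      double mut = mua + mus;

      // distance to the nearest voxel face along dir
      double db = R_PosInf;
      int hit_axis = -1, step_dir = 0;
      if (dir[0] > eps) {
        double d = (ox + (ix + 1) * sx - pos[0]) / dir[0];
        if (d < db) { db = d; hit_axis = 0; step_dir = 1; }
      } else if (dir[0] < -eps) {
        double d = (ox + ix * sx - pos[0]) / dir[0];
        if (d < db) { db = d; hit_axis = 0; step_dir = -1; }
      }
      if (dir[1] > eps) {
        double d = (oy + (iy + 1) * sy - pos[1]) / dir[1];
        if (d < db) { db = d; hit_axis = 1; step_dir = 1; }
      } else if (dir[1] < -eps) {
        double d = (oy + iy * sy - pos[1]) / dir[1];
        if (d < db) { db = d; hit_axis = 1; step_dir = -1; }
      }
      if (dir[2] > eps) {
        double d = (oz + (iz + 1) * sz - pos[2]) / dir[2];
        if (d < db) { db = d; hit_axis = 2; step_dir = 1; }
      } else if (dir[2] < -eps) {
        double d = (oz + iz * sz - pos[2]) / dir[2];
        if (d < db) { db = d; hit_axis = 2; step_dir = -1; }
      }
      if (db < 0.0) db = 0.0;

      double ds = (mut > 0.0) ? s / mut : R_PosInf;
      if (ds < db) {
        // interaction inside this voxel
        pos[0] += ds * dir[0];
        pos[1] += ds * dir[1];
        pos[2] += ds * dir[2];
        tracklen[v] += W * ds;
        double dW = W * mua / mut;
        deposited[v] += dW;
        W -= dW;
        hg_scatter(g_tab[lab], dir);
        if (W < w_threshold) {
          // Russian roulette with pathwise-exact bookkeeping: survivors'
          // weight boost is debited from the discard tally so that
          // deposited + escaped + discarded == launched identically
          // (the tally is the NET weight removed by roulette).
          if (unif_rand() <= p_survive) {
            double boosted = W / p_survive;
            discarded -= boosted - W;
            W = boosted;
          } else {
            discarded += W;
            break;
          }
        }
        s = -std::log(unif_rand());
      } else {
        // advance to the voxel face and cross it
        pos[0] += db * dir[0];
        pos[1] += db * dir[1];
        pos[2] += db * dir[2];
        tracklen[v] += W * db;
        if (mut > 0.0) s -= db * mut;
        if (s < 0.0) s = 0.0;
        if (hit_axis == 0) {
          ix += step_dir;
          pos[0] = ox + (step_dir > 0 ? ix : ix + 1) * sx;
          if (ix < 0 || ix >= nx) { escaped += W; break; }
        } else if (hit_axis == 1) {
          iy += step_dir;
          pos[1] = oy + (step_dir > 0 ? iy : iy + 1) * sy;
          if (iy < 0 || iy >= ny) { escaped += W; break; }
        } else if (hit_axis == 2) {
          iz += step_dir;
          pos[2] = oz + (step_dir > 0 ? iz : iz + 1) * sz;
          if (iz < 0 || iz >= nz) { escaped += W; break; }
        } else {
          // direction numerically degenerate; drop the packet as escaped
          escaped += W;
          break;
        }
      }
    }
  }

  double dep_total = 0.0;
  for (R_xlen_t i = 0; i < nvox; ++i) dep_total += deposited[i];

  return List::create(
      _["deposited"] = deposited,
      _["tracklen"] = tracklen,
      _["deposited_weight"] = dep_total,
      _["escaped_weight"] = escaped,
      _["roulette_discarded_weight"] = discarded,
      _["launched_weight"] = (double)n_photons);
}
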