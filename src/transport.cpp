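// Condensed-history proton transport through vacuum gaps, nickel trimmer
// blades and a voxelized water phantom, with per-step (eps, l, eps^2/l)
// scoring and plane-crossing records.
//
// Scheme: deterministic mean energy loss from the stopping table plus
// Gaussian (Bohr) straggling, Highland multiple Coulomb scattering, and a
// parameterized nuclear-interaction surrogate. Steps are refined near the
// end of range (ds <= 0.2 * residual range) and split at voxel faces for
// scoring. One counter-based RNG stream per history index, so batches are
// order-independent and seeded runs are bit-reproducible.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---- counter-based RNG (splitmix64 streams) -------------------------------

struct HistoryRng {
  uint64_t state;
  bool has_spare;
  double spare;
  explicit HistoryRng(uint64_t seed, uint64_t history)
      : has_spare(false), spare(0.0) {
    state = seed ^ (0x9E3779B97F4A7C15ULL * (history + 1));
    // burn-in to decorrelate nearby streams
    next();
    next();
  }
  uint64_t next() {
    uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double u01() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  double uopen() {
    double u = u01();
    return u > 0 ? u : 5e-324;
  }
  double gauss() {
    if (has_spare) {
      has_spare = false;
      return spare;
    }
    double u1 = uopen(), u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    double a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

// ---- material tables ------------------------------------------------------

struct Material {
  std::vector<double> log_e, log_s, log_r;
  double density, z_over_a, x0_gcm2, e_min, e_max;

  static double interp(const std::vector<double>& xs,
                       const std::vector<double>& ys, double x) {
    if (x <= xs.front()) return ys.front();
    if (x >= xs.back()) return ys.back();
    size_t hi = std::upper_bound(xs.begin(), xs.end(), x) - xs.begin();
    size_t lo = hi - 1;
    double t = (x - xs[lo]) / (xs[hi] - xs[lo]);
    return ys[lo] + t * (ys[hi] - ys[lo]);
  }
  // mass stopping power, MeV cm^2/g
  double S(double e) const { return std::exp(interp(log_e, log_s, std::log(e))); }
  // residual CSDA range above the cutoff, cm
  double range(double e) const {
    if (e <= e_min) return 0.0;
    return std::exp(interp(log_e, log_r, std::log(e)));
  }
  // inverse: energy whose residual range is r (exact CSDA step closure)
  double energy_at(double r) const {
    if (r <= std::exp(log_r.front())) return e_min;
    return std::exp(interp(log_r, log_e, std::log(r)));
  }
};

static Material material_from_list(List m) {
  Material out;
  NumericVector le = m["log_e"], ls = m["log_s"], lr = m["log_r"];
  out.log_e.assign(le.begin(), le.end());
  out.log_s.assign(ls.begin(), ls.end());
  out.log_r.assign(lr.begin(), lr.end());
  out.density = as<double>(m["density"]);
  out.z_over_a = as<double>(m["z_over_a"]);
  out.x0_gcm2 = as<double>(m["x0"]);
  out.e_min = as<double>(m["e_min"]);
  out.e_max = as<double>(m["e_max"]);
  return out;
}

// ---- geometry -------------------------------------------------------------

struct Blade {
  int axis;     // 0 = X, 1 = Y
  double side;  // +1 or -1
  double z_lo, z_hi, offset, extent, z_center;
};

struct Geometry {
  std::vector<Blade> blades;
  double g0[3], sp[3];
  int nd[3];
  double g1[3];
  double source_distance;

  bool in_grid(const double* p) const {
    return p[0] >= g0[0] && p[0] < g1[0] && p[1] >= g0[1] && p[1] < g1[1] &&
           p[2] >= g0[2] && p[2] < g1[2];
  }
  // 0 vacuum, 1 water (grid), 2 nickel
  int medium(const double* p) const {
    if (in_grid(p)) return 1;
    for (const Blade& b : blades) {
      if (p[2] >= b.z_lo && p[2] < b.z_hi) {
        double c = (b.axis == 0) ? p[0] : p[1];
        double mag = (p[2] + source_distance) / (b.z_center + source_distance);
        double edge = b.side * b.offset * mag;
        if (b.side > 0) {
          if (c >= edge && c <= edge + b.extent) return 2;
        } else {
          if (c <= edge && c >= edge - b.extent) return 2;
        }
      }
    }
    return 0;
  }
};

static const double HIGHLAND_E = 13.6;  // MeV
static const double PROTON_M = 938.272;

static double highland_theta0(double e, double path_gcm2, double x0) {
  if (path_gcm2 <= 0 || e <= 0) return 0.0;
  double g = 1.0 + e / PROTON_M;
  double pc = std::sqrt(e * (e + 2.0 * PROTON_M));
  double beta = pc / (e + PROTON_M);
  double t = path_gcm2 / x0;
  double th = HIGHLAND_E / (beta * pc) * std::sqrt(t) *
              (1.0 + 0.038 * std::log(t));
  (void)g;
  if (th < 0) th = 0;
  if (th > 1.5) th = 1.5;
  return th;
}

// ---- scoring --------------------------------------------------------------

struct Scorer {
  const Geometry* geo;
  double *sum_e, *sum_l, *sum_e2l, *sum_dose;
  double scored, external;

  int vox(const double* p, int idx[3]) const {
    for (int a = 0; a < 3; ++a) {
      double f = (p[a] - geo->g0[a]) / geo->sp[a];
      int i = (int)std::floor(f);
      if (i < 0 || i >= geo->nd[a]) return 0;
      idx[a] = i;
    }
    return 1;
  }
  int lin(const int idx[3]) const {
    return idx[0] + geo->nd[0] * (idx[1] + geo->nd[1] * idx[2]);
  }
  // point deposit: dose only, excluded from LET accumulators
  void point(const double* p, double eps) {
    int idx[3];
    if (vox(p, idx)) {
      sum_dose[lin(idx)] += eps;
      scored += eps;
    } else {
      external += eps;
    }
  }
  // segment deposit with voxel-face splitting (Amanatides-Woo traversal)
  void segment(const double* p0, const double* u, double len, double eps) {
    if (len <= 0) {
      if (eps > 0) point(p0, eps);
      return;
    }
    // clip to grid box
    double t0 = 0, t1 = len;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(u[a]) < 1e-14) {
        if (p0[a] < geo->g0[a] || p0[a] >= geo->g1[a]) { t1 = -1; break; }
      } else {
        double ta = (geo->g0[a] - p0[a]) / u[a];
        double tb = (geo->g1[a] - p0[a]) / u[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (t1 <= t0) {
      external += eps;
      return;
    }
    double covered = 0.0;
    double t = t0;
    double q[3] = {p0[0] + (t0 + 1e-12) * u[0], p0[1] + (t0 + 1e-12) * u[1],
                   p0[2] + (t0 + 1e-12) * u[2]};
    int idx[3];
    if (!vox(q, idx)) {
      external += eps;
      return;
    }
    while (t < t1 - 1e-12) {
      // distance to next voxel face
      double tnext = t1;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(u[a]) < 1e-14) continue;
        double face = geo->g0[a] + geo->sp[a] * (idx[a] + (u[a] > 0 ? 1 : 0));
        double tf = (face - p0[a]) / u[a];
        if (tf > t + 1e-12 && tf < tnext) tnext = tf;
      }
      double lj = tnext - t;
      if (lj > 1e-14) {
        double ej = eps * lj / len;
        int li = lin(idx);
        sum_e[li] += ej;
        sum_dose[li] += ej;
        sum_l[li] += lj;
        sum_e2l[li] += ej * ej / lj;
        scored += ej;
        covered += lj;
      }
      t = tnext;
      if (t >= t1 - 1e-12) break;
      double qm[3] = {p0[0] + (t + 1e-9) * u[0], p0[1] + (t + 1e-9) * u[1],
                      p0[2] + (t + 1e-9) * u[2]};
      if (!vox(qm, idx)) break;
    }
    double rem = eps * (len - covered) / len;
    if (rem > 0) external += rem;
  }
};

// deflect direction u by gaussian angles gx, gy in two orthogonal planes
static void deflect(double* u, double gx, double gy) {
  // orthonormal basis perpendicular to u
  double e1[3], e2[3];
  if (std::fabs(u[2]) < 0.99) {
    // e1 = u x z_hat
    e1[0] = u[1]; e1[1] = -u[0]; e1[2] = 0.0;
  } else {
    e1[0] = 1.0; e1[1] = 0.0; e1[2] = 0.0;
  }
  double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  for (int a = 0; a < 3; ++a) e1[a] /= n1;
  e2[0] = u[1]*e1[2] - u[2]*e1[1];
  e2[1] = u[2]*e1[0] - u[0]*e1[2];
  e2[2] = u[0]*e1[1] - u[1]*e1[0];
  double v[3];
  for (int a = 0; a < 3; ++a) v[a] = u[a] + gx * e1[a] + gy * e2[a];
  double n = std::sqrt(v[0]*v[0] + v[1]*v[1] + v[2]*v[2]);
  for (int a = 0; a < 3; ++a) u[a] = v[a] / n;
}

struct Particle {
  double p[3], u[3], e, w;
  int origin;  // 0 primary, 1 collimator_scatter, 2 nuclear_secondary
};

// [[Rcpp::export]]
List cpp_transport(NumericMatrix particles, IntegerVector origin,
                   List water_l, List nickel_l, NumericMatrix blades_m,
                   NumericVector grid_origin, NumericVector grid_spacing,
                   IntegerVector grid_dims, List config) {
  Material water = material_from_list(water_l);
  Material nickel = material_from_list(nickel_l);

  Geometry geo;
  geo.source_distance = as<double>(config["source_distance"]);
  for (int a = 0; a < 3; ++a) {
    geo.g0[a] = grid_origin[a];
    geo.sp[a] = grid_spacing[a];
    geo.nd[a] = grid_dims[a];
    geo.g1[a] = geo.g0[a] + geo.sp[a] * geo.nd[a];
  }
  for (int i = 0; i < blades_m.nrow(); ++i) {
    Blade b;
    b.axis = (int)blades_m(i, 0);
    b.side = blades_m(i, 1);
    b.z_lo = blades_m(i, 2);
    b.z_hi = blades_m(i, 3);
    b.offset = blades_m(i, 4);
    b.extent = blades_m(i, 5);
    b.z_center = blades_m(i, 6);
    geo.blades.push_back(b);
  }

  double max_step_w = as<double>(config["max_step_water"]);
  double max_step_n = as<double>(config["max_step_nickel"]);
  double cutoff = as<double>(config["energy_cutoff"]);
  bool nuclear_on = as<bool>(config["nuclear_model"]);
  double nuc_rate = as<double>(config["nuclear_rate_per_cm"]);
  double nuc_frac = as<double>(config["nuclear_local_fraction"]);
  bool straggle = as<bool>(config["straggling"]);
  bool scatter = as<bool>(config["scattering"]);
  double plane_z = as<double>(config["plane_z"]);
  bool record_plane = as<bool>(config["record_plane"]);
  uint64_t seed = (uint64_t)as<double>(config["seed"]);

  int n = particles.nrow();
  R_xlen_t nvox = (R_xlen_t)geo.nd[0] * geo.nd[1] * geo.nd[2];
  NumericVector sum_e(nvox), sum_l(nvox), sum_e2l(nvox), sum_dose(nvox);

  Scorer sc;
  sc.geo = &geo;
  sc.sum_e = REAL(sum_e);
  sc.sum_dose = REAL(sum_dose);
  sc.sum_l = REAL(sum_l);
  sc.sum_e2l = REAL(sum_e2l);
  sc.scored = 0.0;
  sc.external = 0.0;

  std::vector<double> cr_e, cr_x, cr_y, cr_w;
  std::vector<int> cr_o;
  double initial = 0.0, escaped = 0.0, nuclear_unacc = 0.0;

  const double world_zmax = geo.g1[2] + 1.0;

  for (int h = 0; h < n; ++h) {
    HistoryRng rng(seed, (uint64_t)h);
    std::vector<Particle> stack;
    Particle pr;
    for (int a = 0; a < 3; ++a) {
      pr.p[a] = particles(h, a);
      pr.u[a] = particles(h, 3 + a);
    }
    pr.e = particles(h, 6);
    pr.w = particles(h, 7);
    pr.origin = origin[h];
    initial += pr.e * pr.w;
    stack.push_back(pr);

    while (!stack.empty()) {
      Particle pt = stack.back();
      stack.pop_back();
      bool alive = true;
      int guard = 0;
      while (alive && ++guard < 1000000) {
        if (pt.e < cutoff) {
          sc.point(pt.p, pt.e * pt.w);
          alive = false;
          break;
        }
        double nudge[3] = {pt.p[0] + 1e-9 * pt.u[0], pt.p[1] + 1e-9 * pt.u[1],
                           pt.p[2] + 1e-9 * pt.u[2]};
        int med = geo.medium(nudge);
        if (med == 0) {
          // vacuum: fly to the next boundary plane along +z
          if (pt.u[2] <= 1e-9) {
            escaped += pt.e * pt.w;
            alive = false;
            break;
          }
          double tmin = 1e30;
          double zc = pt.p[2];
          auto consider = [&](double zp) {
            if (zp > zc + 1e-9) {
              double t = (zp - zc) / pt.u[2];
              if (t < tmin) tmin = t;
            }
          };
          for (const Blade& b : geo.blades) {
            consider(b.z_lo);
            consider(b.z_hi);
          }
          consider(geo.g0[2]);
          consider(world_zmax);
          if (tmin >= 1e29) {
            escaped += pt.e * pt.w;
            alive = false;
            break;
          }
          double znew = pt.p[2] + tmin * pt.u[2];
          if (record_plane && pt.p[2] < plane_z && znew >= plane_z) {
            double tc = (plane_z - pt.p[2]) / pt.u[2];
            cr_e.push_back(pt.e);
            cr_x.push_back(pt.p[0] + tc * pt.u[0]);
            cr_y.push_back(pt.p[1] + tc * pt.u[1]);
            cr_w.push_back(pt.w);
            cr_o.push_back(pt.origin);
          }
          for (int a = 0; a < 3; ++a) pt.p[a] += (tmin + 1e-7) * pt.u[a];
          if (pt.p[2] >= world_zmax - 0.5) {
            escaped += pt.e * pt.w;
            alive = false;
          }
          continue;
        }

        const Material& m = (med == 1) ? water : nickel;
        double max_step = (med == 1) ? max_step_w : max_step_n;
        if (med == 2 && pt.origin == 0) pt.origin = 1;

        double res_range = m.range(pt.e);
        double ds = std::min(max_step, std::max(0.2 * res_range, 1e-4));
        if (res_range <= ds) {
          // ranges out within this step: score the above-cutoff track over
          // the true residual range; the sub-cutoff remainder is a point
          // deposit (dose only, excluded from the LET accumulators)
          if (res_range >= 1e-4) {
            double eps_seg = (pt.e - m.e_min) * pt.w;
            if (med == 1) {
              sc.segment(pt.p, pt.u, res_range, eps_seg);
            } else {
              sc.external += eps_seg;
            }
            for (int a = 0; a < 3; ++a) pt.p[a] += res_range * pt.u[a];
            sc.point(pt.p, m.e_min * pt.w);
          } else {
            sc.point(pt.p, pt.e * pt.w);
          }
          alive = false;
          break;
        }
        double eps;
        {
          // exact CSDA mean loss via range inversion
          double mean_loss = pt.e - m.energy_at(res_range - ds);
          double sig = 0.0;
          if (straggle) sig = std::sqrt(0.1569 * m.z_over_a * m.density * ds);
          eps = mean_loss + sig * rng.gauss();
          if (eps < 0) eps = 0;
          if (eps > pt.e) eps = pt.e;
        }

        double znew = pt.p[2] + ds * pt.u[2];
        if (record_plane && pt.p[2] < plane_z && znew >= plane_z) {
          double tc = (plane_z - pt.p[2]) / pt.u[2];
          cr_e.push_back(pt.e);
          cr_x.push_back(pt.p[0] + tc * pt.u[0]);
          cr_y.push_back(pt.p[1] + tc * pt.u[1]);
          cr_w.push_back(pt.w);
          cr_o.push_back(pt.origin);
        }

        if (med == 1) {
          sc.segment(pt.p, pt.u, ds, eps * pt.w);
        } else {
          sc.external += eps * pt.w;
        }
        for (int a = 0; a < 3; ++a) pt.p[a] += ds * pt.u[a];
        pt.e -= eps;
        if (pt.e < cutoff) {
          sc.point(pt.p, pt.e * pt.w);
          alive = false;
          break;
        }

        // nuclear-interaction surrogate (no secondary chains)
        if (nuclear_on && pt.origin != 2) {
          double f = pt.e >= 20.0 ? 1.0 : pt.e / 20.0;
          double rate = nuc_rate * m.density * f;
          double pint = 1.0 - std::exp(-ds * rate);
          if (rng.u01() < pint) {
            double local = nuc_frac * pt.e;
            sc.point(pt.p, local * pt.w);
            double rem = pt.e - local;
            if (0.5 * pt.e > 5.0) {
              double esec = 5.0 + rng.u01() * (0.5 * pt.e - 5.0);
              double ct = 0.5 + 0.5 * rng.u01();
              double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
              double phi = 2.0 * M_PI * rng.u01();
              Particle sec = pt;
              sec.e = esec;
              sec.origin = 2;
              // direction: polar angle about the parent direction
              double gx = st * std::cos(phi), gy = st * std::sin(phi);
              sec.u[0] = pt.u[0]; sec.u[1] = pt.u[1]; sec.u[2] = pt.u[2];
              // rotate: scale parent dir by ct and add transverse
              double e1[3], e2[3];
              if (std::fabs(pt.u[2]) < 0.99) {
                e1[0] = pt.u[1]; e1[1] = -pt.u[0]; e1[2] = 0.0;
              } else {
                e1[0] = 1.0; e1[1] = 0.0; e1[2] = 0.0;
              }
              double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
              for (int a = 0; a < 3; ++a) e1[a] /= n1;
              e2[0] = pt.u[1]*e1[2] - pt.u[2]*e1[1];
              e2[1] = pt.u[2]*e1[0] - pt.u[0]*e1[2];
              e2[2] = pt.u[0]*e1[1] - pt.u[1]*e1[0];
              for (int a = 0; a < 3; ++a)
                sec.u[a] = ct * pt.u[a] + gx * e1[a] + gy * e2[a];
              double nn = std::sqrt(sec.u[0]*sec.u[0] + sec.u[1]*sec.u[1] +
                                    sec.u[2]*sec.u[2]);
              for (int a = 0; a < 3; ++a) sec.u[a] /= nn;
              stack.push_back(sec);
              rem -= esec;
            }
            nuclear_unacc += rem * pt.w;
            alive = false;
            break;
          }
        }

        if (scatter) {
          double th0 = highland_theta0(pt.e, ds * m.density, m.x0_gcm2);
          if (th0 > 0) deflect(pt.u, th0 * rng.gauss(), th0 * rng.gauss());
        }

        if (pt.p[2] >= world_zmax) {
          escaped += pt.e * pt.w;
          alive = false;
        }
      }
      if (guard >= 1000000) escaped += pt.e * pt.w;
    }
  }

  int nc = (int)cr_e.size();
  NumericMatrix crossings(nc, 4);
  IntegerVector cr_origin(nc);
  for (int i = 0; i < nc; ++i) {
    crossings(i, 0) = cr_e[i];
    crossings(i, 1) = cr_x[i];
    crossings(i, 2) = cr_y[i];
    crossings(i, 3) = cr_w[i];
    cr_origin[i] = cr_o[i];
  }

  return List::create(
    _["sum_e"] = sum_e, _["sum_l"] = sum_l, _["sum_e2l"] = sum_e2l,
    _["sum_dose"] = sum_dose,
    _["crossings"] = crossings, _["crossing_origin"] = cr_origin,
    _["ledger"] = NumericVector::create(
      _["initial"] = initial, _["scored"] = sc.scored,
      _["external"] = sc.external, _["escaped"] = escaped,
      _["nuclear_unaccounted"] = nuclear_unacc));
}
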