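// Voxelized time-resolved Monte Carlo photon transport.
//
// One engine serves both steps of the fluorescence workflow:
//   * excitation: collimated planar / pencil / pattern-weighted launches from
//     the top surface; absorbed energy is tallied per voxel and, inside
//     fluorescent voxels, as an event table (position, time, weight, launch-x)
//     from which emission sources are formed;
//   * emission: isotropic launches from a pre-sampled source table (position,
//     start time, weight, inherited launch-x tag).
//
// Conventions: lengths in mm, time in ps, speed of light 0.299792 mm/ps.
// Survival weighting (w *= 1 - mua/mut at every interaction), Russian roulette
// below `w_min` with survival chance `p_survive`. Heterogeneity is handled by
// DDA ray marching: a sampled optical depth is consumed voxel-by-voxel, so a
// step may cross any number of tissue boundaries exactly.
// Top boundary (z = 0): Fresnel reflection for the n_in/n_out mismatch; exits
// are recorded in the detected-photon table. Side and bottom faces absorb
// (weights tallied, exits optionally recorded with a face code).
// All randomness comes from R's RNG (RNGScope), so set.seed() in R gives
// bit-reproducible runs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double C_MM_PER_PS = 0.299792;

struct Medium {
  std::vector<double> mua, mus, mut, g;
};

struct Tallies {
  double launched = 0, specular = 0, absorbed = 0;
  double escaped_top = 0, escaped_bottom = 0, escaped_side = 0;
  double roulette_net = 0;
};

static inline double rexp_unit() {
  double u = unif_rand();
  while (u <= 0.0) u = unif_rand();
  return -std::log(u);
}

static inline double fresnel_R(double cosi, double n1, double n2) {
  // unpolarized Fresnel reflectance for incidence cosine cosi (>0)
  if (cosi > 1.0) cosi = 1.0;
  double sini = std::sqrt(std::max(0.0, 1.0 - cosi * cosi));
  double sint = n1 / n2 * sini;
  if (sint >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(std::max(0.0, 1.0 - sint * sint));
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

static inline double hg_cosine(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-6) return 2.0 * u - 1.0;
  double s = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double c = (1.0 + g * g - s * s) / (2.0 * g);
  if (c > 1.0) c = 1.0;
  if (c < -1.0) c = -1.0;
  return c;
}

static inline void scatter_direction(double &ux, double &uy, double &uz, double g) {
  double ct = hg_cosine(g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * M_PI * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  if (std::fabs(uz) > 0.99999) {
    ux = st * cp;
    uy = st * sp;
    uz = ct * (uz >= 0 ? 1.0 : -1.0);
  } else {
    double denom = std::sqrt(1.0 - uz * uz);
    double nx = st * (ux * uz * cp - uy * sp) / denom + ux * ct;
    double ny = st * (uy * uz * cp + ux * sp) / denom + uy * ct;
    double nz = -st * cp * denom + uz * ct;
    ux = nx; uy = ny; uz = nz;
  }
  double norm = std::sqrt(ux * ux + uy * uy + uz * uz);
  ux /= norm; uy /= norm; uz /= norm;
}

class Transport {
public:
  int nx, ny, nz;
  double h, Lx, Ly, Lz;
  const int *labels;       // 0-based tissue index per voxel
  Medium med;
  const double *yield;     // per-voxel fluorescence yield (may be null)
  double n_in, n_out;
  double w_min, p_survive;
  bool record_events, record_exits, record_nontop;
  double t_max;            // drop photons whose clock exceeds this (ps); <=0: off

  std::vector<double> absorbed;       // per voxel, time-integrated
  std::vector<double> ev;             // events: x,y,z,t,w,launch_x,vox(1-based)
  std::vector<double> det;            // exits: x,y,t,w,launch_x,face
  Tallies tal;

  Transport(IntegerVector lab, int nx_, int ny_, int nz_, double h_,
            NumericMatrix props, NumericVector yld,
            double nin, double nout, double wmin, double psurv,
            bool rec_ev, bool rec_ex, bool rec_nontop, double tmax)
      : nx(nx_), ny(ny_), nz(nz_), h(h_),
        labels(INTEGER(lab)), n_in(nin), n_out(nout),
        w_min(wmin), p_survive(psurv),
        record_events(rec_ev), record_exits(rec_ex),
        record_nontop(rec_nontop), t_max(tmax) {
    Lx = nx * h; Ly = ny * h; Lz = nz * h;
    int nt = props.nrow();
    med.mua.resize(nt); med.mus.resize(nt); med.mut.resize(nt); med.g.resize(nt);
    for (int i = 0; i < nt; ++i) {
      med.mua[i] = props(i, 0);
      med.mus[i] = props(i, 1);
      med.g[i]   = props(i, 2);
      med.mut[i] = med.mua[i] + med.mus[i];
    }
    yield = yld.size() ? REAL(yld) : nullptr;
    absorbed.assign((size_t)nx * ny * nz, 0.0);
    compute_het_box();
  }

  inline size_t vox_of(double x, double y, double z, int &ix, int &iy, int &iz) const {
    ix = (int)std::floor(x / h); iy = (int)std::floor(y / h); iz = (int)std::floor(z / h);
    if (ix < 0) ix = 0; if (ix >= nx) ix = nx - 1;
    if (iy < 0) iy = 0; if (iy >= ny) iy = ny - 1;
    if (iz < 0) iz = 0; if (iz >= nz) iz = nz - 1;
    return (size_t)ix + (size_t)nx * ((size_t)iy + (size_t)ny * (size_t)iz);
  }

  // bounding box (mm) of voxels that differ from the bulk (label 1) or carry
  // fluorophore; outside it the medium is homogeneous bulk and photons can
  // take analytic steps without voxel marching
  bool has_het = false;
  double bx0, bx1, by0, by1, bz0, bz1;
  void compute_het_box() {
    int x0 = nx, x1 = -1, y0 = ny, y1 = -1, z0 = nz, z1 = -1;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i, ++idx) {
          if (labels[idx] != 1 || (yield && yield[idx] > 0)) {
            if (i < x0) x0 = i; if (i > x1) x1 = i;
            if (j < y0) y0 = j; if (j > y1) y1 = j;
            if (k < z0) z0 = k; if (k > z1) z1 = k;
          }
        }
    has_het = x1 >= 0;
    if (has_het) {
      bx0 = x0 * h; bx1 = (x1 + 1) * h;
      by0 = y0 * h; by1 = (y1 + 1) * h;
      bz0 = z0 * h; bz1 = (z1 + 1) * h;
    }
  }
  inline bool in_het(double x, double y, double z) const {
    return has_het && x >= bx0 && x <= bx1 && y >= by0 && y <= by1 &&
           z >= bz0 && z <= bz1;
  }
  // distance along the ray to het-box entry (slab method); inf if missed
  inline double dist_to_het(double x, double y, double z,
                            double ux, double uy, double uz) const {
    if (!has_het) return 1e30;
    double tmin = -1e30, tmax = 1e30;
    const double lo[3] = {bx0, by0, bz0}, hi[3] = {bx1, by1, bz1};
    const double p[3] = {x, y, z}, u[3] = {ux, uy, uz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(u[a]) < 1e-12) {
        if (p[a] < lo[a] || p[a] > hi[a]) return 1e30;
      } else {
        double t1 = (lo[a] - p[a]) / u[a], t2 = (hi[a] - p[a]) / u[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (tmax < tmin || tmax < 0) return 1e30;
    return tmin > 0 ? tmin : 0;
  }
  // distance to the volume boundary along the ray
  inline double dist_to_volume(double x, double y, double z,
                               double ux, double uy, double uz) const {
    double d = 1e30;
    if (ux > 1e-12)       d = std::min(d, (Lx - x) / ux);
    else if (ux < -1e-12) d = std::min(d, -x / ux);
    if (uy > 1e-12)       d = std::min(d, (Ly - y) / uy);
    else if (uy < -1e-12) d = std::min(d, -y / uy);
    if (uz > 1e-12)       d = std::min(d, (Lz - z) / uz);
    else if (uz < -1e-12) d = std::min(d, -z / uz);
    return d;
  }

  // Interaction bookkeeping shared by the fast and DDA paths.
  // Returns false when the photon is terminated (fully absorbed / roulette).
  inline bool interact(double &x, double &y, double &z,
                       double &ux, double &uy, double &uz,
                       double &w, double t, double launch_x) {
    int ix, iy, iz;
    size_t vi = vox_of(x, y, z, ix, iy, iz);
    int lab = labels[vi] - 1;  // R labels are 1-based
    double mut = med.mut[lab];
    if (mut <= 0) return true;  // transparent voxel: nothing to do
    double mua = med.mua[lab];
    double dep = w * mua / mut;
    if (dep > 0) {
      absorbed[vi] += dep;
      tal.absorbed += dep;
      if (record_events && yield && yield[vi] > 0) {
        ev.push_back(x); ev.push_back(y); ev.push_back(z);
        ev.push_back(t); ev.push_back(dep); ev.push_back(launch_x);
        ev.push_back((double)(vi + 1));
      }
    }
    w -= dep;
    if (w <= 0) return false;
    if (w < w_min) {
      if (unif_rand() < p_survive) {
        tal.roulette_net -= w * (1.0 / p_survive - 1.0);
        w /= p_survive;
      } else {
        tal.roulette_net += w;
        return false;
      }
    }
    scatter_direction(ux, uy, uz, med.g[lab]);
    return true;
  }

  // Handle arrival at the volume boundary; position must be just past it.
  // Returns 0 = reflected back inside (continue), 1 = photon gone.
  inline int boundary(double &x, double &y, double &z,
                      double &ux, double &uy, double &uz,
                      double w, double t, double launch_x) {
    const double eps = 1e-9;
    if (z < 0) {
      double over = -z / std::max(std::fabs(uz), eps);
      double xs = x - ux * over, ys = y - uy * over;
      double ts = t - over * n_in / C_MM_PER_PS;
      double R = fresnel_R(std::fabs(uz), n_in, n_out);
      if (unif_rand() < R) { z = -z; uz = -uz; return 0; }
      tal.escaped_top += w;
      if (record_exits) {
        det.push_back(xs); det.push_back(ys); det.push_back(ts);
        det.push_back(w); det.push_back(launch_x); det.push_back(0.0);
      }
      return 1;
    }
    if (z > Lz) {
      tal.escaped_bottom += w;
      if (record_exits && record_nontop) {
        det.push_back(x); det.push_back(y); det.push_back(t);
        det.push_back(w); det.push_back(launch_x); det.push_back(1.0);
      }
      return 1;
    }
    if (x < 0 || x > Lx || y < 0 || y > Ly) {
      tal.escaped_side += w;
      if (record_exits && record_nontop) {
        det.push_back(x); det.push_back(y); det.push_back(t);
        det.push_back(w); det.push_back(launch_x); det.push_back(2.0);
      }
      return 1;
    }
    return 0;  // numerically still inside; carry on
  }

  // Propagate one photon already inside the medium.
  void run_photon(double x, double y, double z,
                  double ux, double uy, double uz,
                  double w, double t, double launch_x) {
    const double eps = 1e-9;
    const double bulk_mut = med.mut[0];
    for (;;) {
      double tau = rexp_unit();  // sampled optical depth to next interaction
      for (;;) {
        if (t_max > 0 && t > t_max) { tal.escaped_side += w; return; }  // stale
        if (!in_het(x, y, z)) {
          // homogeneous-bulk fast path: analytic step, no voxel marching
          double s_int = bulk_mut > 0 ? tau / bulk_mut : 1e30;
          double d_het = dist_to_het(x, y, z, ux, uy, uz);
          double d_vol = dist_to_volume(x, y, z, ux, uy, uz);
          double lim = std::min(d_het, d_vol);
          if (s_int <= lim) {
            x += ux * s_int; y += uy * s_int; z += uz * s_int;
            t += s_int * n_in / C_MM_PER_PS;
            if (!interact(x, y, z, ux, uy, uz, w, t, launch_x)) return;
            break;  // fresh tau
          }
          double step = lim + eps;
          x += ux * step; y += uy * step; z += uz * step;
          t += step * n_in / C_MM_PER_PS;
          tau -= bulk_mut * lim;
          if (tau < 0) tau = 0;
          if (d_het < d_vol) continue;  // entered the heterogeneous box
          if (boundary(x, y, z, ux, uy, uz, w, t, launch_x)) return;
          continue;
        }
        // heterogeneous region: DDA, one voxel at a time
        int ix, iy, iz;
        size_t vi = vox_of(x, y, z, ix, iy, iz);
        int lab = labels[vi] - 1;
        double mut = med.mut[lab];
        double db = 1e30;
        if (ux > eps)       db = std::min(db, ((ix + 1) * h - x) / ux);
        else if (ux < -eps) db = std::min(db, (ix * h - x) / ux);
        if (uy > eps)       db = std::min(db, ((iy + 1) * h - y) / uy);
        else if (uy < -eps) db = std::min(db, (iy * h - y) / uy);
        if (uz > eps)       db = std::min(db, ((iz + 1) * h - z) / uz);
        else if (uz < -eps) db = std::min(db, (iz * h - z) / uz);
        if (db < 0) db = 0;
        if (mut > 0 && mut * db >= tau) {
          double s = tau / mut;
          x += ux * s; y += uy * s; z += uz * s;
          t += s * n_in / C_MM_PER_PS;
          if (!interact(x, y, z, ux, uy, uz, w, t, launch_x)) return;
          break;  // fresh tau
        }
        double step = db + eps;
        x += ux * step; y += uy * step; z += uz * step;
        t += step * n_in / C_MM_PER_PS;
        tau -= mut * db;
        if (tau < 0) tau = 0;
        if (boundary(x, y, z, ux, uy, uz, w, t, launch_x)) return;
      }
    }
  }
};

static List wrap_result(Transport &tr, int nx, int ny, int nz) {
  NumericVector abs_out(tr.absorbed.begin(), tr.absorbed.end());
  abs_out.attr("dim") = IntegerVector::create(nx, ny, nz);
  size_t nev = tr.ev.size() / 7;
  NumericMatrix events((int)nev, 7);
  for (size_t i = 0; i < nev; ++i)
    for (int j = 0; j < 7; ++j) events((int)i, j) = tr.ev[i * 7 + j];
  colnames(events) = CharacterVector::create("x", "y", "z", "t_ps", "weight",
                                             "launch_x", "voxel");
  size_t ndet = tr.det.size() / 6;
  NumericMatrix det((int)ndet, 6);
  for (size_t i = 0; i < ndet; ++i)
    for (int j = 0; j < 6; ++j) det((int)i, j) = tr.det[i * 6 + j];
  colnames(det) = CharacterVector::create("x", "y", "t_ps", "weight",
                                          "launch_x", "face");
  NumericVector totals = NumericVector::create(
      _["launched"] = tr.tal.launched, _["specular"] = tr.tal.specular,
      _["absorbed"] = tr.tal.absorbed, _["escaped_top"] = tr.tal.escaped_top,
      _["escaped_bottom"] = tr.tal.escaped_bottom,
      _["escaped_side"] = tr.tal.escaped_side,
      _["roulette_net"] = tr.tal.roulette_net);
  return List::create(_["absorbed"] = abs_out, _["events"] = events,
                      _["detected"] = det, _["totals"] = totals);
}

// [[Rcpp::export(name = ".cpp_mc_excitation")]]
List cpp_mc_excitation(IntegerVector labels, IntegerVector dims, double voxel,
                       NumericMatrix props, NumericVector yield,
                       double n_in, double n_out,
                       int n_photons, int source_type,
                       NumericVector source_pos, NumericVector launch_x,
                       double w_min, double p_survive,
                       bool record_events, bool record_exits,
                       bool record_nontop, double t_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  Transport tr(labels, nx, ny, nz, voxel, props, yield, n_in, n_out,
               w_min, p_survive, record_events, record_exits, record_nontop,
               t_max);
  RNGScope scope;
  double Rspec = fresnel_R(1.0, n_out, n_in);  // normal-incidence entry loss
  for (int i = 0; i < n_photons; ++i) {
    double x, y;
    if (source_type == 1) {            // pencil
      x = source_pos[0]; y = source_pos[1];
    } else if (source_type == 2) {     // pattern-weighted launch positions
      x = launch_x[i]; y = unif_rand() * tr.Ly;
    } else {                           // uniform planar
      x = unif_rand() * tr.Lx; y = unif_rand() * tr.Ly;
    }
    double w = 1.0;
    tr.tal.launched += w;
    if (Rspec > 0) { tr.tal.specular += w * Rspec; w *= (1.0 - Rspec); }
    tr.run_photon(x, y, 1e-9, 0.0, 0.0, 1.0, w, 0.0, x);
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return wrap_result(tr, nx, ny, nz);
}

// [[Rcpp::export(name = ".cpp_mc_emission")]]
List cpp_mc_emission(IntegerVector labels, IntegerVector dims, double voxel,
                     NumericMatrix props, double n_in, double n_out,
                     NumericMatrix sources,  // x,y,z,t_ps,weight,launch_x
                     double w_min, double p_survive,
                     bool record_exits, bool record_nontop, double t_max) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector no_yield(0);
  Transport tr(labels, nx, ny, nz, voxel, props, no_yield, n_in, n_out,
               w_min, p_survive, false, record_exits, record_nontop, t_max);
  RNGScope scope;
  int n = sources.nrow();
  for (int i = 0; i < n; ++i) {
    double uz = 2.0 * unif_rand() - 1.0;
    double st = std::sqrt(std::max(0.0, 1.0 - uz * uz));
    double phi = 2.0 * M_PI * unif_rand();
    double w = sources(i, 4);
    tr.tal.launched += w;
    tr.run_photon(sources(i, 0), sources(i, 1), sources(i, 2),
                  st * std::cos(phi), st * std::sin(phi), uz,
                  w, sources(i, 3), sources(i, 5));
    if ((i & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  return wrap_result(tr, nx, ny, nz);
}

// [[Rcpp::export(name = ".cpp_hg_sample")]]
NumericVector cpp_hg_sample(int n, double g) {
  RNGScope scope;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = hg_cosine(g);
  return out;
}

// Histogram detected photons into an (n_time, ny_img, nx_img) stack with a
// per-photon weight multiplier (pattern reweighting happens in R).
// [[Rcpp::export(name = ".cpp_bin_stack")]]
NumericVector cpp_bin_stack(NumericVector x, NumericVector y, NumericVector t,
                            NumericVector w, double pitch,
                            int nx_img, int ny_img,
                            double t0, double dt, int nt) {
  NumericVector out((R_xlen_t)nt * ny_img * nx_img);
  R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    int ix = (int)std::floor(x[i] / pitch);
    int iy = (int)std::floor(y[i] / pitch);
    if (ix < 0 || ix >= nx_img || iy < 0 || iy >= ny_img) continue;
    int it = 0;
    if (nt > 1) {
      it = (int)std::floor((t[i] - t0) / dt);
      if (it < 0 || it >= nt) continue;
    }
    out[(R_xlen_t)it + (R_xlen_t)nt * ((R_xlen_t)iy + (R_xlen_t)ny_img * ix)] += w[i];
  }
  out.attr("dim") = IntegerVector::create(nt, ny_img, nx_img);
  return out;
}
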