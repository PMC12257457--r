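// Simplified voxel Monte Carlo photon/electron transport for a point-source
// beam model.
//
// Photons: analog interaction sampling (Compton via Kahn's Klein-Nishina
// rejection; photoelectric/pair lumped into absorption) on density-scaled
// water cross sections, with dose scored either by a track-length
// collision-kerma estimator (expected-value scoring, optionally smeared
// forward over the mean secondary-electron range to reproduce buildup) or
// by analog secondary-electron transport.
//
// Electrons: condensed-history steps under the continuous slowing down
// approximation with Highland multiple scattering and first-order magnetic
// deflection dv = (s/R) (v x B)/|v x B|, R the relativistic gyroradius.
//
// All randomness comes from a self-contained xoshiro256+ stream seeded by
// splitmix64, so runs are bit-identical for a given seed on any platform.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// ------------------------------------------------------------------ RNG ---

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    // splitmix64 expansion of the seed
    uint64_t x = seed + 0x9E3779B97f4A7C15ULL;
    for (int i = 0; i < 4; ++i) {
      uint64_t z = (x += 0x9E3779B97f4A7C15ULL);
      z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
      z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = s[0] + s[3];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double u01() {  // uniform in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double gauss() {  // Box-Muller (one value, second discarded)
    double u1 = u01(), u2 = u01();
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

// ------------------------------------------------------- table lookups ----

struct LogTable {  // log-spaced energy grid, linear interpolation
  double loge0, dloge;
  int n;
  const double* y;
  LogTable(const NumericVector& egrid, const NumericVector& yv)
      : loge0(std::log(egrid[0])),
        dloge(std::log(egrid[egrid.size() - 1] / egrid[0]) / (egrid.size() - 1)),
        n(egrid.size()), y(REAL(yv)) {}
  inline double at(double e) const {
    double t = (std::log(e) - loge0) / dloge;
    if (t <= 0) return y[0];
    if (t >= n - 1) return y[n - 1];
    int i = (int)t;
    double f = t - i;
    return y[i] * (1 - f) + y[i + 1] * f;
  }
};

// ----------------------------------------------------------- geometry -----

struct Grid {
  int nx, ny, nz;
  double vx, vy, vz;      // voxel sizes (cm)
  double x0, y0, z0;      // min corner (cm)
  const double* rho;
  // z-fastest memory layout: depth-marching particles touch contiguous
  // memory (the R wrapper permutes arrays accordingly)
  inline long idx(int i, int j, int k) const {
    return (long)k + (long)nz * ((long)i + (long)nx * (long)j);
  }
  inline bool voxel_of(const double* p, int* v) const {
    v[0] = (int)std::floor((p[0] - x0) / vx);
    v[1] = (int)std::floor((p[1] - y0) / vy);
    v[2] = (int)std::floor((p[2] - z0) / vz);
    return v[0] >= 0 && v[0] < nx && v[1] >= 0 && v[1] < ny &&
           v[2] >= 0 && v[2] < nz;
  }
  inline double density_at(const double* p) const {
    int v[3];
    if (!voxel_of(p, v)) return 0.0;
    return rho[idx(v[0], v[1], v[2])];
  }
  // slab intersection; returns false when the ray misses the box
  bool enter(const double* p, const double* d, double* tmin_out) const {
    double tmin = 0.0, tmax = 1e30;
    const double lo[3] = {x0, y0, z0};
    const double hi[3] = {x0 + nx * vx, y0 + ny * vy, z0 + nz * vz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (p[a] < lo[a] || p[a] > hi[a]) return false;
      } else {
        double t1 = (lo[a] - p[a]) / d[a], t2 = (hi[a] - p[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (tmax <= tmin) return false;
    *tmin_out = tmin;
    return true;
  }
};

// batch-statistics accumulator
struct Scorer {
  long n;
  int nb;
  std::vector<double> sum, sq, cur;
  int cur_batch;
  Scorer(long nvox, int nbatch)
      : n(nvox), nb(nbatch), sum(nvox, 0.0), sq(nvox, 0.0), cur(nvox, 0.0),
        cur_batch(0) {}
  inline void add(long i, double v) { cur[i] += v; }
  void flush() {
    for (long i = 0; i < n; ++i) {
      double c = cur[i];
      if (c != 0.0) {
        sum[i] += c;
        sq[i] += c * c;
        cur[i] = 0.0;
      }
    }
    ++cur_batch;
  }
  void maybe_flush(int batch) {
    while (cur_batch < batch) flush();
  }
};

// write batch totals back in the caller's native [x, y, z] layout
static void finalize(Scorer& sc, const Grid& g, NumericVector& dose,
                     NumericVector& unc) {
  int nb = sc.nb;
  double* dp = REAL(dose);
  double* up = REAL(unc);
  for (int k = 0; k < g.nz; ++k)
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i) {
        long zi = g.idx(i, j, k);
        long ni = (long)i + (long)g.nx * ((long)j + (long)g.ny * (long)k);
        double s = sc.sum[zi];
        if (!std::isfinite(s)) stop("NaN dose score encountered");
        double m = s / nb;
        double var = nb > 1 ? (sc.sq[zi] / nb - m * m) / (nb - 1) : 0.0;
        dp[ni] = s;
        up[ni] = (m > 0 && var > 0) ? std::sqrt(var) / m : 0.0;
      }
}

// ------------------------------------------------------ particle source ---

struct Source {
  // separable energy fluence: spatial pmf over pixels, energy pmf over bins
  int nx, ny, ne;
  double px;                 // pixel size (cm)
  double x0, y0;             // first pixel center (cm)
  std::vector<double> cdf;   // flattened spatial cdf (independence backend)
  std::vector<double> ecdf;
  const double* f;
  const double* eb;          // bin centers (MeV)
  double sad, start_z;       // source at (0,0,-sad); start plane z = start_z
  int backend;               // 0 independence, 1 Metropolis-Hastings
  double mh_sigma_px;
  int burnin;
  int cx, cy;                // MH chain state
  double fcur;

  Source(const NumericMatrix& fv, double px_, double x0_, double y0_,
         const NumericVector& ebins, const NumericVector& ew, double sad_,
         double start_z_, int backend_, double mh_sigma_px_, int burnin_,
         Rng& rng)
      : nx(fv.nrow()), ny(fv.ncol()), ne(ebins.size()), px(px_), x0(x0_),
        y0(y0_), f(REAL(fv)), eb(REAL(ebins)), sad(sad_), start_z(start_z_),
        backend(backend_), mh_sigma_px(mh_sigma_px_), burnin(burnin_) {
    double tot = 0;
    cdf.resize((size_t)nx * ny);
    for (size_t i = 0; i < cdf.size(); ++i) { tot += f[i]; cdf[i] = tot; }
    for (size_t i = 0; i < cdf.size(); ++i) cdf[i] /= tot;
    double et = 0;
    ecdf.resize(ne);
    for (int i = 0; i < ne; ++i) { et += ew[i]; ecdf[i] = et; }
    for (int i = 0; i < ne; ++i) ecdf[i] /= et;
    // MH chain starts at the fluence maximum, then burns in
    long imax = 0;
    for (long i = 1; i < (long)cdf.size(); ++i)
      if (f[i] > f[imax]) imax = i;
    cx = imax % nx; cy = imax / nx;
    fcur = f[imax];
    if (backend == 1)
      for (int i = 0; i < burnin; ++i) mh_step(rng);
  }

  inline void mh_step(Rng& rng) {
    int pxn = cx + (int)std::lround(rng.gauss() * mh_sigma_px);
    int pyn = cy + (int)std::lround(rng.gauss() * mh_sigma_px);
    if (pxn < 0 || pxn >= nx || pyn < 0 || pyn >= ny) return;
    double fn = f[(long)pxn + (long)nx * pyn];
    if (fn <= 0) return;
    if (fn >= fcur || rng.u01() < fn / fcur) {
      cx = pxn; cy = pyn; fcur = fn;
    }
  }

  // draws one particle: start position on the start plane, unit direction
  // from the point source through the sampled SAD-plane position, energy.
  // Energies use a jittered golden-ratio low-discrepancy sequence over the
  // spectrum CDF: the energy mix of a run is then nearly exact, removing
  // the dominant shape-noise mode of depth-dose curves.
  inline void draw(Rng& rng, long i, long ntot, double* pos, double* dir,
                   double* e) {
    long pix;
    if (backend == 1) {
      mh_step(rng);
      pix = (long)cx + (long)nx * cy;
    } else {
      double u = rng.u01();
      long lo = 0, hi = (long)cdf.size() - 1;
      while (lo < hi) {
        long mid = (lo + hi) / 2;
        if (cdf[mid] < u) lo = mid + 1; else hi = mid;
      }
      pix = lo;
    }
    int ix = pix % nx, iy = pix / nx;
    double xs = x0 + ix * px + (rng.u01() - 0.5) * px;
    double ys = y0 + iy * px + (rng.u01() - 0.5) * px;
    // source at (0, 0, -sad); SAD plane at z = 0 (isocenter plane)
    double d[3] = {xs, ys, sad};
    double nrm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    dir[0] = d[0] / nrm; dir[1] = d[1] / nrm; dir[2] = d[2] / nrm;
    double t = (sad + start_z) / sad;  // back-project to the start plane
    pos[0] = xs * t; pos[1] = ys * t; pos[2] = start_z;
    double uu = i * 0.618033988749895 + rng.u01() / (double)ntot;
    double u = uu - std::floor(uu);
    int lo = 0, hi = ne - 1;
    while (lo < hi) {
      int mid = (lo + hi) / 2;
      if (ecdf[mid] < u) lo = mid + 1; else hi = mid;
    }
    *e = eb[lo];
  }
};

// [[Rcpp::export]]
List cpp_sample_particles(NumericMatrix fvals, double px_cm, double x0_cm,
                          double y0_cm, NumericVector ebins,
                          NumericVector eweights, int n, double sad_cm,
                          double start_z_cm, int backend, double mh_sigma_px,
                          int burnin, double seed) {
  Rng rng((uint64_t)seed);
  Source src(fvals, px_cm, x0_cm, y0_cm, ebins, eweights, sad_cm, start_z_cm,
             backend, mh_sigma_px, burnin, rng);
  NumericMatrix out(n, 7);  // x y z vx vy vz E
  double pos[3], dir[3], e;
  for (int i = 0; i < n; ++i) {
    Rng prng((uint64_t)seed + (uint64_t)(i + 1) * 0x9E3779B97f4A7C15ULL);
    src.draw(backend == 1 ? rng : prng, i, n, pos, dir, &e);
    out(i, 0) = pos[0]; out(i, 1) = pos[1]; out(i, 2) = pos[2];
    out(i, 3) = dir[0]; out(i, 4) = dir[1]; out(i, 5) = dir[2];
    out(i, 6) = e;
  }
  colnames(out) = CharacterVector::create("x", "y", "z", "vx", "vy", "vz",
                                          "energy");
  return List::create(_["particles"] = out);
}

// rotate `dir` by polar angle acos(ct) about itself with uniform azimuth
static inline void rotate_dir(Rng& rng, double* dir, double ct) {
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 6.283185307179586 * rng.u01();
  double sp = std::sin(phi), cp = std::cos(phi);
  double u = dir[0], v = dir[1], w = dir[2];
  double s2 = std::sqrt(std::max(1e-20, 1.0 - w * w));
  double nu, nv, nw;
  if (s2 > 1e-8) {
    nu = u * ct + st * (u * w * cp - v * sp) / s2;
    nv = v * ct + st * (v * w * cp + u * sp) / s2;
    nw = w * ct - st * cp * s2;
  } else {
    nu = st * cp; nv = st * sp; nw = (w > 0 ? ct : -ct);
  }
  double nn = std::sqrt(nu * nu + nv * nv + nw * nw);
  dir[0] = nu / nn; dir[1] = nv / nn; dir[2] = nw / nn;
}

// --------------------------------------------------------- electrons ------

struct ETables {
  LogTable stop;   // MeV cm^2/g
  ETables(const NumericVector& eg, const NumericVector& sp) : stop(eg, sp) {}
};

struct BField {
  bool present;
  const double* bx; const double* by; const double* bz;
};

static inline void bfield_at(const Grid& g, const BField& B, const double* p,
                             double* bv) {
  bv[0] = bv[1] = bv[2] = 0.0;
  if (!B.present) return;
  int v[3];
  if (!g.voxel_of(p, v)) return;  // field defined on the phantom grid only
  long i = g.idx(v[0], v[1], v[2]);
  bv[0] = B.bx[i]; bv[1] = B.by[i]; bv[2] = B.bz[i];
}

// one condensed-history electron; deposits into sc (mass dose: MeV/g)
static void track_electron(const Grid& g, const ETables& et, const BField& B,
                           Scorer& sc, Rng& rng, double* pos, double* dir,
                           double e, double w, double ecut, double step_cm,
                           double voxvol) {
  double path = 0.0;
  const double X0 = 36.08;  // radiation length of water, g/cm^2
  while (e > ecut && path < 500.0) {
    double rho = g.density_at(pos);
    bool vac = rho < 1e-3;
    double s = vac ? 2.5 * step_cm : step_cm;
    double de = 0.0;
    if (!vac) {
      double sp = et.stop.at(e);
      de = sp * rho * s;
      if (de >= e - ecut) {          // range end inside this step
        s = (e - ecut) / (sp * rho);
        de = e;                      // deposit everything incl. sub-cutoff
      }
    }
    // magnetic deflection (first order): dv = (s/R) vxB/|vxB|
    double bv[3];
    bfield_at(g, B, pos, bv);
    double cx = dir[1] * bv[2] - dir[2] * bv[1];
    double cy = dir[2] * bv[0] - dir[0] * bv[2];
    double cz = dir[0] * bv[1] - dir[1] * bv[0];
    double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (cn > 1e-12) {
      double pc = std::sqrt(e * (e + 2.0 * 0.51099895));
      double R = pc / (2.99792458 * cn);  // gyroradius, cm (pc MeV, |vxB| T)
      double fac = s / R;
      double nv[3] = {dir[0] + fac * cx / cn, dir[1] + fac * cy / cn,
                      dir[2] + fac * cz / cn};
      double nn = std::sqrt(nv[0] * nv[0] + nv[1] * nv[1] + nv[2] * nv[2]);
      dir[0] = nv[0] / nn; dir[1] = nv[1] / nn; dir[2] = nv[2] / nn;
    }
    // Highland multiple scattering in medium
    if (!vac) {
      double xo = s * rho / X0;
      double pc = std::sqrt(e * (e + 2.0 * 0.51099895));
      double beta_pc = pc * pc / (e + 0.51099895);
      double th0 = 13.6 / beta_pc * std::sqrt(xo) *
                   (1.0 + 0.038 * std::log(std::max(xo, 1e-12)));
      if (th0 > 1.0) th0 = 1.0;  // condensed-history step sanity bound
      if (th0 > 0) {
        double g1 = rng.gauss(), g2 = rng.gauss();
        double th = th0 * std::sqrt(g1 * g1 + g2 * g2);
        rotate_dir(rng, dir, std::cos(th));
      }
    }
    // move, deposit at the segment midpoint voxel
    double mid[3] = {pos[0] + 0.5 * s * dir[0], pos[1] + 0.5 * s * dir[1],
                     pos[2] + 0.5 * s * dir[2]};
    if (de > 0) {
      int v[3];
      if (g.voxel_of(mid, v)) {
        double rv = g.rho[g.idx(v[0], v[1], v[2])];
        if (rv > 1e-6) sc.add(g.idx(v[0], v[1], v[2]), w * de / (rv * voxvol));
      }
    }
    pos[0] += s * dir[0]; pos[1] += s * dir[1]; pos[2] += s * dir[2];
    e -= de;
    path += s;
    if (vac) {
      // outside the grid and not heading back: stop tracking
      double tenter;
      if (!g.enter(pos, dir, &tenter) && !B.present) break;
    }
  }
}

// --------------------------------------------------------- photons --------

struct XTables {
  LogTable mu;      // mu/rho total (cm^2/g)
  LogTable muen;    // muen/rho (cm^2/g)
  LogTable pcompt;  // Compton fraction of mu
  LogTable smear;   // forward smear distance (cm, unit density)
  XTables(const NumericVector& eg, const NumericVector& m,
          const NumericVector& me, const NumericVector& pc,
          const NumericVector& sm)
      : mu(eg, m), muen(eg, me), pcompt(eg, pc), smear(eg, sm) {}
};

// Kahn's rejection sampling of the Klein-Nishina scattered-photon energy.
// Returns x = E/E'; cos(theta) = 1 - (x-1)/k.
static inline double kahn_x(Rng& rng, double k) {
  for (;;) {
    double r1 = rng.u01(), r2 = rng.u01(), r3 = rng.u01();
    if (r1 <= (2.0 * k + 1.0) / (2.0 * k + 9.0)) {
      double x = 1.0 + 2.0 * k * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) return x;
    } else {
      double x = (2.0 * k + 1.0) / (1.0 + 2.0 * k * r2);
      double ct = 1.0 - (x - 1.0) / k;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) return x;
    }
  }
}

struct PhotonOpts {
  double ecut;        // photon cutoff (MeV)
  double ecut_e;      // electron cutoff (MeV)
  bool scatter;       // track Compton-scattered photons
  bool smear;         // forward electron-range smearing of the kerma score
  bool analog_e;      // transport secondary electrons instead of kerma
  int score_mode;     // 0 = kerma/dose, 1 = primary track-length fluence
  double estep;       // electron step (cm)
};

static void track_photon(const Grid& g, const XTables& xt, const ETables& et,
                         const BField& B, Scorer& sc, Rng& rng, double* pos0,
                         double* dir0, double e0, double w, const PhotonOpts& o,
                         double voxvol) {
  double pos[3] = {pos0[0], pos0[1], pos0[2]};
  double dir[3] = {dir0[0], dir0[1], dir0[2]};
  double e = e0;
  int generation = 0;
  for (;;) {  // one loop pass per flight (generation)
    double t0;
    if (!g.enter(pos, dir, &t0)) return;
    if (t0 > 0) {
      pos[0] += t0 * dir[0]; pos[1] += t0 * dir[1]; pos[2] += t0 * dir[2];
    }
    double tau = -std::log(rng.u01());
    double mu_rho = xt.mu.at(e);
    double muen_rho = xt.muen.at(e);
    double smear_cm = o.smear ? xt.smear.at(e) : 0.0;
    // Primary flights use expected-value scoring: the deposit along every
    // segment of the whole ray is weighted by the survival probability
    // exp(-optical depth), which removes the interaction-truncation noise
    // from the primary dose; the sampled interaction point still spawns
    // the (analog) scattered branch.  Scattered flights keep plain analog
    // track-length scoring.
    bool expval = (generation == 0);
    double tau_acc = 0.0;
    bool interacted = false;
    double pint[3] = {0, 0, 0};
    int v[3];
    // nudge inside
    pos[0] += 1e-9 * dir[0]; pos[1] += 1e-9 * dir[1]; pos[2] += 1e-9 * dir[2];
    while (g.voxel_of(pos, v)) {
      long vi = g.idx(v[0], v[1], v[2]);
      double rho = g.rho[vi];
      // distance to next voxel boundary
      double dl = 1e30;
      if (dir[0] > 1e-12) dl = std::min(dl, (g.x0 + (v[0] + 1) * g.vx - pos[0]) / dir[0]);
      else if (dir[0] < -1e-12) dl = std::min(dl, (g.x0 + v[0] * g.vx - pos[0]) / dir[0]);
      if (dir[1] > 1e-12) dl = std::min(dl, (g.y0 + (v[1] + 1) * g.vy - pos[1]) / dir[1]);
      else if (dir[1] < -1e-12) dl = std::min(dl, (g.y0 + v[1] * g.vy - pos[1]) / dir[1]);
      if (dir[2] > 1e-12) dl = std::min(dl, (g.z0 + (v[2] + 1) * g.vz - pos[2]) / dir[2]);
      else if (dir[2] < -1e-12) dl = std::min(dl, (g.z0 + v[2] * g.vz - pos[2]) / dir[2]);
      if (dl < 0) dl = 0;
      double mu_lin = mu_rho * rho;
      double seg = dl + 1e-9;
      if (!expval) {
        if (mu_lin > 0 && tau < mu_lin * seg) {
          seg = tau / mu_lin;
          interacted = true;
        } else {
          tau -= mu_lin * seg;
        }
      } else if (!interacted && mu_lin > 0 &&
                 tau < tau_acc + mu_lin * seg) {
        // sampled interaction point (branching only; scoring continues)
        double si = (tau - tau_acc) / mu_lin;
        pint[0] = pos[0] + si * dir[0];
        pint[1] = pos[1] + si * dir[1];
        pint[2] = pos[2] + si * dir[2];
        interacted = true;
      }
      double tw = 1.0;
      if (expval) {
        tw = std::exp(-(tau_acc + 0.5 * mu_lin * seg));
        tau_acc += mu_lin * seg;
      }
      // scoring along the segment
      if (o.score_mode == 1) {
        if (generation == 0) sc.add(vi, tw * w * seg / voxvol);
      } else if (!o.analog_e && rho > 1e-6) {
        double kerma = tw * w * e * muen_rho * seg / voxvol;  // MeV/g
        if (smear_cm > 0 && generation == 0) {
          // primary-fluence buildup: advance the deposit by the mean
          // forward displacement (half the secondary-electron range) of
          // the CSDA electrons set in motion; the spectrum mix of ranges
          // smooths the resulting depth ramp.  Scattered-photon kerma is
          // diffuse already and is deposited locally.
          double off = 0.5 * seg + 0.5 * smear_cm / rho;
          double pp[3] = {pos[0] + off * dir[0], pos[1] + off * dir[1],
                          pos[2] + off * dir[2]};
          int vv[3];
          if (g.voxel_of(pp, vv)) sc.add(g.idx(vv[0], vv[1], vv[2]), kerma);
        } else {
          sc.add(vi, kerma);
        }
      }
      pos[0] += seg * dir[0]; pos[1] += seg * dir[1]; pos[2] += seg * dir[2];
      if (!expval && interacted) break;
    }
    if (!interacted) return;   // escaped the grid (or never interacted)
    if (expval) {
      pos[0] = pint[0]; pos[1] = pint[1]; pos[2] = pint[2];
    }
    // interaction
    double pc_frac = xt.pcompt.at(e);
    if (rng.u01() < pc_frac) {
      double k = e / 0.51099895;
      double x = kahn_x(rng, k);
      double ct = 1.0 - (x - 1.0) / k;
      double eprime = e / x;
      double t_e = e - eprime;
      if (o.analog_e && t_e > o.ecut_e) {
        // Compton electron kinematics: cot(theta_e) = (1+k) tan(theta/2)
        double edir[3] = {dir[0], dir[1], dir[2]};
        double tan_half = std::sqrt(std::max(0.0, (1.0 - ct) / (1.0 + ct)));
        double cot_e = (1.0 + k) * tan_half;
        double th_e = std::atan2(1.0, cot_e);
        double cte = std::cos(th_e);
        rotate_dir(rng, edir, cte);
        double ep[3] = {pos[0], pos[1], pos[2]};
        track_electron(g, et, B, sc, rng, ep, edir, t_e, w, o.ecut_e, o.estep,
                       voxvol);
      } else if (o.analog_e) {
        // sub-cutoff Compton electron: deposit locally
        int vv[3];
        if (g.voxel_of(pos, vv)) {
          double rv = g.rho[g.idx(vv[0], vv[1], vv[2])];
          if (rv > 1e-6) sc.add(g.idx(vv[0], vv[1], vv[2]), w * t_e / (rv * voxvol));
        }
      }
      rotate_dir(rng, dir, ct);
      e = eprime;
      ++generation;
      if (!o.scatter || e < o.ecut) return;
      // unbiased survival roulette on multiply-scattered photons: the
      // low-energy random walk otherwise dominates runtime while carrying
      // a small fraction of the dose.  A weight window (cap 8x) keeps the
      // variance bounded: without it, rare long chains carry 2^n weights
      // and deposit pathological local blobs.
      if (generation >= 2 && w < 8.0) {
        if (rng.u01() < 0.5) w *= 2.0; else return;
      }
      // continue the loop with the scattered photon
    } else {
      // photoelectric / pair lumped: local absorption
      if (o.analog_e) {
        double edir[3] = {dir[0], dir[1], dir[2]};
        double ep[3] = {pos[0], pos[1], pos[2]};
        if (e > o.ecut_e)
          track_electron(g, et, B, sc, rng, ep, edir, e, w, o.ecut_e, o.estep,
                         voxvol);
      }
      return;
    }
  }
}

// native [x, y, z] input permuted into the engine's z-fastest layout
static void permute_zfirst(const double* src, int nx, int ny, int nz,
                           std::vector<double>& dst) {
  dst.resize((size_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const double* row = src + (size_t)nx * ((size_t)j + (size_t)ny * k);
      for (int i = 0; i < nx; ++i)
        dst[(size_t)k + (size_t)nz * ((size_t)i + (size_t)nx * j)] = row[i];
    }
}

static Grid make_grid(const NumericVector& density, const IntegerVector& dims,
                      const NumericVector& voxel, const NumericVector& origin,
                      std::vector<double>& store) {
  Grid g;
  g.nx = dims[0]; g.ny = dims[1]; g.nz = dims[2];
  g.vx = voxel[0]; g.vy = voxel[1]; g.vz = voxel[2];
  g.x0 = origin[0] - voxel[0] / 2;
  g.y0 = origin[1] - voxel[1] / 2;
  g.z0 = origin[2] - voxel[2] / 2;
  permute_zfirst(REAL(density), g.nx, g.ny, g.nz, store);
  g.rho = store.data();
  return g;
}

// Transport with the source fused in (photons sampled on the fly), or from
// an explicit particle matrix when `particles` has rows.
// [[Rcpp::export]]
List cpp_transport_photons(NumericVector density, IntegerVector dims,
                           NumericVector voxel, NumericVector origin,
                           NumericMatrix particles, NumericMatrix fvals,
                           double px_cm, double x0_cm, double y0_cm,
                           NumericVector ebins, NumericVector eweights,
                           int n, double sad_cm, double start_z_cm,
                           int backend, double mh_sigma_px, int burnin,
                           NumericVector xt_egrid, NumericVector xt_mu,
                           NumericVector xt_muen, NumericVector xt_pc,
                           NumericVector xt_smear, NumericVector et_egrid,
                           NumericVector et_stop, List bfield, double seed,
                           int nbatch, double ecut, double ecut_e,
                           bool scatter, bool smear, bool analog_e,
                           int score_mode, double estep) {
  std::vector<double> rho_store, bx_s, by_s, bz_s;
  Grid g = make_grid(density, dims, voxel, origin, rho_store);
  XTables xt(xt_egrid, xt_mu, xt_muen, xt_pc, xt_smear);
  ETables et(et_egrid, et_stop);
  BField B{false, nullptr, nullptr, nullptr};
  if (bfield.size() == 3) {
    B.present = true;
    permute_zfirst(REAL((SEXP)bfield[0]), g.nx, g.ny, g.nz, bx_s);
    permute_zfirst(REAL((SEXP)bfield[1]), g.nx, g.ny, g.nz, by_s);
    permute_zfirst(REAL((SEXP)bfield[2]), g.nx, g.ny, g.nz, bz_s);
    B.bx = bx_s.data(); B.by = by_s.data(); B.bz = bz_s.data();
  }
  long nvox = (long)g.nx * g.ny * g.nz;
  double voxvol = g.vx * g.vy * g.vz;
  Scorer sc(nvox, nbatch);
  PhotonOpts o{ecut, ecut_e, scatter, smear, analog_e, score_mode, estep};
  Rng rng((uint64_t)seed);
  bool fused = particles.nrow() == 0;
  Source* src = nullptr;
  if (fused)
    src = new Source(fvals, px_cm, x0_cm, y0_cm, ebins, eweights, sad_cm,
                     start_z_cm, backend, mh_sigma_px, burnin, rng);
  int ntot = fused ? n : particles.nrow();
  double e_in = 0.0;
  for (int i = 0; i < ntot; ++i) {
    sc.maybe_flush((int)(((long)i * nbatch) / ntot));
    // per-history substream: rejection sampling consumes a variable number
    // of draws, so a shared stream would decohere every downstream history
    // after any parameter change; per-history streams keep perturbations
    // local (and make the result independent of history order)
    Rng prng((uint64_t)seed + (uint64_t)(i + 1) * 0x9E3779B97f4A7C15ULL);
    double pos[3], dir[3], e;
    if (fused) {
      src->draw(backend == 1 ? rng : prng, i, ntot, pos, dir, &e);
    } else {
      pos[0] = particles(i, 0); pos[1] = particles(i, 1); pos[2] = particles(i, 2);
      dir[0] = particles(i, 3); dir[1] = particles(i, 4); dir[2] = particles(i, 5);
      e = particles(i, 6);
    }
    e_in += e;
    track_photon(g, xt, et, B, sc, prng, pos, dir, e, 1.0, o, voxvol);
  }
  sc.maybe_flush(nbatch);
  delete src;
  NumericVector dose(nvox), unc(nvox);
  finalize(sc, g, dose, unc);
  return List::create(_["dose"] = dose, _["unc"] = unc,
                      _["energy_in"] = e_in, _["n"] = ntot);
}

// [[Rcpp::export]]
List cpp_transport_electrons(NumericVector density, IntegerVector dims,
                             NumericVector voxel, NumericVector origin,
                             NumericMatrix particles, NumericMatrix fvals,
                             double px_cm, double x0_cm, double y0_cm,
                             NumericVector ebins, NumericVector eweights,
                             int n, double sad_cm, double start_z_cm,
                             int backend, double mh_sigma_px, int burnin,
                             NumericVector et_egrid, NumericVector et_stop,
                             List bfield, double seed, int nbatch,
                             double ecut_e, double estep) {
  std::vector<double> rho_store, bx_s, by_s, bz_s;
  Grid g = make_grid(density, dims, voxel, origin, rho_store);
  ETables et(et_egrid, et_stop);
  BField B{false, nullptr, nullptr, nullptr};
  if (bfield.size() == 3) {
    B.present = true;
    permute_zfirst(REAL((SEXP)bfield[0]), g.nx, g.ny, g.nz, bx_s);
    permute_zfirst(REAL((SEXP)bfield[1]), g.nx, g.ny, g.nz, by_s);
    permute_zfirst(REAL((SEXP)bfield[2]), g.nx, g.ny, g.nz, bz_s);
    B.bx = bx_s.data(); B.by = by_s.data(); B.bz = bz_s.data();
  }
  long nvox = (long)g.nx * g.ny * g.nz;
  double voxvol = g.vx * g.vy * g.vz;
  Scorer sc(nvox, nbatch);
  Rng rng((uint64_t)seed);
  bool fused = particles.nrow() == 0;
  Source* src = nullptr;
  if (fused)
    src = new Source(fvals, px_cm, x0_cm, y0_cm, ebins, eweights, sad_cm,
                     start_z_cm, backend, mh_sigma_px, burnin, rng);
  int ntot = fused ? n : particles.nrow();
  double e_in = 0.0;
  for (int i = 0; i < ntot; ++i) {
    sc.maybe_flush((int)(((long)i * nbatch) / ntot));
    Rng prng((uint64_t)seed + (uint64_t)(i + 1) * 0x9E3779B97f4A7C15ULL);
    double pos[3], dir[3], e;
    if (fused) {
      src->draw(backend == 1 ? rng : prng, i, ntot, pos, dir, &e);
    } else {
      pos[0] = particles(i, 0); pos[1] = particles(i, 1); pos[2] = particles(i, 2);
      dir[0] = particles(i, 3); dir[1] = particles(i, 4); dir[2] = particles(i, 5);
      e = particles(i, 6);
    }
    e_in += e;
    if (e > ecut_e)
      track_electron(g, et, B, sc, prng, pos, dir, e, 1.0, ecut_e, estep,
                     voxvol);
  }
  sc.maybe_flush(nbatch);
  delete src;
  NumericVector dose(nvox), unc(nvox);
  finalize(sc, g, dose, unc);
  return List::create(_["dose"] = dose, _["unc"] = unc,
                      _["energy_in"] = e_in, _["n"] = ntot);
}
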