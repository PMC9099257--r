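// Coarse-grained energy model and BAOAB Langevin propagator.
//
// Units: coordinates in Angstrom, energies in kcal/mol, time in ps, masses in
// amu, temperatures in K.  Conversion: 1 amu*A^2/ps^2 = 0.00239005736 kcal/mol
// (equivalently a[A/ps^2] = 418.4 * F[kcal/mol/A] / m[amu]).
//
// All harmonic terms use the E = k*x^2 convention (no 1/2 factor).
//
// gREST term classes: 0 = uu (scaled by lambda), 1 = uv (scaled by
// sqrt(lambda)), 2 = vv (unscaled), 3 = restraint (unscaled, reported
// separately and never mixed into the solute partition).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double KB = 0.0019872041;        // kcal/mol/K
static const double ACC_FAC = 418.4;          // (kcal/mol/A)/amu -> A/ps^2

// ---------------------------------------------------------------------------
// Deterministic counter-style RNG (splitmix64 stream + Box-Muller normals).
// Streams are seeded from (master seed, replica id, segment counter) so that
// exchanges can swap parameters without touching a replica's noise sequence.
// ---------------------------------------------------------------------------
struct Rng {
  uint64_t s;
  bool have_spare;
  double spare;
  explicit Rng(uint64_t seed) : s(seed), have_spare(false), spare(0.0) {}
  uint64_t next_u64() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double u01() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = u01();
    while (u1 <= 1e-300) u1 = u01();
    double u2 = u01();
    double r = std::sqrt(-2.0 * std::log(u1));
    double th = 2.0 * M_PI * u2;
    spare = r * std::sin(th);
    have_spare = true;
    return r * std::cos(th);
  }
};

static uint64_t mix64(uint64_t a, uint64_t b) {
  uint64_t z = a + 0x9E3779B97F4A7C15ULL * (b + 1);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// [[Rcpp::export(name = ".stream_seed")]]
double stream_seed_cpp(double master, double replica, double segment) {
  uint64_t s = mix64(mix64((uint64_t)master, (uint64_t)replica),
                     (uint64_t)segment);
  // return as double holding an exact 53-bit value
  return (double)(s >> 11);
}

// ---------------------------------------------------------------------------
// Energy evaluation
// ---------------------------------------------------------------------------

struct EnergyAcc {
  double E[4];      // uu, uv, vv, restraint
  EnergyAcc() { E[0] = E[1] = E[2] = E[3] = 0.0; }
};

static inline double scale_factor(int cls, double lambda, double sqrtl) {
  if (cls == 0) return lambda;
  if (cls == 1) return sqrtl;
  return 1.0;
}

// Accumulates breakdown energies and *scaled* forces.  coords/f are n x 3.
static void compute_all(const NumericMatrix& X, const List& sys, double lambda,
                        const List& restr, EnergyAcc& acc, NumericMatrix& F,
                        bool want_forces) {
  const double sqrtl = std::sqrt(lambda);
  const int n = X.nrow();

  // --- tethers: E = k * |x - p|^2
  NumericMatrix teth = sys["tethers"];
  for (int t = 0; t < teth.nrow(); ++t) {
    int b = (int)teth(t, 0);
    double k = teth(t, 4);
    int cls = (int)teth(t, 5);
    double dx = X(b, 0) - teth(t, 1), dy = X(b, 1) - teth(t, 2),
           dz = X(b, 2) - teth(t, 3);
    acc.E[cls] += k * (dx * dx + dy * dy + dz * dz);
    if (want_forces) {
      double s = scale_factor(cls, lambda, sqrtl);
      F(b, 0) -= 2.0 * s * k * dx;
      F(b, 1) -= 2.0 * s * k * dy;
      F(b, 2) -= 2.0 * s * k * dz;
    }
  }

  // --- box walls (half-harmonic, always vv): per dimension
  NumericMatrix box = sys["box"];   // 3 x 2 (lo, hi)
  double kwall = as<double>(sys["kwall"]);
  IntegerVector frozen = sys["frozen"];
  for (int i = 0; i < n; ++i) {
    if (frozen[i]) continue;
    for (int d = 0; d < 3; ++d) {
      double lo = box(d, 0), hi = box(d, 1), x = X(i, d);
      if (x < lo) {
        double dx = x - lo;
        acc.E[2] += kwall * dx * dx;
        if (want_forces) F(i, d) -= 2.0 * kwall * dx;
      } else if (x > hi) {
        double dx = x - hi;
        acc.E[2] += kwall * dx * dx;
        if (want_forces) F(i, d) -= 2.0 * kwall * dx;
      }
    }
  }

  // --- bonds: E = kb * (r - r0)^2
  NumericMatrix bonds = sys["bonds"];
  for (int t = 0; t < bonds.nrow(); ++t) {
    int i = (int)bonds(t, 0), j = (int)bonds(t, 1);
    double kb = bonds(t, 2), r0 = bonds(t, 3);
    int cls = (int)bonds(t, 4);
    double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
           dz = X(i, 2) - X(j, 2);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    double dr = r - r0;
    acc.E[cls] += kb * dr * dr;
    if (want_forces && r > 1e-12) {
      double s = scale_factor(cls, lambda, sqrtl);
      double c = -2.0 * s * kb * dr / r;
      F(i, 0) += c * dx; F(i, 1) += c * dy; F(i, 2) += c * dz;
      F(j, 0) -= c * dx; F(j, 1) -= c * dy; F(j, 2) -= c * dz;
    }
  }

  // --- angles: E = ka * (theta - theta0)^2
  NumericMatrix angles = sys["angles"];
  for (int t = 0; t < angles.nrow(); ++t) {
    int i = (int)angles(t, 0), j = (int)angles(t, 1), k = (int)angles(t, 2);
    double ka = angles(t, 3), th0 = angles(t, 4);
    int cls = (int)angles(t, 5);
    double ux = X(i, 0) - X(j, 0), uy = X(i, 1) - X(j, 1), uz = X(i, 2) - X(j, 2);
    double vx = X(k, 0) - X(j, 0), vy = X(k, 1) - X(j, 1), vz = X(k, 2) - X(j, 2);
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    double nv = std::sqrt(vx * vx + vy * vy + vz * vz);
    if (nu < 1e-12 || nv < 1e-12) continue;
    double cth = (ux * vx + uy * vy + uz * vz) / (nu * nv);
    cth = std::max(-1.0, std::min(1.0, cth));
    double th = std::acos(cth);
    double dth = th - th0;
    acc.E[cls] += ka * dth * dth;
    if (want_forces) {
      double sth = std::sqrt(std::max(1.0 - cth * cth, 1e-12));
      double s = scale_factor(cls, lambda, sqrtl);
      double dEdth = 2.0 * s * ka * dth;
      double pref = -dEdth / sth;
      // dtheta/dri etc.
      double fix = pref * (vx / (nu * nv) - cth * ux / (nu * nu)) * -1.0;
      double fiy = pref * (vy / (nu * nv) - cth * uy / (nu * nu)) * -1.0;
      double fiz = pref * (vz / (nu * nv) - cth * uz / (nu * nu)) * -1.0;
      double fkx = pref * (ux / (nu * nv) - cth * vx / (nv * nv)) * -1.0;
      double fky = pref * (uy / (nu * nv) - cth * vy / (nv * nv)) * -1.0;
      double fkz = pref * (uz / (nu * nv) - cth * vz / (nv * nv)) * -1.0;
      F(i, 0) += fix; F(i, 1) += fiy; F(i, 2) += fiz;
      F(k, 0) += fkx; F(k, 1) += fky; F(k, 2) += fkz;
      F(j, 0) -= fix + fkx; F(j, 1) -= fiy + fky; F(j, 2) -= fiz + fkz;
    }
  }

  // --- dihedrals: E = kd * (1 + cos(m*phi - phase))
  NumericMatrix dih = sys["dihedrals"];
  for (int t = 0; t < dih.nrow(); ++t) {
    int ai = (int)dih(t, 0), aj = (int)dih(t, 1), ak = (int)dih(t, 2),
        al = (int)dih(t, 3);
    double kd = dih(t, 4);
    int m = (int)dih(t, 5);
    double phase = dih(t, 6);
    int cls = (int)dih(t, 7);
    double b1[3] = {X(aj,0)-X(ai,0), X(aj,1)-X(ai,1), X(aj,2)-X(ai,2)};
    double b2[3] = {X(ak,0)-X(aj,0), X(ak,1)-X(aj,1), X(ak,2)-X(aj,2)};
    double b3[3] = {X(al,0)-X(ak,0), X(al,1)-X(ak,1), X(al,2)-X(ak,2)};
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2],
                    b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2],
                    b2[0]*b3[1]-b2[1]*b3[0]};
    double nb2 = std::sqrt(b2[0]*b2[0]+b2[1]*b2[1]+b2[2]*b2[2]);
    double n1sq = n1[0]*n1[0]+n1[1]*n1[1]+n1[2]*n1[2];
    double n2sq = n2[0]*n2[0]+n2[1]*n2[1]+n2[2]*n2[2];
    if (nb2 < 1e-12 || n1sq < 1e-24 || n2sq < 1e-24) continue;
    double m1[3] = {n1[1]*b2[2]-n1[2]*b2[1], n1[2]*b2[0]-n1[0]*b2[2],
                    n1[0]*b2[1]-n1[1]*b2[0]};
    double x = n1[0]*n2[0]+n1[1]*n2[1]+n1[2]*n2[2];
    double y = (m1[0]*n2[0]+m1[1]*n2[1]+m1[2]*n2[2]) / nb2;
    double phi = std::atan2(y, x);
    acc.E[cls] += kd * (1.0 + std::cos(m * phi - phase));
    if (want_forces) {
      double s = scale_factor(cls, lambda, sqrtl);
      double dEdphi = -s * kd * m * std::sin(m * phi - phase);
      double fi[3], fl[3];
      for (int d = 0; d < 3; ++d) {
        fi[d] = -dEdphi * nb2 / n1sq * n1[d];
        fl[d] =  dEdphi * nb2 / n2sq * n2[d];
      }
      double tb = (b1[0]*b2[0]+b1[1]*b2[1]+b1[2]*b2[2]) / (nb2 * nb2);
      double sb = (b3[0]*b2[0]+b3[1]*b2[1]+b3[2]*b2[2]) / (nb2 * nb2);
      // with b1 = r_j - r_i and b3 = r_l - r_k the projection coefficients
      // enter as (1 + t) and (1 + s); forces sum to zero by construction
      for (int d = 0; d < 3; ++d) {
        double fj = -(1.0 + tb) * fi[d] + sb * fl[d];
        double fk = tb * fi[d] - (1.0 + sb) * fl[d];
        F(ai, d) += fi[d];
        F(aj, d) += fj;
        F(ak, d) += fk;
        F(al, d) += fl[d];
      }
    }
  }

  // --- nonbonded pairs: Gaussian well + soft-core repulsion (functions of r^2)
  //     E = -eps * exp(-r^2 / (2 w^2)) + A * (sigma^2 / (r^2 + sigma^2))^6
  NumericMatrix pairs = sys["pairs"];
  for (int t = 0; t < pairs.nrow(); ++t) {
    int i = (int)pairs(t, 0), j = (int)pairs(t, 1);
    double eps = pairs(t, 2), w = pairs(t, 3), A = pairs(t, 4),
           sig = pairs(t, 5);
    int cls = (int)pairs(t, 6);
    double dx = X(i, 0) - X(j, 0), dy = X(i, 1) - X(j, 1),
           dz = X(i, 2) - X(j, 2);
    double r2 = dx * dx + dy * dy + dz * dz;
    double e = 0.0, dEdr2 = 0.0;
    if (eps != 0.0) {
      double g = std::exp(-r2 / (2.0 * w * w));
      e += -eps * g;
      dEdr2 += eps * g / (2.0 * w * w);
    }
    if (A != 0.0) {
      double s2 = sig * sig;
      double q = s2 / (r2 + s2);
      double q6 = q * q * q; q6 *= q6;
      e += A * q6;
      dEdr2 += -6.0 * A * q6 / (r2 + s2);
    }
    acc.E[cls] += e;
    if (want_forces) {
      double s = scale_factor(cls, lambda, sqrtl);
      double c = -2.0 * s * dEdr2;
      F(i, 0) += c * dx; F(i, 1) += c * dy; F(i, 2) += c * dz;
      F(j, 0) -= c * dx; F(j, 1) -= c * dy; F(j, 2) -= c * dz;
    }
  }

  // --- restraints (never scaled): positional + umbrella on the COM-distance CV
  if (restr.size() > 0) {
    if (restr.containsElementNamed("pos") && !Rf_isNull(restr["pos"])) {
      NumericMatrix pos = restr["pos"];
      for (int t = 0; t < pos.nrow(); ++t) {
        int b = (int)pos(t, 0);
        double k = pos(t, 4);
        double dx = X(b, 0) - pos(t, 1), dy = X(b, 1) - pos(t, 2),
               dz = X(b, 2) - pos(t, 3);
        acc.E[3] += k * (dx * dx + dy * dy + dz * dz);
        if (want_forces) {
          F(b, 0) -= 2.0 * k * dx;
          F(b, 1) -= 2.0 * k * dy;
          F(b, 2) -= 2.0 * k * dz;
        }
      }
    }
    if (restr.containsElementNamed("umb") && !Rf_isNull(restr["umb"])) {
      List umb = restr["umb"];
      IntegerVector anc = umb["anchor"], lig = umb["ligand"];
      NumericVector awt = umb["awt"], lwt = umb["lwt"];
      double c0 = as<double>(umb["center"]), ku = as<double>(umb["k"]);
      double Ra[3] = {0, 0, 0}, Rl[3] = {0, 0, 0};
      for (int t = 0; t < anc.size(); ++t)
        for (int d = 0; d < 3; ++d) Ra[d] += awt[t] * X(anc[t], d);
      for (int t = 0; t < lig.size(); ++t)
        for (int d = 0; d < 3; ++d) Rl[d] += lwt[t] * X(lig[t], d);
      double dv[3] = {Ra[0] - Rl[0], Ra[1] - Rl[1], Ra[2] - Rl[2]};
      double xi = std::sqrt(dv[0]*dv[0] + dv[1]*dv[1] + dv[2]*dv[2]);
      double dxi = xi - c0;
      acc.E[3] += ku * dxi * dxi;
      if (want_forces && xi > 1e-8) {
        double pref = -2.0 * ku * dxi / xi;
        for (int t = 0; t < anc.size(); ++t)
          for (int d = 0; d < 3; ++d) F(anc[t], d) += pref * awt[t] * dv[d];
        for (int t = 0; t < lig.size(); ++t)
          for (int d = 0; d < 3; ++d) F(lig[t], d) -= pref * lwt[t] * dv[d];
      }
    }
  }
}

static double cv_value(const NumericMatrix& X, const List& cvg) {
  if (cvg.size() == 0) return NA_REAL;
  IntegerVector anc = cvg["anchor"], lig = cvg["ligand"];
  NumericVector awt = cvg["awt"], lwt = cvg["lwt"];
  double Ra[3] = {0, 0, 0}, Rl[3] = {0, 0, 0};
  for (int t = 0; t < anc.size(); ++t)
    for (int d = 0; d < 3; ++d) Ra[d] += awt[t] * X(anc[t], d);
  for (int t = 0; t < lig.size(); ++t)
    for (int d = 0; d < 3; ++d) Rl[d] += lwt[t] * X(lig[t], d);
  double dx = Ra[0]-Rl[0], dy = Ra[1]-Rl[1], dz = Ra[2]-Rl[2];
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export(name = ".energy_cpp")]]
List energy_cpp(NumericMatrix coords, List sys, double lambda, List restr,
                bool want_forces) {
  EnergyAcc acc;
  NumericMatrix F(coords.nrow(), 3);
  compute_all(coords, sys, lambda, restr, acc, F, want_forces);
  double total_unscaled = acc.E[0] + acc.E[1] + acc.E[2] + acc.E[3];
  double scaled = lambda * acc.E[0] + std::sqrt(lambda) * acc.E[1] +
                  acc.E[2] + acc.E[3];
  return List::create(_["E_uu"] = acc.E[0], _["E_uv"] = acc.E[1],
                      _["E_vv"] = acc.E[2], _["E_restraint"] = acc.E[3],
                      _["total_unscaled"] = total_unscaled,
                      _["scaled_total"] = scaled, _["forces"] = F);
}

// [[Rcpp::export(name = ".propagate_cpp")]]
List propagate_cpp(NumericMatrix coords, NumericMatrix vels, List sys,
                   double lambda, List restr, List cvg, double dt, double gamma,
                   double Tsim, int nsteps, int stride, double stream,
                   bool record_coords, double t0) {
  int n = coords.nrow();
  NumericMatrix X = clone(coords), V = clone(vels);
  NumericVector mass = sys["mass"];
  IntegerVector frozen = sys["frozen"];
  Rng rng((uint64_t)stream);

  double c1 = std::exp(-gamma * dt);
  double kT = KB * Tsim;
  std::vector<double> sd_o(n), inv_m(n);
  for (int i = 0; i < n; ++i) {
    inv_m[i] = frozen[i] ? 0.0 : ACC_FAC / mass[i];
    sd_o[i] = frozen[i] ? 0.0
                        : std::sqrt((1.0 - c1 * c1) * kT * ACC_FAC / mass[i]);
  }

  int nframes = (stride > 0) ? nsteps / stride : 0;
  NumericMatrix frames(nframes, 9);
  NumericVector fcoords(record_coords ? (R_xlen_t)nframes * n * 3 : 0);

  EnergyAcc acc;
  NumericMatrix F(n, 3);
  compute_all(X, sys, lambda, restr, acc, F, true);

  int fidx = 0;
  for (int step = 1; step <= nsteps; ++step) {
    // B: half kick
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d) * inv_m[i];
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    }
    // O: Ornstein-Uhlenbeck
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) V(i, d) = c1 * V(i, d) + sd_o[i] * rng.norm();
    }
    // A: half drift
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) X(i, d) += 0.5 * dt * V(i, d);
    }
    // recompute forces, B: half kick
    acc = EnergyAcc();
    std::fill(F.begin(), F.end(), 0.0);
    compute_all(X, sys, lambda, restr, acc, F, true);
    double etot = acc.E[0] + acc.E[1] + acc.E[2] + acc.E[3];
    if (!std::isfinite(etot))
      stop("non-finite energy encountered at step %d", step);
    for (int i = 0; i < n; ++i) {
      if (frozen[i]) continue;
      for (int d = 0; d < 3; ++d) V(i, d) += 0.5 * dt * F(i, d) * inv_m[i];
    }

    if (stride > 0 && step % stride == 0 && fidx < nframes) {
      frames(fidx, 0) = step;
      frames(fidx, 1) = t0 + step * dt;
      frames(fidx, 2) = cv_value(X, cvg);
      frames(fidx, 3) = acc.E[0];
      frames(fidx, 4) = acc.E[1];
      frames(fidx, 5) = acc.E[2];
      frames(fidx, 6) = acc.E[3];
      frames(fidx, 7) = acc.E[0] + acc.E[1] + acc.E[2] + acc.E[3];
      frames(fidx, 8) = lambda * acc.E[0] + std::sqrt(lambda) * acc.E[1] +
                        acc.E[2] + acc.E[3];
      if (record_coords) {
        for (int i = 0; i < n; ++i)
          for (int d = 0; d < 3; ++d)
            fcoords[(R_xlen_t)fidx * n * 3 + (R_xlen_t)i * 3 + d] = X(i, d);
      }
      ++fidx;
    }
  }

  return List::create(_["coords"] = X, _["vels"] = V, _["frames"] = frames,
                      _["frame_coords"] = fcoords,
                      _["cv"] = cv_value(X, cvg));
}
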