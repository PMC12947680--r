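// Metropolis Monte Carlo engine for coarse-grained charged nanogels.
//
// Energies are in units of k_B T at the run temperature; lengths in nm.
// Electrostatics: Ewald summation with conducting ("tinfoil") boundary
// conditions. Coordinates are kept unwrapped (the network stays a
// contiguous object in real space); all distances use the minimum-image
// convention and reciprocal-space phases are periodic, so wrapping is
// never required during sampling.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <complex>
#include <cmath>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;
typedef std::complex<double> cplx;

// ---------------------------------------------------------------- RNG
// xoshiro256++ seeded through splitmix64: deterministic and identical
// across platforms, independent of R's RNG state.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  int randint(int n) {
    int v = (int)(unif() * n);
    return v >= n ? n - 1 : v;
  }
};

// ------------------------------------------------------------- system
struct Sys {
  int n;
  std::vector<double> px, py, pz;   // unwrapped positions (nm)
  std::vector<int> q;               // valence (e)
  std::vector<double> diam;         // diameter (nm)
  std::vector<char> hyd;            // hydrophobic-eligible flag
  std::vector<std::array<int, 2>> bonds;
  std::vector<std::vector<int>> bondOf;   // bond ids per bead
  std::vector<int> netIds;          // network beads (monomer+crosslinker)
  double L;
  // interaction constants (kT units, nm)
  double lB, epsW, ke, r0, kh, rh, epsh;
  double hcut2;                     // hydrophobic cutoff^2
  // Ewald
  double alpha, rcut, rcut2;
  int nmax;
  std::vector<std::array<int, 3>> kn;
  std::vector<double> kcoef;
  std::vector<cplx> S;
  double Uself;
  std::vector<int> chg;             // charged bead ids

  double mi(double dx) const { return dx - L * std::round(dx / L); }
  double dist2(int i, int j) const {
    double dx = mi(px[i] - px[j]), dy = mi(py[i] - py[j]),
           dz = mi(pz[i] - pz[j]);
    return dx * dx + dy * dy + dz * dz;
  }

  void setupK() {
    kn.clear(); kcoef.clear();
    double tpl = 2.0 * M_PI / L, V = L * L * L;
    for (int nx = 0; nx <= nmax; ++nx)
      for (int ny = -nmax; ny <= nmax; ++ny)
        for (int nz = -nmax; nz <= nmax; ++nz) {
          if (!(nx > 0 || (nx == 0 && ny > 0) ||
                (nx == 0 && ny == 0 && nz > 0))) continue;
          int n2 = nx * nx + ny * ny + nz * nz;
          if (n2 > nmax * nmax) continue;
          double k2 = tpl * tpl * n2;
          kn.push_back({nx, ny, nz});
          kcoef.push_back(2.0 * (2.0 * M_PI / V) *
                          std::exp(-k2 / (4.0 * alpha * alpha)) / k2);
        }
  }

  // phase factors e^{i 2 pi n x / L} for n = -nmax..nmax along one axis
  void axisPhases(double x, std::vector<cplx>& e) const {
    e.assign(2 * nmax + 1, cplx(1, 0));
    cplx f = std::exp(cplx(0, 2.0 * M_PI * x / L));
    for (int nq = 1; nq <= nmax; ++nq) {
      e[nmax + nq] = e[nmax + nq - 1] * f;
      e[nmax - nq] = std::conj(e[nmax + nq]);
    }
  }

  void buildS() {
    S.assign(kn.size(), cplx(0, 0));
    std::vector<cplx> ex, ey, ez;
    for (int id : chg) {
      axisPhases(px[id], ex); axisPhases(py[id], ey); axisPhases(pz[id], ez);
      double zq = q[id];
      for (size_t k = 0; k < kn.size(); ++k) {
        S[k] += zq * ex[nmax + kn[k][0]] * ey[nmax + kn[k][1]] *
                ez[nmax + kn[k][2]];
      }
    }
  }

  double recipEnergy() const {
    double u = 0;
    for (size_t k = 0; k < kn.size(); ++k) u += kcoef[k] * std::norm(S[k]);
    return lB * u;
  }

  // short-range non-bonded pair energy (WCA + hydrophobic) plus
  // real-space screened Coulomb, between beads i and j
  double pairE(int i, int j) const {
    double r2 = dist2(i, j), e = 0;
    double dij = 0.5 * (diam[i] + diam[j]);
    double wc2 = std::cbrt(2.0) * dij * dij;   // (2^{1/6} d)^2
    if (r2 < wc2) {
      if (r2 <= 0) stop("bead overlap at zero distance");
      double s2 = dij * dij / r2, s6 = s2 * s2 * s2;
      e += epsW * (s6 * s6 - s6 + 0.25);
    }
    if (hyd[i] && hyd[j] && r2 < hcut2) {
      double r = std::sqrt(r2);
      e += -0.5 * epsh * (1.0 - std::tanh(kh * (r - rh)));
    }
    if (q[i] != 0 && q[j] != 0 && r2 < rcut2) {
      double r = std::sqrt(r2);
      e += lB * q[i] * q[j] * std::erfc(alpha * r) / r;
    }
    return e;
  }

  double bondE(int b) const {
    double r = std::sqrt(dist2(bonds[b][0], bonds[b][1]));
    double d = r - r0;
    return 0.5 * ke * d * d;
  }

  // full energy breakdown (kT units)
  void totalEnergy(double& wca, double& bond, double& hydro,
                   double& elec) const {
    wca = bond = hydro = 0;
    double real = 0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double r2 = dist2(i, j);
        double dij = 0.5 * (diam[i] + diam[j]);
        double wc2 = std::cbrt(2.0) * dij * dij;
        if (r2 < wc2) {
          if (r2 <= 0) stop("bead overlap at zero distance");
          double s2 = dij * dij / r2, s6 = s2 * s2 * s2;
          wca += epsW * (s6 * s6 - s6 + 0.25);
        }
        if (hyd[i] && hyd[j] && r2 < hcut2) {
          double r = std::sqrt(r2);
          hydro += -0.5 * epsh * (1.0 - std::tanh(kh * (r - rh)));
        }
        if (q[i] != 0 && q[j] != 0 && r2 < rcut2) {
          double r = std::sqrt(r2);
          real += lB * q[i] * q[j] * std::erfc(alpha * r) / r;
        }
      }
    for (size_t b = 0; b < bonds.size(); ++b) bond += bondE(b);
    elec = real + recipEnergy() + Uself;
  }

  double totalE() const {
    double w, b, h, e;
    totalEnergy(w, b, h, e);
    return w + b + h + e;
  }

  // incremental energy change for a rigid translation of `mv` by t.
  // Pairs internal to the moved set are unchanged (minimum-image
  // distances are invariant under rigid translation); only moved-vs-
  // static pairs, boundary-crossing bonds and the structure factors
  // are recomputed. dS receives the structure-factor update.
  double deltaTranslate(const std::vector<int>& mv, double tx, double ty,
                        double tz, std::vector<cplx>& dS,
                        const std::vector<char>& inMv) {
    double dU = 0;
    for (int i : mv) {
      double ox = px[i], oy = py[i], oz = pz[i];
      for (int j = 0; j < n; ++j) {
        if (inMv[j]) continue;
        dU -= pairE(i, j);
      }
      px[i] = ox + tx; py[i] = oy + ty; pz[i] = oz + tz;
      for (int j = 0; j < n; ++j) {
        if (inMv[j]) continue;
        dU += pairE(i, j);
      }
      px[i] = ox; py[i] = oy; pz[i] = oz;
    }
    for (int i : mv) {
      for (int b : bondOf[i]) {
        int a = bonds[b][0], c = bonds[b][1];
        if (inMv[a] && inMv[c]) continue;
        double old = bondE(b);
        int other = inMv[a] ? c : a;
        int moved = inMv[a] ? a : c;
        double dx = mi(px[moved] + tx - px[other]);
        double dy = mi(py[moved] + ty - py[other]);
        double dz = mi(pz[moved] + tz - pz[other]);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz) - r0;
        dU += 0.5 * ke * r * r - old;
      }
    }
    // reciprocal space
    dS.assign(kn.size(), cplx(0, 0));
    bool any = false;
    std::vector<cplx> exo, eyo, ezo, exn, eyn, ezn;
    for (int i : mv) {
      if (q[i] == 0) continue;
      any = true;
      axisPhases(px[i], exo); axisPhases(py[i], eyo); axisPhases(pz[i], ezo);
      axisPhases(px[i] + tx, exn); axisPhases(py[i] + ty, eyn);
      axisPhases(pz[i] + tz, ezn);
      double zq = q[i];
      for (size_t k = 0; k < kn.size(); ++k) {
        dS[k] += zq * (exn[nmax + kn[k][0]] * eyn[nmax + kn[k][1]] *
                       ezn[nmax + kn[k][2]] -
                       exo[nmax + kn[k][0]] * eyo[nmax + kn[k][1]] *
                       ezo[nmax + kn[k][2]]);
      }
    }
    if (any) {
      double dRec = 0;
      for (size_t k = 0; k < kn.size(); ++k) {
        dRec += kcoef[k] * (std::norm(S[k] + dS[k]) - std::norm(S[k]));
      }
      dU += lB * dRec;
    }
    return dU;
  }

  void commitTranslate(const std::vector<int>& mv, double tx, double ty,
                       double tz, const std::vector<cplx>& dS) {
    for (int i : mv) { px[i] += tx; py[i] += ty; pz[i] += tz; }
    bool any = false;
    for (int i : mv) if (q[i] != 0) { any = true; break; }
    if (any) for (size_t k = 0; k < kn.size(); ++k) S[k] += dS[k];
  }
};

static Sys makeSys(const NumericMatrix& pos, const IntegerVector& val,
                   const NumericVector& diam, const LogicalVector& hyd,
                   const IntegerMatrix& bonds, const IntegerVector& netIds,
                   double L, double lB, double alpha, double rcut,
                   int nmax, double epsW, double ke, double r0,
                   double kh, double rh, double epsh) {
  Sys s;
  s.n = pos.nrow();
  s.px.resize(s.n); s.py.resize(s.n); s.pz.resize(s.n);
  for (int i = 0; i < s.n; ++i) {
    s.px[i] = pos(i, 0); s.py[i] = pos(i, 1); s.pz[i] = pos(i, 2);
  }
  s.q = std::vector<int>(val.begin(), val.end());
  s.diam = std::vector<double>(diam.begin(), diam.end());
  s.hyd.resize(s.n);
  for (int i = 0; i < s.n; ++i) s.hyd[i] = hyd[i] ? 1 : 0;
  s.bondOf.resize(s.n);
  for (int b = 0; b < bonds.nrow(); ++b) {
    std::array<int, 2> e = {bonds(b, 0), bonds(b, 1)};
    s.bonds.push_back(e);
    s.bondOf[e[0]].push_back(b);
    s.bondOf[e[1]].push_back(b);
  }
  s.netIds = std::vector<int>(netIds.begin(), netIds.end());
  s.L = L; s.lB = lB; s.alpha = alpha; s.rcut = rcut; s.rcut2 = rcut * rcut;
  s.nmax = nmax;
  s.epsW = epsW; s.ke = ke; s.r0 = r0; s.kh = kh; s.rh = rh; s.epsh = epsh;
  double hc = rh + 1.5;
  s.hcut2 = hc * hc;
  long zsum = 0; double z2 = 0;
  for (int i = 0; i < s.n; ++i) {
    if (s.q[i] != 0) s.chg.push_back(i);
    zsum += s.q[i]; z2 += (double)s.q[i] * s.q[i];
  }
  if (zsum != 0) stop("configuration is not electroneutral (sum z = %d)",
                      (int)zsum);
  if (rcut > L / 2 + 1e-9) stop("Ewald real-space cutoff exceeds L/2");
  s.Uself = -lB * alpha / std::sqrt(M_PI) * z2;
  s.setupK();
  s.buildS();
  return s;
}

// [[Rcpp::export]]
List cpp_ewald_energy(NumericMatrix pos, IntegerVector val, double L,
                      double lB, double alpha, double rcut, int nmax) {
  NumericVector dm(pos.nrow(), 1.0);
  LogicalVector hy(pos.nrow(), false);
  IntegerMatrix bd(0, 2);
  IntegerVector ni(0);
  Sys s = makeSys(pos, val, dm, hy, bd, ni, L, lB, alpha, rcut, nmax,
                  0, 0, 1, 1, 1, 0);
  double real = 0;
  for (size_t a = 0; a < s.chg.size(); ++a)
    for (size_t b = a + 1; b < s.chg.size(); ++b) {
      int i = s.chg[a], j = s.chg[b];
      double r2 = s.dist2(i, j);
      if (r2 < s.rcut2) {
        double r = std::sqrt(r2);
        real += lB * s.q[i] * s.q[j] * std::erfc(alpha * r) / r;
      }
    }
  double rec = s.recipEnergy();
  return List::create(_["real"] = real, _["recip"] = rec,
                      _["self"] = s.Uself,
                      _["total"] = real + rec + s.Uself);
}

// [[Rcpp::export]]
List cpp_total_energy(NumericMatrix pos, IntegerVector val,
                      NumericVector diam, LogicalVector hyd,
                      IntegerMatrix bonds, double L, double lB,
                      double alpha, double rcut, int nmax, double epsW,
                      double ke, double r0, double kh, double rh,
                      double epsh) {
  IntegerVector ni(0);
  Sys s = makeSys(pos, val, diam, hyd, bonds, ni, L, lB, alpha, rcut,
                  nmax, epsW, ke, r0, kh, rh, epsh);
  double w, b, h, e;
  s.totalEnergy(w, b, h, e);
  return List::create(_["wca"] = w, _["bond"] = b, _["hydrophobic"] = h,
                      _["electrostatic"] = e, _["total"] = w + b + h + e);
}

// [[Rcpp::export]]
double cpp_delta_energy(NumericMatrix pos, IntegerVector val,
                        NumericVector diam, LogicalVector hyd,
                        IntegerMatrix bonds, double L, double lB,
                        double alpha, double rcut, int nmax, double epsW,
                        double ke, double r0, double kh, double rh,
                        double epsh, IntegerVector moved,
                        NumericVector disp) {
  IntegerVector ni(0);
  Sys s = makeSys(pos, val, diam, hyd, bonds, ni, L, lB, alpha, rcut,
                  nmax, epsW, ke, r0, kh, rh, epsh);
  std::vector<int> mv(moved.begin(), moved.end());
  std::vector<char> inMv(s.n, 0);
  for (int i : mv) inMv[i] = 1;
  std::vector<cplx> dS;
  return s.deltaTranslate(mv, disp[0], disp[1], disp[2], dS, inMv);
}

// ------------------------------------------------------------ MC run
// move classes: 0 network bead, 1 anion, 2 cation, 3 nanoparticle
// (single), 4 NP-counterion cluster, 5 network scaling
static const int NCLS = 6;

struct Counters {
  long att[NCLS] = {0}, acc[NCLS] = {0};
  long wAtt[NCLS] = {0}, wAcc[NCLS] = {0};   // adaptation window
};

// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, IntegerVector val, NumericVector diam,
                LogicalVector hyd, IntegerMatrix bonds,
                IntegerVector netIds, IntegerVector cls, double L,
                double lB, double alpha, double rcut, int nmax,
                double epsW, double ke, double r0, double kh, double rh,
                double epsh, long n_equil, long n_prod,
                long sample_interval, long cluster_interval,
                long scale_interval, bool scale_enabled,
                long adapt_interval, NumericVector step0,
                double cluster_shell, int seed, bool store_frames) {
  Sys s = makeSys(pos, val, diam, hyd, bonds, netIds, L, lB, alpha, rcut,
                  nmax, epsW, ke, r0, kh, rh, epsh);
  Xoshiro rng((uint64_t)seed * 0x9e3779b97f4a7c15ULL + 12345u);
  std::vector<int> clsOf(cls.begin(), cls.end());
  std::vector<int> npIds;
  std::vector<int> catIds;
  for (int i = 0; i < s.n; ++i) {
    if (clsOf[i] == 3) npIds.push_back(i);
    if (clsOf[i] == 2) catIds.push_back(i);
  }
  double step[NCLS];
  for (int c = 0; c < NCLS; ++c) step[c] = step0[c];
  Counters ct;
  double U = s.totalE();
  long nTot = n_equil + n_prod;
  int npCycle = 0;
  std::vector<char> inMv(s.n, 0);
  std::vector<cplx> dS;
  std::vector<int> mv1(1);

  // samplers
  std::vector<double> smStep, smRg, smNin, smU, smPhase;
  std::vector<NumericMatrix> frames;

  auto netCM = [&](double& cx, double& cy, double& cz) {
    cx = cy = cz = 0;
    for (int i : s.netIds) { cx += s.px[i]; cy += s.py[i]; cz += s.pz[i]; }
    int m = s.netIds.size();
    if (m) { cx /= m; cy /= m; cz /= m; }
  };
  auto rgyr = [&]() {
    if (s.netIds.empty()) return 0.0;
    double cx, cy, cz; netCM(cx, cy, cz);
    double acc2 = 0;
    for (int i : s.netIds) {
      double dx = s.px[i] - cx, dy = s.py[i] - cy, dz = s.pz[i] - cz;
      acc2 += dx * dx + dy * dy + dz * dz;
    }
    return std::sqrt(acc2 / s.netIds.size());
  };
  auto nInside = [&](double rgeo) {
    if (npIds.empty() || s.netIds.empty()) return 0;
    double cx, cy, cz; netCM(cx, cy, cz);
    int c = 0;
    for (int i : npIds) {
      double dx = s.mi(s.px[i] - cx), dy = s.mi(s.py[i] - cy),
             dz = s.mi(s.pz[i] - cz);
      if (std::sqrt(dx * dx + dy * dy + dz * dz) < rgeo) ++c;
    }
    return c;
  };
  auto metropolis = [&](double dU, double lnJac) {
    double lnA = -dU + lnJac;
    if (lnA >= 0) return true;
    if (lnA < -700.0) return false;
    return rng.unif() < std::exp(lnA);
  };
  // cluster membership: cations whose centre lies in the spherical
  // layer of thickness `cluster_shell` outside NP-cation contact
  auto clusterOf = [&](int npi, double ox, double oy, double oz) {
    std::vector<int> m;
    double rin = 0.5 * (s.diam[npi] + (catIds.empty() ? 0 :
                        s.diam[catIds[0]]));
    double rout = rin + cluster_shell;
    for (int c : catIds) {
      double dx = s.mi(s.px[c] - ox), dy = s.mi(s.py[c] - oy),
             dz = s.mi(s.pz[c] - oz);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (r >= rin && r <= rout) m.push_back(c);
    }
    return m;
  };

  for (long it = 0; it < nTot; ++it) {
    bool equil = it < n_equil;
    bool didScale = false;
    if (scale_enabled && equil && !s.netIds.empty() &&
        scale_interval > 0 && (it + 1) % scale_interval == 0) {
      // ---- network scaling move (thermalization only)
      didScale = true;
      double del = (2 * rng.unif() - 1) * step[5];
      double sc = std::exp(del);
      double cx, cy, cz; netCM(cx, cy, cz);
      double rg = rgyr(), rgeo = std::sqrt(5.0 / 3.0) * rg;
      std::vector<int> mv = s.netIds;
      for (int i = 0; i < s.n; ++i) {
        if (clsOf[i] == 0) continue;
        double dx = s.mi(s.px[i] - cx), dy = s.mi(s.py[i] - cy),
               dz = s.mi(s.pz[i] - cz);
        if (std::sqrt(dx * dx + dy * dy + dz * dz) < rgeo) mv.push_back(i);
      }
      double U0 = U;
      std::vector<double> ox(mv.size()), oy(mv.size()), oz(mv.size());
      for (size_t m = 0; m < mv.size(); ++m) {
        int i = mv[m];
        ox[m] = s.px[i]; oy[m] = s.py[i]; oz[m] = s.pz[i];
        double dx = s.mi(s.px[i] - cx), dy = s.mi(s.py[i] - cy),
               dz = s.mi(s.pz[i] - cz);
        s.px[i] = cx + sc * dx; s.py[i] = cy + sc * dy;
        s.pz[i] = cz + sc * dz;
      }
      double U1 = s.totalE() - s.recipEnergy();
      std::vector<cplx> Sold = s.S;
      s.buildS();
      U1 += s.recipEnergy();
      double dU = U1 - U0;
      // symmetric proposal in ln s: Jacobian factor s^{3 N_moved}
      ct.att[5]++; ct.wAtt[5]++;
      if (metropolis(dU, 3.0 * mv.size() * del)) {
        U = U1;
        ct.acc[5]++; ct.wAcc[5]++;
      } else {
        for (size_t m = 0; m < mv.size(); ++m) {
          int i = mv[m];
          s.px[i] = ox[m]; s.py[i] = oy[m]; s.pz[i] = oz[m];
        }
        s.S = Sold;
      }
    } else if (!npIds.empty() && cluster_interval > 0 &&
               (it + 1) % cluster_interval == 0) {
      // ---- cluster move: NP + nearest cations, rigid translation
      int npi = npIds[npCycle++ % npIds.size()];
      std::vector<int> mem = clusterOf(npi, s.px[npi], s.py[npi],
                                       s.pz[npi]);
      std::vector<int> mv;
      mv.push_back(npi);
      mv.insert(mv.end(), mem.begin(), mem.end());
      double tx = (2 * rng.unif() - 1) * step[4],
             ty = (2 * rng.unif() - 1) * step[4],
             tz = (2 * rng.unif() - 1) * step[4];
      ct.att[4]++; ct.wAtt[4]++;
      // detailed balance: membership recomputed at the destination
      // (with the cluster's cations displaced) must be identical,
      // otherwise the reverse move could not reconstruct the cluster
      std::vector<char> inC(s.n, 0);
      for (int i : mv) inC[i] = 1;
      bool same = true;
      {
        double nx = s.px[npi] + tx, ny = s.py[npi] + ty,
               nz = s.pz[npi] + tz;
        double rin = 0.5 * (s.diam[npi] + (catIds.empty() ? 0 :
                            s.diam[catIds[0]]));
        double rout = rin + cluster_shell;
        std::vector<int> memNew;
        for (int c : catIds) {
          double cxp = s.px[c] + (inC[c] ? tx : 0);
          double cyp = s.py[c] + (inC[c] ? ty : 0);
          double czp = s.pz[c] + (inC[c] ? tz : 0);
          double dx = s.mi(cxp - nx), dy = s.mi(cyp - ny),
                 dz = s.mi(czp - nz);
          double r = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (r >= rin && r <= rout) memNew.push_back(c);
        }
        same = (memNew == mem);
      }
      if (same) {
        for (int i : mv) inMv[i] = 1;
        double dU = s.deltaTranslate(mv, tx, ty, tz, dS, inMv);
        if (metropolis(dU, 0)) {
          s.commitTranslate(mv, tx, ty, tz, dS);
          U += dU;
          ct.acc[4]++; ct.wAcc[4]++;
        }
        for (int i : mv) inMv[i] = 0;
      }
    } else {
      // ---- single-bead move
      int id = rng.randint(s.n);
      int c = clsOf[id];
      double tx = (2 * rng.unif() - 1) * step[c],
             ty = (2 * rng.unif() - 1) * step[c],
             tz = (2 * rng.unif() - 1) * step[c];
      mv1[0] = id; inMv[id] = 1;
      double dU = s.deltaTranslate(mv1, tx, ty, tz, dS, inMv);
      ct.att[c]++; ct.wAtt[c]++;
      if (metropolis(dU, 0)) {
        s.commitTranslate(mv1, tx, ty, tz, dS);
        U += dU;
        ct.acc[c]++; ct.wAcc[c]++;
      }
      inMv[id] = 0;
    }
    (void)didScale;

    if (!std::isfinite(U)) stop("energy became non-finite at step %ld", it);

    // step-size adaptation towards ~50% acceptance (equilibration only)
    if (equil && adapt_interval > 0) {
      for (int c = 0; c < NCLS; ++c) {
        if (ct.wAtt[c] >= adapt_interval) {
          double rate = (double)ct.wAcc[c] / ct.wAtt[c];
          step[c] *= (rate > 0.5) ? 1.05 : 0.95;
          double lo = (c == 5) ? 1e-4 : 1e-3;
          double hi = (c == 5) ? 0.5 : L / 4;
          step[c] = std::min(hi, std::max(lo, step[c]));
          ct.wAtt[c] = ct.wAcc[c] = 0;
        }
      }
    }

    if (sample_interval > 0 && (it + 1) % sample_interval == 0) {
      double rg = rgyr();
      smStep.push_back((double)(it + 1));
      smPhase.push_back(equil ? 0.0 : 1.0);
      smRg.push_back(rg);
      smNin.push_back((double)nInside(std::sqrt(5.0 / 3.0) * rg));
      smU.push_back(U);
      if (!equil && store_frames) {
        NumericMatrix fr(s.n, 3);
        for (int i = 0; i < s.n; ++i) {
          fr(i, 0) = s.px[i]; fr(i, 1) = s.py[i]; fr(i, 2) = s.pz[i];
        }
        frames.push_back(fr);
      }
    }
  }

  double Ufresh = s.totalE();
  NumericMatrix fin(s.n, 3);
  for (int i = 0; i < s.n; ++i) {
    fin(i, 0) = s.px[i]; fin(i, 1) = s.py[i]; fin(i, 2) = s.pz[i];
  }
  NumericVector attv(NCLS), accv(NCLS), stepv(NCLS);
  for (int c = 0; c < NCLS; ++c) {
    attv[c] = (double)ct.att[c]; accv[c] = (double)ct.acc[c];
    stepv[c] = step[c];
  }
  List fr(frames.size());
  for (size_t f = 0; f < frames.size(); ++f) fr[f] = frames[f];
  return List::create(
    _["pos"] = fin,
    _["samples"] = DataFrame::create(
      _["step"] = smStep, _["phase"] = smPhase, _["r_gyr"] = smRg,
      _["n_inside"] = smNin, _["energy"] = smU),
    _["frames"] = fr,
    _["attempts"] = attv, _["accepts"] = accv, _["step_sizes"] = stepv,
    _["energy_running"] = U, _["energy_recomputed"] = Ufresh);
}
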