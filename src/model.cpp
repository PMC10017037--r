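// Coarse-grained model kernels: one-particle-thick fluid membrane
// (orientation-dependent pair potential), discrete elastic-rod filaments
// (harmonic stretch / bend / torsion), tilt-sensitive bead-membrane
// adhesion, bead-bead volume exclusion, and an overdamped Langevin
// integrator with periodic z boundary.
//
// Units: length sigma, energy kBT, friction 1 (time in sigma^2/(kBT*mobility)).

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double a, double b, double c) : x(a), y(b), z(c) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  Vec3& operator+=(const Vec3& o) { x += o.x; y += o.y; z += o.z; return *this; }
  Vec3& operator-=(const Vec3& o) { x -= o.x; y -= o.y; z -= o.z; return *this; }
};
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return Vec3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x);
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }
static inline Vec3 unit(const Vec3& a) {
  double n = norm(a);
  return (n > 0) ? a * (1.0 / n) : Vec3(0, 0, 1);
}

// ---------------------------------------------------------------------------
// parameter bundles

struct MemParams {
  double eps, mu, rmin, rcut;
  int zeta;
  double wca_eps, wca_sigma;   // bead-bead excluded volume
  double align_w;              // adhesion angular width (cosine units)
};

struct SpeciesParams {
  double k_bond, l0, k_bend, th0, k_twist, phi0, tilt;
  double adh_eps, adh_r0, adh_rc;
  double ddot_rest;   // rest dot product of successive binding directors
};

// system state (plain arrays, modified in place)
struct System {
  std::vector<Vec3> mx, mn;          // membrane positions, directors
  std::vector<Vec3> fx, fd;          // filament beads, binding directors
  std::vector<int> fil_of_bead;      // filament index per bead
  std::vector<int> sp_of_fil;        // species row per filament
  std::vector<int> fstart, flen;     // bead ranges per filament
  double Lz;                         // periodic box length in z
  MemParams mp;
  std::vector<SpeciesParams> sp;
};

static inline double pbc_dz(double dz, double Lz) {
  if (Lz <= 0) return dz;
  while (dz > 0.5 * Lz) dz -= Lz;
  while (dz < -0.5 * Lz) dz += Lz;
  return dz;
}

// ---------------------------------------------------------------------------
// pair potentials
//
// Radial shape shared by membrane-membrane and bead-membrane terms:
//   r < rmin : uR(r) + (1 - phi) * eps
//   r < rcut : uA(r) * phi
// with uR = eps((rmin/r)^4 - 2(rmin/r)^2), uA = -eps cos^{2z}(k(r - rmin)),
// phi the orientation factor in [.,1].

struct PairOut {
  double u;        // energy
  double dudr;     // radial derivative
  double dudphi;   // derivative wrt orientation factor
};

static inline PairOut radial_pair(double r, double eps, double rmin,
                                  double rcut, int zeta, double phi) {
  PairOut o{0, 0, 0};
  if (r >= rcut) return o;
  if (r < rmin) {
    double s2 = (rmin / r) * (rmin / r);
    double s4 = s2 * s2;
    double uR = eps * (s4 - 2.0 * s2);
    double duR = eps * (-4.0 * s4 / r + 4.0 * s2 / r);
    o.u = uR + (1.0 - phi) * eps;
    o.dudr = duR;
    o.dudphi = -eps;
  } else {
    double k = M_PI_2 / (rcut - rmin);
    double c = std::cos(k * (r - rmin));
    double cz1 = 1.0;
    for (int i = 0; i < 2 * zeta - 1; ++i) cz1 *= c;
    double cz = cz1 * c;
    double uA = -eps * cz;
    double duA = eps * 2.0 * zeta * k * cz1 * std::sin(k * (r - rmin));
    o.u = uA * phi;
    o.dudr = duA * phi;
    o.dudphi = uA;
  }
  return o;
}

// ---------------------------------------------------------------------------
// cell list over all particles (membrane first, then beads)

struct CellList {
  double cell;
  int nx, ny, nz;
  double x0, y0, z0;
  double Lz;
  bool periodic;
  std::vector<std::vector<int> > cells;

  void build(const System& S, double cutoff) {
    size_t old_n = cells.size();
    size_t nm = S.mx.size(), nf = S.fx.size();
    double xmin = 1e30, xmax = -1e30, ymin = 1e30, ymax = -1e30,
           zmin = 1e30, zmax = -1e30;
    for (size_t i = 0; i < nm + nf; ++i) {
      const Vec3& p = (i < nm) ? S.mx[i] : S.fx[i - nm];
      xmin = std::min(xmin, p.x); xmax = std::max(xmax, p.x);
      ymin = std::min(ymin, p.y); ymax = std::max(ymax, p.y);
      zmin = std::min(zmin, p.z); zmax = std::max(zmax, p.z);
    }
    cell = cutoff;
    Lz = S.Lz;
    periodic = (Lz > 0 && Lz < 1e8);
    x0 = xmin - 1e-9; y0 = ymin - 1e-9;
    nx = std::max(1, (int)std::floor((xmax - x0) / cell) + 1);
    ny = std::max(1, (int)std::floor((ymax - y0) / cell) + 1);
    if (periodic) {
      z0 = 0;
      nz = std::max(1, (int)std::floor(Lz / cell));
      if (nz < 3) periodic = false;   // too small to wrap via cells
    }
    if (!periodic) {
      z0 = zmin - 1e-9;
      nz = std::max(1, (int)std::floor((zmax - z0) / cell) + 1);
    }
    size_t need = (size_t)nx * ny * nz;
    if (need > 8000000)
      stop("simulation box expanded beyond expected bounds (particles "
           "escaping); reduce the timestep");
    if (need != old_n) cells.resize(need);
    for (size_t c = 0; c < need; ++c) cells[c].clear();
    for (size_t i = 0; i < nm + nf; ++i) {
      const Vec3& p = (i < nm) ? S.mx[i] : S.fx[i - nm];
      cells[index_of(p)].push_back((int)i);
    }
  }
  int index_of(const Vec3& p) const {
    int ix = std::min(nx - 1, std::max(0, (int)((p.x - x0) / cell)));
    int iy = std::min(ny - 1, std::max(0, (int)((p.y - y0) / cell)));
    int iz;
    if (periodic) {
      double zz = p.z - Lz * std::floor(p.z / Lz);
      iz = std::min(nz - 1, std::max(0, (int)(zz / (Lz / nz))));
    } else {
      iz = std::min(nz - 1, std::max(0, (int)((p.z - z0) / cell)));
    }
    return (ix * ny + iy) * nz + iz;
  }
  template <class F>
  void for_neighbours(const System& S, F&& fn) const {
    // half stencil: same cell (i<j) plus 13 forward neighbour offsets
    static const int offs[13][3] = {
      {1, 0, 0}, {0, 1, 0}, {1, 1, 0}, {1, -1, 0},
      {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}, {1, -1, 1},
      {-1, 0, 1}, {0, -1, 1}, {-1, 1, 1}, {-1, -1, 1}
    };
    for (int ix = 0; ix < nx; ++ix)
      for (int iy = 0; iy < ny; ++iy)
        for (int iz = 0; iz < nz; ++iz) {
          size_t ci = (size_t)(ix * ny + iy) * nz + iz;
          const std::vector<int>& a = cells[ci];
          if (a.empty()) continue;
          for (size_t u = 0; u < a.size(); ++u)
            for (size_t v = u + 1; v < a.size(); ++v)
              fn(a[u], a[v]);
          for (int o = 0; o < 13; ++o) {
            int jx = ix + offs[o][0], jy = iy + offs[o][1],
                jz = iz + offs[o][2];
            if (jx < 0 || jx >= nx || jy < 0 || jy >= ny) continue;
            if (periodic) { jz = (jz + nz) % nz; }
            else if (jz < 0 || jz >= nz) continue;
            size_t cj = (size_t)(jx * ny + jy) * nz + jz;
            if (cj == ci) continue;
            const std::vector<int>& b = cells[cj];
            for (size_t u = 0; u < a.size(); ++u)
              for (size_t v = 0; v < b.size(); ++v)
                fn(a[u], b[v]);
          }
        }
  }
};

// ---------------------------------------------------------------------------
// force evaluation

struct Forces {
  std::vector<Vec3> f_mx, g_mn, f_fx, g_fd;  // -dU/dx and +dU/dn (torques)
  double e_mem, e_adh, e_wca, e_stretch, e_bend, e_twist, e_dir;
  void reset(size_t nm, size_t nf) {
    f_mx.assign(nm, Vec3()); g_mn.assign(nm, Vec3());
    f_fx.assign(nf, Vec3()); g_fd.assign(nf, Vec3());
    e_mem = e_adh = e_wca = e_stretch = e_bend = e_twist = e_dir = 0;
  }
};

static double max_cutoff(const System& S);

static void pair_forces(const System& S, Forces& F, const CellList& cl) {
  size_t nm = S.mx.size();
  const MemParams& mp = S.mp;
  double wca_cut = mp.wca_sigma * std::pow(2.0, 1.0 / 6.0);

  double cut2_all = max_cutoff(S); cut2_all *= cut2_all;
  cl.for_neighbours(S, [&](int I, int J) {
    bool imem = (size_t)I < nm, jmem = (size_t)J < nm;
    const Vec3& xi = imem ? S.mx[I] : S.fx[I - nm];
    const Vec3& xj = jmem ? S.mx[J] : S.fx[J - nm];
    Vec3 rij = xj - xi;
    rij.z = pbc_dz(rij.z, S.Lz);
    double r2 = dot(rij, rij);
    if (r2 < 1e-12 || r2 >= cut2_all) return;
    double r = std::sqrt(r2);

    if (imem && jmem) {
      if (r >= mp.rcut) return;
      Vec3 rh = rij * (1.0 / r);
      const Vec3 &ni = S.mn[I], &nj = S.mn[J];
      double nidr = dot(ni, rh), njdr = dot(nj, rh);
      double a = dot(ni, nj) - nidr * njdr;
      double phi = 1.0 + mp.mu * (a - 1.0);
      PairOut o = radial_pair(r, mp.eps, mp.rmin, mp.rcut, mp.zeta, phi);
      F.e_mem += o.u;
      double dudA = o.dudphi * mp.mu;
      // positional force: radial part + angular part through r-hat
      Vec3 dAdrh = (ni * njdr + nj * nidr) * (-1.0);
      // grad_xj U = dudr*rh + dudA * (I - rh rh^T)/r * dAdrh
      Vec3 t = dAdrh - rh * dot(rh, dAdrh);
      Vec3 grad = rh * o.dudr + t * (dudA / r);
      F.f_mx[J] -= grad;
      F.f_mx[I] += grad;
      // director torques: dU/dni = dudA*(nj - rh*njdr), sym.
      F.g_mn[I] += (nj - rh * njdr) * dudA;
      F.g_mn[J] += (ni - rh * nidr) * dudA;
    } else if (imem != jmem) {
      // adhesion: membrane particle <-> filament bead. Same continuous
      // radial shape as the membrane pair potential (repulsive core below
      // contact, smooth attractive tail), with the orientation factor a
      // Gaussian in cos(psi) peaked at the species tilt, where psi is the
      // facing angle between the bead's binding director d and the inward
      // membrane normal -n_mem.
      int m = imem ? I : J;
      int b = imem ? (J - (int)nm) : (I - (int)nm);
      const SpeciesParams& P = S.sp[S.sp_of_fil[S.fil_of_bead[b]]];
      if (P.adh_eps <= 0) {
        // non-adhesive species still cannot cross the membrane
        if (r >= wca_cut) return;
        double s2 = mp.wca_sigma * mp.wca_sigma / r2;
        double s6 = s2 * s2 * s2;
        F.e_wca += 4.0 * mp.wca_eps * (s6 * s6 - s6) + mp.wca_eps;
        double du = 4.0 * mp.wca_eps * (-12.0 * s6 * s6 + 6.0 * s6) / r;
        Vec3 grad = rij * (du / r);
        if (imem) { F.f_mx[I] += grad; F.f_fx[b] -= grad; }
        else { F.f_fx[b] += grad; F.f_mx[m] -= grad; }
        return;
      }
      if (r >= P.adh_rc) return;
      Vec3 d = S.fd[b], nmv = S.mn[m];
      double c = -dot(d, nmv);                    // cos(psi)
      double ct = std::cos(P.tilt);
      double dev = (c - ct) / mp.align_w;
      double g = std::exp(-0.5 * dev * dev);
      PairOut o = radial_pair(r, P.adh_eps, P.adh_r0, P.adh_rc, 2, g);
      F.e_adh += o.u;
      double dgdc = -g * (c - ct) / (mp.align_w * mp.align_w);
      double dudc = o.dudphi * dgdc;
      Vec3 rh = rij * (1.0 / r);
      Vec3 grad = rh * o.dudr;                    // rij points i -> j
      // force signs: grad is dU/dxj
      if (imem) { F.f_fx[b] -= grad; F.f_mx[I] += grad; }
      else { F.f_mx[m] -= grad; F.f_fx[b] += grad; }
      // torques: dU/dd = dudc * (-n), dU/dn = dudc * (-d)
      F.g_fd[b] += nmv * (-dudc);
      F.g_mn[m] += d * (-dudc);
    } else {
      // bead-bead excluded volume (skip bonded neighbours in same filament)
      int bi = I - (int)nm, bj = J - (int)nm;
      if (S.fil_of_bead[bi] == S.fil_of_bead[bj] && std::abs(bi - bj) <= 1)
        return;
      if (r >= wca_cut) return;
      double s2 = mp.wca_sigma * mp.wca_sigma / r2;
      double s6 = s2 * s2 * s2;
      F.e_wca += 4.0 * mp.wca_eps * (s6 * s6 - s6) + mp.wca_eps;
      double du = 4.0 * mp.wca_eps * (-12.0 * s6 * s6 + 6.0 * s6) / r;
      Vec3 grad = rij * (du / r);
      F.f_fx[bj] -= grad;
      F.f_fx[bi] += grad;
    }
  });
}

static void bonded_forces(const System& S, Forces& F) {
  for (size_t f = 0; f < S.fstart.size(); ++f) {
    const SpeciesParams& P = S.sp[S.sp_of_fil[f]];
    int s = S.fstart[f], n = S.flen[f];
    // stretch
    for (int i = s; i < s + n - 1; ++i) {
      Vec3 b = S.fx[i + 1] - S.fx[i];
      double l = norm(b);
      F.e_stretch += 0.5 * P.k_bond * (l - P.l0) * (l - P.l0);
      Vec3 grad = b * (P.k_bond * (l - P.l0) / l);   // dU/dx_{i+1}
      F.f_fx[i + 1] -= grad;
      F.f_fx[i] += grad;
    }
    // bend: cosine-harmonic, curvature-matched to k_bend at the rest angle
    // (smooth at straight configurations, unlike harmonic-in-theta)
    {
      double c0 = std::cos(P.th0);
      double s02 = std::max(1.0 - c0 * c0, 0.01);
      double kc = P.k_bend / s02;
      for (int i = s + 1; i < s + n - 1; ++i) {
        Vec3 a = S.fx[i - 1] - S.fx[i], b = S.fx[i + 1] - S.fx[i];
        double la = norm(a), lb = norm(b);
        Vec3 ah = a * (1.0 / la), bh = b * (1.0 / lb);
        double ct = dot(ah, bh);
        F.e_bend += 0.5 * kc * (ct - c0) * (ct - c0);
        double dE = kc * (ct - c0);
        Vec3 da = (bh - ah * ct) * (1.0 / la);   // grad_a cos(theta)
        Vec3 db = (ah - bh * ct) * (1.0 / lb);
        F.f_fx[i - 1] -= da * dE;
        F.f_fx[i + 1] -= db * dE;
        F.f_fx[i] += (da + db) * dE;
      }
    }
    // torsion: backbone dihedral with Blondel-Karplus gradients, softened
    // by S(x) = x/(x+c) on the squared bond-cross norms so the energy
    // vanishes continuously at collinear triples. The switch gradient can
    // spike in a narrow shell around collinearity, so the net force of
    // each quad is clamped to |F| <= 30 kBT/sigma -- conservative
    // everywhere the filament normally operates, bounded in the rare
    // degenerate excursions a fixed-step integrator must survive.
    if (P.k_twist > 0) for (int i = s; i < s + n - 3; ++i) {
      const double csw = 5e-4;
      Vec3 b1 = S.fx[i + 1] - S.fx[i];
      Vec3 b2 = S.fx[i + 2] - S.fx[i + 1];
      Vec3 b3 = S.fx[i + 3] - S.fx[i + 2];
      Vec3 n1 = cross(b1, b2), n2 = cross(b2, b3);
      double n1s = dot(n1, n1), n2s = dot(n2, n2);
      if (n1s < 1e-14 || n2s < 1e-14) continue;  // w ~ 0 there anyway
      double lb2 = norm(b2);
      Vec3 m1 = cross(n1, b2 * (1.0 / lb2));
      double phi = std::atan2(dot(m1, n2), dot(n1, n2));
      double dphi = phi - P.phi0;
      while (dphi > M_PI) dphi -= 2 * M_PI;
      while (dphi < -M_PI) dphi += 2 * M_PI;
      double S1 = n1s / (n1s + csw), S2 = n2s / (n2s + csw);
      double w = S1 * S2;
      F.e_twist += 0.5 * P.k_twist * w * dphi * dphi;
      // phi-gradient part
      double dE = P.k_twist * w * dphi;
      double u12 = dot(b1, b2) / (lb2 * n1s);
      double u32 = dot(b3, b2) / (lb2 * n2s);
      Vec3 dp1 = n1 * (lb2 / n1s);
      Vec3 dp4 = n2 * (-lb2 / n2s);
      Vec3 dp2 = dp1 * (-1.0) - n1 * u12 - n2 * u32;
      Vec3 dp3 = dp4 * (-1.0) + n1 * u12 + n2 * u32;
      Vec3 f1 = dp1 * (-dE);
      Vec3 f2 = dp2 * (-dE);
      Vec3 f3 = dp3 * (-dE);
      Vec3 f4 = dp4 * (-dE);
      // switch-gradient part, via n1s = b1^2 b2^2 - (b1.b2)^2 etc.
      double pref = 0.5 * P.k_twist * dphi * dphi;
      double dS1 = csw / ((n1s + csw) * (n1s + csw)) * S2 * pref;
      double dS2 = csw / ((n2s + csw) * (n2s + csw)) * S1 * pref;
      double b1b2 = dot(b1, b2), b2b3 = dot(b2, b3);
      double b1sq = dot(b1, b1), b2sq = dot(b2, b2), b3sq = dot(b3, b3);
      Vec3 dn1_db1 = b1 * (2.0 * b2sq) - b2 * (2.0 * b1b2);
      Vec3 dn1_db2 = b2 * (2.0 * b1sq) - b1 * (2.0 * b1b2);
      Vec3 dn2_db2 = b2 * (2.0 * b3sq) - b3 * (2.0 * b2b3);
      Vec3 dn2_db3 = b3 * (2.0 * b2sq) - b2 * (2.0 * b2b3);
      f1 += dn1_db1 * dS1;
      f2 -= dn1_db1 * dS1;
      f2 += dn1_db2 * dS1 + dn2_db2 * dS2;
      f3 -= dn1_db2 * dS1 + dn2_db2 * dS2;
      f3 += dn2_db3 * dS2;
      f4 -= dn2_db3 * dS2;
      double fmax = std::sqrt(std::max(std::max(dot(f1, f1), dot(f2, f2)),
                                       std::max(dot(f3, f3), dot(f4, f4))));
      if (fmax > 30.0) {
        double sc = 30.0 / fmax;
        f1 = f1 * sc; f2 = f2 * sc; f3 = f3 * sc; f4 = f4 * sc;
      }
      F.f_fx[i] += f1;
      F.f_fx[i + 1] += f2;
      F.f_fx[i + 2] += f3;
      F.f_fx[i + 3] += f4;
    }
    // binding-director restoring toward tilted rest orientation in the
    // instantaneous discrete frame (torque on directors only)
    if (P.k_twist > 0 && S.fd.size() == S.fx.size())
      for (int i = s + 1; i < s + n - 1; ++i) {
      Vec3 a = S.fx[i - 1] - S.fx[i], b = S.fx[i + 1] - S.fx[i];
      Vec3 m = unit(a) + unit(b);
      double nm2 = norm(m);
      if (nm2 < 1e-9) continue;
      m = m * (1.0 / nm2);
      Vec3 bb = cross(a * (-1.0), b);
      double nb = norm(bb);
      if (nb < 1e-9) continue;
      bb = bb * (1.0 / nb);
      Vec3 e = m * std::cos(P.tilt) + bb * std::sin(P.tilt);
      F.e_dir += P.k_twist * (1.0 - dot(S.fd[i], e));
      F.g_fd[i] -= e * P.k_twist;   // dU/dd = -k e
    }
  }
}

static double max_cutoff(const System& S) {
  double c = S.mp.rcut;
  c = std::max(c, S.mp.wca_sigma * 1.2);
  for (size_t i = 0; i < S.sp.size(); ++i)
    c = std::max(c, S.sp[i].adh_rc);
  return c;
}

static void compute_all(const System& S, Forces& F, CellList& cl) {
  F.reset(S.mx.size(), S.fx.size());
  if (S.mx.size() + S.fx.size() > 0) {
    cl.build(S, max_cutoff(S));
    pair_forces(S, F, cl);
  }
  bonded_forces(S, F);
}

static void compute_all(const System& S, Forces& F) {
  CellList cl;
  compute_all(S, F, cl);
}

// ---------------------------------------------------------------------------
// R interface helpers

static std::vector<Vec3> to_vec3(const NumericMatrix& m) {
  std::vector<Vec3> v(m.nrow());
  for (int i = 0; i < m.nrow(); ++i) v[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
  return v;
}
static NumericMatrix from_vec3(const std::vector<Vec3>& v) {
  NumericMatrix m(v.size(), 3);
  for (size_t i = 0; i < v.size(); ++i) {
    m(i, 0) = v[i].x; m(i, 1) = v[i].y; m(i, 2) = v[i].z;
  }
  return m;
}

static System build_system(NumericMatrix mem_x, NumericMatrix mem_n,
                           NumericMatrix fil_x, NumericMatrix fil_d,
                           IntegerVector fil_len, IntegerVector sp_of_fil,
                           NumericMatrix sp_params, NumericVector mem_params,
                           double Lz) {
  System S;
  S.mx = to_vec3(mem_x); S.mn = to_vec3(mem_n);
  S.fx = to_vec3(fil_x); S.fd = to_vec3(fil_d);
  S.Lz = Lz;
  int off = 0;
  for (int f = 0; f < fil_len.size(); ++f) {
    S.fstart.push_back(off);
    S.flen.push_back(fil_len[f]);
    S.sp_of_fil.push_back(sp_of_fil[f]);
    for (int i = 0; i < fil_len[f]; ++i) S.fil_of_bead.push_back(f);
    off += fil_len[f];
  }
  if (off != fil_x.nrow()) stop("fil_len does not match fil_x rows");
  S.mp.eps = mem_params[0]; S.mp.mu = mem_params[1];
  S.mp.zeta = (int)mem_params[2];
  S.mp.rmin = mem_params[3]; S.mp.rcut = mem_params[4];
  S.mp.wca_eps = mem_params[5]; S.mp.wca_sigma = mem_params[6];
  S.mp.align_w = mem_params[7];
  for (int r = 0; r < sp_params.nrow(); ++r) {
    SpeciesParams P;
    P.k_bond = sp_params(r, 0); P.l0 = sp_params(r, 1);
    P.k_bend = sp_params(r, 2); P.th0 = sp_params(r, 3);
    P.k_twist = sp_params(r, 4); P.phi0 = sp_params(r, 5);
    P.tilt = sp_params(r, 6);
    P.adh_eps = sp_params(r, 7); P.adh_r0 = sp_params(r, 8);
    P.adh_rc = sp_params(r, 9);
    P.ddot_rest = (sp_params.ncol() > 10) ? sp_params(r, 10) : 1.0;
    S.sp.push_back(P);
  }
  return S;
}

// [[Rcpp::export(name = ".cpp_total_energy")]]
List cpp_total_energy(NumericMatrix mem_x, NumericMatrix mem_n,
                      NumericMatrix fil_x, NumericMatrix fil_d,
                      IntegerVector fil_len, IntegerVector sp_of_fil,
                      NumericMatrix sp_params, NumericVector mem_params,
                      double Lz) {
  System S = build_system(mem_x, mem_n, fil_x, fil_d, fil_len, sp_of_fil,
                          sp_params, mem_params, Lz);
  Forces F;
  compute_all(S, F);
  double tot = F.e_mem + F.e_adh + F.e_wca + F.e_stretch + F.e_bend +
               F.e_twist + F.e_dir;
  return List::create(_["membrane"] = F.e_mem, _["adhesion"] = F.e_adh,
                      _["excluded"] = F.e_wca, _["stretch"] = F.e_stretch,
                      _["bend"] = F.e_bend, _["twist_tilt"] = F.e_twist + F.e_dir,
                      _["total"] = tot);
}

// [[Rcpp::export(name = ".cpp_forces")]]
List cpp_forces(NumericMatrix mem_x, NumericMatrix mem_n,
                NumericMatrix fil_x, NumericMatrix fil_d,
                IntegerVector fil_len, IntegerVector sp_of_fil,
                NumericMatrix sp_params, NumericVector mem_params,
                double Lz) {
  System S = build_system(mem_x, mem_n, fil_x, fil_d, fil_len, sp_of_fil,
                          sp_params, mem_params, Lz);
  Forces F;
  compute_all(S, F);
  return List::create(_["f_mem"] = from_vec3(F.f_mx),
                      _["t_mem"] = from_vec3(F.g_mn),
                      _["f_fil"] = from_vec3(F.f_fx),
                      _["t_fil"] = from_vec3(F.g_fd));
}

// overdamped Langevin segment; returns snapshots and final state
// [[Rcpp::export(name = ".cpp_langevin_run")]]
List cpp_langevin_run(NumericMatrix mem_x, NumericMatrix mem_n,
                      NumericMatrix fil_x, NumericMatrix fil_d,
                      IntegerVector fil_len, IntegerVector sp_of_fil,
                      NumericMatrix sp_params, NumericVector mem_params,
                      double Lz, double dt, double temperature,
                      int n_steps, int snap_every, int seed) {
  System S = build_system(mem_x, mem_n, fil_x, fil_d, fil_len, sp_of_fil,
                          sp_params, mem_params, Lz);
  Forces F;
  CellList cl;
  std::mt19937_64 rng((uint64_t)seed);
  std::normal_distribution<double> gauss(0.0, 1.0);
  double amp = std::sqrt(2.0 * temperature * dt);

  List snaps;
  std::vector<double> snap_times;
  size_t nm = S.mx.size(), nf = S.fx.size();
  // cap the deterministic drift per step: stiff-core force spikes under
  // strong constriction are bounded without affecting normal dynamics
  // (typical drifts are an order of magnitude below the cap)
  const double max_drift = 0.05;
  auto capped = [max_drift, dt](const Vec3& f) {
    Vec3 d = f * dt;
    double n2 = dot(d, d);
    if (n2 > max_drift * max_drift) d = d * (max_drift / std::sqrt(n2));
    return d;
  };

  for (int step = 1; step <= n_steps; ++step) {
    compute_all(S, F, cl);
    // guard against blow-up
    for (size_t i = 0; i < nm; ++i)
      if (!std::isfinite(F.f_mx[i].x + F.f_mx[i].y + F.f_mx[i].z))
        stop("non-finite force on membrane particle %d at step %d",
             (int)i + 1, step);
    for (size_t i = 0; i < nf; ++i)
      if (!std::isfinite(F.f_fx[i].x + F.f_fx[i].y + F.f_fx[i].z))
        stop("non-finite force on filament bead %d at step %d",
             (int)i + 1, step);
    for (size_t i = 0; i < nm; ++i) {
      Vec3 xi = S.mx[i];
      xi += capped(F.f_mx[i]);
      if (temperature > 0)
        xi += Vec3(gauss(rng), gauss(rng), gauss(rng)) * amp;
      xi.z -= Lz * std::floor(xi.z / Lz);
      S.mx[i] = xi;
      // rotational update: remove parallel component, renormalize
      Vec3 g = F.g_mn[i];
      Vec3 n = S.mn[i];
      Vec3 gp = g - n * dot(g, n);
      Vec3 nn = n - gp * dt;
      if (temperature > 0) {
        Vec3 xi2(gauss(rng), gauss(rng), gauss(rng));
        Vec3 xp = xi2 - n * dot(xi2, n);
        nn += xp * amp;
      }
      S.mn[i] = unit(nn);
    }
    for (size_t i = 0; i < nf; ++i) {
      Vec3 xi = S.fx[i];
      xi += capped(F.f_fx[i]);
      if (temperature > 0)
        xi += Vec3(gauss(rng), gauss(rng), gauss(rng)) * amp;
      // beads keep continuous z (bonded terms are not minimum-imaged);
      // the cell list and pair terms wrap internally
      S.fx[i] = xi;
      Vec3 g = F.g_fd[i];
      Vec3 d = S.fd[i];
      Vec3 gp = g - d * dot(g, d);
      Vec3 dd = d - gp * dt;
      if (temperature > 0) {
        Vec3 xi2(gauss(rng), gauss(rng), gauss(rng));
        Vec3 xp = xi2 - d * dot(xi2, d);
        dd += xp * amp;
      }
      S.fd[i] = unit(dd);
    }
    if (snap_every > 0 && (step % snap_every == 0 || step == n_steps)) {
      snaps.push_back(List::create(
        _["step"] = step,
        _["mem_x"] = from_vec3(S.mx), _["mem_n"] = from_vec3(S.mn),
        _["fil_x"] = from_vec3(S.fx), _["fil_d"] = from_vec3(S.fd)));
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["snapshots"] = snaps,
    _["mem_x"] = from_vec3(S.mx), _["mem_n"] = from_vec3(S.mn),
    _["fil_x"] = from_vec3(S.fx), _["fil_d"] = from_vec3(S.fd));
}

// fast filament-only energy/gradient for zero-temperature relaxation
// [[Rcpp::export(name = ".cpp_filament_eg")]]
List cpp_filament_eg(NumericMatrix pos, double k_bond, double l0,
                     double k_bend, double th0, double k_twist, double phi0) {
  System S;
  S.fx = to_vec3(pos);
  S.Lz = 1e9;
  S.fstart.push_back(0); S.flen.push_back(pos.nrow());
  S.sp_of_fil.push_back(0);
  for (int i = 0; i < pos.nrow(); ++i) S.fil_of_bead.push_back(0);
  SpeciesParams P;
  P.k_bond = k_bond; P.l0 = l0; P.k_bend = k_bend; P.th0 = th0;
  P.k_twist = k_twist; P.phi0 = phi0; P.tilt = 0;
  P.adh_eps = 0; P.adh_r0 = 0.5; P.adh_rc = 1.0;
  P.ddot_rest = 1.0;
  S.sp.push_back(P);
  S.mp.eps = 0; S.mp.mu = 3; S.mp.zeta = 4; S.mp.rmin = 1; S.mp.rcut = 1.1;
  S.mp.wca_eps = 0; S.mp.wca_sigma = 0.01; S.mp.align_w = 0.35;
  Forces F;
  F.reset(0, S.fx.size());
  bonded_forces(S, F);
  NumericMatrix g(pos.nrow(), 3);
  for (int i = 0; i < pos.nrow(); ++i) {
    g(i, 0) = -F.f_fx[i].x; g(i, 1) = -F.f_fx[i].y; g(i, 2) = -F.f_fx[i].z;
  }
  return List::create(
    _["energy"] = F.e_stretch + F.e_bend + F.e_twist,
    _["gradient"] = g);
}
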