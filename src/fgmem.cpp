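// Core engine for the two-component fluid-membrane model: a closed
// dynamically triangulated surface with a binary phase label per triangle,
// evolved by Metropolis vertex moves and phase-conserving bond flips under
//   S = lambda*S0 + S1 + kappa*S2,
//   S0 = sum_ij (1 - sigma_i sigma_j)          (aggregation / line tension)
//   S1 = sum_ij gamma_ij l_ij^2                (Gaussian / tension)
//   S2 = sum_ij kappa_ij (1 - n_i . n_j)       (bending)
// with per-bond coefficients gamma_ij, kappa_ij derived from the Finsler
// metric factor rho (= c on Lo triangles, 1 on Ld triangles).
//
// All randomness is drawn from R's RNG (unif_rand), so a single set.seed
// on the R side makes every simulation reproducible.

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <functional>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------- coefficients

struct Params {
  double lambda, kappa, c;
  int model; // 1 or 2
};

static inline double rho_of(int s, double c) { return s > 0 ? c : 1.0; }

static inline double kap_ij(int si, int sj, double c) {
  const double ri = rho_of(si, c), rj = rho_of(sj, c);
  return 0.25 * (ri + 1.0 / ri + rj + 1.0 / rj);
}

static inline double gam_ij(int si, int sj, double c, int model) {
  return model == 1 ? 1.0 : kap_ij(si, sj, c);
}

// ---------------------------------------------------------------------- mesh

// Closed orientable triangulation, sphere topology.  Faces are stored with
// consistent outward (counter-clockwise seen from outside) winding; each
// undirected bond records the face containing the directed edge BU->BV in
// BF1 and the face containing BV->BU in BF2.
struct Mesh {
  int N = 0, NT = 0, NB = 0;
  std::vector<double> X;                     // 3*N vertex coordinates
  std::vector<int> F;                        // 3*NT vertex indices (0-based)
  std::vector<int> sig;                      // NT labels, +1 (Lo) / -1 (Ld)
  std::vector<int> BU, BV, BF1, BF2;         // per-bond tables
  std::vector<std::array<int, 3> > FB;       // 3 bond ids per face
  std::vector<std::vector<int> > vadj;       // neighbour vertices
  std::vector<std::vector<int> > vbond;      // parallel bond ids
  std::vector<std::vector<int> > vface;      // faces incident to each vertex

  int findBond(int u, int v) const {
    const std::vector<int>& a = vadj[u];
    for (size_t k = 0; k < a.size(); ++k)
      if (a[k] == v) return vbond[u][k];
    return -1;
  }

  void init(const NumericMatrix& Vm, const IntegerMatrix& Fm,
            const IntegerVector& sg, bool canonical) {
    N = Vm.nrow();
    NT = Fm.nrow();
    X.resize(3 * (size_t)N);
    for (int i = 0; i < N; ++i) {
      X[3 * (size_t)i] = Vm(i, 0);
      X[3 * (size_t)i + 1] = Vm(i, 1);
      X[3 * (size_t)i + 2] = Vm(i, 2);
    }
    F.resize(3 * (size_t)NT);
    for (int f = 0; f < NT; ++f)
      for (int k = 0; k < 3; ++k) {
        int v = Fm(f, k) - 1;
        if (v < 0 || v >= N) stop("triangle references a vertex outside 1..N");
        F[3 * (size_t)f + k] = v;
      }
    sig.assign(NT, 1);
    if (sg.size() == NT) {
      for (int f = 0; f < NT; ++f) {
        if (sg[f] != 1 && sg[f] != -1) stop("sigma must be +1 or -1");
        sig[f] = sg[f];
      }
    } else if (sg.size() != 0) {
      stop("sigma must have one entry per triangle");
    }
    buildBonds();
    if (canonical) canonicalize();
  }

  void buildBonds() {
    vadj.assign(N, std::vector<int>());
    vbond.assign(N, std::vector<int>());
    vface.assign(N, std::vector<int>());
    BU.clear(); BV.clear(); BF1.clear(); BF2.clear();
    FB.assign(NT, std::array<int, 3>());
    for (int f = 0; f < NT; ++f) {
      for (int k = 0; k < 3; ++k) {
        int u = F[3 * (size_t)f + k], v = F[3 * (size_t)f + (k + 1) % 3];
        if (u == v) stop("degenerate triangle: repeated vertex index");
        int b = findBond(u, v);
        if (b < 0) {
          b = (int)BU.size();
          BU.push_back(u); BV.push_back(v);
          BF1.push_back(f); BF2.push_back(-1);
          vadj[u].push_back(v); vbond[u].push_back(b);
          vadj[v].push_back(u); vbond[v].push_back(b);
        } else {
          if (BU[b] == u)
            stop("inconsistent winding: directed edge traversed twice");
          if (BF2[b] >= 0)
            stop("non-manifold edge: more than two incident triangles");
          BF2[b] = f;
        }
        FB[f][k] = b;
      }
      vface[F[3 * (size_t)f]].push_back(f);
      vface[F[3 * (size_t)f + 1]].push_back(f);
      vface[F[3 * (size_t)f + 2]].push_back(f);
    }
    NB = (int)BU.size();
    for (int b = 0; b < NB; ++b)
      if (BF2[b] < 0) stop("open edge found: surface is not closed");
    for (int i = 0; i < N; ++i)
      if ((int)vadj[i].size() < 3) stop("vertex with coordination number < 3");
  }

  // Deterministic bond ordering (sorted by unordered endpoint pair) so that
  // bond ids exposed to R are a pure function of the triangulation.
  void canonicalize() {
    std::vector<int> idx(NB);
    for (int b = 0; b < NB; ++b) idx[b] = b;
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
      int au = std::min(BU[a], BV[a]), av = std::max(BU[a], BV[a]);
      int bu = std::min(BU[b], BV[b]), bv = std::max(BU[b], BV[b]);
      return au < bu || (au == bu && av < bv);
    });
    std::vector<int> newId(NB);
    for (int r = 0; r < NB; ++r) newId[idx[r]] = r;
    std::vector<int> u2(NB), v2(NB), f12(NB), f22(NB);
    for (int b = 0; b < NB; ++b) {
      u2[newId[b]] = BU[b]; v2[newId[b]] = BV[b];
      f12[newId[b]] = BF1[b]; f22[newId[b]] = BF2[b];
    }
    BU.swap(u2); BV.swap(v2); BF1.swap(f12); BF2.swap(f22);
    for (int f = 0; f < NT; ++f)
      for (int k = 0; k < 3; ++k) FB[f][k] = newId[FB[f][k]];
    for (int i = 0; i < N; ++i)
      for (size_t k = 0; k < vbond[i].size(); ++k)
        vbond[i][k] = newId[vbond[i][k]];
  }

  inline const double* pos(int v) const { return &X[3 * (size_t)v]; }

  inline double len2(int b) const {
    const double* a = pos(BU[b]);
    const double* c = pos(BV[b]);
    const double dx = a[0] - c[0], dy = a[1] - c[1], dz = a[2] - c[2];
    return dx * dx + dy * dy + dz * dz;
  }

  // Unit outward normal; false when the triangle is (numerically) degenerate.
  inline bool normal(int f, double* n) const {
    const double* a = pos(F[3 * (size_t)f]);
    const double* b = pos(F[3 * (size_t)f + 1]);
    const double* c = pos(F[3 * (size_t)f + 2]);
    const double ux = b[0] - a[0], uy = b[1] - a[1], uz = b[2] - a[2];
    const double vx = c[0] - a[0], vy = c[1] - a[1], vz = c[2] - a[2];
    n[0] = uy * vz - uz * vy;
    n[1] = uz * vx - ux * vz;
    n[2] = ux * vy - uy * vx;
    const double q = n[0] * n[0] + n[1] * n[1] + n[2] * n[2];
    if (q < 1e-24) return false;
    const double s = 1.0 / std::sqrt(q);
    n[0] *= s; n[1] *= s; n[2] *= s;
    return true;
  }

  bool totalEnergy(const Params& P, double& S0, double& S1, double& S2) const {
    std::vector<double> nrm(3 * (size_t)NT);
    for (int f = 0; f < NT; ++f)
      if (!normal(f, &nrm[3 * (size_t)f])) return false;
    S0 = S1 = S2 = 0.0;
    for (int b = 0; b < NB; ++b) {
      const int s1 = sig[BF1[b]], s2 = sig[BF2[b]];
      S0 += 1 - s1 * s2;
      S1 += gam_ij(s1, s2, P.c, P.model) * len2(b);
      const double* n1 = &nrm[3 * (size_t)BF1[b]];
      const double* n2 = &nrm[3 * (size_t)BF2[b]];
      S2 += kap_ij(s1, s2, P.c) *
            (1.0 - (n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2]));
    }
    return true;
  }

  double localS0(const std::vector<int>& bs) const {
    double s = 0;
    for (size_t k = 0; k < bs.size(); ++k)
      s += 1 - sig[BF1[bs[k]]] * sig[BF2[bs[k]]];
    return s;
  }

  bool localS12(const std::vector<int>& bs, const Params& P,
                double& S1, double& S2) const {
    S1 = S2 = 0.0;
    double n1[3], n2[3];
    for (size_t k = 0; k < bs.size(); ++k) {
      const int b = bs[k];
      const int s1 = sig[BF1[b]], s2 = sig[BF2[b]];
      S1 += gam_ij(s1, s2, P.c, P.model) * len2(b);
      if (!normal(BF1[b], n1) || !normal(BF2[b], n2)) return false;
      S2 += kap_ij(s1, s2, P.c) *
            (1.0 - (n1[0] * n2[0] + n1[1] * n2[1] + n1[2] * n2[2]));
    }
    return true;
  }

  // All bonds whose S1 or S2 term can change when vertex i moves: the bonds
  // of every triangle in the star of i (bond lengths change only on bonds
  // incident to i, but normals change on every star-triangle bond).
  std::vector<int> starBonds(int i) const {
    std::vector<int> bs;
    bs.reserve(3 * vface[i].size());
    for (size_t k = 0; k < vface[i].size(); ++k) {
      const std::array<int, 3>& fb = FB[vface[i][k]];
      bs.push_back(fb[0]); bs.push_back(fb[1]); bs.push_back(fb[2]);
    }
    std::sort(bs.begin(), bs.end());
    bs.erase(std::unique(bs.begin(), bs.end()), bs.end());
    return bs;
  }

  // S0 never changes under a vertex move; returns false on degenerate
  // proposed triangles (caller treats as dS = +Inf).
  bool vertexDelta(int i, const double* np, const Params& P,
                   double& d1, double& d2) {
    const std::vector<int> bs = starBonds(i);
    double a1, a2, b1, b2;
    if (!localS12(bs, P, a1, a2)) return false;
    double old[3] = { X[3 * (size_t)i], X[3 * (size_t)i + 1], X[3 * (size_t)i + 2] };
    X[3 * (size_t)i] = np[0];
    X[3 * (size_t)i + 1] = np[1];
    X[3 * (size_t)i + 2] = np[2];
    const bool ok = localS12(bs, P, b1, b2);
    X[3 * (size_t)i] = old[0];
    X[3 * (size_t)i + 1] = old[1];
    X[3 * (size_t)i + 2] = old[2];
    if (!ok) return false;
    d1 = b1 - a1;
    d2 = b2 - a2;
    return true;
  }

  // ------------------------------------------------------------- bond flips

  // Flip of bond b = (u,v) shared by f1 = (u,v,p) and f2 = (v,u,q): the
  // diagonal (u,v) of the quadrilateral u-q-v-p is replaced by (p,q), the
  // faces become f1' = (u,q,p) and f2' = (v,p,q) (winding preserved).
  struct FlipInfo {
    int b, u, v, p, q, f1, f2;
    int b_vp, b_pu, b_uq, b_qv;
    int s1, s2, ns1, ns2;
    bool legal;
  };

  // sigma reassignment rule: equal labels stay equal; different labels are
  // redistributed at random over the two new triangles (coin in [0,1)).
  // The Lo triangle count is conserved in both cases.
  FlipInfo flipInfo(int b, double coin) const {
    FlipInfo fi;
    fi.legal = false;
    fi.b = b;
    const int u = BU[b], v = BV[b], f1 = BF1[b], f2 = BF2[b];
    int p = -1, q = -1;
    for (int k = 0; k < 3; ++k) {
      const int w1 = F[3 * (size_t)f1 + k];
      if (w1 != u && w1 != v) p = w1;
      const int w2 = F[3 * (size_t)f2 + k];
      if (w2 != u && w2 != v) q = w2;
    }
    fi.u = u; fi.v = v; fi.p = p; fi.q = q; fi.f1 = f1; fi.f2 = f2;
    fi.s1 = sig[f1];
    fi.s2 = sig[f2];
    if (p == q) return fi;                       // faces share two bonds
    if ((int)vadj[u].size() < 4 || (int)vadj[v].size() < 4) return fi;
    if (findBond(p, q) >= 0) return fi;          // new diagonal already a bond
    fi.b_vp = findBond(v, p);
    fi.b_pu = findBond(p, u);
    fi.b_uq = findBond(u, q);
    fi.b_qv = findBond(q, v);
    if (fi.s1 == fi.s2) {
      fi.ns1 = fi.s1; fi.ns2 = fi.s2;
    } else if (coin < 0.5) {
      fi.ns1 = fi.s1; fi.ns2 = fi.s2;
    } else {
      fi.ns1 = fi.s2; fi.ns2 = fi.s1;
    }
    fi.legal = true;
    return fi;
  }

  void eraseVal(std::vector<int>& v, int x) {
    for (size_t k = 0; k < v.size(); ++k)
      if (v[k] == x) { v[k] = v.back(); v.pop_back(); return; }
    stop("internal error: value not found during flip bookkeeping");
  }

  void removeAdj(int u, int v) {
    std::vector<int>& a = vadj[u];
    std::vector<int>& b = vbond[u];
    for (size_t k = 0; k < a.size(); ++k)
      if (a[k] == v) {
        a[k] = a.back(); a.pop_back();
        b[k] = b.back(); b.pop_back();
        return;
      }
    stop("internal error: adjacency entry not found");
  }

  void replaceFaceRef(int b, int from, int to) {
    if (BF1[b] == from) BF1[b] = to;
    else if (BF2[b] == from) BF2[b] = to;
    else stop("internal error: face reference not found on bond");
  }

  void applyFlip(const FlipInfo& fi) {
    const int u = fi.u, v = fi.v, p = fi.p, q = fi.q;
    const int f1 = fi.f1, f2 = fi.f2, b = fi.b;
    F[3 * (size_t)f1] = u; F[3 * (size_t)f1 + 1] = q; F[3 * (size_t)f1 + 2] = p;
    F[3 * (size_t)f2] = v; F[3 * (size_t)f2 + 1] = p; F[3 * (size_t)f2 + 2] = q;
    sig[f1] = fi.ns1;
    sig[f2] = fi.ns2;
    removeAdj(u, v); removeAdj(v, u);
    BU[b] = p; BV[b] = q; BF1[b] = f2; BF2[b] = f1; // f2' holds p->q
    vadj[p].push_back(q); vbond[p].push_back(b);
    vadj[q].push_back(p); vbond[q].push_back(b);
    replaceFaceRef(fi.b_vp, f1, f2); // directed v->p moves from f1 to f2'
    replaceFaceRef(fi.b_uq, f2, f1); // directed u->q moves from f2 to f1'
    FB[f1] = { fi.b_uq, b, fi.b_pu };
    FB[f2] = { fi.b_vp, b, fi.b_qv };
    eraseVal(vface[v], f1); vface[q].push_back(f1);
    eraseVal(vface[u], f2); vface[p].push_back(f2);
  }

  void revertFlip(const FlipInfo& fi) {
    const int u = fi.u, v = fi.v, p = fi.p, q = fi.q;
    const int f1 = fi.f1, f2 = fi.f2, b = fi.b;
    F[3 * (size_t)f1] = u; F[3 * (size_t)f1 + 1] = v; F[3 * (size_t)f1 + 2] = p;
    F[3 * (size_t)f2] = v; F[3 * (size_t)f2 + 1] = u; F[3 * (size_t)f2 + 2] = q;
    sig[f1] = fi.s1;
    sig[f2] = fi.s2;
    removeAdj(p, q); removeAdj(q, p);
    BU[b] = u; BV[b] = v; BF1[b] = f1; BF2[b] = f2;
    vadj[u].push_back(v); vbond[u].push_back(b);
    vadj[v].push_back(u); vbond[v].push_back(b);
    replaceFaceRef(fi.b_vp, f2, f1);
    replaceFaceRef(fi.b_uq, f1, f2);
    FB[f1] = { b, fi.b_vp, fi.b_pu };
    FB[f2] = { b, fi.b_uq, fi.b_qv };
    eraseVal(vface[q], f1); vface[v].push_back(f1);
    eraseVal(vface[p], f2); vface[u].push_back(f2);
  }

  std::vector<int> flipBonds(const FlipInfo& fi) const {
    std::vector<int> bs;
    bs.push_back(fi.b);
    bs.push_back(fi.b_vp);
    bs.push_back(fi.b_pu);
    bs.push_back(fi.b_uq);
    bs.push_back(fi.b_qv);
    return bs;
  }

  // Energy difference of a flip from the 5-bond patch (flipped bond + the
  // quadrilateral boundary); S0, S1 and S2 all change only there.
  bool flipDelta(const FlipInfo& fi, const Params& P,
                 double& d0, double& d1, double& d2) {
    const std::vector<int> bs = flipBonds(fi);
    const double a0 = localS0(bs);
    double a1, a2, b1, b2;
    if (!localS12(bs, P, a1, a2)) return false;
    Mesh* self = const_cast<Mesh*>(this);
    self->applyFlip(fi);
    const double c0 = localS0(bs);
    const bool ok = localS12(bs, P, b1, b2);
    self->revertFlip(fi);
    if (!ok) return false;
    d0 = c0 - a0;
    d1 = b1 - a1;
    d2 = b2 - a2;
    return true;
  }

  // --------------------------------------------------------------- auditing

  void checkInvariants(int expectNTo) const {
    if (NB != 3 * N - 6 || NT != 2 * N - 4)
      stop("sphere-topology counts violated");
    if (N - NB + NT != 2) stop("Euler characteristic != 2");
    // winding: rebuild directed-edge multiset
    std::vector<std::vector<int> > seen(N);
    for (int f = 0; f < NT; ++f)
      for (int k = 0; k < 3; ++k) {
        const int u = F[3 * (size_t)f + k], v = F[3 * (size_t)f + (k + 1) % 3];
        for (size_t j = 0; j < seen[u].size(); ++j)
          if (seen[u][j] == v) stop("directed edge traversed twice");
        seen[u].push_back(v);
      }
    for (int i = 0; i < N; ++i) {
      if ((int)vadj[i].size() < 3) stop("vertex coordination < 3");
      if (seen[i].size() != vadj[i].size())
        stop("adjacency tables out of sync with faces");
    }
    int nto = 0;
    for (int f = 0; f < NT; ++f) if (sig[f] > 0) ++nto;
    if (expectNTo >= 0 && nto != expectNTo)
      stop("Lo triangle count not conserved");
    for (int b = 0; b < NB; ++b) {
      bool ok1 = false, ok2 = false;
      for (int k = 0; k < 3; ++k) {
        const int f = BF1[b];
        if (F[3 * (size_t)f + k] == BU[b] &&
            F[3 * (size_t)f + (k + 1) % 3] == BV[b]) ok1 = true;
        const int g = BF2[b];
        if (F[3 * (size_t)g + k] == BV[b] &&
            F[3 * (size_t)g + (k + 1) % 3] == BU[b]) ok2 = true;
      }
      if (!ok1 || !ok2) stop("bond-face incidence tables corrupted");
    }
  }
};

// ------------------------------------------------------------- linear algebra

// Cyclic Jacobi eigensolver for a symmetric 3x3 matrix.
static void jacobi3(double A[3][3], double V[3][3], double d[3]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) V[i][j] = (i == j) ? 1.0 : 0.0;
  for (int sweep = 0; sweep < 64; ++sweep) {
    double off = std::fabs(A[0][1]) + std::fabs(A[0][2]) + std::fabs(A[1][2]);
    if (off < 1e-15) break;
    for (int p = 0; p < 2; ++p)
      for (int q = p + 1; q < 3; ++q) {
        if (std::fabs(A[p][q]) < 1e-18) continue;
        const double theta = (A[q][q] - A[p][p]) / (2.0 * A[p][q]);
        const double t = (theta >= 0 ? 1.0 : -1.0) /
                         (std::fabs(theta) + std::sqrt(theta * theta + 1.0));
        const double cth = 1.0 / std::sqrt(t * t + 1.0);
        const double sth = t * cth;
        for (int k = 0; k < 3; ++k) {
          const double akp = A[k][p], akq = A[k][q];
          A[k][p] = cth * akp - sth * akq;
          A[k][q] = sth * akp + cth * akq;
        }
        for (int k = 0; k < 3; ++k) {
          const double apk = A[p][k], aqk = A[q][k];
          A[p][k] = cth * apk - sth * aqk;
          A[q][k] = sth * apk + cth * aqk;
        }
        for (int k = 0; k < 3; ++k) {
          const double vkp = V[k][p], vkq = V[k][q];
          V[k][p] = cth * vkp - sth * vkq;
          V[k][q] = sth * vkp + cth * vkq;
        }
      }
  }
  for (int i = 0; i < 3; ++i) d[i] = A[i][i];
}

// Full extents (max - min vertex projection) along the principal axes of the
// second-moment tensor about the centre of mass, sorted descending.
static void semiAxesOf(const Mesh& m, double D[3]) {
  double com[3] = { 0, 0, 0 };
  for (int i = 0; i < m.N; ++i)
    for (int k = 0; k < 3; ++k) com[k] += m.X[3 * (size_t)i + k];
  for (int k = 0; k < 3; ++k) com[k] /= m.N;
  double A[3][3] = { { 0, 0, 0 }, { 0, 0, 0 }, { 0, 0, 0 } };
  for (int i = 0; i < m.N; ++i) {
    double r[3];
    for (int k = 0; k < 3; ++k) r[k] = m.X[3 * (size_t)i + k] - com[k];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) A[a][b] += r[a] * r[b];
  }
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) A[a][b] /= m.N;
  double V[3][3], d[3];
  jacobi3(A, V, d);
  for (int ax = 0; ax < 3; ++ax) {
    double lo = R_PosInf, hi = R_NegInf;
    for (int i = 0; i < m.N; ++i) {
      double pr = 0;
      for (int k = 0; k < 3; ++k)
        pr += (m.X[3 * (size_t)i + k] - com[k]) * V[k][ax];
      if (pr < lo) lo = pr;
      if (pr > hi) hi = pr;
    }
    D[ax] = hi - lo;
  }
  std::sort(D, D + 3, std::greater<double>());
}

// Union-find over triangles: components of equal-sigma face adjacency.
static void phaseComponents(const Mesh& m, int& nLo, int& nLd) {
  std::vector<int> parent(m.NT);
  for (int f = 0; f < m.NT; ++f) parent[f] = f;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int b = 0; b < m.NB; ++b) {
    const int f1 = m.BF1[b], f2 = m.BF2[b];
    if (m.sig[f1] == m.sig[f2]) {
      const int r1 = find(f1), r2 = find(f2);
      if (r1 != r2) parent[r1] = r2;
    }
  }
  nLo = nLd = 0;
  for (int f = 0; f < m.NT; ++f)
    if (find(f) == f) {
      if (m.sig[f] > 0) ++nLo; else ++nLd;
    }
}

static void meanAreas(const Mesh& m, double& aLo, double& aLd) {
  double sLo = 0, sLd = 0;
  int nLo = 0, nLd = 0;
  for (int f = 0; f < m.NT; ++f) {
    const double* a = m.pos(m.F[3 * (size_t)f]);
    const double* b = m.pos(m.F[3 * (size_t)f + 1]);
    const double* c = m.pos(m.F[3 * (size_t)f + 2]);
    const double ux = b[0] - a[0], uy = b[1] - a[1], uz = b[2] - a[2];
    const double vx = c[0] - a[0], vy = c[1] - a[1], vz = c[2] - a[2];
    const double cx = uy * vz - uz * vy;
    const double cy = uz * vx - ux * vz;
    const double cz = ux * vy - uy * vx;
    const double ar = 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
    if (m.sig[f] > 0) { sLo += ar; ++nLo; } else { sLd += ar; ++nLd; }
  }
  aLo = nLo ? sLo / nLo : NA_REAL;
  aLd = nLd ? sLd / nLd : NA_REAL;
}

// --------------------------------------------------------------- R interface

static NumericMatrix vertsOut(const Mesh& m) {
  NumericMatrix Vm(m.N, 3);
  for (int i = 0; i < m.N; ++i)
    for (int k = 0; k < 3; ++k) Vm(i, k) = m.X[3 * (size_t)i + k];
  return Vm;
}

static IntegerMatrix facesOut(const Mesh& m) {
  IntegerMatrix Fm(m.NT, 3);
  for (int f = 0; f < m.NT; ++f)
    for (int k = 0; k < 3; ++k) Fm(f, k) = m.F[3 * (size_t)f + k] + 1;
  return Fm;
}

static IntegerVector sigOut(const Mesh& m) {
  IntegerVector s(m.NT);
  for (int f = 0; f < m.NT; ++f) s[f] = m.sig[f];
  return s;
}

// [[Rcpp::export]]
List cpp_validate(NumericMatrix V, IntegerMatrix F, IntegerVector sigma) {
  Mesh m;
  std::string msg = "";
  bool ok = true;
  try {
    m.init(V, F, sigma, false);
    m.checkInvariants(-1);
  } catch (std::exception& e) {
    ok = false;
    msg = e.what();
  }
  if (!ok)
    return List::create(_["ok"] = false, _["message"] = msg);
  int nto = 0;
  for (int f = 0; f < m.NT; ++f) if (m.sig[f] > 0) ++nto;
  return List::create(
    _["ok"] = true, _["message"] = "",
    _["N"] = m.N, _["NT"] = m.NT, _["NB"] = m.NB,
    _["euler"] = m.N - m.NB + m.NT, _["NTo"] = nto);
}

// Canonically ordered bond table: endpoints and the two incident faces
// (f1 contains the directed edge u->v).
// [[Rcpp::export]]
IntegerMatrix cpp_bonds(NumericMatrix V, IntegerMatrix F, IntegerVector sigma) {
  Mesh m;
  m.init(V, F, sigma, true);
  IntegerMatrix B(m.NB, 4);
  for (int b = 0; b < m.NB; ++b) {
    // orientation-normalized: u < v, face1 holds the directed edge u -> v
    const bool fwd = m.BU[b] < m.BV[b];
    B(b, 0) = (fwd ? m.BU[b] : m.BV[b]) + 1;
    B(b, 1) = (fwd ? m.BV[b] : m.BU[b]) + 1;
    B(b, 2) = (fwd ? m.BF1[b] : m.BF2[b]) + 1;
    B(b, 3) = (fwd ? m.BF2[b] : m.BF1[b]) + 1;
  }
  colnames(B) = CharacterVector::create("u", "v", "face1", "face2");
  return B;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix V, IntegerMatrix F,
                               IntegerVector sigma, double lambda,
                               double kappa, double c, int model) {
  Mesh m;
  m.init(V, F, sigma, false);
  Params P = { lambda, kappa, c, model };
  double s0, s1, s2;
  if (!m.totalEnergy(P, s0, s1, s2))
    stop("degenerate (zero-area) triangle: face normal undefined");
  return NumericVector::create(
    _["S0"] = s0, _["S1"] = s1, _["S2"] = s2,
    _["total"] = lambda * s0 + s1 + kappa * s2);
}

// [[Rcpp::export]]
double cpp_delta_vertex(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                        double lambda, double kappa, double c, int model,
                        int vertex, NumericVector newPos) {
  Mesh m;
  m.init(V, F, sigma, false);
  if (vertex < 1 || vertex > m.N) stop("vertex index out of range");
  Params P = { lambda, kappa, c, model };
  double d1, d2;
  double np[3] = { newPos[0], newPos[1], newPos[2] };
  if (!m.vertexDelta(vertex - 1, np, P, d1, d2)) return R_PosInf;
  return d1 + kappa * d2;
}

// [[Rcpp::export]]
List cpp_flip_candidate(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                        int bond, double coin) {
  Mesh m;
  m.init(V, F, sigma, true);
  if (bond < 1 || bond > m.NB) stop("bond index out of range");
  Mesh::FlipInfo fi = m.flipInfo(bond - 1, coin);
  return List::create(
    _["legal"] = fi.legal, _["bond"] = bond,
    _["u"] = fi.u + 1, _["v"] = fi.v + 1,
    _["p"] = fi.p + 1, _["q"] = fi.q + 1,
    _["face1"] = fi.f1 + 1, _["face2"] = fi.f2 + 1,
    _["oldSigma"] = IntegerVector::create(fi.s1, fi.s2),
    _["newSigma"] = fi.legal
      ? IntegerVector::create(fi.ns1, fi.ns2)
      : IntegerVector::create(NA_INTEGER, NA_INTEGER));
}

// Applies a flip with an explicit sigma assignment for the two new
// triangles (slots face1, face2 of the canonical bond table).
// [[Rcpp::export]]
List cpp_apply_flip(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                    int bond, IntegerVector newSigma) {
  Mesh m;
  m.init(V, F, sigma, true);
  if (bond < 1 || bond > m.NB) stop("bond index out of range");
  Mesh::FlipInfo fi = m.flipInfo(bond - 1, 0.0);
  if (!fi.legal) stop("flip is topologically illegal for this bond");
  fi.ns1 = newSigma[0];
  fi.ns2 = newSigma[1];
  m.applyFlip(fi);
  return List::create(_["triangles"] = facesOut(m), _["sigma"] = sigOut(m));
}

// [[Rcpp::export]]
double cpp_delta_flip(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                      double lambda, double kappa, double c, int model,
                      int bond, IntegerVector newSigma) {
  Mesh m;
  m.init(V, F, sigma, true);
  Mesh::FlipInfo fi = m.flipInfo(bond - 1, 0.0);
  if (!fi.legal) stop("flip is topologically illegal for this bond");
  fi.ns1 = newSigma[0];
  fi.ns2 = newSigma[1];
  Params P = { lambda, kappa, c, model };
  double d0, d1, d2;
  if (!m.flipDelta(fi, P, d0, d1, d2)) return R_PosInf;
  return lambda * d0 + d1 + kappa * d2;
}

// One Metropolis vertex-move attempt (R RNG): uniform random vertex, delta r
// uniform in the ball of radius R, acceptance min(1, exp(-dS)) at kT = 1.
// [[Rcpp::export]]
List cpp_vertex_update(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                       double lambda, double kappa, double c, int model,
                       double moveRadius) {
  Mesh m;
  m.init(V, F, sigma, false);
  Params P = { lambda, kappa, c, model };
  const int i = (int)std::floor(unif_rand() * m.N);
  double dr[3];
  do {
    dr[0] = 2.0 * unif_rand() - 1.0;
    dr[1] = 2.0 * unif_rand() - 1.0;
    dr[2] = 2.0 * unif_rand() - 1.0;
  } while (dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2] > 1.0);
  double np[3];
  for (int k = 0; k < 3; ++k)
    np[k] = m.X[3 * (size_t)i + k] + moveRadius * dr[k];
  double d1, d2, dS;
  bool ok = m.vertexDelta(i, np, P, d1, d2);
  dS = ok ? d1 + kappa * d2 : R_PosInf;
  bool accepted = false;
  if (dS <= 0.0 || unif_rand() < std::exp(-dS)) accepted = true;
  if (!ok) accepted = false;
  if (accepted)
    for (int k = 0; k < 3; ++k) m.X[3 * (size_t)i + k] = np[k];
  return List::create(
    _["vertices"] = vertsOut(m), _["accepted"] = accepted,
    _["dS"] = dS, _["vertex"] = i + 1);
}

// One Metropolis bond-flip attempt (R RNG): uniform random bond; illegal
// flips count as rejected.
// [[Rcpp::export]]
List cpp_flip_update(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                     double lambda, double kappa, double c, int model) {
  Mesh m;
  m.init(V, F, sigma, true);
  Params P = { lambda, kappa, c, model };
  const int b = (int)std::floor(unif_rand() * m.NB);
  Mesh::FlipInfo fi = m.flipInfo(b, unif_rand());
  bool accepted = false;
  double dS = NA_REAL;
  if (fi.legal) {
    double d0, d1, d2;
    if (m.flipDelta(fi, P, d0, d1, d2)) {
      dS = lambda * d0 + d1 + kappa * d2;
      if (dS <= 0.0 || unif_rand() < std::exp(-dS)) {
        m.applyFlip(fi);
        accepted = true;
      }
    }
  }
  return List::create(
    _["triangles"] = facesOut(m), _["sigma"] = sigOut(m),
    _["accepted"] = accepted, _["legal"] = fi.legal,
    _["dS"] = dS, _["bond"] = b + 1);
}

// Topology stress test: nAttempts random flips applied whenever legal
// (no Metropolis weighting), with full invariant checks every checkEvery
// attempts.  Errors out on the first violated invariant.
// [[Rcpp::export]]
List cpp_flip_storm(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                    int nAttempts, int checkEvery) {
  Mesh m;
  m.init(V, F, sigma, true);
  int nto = 0;
  for (int f = 0; f < m.NT; ++f) if (m.sig[f] > 0) ++nto;
  int applied = 0, checks = 0;
  for (int t = 1; t <= nAttempts; ++t) {
    const int b = (int)std::floor(unif_rand() * m.NB);
    Mesh::FlipInfo fi = m.flipInfo(b, unif_rand());
    if (fi.legal) {
      m.applyFlip(fi);
      ++applied;
    }
    if (t % checkEvery == 0 || t == nAttempts) {
      m.checkInvariants(nto);
      ++checks;
    }
  }
  return List::create(
    _["triangles"] = facesOut(m), _["sigma"] = sigOut(m),
    _["attempted"] = nAttempts, _["applied"] = applied,
    _["checks"] = checks);
}

// Main simulation chunk: nSweeps sweeps of N vertex-move attempts and N
// flip attempts in randomized interleaving, with recentering after each
// sweep, optional multiplicative move-radius tuning toward a target
// acceptance, optional measurement records, and periodic full energy
// recomputation to audit incremental drift.
// [[Rcpp::export]]
List cpp_run_chunk(NumericMatrix V, IntegerMatrix F, IntegerVector sigma,
                   double lambda, double kappa, double c, int model,
                   int nSweeps, int sweepOffset, double moveRadius,
                   bool tune, int tuneInterval, double targetAcc,
                   bool measure, int measInterval, int recomputeInterval) {
  Mesh m;
  m.init(V, F, sigma, false);
  Params P = { lambda, kappa, c, model };
  const int N = m.N, NB = m.NB;
  double S0, S1, S2;
  if (!m.totalEnergy(P, S0, S1, S2))
    stop("degenerate triangle in the initial surface");

  double R = moveRadius;
  long vAtt = 0, vAcc = 0, fAtt = 0, fAcc = 0;          // chunk totals
  long vAttW = 0, vAccW = 0;                            // tuning window
  long vAttR = 0, vAccR = 0, fAttR = 0, fAccR = 0;      // record window
  double sumS1perN = 0.0;
  double maxDrift = 0.0;

  std::vector<double> rec;
  const int nCols = 17;
  int nRec = 0;

  for (int sweep = 1; sweep <= nSweeps; ++sweep) {
    int nv = N, nf = N;
    for (int step = 0; step < 2 * N; ++step) {
      const bool doVertex =
        unif_rand() * (nv + nf) < nv; // exact N of each, random interleave
      if (doVertex) {
        --nv;
        ++vAtt; ++vAttW; ++vAttR;
        const int i = (int)std::floor(unif_rand() * N);
        double dr[3];
        do {
          dr[0] = 2.0 * unif_rand() - 1.0;
          dr[1] = 2.0 * unif_rand() - 1.0;
          dr[2] = 2.0 * unif_rand() - 1.0;
        } while (dr[0] * dr[0] + dr[1] * dr[1] + dr[2] * dr[2] > 1.0);
        double np[3];
        for (int k = 0; k < 3; ++k)
          np[k] = m.X[3 * (size_t)i + k] + R * dr[k];
        double d1, d2;
        if (m.vertexDelta(i, np, P, d1, d2)) {
          const double dS = d1 + kappa * d2;
          if (dS <= 0.0 || unif_rand() < std::exp(-dS)) {
            for (int k = 0; k < 3; ++k) m.X[3 * (size_t)i + k] = np[k];
            S1 += d1; S2 += d2;
            ++vAcc; ++vAccW; ++vAccR;
          }
        }
      } else {
        --nf;
        ++fAtt; ++fAttR;
        const int b = (int)std::floor(unif_rand() * NB);
        Mesh::FlipInfo fi = m.flipInfo(b, unif_rand());
        if (fi.legal) {
          double d0, d1, d2;
          if (m.flipDelta(fi, P, d0, d1, d2)) {
            const double dS = lambda * d0 + d1 + kappa * d2;
            if (dS <= 0.0 || unif_rand() < std::exp(-dS)) {
              m.applyFlip(fi);
              S0 += d0; S1 += d1; S2 += d2;
              ++fAcc; ++fAccR;
            }
          }
        }
      }
    }

    // recenter: the energy is translation invariant, so pinning the centre
    // of mass at the origin does not bias sampling
    double com[3] = { 0, 0, 0 };
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) com[k] += m.X[3 * (size_t)i + k];
    for (int k = 0; k < 3; ++k) com[k] /= N;
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < 3; ++k) m.X[3 * (size_t)i + k] -= com[k];

    if (tune && sweep % tuneInterval == 0 && vAttW > 0) {
      const double acc = (double)vAccW / (double)vAttW;
      double fac = acc / targetAcc;
      if (fac < 0.5) fac = 0.5;
      if (fac > 1.5) fac = 1.5;
      R *= fac;
      if (R < 1e-8) R = 1e-8;
      if (R > 1e3) R = 1e3;
      vAttW = vAccW = 0;
    }

    if (recomputeInterval > 0 && sweep % recomputeInterval == 0) {
      double t0, t1, t2;
      if (!m.totalEnergy(P, t0, t1, t2))
        stop("degenerate triangle encountered during run");
      const double scale = std::fabs(t1) + std::fabs(kappa * t2) + 1.0;
      const double drift =
        (std::fabs(S0 - t0) + std::fabs(S1 - t1) + std::fabs(S2 - t2)) / scale;
      if (drift > maxDrift) maxDrift = drift;
      S0 = t0; S1 = t1; S2 = t2;
    }

    if (measure) {
      sumS1perN += S1 / N;
      if (sweep % measInterval == 0) {
        int nLo, nLd;
        phaseComponents(m, nLo, nLd);
        double aLo, aLd, D[3];
        meanAreas(m, aLo, aLd);
        semiAxesOf(m, D);
        int nto = 0;
        for (int f = 0; f < m.NT; ++f) if (m.sig[f] > 0) ++nto;
        const int ntd = m.NT - nto;
        const double afrac =
          (nto && ntd) ? nto * aLo / (nto * aLo + ntd * aLd)
                       : (nto ? 1.0 : 0.0);
        rec.push_back(sweepOffset + sweep);
        rec.push_back(S0);
        rec.push_back(S1 / N);
        rec.push_back(S2 / NB);
        rec.push_back(lambda * S0 + S1 + kappa * S2);
        rec.push_back(S0 / 2.0);
        rec.push_back(nLo);
        rec.push_back(nLd);
        rec.push_back(aLo);
        rec.push_back(aLd);
        rec.push_back(afrac);
        rec.push_back(D[0]);
        rec.push_back(D[1]);
        rec.push_back(D[2]);
        rec.push_back(R);
        rec.push_back(vAttR ? (double)vAccR / vAttR : NA_REAL);
        rec.push_back(fAttR ? (double)fAccR / fAttR : NA_REAL);
        vAttR = vAccR = fAttR = fAccR = 0;
        ++nRec;
      }
    }
  }

  // final audit of the incremental energy
  {
    double t0, t1, t2;
    if (m.totalEnergy(P, t0, t1, t2)) {
      const double scale = std::fabs(t1) + std::fabs(kappa * t2) + 1.0;
      const double drift =
        (std::fabs(S0 - t0) + std::fabs(S1 - t1) + std::fabs(S2 - t2)) / scale;
      if (drift > maxDrift) maxDrift = drift;
      S0 = t0; S1 = t1; S2 = t2;
    }
  }

  NumericMatrix records(nRec, nCols);
  for (int r = 0; r < nRec; ++r)
    for (int cix = 0; cix < nCols; ++cix)
      records(r, cix) = rec[(size_t)r * nCols + cix];
  colnames(records) = CharacterVector::create(
    "sweep", "S0", "S1_per_N", "S2_per_NB", "S_total", "boundary_bonds",
    "n_lo_components", "n_ld_components", "area_lo", "area_ld",
    "area_fraction_lo", "D1", "D2", "D3", "move_radius",
    "acc_vertex", "acc_flip");

  return List::create(
    _["vertices"] = vertsOut(m), _["triangles"] = facesOut(m),
    _["sigma"] = sigOut(m), _["moveRadius"] = R,
    _["records"] = records,
    _["sumS1perN"] = sumS1perN, _["nMeasuredSweeps"] = measure ? nSweeps : 0,
    _["vertexAttempted"] = (double)vAtt, _["vertexAccepted"] = (double)vAcc,
    _["flipAttempted"] = (double)fAtt, _["flipAccepted"] = (double)fAcc,
    _["energy"] = NumericVector::create(
      _["S0"] = S0, _["S1"] = S1, _["S2"] = S2,
      _["total"] = lambda * S0 + S1 + kappa * S2),
    _["maxDrift"] = maxDrift);
}

// [[Rcpp::export]]
NumericVector cpp_semi_axes(NumericMatrix V) {
  Mesh m;
  m.N = V.nrow();
  m.X.resize(3 * (size_t)m.N);
  for (int i = 0; i < m.N; ++i)
    for (int k = 0; k < 3; ++k) m.X[3 * (size_t)i + k] = V(i, k);
  double D[3];
  semiAxesOf(m, D);
  return NumericVector::create(_["D1"] = D[0], _["D2"] = D[1], _["D3"] = D[2]);
}
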