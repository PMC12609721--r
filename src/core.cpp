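#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------

static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

static inline double triArea(const double* a, const double* b,
                             const double* c) {
  double e1[3], e2[3], cr[3];
  vsub(b, a, e1); vsub(c, a, e2); vcross(e1, e2, cr);
  return 0.5 * vnorm(cr);
}

// closest distance from point p to triangle (a, b, c)
static double pointTriDist(const double* p, const double* a,
                           const double* b, const double* c) {
  double ab[3], ac[3], ap[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(p, a, ap);
  double d1 = vdot(ab, ap), d2 = vdot(ac, ap);
  if (d1 <= 0 && d2 <= 0) { double d[3]; vsub(p, a, d); return vnorm(d); }
  double bp[3]; vsub(p, b, bp);
  double d3 = vdot(ab, bp), d4 = vdot(ac, bp);
  if (d3 >= 0 && d4 <= d3) { double d[3]; vsub(p, b, d); return vnorm(d); }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double t = d1 / (d1 - d3);
    double q[3] = {a[0] + t * ab[0], a[1] + t * ab[1], a[2] + t * ab[2]};
    double d[3]; vsub(p, q, d); return vnorm(d);
  }
  double cp[3]; vsub(p, c, cp);
  double d5 = vdot(ab, cp), d6 = vdot(ac, cp);
  if (d6 >= 0 && d5 <= d6) { double d[3]; vsub(p, c, d); return vnorm(d); }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double t = d2 / (d2 - d6);
    double q[3] = {a[0] + t * ac[0], a[1] + t * ac[1], a[2] + t * ac[2]};
    double d[3]; vsub(p, q, d); return vnorm(d);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double t = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + t * (c[0] - b[0]), b[1] + t * (c[1] - b[1]),
                   b[2] + t * (c[2] - b[2])};
    double d[3]; vsub(p, q, d); return vnorm(d);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0] + ab[0] * v + ac[0] * w, a[1] + ab[1] * v + ac[1] * w,
                 a[2] + ab[2] * v + ac[2] * w};
  double d[3]; vsub(p, q, d); return vnorm(d);
}

// segment (p, q) vs triangle (a, b, c) intersection test
static bool segTriIntersect(const double* p, const double* q,
                            const double* a, const double* b,
                            const double* c) {
  double ab[3], ac[3], dir[3], n[3];
  vsub(b, a, ab); vsub(c, a, ac); vsub(q, p, dir);
  vcross(ab, ac, n);
  double denom = vdot(n, dir);
  double ap[3]; vsub(a, p, ap);
  double num = vdot(n, ap);
  if (std::fabs(denom) < 1e-300) return false;  // parallel: treat as no hit
  double t = num / denom;
  if (t < 0.0 || t > 1.0) return false;
  double x[3] = {p[0] + t * dir[0], p[1] + t * dir[1], p[2] + t * dir[2]};
  // barycentric inside test
  double v0[3], v1[3], v2[3];
  vsub(b, a, v0); vsub(c, a, v1); vsub(x, a, v2);
  double d00 = vdot(v0, v0), d01 = vdot(v0, v1), d11 = vdot(v1, v1);
  double d20 = vdot(v2, v0), d21 = vdot(v2, v1);
  double den = d00 * d11 - d01 * d01;
  if (std::fabs(den) < 1e-300) return false;
  double bv = (d11 * d20 - d01 * d21) / den;
  double bw = (d00 * d21 - d01 * d20) / den;
  return bv >= -1e-12 && bw >= -1e-12 && (bv + bw) <= 1 + 1e-12;
}

// do two triangles intersect? (edge-vs-triangle both ways)
static bool triTriIntersect(const double* a0, const double* a1,
                            const double* a2, const double* b0,
                            const double* b1, const double* b2) {
  if (segTriIntersect(a0, a1, b0, b1, b2)) return true;
  if (segTriIntersect(a1, a2, b0, b1, b2)) return true;
  if (segTriIntersect(a2, a0, b0, b1, b2)) return true;
  if (segTriIntersect(b0, b1, a0, a1, a2)) return true;
  if (segTriIntersect(b1, b2, a0, a1, a2)) return true;
  if (segTriIntersect(b2, b0, a0, a1, a2)) return true;
  return false;
}

// [[Rcpp::export]]
bool cpp_tris_intersect(NumericMatrix AV, IntegerMatrix AF,
                        NumericMatrix BV, IntegerMatrix BF) {
  int ma = AF.nrow(), mb = BF.nrow();
  std::vector<double> av(AV.begin(), AV.end());
  std::vector<double> bv(BV.begin(), BV.end());
  int na = AV.nrow(), nb = BV.nrow();
  for (int i = 0; i < ma; ++i) {
    double ta[3][3];
    for (int k = 0; k < 3; ++k) {
      int vi = AF(i, k) - 1;
      ta[k][0] = av[vi]; ta[k][1] = av[vi + na]; ta[k][2] = av[vi + 2 * na];
    }
    for (int j = 0; j < mb; ++j) {
      double tb[3][3];
      for (int k = 0; k < 3; ++k) {
        int vj = BF(j, k) - 1;
        tb[k][0] = bv[vj]; tb[k][1] = bv[vj + nb]; tb[k][2] = bv[vj + 2 * nb];
      }
      if (triTriIntersect(ta[0], ta[1], ta[2], tb[0], tb[1], tb[2]))
        return true;
    }
  }
  return false;
}

// ---------------------------------------------------------------------------
// particle flight with specular reflection (piston chamber)
// ---------------------------------------------------------------------------

// reflect coordinate into [lo, hi], counting hits on the hi wall (count_hi)
// and lo wall (count_lo); velocity sign updated
static void reflect1d(double& x, double& v, double lo, double hi,
                      int& hitLo, int& hitHi) {
  double span = hi - lo;
  int guard = 0;
  while ((x < lo || x > hi) && guard++ < 10000) {
    if (x < lo) { x = 2 * lo - x; v = -v; ++hitLo; }
    else        { x = 2 * hi - x; v = -v; ++hitHi; }
  }
  if (x < lo) x = lo;
  if (x > hi) x = hi;
}

// [[Rcpp::export]]
List cpp_advance_particles(NumericMatrix pos, NumericMatrix vel,
                           NumericVector mass, IntegerVector topside,
                           double L, double zp, double dt) {
  int n = pos.nrow();
  NumericMatrix p = clone(pos);
  NumericMatrix v = clone(vel);
  int collTop = 0, collBottom = 0;
  double impTop = 0.0, impBottom = 0.0;
  for (int i = 0; i < n; ++i) {
    int dum = 0, dum2 = 0;
    double x = p(i, 0) + v(i, 0) * dt;
    double y = p(i, 1) + v(i, 1) * dt;
    double z = p(i, 2) + v(i, 2) * dt;
    double vx = v(i, 0), vy = v(i, 1), vz = v(i, 2);
    reflect1d(x, vx, 0.0, L, dum, dum2);
    reflect1d(y, vy, 0.0, L, dum, dum2);
    int hitLo = 0, hitHi = 0;
    if (topside[i]) {
      reflect1d(z, vz, zp, L, hitLo, hitHi);  // piston is the low wall
      if (hitLo > 0) {
        collTop += hitLo;
        impTop += hitLo * 2.0 * mass[i] * std::fabs(v(i, 2));
      }
    } else {
      reflect1d(z, vz, 0.0, zp, hitLo, hitHi);  // piston is the high wall
      if (hitHi > 0) {
        collBottom += hitHi;
        impBottom += hitHi * 2.0 * mass[i] * std::fabs(v(i, 2));
      }
    }
    p(i, 0) = x; p(i, 1) = y; p(i, 2) = z;
    v(i, 0) = vx; v(i, 1) = vy; v(i, 2) = vz;
  }
  return List::create(_["positions"] = p, _["velocities"] = v,
                      _["collTop"] = collTop, _["collBottom"] = collBottom,
                      _["impulseTop"] = impTop,
                      _["impulseBottom"] = impBottom);
}

// ---------------------------------------------------------------------------
// Metropolis vertex sweeps
// ---------------------------------------------------------------------------

struct LocalEnergyCtx {
  const double* V;      // column-major n x 3
  int n;
  const int* F;         // column-major m x 3, 0-based
  int m;
  const double* rest;   // m
  double kappa;
  // adhesion bonds
  const int* bondFace;       // per bond, 0-based face id (or nullptr)
  const double* bondBary;    // b x 3 column-major
  const double* bondStatic;  // b x 3 column-major
  int nb;
  double kBond, restLen;
  const int* fbPtr;     // m + 1 CSR of face -> bond ids
  const int* fbIdx;
};

// energy of faces incident to vertex vid, with vertex vid at 'pos'
static double localEnergy(const LocalEnergyCtx& c, int vid, const double* pos,
                          const int* vfIdx, int vfBegin, int vfEnd,
                          double areaTol, bool* degenerate) {
  double E = 0.0;
  *degenerate = false;
  for (int t = vfBegin; t < vfEnd; ++t) {
    int fid = vfIdx[t];
    double tv[3][3];
    for (int k = 0; k < 3; ++k) {
      int vi = c.F[fid + k * c.m];
      if (vi == vid) {
        tv[k][0] = pos[0]; tv[k][1] = pos[1]; tv[k][2] = pos[2];
      } else {
        tv[k][0] = c.V[vi]; tv[k][1] = c.V[vi + c.n];
        tv[k][2] = c.V[vi + 2 * c.n];
      }
    }
    double A = triArea(tv[0], tv[1], tv[2]);
    if (A < areaTol) *degenerate = true;
    double a = c.rest[fid];
    double da = A - a;
    E += c.kappa / (2.0 * a * a) * da * da;
    if (c.fbPtr) {
      for (int bi = c.fbPtr[fid]; bi < c.fbPtr[fid + 1]; ++bi) {
        int b = c.fbIdx[bi];
        double anchor[3] = {0, 0, 0};
        for (int k = 0; k < 3; ++k) {
          double w = c.bondBary[b + k * c.nb];
          anchor[0] += w * tv[k][0];
          anchor[1] += w * tv[k][1];
          anchor[2] += w * tv[k][2];
        }
        double dx = anchor[0] - c.bondStatic[b];
        double dy = anchor[1] - c.bondStatic[b + c.nb];
        double dz = anchor[2] - c.bondStatic[b + 2 * c.nb];
        double d = std::sqrt(dx * dx + dy * dy + dz * dz) - c.restLen;
        E += 0.5 * c.kBond * d * d;
      }
    }
  }
  return E;
}

// One (or several) full Metropolis sweeps over the free vertices of a mesh.
// V, F as matrices; vfPtr/vfIdx: CSR vertex -> incident faces (0-based);
// order: 0-based visit order, resampled in R per sweep when nSweeps == 1.
// sphere: length-4 (cx, cy, cz, r); r <= 0 disables the rigid-sphere
// constraint. traceVertex >= 0 records that vertex's position per sweep.
// [[Rcpp::export]]
List cpp_sweep_vertices(NumericMatrix V, IntegerMatrix F,
                        NumericVector restArea, LogicalVector clamped,
                        IntegerVector vfPtr, IntegerVector vfIdx,
                        double kappa, double sigma,
                        NumericVector boxLo, NumericVector boxHi,
                        double areaTol, NumericVector sphere,
                        double crossTol,
                        IntegerVector bondFace, NumericMatrix bondBary,
                        NumericMatrix bondStatic, double kBond,
                        double restLen,
                        int nSweeps, int traceVertex) {
  int n = V.nrow(), m = F.nrow();
  NumericMatrix Vw = clone(V);
  IntegerMatrix F0(m, 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < m; ++i) F0(i, j) = F(i, j) - 1;

  int nb = bondFace.size();
  std::vector<int> fbPtr, fbIdx;
  if (nb > 0) {
    fbPtr.assign(m + 1, 0);
    for (int b = 0; b < nb; ++b) fbPtr[bondFace[b] + 1]++;
    for (int i = 0; i < m; ++i) fbPtr[i + 1] += fbPtr[i];
    fbIdx.assign(nb, 0);
    std::vector<int> cur(fbPtr.begin(), fbPtr.end() - 1);
    for (int b = 0; b < nb; ++b) fbIdx[cur[bondFace[b]]++] = b;
  }

  LocalEnergyCtx ctx;
  ctx.V = Vw.begin(); ctx.n = n;
  ctx.F = F0.begin(); ctx.m = m;
  ctx.rest = restArea.begin();
  ctx.kappa = kappa;
  ctx.nb = nb;
  ctx.kBond = kBond; ctx.restLen = restLen;
  if (nb > 0) {
    ctx.bondFace = bondFace.begin();
    ctx.bondBary = bondBary.begin();
    ctx.bondStatic = bondStatic.begin();
    ctx.fbPtr = fbPtr.data(); ctx.fbIdx = fbIdx.data();
  } else {
    ctx.bondFace = nullptr; ctx.bondBary = nullptr;
    ctx.bondStatic = nullptr; ctx.fbPtr = nullptr; ctx.fbIdx = nullptr;
  }

  bool sphereOn = sphere[3] > 0;
  double scx = sphere[0], scy = sphere[1], scz = sphere[2], sr = sphere[3];
  long accepted = 0, attempted = 0;
  NumericMatrix trace(traceVertex >= 0 ? nSweeps : 0, 3);

  std::vector<int> order(n);
  for (int sweep = 0; sweep < nSweeps; ++sweep) {
    // seeded permutation via R RNG (Fisher-Yates)
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < n; ++oi) {
      int vid = order[oi];
      if (clamped[vid]) continue;
      double oldPos[3] = {Vw(vid, 0), Vw(vid, 1), Vw(vid, 2)};
      double newPos[3] = {oldPos[0] + sigma * norm_rand(),
                          oldPos[1] + sigma * norm_rand(),
                          oldPos[2] + sigma * norm_rand()};
      ++attempted;
      // movement-space bounds
      if (newPos[0] < boxLo[0] || newPos[0] > boxHi[0] ||
          newPos[1] < boxLo[1] || newPos[1] > boxHi[1] ||
          newPos[2] < boxLo[2] || newPos[2] > boxHi[2]) continue;
      bool degen = false;
      double eOld = localEnergy(ctx, vid, oldPos, vfIdx.begin(),
                                vfPtr[vid], vfPtr[vid + 1], areaTol, &degen);
      double eNew = localEnergy(ctx, vid, newPos, vfIdx.begin(),
                                vfPtr[vid], vfPtr[vid + 1], areaTol, &degen);
      if (degen) continue;  // degenerate face after the move
      if (sphereOn) {
        // incident faces must stay outside the rigid sphere
        bool cross = false;
        double sc[3] = {scx, scy, scz};
        for (int t = vfPtr[vid]; t < vfPtr[vid + 1] && !cross; ++t) {
          int fid = vfIdx[t];
          double tv[3][3];
          for (int k = 0; k < 3; ++k) {
            int vi = F0(fid, k);
            if (vi == vid) {
              tv[k][0] = newPos[0]; tv[k][1] = newPos[1];
              tv[k][2] = newPos[2];
            } else {
              tv[k][0] = Vw(vi, 0); tv[k][1] = Vw(vi, 1);
              tv[k][2] = Vw(vi, 2);
            }
          }
          if (pointTriDist(sc, tv[0], tv[1], tv[2]) < sr - crossTol)
            cross = true;
        }
        if (cross) continue;
      }
      double dE = eNew - eOld;
      bool accept = dE <= 0.0 || unif_rand() < std::exp(-dE);
      if (accept) {
        Vw(vid, 0) = newPos[0]; Vw(vid, 1) = newPos[1];
        Vw(vid, 2) = newPos[2];
        ++accepted;
      }
    }
    if (traceVertex >= 0) {
      trace(sweep, 0) = Vw(traceVertex, 0);
      trace(sweep, 1) = Vw(traceVertex, 1);
      trace(sweep, 2) = Vw(traceVertex, 2);
    }
  }
  return List::create(_["vertices"] = Vw, _["accepted"] = (double)accepted,
                      _["attempted"] = (double)attempted,
                      _["trace"] = trace);
}

// ---------------------------------------------------------------------------
// surface diffusion with edge unfolding
// ---------------------------------------------------------------------------

static void faceVerts(const NumericMatrix& V, const IntegerMatrix& F0,
                      int fid, double tv[3][3]) {
  for (int k = 0; k < 3; ++k) {
    int vi = F0(fid, k);
    tv[k][0] = V(vi, 0); tv[k][1] = V(vi, 1); tv[k][2] = V(vi, 2);
  }
}

static void faceNormal(const double tv[3][3], double* nrm) {
  double e1[3], e2[3];
  vsub(tv[1], tv[0], e1); vsub(tv[2], tv[0], e2);
  vcross(e1, e2, nrm);
  double L = vnorm(nrm);
  if (L > 0) { nrm[0] /= L; nrm[1] /= L; nrm[2] /= L; }
}

// barycentric coordinates of p in triangle tv (projected onto its plane)
static void baryCoords(const double tv[3][3], const double* p, double* b) {
  double v0[3], v1[3], v2[3];
  vsub(tv[1], tv[0], v0); vsub(tv[2], tv[0], v1); vsub(p, tv[0], v2);
  double d00 = vdot(v0, v0), d01 = vdot(v0, v1), d11 = vdot(v1, v1);
  double d20 = vdot(v2, v0), d21 = vdot(v2, v1);
  double den = d00 * d11 - d01 * d01;
  double bv = (d11 * d20 - d01 * d21) / den;
  double bw = (d00 * d21 - d01 * d20) / den;
  b[0] = 1.0 - bv - bw; b[1] = bv; b[2] = bw;
}

// [[Rcpp::export]]
List cpp_diffuse_on_surface(NumericMatrix V, IntegerMatrix F,
                            IntegerMatrix adj, IntegerVector face,
                            NumericMatrix bary, LogicalVector frozen,
                            NumericVector stepSD) {
  int m = F.nrow();
  int nmol = face.size();
  IntegerMatrix F0(m, 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < m; ++i) F0(i, j) = F(i, j) - 1;
  IntegerMatrix A0(m, 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < m; ++i) A0(i, j) = adj(i, j) - 1;  // -1 = boundary

  IntegerVector faceOut = clone(face);
  NumericMatrix baryOut = clone(bary);

  for (int i = 0; i < nmol; ++i) {
    double s1 = stepSD[i] * norm_rand();
    double s2 = stepSD[i] * norm_rand();
    if (frozen[i] || stepSD[i] <= 0) continue;
    int fid = face[i] - 1;
    double tv[3][3];
    faceVerts(V, F0, fid, tv);
    // current cartesian position
    double p[3] = {0, 0, 0};
    for (int k = 0; k < 3; ++k)
      for (int ax = 0; ax < 3; ++ax) p[ax] += bary(i, k) * tv[k][ax];
    // orthonormal tangent basis of the face
    double e1[3], nrm[3], e2[3];
    vsub(tv[1], tv[0], e1);
    double L1 = vnorm(e1);
    e1[0] /= L1; e1[1] /= L1; e1[2] /= L1;
    faceNormal(tv, nrm);
    vcross(nrm, e1, e2);
    double r[3] = {s1 * e1[0] + s2 * e2[0], s1 * e1[1] + s2 * e2[1],
                   s1 * e1[2] + s2 * e2[2]};
    int hops = 0;
    while (hops++ < 64) {
      double q[3] = {p[0] + r[0], p[1] + r[1], p[2] + r[2]};
      double bq[3];
      baryCoords(tv, q, bq);
      if (bq[0] >= -1e-12 && bq[1] >= -1e-12 && bq[2] >= -1e-12) {
        // inside: done
        for (int k = 0; k < 3; ++k) if (bq[k] < 0) bq[k] = 0;
        double s = bq[0] + bq[1] + bq[2];
        faceOut[i] = fid + 1;
        baryOut(i, 0) = bq[0] / s; baryOut(i, 1) = bq[1] / s;
        baryOut(i, 2) = bq[2] / s;
        break;
      }
      // find first barycentric coordinate to hit zero along p -> q
      double bp[3];
      baryCoords(tv, p, bp);
      double tmin = 2.0; int cross = -1;
      for (int k = 0; k < 3; ++k) {
        double db = bq[k] - bp[k];
        if (db < -1e-15 && bp[k] > 0) {
          double t = bp[k] / (-db);
          if (t < tmin) { tmin = t; cross = k; }
        }
      }
      if (cross < 0 || tmin > 1.0) {
        // numerical corner case: clamp into the face
        double bq2[3];
        baryCoords(tv, q, bq2);
        for (int k = 0; k < 3; ++k) if (bq2[k] < 0) bq2[k] = 0;
        double s = bq2[0] + bq2[1] + bq2[2];
        faceOut[i] = fid + 1;
        baryOut(i, 0) = bq2[0] / s; baryOut(i, 1) = bq2[1] / s;
        baryOut(i, 2) = bq2[2] / s;
        break;
      }
      // advance to the edge crossing point
      double hit[3] = {p[0] + tmin * r[0], p[1] + tmin * r[1],
                       p[2] + tmin * r[2]};
      double rem[3] = {(1 - tmin) * r[0], (1 - tmin) * r[1],
                       (1 - tmin) * r[2]};
      // crossed edge: opposite corner 'cross' -> edge slot (cross+1)%3
      int slot = (cross + 1) % 3;
      int nfid = A0(fid, slot);
      int c1 = slot, c2 = (slot + 1) % 3;  // edge corners
      double eAxis[3];
      vsub(tv[c2], tv[c1], eAxis);
      double Le = vnorm(eAxis);
      eAxis[0] /= Le; eAxis[1] /= Le; eAxis[2] /= Le;
      double n1[3];
      faceNormal(tv, n1);
      if (nfid < 0) {
        // boundary: specular reflection within the face plane about the edge
        double rePar = vdot(rem, eAxis);
        double perp[3] = {rem[0] - rePar * eAxis[0],
                          rem[1] - rePar * eAxis[1],
                          rem[2] - rePar * eAxis[2]};
        rem[0] = rePar * eAxis[0] - perp[0];
        rem[1] = rePar * eAxis[1] - perp[1];
        rem[2] = rePar * eAxis[2] - perp[2];
        p[0] = hit[0]; p[1] = hit[1]; p[2] = hit[2];
        r[0] = rem[0]; r[1] = rem[1]; r[2] = rem[2];
        continue;
      }
      // rotate remaining step into the neighbour's plane about the edge
      double tv2[3][3];
      faceVerts(V, F0, nfid, tv2);
      double n2[3];
      faceNormal(tv2, n2);
      double cosT = vdot(n1, n2);
      double n1xn2[3];
      vcross(n1, n2, n1xn2);
      double sinT = vdot(eAxis, n1xn2);
      double rePar = vdot(rem, eAxis);
      double perp[3] = {rem[0] - rePar * eAxis[0], rem[1] - rePar * eAxis[1],
                        rem[2] - rePar * eAxis[2]};
      double eXp[3];
      vcross(eAxis, perp, eXp);
      for (int ax = 0; ax < 3; ++ax)
        rem[ax] = rePar * eAxis[ax] + cosT * perp[ax] + sinT * eXp[ax];
      // re-project to neighbour plane for numerical safety
      double along = vdot(rem, n2);
      for (int ax = 0; ax < 3; ++ax) rem[ax] -= along * n2[ax];
      fid = nfid;
      faceVerts(V, F0, fid, tv);
      p[0] = hit[0]; p[1] = hit[1]; p[2] = hit[2];
      r[0] = rem[0]; r[1] = rem[1]; r[2] = rem[2];
    }
    if (hops > 64) {
      // pathological: park at the last point reached
      double bp[3];
      baryCoords(tv, p, bp);
      for (int k = 0; k < 3; ++k) if (bp[k] < 0) bp[k] = 0;
      double s = bp[0] + bp[1] + bp[2];
      faceOut[i] = fid + 1;
      baryOut(i, 0) = bp[0] / s; baryOut(i, 1) = bp[1] / s;
      baryOut(i, 2) = bp[2] / s;
    }
  }
  return List::create(_["face"] = faceOut, _["bary"] = baryOut);
}

// ---------------------------------------------------------------------------
// uniform-grid neighbour candidates (mobile vs static molecules)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_pair_candidates(NumericMatrix mobile, NumericMatrix staticPos,
                         double cutoff) {
  int nm = mobile.nrow(), ns = staticPos.nrow();
  std::vector<int> outI, outJ;
  std::vector<double> outD;
  if (nm == 0 || ns == 0 || cutoff <= 0) {
    return List::create(_["i"] = IntegerVector(0), _["j"] = IntegerVector(0),
                        _["d"] = NumericVector(0));
  }
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = staticPos(0, ax); hi[ax] = staticPos(0, ax);
    for (int j = 1; j < ns; ++j) {
      lo[ax] = std::min(lo[ax], staticPos(j, ax));
      hi[ax] = std::max(hi[ax], staticPos(j, ax));
    }
  }
  double cell = cutoff;
  int dims[3];
  for (int ax = 0; ax < 3; ++ax) {
    dims[ax] = std::max(1, (int)std::floor((hi[ax] - lo[ax]) / cell) + 1);
    dims[ax] = std::min(dims[ax], 512);
  }
  double inv[3];
  for (int ax = 0; ax < 3; ++ax)
    inv[ax] = dims[ax] / std::max(hi[ax] - lo[ax], 1e-12);
  long ncell = (long)dims[0] * dims[1] * dims[2];
  std::vector<std::vector<int> > grid(ncell);
  auto cellOf = [&](double x, double y, double z) {
    int cx = (int)((x - lo[0]) * inv[0]); cx = std::max(0, std::min(cx, dims[0] - 1));
    int cy = (int)((y - lo[1]) * inv[1]); cy = std::max(0, std::min(cy, dims[1] - 1));
    int cz = (int)((z - lo[2]) * inv[2]); cz = std::max(0, std::min(cz, dims[2] - 1));
    return (long)cx + (long)dims[0] * (cy + (long)dims[1] * cz);
  };
  for (int j = 0; j < ns; ++j)
    grid[cellOf(staticPos(j, 0), staticPos(j, 1), staticPos(j, 2))].push_back(j);
  double cut2 = cutoff * cutoff;
  for (int i = 0; i < nm; ++i) {
    double x = mobile(i, 0), y = mobile(i, 1), z = mobile(i, 2);
    int cx = (int)((x - lo[0]) * inv[0]);
    int cy = (int)((y - lo[1]) * inv[1]);
    int cz = (int)((z - lo[2]) * inv[2]);
    // cell size may exceed cutoff after dimension clamping -> widen reach
    int rx = (int)std::ceil(cutoff * inv[0]) + 1;
    int ry = (int)std::ceil(cutoff * inv[1]) + 1;
    int rz = (int)std::ceil(cutoff * inv[2]) + 1;
    for (int dx = cx - rx; dx <= cx + rx; ++dx) {
      if (dx < 0 || dx >= dims[0]) continue;
      for (int dy = cy - ry; dy <= cy + ry; ++dy) {
        if (dy < 0 || dy >= dims[1]) continue;
        for (int dz = cz - rz; dz <= cz + rz; ++dz) {
          if (dz < 0 || dz >= dims[2]) continue;
          const std::vector<int>& bucket =
            grid[(long)dx + (long)dims[0] * (dy + (long)dims[1] * dz)];
          for (size_t t = 0; t < bucket.size(); ++t) {
            int j = bucket[t];
            double ddx = x - staticPos(j, 0);
            double ddy = y - staticPos(j, 1);
            double ddz = z - staticPos(j, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            if (d2 <= cut2) {
              outI.push_back(i + 1);
              outJ.push_back(j + 1);
              outD.push_back(std::sqrt(d2));
            }
          }
        }
      }
    }
  }
  return List::create(_["i"] = wrap(outI), _["j"] = wrap(outJ),
                      _["d"] = wrap(outD));
}
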