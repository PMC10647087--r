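// Exact triangle-mesh proximity kernels.
//
// Triangle-triangle distance uses the closed-form region decomposition:
// the minimum over the 6 vertex-to-triangle and 9 edge-to-edge closest-point
// problems, plus an edge-piercing test so that interpenetrating surfaces
// report distance 0 (unsigned clamp; no penetration depth).
// Accelerated mesh-to-mesh queries run a dual bounding-volume-hierarchy
// traversal with branch-and-bound pruning on AABB distances; results are
// bit-identical to the brute-force scan because leaf tests use the same
// closed-form primitive.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 operator+(const V3& a, const V3& b) { return V3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 operator-(const V3& a, const V3& b) { return V3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 operator*(double s, const V3& a) { return V3(s * a.x, s * a.y, s * a.z); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double norm2(const V3& a) { return dot(a, a); }

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time
// Collision Detection, 5.1.5. Also reports barycentric coordinates.
static V3 closestPtTriangle(const V3& p, const V3& a, const V3& b, const V3& c,
                            double* bary = nullptr) {
  V3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) { if (bary) { bary[0] = 1; bary[1] = 0; bary[2] = 0; } return a; }
  V3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) { if (bary) { bary[0] = 0; bary[1] = 1; bary[2] = 0; } return b; }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    if (bary) { bary[0] = 1 - v; bary[1] = v; bary[2] = 0; }
    return a + v * ab;
  }
  V3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) { if (bary) { bary[0] = 0; bary[1] = 0; bary[2] = 1; } return c; }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    if (bary) { bary[0] = 1 - w; bary[1] = 0; bary[2] = w; }
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    if (bary) { bary[0] = 0; bary[1] = 1 - w; bary[2] = w; }
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  if (bary) { bary[0] = 1 - v - w; bary[1] = v; bary[2] = w; }
  return a + v * ab + w * ac;
}

// Closest points between segments p1+s*d1 (s in [0,1]) and p2+t*d2.
// Ericson 5.1.9.
static double closestSegSeg(const V3& p1, const V3& q1, const V3& p2, const V3& q2,
                            V3& c1, V3& c2) {
  const double EPS = 1e-12;
  V3 d1 = q1 - p1, d2 = q2 - p2, r = p1 - p2;
  double a = norm2(d1), e = norm2(d2), f = dot(d2, r);
  double s, t;
  if (a <= EPS && e <= EPS) { c1 = p1; c2 = p2; return std::sqrt(norm2(c1 - c2)); }
  if (a <= EPS) {
    s = 0.0; t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = dot(d1, r);
    if (e <= EPS) {
      t = 0.0; s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  c1 = p1 + s * d1;
  c2 = p2 + t * d2;
  return std::sqrt(norm2(c1 - c2));
}

// Does segment (p,q) pierce triangle (a,b,c)? Parametric plane crossing +
// barycentric containment; coplanar crossings are caught by the seg-seg and
// point-triangle terms of the caller.
static bool segPiercesTri(const V3& p, const V3& q, const V3& a, const V3& b, const V3& c) {
  V3 n = cross(b - a, c - a);
  double dp = dot(n, p - a), dq = dot(n, q - a);
  if (dp * dq > 0.0) return false;
  double denom = dp - dq;
  if (std::fabs(denom) < 1e-14) return false;  // coplanar
  double t = dp / denom;
  V3 x = p + t * (q - p);
  // barycentric containment of x
  V3 v0 = b - a, v1 = c - a, v2 = x - a;
  double d00 = dot(v0, v0), d01 = dot(v0, v1), d11 = dot(v1, v1);
  double d20 = dot(v2, v0), d21 = dot(v2, v1);
  double dd = d00 * d11 - d01 * d01;
  if (std::fabs(dd) < 1e-20) return false;
  double v = (d11 * d20 - d01 * d21) / dd, w = (d00 * d21 - d01 * d20) / dd;
  return v >= 0.0 && w >= 0.0 && (v + w) <= 1.0;
}

// Exact distance between two triangles with closest points.
static double triTriDist(const V3 A[3], const V3 B[3], V3& pa, V3& pb) {
  double best = std::numeric_limits<double>::infinity();
  // vertices of A vs triangle B, and vice versa
  for (int i = 0; i < 3; ++i) {
    V3 q = closestPtTriangle(A[i], B[0], B[1], B[2]);
    double d2 = norm2(A[i] - q);
    if (d2 < best) { best = d2; pa = A[i]; pb = q; }
    V3 r = closestPtTriangle(B[i], A[0], A[1], A[2]);
    double e2 = norm2(B[i] - r);
    if (e2 < best) { best = e2; pa = r; pb = B[i]; }
  }
  // edge-edge pairs
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      V3 c1, c2;
      double d = closestSegSeg(A[i], A[(i + 1) % 3], B[j], B[(j + 1) % 3], c1, c2);
      if (d * d < best) { best = d * d; pa = c1; pb = c2; }
    }
  }
  if (best > 0.0) {
    for (int i = 0; i < 3; ++i) {
      if (segPiercesTri(A[i], A[(i + 1) % 3], B[0], B[1], B[2]) ||
          segPiercesTri(B[i], B[(i + 1) % 3], A[0], A[1], A[2])) {
        pa = pb = A[i];
        return 0.0;
      }
    }
  }
  return std::sqrt(best);
}

// ---------------------------------------------------------------------------
// BVH over triangles

struct Tri { V3 v[3]; int id; };

struct Node {
  V3 lo, hi;
  int left, right;    // -1 for leaf
  int begin, end;     // leaf triangle range
};

struct BVH {
  std::vector<Tri> tris;   // permuted
  std::vector<Node> nodes;

  void bounds(int begin, int end, V3& lo, V3& hi) const {
    lo = V3(1e300, 1e300, 1e300); hi = V3(-1e300, -1e300, -1e300);
    for (int i = begin; i < end; ++i)
      for (int k = 0; k < 3; ++k) {
        const V3& p = tris[i].v[k];
        lo.x = std::min(lo.x, p.x); lo.y = std::min(lo.y, p.y); lo.z = std::min(lo.z, p.z);
        hi.x = std::max(hi.x, p.x); hi.y = std::max(hi.y, p.y); hi.z = std::max(hi.z, p.z);
      }
  }

  int build(int begin, int end) {
    Node nd;
    bounds(begin, end, nd.lo, nd.hi);
    nd.left = nd.right = -1;
    nd.begin = begin; nd.end = end;
    int idx = (int)nodes.size();
    nodes.push_back(nd);
    if (end - begin > 4) {
      V3 ext = nd.hi - nd.lo;
      int ax = (ext.x >= ext.y && ext.x >= ext.z) ? 0 : (ext.y >= ext.z ? 1 : 2);
      int mid = (begin + end) / 2;
      std::nth_element(tris.begin() + begin, tris.begin() + mid, tris.begin() + end,
                       [ax](const Tri& a, const Tri& b) {
                         double ca = a.v[0].x + a.v[1].x + a.v[2].x;
                         double cb = b.v[0].x + b.v[1].x + b.v[2].x;
                         if (ax == 1) { ca = a.v[0].y + a.v[1].y + a.v[2].y; cb = b.v[0].y + b.v[1].y + b.v[2].y; }
                         if (ax == 2) { ca = a.v[0].z + a.v[1].z + a.v[2].z; cb = b.v[0].z + b.v[1].z + b.v[2].z; }
                         return ca < cb;
                       });
      int l = build(begin, mid);
      int r = build(mid, end);
      nodes[idx].left = l;
      nodes[idx].right = r;
    }
    return idx;
  }
};

static BVH makeBVH(const NumericMatrix& V, const IntegerMatrix& F) {
  BVH t;
  t.tris.resize(F.nrow());
  for (int i = 0; i < F.nrow(); ++i) {
    for (int k = 0; k < 3; ++k) {
      int vi = F(i, k);
      t.tris[i].v[k] = V3(V(vi, 0), V(vi, 1), V(vi, 2));
    }
    t.tris[i].id = i;
  }
  t.nodes.reserve(2 * F.nrow() / 4 + 4);
  if (!t.tris.empty()) t.build(0, (int)t.tris.size());
  return t;
}

static inline double aabbDist2(const V3& lo1, const V3& hi1, const V3& lo2, const V3& hi2) {
  double d = 0, t;
  t = std::max(std::max(lo1.x - hi2.x, lo2.x - hi1.x), 0.0); d += t * t;
  t = std::max(std::max(lo1.y - hi2.y, lo2.y - hi1.y), 0.0); d += t * t;
  t = std::max(std::max(lo1.z - hi2.z, lo2.z - hi1.z), 0.0); d += t * t;
  return d;
}

struct PairResult {
  double dist;
  V3 pa, pb;
  int fa, fb;
};

static void dualRecurse(const BVH& A, int ia, const BVH& B, int ib, PairResult& best) {
  const Node& na = A.nodes[ia];
  const Node& nb = B.nodes[ib];
  if (aabbDist2(na.lo, na.hi, nb.lo, nb.hi) >= best.dist * best.dist) return;
  bool la = na.left < 0, lb = nb.left < 0;
  if (la && lb) {
    for (int i = na.begin; i < na.end; ++i)
      for (int j = nb.begin; j < nb.end; ++j) {
        V3 pa, pb;
        double d = triTriDist(A.tris[i].v, B.tris[j].v, pa, pb);
        if (d < best.dist) {
          best.dist = d; best.pa = pa; best.pb = pb;
          best.fa = A.tris[i].id; best.fb = B.tris[j].id;
          if (d == 0.0) return;
        }
      }
    return;
  }
  // descend the larger box first, ordering children by bound
  if (lb || (!la && (norm2(na.hi - na.lo) >= norm2(nb.hi - nb.lo)))) {
    int c1 = na.left, c2 = na.right;
    double d1 = aabbDist2(A.nodes[c1].lo, A.nodes[c1].hi, nb.lo, nb.hi);
    double d2 = aabbDist2(A.nodes[c2].lo, A.nodes[c2].hi, nb.lo, nb.hi);
    if (d2 < d1) std::swap(c1, c2);
    dualRecurse(A, c1, B, ib, best);
    dualRecurse(A, c2, B, ib, best);
  } else {
    int c1 = nb.left, c2 = nb.right;
    double d1 = aabbDist2(na.lo, na.hi, B.nodes[c1].lo, B.nodes[c1].hi);
    double d2 = aabbDist2(na.lo, na.hi, B.nodes[c2].lo, B.nodes[c2].hi);
    if (d2 < d1) std::swap(c1, c2);
    dualRecurse(A, ia, B, c1, best);
    dualRecurse(A, ia, B, c2, best);
  }
}

static List resultToList(const PairResult& r) {
  return List::create(
      _["distance"] = r.dist,
      _["point_a"] = NumericVector::create(r.pa.x, r.pa.y, r.pa.z),
      _["point_b"] = NumericVector::create(r.pb.x, r.pb.y, r.pb.z),
      _["face_a"] = r.fa + 1,
      _["face_b"] = r.fb + 1);
}

// [[Rcpp::export(name = "cpp_point_tri")]]
List cpp_point_tri(NumericVector p, NumericMatrix tri) {
  V3 pp(p[0], p[1], p[2]);
  V3 a(tri(0, 0), tri(0, 1), tri(0, 2));
  V3 b(tri(1, 0), tri(1, 1), tri(1, 2));
  V3 c(tri(2, 0), tri(2, 1), tri(2, 2));
  double bary[3];
  V3 q = closestPtTriangle(pp, a, b, c, bary);
  return List::create(
      _["distance"] = std::sqrt(norm2(pp - q)),
      _["closest"] = NumericVector::create(q.x, q.y, q.z),
      _["barycentric"] = NumericVector::create(bary[0], bary[1], bary[2]));
}

// [[Rcpp::export(name = "cpp_tri_tri")]]
List cpp_tri_tri(NumericMatrix ta, NumericMatrix tb) {
  V3 A[3], B[3];
  for (int k = 0; k < 3; ++k) {
    A[k] = V3(ta(k, 0), ta(k, 1), ta(k, 2));
    B[k] = V3(tb(k, 0), tb(k, 1), tb(k, 2));
  }
  V3 pa, pb;
  double d = triTriDist(A, B, pa, pb);
  return List::create(
      _["distance"] = d,
      _["point_a"] = NumericVector::create(pa.x, pa.y, pa.z),
      _["point_b"] = NumericVector::create(pb.x, pb.y, pb.z));
}

// F matrices are 0-based here; R wrappers convert.
// [[Rcpp::export(name = "cpp_mesh_distance_brute")]]
List cpp_mesh_distance_brute(NumericMatrix VA, IntegerMatrix FA,
                             NumericMatrix VB, IntegerMatrix FB) {
  PairResult best;
  best.dist = std::numeric_limits<double>::infinity();
  best.fa = best.fb = -1;
  std::vector<Tri> A(FA.nrow()), B(FB.nrow());
  for (int i = 0; i < FA.nrow(); ++i)
    for (int k = 0; k < 3; ++k) A[i].v[k] = V3(VA(FA(i, k), 0), VA(FA(i, k), 1), VA(FA(i, k), 2));
  for (int j = 0; j < FB.nrow(); ++j)
    for (int k = 0; k < 3; ++k) B[j].v[k] = V3(VB(FB(j, k), 0), VB(FB(j, k), 1), VB(FB(j, k), 2));
  for (int i = 0; i < (int)A.size(); ++i)
    for (int j = 0; j < (int)B.size(); ++j) {
      V3 pa, pb;
      double d = triTriDist(A[i].v, B[j].v, pa, pb);
      if (d < best.dist) {
        best.dist = d; best.pa = pa; best.pb = pb; best.fa = i; best.fb = j;
      }
    }
  return resultToList(best);
}

// [[Rcpp::export(name = "cpp_mesh_distance_bvh")]]
List cpp_mesh_distance_bvh(NumericMatrix VA, IntegerMatrix FA,
                           NumericMatrix VB, IntegerMatrix FB) {
  BVH A = makeBVH(VA, FA), B = makeBVH(VB, FB);
  PairResult best;
  best.dist = std::numeric_limits<double>::infinity();
  best.fa = best.fb = -1;
  dualRecurse(A, 0, B, 0, best);
  return resultToList(best);
}

static void pointRecurse(const BVH& T, int in, const V3& p, double& best, V3& cp, int& fid) {
  const Node& nd = T.nodes[in];
  V3 lo = nd.lo, hi = nd.hi;
  double dx = std::max(std::max(lo.x - p.x, p.x - hi.x), 0.0);
  double dy = std::max(std::max(lo.y - p.y, p.y - hi.y), 0.0);
  double dz = std::max(std::max(lo.z - p.z, p.z - hi.z), 0.0);
  if (dx * dx + dy * dy + dz * dz >= best * best) return;
  if (nd.left < 0) {
    for (int i = nd.begin; i < nd.end; ++i) {
      V3 q = closestPtTriangle(p, T.tris[i].v[0], T.tris[i].v[1], T.tris[i].v[2]);
      double d = std::sqrt(norm2(p - q));
      if (d < best) { best = d; cp = q; fid = T.tris[i].id; }
    }
    return;
  }
  pointRecurse(T, nd.left, p, best, cp, fid);
  pointRecurse(T, nd.right, p, best, cp, fid);
}

// Distance from each row of P to the surface (V, F).
// [[Rcpp::export(name = "cpp_point_mesh")]]
List cpp_point_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  BVH T = makeBVH(V, F);
  int n = P.nrow();
  NumericVector d(n);
  NumericMatrix C(n, 3);
  IntegerVector fid(n);
  for (int i = 0; i < n; ++i) {
    V3 p(P(i, 0), P(i, 1), P(i, 2));
    double best = std::numeric_limits<double>::infinity();
    V3 cp; int f = -1;
    pointRecurse(T, 0, p, best, cp, f);
    d[i] = best;
    C(i, 0) = cp.x; C(i, 1) = cp.y; C(i, 2) = cp.z;
    fid[i] = f + 1;
  }
  return List::create(_["distance"] = d, _["closest"] = C, _["face"] = fid);
}

// Scaption sweep: the humerus rotates by +theta about (axis, center) while
// the scapula stays fixed. Computed in the humerus-fixed equivalent frame
// (acromion rotated by -theta) so the humerus BVH is built once; closest
// points are mapped back to the world pose.
// [[Rcpp::export(name = "cpp_sweep")]]
List cpp_sweep(NumericMatrix VA, IntegerMatrix FA,
               NumericMatrix VH, IntegerMatrix FH,
               NumericVector center, NumericVector axis,
               NumericVector angles_rad) {
  BVH H = makeBVH(VH, FH);
  int nA = VA.nrow(), nth = angles_rad.size();
  V3 c(center[0], center[1], center[2]);
  V3 u(axis[0], axis[1], axis[2]);
  double un = std::sqrt(norm2(u));
  u = (1.0 / un) * u;
  NumericVector dist(nth);
  NumericMatrix PA(nth, 3), PH(nth, 3);
  NumericMatrix VAr(nA, 3);
  int prevFa = -1, prevFb = -1;
  for (int t = 0; t < nth; ++t) {
    double th = -angles_rad[t];  // rotate acromion by -theta
    double ct = std::cos(th), st = std::sin(th), vt = 1.0 - ct;
    double R[3][3] = {
      {ct + u.x * u.x * vt, u.x * u.y * vt - u.z * st, u.x * u.z * vt + u.y * st},
      {u.y * u.x * vt + u.z * st, ct + u.y * u.y * vt, u.y * u.z * vt - u.x * st},
      {u.z * u.x * vt - u.y * st, u.z * u.y * vt + u.x * st, ct + u.z * u.z * vt}};
    for (int i = 0; i < nA; ++i) {
      double px = VA(i, 0) - c.x, py = VA(i, 1) - c.y, pz = VA(i, 2) - c.z;
      VAr(i, 0) = R[0][0] * px + R[0][1] * py + R[0][2] * pz + c.x;
      VAr(i, 1) = R[1][0] * px + R[1][1] * py + R[1][2] * pz + c.y;
      VAr(i, 2) = R[2][0] * px + R[2][1] * py + R[2][2] * pz + c.z;
    }
    BVH A = makeBVH(VAr, FA);
    PairResult best;
    best.dist = std::numeric_limits<double>::infinity();
    best.fa = best.fb = -1;
    if (t > 0 && prevFa >= 0) {
      // warm start: the previous step's closest pair is a tight upper bound
      V3 TA[3], TH[3];
      for (int k = 0; k < 3; ++k) {
        int va = FA(prevFa, k), vh = FH(prevFb, k);
        TA[k] = V3(VAr(va, 0), VAr(va, 1), VAr(va, 2));
        TH[k] = V3(VH(vh, 0), VH(vh, 1), VH(vh, 2));
      }
      V3 pa, pb;
      best.dist = triTriDist(TA, TH, pa, pb);
      best.pa = pa; best.pb = pb; best.fa = prevFa; best.fb = prevFb;
    }
    dualRecurse(A, 0, H, 0, best);
    prevFa = best.fa; prevFb = best.fb;
    dist[t] = best.dist;
    // map both closest points back to the world pose (forward rotation)
    double F[3][3] = {
      {R[0][0], R[1][0], R[2][0]},
      {R[0][1], R[1][1], R[2][1]},
      {R[0][2], R[1][2], R[2][2]}};  // transpose = inverse
    V3 pts[2] = {best.pa, best.pb};
    for (int k = 0; k < 2; ++k) {
      double px = pts[k].x - c.x, py = pts[k].y - c.y, pz = pts[k].z - c.z;
      V3 w(F[0][0] * px + F[0][1] * py + F[0][2] * pz + c.x,
           F[1][0] * px + F[1][1] * py + F[1][2] * pz + c.y,
           F[2][0] * px + F[2][1] * py + F[2][2] * pz + c.z);
      if (k == 0) { PA(t, 0) = w.x; PA(t, 1) = w.y; PA(t, 2) = w.z; }
      else { PH(t, 0) = w.x; PH(t, 1) = w.y; PH(t, 2) = w.z; }
    }
  }
  return List::create(_["distance"] = dist, _["point_scapula"] = PA,
                      _["point_humerus"] = PH);
}
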