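// Triangulated surfaces over grain point clouds:
//  * quickhull3: 3D convex hull (the alpha-shape limit for large alpha)
//  * alpha_boundary: boundary triangles of the alpha shape of a densely
//    sampled voxel shell, via the empty-circumball (alpha-exposed) test.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct V3 {
  double x, y, z;
};
static inline V3 sub(const V3 &a, const V3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline V3 cross(const V3 &a, const V3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double dot(const V3 &a, const V3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const V3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;
  V3 n;      // unit outward normal
  double d;  // plane offset: dot(n, p) - d > 0 means outside
  bool alive;
  std::vector<int> outside;
};

static Face make_face(int a, int b, int c, const std::vector<V3> &P,
                      const V3 &inner) {
  Face f;
  f.a = a; f.b = b; f.c = c;
  V3 n = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double ln = norm(n);
  if (ln > 0) { n.x /= ln; n.y /= ln; n.z /= ln; }
  double d = dot(n, P[a]);
  if (dot(n, inner) - d > 0) { // orient outward
    std::swap(f.b, f.c);
    n.x = -n.x; n.y = -n.y; n.z = -n.z;
    d = -d;
  }
  f.n = n; f.d = d; f.alive = true;
  return f;
}

// [[Rcpp::export(name = ".quickhull3")]]
List quickhull3(const NumericMatrix &pts) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points for a 3D hull");
  std::vector<V3> P(n);
  double scale = 0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  const double tol = 1e-9 * std::max(scale, 1.0);

  // initial simplex: farthest pair among axis extremes, then line, then plane
  int ex[6] = {0, 0, 0, 0, 0, 0};
  for (int i = 1; i < n; ++i) {
    if (P[i].x < P[ex[0]].x) ex[0] = i;
    if (P[i].x > P[ex[1]].x) ex[1] = i;
    if (P[i].y < P[ex[2]].y) ex[2] = i;
    if (P[i].y > P[ex[3]].y) ex[3] = i;
    if (P[i].z < P[ex[4]].z) ex[4] = i;
    if (P[i].z > P[ex[5]].z) ex[5] = i;
  }
  int i0 = 0, i1 = 1;
  double best = -1;
  for (int a = 0; a < 6; ++a)
    for (int b = a + 1; b < 6; ++b) {
      double d = norm(sub(P[ex[a]], P[ex[b]]));
      if (d > best) { best = d; i0 = ex[a]; i1 = ex[b]; }
    }
  if (best < tol) stop("degenerate grain geometry");
  V3 dir = sub(P[i1], P[i0]);
  int i2 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(dir, sub(P[i], P[i0]))) / norm(dir);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate grain geometry");
  V3 nrm = cross(dir, sub(P[i2], P[i0]));
  double ln = norm(nrm);
  nrm.x /= ln; nrm.y /= ln; nrm.z /= ln;
  int i3 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate grain geometry");

  V3 inner = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4,
              (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4,
              (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4};

  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, inner));
  faces.push_back(make_face(i0, i1, i3, P, inner));
  faces.push_back(make_face(i0, i2, i3, P, inner));
  faces.push_back(make_face(i1, i2, i3, P, inner));

  std::vector<int> cand(n);
  for (int i = 0; i < n; ++i) cand[i] = i;
  for (int i : cand)
    for (auto &f : faces)
      if (dot(f.n, P[i]) - f.d > tol) { f.outside.push_back(i); break; }

  for (;;) {
    int fi = -1;
    for (size_t k = 0; k < faces.size(); ++k)
      if (faces[k].alive && !faces[k].outside.empty()) { fi = (int)k; break; }
    if (fi < 0) break;
    Face &f = faces[fi];
    int far = f.outside[0];
    double fd = dot(f.n, P[far]) - f.d;
    for (int i : f.outside) {
      double d = dot(f.n, P[i]) - f.d;
      if (d > fd) { fd = d; far = i; }
    }
    // visible faces (full scan), horizon = directed edges not shared inside
    std::vector<int> vis;
    std::unordered_map<long long, int> edges; // directed edge -> count
    std::vector<int> orphan;
    for (size_t k = 0; k < faces.size(); ++k) {
      Face &g = faces[k];
      if (!g.alive) continue;
      if (dot(g.n, P[far]) - g.d > tol) {
        vis.push_back((int)k);
        int e[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
        for (auto &ed : e)
          edges[((long long)ed[0] << 32) | (unsigned int)ed[1]] = 1;
        orphan.insert(orphan.end(), g.outside.begin(), g.outside.end());
      }
    }
    std::vector<std::pair<int, int>> horizon;
    for (int k : vis) {
      Face &g = faces[k];
      int e[3][2] = {{g.a, g.b}, {g.b, g.c}, {g.c, g.a}};
      for (auto &ed : e) {
        long long rev = ((long long)ed[1] << 32) | (unsigned int)ed[0];
        if (edges.find(rev) == edges.end())
          horizon.push_back({ed[0], ed[1]});
      }
      g.alive = false;
      g.outside.clear();
    }
    size_t first_new = faces.size();
    for (auto &h : horizon)
      faces.push_back(make_face(h.first, h.second, far, P, inner));
    for (int i : orphan) {
      if (i == far) continue;
      for (size_t k = first_new; k < faces.size(); ++k)
        if (dot(faces[k].n, P[i]) - faces[k].d > tol) {
          faces[k].outside.push_back(i);
          break;
        }
    }
  }

  double area = 0;
  std::vector<int> ta, tb, tc;
  for (auto &f : faces) {
    if (!f.alive) continue;
    area += 0.5 * norm(cross(sub(P[f.b], P[f.a]), sub(P[f.c], P[f.a])));
    ta.push_back(f.a + 1); tb.push_back(f.b + 1); tc.push_back(f.c + 1);
  }
  IntegerMatrix tri(ta.size(), 3);
  for (size_t k = 0; k < ta.size(); ++k) {
    tri(k, 0) = ta[k]; tri(k, 1) = tb[k]; tri(k, 2) = tc[k];
  }
  return List::create(_["triangles"] = tri, _["area"] = area);
}

// --- alpha shape -----------------------------------------------------------
// A triangle with circumradius <= alpha is alpha-exposed (a boundary face of
// the alpha shape) iff one of the two balls of radius alpha through its
// vertices contains no other point (Edelsbrunner's criterion). Candidate
// triangles are restricted to edges <= edge_cap; on a unit-spaced voxel
// shell a ball of radius alpha resting across lattice steps of height ~1
// touches summit points up to the chord 2*sqrt(2*alpha) apart, so the
// caller passes that as the cap. The alpha shape of a one-voxel-thick shell
// is a thin slab: where the alpha ball fits on both sides the boundary has
// an outer and an inner face and the summed area approaches twice the
// one-sided geometric surface; where the cavity cannot host the ball (small
// convex grains) the mesh is single-sided. A tiny deterministic jitter
// breaks grid cosphericities. Blocking points are searched among the local
// candidates first and the test exits on the first hit, which keeps the
// quadratic candidate enumeration affordable.
static inline double frac_hash(int i, int d) {
  double s = std::sin(i * 12.9898 + d * 78.233) * 43758.5453;
  return s - std::floor(s);
}

// [[Rcpp::export(name = ".alpha_boundary")]]
List alpha_boundary(const NumericMatrix &pts, double alpha,
                    double edge_cap) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<V3> P(n);
  for (int i = 0; i < n; ++i)
    P[i] = {pts(i, 0) + 1e-4 * (frac_hash(i, 0) - 0.5),
            pts(i, 1) + 1e-4 * (frac_hash(i, 1) - 0.5),
            pts(i, 2) + 1e-4 * (frac_hash(i, 2) - 0.5)};

  // two grids: fine (edge_cap) for candidate edges, coarse for ball queries
  auto build_grid = [&](double cell,
                        std::unordered_map<long long, std::vector<int>> &g) {
    for (int i = 0; i < n; ++i) {
      long long k =
          ((long long)((int)std::floor(P[i].x / cell) + 1048576) << 42) |
          ((long long)((int)std::floor(P[i].y / cell) + 1048576) << 21) |
          (long long)((int)std::floor(P[i].z / cell) + 1048576);
      g[k].push_back(i);
    }
  };
  std::unordered_map<long long, std::vector<int>> gfine, gball;
  const double ball_cell = std::max(alpha / 2.0, 1.0);
  build_grid(edge_cap, gfine);
  build_grid(ball_cell, gball);

  auto near = [&](const V3 &q, double r, double cell,
                  std::unordered_map<long long, std::vector<int>> &g,
                  std::vector<int> &out) {
    out.clear();
    const double r2 = r * r;
    int x0 = (int)std::floor((q.x - r) / cell), x1 = (int)std::floor((q.x + r) / cell);
    int y0 = (int)std::floor((q.y - r) / cell), y1 = (int)std::floor((q.y + r) / cell);
    int z0 = (int)std::floor((q.z - r) / cell), z1 = (int)std::floor((q.z + r) / cell);
    for (int a = x0; a <= x1; ++a)
      for (int b = y0; b <= y1; ++b)
        for (int c = z0; c <= z1; ++c) {
          auto it = g.find((((long long)(a + 1048576)) << 42) |
                           (((long long)(b + 1048576)) << 21) |
                           (long long)(c + 1048576));
          if (it == g.end()) continue;
          for (int j : it->second) {
            V3 dd = sub(P[j], q);
            if (dot(dd, dd) <= r2) out.push_back(j);
          }
        }
  };

  const double tol = 1e-7;
  const double cap2 = edge_cap * edge_cap;
  std::vector<int> nbr;
  std::vector<int> ta, tb, tc;
  double area = 0;

  // true iff any point other than i/j/k lies strictly inside the ball;
  // checks the local candidate list first, then the coarse grid, exiting
  // on the first blocker found
  auto blocked = [&](const V3 &ctr, int i, int j, int k,
                     const std::vector<int> &loc) {
    const double r2 = (alpha - tol) * (alpha - tol);
    for (int q : loc) {
      if (q == i || q == j || q == k) continue;
      V3 dd = sub(P[q], ctr);
      if (dot(dd, dd) < r2) return true;
    }
    const double r = alpha - tol;
    int x0 = (int)std::floor((ctr.x - r) / ball_cell),
        x1 = (int)std::floor((ctr.x + r) / ball_cell);
    int y0 = (int)std::floor((ctr.y - r) / ball_cell),
        y1 = (int)std::floor((ctr.y + r) / ball_cell);
    int z0 = (int)std::floor((ctr.z - r) / ball_cell),
        z1 = (int)std::floor((ctr.z + r) / ball_cell);
    for (int a = x0; a <= x1; ++a)
      for (int b = y0; b <= y1; ++b)
        for (int c = z0; c <= z1; ++c) {
          auto it = gball.find((((long long)(a + 1048576)) << 42) |
                               (((long long)(b + 1048576)) << 21) |
                               (long long)(c + 1048576));
          if (it == gball.end()) continue;
          for (int q : it->second) {
            if (q == i || q == j || q == k) continue;
            V3 dd = sub(P[q], ctr);
            if (dot(dd, dd) < r2) return true;
          }
        }
    return false;
  };

  for (int i = 0; i < n; ++i) {
    near(P[i], edge_cap, edge_cap, gfine, nbr);
    std::sort(nbr.begin(), nbr.end());
    const std::vector<int> loc = nbr; // local blocker shortlist
    std::vector<int> cand;
    for (int j : nbr)
      if (j > i) cand.push_back(j);
    for (size_t u = 0; u < cand.size(); ++u)
      for (size_t v = u + 1; v < cand.size(); ++v) {
        const int j = cand[u], k = cand[v];
        V3 djk = sub(P[k], P[j]);
        if (dot(djk, djk) > cap2) continue;
        V3 ab = sub(P[j], P[i]), ac = sub(P[k], P[i]);
        V3 cr = cross(ab, ac);
        double cr2 = dot(cr, cr);
        if (cr2 < 1e-12) continue; // collinear
        double tri_area = 0.5 * std::sqrt(cr2);
        // circumradius = |ab||bc||ca| / (4 area)
        double la = norm(ab), lb = norm(djk), lc = norm(ac);
        double R = la * lb * lc / (4.0 * tri_area);
        if (R > alpha) continue;
        // circumcenter: A + (|AC|^2 (ABxAC)xAB + |AB|^2 ACx(ABxAC)) / (2|ABxAC|^2)
        double ab2 = dot(ab, ab), ac2 = dot(ac, ac);
        V3 t1 = cross(cr, ab), t2 = cross(ac, cr);
        V3 cc = {P[i].x + (ac2 * t1.x + ab2 * t2.x) / (2 * cr2),
              P[i].y + (ac2 * t1.y + ab2 * t2.y) / (2 * cr2),
              P[i].z + (ac2 * t1.z + ab2 * t2.z) / (2 * cr2)};
        double h2 = alpha * alpha - R * R;
        if (h2 < 0) continue;
        double h = std::sqrt(h2);
        V3 un = {cr.x / std::sqrt(cr2), cr.y / std::sqrt(cr2),
                 cr.z / std::sqrt(cr2)};
        bool exposed = false;
        for (int side = 0; side < 2 && !exposed; ++side) {
          V3 ctr = {cc.x + (side ? h : -h) * un.x,
                    cc.y + (side ? h : -h) * un.y,
                    cc.z + (side ? h : -h) * un.z};
          if (!blocked(ctr, i, j, k, loc)) exposed = true;
        }
        if (exposed) {
          area += tri_area;
          ta.push_back(i + 1); tb.push_back(j + 1); tc.push_back(k + 1);
        }
      }
  }
  IntegerMatrix tri(ta.size(), 3);
  for (size_t q = 0; q < ta.size(); ++q) {
    tri(q, 0) = ta[q]; tri(q, 1) = tb[q]; tri(q, 2) = tc[q];
  }
  return List::create(_["triangles"] = tri, _["area"] = area);
}
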