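// Incremental (Bowyer-Watson) 3D Delaunay tetrahedralization.
//
// The convex hull is closed with "ghost" tetrahedra sharing one virtual
// vertex at infinity, so every face always has a neighbor and point
// insertion outside the current hull needs no special casing.  Predicates
// are evaluated in long double; callers are expected to supply points in
// general position (the R wrapper applies a deterministic sub-precision
// jitter).

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <random>
#include <cstdint>
#include <cmath>

using namespace Rcpp;
typedef long double ld;

namespace {

struct Tet {
  int v[4];   // point indices; INF vertex == npts
  int nb[4];  // neighbor opposite vertex i
  bool alive;
  int stamp;  // cavity BFS mark
};

struct Mesh {
  int npts;                 // INF vertex id == npts
  const double *x, *y, *z;  // column pointers
  std::vector<Tet> tets;
  std::vector<int> freelist;
  int stamp_ctr = 0;

  bool is_inf(int v) const { return v == npts; }

  inline void coord(int v, ld *out) const {
    out[0] = x[v]; out[1] = y[v]; out[2] = z[v];
  }

  ld orient3d(int a, int b, int c, int d) const {
    ld pa[3], pb[3], pc[3], pd[3];
    coord(a, pa); coord(b, pb); coord(c, pc); coord(d, pd);
    ld adx = pa[0]-pd[0], ady = pa[1]-pd[1], adz = pa[2]-pd[2];
    ld bdx = pb[0]-pd[0], bdy = pb[1]-pd[1], bdz = pb[2]-pd[2];
    ld cdx = pc[0]-pd[0], cdy = pc[1]-pd[1], cdz = pc[2]-pd[2];
    return adx*(bdy*cdz - bdz*cdy)
         - ady*(bdx*cdz - bdz*cdx)
         + adz*(bdx*cdy - bdy*cdx);
  }

  // > 0 iff p strictly inside circumsphere of positively oriented (a,b,c,d)
  ld insphere(int a, int b, int c, int d, int p) const {
    int idx[4] = {a, b, c, d};
    ld m[4][4];
    ld pe[3]; coord(p, pe);
    for (int k = 0; k < 4; ++k) {
      ld pk[3]; coord(idx[k], pk);
      ld dx = pk[0]-pe[0], dy = pk[1]-pe[1], dz = pk[2]-pe[2];
      m[k][0] = dx; m[k][1] = dy; m[k][2] = dz;
      m[k][3] = dx*dx + dy*dy + dz*dz;
    }
    // 4x4 determinant by cofactor expansion on last column
    ld det = 0;
    for (int k = 0; k < 4; ++k) {
      int r[3], t = 0;
      for (int j = 0; j < 4; ++j) if (j != k) r[t++] = j;
      ld minor =
          m[r[0]][0]*(m[r[1]][1]*m[r[2]][2] - m[r[1]][2]*m[r[2]][1])
        - m[r[0]][1]*(m[r[1]][0]*m[r[2]][2] - m[r[1]][2]*m[r[2]][0])
        + m[r[0]][2]*(m[r[1]][0]*m[r[2]][1] - m[r[1]][1]*m[r[2]][0]);
      det += ((k % 2) ? 1.0L : -1.0L) * m[k][3] * minor;  // sign (-1)^(k+3+1)... fixed below
    }
    // expansion along column 3 (0-based): det = sum_k (-1)^(k+3) m[k][3] M_k
    // (-1)^(k+3): k=0 -> -1, k=1 -> +1, k=2 -> -1, k=3 -> +1  == ((k%2)?+1:-1)
    return det;
  }

  // is point p inside the "circumsphere" of tet t (ghost-aware)
  bool in_conflict(int t, int p) {
    const Tet &T = tets[t];
    int infpos = -1;
    for (int i = 0; i < 4; ++i) if (is_inf(T.v[i])) { infpos = i; break; }
    if (infpos < 0) {
      return insphere(T.v[0], T.v[1], T.v[2], T.v[3], p) > 0;
    }
    // ghost: conflict iff p strictly outside the hull face (on the opposite
    // side from the interior reference vertex of the inner neighbor tet)
    int r[3], t2 = 0;
    for (int i = 0; i < 4; ++i) if (i != infpos) r[t2++] = T.v[i];
    int inner = T.nb[infpos];  // real tet sharing the hull face
    int q = -1;
    const Tet &N = tets[inner];
    for (int i = 0; i < 4; ++i) {
      int w = N.v[i];
      if (w != r[0] && w != r[1] && w != r[2]) { q = w; break; }
    }
    ld sp = orient3d(r[0], r[1], r[2], p);
    ld sq = orient3d(r[0], r[1], r[2], q);
    return sp * sq < 0;
  }

  int new_tet() {
    int id;
    if (!freelist.empty()) { id = freelist.back(); freelist.pop_back(); }
    else { tets.push_back(Tet()); id = (int)tets.size() - 1; }
    tets[id].alive = true;
    tets[id].stamp = -1;
    for (int i = 0; i < 4; ++i) tets[id].nb[i] = -1;
    return id;
  }

  // walk toward p; return any tet in conflict with p
  int locate(int start, int p) {
    int t = start, steps = 0, maxsteps = (int)tets.size() + 64;
    while (steps++ < maxsteps) {
      Tet &T = tets[t];
      bool ghost = false;
      for (int i = 0; i < 4; ++i) if (is_inf(T.v[i])) ghost = true;
      if (ghost) {
        if (in_conflict(t, p)) return t;
        // walk along the hull: move across a side face toward p
        // fall through to scan fallback if stuck
        int moved = -1;
        for (int i = 0; i < 4 && moved < 0; ++i) {
          int nbt = T.nb[i];
          if (nbt >= 0 && in_conflict(nbt, p)) moved = nbt;
        }
        if (moved >= 0) return moved;
        break;  // fallback scan
      }
      // real tet: standard orientation walk
      int next = -1;
      for (int i = 0; i < 4; ++i) {
        int f[3], t2 = 0;
        for (int j = 0; j < 4; ++j) if (j != i) f[t2++] = T.v[j];
        ld sref = orient3d(f[0], f[1], f[2], T.v[i]);
        ld sp   = orient3d(f[0], f[1], f[2], p);
        if (sref * sp < 0) { next = T.nb[i]; break; }
      }
      if (next < 0) return t;  // contained in t
      t = next;
    }
    // robust fallback: linear scan
    for (int i = 0; i < (int)tets.size(); ++i)
      if (tets[i].alive && in_conflict(i, p)) return i;
    stop("delaunay: point location failed");
    return -1;  // unreachable
  }

  void insert(int p, int &hint) {
    int seed = locate(hint, p);
    // cavity BFS
    ++stamp_ctr;
    std::vector<int> bad, stack;
    stack.push_back(seed);
    tets[seed].stamp = stamp_ctr;
    while (!stack.empty()) {
      int t = stack.back(); stack.pop_back();
      bad.push_back(t);
      for (int i = 0; i < 4; ++i) {
        int nbt = tets[t].nb[i];
        if (nbt >= 0 && tets[nbt].alive && tets[nbt].stamp != stamp_ctr &&
            in_conflict(nbt, p)) {
          tets[nbt].stamp = stamp_ctr;
          stack.push_back(nbt);
        }
      }
    }
    // collect boundary faces (bad tet face whose neighbor is good)
    struct BFace { int f[3]; int good; };
    std::vector<BFace> bfaces;
    for (int t : bad) {
      for (int i = 0; i < 4; ++i) {
        int nbt = tets[t].nb[i];
        if (nbt >= 0 && tets[nbt].stamp != stamp_ctr) {
          BFace bf;
          int t2 = 0;
          for (int j = 0; j < 4; ++j) if (j != i) bf.f[t2++] = tets[t].v[j];
          bf.good = nbt;
          bfaces.push_back(bf);
        }
      }
    }
    // retire bad tets
    for (int t : bad) { tets[t].alive = false; freelist.push_back(t); }
    // build new tets: (face, p); wire adjacency through shared edges
    std::unordered_map<long long, std::pair<int,int> > edgemap;
    edgemap.reserve(bfaces.size() * 3);
    long long NV = (long long)npts + 2;
    int lastnew = -1;
    for (const BFace &bf : bfaces) {
      int id = new_tet();
      Tet &T = tets[id];
      T.v[0] = bf.f[0]; T.v[1] = bf.f[1]; T.v[2] = bf.f[2]; T.v[3] = p;
      bool ghost = is_inf(T.v[0]) || is_inf(T.v[1]) || is_inf(T.v[2]);
      if (!ghost && orient3d(T.v[0], T.v[1], T.v[2], T.v[3]) < 0)
        std::swap(T.v[0], T.v[1]);
      // boundary face is opposite p == index of p in v
      int ppos = 3;
      for (int i = 0; i < 4; ++i) if (T.v[i] == p) ppos = i;
      T.nb[ppos] = bf.good;
      // fix back pointer of the good tet (it pointed at a retired bad tet);
      // the face it shares with the new tet is bf.f, i.e. it is opposite
      // the one vertex of the good tet not in bf.f
      Tet &G = tets[bf.good];
      for (int i = 0; i < 4; ++i) {
        int w = G.v[i];
        if (w != bf.f[0] && w != bf.f[1] && w != bf.f[2]) { G.nb[i] = id; break; }
      }
      // internal faces: opposite each face vertex; keyed by remaining edge
      for (int i = 0; i < 4; ++i) {
        if (i == ppos) continue;
        int e[2], t2 = 0;
        for (int j = 0; j < 4; ++j)
          if (j != i && j != ppos) e[t2++] = T.v[j];
        long long a = e[0], b = e[1];
        if (a > b) std::swap(a, b);
        long long key = a * NV + b;
        auto it = edgemap.find(key);
        if (it == edgemap.end()) {
          edgemap[key] = std::make_pair(id, i);
        } else {
          T.nb[i] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          edgemap.erase(it);
        }
      }
      lastnew = id;
    }
    if (lastnew < 0) stop("delaunay: empty cavity boundary");
    hint = lastnew;
  }
};

}  // namespace

// [[Rcpp::export(name = ".delaunay3d_cpp")]]
IntegerMatrix delaunay3d_cpp(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");
  std::vector<double> xs(n), ys(n), zs(n);
  for (int i = 0; i < n; ++i) {
    xs[i] = pts(i, 0); ys[i] = pts(i, 1); zs[i] = pts(i, 2);
  }
  Mesh M;
  M.npts = n;
  M.x = xs.data(); M.y = ys.data(); M.z = zs.data();

  // deterministic insertion order (independent of R's RNG)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::mt19937 rng(0x5eedu ^ (uint32_t)n);
  for (int i = n - 1; i > 0; --i) {
    std::uniform_int_distribution<int> d(0, i);
    std::swap(order[i], order[d(rng)]);
  }

  // initial tet: first four affinely independent points of the order
  int i0 = order[0], i1 = -1, i2 = -1, i3 = -1;
  {
    size_t k = 1;
    for (; k < order.size() && i1 < 0; ++k) {
      int c = order[k];
      ld dx = xs[c]-xs[i0], dy = ys[c]-ys[i0], dz = zs[c]-zs[i0];
      if (dx*dx + dy*dy + dz*dz > 0) i1 = c;
    }
    for (; k < order.size() && i2 < 0; ++k) {
      int c = order[k];
      ld ux = xs[i1]-xs[i0], uy = ys[i1]-ys[i0], uz = zs[i1]-zs[i0];
      ld vx = xs[c]-xs[i0],  vy = ys[c]-ys[i0],  vz = zs[c]-zs[i0];
      ld cx = uy*vz - uz*vy, cy = uz*vx - ux*vz, cz = ux*vy - uy*vx;
      if (cx*cx + cy*cy + cz*cz > 0) i2 = c;
    }
    for (; k < order.size() && i3 < 0; ++k) {
      int c = order[k];
      if (M.orient3d(i0, i1, i2, c) != 0) i3 = c;
    }
  }
  if (i3 < 0) stop("points do not span 3 dimensions");
  if (M.orient3d(i0, i1, i2, i3) < 0) std::swap(i0, i1);

  int T0 = M.new_tet();
  M.tets[T0].v[0] = i0; M.tets[T0].v[1] = i1;
  M.tets[T0].v[2] = i2; M.tets[T0].v[3] = i3;
  int gid[4];
  for (int i = 0; i < 4; ++i) {
    gid[i] = M.new_tet();
    Tet &G = M.tets[gid[i]];
    int t2 = 0;
    for (int j = 0; j < 4; ++j)
      if (j != i) G.v[t2++] = M.tets[T0].v[j];
    G.v[3] = n;  // INF
    G.nb[3] = T0;
    M.tets[T0].nb[i] = gid[i];
  }
  // ghost-ghost adjacency: face of G_i opposite vertex w (w != INF) is
  // shared with the ghost missing w
  for (int i = 0; i < 4; ++i) {
    Tet &G = M.tets[gid[i]];
    for (int a = 0; a < 3; ++a) {
      int w = G.v[a];
      int miss = -1;
      for (int j = 0; j < 4; ++j) if (M.tets[T0].v[j] == w) miss = j;
      G.nb[a] = gid[miss];
    }
  }

  int hint = T0;
  std::vector<bool> used(n, false);
  used[i0] = used[i1] = used[i2] = used[i3] = true;
  for (int k = 0; k < n; ++k) {
    int p = order[k];
    if (used[p]) continue;
    M.insert(p, hint);
    if (k % 512 == 0) Rcpp::checkUserInterrupt();
  }

  // emit real tets, 1-based
  int m = 0;
  for (const Tet &T : M.tets)
    if (T.alive && !(M.is_inf(T.v[0]) || M.is_inf(T.v[1]) ||
                     M.is_inf(T.v[2]) || M.is_inf(T.v[3]))) ++m;
  IntegerMatrix out(m, 4);
  int r = 0;
  for (const Tet &T : M.tets) {
    if (!T.alive) continue;
    if (M.is_inf(T.v[0]) || M.is_inf(T.v[1]) ||
        M.is_inf(T.v[2]) || M.is_inf(T.v[3])) continue;
    for (int j = 0; j < 4; ++j) out(r, j) = T.v[j] + 1;
    ++r;
  }
  return out;
}
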