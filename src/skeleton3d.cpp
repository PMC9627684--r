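// 3D curve-skeleton core: topology-preserving thinning, distance transforms,
// and 26-neighbourhood counting on logical/integer voxel grids.
//
// Grids come in as R arrays with dim = c(nx, ny, nz); the first index is the
// fastest-varying (column-major), so linear index = x + nx*(y + ny*z), 0-based.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  long n() const { return (long)nx * ny * nz; }
  inline long idx(int x, int y, int z) const { return x + (long)nx * (y + (long)ny * z); }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// offsets of the full 26-neighbourhood
static const int OFF26[26][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1, 0},{0,-1, 0},{1,-1, 0},{-1,0, 0},         {1,0, 0},{-1,1, 0},{0,1, 0},{1,1, 0},
  {-1,-1, 1},{0,-1, 1},{1,-1, 1},{-1,0, 1},{0,0, 1},{1,0, 1},{-1,1, 1},{0,1, 1},{1,1, 1}
};

inline int nb26_count(const std::vector<unsigned char>& fg, const Grid& g, int x, int y, int z) {
  int c = 0;
  for (int k = 0; k < 26; ++k) {
    int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
    if (g.inside(xx, yy, zz) && fg[g.idx(xx, yy, zz)]) ++c;
  }
  return c;
}

// Local 3x3x3 neighbourhood snapshot; centre at (1,1,1). Out-of-grid = background.
inline void snapshot(const std::vector<unsigned char>& fg, const Grid& g,
                     int x, int y, int z, unsigned char nb[27]) {
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        nb[k] = (g.inside(xx, yy, zz) && fg[g.idx(xx, yy, zz)]) ? 1 : 0;
      }
}

inline int lidx(int dx, int dy, int dz) { // local 3x3x3 index, offsets in {-1,0,1}
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// Number of 26-connected components of foreground within N26* (centre excluded).
int cc26_foreground(const unsigned char nb[27]) {
  int label[27]; for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || label[s] >= 0) continue;
    // BFS over the 26 cells (centre excluded)
    std::vector<int> st; st.push_back(s); label[s] = ncomp;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
            int t = xx + 3 * (yy + 3 * zz);
            if (t == 13 || !nb[t] || label[t] >= 0) continue;
            label[t] = ncomp; st.push_back(t);
          }
    }
    ++ncomp;
  }
  return ncomp;
}

// Number of 6-connected components of background within N18 that touch a
// 6-neighbour of the centre (Bertrand-Malandain background condition).
int cc6_background(const unsigned char nb[27]) {
  // N18 membership: |dx|+|dy|+|dz| <= 2 and not the centre
  auto in18 = [](int s) {
    int dx = s % 3 - 1, dy = (s / 3) % 3 - 1, dz = s / 9 - 1;
    int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
    return m >= 1 && m <= 2;
  };
  auto isface = [](int s) {
    int dx = s % 3 - 1, dy = (s / 3) % 3 - 1, dz = s / 9 - 1;
    return std::abs(dx) + std::abs(dy) + std::abs(dz) == 1;
  };
  int label[27]; for (int i = 0; i < 27; ++i) label[i] = -1;
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18(s) || nb[s] || label[s] >= 0) continue;
    bool touches = false;
    std::vector<int> st; st.push_back(s); label[s] = ncomp;
    while (!st.empty()) {
      int c = st.back(); st.pop_back();
      if (isface(c)) touches = true;
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int F6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = cx + F6[k][0], yy = cy + F6[k][1], zz = cz + F6[k][2];
        if (xx < 0 || xx > 2 || yy < 0 || yy > 2 || zz < 0 || zz > 2) continue;
        int t = xx + 3 * (yy + 3 * zz);
        if (!in18(t) || nb[t] || label[t] >= 0) continue;
        label[t] = ncomp; st.push_back(t);
      }
    }
    if (touches) ++ncomp; // only components 6-adjacent to the centre count
  }
  return ncomp;
}

inline bool is_simple(const std::vector<unsigned char>& fg, const Grid& g, int x, int y, int z) {
  unsigned char nb[27];
  snapshot(fg, g, x, y, z, nb);
  nb[13] = 0; // centre excluded from its own neighbourhood
  return cc26_foreground(nb) == 1 && cc6_background(nb) == 1;
}

// Exact squared Euclidean DT along one axis (Felzenszwalb-Huttenlocher lower
// envelope), sample spacing h.
void dt1d(const std::vector<double>& f, std::vector<double>& d, double h) {
  int n = (int)f.size();
  std::vector<int> v(n); std::vector<double> zb(n + 1);
  int k = 0; v[0] = 0; zb[0] = -std::numeric_limits<double>::infinity();
  zb[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * h, xv = v[k] * h;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * h;
    while (zb[k + 1] < xq) ++k;
    double dd = xq - v[k] * h;
    d[q] = dd * dd + f[v[k]];
  }
}

} // namespace

//' @useDynLib upvs, .registration = TRUE
//' @importFrom Rcpp sourceCpp

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector fg_in, IntegerVector dims, NumericVector spacing) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = g.n();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> d(n);
  for (long i = 0; i < n; ++i) d[i] = fg_in[i] ? INF : 0.0;

  // pass over x
  {
    std::vector<double> f(g.nx), o(g.nx);
    for (int z = 0; z < g.nz; ++z) for (int y = 0; y < g.ny; ++y) {
      for (int x = 0; x < g.nx; ++x) f[x] = d[g.idx(x, y, z)];
      dt1d(f, o, spacing[0]);
      for (int x = 0; x < g.nx; ++x) d[g.idx(x, y, z)] = o[x];
    }
  }
  // pass over y
  {
    std::vector<double> f(g.ny), o(g.ny);
    for (int z = 0; z < g.nz; ++z) for (int x = 0; x < g.nx; ++x) {
      for (int y = 0; y < g.ny; ++y) f[y] = d[g.idx(x, y, z)];
      dt1d(f, o, spacing[1]);
      for (int y = 0; y < g.ny; ++y) d[g.idx(x, y, z)] = o[y];
    }
  }
  // pass over z
  {
    std::vector<double> f(g.nz), o(g.nz);
    for (int y = 0; y < g.ny; ++y) for (int x = 0; x < g.nx; ++x) {
      for (int z = 0; z < g.nz; ++z) f[z] = d[g.idx(x, y, z)];
      dt1d(f, o, spacing[2]);
      for (int z = 0; z < g.nz; ++z) d[g.idx(x, y, z)] = o[z];
    }
  }
  NumericVector out(n);
  for (long i = 0; i < n; ++i) out[i] = std::sqrt(d[i]);
  out.attr("dim") = dims;
  return out;
}

// Chessboard (26-neighbourhood chamfer) distance to background, in peel counts.
// [[Rcpp::export(name = ".chessboard_dt_cpp")]]
IntegerVector chessboard_dt_cpp(LogicalVector fg_in, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = g.n();
  const int INF = INT_MAX / 2;
  std::vector<int> d(n);
  for (long i = 0; i < n; ++i) d[i] = fg_in[i] ? INF : 0;
  // forward pass
  for (int z = 0; z < g.nz; ++z) for (int y = 0; y < g.ny; ++y) for (int x = 0; x < g.nx; ++x) {
    long i = g.idx(x, y, z);
    if (d[i] == 0) continue;
    int best = d[i];
    // border voxels are one peel from outside the grid? No: outside counts as background
    if (x == 0 || y == 0 || z == 0 || x == g.nx - 1 || y == g.ny - 1 || z == g.nz - 1) best = std::min(best, 1);
    for (int k = 0; k < 26; ++k) {
      int dx = OFF26[k][0], dy = OFF26[k][1], dz = OFF26[k][2];
      if (dz > 0 || (dz == 0 && (dy > 0 || (dy == 0 && dx >= 0)))) continue; // causal half
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (g.inside(xx, yy, zz)) best = std::min(best, d[g.idx(xx, yy, zz)] + 1);
    }
    d[i] = best;
  }
  // backward pass
  for (int z = g.nz - 1; z >= 0; --z) for (int y = g.ny - 1; y >= 0; --y) for (int x = g.nx - 1; x >= 0; --x) {
    long i = g.idx(x, y, z);
    if (d[i] == 0) continue;
    int best = d[i];
    for (int k = 0; k < 26; ++k) {
      int dx = OFF26[k][0], dy = OFF26[k][1], dz = OFF26[k][2];
      if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0)))) continue;
      int xx = x + dx, yy = y + dy, zz = z + dz;
      if (g.inside(xx, yy, zz)) best = std::min(best, d[g.idx(xx, yy, zz)] + 1);
    }
    d[i] = best;
  }
  IntegerVector out(n);
  for (long i = 0; i < n; ++i) out[i] = d[i] >= INF ? NA_INTEGER : d[i];
  out.attr("dim") = dims;
  return out;
}

// Per-voxel count of foreground voxels among the 26 neighbours.
// [[Rcpp::export(name = ".neighbor_count_cpp")]]
IntegerVector neighbor_count_cpp(LogicalVector fg_in, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = g.n();
  std::vector<unsigned char> fg(n);
  for (long i = 0; i < n; ++i) fg[i] = fg_in[i] ? 1 : 0;
  IntegerVector out(n);
  for (int z = 0; z < g.nz; ++z) for (int y = 0; y < g.ny; ++y) for (int x = 0; x < g.nx; ++x) {
    long i = g.idx(x, y, z);
    out[i] = fg[i] ? nb26_count(fg, g, x, y, z) : NA_INTEGER;
  }
  out.attr("dim") = dims;
  return out;
}

// Distance-ordered homotopic thinning to a curve skeleton.
// Foreground is 26-connected, background 6-connected; a voxel is removed only
// if it is simple (removal preserves topology) and not a curve endpoint
// (<= 1 foreground neighbour). Candidates are processed in increasing order of
// the Euclidean distance transform so the outermost layer peels first; ties
// break on linear index, making the result deterministic. The first pass
// additionally anchors local maxima of the distance transform (approximate
// centers of maximal balls), which pins the medial axis and prevents tube
// ends from eroding longitudinally; a second pass then reduces residual
// ridge plateaus by deleting only voxels with >= 3 neighbours, so one-wide
// (possibly zigzag) curves can no longer erode.
// [[Rcpp::export(name = ".thin_cpp")]]
LogicalVector thin_cpp(LogicalVector fg_in, IntegerVector dims, NumericVector spacing) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = g.n();
  std::vector<unsigned char> fg(n);
  for (long i = 0; i < n; ++i) fg[i] = fg_in[i] ? 1 : 0;

  NumericVector edt = edt_cpp(fg_in, dims, spacing);

  // anchors: EDT local maxima (plateaus included) over the 26-neighbourhood
  std::vector<unsigned char> anchor(n, 0);
  for (int z = 0; z < g.nz; ++z) for (int y = 0; y < g.ny; ++y) for (int x = 0; x < g.nx; ++x) {
    long i = g.idx(x, y, z);
    if (!fg[i]) continue;
    bool mx = true;
    for (int k = 0; k < 26 && mx; ++k) {
      int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
      if (!g.inside(xx, yy, zz)) continue;
      long j = g.idx(xx, yy, zz);
      if (fg[j] && edt[j] > edt[i] + 1e-9) mx = false;
    }
    anchor[i] = mx ? 1 : 0;
  }

  typedef std::pair<double, long> Item; // (distance, linear index)
  // mode 0: anchored homotopic peel (endpoints protected)
  // mode 1: width reduction (only voxels with >= 3 neighbours removable)
  // mode 2: taut-string cleanup (degree-2 corners with mutually adjacent
  //         neighbours), which dissolves residual 3-clique corners
  auto run_pass = [&](int mode) -> long {
    std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
    for (long i = 0; i < n; ++i) if (fg[i]) pq.push(Item(edt[i], i));
    std::vector<unsigned char> permanent(n, 0);
    long deleted = 0;
    while (!pq.empty()) {
      long i = pq.top().second; pq.pop();
      if (!fg[i] || permanent[i]) continue;
      if (mode == 0 && anchor[i]) continue;
      int x = (int)(i % g.nx), y = (int)((i / g.nx) % g.ny), z = (int)(i / ((long)g.nx * g.ny));
      int nb = nb26_count(fg, g, x, y, z);
      bool removable;
      // endpoints are protected only where the distance transform is locally
      // maximal: a tip on the medial ridge is a true curve end, an unanchored
      // tip is a parasitic strand and may retract
      if (mode == 0) removable = nb > 1 || (nb == 1 && !anchor[i]);
      else if (mode == 1) removable = nb > 2;
      else {
        removable = false;
        if (nb == 2) {
          // the two neighbours must be 26-adjacent to each other
          int fx[2], fy[2], fz[2], c = 0;
          for (int k = 0; k < 26; ++k) {
            int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
            if (g.inside(xx, yy, zz) && fg[g.idx(xx, yy, zz)]) { fx[c] = xx; fy[c] = yy; fz[c] = zz; ++c; }
          }
          removable = std::abs(fx[0] - fx[1]) <= 1 && std::abs(fy[0] - fy[1]) <= 1 &&
                      std::abs(fz[0] - fz[1]) <= 1;
        }
      }
      if (!removable) { if (mode != 2 && nb <= 1) permanent[i] = 1; continue; }
      if (is_simple(fg, g, x, y, z)) {
        fg[i] = 0; ++deleted;
        for (int k = 0; k < 26; ++k) {
          int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
          if (!g.inside(xx, yy, zz)) continue;
          long j = g.idx(xx, yy, zz);
          if (fg[j] && !permanent[j]) pq.push(Item(edt[j], j));
        }
      }
    }
    return deleted;
  };
  run_pass(0);
  for (int round = 0; round < 100; ++round) {
    long del = run_pass(1);
    del += run_pass(2);
    if (del == 0) break;
  }
  LogicalVector out(n);
  for (long i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// 26-connected component labelling (0 = background).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector fg_in, IntegerVector dims) {
  Grid g{dims[0], dims[1], dims[2]};
  long n = g.n();
  std::vector<unsigned char> fg(n);
  for (long i = 0; i < n; ++i) fg[i] = fg_in[i] ? 1 : 0;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long> st;
  for (long s = 0; s < n; ++s) {
    if (!fg[s] || lab[s] > 0) continue;
    ++next; lab[s] = next; st.push_back(s);
    while (!st.empty()) {
      long c = st.back(); st.pop_back();
      int x = (int)(c % g.nx), y = (int)((c / g.nx) % g.ny), z = (int)(c / ((long)g.nx * g.ny));
      for (int k = 0; k < 26; ++k) {
        int xx = x + OFF26[k][0], yy = y + OFF26[k][1], zz = z + OFF26[k][2];
        if (!g.inside(xx, yy, zz)) continue;
        long j = g.idx(xx, yy, zz);
        if (fg[j] && lab[j] == 0) { lab[j] = next; st.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
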