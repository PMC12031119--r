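#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Disjoint-set with union by rank; each root tracks the minimum function
// value (elder birth) of its component and the index realizing it.
struct UnionFind {
  std::vector<int> parent;
  std::vector<int> rnk;
  explicit UnionFind(int n) : parent(n), rnk(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
  // returns new root
  int unite(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return a;
    if (rnk[a] < rnk[b]) std::swap(a, b);
    parent[b] = a;
    if (rnk[a] == rnk[b]) ++rnk[a];
    return a;
  }
};

// Sublevel-set H0 persistence of a 1-D piecewise-linear function.
// Samples are processed in increasing value (ties left-to-right); each local
// minimum births a component, merges follow the elder rule, and the
// essential component is closed at the global maximum.
// Returns a matrix with columns (birth, death, essential).
// [[Rcpp::export]]
NumericMatrix cpp_sublevel_h0(NumericVector x) {
  const int n = x.size();
  if (n < 2) stop("series must have length >= 2");
  for (int i = 0; i < n; ++i)
    if (!R_finite(x[i])) stop("series contains non-finite values");

  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (x[a] != x[b]) return x[a] < x[b];
    return a < b; // plateaus processed left-to-right
  });

  UnionFind uf(n);
  std::vector<char> active(n, 0);
  std::vector<double> comp_min(n, 0.0); // valid at roots
  std::vector<double> births, deaths;

  for (int k = 0; k < n; ++k) {
    const int i = ord[k];
    active[i] = 1;
    comp_min[i] = x[i];
    const bool left = (i > 0) && active[i - 1];
    const bool right = (i + 1 < n) && active[i + 1];
    if (left && right) {
      int rl = uf.find(i - 1), rr = uf.find(i + 1);
      double ml = comp_min[rl], mr = comp_min[rr];
      // the younger component (larger minimum) dies here
      double young = std::max(ml, mr);
      double elder = std::min(ml, mr);
      births.push_back(young);
      deaths.push_back(x[i]);
      int r = uf.unite(rl, rr);
      r = uf.unite(r, i);
      comp_min[r] = elder;
    } else if (left || right) {
      int rn = uf.find(left ? i - 1 : i + 1);
      double m = comp_min[rn];
      int r = uf.unite(rn, i);
      comp_min[r] = std::min(m, x[i]);
    }
    // isolated: new component born at x[i]
  }

  // essential class: global minimum, closed at global maximum
  double gmin = x[ord[0]];
  double gmax = x[ord[n - 1]];
  const int npairs = (int)births.size() + 1;
  NumericMatrix out(npairs, 3);
  for (int k = 0; k < (int)births.size(); ++k) {
    out(k, 0) = births[k];
    out(k, 1) = deaths[k];
    out(k, 2) = 0.0;
  }
  out(npairs - 1, 0) = gmin;
  out(npairs - 1, 1) = gmax;
  out(npairs - 1, 2) = 1.0;
  return out;
}

// Vietoris-Rips persistence (H0, optionally H1) of a Euclidean point cloud.
// Scale convention: an edge enters the filtration at its length (distance
// units, i.e. the diameter 2r for ball radius r).
// H0: deaths are the MST edge lengths (elder rule via union-find); the
// essential class is reported separately. H1: boundary-matrix reduction of
// triangle columns over positive edges, truncated at the enclosing radius
// (the complex is a cone beyond it, so no persistence is lost).
// [[Rcpp::export]]
List cpp_rips(NumericMatrix pts, int maxdim) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  if (n < 1) stop("point cloud is empty");
  if (n > 2000) stop("point cloud too large; subsample first");

  // pairwise distances
  std::vector<double> dist((size_t)n * n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double df = pts(i, k) - pts(j, k);
        s += df * df;
      }
      double dd = std::sqrt(s);
      dist[(size_t)i * n + j] = dd;
      dist[(size_t)j * n + i] = dd;
    }

  struct Edge { double w; int i, j; };
  std::vector<Edge> edges;
  edges.reserve((size_t)n * (n - 1) / 2);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      edges.push_back({dist[(size_t)i * n + j], i, j});
  std::sort(edges.begin(), edges.end(), [](const Edge& a, const Edge& b) {
    if (a.w != b.w) return a.w < b.w;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });

  // H0 via Kruskal; non-tree edges are positive (cycle-creating)
  UnionFind uf(n);
  std::vector<double> h0_deaths;
  std::vector<char> positive(edges.size(), 0);
  for (size_t e = 0; e < edges.size(); ++e) {
    int ra = uf.find(edges[e].i), rb = uf.find(edges[e].j);
    if (ra != rb) {
      uf.unite(ra, rb);
      h0_deaths.push_back(edges[e].w);
    } else {
      positive[e] = 1;
    }
  }

  List out;
  NumericMatrix h0((int)h0_deaths.size(), 2);
  for (int k = 0; k < (int)h0_deaths.size(); ++k) {
    h0(k, 0) = 0.0;
    h0(k, 1) = h0_deaths[k];
  }
  out["h0"] = h0;
  out["n_points"] = n;

  if (maxdim < 1 || n < 3) {
    out["h1"] = NumericMatrix(0, 2);
    return out;
  }

  // enclosing radius: min over points of its farthest distance
  double encl = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double mx = 0.0;
    for (int j = 0; j < n; ++j) mx = std::max(mx, dist[(size_t)i * n + j]);
    encl = std::min(encl, mx);
  }

  // rank of each edge (filtration order) for edges with w <= encl
  // map (i,j) -> edge rank
  std::vector<int> rank_of((size_t)n * n, -1);
  int n_kept = 0;
  for (size_t e = 0; e < edges.size(); ++e) {
    if (edges[e].w > encl) break;
    rank_of[(size_t)edges[e].i * n + edges[e].j] = (int)e;
    rank_of[(size_t)edges[e].j * n + edges[e].i] = (int)e;
    n_kept = (int)e + 1;
  }

  // triangles generated in filtration order without a global sort: walking
  // the edges by rank, each edge e=(i,j) closes the triangles (i,j,k) whose
  // two other edges have smaller rank; their filtration value is w(e).
  struct Tri { double w; int e1, e2, e3; }; // edge ranks, e1<e2<e3
  std::vector<Tri> tris;
  tris.reserve((size_t)n_kept * 8);
  for (int e = 0; e < n_kept; ++e) {
    const int i = edges[e].i, j = edges[e].j;
    const double w = edges[e].w;
    for (int k = 0; k < n; ++k) {
      if (k == i || k == j) continue;
      int a = rank_of[(size_t)i * n + k];
      int b = rank_of[(size_t)j * n + k];
      if (a < 0 || b < 0 || a >= e || b >= e) continue;
      int e1 = std::min(a, b), e2 = std::max(a, b);
      tris.push_back({w, e1, e2, e});
    }
  }

  // column reduction over Z/2 with dense bitset columns (edge rank = bit);
  // pivot = highest set bit. Only pivot-owning reduced columns are stored.
  const int words = (n_kept + 63) / 64;
  std::vector<int> owner(n_kept, -1); // edge rank -> reduced column id
  std::vector<std::vector<uint64_t>> cols;
  std::vector<double> h1_b, h1_d;
  std::vector<uint64_t> work(words);

  // pivot scan resumes from the previous pivot's word (pivots only decrease
  // during the reduction of one column)
  auto highest_bit_from = [&](const std::vector<uint64_t>& v, int from_word) -> int {
    for (int w = std::min(from_word, words - 1); w >= 0; --w) {
      if (v[w]) return w * 64 + 63 - __builtin_clzll(v[w]);
    }
    return -1;
  };

  for (size_t t = 0; t < tris.size(); ++t) {
    std::fill(work.begin(), work.end(), 0ULL);
    work[tris[t].e1 >> 6] ^= 1ULL << (tris[t].e1 & 63);
    work[tris[t].e2 >> 6] ^= 1ULL << (tris[t].e2 & 63);
    work[tris[t].e3 >> 6] ^= 1ULL << (tris[t].e3 & 63);
    int piv = highest_bit_from(work, words - 1);
    while (piv >= 0) {
      int o = owner[piv];
      if (o < 0) break;
      const std::vector<uint64_t>& other = cols[o];
      for (int w = (piv >> 6); w >= 0; --w) work[w] ^= other[w];
      piv = highest_bit_from(work, piv >> 6);
    }
    if (piv >= 0) {
      owner[piv] = (int)cols.size();
      cols.push_back(work);
      double birth = edges[piv].w;
      double death = tris[t].w;
      if (death > birth) { // skip zero-persistence pairs
        h1_b.push_back(birth);
        h1_d.push_back(death);
      }
    }
    // fully reduced to zero: triangle creates an H2 class (ignored)
  }

  NumericMatrix h1((int)h1_b.size(), 2);
  for (int k = 0; k < (int)h1_b.size(); ++k) {
    h1(k, 0) = h1_b[k];
    h1(k, 1) = h1_d[k];
  }
  out["h1"] = h1;
  out["enclosing_radius"] = encl;
  return out;
}

// Farthest-point (maxmin) subsampling; returns 1-based indices, starting
// from the point with the lowest index for determinism.
// [[Rcpp::export]]
IntegerVector cpp_farthest_point_sample(NumericMatrix pts, int k) {
  const int n = pts.nrow();
  const int d = pts.ncol();
  if (k >= n) {
    IntegerVector all(n);
    for (int i = 0; i < n; ++i) all[i] = i + 1;
    return all;
  }
  std::vector<double> mind(n, R_PosInf);
  IntegerVector chosen(k);
  int cur = 0;
  chosen[0] = 1;
  for (int step = 1; step < k; ++step) {
    int best = -1;
    double bestd = -1.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double df = pts(i, c) - pts(cur, c);
        s += df * df;
      }
      if (s < mind[i]) mind[i] = s;
      if (mind[i] > bestd) { bestd = mind[i]; best = i; }
    }
    cur = best;
    chosen[step] = best + 1;
  }
  return chosen;
}
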