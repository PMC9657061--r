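#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>
#include <array>
#include <functional>

using namespace Rcpp;

// Exhaustive depth-first enumeration of interacting self-avoiding walks on the
// simple cubic lattice, with the first step fixed along +x and the remaining
// 48-fold point-group symmetry removed by canonical orientation:
//   * the first step leaving the x axis must be +y  (orbit weight x4),
//   * the first step leaving the xy plane must be +z (orbit weight x2).
// A walk confined to the axis has weight 1, to the plane 4, otherwise 8.
// Counts are accumulated as doubles; they are exact integers well below 2^53
// for every chain length this routine is asked to handle.

namespace {

const int DX[6] = {1, -1, 0, 0, 0, 0};
const int DY[6] = {0, 0, 1, -1, 0, 0};
const int DZ[6] = {0, 0, 0, 0, 1, -1};

struct Enumerator {
  int n_steps;          // number of steps N (N+1 monomers)
  int L;                // lattice span 2*N+1
  std::vector<uint8_t> occ;
  std::vector<int> xs, ys, zs;
  std::vector<double> counts;   // (m, r2) accumulator, row m, col r2
  int m_rows, r2_cols;
  int base_weight;      // symmetry weight of the supplied prefix class

  // span 2n+3: one-site margin so neighbour probes at the extremes stay
  // inside the array
  Enumerator(int n) : n_steps(n), L(2 * n + 3),
    occ((size_t)L * L * L, 0),
    m_rows(3 * n + 2), r2_cols(n * n + 1),
    counts((size_t)(3 * n + 2) * (n * n + 1), 0.0), base_weight(1) {}

  inline size_t idx(int x, int y, int z) const {
    int o = n_steps + 1;
    return ((size_t)(x + o) * L + (y + o)) * L + (z + o);
  }
  inline bool occupied(int x, int y, int z) const { return occ[idx(x, y, z)] != 0; }

  // number of occupied nearest neighbours of (x,y,z)
  inline int neigh_occ(int x, int y, int z) const {
    int c = 0;
    for (int d = 0; d < 6; ++d)
      c += occ[idx(x + DX[d], y + DY[d], z + DZ[d])];
    return c;
  }

  // state: 0 = walk so far on the x axis, 1 = in the xy plane, 2 = full 3D
  void dfs(int step, int x, int y, int z, int m, int state) {
    if (step == n_steps) {
      int r2 = x * x + y * y + z * z;
      int w = (state == 0) ? 1 : (state == 1 ? 4 : 8);
      counts[(size_t)m * r2_cols + r2] += (double)w / base_weight;
      return;
    }
    for (int d = 0; d < 6; ++d) {
      if (state == 0 && (d == 3 || d == 4 || d == 5)) continue; // only +y leaves axis
      if (state == 1 && d == 5) continue;                       // only +z leaves plane
      int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
      size_t k = idx(nx, ny, nz);
      if (occ[k]) continue;
      int nstate = state;
      if (state == 0 && d == 2) nstate = 1;
      if (state <= 1 && d == 4) nstate = 2;
      int dm = neigh_occ(nx, ny, nz) - 1;  // contacts gained (minus chain bond)
      occ[k] = 1;
      dfs(step + 1, nx, ny, nz, m + dm, nstate);
      occ[k] = 0;
    }
  }
};

// classify a prefix: returns state and checks canonical orientation
int prefix_state(const IntegerMatrix& sites) {
  bool off_axis = false, off_plane = false;
  for (int i = 0; i < sites.nrow(); ++i) {
    if (sites(i, 1) != 0 || sites(i, 2) != 0) off_axis = true;
    if (sites(i, 2) != 0) off_plane = true;
  }
  return off_plane ? 2 : (off_axis ? 1 : 0);
}

List counts_to_list(const Enumerator& e) {
  std::vector<int> ms, r2s;
  std::vector<double> cs;
  for (int m = 0; m < e.m_rows; ++m)
    for (int r2 = 0; r2 < e.r2_cols; ++r2) {
      double c = e.counts[(size_t)m * e.r2_cols + r2];
      if (c != 0.0) { ms.push_back(m); r2s.push_back(r2); cs.push_back(c); }
    }
  return List::create(_["m"] = wrap(ms), _["r2"] = wrap(r2s), _["count"] = wrap(cs));
}

} // namespace

// [[Rcpp::export(name = ".enum_reduced")]]
List enum_reduced(int n_steps) {
  if (n_steps < 1) stop("n_steps must be >= 1");
  Enumerator e(n_steps);
  e.occ[e.idx(0, 0, 0)] = 1;
  e.occ[e.idx(1, 0, 0)] = 1;
  if (n_steps == 1) {
    e.counts[(size_t)0 * e.r2_cols + 1] = 1.0;
    return counts_to_list(e);
  }
  e.dfs(1, 1, 0, 0, 0, 0);
  return counts_to_list(e);
}

// Completions of a fixed prefix (rows = lattice sites, starting (0,0,0),(1,0,0)).
// Counts carry the weight of the completed walk relative to the prefix class, so
// multiplying by the prefix multiplicity and summing over jobs reproduces the
// full reduced table.
// [[Rcpp::export(name = ".enum_from_prefix")]]
List enum_from_prefix(IntegerMatrix sites, int n_steps) {
  int p = sites.nrow() - 1; // prefix step count
  if (p < 1 || p > n_steps) stop("prefix length must be between 1 and n_steps");
  Enumerator e(n_steps);
  int m = 0;
  for (int i = 0; i <= p; ++i) {
    int x = sites(i, 0), y = sites(i, 1), z = sites(i, 2);
    if (std::abs(x) > n_steps || std::abs(y) > n_steps || std::abs(z) > n_steps)
      stop("prefix site outside reachable lattice");
    if (e.occupied(x, y, z)) stop("prefix is not self-avoiding");
    if (i >= 1) m += e.neigh_occ(x, y, z) - 1;
    e.occ[e.idx(x, y, z)] = 1;
  }
  int state = prefix_state(sites);
  e.base_weight = (state == 0) ? 1 : (state == 1 ? 4 : 8);
  if (p == n_steps) {
    int x = sites(p, 0), y = sites(p, 1), z = sites(p, 2);
    e.counts[(size_t)m * e.r2_cols + (x * x + y * y + z * z)] = 1.0;
  } else {
    e.dfs(p, sites(p, 0), sites(p, 1), sites(p, 2), m, state);
  }
  return counts_to_list(e);
}

// Canonical prefixes of a given depth with their orbit multiplicities.
// [[Rcpp::export(name = ".list_prefixes")]]
List list_prefixes_cpp(int depth) {
  if (depth < 2) stop("depth must be >= 2");
  Enumerator e(depth);
  e.occ[e.idx(0, 0, 0)] = 1;
  e.occ[e.idx(1, 0, 0)] = 1;
  std::vector<IntegerMatrix> walks;
  std::vector<int> mult;
  // reuse the DFS but collect leaves instead of counts
  std::vector<std::array<int, 3>> path;
  path.push_back({0, 0, 0});
  path.push_back({1, 0, 0});
  std::function<void(int, int)> rec = [&](int step, int state) {
    if (step == depth) {
      IntegerMatrix mat(depth + 1, 3);
      for (int i = 0; i <= depth; ++i)
        for (int j = 0; j < 3; ++j) mat(i, j) = path[i][j];
      walks.push_back(mat);
      mult.push_back(state == 0 ? 1 : (state == 1 ? 4 : 8));
      return;
    }
    int x = path.back()[0], y = path.back()[1], z = path.back()[2];
    for (int d = 0; d < 6; ++d) {
      if (state == 0 && (d == 3 || d == 4 || d == 5)) continue;
      if (state == 1 && d == 5) continue;
      int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
      size_t k = e.idx(nx, ny, nz);
      if (e.occ[k]) continue;
      int nstate = state;
      if (state == 0 && d == 2) nstate = 1;
      if (state <= 1 && d == 4) nstate = 2;
      e.occ[k] = 1;
      path.push_back({nx, ny, nz});
      rec(step + 1, nstate);
      path.pop_back();
      e.occ[k] = 0;
    }
  };
  rec(1, 0);
  List out(walks.size());
  for (size_t i = 0; i < walks.size(); ++i)
    out[i] = List::create(_["sites"] = walks[i], _["multiplicity"] = mult[i]);
  return out;
}

// Long-double Horner evaluation of sum c_m x^m: extended-precision check path.
// [[Rcpp::export(name = ".horner_ld")]]
double horner_ld(NumericVector coeffs, double x) {
  long double acc = 0.0L, xl = (long double)x;
  for (int i = coeffs.size() - 1; i >= 0; --i)
    acc = acc * xl + (long double)coeffs[i];
  return (double)acc;
}
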