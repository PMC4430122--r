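// Lattice polymer Monte-Carlo: self-avoiding-walk growth on the simple cubic
// lattice, and equilibration by single-site bond-fluctuation moves plus
// pivot moves. Uses R's RNG so results are reproducible via set.seed().

#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <array>
#include <cstdint>

using namespace Rcpp;

static inline int64_t pack(int x, int y, int z) {
  const int64_t OFF = 1 << 20;
  return (((int64_t)(x) + OFF) << 42) | (((int64_t)(y) + OFF) << 21) |
         ((int64_t)(z) + OFF);
}

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

static inline int runif_int(int n) {
  int k;
  do { k = (int)(unif_rand() * n); } while (k >= n); // guard unif_rand()==1
  return k;
}

// [[Rcpp::export(name = ".grow_chain_cpp")]]
IntegerMatrix grow_chain_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  std::vector<std::array<int, 3>> chain;
  std::unordered_set<int64_t> occ;
  chain.push_back({0, 0, 0});
  occ.insert(pack(0, 0, 0));
  int rejects = 0;
  while ((int)chain.size() < n) {
    const std::array<int, 3>& tip = chain.back();
    int d = runif_int(6);
    int nx = tip[0] + DX[d], ny = tip[1] + DY[d], nz = tip[2] + DZ[d];
    int64_t key = pack(nx, ny, nz);
    if (occ.count(key)) {
      if (++rejects > 10) {
        // stuck: erase the terminal monomers (up to 10) and keep growing
        int erase = std::min<int>(10, (int)chain.size() - 1);
        for (int i = 0; i < erase; ++i) {
          const std::array<int, 3>& m = chain.back();
          occ.erase(pack(m[0], m[1], m[2]));
          chain.pop_back();
        }
        rejects = 0;
      }
    } else {
      chain.push_back({nx, ny, nz});
      occ.insert(key);
      rejects = 0;
    }
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = chain[i][0];
    out(i, 1) = chain[i][1];
    out(i, 2) = chain[i][2];
  }
  return out;
}

// allowed squared bond lengths for the single-site bond-fluctuation moves
static inline bool bond_ok(int dx, int dy, int dz) {
  int d2 = dx * dx + dy * dy + dz * dz;
  return d2 >= 1 && d2 <= 5; // {1, sqrt2, sqrt3, 2, sqrt5}
}

// the 48 signed permutation matrices of the cubic point group, as
// (permutation, sign) pairs; index 0 is the identity.
struct PointOp { int p[3]; int s[3]; };

static std::vector<PointOp> make_ops() {
  std::vector<PointOp> ops;
  int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                     {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  for (int pi = 0; pi < 6; ++pi)
    for (int sm = 0; sm < 8; ++sm) {
      PointOp op;
      for (int a = 0; a < 3; ++a) {
        op.p[a] = perms[pi][a];
        op.s[a] = (sm >> a) & 1 ? -1 : 1;
      }
      ops.push_back(op);
    }
  // move identity to front so ops[1..47] are the non-identity elements
  for (size_t i = 0; i < ops.size(); ++i) {
    bool ident = ops[i].p[0] == 0 && ops[i].p[1] == 1 && ops[i].p[2] == 2 &&
                 ops[i].s[0] == 1 && ops[i].s[1] == 1 && ops[i].s[2] == 1;
    if (ident) { std::swap(ops[0], ops[i]); break; }
  }
  return ops;
}

// [[Rcpp::export(name = ".equilibrate_cpp")]]
IntegerMatrix equilibrate_cpp(IntegerMatrix coords, int n_sweeps) {
  static std::vector<PointOp> OPS = make_ops();
  int n = coords.nrow();
  std::vector<std::array<int, 3>> chain(n);
  std::unordered_set<int64_t> occ;
  for (int i = 0; i < n; ++i) {
    chain[i] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    occ.insert(pack(chain[i][0], chain[i][1], chain[i][2]));
  }
  if ((int)occ.size() != n) stop("input chain is not self-avoiding");

  for (int sweep = 0; sweep < n_sweeps; ++sweep) {
    // n single-monomer bond-fluctuation attempts
    for (int t = 0; t < n; ++t) {
      int i = runif_int(n);
      int d = runif_int(6);
      int nx = chain[i][0] + DX[d], ny = chain[i][1] + DY[d],
          nz = chain[i][2] + DZ[d];
      if (occ.count(pack(nx, ny, nz))) continue;
      if (i > 0 && !bond_ok(nx - chain[i - 1][0], ny - chain[i - 1][1],
                            nz - chain[i - 1][2]))
        continue;
      if (i < n - 1 && !bond_ok(nx - chain[i + 1][0], ny - chain[i + 1][1],
                                nz - chain[i + 1][2]))
        continue;
      occ.erase(pack(chain[i][0], chain[i][1], chain[i][2]));
      chain[i] = {nx, ny, nz};
      occ.insert(pack(nx, ny, nz));
    }
    // one pivot attempt: rigid point-group operation on the tail
    if (n >= 3) {
      int p = runif_int(n - 2); // pivot so that a non-empty tail remains
      const PointOp& op = OPS[1 + runif_int(47)];
      const std::array<int, 3> piv = chain[p];
      std::vector<std::array<int, 3>> tail(n - p - 1);
      bool ok = true;
      // remove tail from occupancy so only head collisions are checked
      for (int j = p + 1; j < n; ++j)
        occ.erase(pack(chain[j][0], chain[j][1], chain[j][2]));
      std::unordered_set<int64_t> tail_occ;
      for (int j = p + 1; j < n; ++j) {
        int r[3] = {chain[j][0] - piv[0], chain[j][1] - piv[1],
                    chain[j][2] - piv[2]};
        int v[3];
        for (int a = 0; a < 3; ++a) v[a] = op.s[a] * r[op.p[a]];
        std::array<int, 3> np = {piv[0] + v[0], piv[1] + v[1], piv[2] + v[2]};
        int64_t key = pack(np[0], np[1], np[2]);
        if (occ.count(key)) { ok = false; break; }
        tail[j - p - 1] = np;
        tail_occ.insert(key);
      }
      if (ok) {
        for (int j = p + 1; j < n; ++j) chain[j] = tail[j - p - 1];
        for (int64_t k : tail_occ) occ.insert(k);
      } else {
        for (int j = p + 1; j < n; ++j)
          occ.insert(pack(chain[j][0], chain[j][1], chain[j][2]));
      }
    }
  }
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = chain[i][0];
    out(i, 1) = chain[i][1];
    out(i, 2) = chain[i][2];
  }
  return out;
}
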