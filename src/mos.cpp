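#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Monte Carlo equilibration of a closed self-avoiding chain (self-avoiding
// polygon) confined to a cuboid lattice, using the three transformation
// types of the Madras-Orlitsky-Shepp polygon move set: a randomly chosen
// sub-chain between two chain positions i, j is either
//   (0) inverted through the midpoint of (u, v) = (site_i, site_j)
//       (point reflection plus traversal reversal),
//   (1) reflected in a lattice plane containing both u and v, or
//   (2) rotated by 90/180/270 degrees about the axis through u and v
//       (only available when u - v is axis-aligned).
// All three are lattice isometries fixing the sub-chain endpoints, so
// closure is preserved; each proposal is its own inverse (or, for 90-degree
// rotations, paired with the equally likely 270-degree one), so the chain
// samples confined polygons uniformly.
//
// Counting follows the two-stage rejection rule: a proposal that breaks
// self-avoidance (or is geometrically unavailable) keeps the old chain and
// is not counted as an attempt unless count_all is set; a self-avoiding but
// unconfined proposal keeps the old chain and is always counted; a valid
// proposal is accepted and counted.
// [[Rcpp::export]]
List cpp_mos(IntegerMatrix sites_in, IntegerVector dims, double n_attempts,
             bool count_all, double max_proposals) {
  const int n = sites_in.nrow();
  if (n < 4) stop("polygon needs at least 4 sites");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nsite = nx * ny * nz;

  std::vector<std::array<int, 3>> s(n);
  for (int i = 0; i < n; ++i)
    s[i] = {sites_in(i, 0), sites_in(i, 1), sites_in(i, 2)};

  std::vector<int> grid(nsite, -1);
  auto lin = [&](const std::array<int, 3>& p) {
    return p[0] + nx * (p[1] + ny * p[2]);
  };
  auto inside = [&](const std::array<int, 3>& p) {
    return p[0] >= 0 && p[0] < nx && p[1] >= 0 && p[1] < ny &&
           p[2] >= 0 && p[2] < nz;
  };
  for (int i = 0; i < n; ++i) {
    if (!inside(s[i])) stop("initial chain not confined");
    if (grid[lin(s[i])] != -1) stop("initial chain not self-avoiding");
    grid[lin(s[i])] = i;
  }

  std::vector<int> interior;           // chain positions of the moved arc
  std::vector<std::array<int, 3>> newpts;
  double counted = 0.0, accepted = 0.0, proposals = 0.0;

  while (counted < n_attempts) {
    if (++proposals > max_proposals)
      stop("MOS equilibration exceeded the proposal budget");
    int i = (int)(unif_rand() * n) % n;
    int j;
    do { j = (int)(unif_rand() * n) % n; } while (j == i);
    int type = (int)(unif_rand() * 3.0); if (type > 2) type = 2;
    const std::array<int, 3> u = s[i], v = s[j];
    const int len = (j - i - 1 + n) % n;

    interior.clear(); newpts.clear();
    bool available = true;
    if (type == 0) {                       // inversion + reversal
      for (int t = 0; t < len; ++t) {
        interior.push_back((i + 1 + t) % n);
        const std::array<int, 3>& old = s[(j - 1 - t + n) % n];
        newpts.push_back({u[0] + v[0] - old[0], u[1] + v[1] - old[1],
                          u[2] + v[2] - old[2]});
      }
    } else if (type == 1) {                // plane reflection
      int axes[3], navail = 0;
      for (int a = 0; a < 3; ++a) if (u[a] == v[a]) axes[navail++] = a;
      if (navail == 0) {
        available = false;
      } else {
        int a = axes[(int)(unif_rand() * navail) % navail];
        for (int t = 0; t < len; ++t) {
          int kpos = (i + 1 + t) % n;
          interior.push_back(kpos);
          std::array<int, 3> p = s[kpos];
          p[a] = 2 * u[a] - p[a];
          newpts.push_back(p);
        }
      }
    } else {                               // axis rotation
      int diff_axis = -1, ndiff = 0;
      for (int a = 0; a < 3; ++a) if (u[a] != v[a]) { diff_axis = a; ++ndiff; }
      if (ndiff != 1) {
        available = false;
      } else {
        const int b = (diff_axis + 1) % 3, c = (diff_axis + 2) % 3;
        int rot = 1 + ((int)(unif_rand() * 3.0) % 3);   // 1,2,3 quarter turns
        for (int t = 0; t < len; ++t) {
          int kpos = (i + 1 + t) % n;
          interior.push_back(kpos);
          std::array<int, 3> p = s[kpos];
          int db = p[b] - u[b], dc = p[c] - u[c];
          for (int q = 0; q < rot; ++q) { int tmp = db; db = -dc; dc = tmp; }
          p[b] = u[b] + db; p[c] = u[c] + dc;
          newpts.push_back(p);
        }
      }
    }

    if (!available) {                      // geometrically impossible proposal
      if (count_all) counted += 1.0;
      continue;
    }

    // vacate the old arc, then test the proposal
    for (int kpos : interior) grid[lin(s[kpos])] = -1;
    bool saw_ok = true, confined = true;
    std::unordered_set<long long> fresh;
    for (const auto& p : newpts) {
      long long key = ((long long)(p[0] + 512) << 40) |
                      ((long long)(p[1] + 512) << 20) |
                      (long long)(p[2] + 512);
      if (!fresh.insert(key).second) { saw_ok = false; break; }
      if (inside(p)) {
        if (grid[lin(p)] != -1) { saw_ok = false; break; }
      } else {
        confined = false;
      }
    }

    if (saw_ok && confined) {
      for (size_t t = 0; t < interior.size(); ++t) {
        s[interior[t]] = newpts[t];
        grid[lin(newpts[t])] = interior[t];
      }
      counted += 1.0;
      accepted += 1.0;
    } else {
      for (int kpos : interior) grid[lin(s[kpos])] = kpos;  // restore
      if (!saw_ok) { if (count_all) counted += 1.0; }
      else counted += 1.0;                 // self-avoiding but unconfined
    }
  }

  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int a = 0; a < 3; ++a) out(i, a) = s[i][a];
  return List::create(_["sites"] = out, _["counted"] = counted,
                      _["accepted"] = accepted, _["proposals"] = proposals);
}
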