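#include <Rcpp.h>
using namespace Rcpp;

// Nearest-neighbour random walk on the cell lattice with reflecting walls.
// blob_flag: 0 = empty site, 1 = non-target blob, 2 = target blob (exactly
// one). A step into the wall keeps the walker in place but is counted as a
// step. Encounters are arrival events at non-target blob sites; a walk ends
// on first arrival at the target site. Uses R's RNG so results are
// reproducible from set.seed().
//
// start_mode 0: uniform over all cell sites; 1: uniform over the in-cell
// nearest neighbours of the target site.
// [[Rcpp::export]]
List cpp_walk(IntegerVector dims, IntegerVector blob_flag, int n_walkers,
              int start_mode, bool count_start_encounter,
              bool include_target_start, double max_steps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nsite = nx * ny * nz;
  if (blob_flag.size() != nsite) stop("blob_flag length mismatch");
  int target = -1;
  for (int s = 0; s < nsite; ++s)
    if (blob_flag[s] == 2) { if (target >= 0) stop("multiple targets"); target = s; }
  if (target < 0) stop("target blob absent from conformation");

  const int tx = target % nx, ty = (target / nx) % ny, tz = target / (nx * ny);
  const int dx[6] = {1, -1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, 1, -1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, 1, -1};

  std::vector<int> nbr;
  if (start_mode == 1) {
    for (int d = 0; d < 6; ++d) {
      int x = tx + dx[d], y = ty + dy[d], z = tz + dz[d];
      if (x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz)
        nbr.push_back(x + nx * (y + ny * z));
    }
    if (nbr.empty()) stop("target blob has no in-cell neighbour");
  }

  NumericVector steps(n_walkers), encounters(n_walkers);
  for (int w = 0; w < n_walkers; ++w) {
    int pos;
    if (start_mode == 1) {
      pos = nbr[(int)(unif_rand() * nbr.size()) % nbr.size()];
    } else {
      do {
        pos = (int)(unif_rand() * nsite) % nsite;
      } while (!include_target_start && pos == target);
    }
    double n = 0.0, m = 0.0;
    if (pos == target) { steps[w] = 0.0; encounters[w] = 0.0; continue; }
    if (count_start_encounter && blob_flag[pos] == 1) m = 1.0;

    int x = pos % nx, y = (pos / nx) % ny, z = pos / (nx * ny);
    for (;;) {
      if (n >= max_steps) stop("walker exceeded max_steps");
      int d = (int)(unif_rand() * 6.0); if (d > 5) d = 5;
      int x2 = x + dx[d], y2 = y + dy[d], z2 = z + dz[d];
      n += 1.0;
      if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny || z2 < 0 || z2 >= nz)
        continue;  // reflecting wall: stay put, step counted
      x = x2; y = y2; z = z2;
      int s = x + nx * (y + ny * z);
      int f = blob_flag[s];
      if (f == 2) break;       // arrival at the target ends the walk
      if (f == 1) m += 1.0;    // entry into a non-target blob
    }
    steps[w] = n;
    encounters[w] = m;
  }
  return List::create(_["steps"] = steps, _["encounters"] = encounters);
}
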