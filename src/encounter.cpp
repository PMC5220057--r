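#include <Rcpp.h>
using namespace Rcpp;

// Nearest-particle queries for encounter detection and chemotaxis.
//
// For each individual i, scanning only particles of a type its species
// can consume, finds:
//   - the nearest such particle by centre-to-centre distance
//     (the chemotaxis target), and/or
//   - the nearest such particle in physical contact (centre distance
//     <= cell radius + particle radius), the encounter used for
//     consumption.
// Ties break to the lowest particle id.  Internally the particles are
// binned on a uniform grid and searched in expanding shells; this is
// an internal acceleration with a contract identical to the
// brute-force all-pairs scan the tests compare against.

struct Grid {
  int nx;            // bins per axis
  double g;          // bin side
  std::vector<int> start;   // bin -> offset into order
  std::vector<int> order;   // particle indices grouped by bin
  std::vector<int> bx, by, bz;

  Grid(const NumericVector& px, const NumericVector& py,
       const NumericVector& pz, double L, int nbin) : nx(nbin) {
    const int m = px.size();
    g = L / nx;
    bx.resize(m); by.resize(m); bz.resize(m);
    std::vector<int> count(nx * nx * nx + 1, 0);
    for (int j = 0; j < m; ++j) {
      bx[j] = clampi((int)(px[j] / g));
      by[j] = clampi((int)(py[j] / g));
      bz[j] = clampi((int)(pz[j] / g));
      ++count[cell(bx[j], by[j], bz[j]) + 1];
    }
    for (size_t k = 1; k < count.size(); ++k) count[k] += count[k - 1];
    start = count;
    order.resize(m);
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int j = 0; j < m; ++j)
      order[fill[cell(bx[j], by[j], bz[j])]++] = j;
  }
  int clampi(int b) const { return b < 0 ? 0 : (b >= nx ? nx - 1 : b); }
  int cell(int x, int y, int z) const { return (x * nx + y) * nx + z; }
};

struct Best {
  double d2 = R_PosInf;
  int j = -1;
  int id = 0;
  void offer(double cand, int jj, int cid) {
    if (cand < d2 || (cand == d2 && j >= 0 && cid < id)) {
      d2 = cand; j = jj; id = cid;
    }
  }
};

// [[Rcpp::export]]
List nearest_particles_cpp(NumericVector ix, NumericVector iy, NumericVector iz,
                           NumericVector irad, IntegerVector ispecies,
                           NumericVector px, NumericVector py, NumericVector pz,
                           NumericVector prad, IntegerVector ptype,
                           IntegerVector pid, LogicalMatrix consumable,
                           double L, bool want_near, bool want_touch) {
  const int n = ix.size();
  const int m = px.size();
  IntegerVector near_idx(n, NA_INTEGER), touch_idx(n, NA_INTEGER);
  NumericVector near_d(n, NA_REAL), touch_d(n, NA_REAL);
  if (m == 0 || n == 0)
    return List::create(_["near_idx"] = near_idx, _["near_dist"] = near_d,
                        _["touch_idx"] = touch_idx, _["touch_dist"] = touch_d);

  double max_prad = 0.0;
  for (int j = 0; j < m; ++j) if (prad[j] > max_prad) max_prad = prad[j];

  const int nbin = 10;
  Grid grid(px, py, pz, L, nbin);

  for (int i = 0; i < n; ++i) {
    const int sp = ispecies[i] - 1;
    const double xi = ix[i], yi = iy[i], zi = iz[i], ri = irad[i];
    const int cx = grid.clampi((int)(xi / grid.g));
    const int cy = grid.clampi((int)(yi / grid.g));
    const int cz = grid.clampi((int)(zi / grid.g));
    Best nb, tb;

    // scan one bin, updating whichever queries are still wanted
    auto scan_bin = [&](int bxx, int byy, int bzz, bool do_near) {
      const int c = grid.cell(bxx, byy, bzz);
      for (int k = grid.start[c]; k < grid.start[c + 1]; ++k) {
        const int j = grid.order[k];
        if (!consumable(sp, ptype[j] - 1)) continue;
        const double dx = px[j] - xi, dy = py[j] - yi, dz = pz[j] - zi;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (do_near) nb.offer(d2, j, pid[j]);
        if (want_touch) {
          const double reach = ri + prad[j];
          if (d2 <= reach * reach) tb.offer(d2, j, pid[j]);
        }
      }
    };

    // contact search: everything that can touch lies within
    // ri + max_prad, i.e. within kt bins (Chebyshev)
    const int kt = want_touch ?
      (int)((ri + max_prad) / grid.g) + 1 : -1;
    // nearest search: expand shells until the best distance is
    // certainly closer than any unscanned bin
    int kmax = want_near ? grid.nx : kt;
    if (want_touch && kt > kmax) kmax = kt;

    for (int s = 0; s <= kmax; ++s) {
      const bool near_this_shell =
        want_near && !(nb.j >= 0 && std::sqrt(nb.d2) <= (double)(s - 1) * grid.g);
      const bool touch_this_shell = want_touch && s <= kt;
      if (!near_this_shell && !touch_this_shell) break;
      const int x0 = grid.clampi(cx - s), x1 = grid.clampi(cx + s);
      const int y0 = grid.clampi(cy - s), y1 = grid.clampi(cy + s);
      const int z0 = grid.clampi(cz - s), z1 = grid.clampi(cz + s);
      for (int bxx = x0; bxx <= x1; ++bxx)
        for (int byy = y0; byy <= y1; ++byy)
          for (int bzz = z0; bzz <= z1; ++bzz) {
            // shell: skip interior bins already scanned
            const int cheb = std::max(std::abs(bxx - cx),
                              std::max(std::abs(byy - cy),
                                       std::abs(bzz - cz)));
            if (cheb != s) continue;
            scan_bin(bxx, byy, bzz, near_this_shell);
          }
    }

    if (nb.j >= 0) { near_idx[i] = nb.j + 1; near_d[i] = std::sqrt(nb.d2); }
    if (tb.j >= 0) { touch_idx[i] = tb.j + 1; touch_d[i] = std::sqrt(tb.d2); }
  }
  return List::create(_["near_idx"] = near_idx, _["near_dist"] = near_d,
                      _["touch_idx"] = touch_idx, _["touch_dist"] = touch_d);
}
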