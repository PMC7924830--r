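#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Clade codes used throughout: 0 = EMPTY, 1..K = position in the clade
// alphabet (default C, F, G).

namespace {

// Inverse-CDF lookup table for the gamma dispersal kernel, conditional on
// the drawn distance exceeding cell_size / 2 (shorter draws cannot leave
// the source cell, whatever the bearing, so they are thinned out before a
// distance is ever materialised).
struct KernelTable {
  static const int N = 1024;
  double p_stay;   // P(X <= cell_size / 2)
  double p_move;   // 1 - p_stay
  double shape, scale, lo;
  std::vector<double> q; // q[i] = Q(p_stay + (1 - p_stay) * i / N)

  KernelTable(double m, double s, double dt, double cell_size)
      : shape(m * dt / s), scale(s), lo(cell_size / 2.0) {
    if (m <= 0.0) { // degenerate kernel: every draw stays at the source
      p_stay = 1.0;
      p_move = 0.0;
      return;
    }
    p_stay = R::pgamma(lo, shape, scale, 1, 0);
    p_move = 1.0 - p_stay;
    if (p_move <= 0.0) return;
    q.resize(N);
    for (int i = 0; i < N; ++i) {
      double u = p_stay + p_move * (double)i / (double)N;
      q[i] = R::qgamma(u, shape, scale, 1, 0);
    }
  }

  // v uniform on [0, 1): conditional quantile by linear interpolation;
  // the top bin falls back to the exact quantile function (heavy tail).
  double draw(double v) const {
    double t = v * (double)N;
    int j = (int)t;
    if (j >= N - 1) {
      double u = p_stay + p_move * v;
      if (u >= 1.0) u = 1.0 - 1e-16;
      return R::qgamma(u, shape, scale, 1, 0);
    }
    double w = t - (double)j;
    return q[j] * (1.0 - w) + q[j + 1] * w;
  }
};

struct Grid {
  int nr, nc;
  const int *mask; // column-major, 1 = habitable
  inline bool habitable(int r, int c) const {
    return r >= 0 && r < nr && c >= 0 && c < nc && mask[c * nr + r] == 1;
  }
};

} // namespace

// Core driver shared by the single-step, introduction and full-run entry
// points. `occ` is the occupancy matrix (0 = empty); introductions listed
// in (intro_steps, intro_clades) are applied at the head of their step.
// Intro step == n_steps means "after the final dispersal sweep".
// [[Rcpp::export]]
IntegerMatrix cpp_simulate(IntegerMatrix occ, IntegerMatrix mask,
                           double cell_size, double m, double s,
                           double alpha, double dt, int n_steps,
                           IntegerVector intro_steps,
                           IntegerVector intro_clades,
                           IntegerMatrix entry_cells) {
  const int nr = occ.nrow(), nc = occ.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("occupancy and mask dimensions differ");
  Grid g{nr, nc, mask.begin()};

  std::vector<int> state(occ.begin(), occ.end());
  std::vector<int> frozen(state.size());

  // occupied cells, visited in a fixed random permutation; colonised
  // cells are appended and only become sources on the next step
  std::vector<int> occupied;
  occupied.reserve(state.size());
  int n_hab = 0;
  std::vector<int> clade_count(64, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (mask[idx] == 1) ++n_hab;
      if (state[idx] > 0) {
        if (mask[idx] != 1) stop("occupied cell outside the habitable mask");
        occupied.push_back(idx);
        if (state[idx] < 64) ++clade_count[state[idx]];
      }
    }
  for (int i = (int)occupied.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(occupied[i], occupied[j]);
  }

  KernelTable kt(m, s, dt, cell_size);
  const double logq = (kt.p_move > 0.0 && kt.p_move < 1.0)
                          ? std::log1p(-kt.p_move)
                          : 0.0;

  int intro_at = 0;
  const int n_intro = intro_steps.size();

  for (int step = 0; step <= n_steps; ++step) {
    // scheduled clade introductions at the entry cells
    while (intro_at < n_intro && intro_steps[intro_at] == step) {
      int clade = intro_clades[intro_at];
      for (int e = 0; e < entry_cells.nrow(); ++e) {
        int idx = entry_cells(e, 1) * nr + entry_cells(e, 0);
        int cur = state[idx];
        if (cur == 0) {
          state[idx] = clade;
          occupied.push_back(idx);
          ++clade_count[clade];
        } else if (clade > cur && unif_rand() < alpha) {
          --clade_count[cur];
          state[idx] = clade;
          ++clade_count[clade];
        }
      }
      ++intro_at;
    }
    if (step == n_steps) break;

    const int n0 = (int)occupied.size();
    if (n0 == 0 || kt.p_move <= 0.0) continue;

    // a saturated single-clade landscape is static: nothing to disperse into
    int n_present = 0;
    for (int k = 1; k < 64; ++k)
      if (clade_count[k] > 0) ++n_present;
    if (n_present <= 1 && n0 == n_hab) continue;

    std::copy(state.begin(), state.end(), frozen.begin());

    // Bernoulli(p_move) thinning over source cells via geometric skips
    int i = -1;
    for (;;) {
      if (kt.p_move >= 1.0) {
        ++i;
      } else {
        double u = unif_rand();
        i += 1 + (int)std::floor(std::log(u) / logq);
      }
      if (i >= n0 || i < 0) break;

      int src = occupied[i];
      int sr = src % nr, sc = src / nr;
      double d = kt.draw(unif_rand());
      double theta = 2.0 * M_PI * unif_rand();
      int tc = (int)std::floor(sc + 0.5 + d * std::cos(theta) / cell_size);
      int tr = (int)std::floor(sr + 0.5 + d * std::sin(theta) / cell_size);
      if (tr == sr && tc == sc) continue;
      if (!g.habitable(tr, tc)) continue; // absorbing coastline
      int tidx = tc * nr + tr;
      int migrant = frozen[src];
      int resident = state[tidx];
      if (resident == 0) {
        state[tidx] = migrant;
        occupied.push_back(tidx);
        ++clade_count[migrant];
      } else if (migrant > resident && unif_rand() < alpha) {
        // arrival-order replacement: only a later-arriving (newer) clade
        // can displace an earlier resident, with probability alpha
        --clade_count[resident];
        state[tidx] = migrant;
        ++clade_count[migrant];
      }
    }
  }

  IntegerMatrix out(nr, nc);
  std::copy(state.begin(), state.end(), out.begin());
  return out;
}

// Conditional kernel sampler (distance given > cell_size/2) through the
// same lookup table the simulator uses; exposed for distributional tests.
// [[Rcpp::export]]
NumericVector cpp_sample_conditional(int n, double m, double s, double dt,
                                     double cell_size) {
  KernelTable kt(m, s, dt, cell_size);
  NumericVector out(n);
  if (kt.p_move <= 0.0) return out;
  for (int i = 0; i < n; ++i) out[i] = kt.draw(unif_rand());
  return out;
}
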