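#include <Rcpp.h>
using namespace Rcpp;

// Agent-based model on an n x n torus: each spot empty (0), wild-type (1) or
// mutant (2).  One time step processes M hits on occupied spots, where M is
// the occupied count at the step's start; each hit is uniform over currently
// occupied spots (state is updated continuously within a step).  Death is
// evaluated before reproduction; a dead individual does not reproduce.

namespace {

struct SpatialSystem {
  int n, N2;
  double Rw, Dw, Rm, Dm, mu;
  std::vector<int> g;        // spot contents
  std::vector<int> occ;      // indices of occupied spots
  std::vector<int> pos;      // position of a spot in occ, or -1
  long nw, nm;

  SpatialSystem(int n_, double Rw_, double Dw_, double Rm_, double Dm_,
                double mu_)
    : n(n_), N2(n_ * n_), Rw(Rw_), Dw(Dw_), Rm(Rm_), Dm(Dm_), mu(mu_),
      g(N2, 0), pos(N2, -1), nw(0), nm(0) { occ.reserve(N2); }

  void clear() {
    std::fill(g.begin(), g.end(), 0);
    std::fill(pos.begin(), pos.end(), -1);
    occ.clear();
    nw = nm = 0;
  }
  void add(int idx, int type) {
    g[idx] = type;
    pos[idx] = (int)occ.size();
    occ.push_back(idx);
    if (type == 1) ++nw; else ++nm;
  }
  void rem(int idx) {
    int p = pos[idx], last = occ.back();
    occ[p] = last;
    pos[last] = p;
    occ.pop_back();
    pos[idx] = -1;
    if (g[idx] == 1) --nw; else --nm;
    g[idx] = 0;
  }
  int nbr(int idx, int dir) const {
    static const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
    static const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
    int r = idx / n + dr[dir], c = idx % n + dc[dir];
    if (r < 0) r += n; else if (r >= n) r -= n;
    if (c < 0) c += n; else if (c >= n) c -= n;
    return r * n + c;
  }
  void step() {
    int M = (int)occ.size();
    for (int h = 0; h < M; ++h) {
      if (occ.empty()) return;
      int i = (int)(unif_rand() * occ.size());
      if (i >= (int)occ.size()) i = (int)occ.size() - 1;
      int idx = occ[i];
      int type = g[idx];
      if (unif_rand() < (type == 1 ? Dw : Dm)) { rem(idx); continue; }
      if (unif_rand() < (type == 1 ? Rw : Rm)) {
        int dir = (int)(unif_rand() * 8);
        if (dir > 7) dir = 7;
        int j = nbr(idx, dir);
        if (g[j] == 0) {
          int off = type;
          if (type == 1 && mu > 0 && unif_rand() < mu) off = 2;
          add(j, off);
        }
      }
    }
  }
  void seed_random(int count, int type) {
    while (count > 0) {
      int idx = (int)(unif_rand() * N2);
      if (idx >= N2) idx = N2 - 1;
      if (g[idx] == 0) { add(idx, type); --count; }
    }
  }
  void load(const IntegerMatrix& grid) {
    clear();
    for (int idx = 0; idx < N2; ++idx) {
      int v = grid[idx];
      if (v != 0) add(idx, v);
    }
  }
};

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_spatial_step(IntegerMatrix grid, double Rw, double Dw,
                               double Rm, double Dm, double mu, int n_steps) {
  int n = grid.nrow();
  SpatialSystem s(n, Rw, Dw, Rm, Dm, mu);
  s.load(grid);
  for (int t = 0; t < n_steps; ++t) s.step();
  IntegerMatrix out(n, n);
  for (int idx = 0; idx < n * n; ++idx) out[idx] = s.g[idx];
  return out;
}

// Per-replicate mean occupancy after burn_in steps, averaged over a further
// observation window.
// [[Rcpp::export]]
NumericVector cpp_spatial_steady(double Rw, double Dw, int n, int burn_in,
                                 int window, int replicates, int init_count) {
  SpatialSystem s(n, Rw, Dw, Rw, Dw, 0.0);
  NumericVector out(replicates);
  for (int rep = 0; rep < replicates; ++rep) {
    Rcpp::checkUserInterrupt();
    s.clear();
    s.seed_random(init_count, 1);
    for (int t = 0; t < burn_in; ++t) s.step();
    double acc = 0.0;
    for (int t = 0; t < window; ++t) {
      acc += (double)s.occ.size();
      s.step();
    }
    out[rep] = acc / window;
  }
  return out;
}

// Fixation protocol: seed M0 wild-types at distinct random spots, equilibrate
// burn_steps, replace one random wild-type with a mutant, run to monomorphism.
// [[Rcpp::export]]
List cpp_spatial_fixation(double Rw, double Dw, double Rm, double Dm,
                          int n, int M0, int burn_steps, int n_runs) {
  SpatialSystem s(n, Rw, Dw, Rm, Dm, 0.0);
  double n_fix = 0, n_loss = 0, n_ext = 0, n_pre_ext = 0;
  double seed_M_acc = 0.0;
  for (int run = 0; run < n_runs; ++run) {
    if (run % 64 == 0) Rcpp::checkUserInterrupt();
    s.clear();
    s.seed_random(M0, 1);
    for (int t = 0; t < burn_steps; ++t) s.step();
    if (s.nw == 0) { n_pre_ext += 1; continue; }  // died out before seeding
    seed_M_acc += (double)s.occ.size();
    int i = (int)(unif_rand() * s.occ.size());
    if (i >= (int)s.occ.size()) i = (int)s.occ.size() - 1;
    int idx = s.occ[i];
    s.g[idx] = 2; --s.nw; ++s.nm;                 // replace wt with mutant
    while (s.nm > 0 && s.nw > 0) s.step();
    if (s.nm == 0) n_loss += 1;
    else if (s.nw == 0 && s.nm > 0) n_fix += 1;
    else n_ext += 1;
  }
  return List::create(_["n_fixed"] = n_fix, _["n_lost"] = n_loss,
                      _["n_extinct"] = n_ext, _["n_pre_extinct"] = n_pre_ext,
                      _["mean_M_at_seeding"] =
                        n_runs > n_pre_ext ? seed_M_acc / (n_runs - n_pre_ext)
                                           : NA_REAL);
}

// De-novo mutation time series on the grid: counts sampled every
// sample_every steps.
// [[Rcpp::export]]
NumericMatrix cpp_spatial_mutation(double Rw, double Dw, double Rm, double Dm,
                                   double mu, int n, int M0, int t_steps,
                                   int sample_every) {
  SpatialSystem s(n, Rw, Dw, Rm, Dm, mu);
  s.clear();
  s.seed_random(M0, 1);
  int n_samp = t_steps / sample_every + 1;
  NumericMatrix out(n_samp, 3);
  int isamp = 0;
  for (int t = 0; t <= t_steps; ++t) {
    if (t % sample_every == 0 && isamp < n_samp) {
      out(isamp, 0) = t;
      out(isamp, 1) = (double)s.nw;
      out(isamp, 2) = (double)s.nm;
      ++isamp;
    }
    s.step();
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// 8-neighbour table entry for one spot (1-based index in, 1-based out);
// used to verify torus adjacency from R.
// [[Rcpp::export]]
IntegerVector cpp_spatial_neighbors(int n, int idx1) {
  SpatialSystem s(n, 0, 0, 0, 0, 0);
  IntegerVector out(8);
  for (int d = 0; d < 8; ++d) out[d] = s.nbr(idx1 - 1, d) + 1;
  return out;
}
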