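#include <Rcpp.h>
using namespace Rcpp;

// Event-driven core for the deme-structured logistic birth-death model.
// Only the default density shapes b(x) = [1 - x/K]_+, delta(x) = 1 are
// implemented here; generalized shapes go through the R-level stepper and
// the exact solvers.

namespace {

struct DemeSystem {
  int D, K;
  double rw, dw, rm, dm, eps, mu;
  bool crowd;                 // crowd-controlled migration: abort into full demes
  std::vector<int> x, y;
  std::vector<double> Ai;
  double A;
  long X, Y;                  // running totals of the two types
  long ev;                    // events since the last full propensity refresh

  DemeSystem(int D_, int K_, double rw_, double dw_, double rm_, double dm_,
             double eps_, double mu_, bool crowd_)
    : D(D_), K(K_), rw(rw_), dw(dw_), rm(rm_), dm(dm_), eps(eps_), mu(mu_),
      crowd(crowd_), x(D_, 0), y(D_, 0), Ai(D_, 0.0), A(0.0), X(0), Y(0),
      ev(0) {}

  double bracket(int k) const {
    double b = 1.0 - double(x[k] + y[k]) / K;
    return b > 0 ? b : 0.0;
  }
  double prop(int k) const {
    return (rw * x[k] + rm * y[k]) * bracket(k) + dw * x[k] + dm * y[k];
  }
  void refresh() {
    A = 0.0;
    for (int i = 0; i < D; ++i) { Ai[i] = prop(i); A += Ai[i]; }
    ev = 0;
  }
  void reset_full() {
    X = 0; Y = 0;
    for (int i = 0; i < D; ++i) { x[i] = K; y[i] = 0; X += K; }
    refresh();
  }
  void upd(int k) {
    A -= Ai[k];
    Ai[k] = prop(k);
    A += Ai[k];
  }
  // offspring of a division in deme k; applies migration and mutation rules
  void place_offspring(int k, bool mutant) {
    if (mu > 0 && !mutant && unif_rand() < mu) mutant = true;
    if (eps > 0 && unif_rand() < eps) {
      if (D == 1) return;                        // "another deme" excludes self
      int j = (int)(unif_rand() * (D - 1));
      if (j >= D - 1) j = D - 2;
      if (j >= k) ++j;
      if (crowd && x[j] + y[j] >= K) return;     // target full: event aborted
      if (mutant) { ++y[j]; ++Y; } else { ++x[j]; ++X; }
      upd(j);
    } else {
      if (mutant) { ++y[k]; ++Y; } else { ++x[k]; ++X; }
      upd(k);
    }
  }
  // one update of the embedded jump chain; caller must ensure A > 0.
  // A single uniform variate selects the deme and, through its remainder
  // (rescaled to the freshly computed per-deme total), the event within the
  // deme -- distributionally identical to independent hierarchical draws.
  void step() {
    if (++ev >= 16384) refresh();                // cap incremental FP drift
    double u = unif_rand() * A;
    int k = 0;
    double c = 0.0;
    while (c + Ai[k] < u && k < D - 1) { c += Ai[k]; ++k; }
    double b  = bracket(k);
    double bw = rw * x[k] * b;
    double dx = dw * x[k];
    double bm = rm * y[k] * b;
    double dy = dm * y[k];
    double tot = bw + dx + bm + dy;
    if (tot <= 0 || Ai[k] <= 0) { refresh(); return; }  // stale propensity
    double u2 = (u - c) * (tot / Ai[k]);
    if (u2 >= tot) u2 = tot * 0.9999999;
    if (u2 < bw) {
      place_offspring(k, false);
    } else if (u2 < bw + dx) {
      --x[k]; --X; upd(k);
    } else if (u2 < bw + dx + bm) {
      place_offspring(k, true);
    } else {
      --y[k]; --Y; upd(k);
    }
  }
  bool all_full() const {
    for (int i = 0; i < D; ++i) if (x[i] + y[i] < K) return false;
    return true;
  }
};

} // namespace

// Full fixation-experiment protocol: burn-in from all-demes-at-K, seed one
// mutant into a deme below carrying capacity, run to monomorphism.
// [[Rcpp::export]]
List cpp_deme_fixation(double rw, double dw, double rm, double dm,
                       int K, int D, double eps, bool crowd,
                       int n_runs, double burn_in) {
  DemeSystem s(D, K, rw, dw, rm, dm, eps, 0.0, crowd);
  double n_fix = 0, n_loss = 0, n_ext = 0, n_restart = 0;
  for (int run = 0; run < n_runs; ++run) {
    if (run % 256 == 0) Rcpp::checkUserInterrupt();
    s.reset_full();
    for (double e = 0; e < burn_in; e += 1) {
      if (s.A <= 0) { n_restart += 1; s.reset_full(); e = -1; continue; }
      s.step();
    }
    // seed: redraw-with-replacement; if every deme is full, advance one event
    bool seeded = false;
    while (!seeded) {
      if (s.all_full()) {
        if (s.A <= 0) break;                     // cannot happen for d > 0
        s.step();
        continue;
      }
      int j = (int)(unif_rand() * D);
      if (j >= D) j = D - 1;
      if (s.x[j] + s.y[j] < K) {
        ++s.y[j]; ++s.Y; s.upd(j);
        seeded = true;
      }
    }
    if (!seeded) { n_ext += 1; continue; }
    for (;;) {
      if (s.Y == 0) { n_loss += 1; break; }
      if (s.X == 0) { n_fix  += 1; break; }
      if (s.A <= 0) { n_ext  += 1; break; }
      s.step();
    }
  }
  return List::create(_["n_fixed"] = n_fix, _["n_lost"] = n_loss,
                      _["n_extinct"] = n_ext,
                      _["n_burn_restarts"] = n_restart);
}

// Isolated-deme invasion from a fixed initial state (Monte Carlo counterpart
// of the exact first-step solve).
// [[Rcpp::export]]
List cpp_isolated_invasion(double rw, double dw, double rm, double dm,
                           int K, int x0, int y0, int n_runs) {
  DemeSystem s(1, K, rw, dw, rm, dm, 0.0, 0.0, true);
  double n_fix = 0, n_loss = 0;
  for (int run = 0; run < n_runs; ++run) {
    if (run % 1024 == 0) Rcpp::checkUserInterrupt();
    s.x[0] = x0; s.y[0] = y0; s.X = x0; s.Y = y0;
    s.refresh();
    for (;;) {
      if (s.Y == 0) { n_loss += 1; break; }      // invader lost first
      if (s.X == 0) { n_fix  += 1; break; }      // deme converted
      s.step();
    }
  }
  return List::create(_["n_fixed"] = n_fix, _["n_lost"] = n_loss);
}

// De-novo mutation time series: all demes start at K wild-type; sampled totals
// every sample_dt time units up to t_max.
// [[Rcpp::export]]
NumericMatrix cpp_deme_mutation(double rw, double dw, double rm, double dm,
                                int K, int D, double eps, double mu, bool crowd,
                                double t_max, double sample_dt) {
  DemeSystem s(D, K, rw, dw, rm, dm, eps, mu, crowd);
  s.reset_full();
  int n_samp = (int)(t_max / sample_dt) + 1;
  NumericMatrix out(n_samp, 3);
  double t = 0.0;
  long ev = 0;
  for (int isamp = 0; isamp < n_samp; ++isamp) {
    double tnext = isamp * sample_dt;
    for (;;) {
      if (s.A <= 0) break;                       // whole-population extinction
      double dt = exp_rand() / s.A;
      // if no event falls before the sample time, restart the exponential
      // clock there (memorylessness makes this exact)
      if (t + dt >= tnext) { t = tnext; break; }
      t += dt;
      s.step();
      if (++ev % 262144 == 0) Rcpp::checkUserInterrupt();
    }
    out(isamp, 0) = tnext;
    out(isamp, 1) = (double)s.X;
    out(isamp, 2) = (double)s.Y;
  }
  return out;
}

// Expected-holding-time occupancy weights of a single-type isolated deme,
// for comparison against the quasi-stationary distribution.  Weight of
// occupancy n accumulates 1/A per visit (the conditional mean sojourn).
// [[Rcpp::export]]
NumericVector cpp_deme_occupancy_weights(double rw, double dw, int K,
                                         double n_events, double burn_in) {
  DemeSystem s(1, K, rw, dw, rw, dw, 0.0, 0.0, true);
  s.x[0] = K; s.X = K;
  s.refresh();
  NumericVector w(K + 1);
  for (double e = 0; e < burn_in; e += 1) {
    if (s.A <= 0) { s.x[0] = K; s.X = K; s.refresh(); }
    s.step();
  }
  for (double e = 0; e < n_events; e += 1) {
    if (s.A <= 0) { s.x[0] = K; s.X = K; s.refresh(); continue; }
    w[s.x[0]] += 1.0 / s.A;
    s.step();
    if (((long)e) % 262144 == 0) Rcpp::checkUserInterrupt();
  }
  return w;
}
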