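#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gillespie direct method. Reactions are described by reactant indices
// r1, r2 (0-based; r2 = -1 for order 1), a homodimer flag, propensity
// constants cj, and sparse stoichiometric update lists (species index +
// integer delta per reaction). The R random number stream supplies both the
// exponential waiting times and the reaction choices, so a trajectory is a
// pure function of the R RNG state at entry.

struct NetworkView {
  int n_species, n_reactions;
  std::vector<int> r1, r2;
  std::vector<bool> homo;
  std::vector<double> cj;
  // per-reaction update lists
  std::vector< std::vector<int> > up_sp;
  std::vector< std::vector<double> > up_dx;
  // per-species list of reactions whose propensity depends on it
  std::vector< std::vector<int> > dep;

  NetworkView(IntegerVector r1_, IntegerVector r2_, LogicalVector homo_,
              NumericVector cj_, IntegerMatrix S) {
    n_reactions = r1_.size();
    n_species = S.nrow();
    r1.assign(r1_.begin(), r1_.end());
    r2.assign(r2_.begin(), r2_.end());
    homo.resize(n_reactions);
    for (int j = 0; j < n_reactions; j++) homo[j] = homo_[j];
    cj.assign(cj_.begin(), cj_.end());
    up_sp.resize(n_reactions);
    up_dx.resize(n_reactions);
    dep.assign(n_species, std::vector<int>());
    for (int j = 0; j < n_reactions; j++) {
      for (int i = 0; i < n_species; i++) {
        if (S(i, j) != 0) {
          up_sp[j].push_back(i);
          up_dx[j].push_back((double) S(i, j));
        }
      }
    }
    for (int j = 0; j < n_reactions; j++) {
      dep[r1[j]].push_back(j);
      if (r2[j] >= 0 && r2[j] != r1[j]) dep[r2[j]].push_back(j);
    }
  }

  inline double propensity(int j, const std::vector<double>& x) const {
    if (r2[j] < 0) return cj[j] * x[r1[j]];
    if (homo[j])   return cj[j] * x[r1[j]] * (x[r1[j]] - 1.0) * 0.5;
    return cj[j] * x[r1[j]] * x[r2[j]];
  }
};

static inline double sum_all(const std::vector<double>& a) {
  double s = 0.0;
  for (size_t j = 0; j < a.size(); j++) s += a[j];
  return s;
}

// [[Rcpp::export(name = ".ssa_simulate_cpp")]]
List ssa_simulate_cpp(IntegerVector r1, IntegerVector r2, LogicalVector homo,
                      NumericVector cj, IntegerMatrix S, NumericVector x0,
                      double t_end, double max_events) {
  NetworkView nv(r1, r2, homo, cj, S);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(nv.n_reactions);
  for (int j = 0; j < nv.n_reactions; j++) a[j] = nv.propensity(j, x);

  std::vector<double> times;
  std::vector<int> which;
  double t = 0.0;
  RNGScope scope;
  while (true) {
    double a0 = sum_all(a);
    if (a0 <= 0.0) break;          // absorbing state persists to t_end
    t += exp_rand() / a0;
    if (t > t_end) break;
    double u = unif_rand() * a0;
    int j = 0;
    double acc = a[0];
    while (acc < u && j < nv.n_reactions - 1) acc += a[++j];
    for (size_t q = 0; q < nv.up_sp[j].size(); q++)
      x[nv.up_sp[j][q]] += nv.up_dx[j][q];
    for (size_t q = 0; q < nv.up_sp[j].size(); q++) {
      int sp = nv.up_sp[j][q];
      for (size_t d = 0; d < nv.dep[sp].size(); d++) {
        int jj = nv.dep[sp][d];
        a[jj] = nv.propensity(jj, x);
      }
    }
    times.push_back(t);
    which.push_back(j + 1);
    if ((double) times.size() >= max_events)
      stop("event cap exceeded (%g events before t = %g)", max_events, t);
  }
  return List::create(_["times"] = wrap(times), _["reactions"] = wrap(which));
}

// Fused simulate-and-measure pass used by the volume scan: identical event
// loop and RNG consumption as ssa_simulate_cpp, but instead of storing the
// trace it accumulates, per species, exact time-weighted first and second
// moments over [0, w_stats] and [0, w_psd], the frequency of change (events
// in (0, w_stats] that alter the species), and a zero-order-hold sample
// matrix at step sample_dt for the tracked species.
// [[Rcpp::export(name = ".ssa_scan_cpp")]]
List ssa_scan_cpp(IntegerVector r1, IntegerVector r2, LogicalVector homo,
                  NumericVector cj, IntegerMatrix S, NumericVector x0,
                  double t_end, double w_stats, double w_psd,
                  IntegerVector track, double sample_dt, int n_samples,
                  double max_events) {
  NetworkView nv(r1, r2, homo, cj, S);
  int n = nv.n_species;
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> a(nv.n_reactions);
  for (int j = 0; j < nv.n_reactions; j++) a[j] = nv.propensity(j, x);

  std::vector<double> sumT_s(n, 0.0), sumT2_s(n, 0.0);
  std::vector<double> sumT_p(n, 0.0), sumT2_p(n, 0.0);
  std::vector<double> last_t(n, 0.0);
  std::vector<double> fc(n, 0.0);
  double n_events = 0.0;

  int n_track = track.size();
  NumericMatrix samples(n_samples > 0 ? n_samples : 0, n_track);
  int ns = 0;

  RNGScope scope;
  double t = 0.0;
  while (true) {
    double a0 = sum_all(a);
    double t_next;
    if (a0 <= 0.0) t_next = t_end + 1.0;
    else           t_next = t + exp_rand() / a0;

    // emit samples strictly before the next event (post-event value applies
    // at the event instant itself: half-open plateau convention)
    while (ns < n_samples) {
      double ts = ns * sample_dt;
      if (ts >= t_next || ts > t_end) break;
      for (int q = 0; q < n_track; q++) samples(ns, q) = x[track[q]];
      ns++;
    }
    if (t_next > t_end) break;
    t = t_next;

    double u = unif_rand() * a0;
    int j = 0;
    double acc = a[0];
    while (acc < u && j < nv.n_reactions - 1) acc += a[++j];

    // flush time-weighted accumulators for touched species, then update
    for (size_t q = 0; q < nv.up_sp[j].size(); q++) {
      int sp = nv.up_sp[j][q];
      double dt_s = std::min(t, w_stats) - std::min(last_t[sp], w_stats);
      if (dt_s > 0) { sumT_s[sp] += x[sp] * dt_s; sumT2_s[sp] += x[sp] * x[sp] * dt_s; }
      double dt_p = std::min(t, w_psd) - std::min(last_t[sp], w_psd);
      if (dt_p > 0) { sumT_p[sp] += x[sp] * dt_p; sumT2_p[sp] += x[sp] * x[sp] * dt_p; }
      last_t[sp] = t;
      if (t <= w_stats) fc[sp] += 1.0;
      x[sp] += nv.up_dx[j][q];
    }
    for (size_t q = 0; q < nv.up_sp[j].size(); q++) {
      int sp = nv.up_sp[j][q];
      for (size_t d = 0; d < nv.dep[sp].size(); d++) {
        int jj = nv.dep[sp][d];
        a[jj] = nv.propensity(jj, x);
      }
    }
    n_events += 1.0;
    if (n_events >= max_events)
      stop("event cap exceeded (%g events before t = %g)", max_events, t);
  }
  // flush accumulators to the window ends
  for (int sp = 0; sp < n; sp++) {
    double dt_s = w_stats - std::min(last_t[sp], w_stats);
    if (dt_s > 0) { sumT_s[sp] += x[sp] * dt_s; sumT2_s[sp] += x[sp] * x[sp] * dt_s; }
    double dt_p = w_psd - std::min(last_t[sp], w_psd);
    if (dt_p > 0) { sumT_p[sp] += x[sp] * dt_p; sumT2_p[sp] += x[sp] * x[sp] * dt_p; }
  }
  NumericVector mean_s(n), var_s(n), mean_p(n), var_p(n);
  for (int sp = 0; sp < n; sp++) {
    double m = sumT_s[sp] / w_stats;
    mean_s[sp] = m;
    var_s[sp] = std::max(sumT2_s[sp] / w_stats - m * m, 0.0);
    double mp = sumT_p[sp] / w_psd;
    mean_p[sp] = mp;
    var_p[sp] = std::max(sumT2_p[sp] / w_psd - mp * mp, 0.0);
  }
  return List::create(
    _["samples"] = samples, _["mean_stats"] = mean_s, _["var_stats"] = var_s,
    _["mean_psd"] = mean_p, _["var_psd"] = var_p, _["fc"] = wrap(fc),
    _["n_events"] = n_events, _["x_final"] = wrap(x));
}
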