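// Stochastic simulation backends for the SIR epidemic with preventive
// dropping of edges on configuration-model networks.
//
// Two exact backends are provided:
//   * the effective-degree Markov chain, in which the network is paired up
//     only as transmission/warning events occur (states: susceptibles and
//     infectives by number of unpaired stubs, plus recovered stubs);
//   * an explicit-graph backend that pairs all stubs first (self-loops and
//     multi-edges retained) and runs the per-edge dynamics.
// Both consume R's RNG stream so that set.seed() in R controls everything.

#include <Rcpp.h>
using namespace Rcpp;

static inline double runif01() { return unif_rand(); }

// pick index in [0, n) proportional to w[i] (w >= 0, sum > 0), linear scan
static int pick_weighted(const std::vector<double>& w, double total) {
  double u = runif01() * total;
  double acc = 0.0;
  int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    acc += w[i];
    if (u <= acc) return i;
  }
  return n - 1;
}

struct EffdegResult {
  std::vector<int> x_final;
  int final_size;
  double ext_time;
};

// Core effective-degree Gillespie run.
// x, y: counts of susceptibles/infectives by effective degree 0..M (modified
// in place). Returns when no infective stub can ever pair again and (if
// gamma > 0) all infectives have recovered.
static EffdegResult run_effdeg(std::vector<int> x, std::vector<int> y,
                               double beta, double gamma, double omega,
                               bool record,
                               std::vector<double>* t_rec,
                               std::vector<double>* yn_rec,
                               std::vector<double>* xn_rec,
                               std::vector<double>* ye_rec) {
  const int M = (int)x.size() - 1;
  long nx = 0, ny = 0, z = 0;
  long xsum = 0, ysum = 0;
  for (int i = 0; i <= M; ++i) {
    nx += (long)i * x[i];
    ny += (long)i * y[i];
    xsum += x[i];
    ysum += y[i];
  }
  int infected = (int)ysum;  // initial infectives count towards final size
  double t = 0.0;
  const double bw = beta + omega;
  std::vector<double> w(M + 1);

  auto rec = [&]() {
    if (record) {
      t_rec->push_back(t);
      yn_rec->push_back((double)ysum);
      xn_rec->push_back((double)xsum);
      ye_rec->push_back((double)ny);
    }
  };
  rec();

  for (;;) {
    long tot = nx + ny + z;
    double rate_act = (ny > 0 && tot >= 2) ? bw * (double)ny : 0.0;
    double rate_rec = gamma * (double)ysum;
    double total = rate_act + rate_rec;
    if (total <= 0.0) {
      if (ysum > 0) t = R_PosInf;  // gamma = 0 and no pairable stubs
      break;
    }
    t += exp_rand() / total;
    if (runif01() * total < rate_act) {
      // an infective stub activates: pick actor type i prop. to i*y_i
      for (int i = 0; i <= M; ++i) w[i] = (double)i * y[i];
      int i = pick_weighted(w, (double)ny);
      bool infection = (runif01() * bw < beta);
      // partner stub uniform among the tot-1 other stubs
      double u = runif01() * (double)(tot - 1);
      // category scan: susceptible stubs, recovered stubs, own stubs,
      // other infective stubs
      if (u < (double)nx) {
        // partner is a type-j susceptible stub
        for (int j = 0; j <= M; ++j) w[j] = (double)j * x[j];
        int j = pick_weighted(w, (double)nx);
        y[i]--; y[i - 1]++;
        x[j]--; nx -= j; xsum--;
        if (infection) {
          y[j - 1]++; ysum++; infected++;
          ny += (j - 1) - 1;
        } else {
          x[j - 1]++; xsum++;
          nx += j - 1;
          ny -= 1;
        }
      } else if (u < (double)(nx + z)) {
        // partner is a recovered stub: edge formed, both consumed
        y[i]--; y[i - 1]++;
        z--; ny--;
      } else if (u < (double)(nx + z + (i - 1))) {
        // self-pairing: actor pairs two of its own stubs
        y[i]--; y[i - 2]++;
        ny -= 2;
      } else {
        // partner is another infective's stub (type j, excluding the
        // actor's own stubs)
        for (int j = 0; j <= M; ++j)
          w[j] = (double)j * y[j] - (j == i ? (double)i : 0.0);
        int j = pick_weighted(w, (double)(ny - i));
        y[i]--; y[i - 1]++;
        y[j]--; y[j - 1]++;
        ny -= 2;
      }
    } else {
      // recovery: pick type i prop. to y_i
      for (int i = 0; i <= M; ++i) w[i] = (double)y[i];
      int i = pick_weighted(w, (double)ysum);
      y[i]--; ysum--;
      z += i; ny -= i;
    }
    rec();
    if (ysum == 0) break;
  }

  EffdegResult res;
  res.x_final = x;
  res.final_size = infected;
  res.ext_time = t;
  return res;
}

// [[Rcpp::export]]
List sim_effdeg_cpp(IntegerVector x0, IntegerVector y0, double beta,
                    double gamma, double omega, bool record) {
  std::vector<int> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> tr, yr, xr, yer;
  EffdegResult r = run_effdeg(x, y, beta, gamma, omega, record,
                              &tr, &yr, &xr, &yer);
  List out = List::create(
    _["x_final"] = IntegerVector(r.x_final.begin(), r.x_final.end()),
    _["final_size"] = r.final_size,
    _["extinction_time"] = r.ext_time);
  if (record) {
    out["trajectory"] = DataFrame::create(
      _["time"] = NumericVector(tr.begin(), tr.end()),
      _["infectives"] = NumericVector(yr.begin(), yr.end()),
      _["susceptibles"] = NumericVector(xr.begin(), xr.end()),
      _["infective_stubs"] = NumericVector(yer.begin(), yer.end()));
  }
  return out;
}

// Ensemble of effective-degree runs. For NSW graphs, each replicate draws N
// iid degrees from pmf and infects i0 individuals chosen uniformly at random;
// for MR graphs the fixed initial counts (x0, y0) are reused.
// [[Rcpp::export]]
NumericMatrix sim_effdeg_ensemble_cpp(NumericVector pmf, int N, int i0,
                                      bool nsw, IntegerVector x0,
                                      IntegerVector y0, double beta,
                                      double gamma, double omega, int reps) {
  NumericMatrix out(reps, 2);
  const int M = nsw ? (pmf.size() - 1) : (x0.size() - 1);
  std::vector<double> cum;
  if (nsw) {
    cum.resize(pmf.size());
    double a = 0.0;
    for (int k = 0; k < pmf.size(); ++k) { a += pmf[k]; cum[k] = a; }
    cum[pmf.size() - 1] = 1.0;
  }
  for (int r = 0; r < reps; ++r) {
    std::vector<int> x(M + 1, 0), y(M + 1, 0);
    if (nsw) {
      std::vector<int> deg(N);
      for (int v = 0; v < N; ++v) {
        double u = runif01();
        int k = 0;
        while (cum[k] < u) ++k;
        deg[v] = k;
      }
      // choose i0 distinct initial infectives uniformly (partial shuffle)
      for (int j = 0; j < i0; ++j) {
        int pick = j + (int)std::floor(runif01() * (N - j));
        if (pick >= N) pick = N - 1;
        std::swap(deg[j], deg[pick]);
      }
      for (int v = 0; v < N; ++v) {
        if (v < i0) y[deg[v]]++; else x[deg[v]]++;
      }
    } else {
      x.assign(x0.begin(), x0.end());
      y.assign(y0.begin(), y0.end());
    }
    EffdegResult res = run_effdeg(x, y, beta, gamma, omega, false,
                                  nullptr, nullptr, nullptr, nullptr);
    out(r, 0) = res.final_size;
    out(r, 1) = res.ext_time;
  }
  return out;
}

// Explicit-graph backend: pair all stubs uniformly at random (a left-over
// stub when the total is odd is ignored; self-loops and multi-edges kept),
// then run per-edge dynamics: infection at rate beta and dropping at rate
// omega on each susceptible-infective edge, recovery at rate gamma.
// [[Rcpp::export]]
List sim_graph_cpp(IntegerVector degrees, IntegerVector init_infective,
                   double beta, double gamma, double omega) {
  const int N = degrees.size();
  std::vector<int> stubs;
  for (int v = 0; v < N; ++v)
    for (int d = 0; d < degrees[v]; ++d) stubs.push_back(v);
  // Fisher-Yates shuffle with R's RNG
  for (int i = (int)stubs.size() - 1; i > 0; --i) {
    int j = (int)std::floor(runif01() * (i + 1));
    if (j > i) j = i;
    std::swap(stubs[i], stubs[j]);
  }
  int nedge = (int)stubs.size() / 2;  // odd left-over stub ignored
  std::vector<int> eu(nedge), ev(nedge);
  std::vector<bool> alive(nedge, true);
  std::vector<int> si_pos(nedge, -1);     // index in SI set, or -1
  std::vector<std::vector<int>> inc(N);   // incident edge ids
  for (int e = 0; e < nedge; ++e) {
    eu[e] = stubs[2 * e]; ev[e] = stubs[2 * e + 1];
    inc[eu[e]].push_back(e);
    if (ev[e] != eu[e]) inc[ev[e]].push_back(e);
  }

  std::vector<int> status(N, 0);  // 0 = S, 1 = I, 2 = R
  std::vector<int> inf_ids; inf_ids.reserve(N);
  std::vector<int> inf_pos(N, -1);
  for (int j = 0; j < init_infective.size(); ++j) {
    int v = init_infective[j];
    status[v] = 1;
    inf_pos[v] = (int)inf_ids.size();
    inf_ids.push_back(v);
  }
  int infected = (int)inf_ids.size();

  std::vector<int> si;  // SI edge ids
  auto is_si = [&](int e) {
    if (!alive[e] || eu[e] == ev[e]) return false;
    int a = status[eu[e]], b = status[ev[e]];
    return (a == 0 && b == 1) || (a == 1 && b == 0);
  };
  auto si_add = [&](int e) {
    if (si_pos[e] >= 0) return;
    si_pos[e] = (int)si.size();
    si.push_back(e);
  };
  auto si_remove = [&](int e) {
    int p = si_pos[e];
    if (p < 0) return;
    int last = si.back();
    si[p] = last; si_pos[last] = p;
    si.pop_back(); si_pos[e] = -1;
  };
  auto refresh_edges_of = [&](int v) {
    for (int e : inc[v]) {
      if (is_si(e)) si_add(e); else si_remove(e);
    }
  };
  for (int e = 0; e < nedge; ++e) if (is_si(e)) si_add(e);

  double t = 0.0;
  while (!inf_ids.empty()) {
    double rate_si = (beta + omega) * (double)si.size();
    double rate_rec = gamma * (double)inf_ids.size();
    double total = rate_si + rate_rec;
    if (total <= 0.0) { t = R_PosInf; break; }
    t += exp_rand() / total;
    if (runif01() * total < rate_si) {
      int e = si[(int)std::floor(runif01() * si.size())];
      if (runif01() * (beta + omega) < beta) {
        // transmission along e: the susceptible endpoint becomes infective
        int s = (status[eu[e]] == 0) ? eu[e] : ev[e];
        status[s] = 1;
        inf_pos[s] = (int)inf_ids.size();
        inf_ids.push_back(s);
        ++infected;
        refresh_edges_of(s);
      } else {
        // the susceptible endpoint drops the edge
        alive[e] = false;
        si_remove(e);
      }
    } else {
      int idx = (int)std::floor(runif01() * inf_ids.size());
      int v = inf_ids[idx];
      int last = inf_ids.back();
      inf_ids[idx] = last; inf_pos[last] = idx;
      inf_ids.pop_back(); inf_pos[v] = -1;
      status[v] = 2;
      refresh_edges_of(v);
    }
  }
  return List::create(_["final_size"] = infected, _["extinction_time"] = t);
}

// [[Rcpp::export]]
NumericMatrix sim_graph_ensemble_cpp(NumericVector pmf, int N, int i0,
                                     bool nsw, IntegerVector degrees_mr,
                                     double beta, double gamma, double omega,
                                     int reps) {
  NumericMatrix out(reps, 2);
  std::vector<double> cum(pmf.size());
  double a = 0.0;
  for (int k = 0; k < pmf.size(); ++k) { a += pmf[k]; cum[k] = a; }
  cum[pmf.size() - 1] = 1.0;
  for (int r = 0; r < reps; ++r) {
    IntegerVector deg(N);
    if (nsw) {
      for (int v = 0; v < N; ++v) {
        double u = runif01();
        int k = 0;
        while (cum[k] < u) ++k;
        deg[v] = k;
      }
    } else {
      deg = clone(degrees_mr);
    }
    // initial infectives chosen uniformly without replacement
    std::vector<int> ids(N);
    for (int v = 0; v < N; ++v) ids[v] = v;
    IntegerVector init(i0);
    for (int j = 0; j < i0; ++j) {
      int pick = j + (int)std::floor(runif01() * (N - j));
      if (pick >= N) pick = N - 1;
      std::swap(ids[j], ids[pick]);
      init[j] = ids[j];
    }
    List res = sim_graph_cpp(deg, init, beta, gamma, omega);
    out(r, 0) = as<double>(res["final_size"]);
    out(r, 1) = as<double>(res["extinction_time"]);
  }
  return out;
}
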