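#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Exact Gillespie direct-method sampler for mass-action networks.
// Propensities use the stochastic falling-factorial convention
// kappa * prod_i x_i (x_i - 1) ... (x_i - m_i + 1) / m_i!.
// Randomness comes from R's generator (unif_rand), so set.seed() on the R
// side makes every trajectory reproducible.
//
// Stopping: the horizon t_end, an event-count guard, or a cap on the total
// propensity (explosion guard). When every propensity vanishes the state is
// absorbed and the remaining grid points are filled with it.
//
// [[Rcpp::export(name = ".ssa_engine")]]
List ssa_engine(NumericVector rates, IntegerMatrix reac, IntegerMatrix net,
                NumericVector x0, double t_end, double max_events,
                double prop_cap, NumericVector grid_times, double burn_in,
                bool record_events, int max_record) {
  const int d = reac.nrow();
  const int K = reac.ncol();
  // sparse reactant / update lists
  std::vector<std::vector<std::pair<int, int>>> need(K);   // (species, mult)
  std::vector<std::vector<std::pair<int, int>>> upd(K);    // (species, delta)
  std::vector<double> fact(K, 1.0);
  for (int k = 0; k < K; ++k) {
    for (int i = 0; i < d; ++i) {
      int m = reac(i, k);
      if (m > 0) {
        need[k].push_back(std::make_pair(i, m));
        for (int j = 2; j <= m; ++j) fact[k] *= j;
      }
      if (net(i, k) != 0) upd[k].push_back(std::make_pair(i, net(i, k)));
    }
  }
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> lam(K);
  const int G = grid_times.size();
  NumericMatrix grid_states(G, d);
  int gi = 0;
  std::vector<double> acc(d, 0.0);
  double acc_time = 0.0;
  double t = 0.0;
  double n_events = 0.0;
  std::string stopped = "horizon";
  std::vector<double> ev_t;
  std::vector<double> ev_x;
  if (record_events) {
    ev_t.reserve(1024);
    ev_x.reserve(1024 * d);
    ev_t.push_back(0.0);
    for (int i = 0; i < d; ++i) ev_x.push_back(x[i]);
  }

  while (t < t_end) {
    double tot = 0.0;
    for (int k = 0; k < K; ++k) {
      double p = rates[k];
      for (size_t q = 0; q < need[k].size(); ++q) {
        int i = need[k][q].first, m = need[k][q].second;
        double xi = x[i];
        if (xi < m) { p = 0.0; break; }
        for (int j = 0; j < m; ++j) p *= (xi - j);
      }
      if (p > 0.0) p /= fact[k];
      lam[k] = p;
      tot += p;
    }
    if (tot > prop_cap) { stopped = "explosion_guard"; break; }
    if (tot <= 0.0) {
      stopped = "absorbed";
      while (gi < G) {
        for (int i = 0; i < d; ++i) grid_states(gi, i) = x[i];
        ++gi;
      }
      double hold = t_end - std::max(t, burn_in);
      if (hold > 0) {
        for (int i = 0; i < d; ++i) acc[i] += x[i] * hold;
        acc_time += hold;
      }
      t = t_end;
      break;
    }
    double dt = -std::log(unif_rand()) / tot;
    double tnew = t + dt;
    double tcap = std::min(tnew, t_end);
    while (gi < G && grid_times[gi] <= tcap) {
      for (int i = 0; i < d; ++i) grid_states(gi, i) = x[i];
      ++gi;
    }
    double lo = std::max(t, burn_in), hi = std::min(tcap, t_end);
    if (hi > lo) {
      for (int i = 0; i < d; ++i) acc[i] += x[i] * (hi - lo);
      acc_time += hi - lo;
    }
    t = tnew;
    if (t >= t_end) { t = t_end; break; }
    double u = unif_rand() * tot;
    double s = 0.0;
    int k = K - 1;
    for (int kk = 0; kk < K; ++kk) {
      s += lam[kk];
      if (s >= u) { k = kk; break; }
    }
    for (size_t q = 0; q < upd[k].size(); ++q)
      x[upd[k][q].first] += upd[k][q].second;
    n_events += 1.0;
    if (record_events && (int)ev_t.size() < max_record) {
      ev_t.push_back(t);
      for (int i = 0; i < d; ++i) ev_x.push_back(x[i]);
    }
    if (n_events >= max_events) { stopped = "max_events"; break; }
  }
  while (stopped == "horizon" && gi < G && grid_times[gi] <= t_end) {
    for (int i = 0; i < d; ++i) grid_states(gi, i) = x[i];
    ++gi;
  }
  NumericVector tavg(d, NA_REAL);
  if (acc_time > 0) {
    tavg = NumericVector(d);
    for (int i = 0; i < d; ++i) tavg[i] = acc[i] / acc_time;
  }
  NumericVector xfin(d);
  for (int i = 0; i < d; ++i) xfin[i] = x[i];
  List out = List::create(
    _["t_final"] = t, _["x_final"] = xfin, _["n_events"] = n_events,
    _["stopped"] = stopped, _["grid_states"] = grid_states,
    _["grid_filled"] = gi, _["time_average"] = tavg,
    _["tavg_time"] = acc_time);
  if (record_events) {
    int ne = ev_t.size();
    NumericMatrix em(ne, d);
    for (int r = 0; r < ne; ++r)
      for (int i = 0; i < d; ++i) em(r, i) = ev_x[(size_t)r * d + i];
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_states"] = em;
  }
  return out;
}
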