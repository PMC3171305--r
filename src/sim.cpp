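// Simulation cores: Gillespie direct method (DM), Gibson-Bruck next reaction
// method (NRM), and their importance-sampling weighted variants (wSSA, wNRM).
//
// All four share the same trajectory contract: start at x0, stop when the
// rare-event region is reached or when t exceeds the horizon T.  Weighted
// variants bias only the reaction-selection probabilities; the inter-event
// time law Exponential(a0(x)) is preserved (weighted NRM uses putative rates
// d_m = q_m * a0 so that sum(d) == a0).  Trajectory weights accumulate in
// log-space and are exponentiated once on success.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// network, event and scheme descriptors (prepared by R wrappers)

struct Net {
  int M, N;
  std::vector<int> s1, s2;      // 0-based reactant species slots (-1 = none)
  std::vector<int> order;       // total reactant order: 0, 1, 2
  std::vector<int> dimer;       // 1 if two identical reactant molecules
  std::vector<double> rate;
  std::vector<std::vector<int> > nu;   // per-reaction sparse state change
  std::vector<std::vector<int> > nuv;
  std::vector<std::vector<int> > dep;  // dependency graph, 0-based
};

static Net make_net(const List& sys) {
  Net net;
  IntegerMatrix nu = sys["nu"];          // M x N
  net.M = nu.nrow();
  net.N = nu.ncol();
  net.s1 = as<std::vector<int> >(sys["s1"]);
  net.s2 = as<std::vector<int> >(sys["s2"]);
  net.order = as<std::vector<int> >(sys["order"]);
  net.dimer = as<std::vector<int> >(sys["dimer"]);
  net.rate = as<std::vector<double> >(sys["rate"]);
  net.nu.resize(net.M);
  net.nuv.resize(net.M);
  for (int m = 0; m < net.M; ++m) {
    for (int s = 0; s < net.N; ++s) {
      if (nu(m, s) != 0) {
        net.nu[m].push_back(s);
        net.nuv[m].push_back(nu(m, s));
      }
    }
  }
  List dep = sys["dep"];
  net.dep.resize(net.M);
  for (int m = 0; m < net.M; ++m)
    net.dep[m] = as<std::vector<int> >(dep[m]);
  return net;
}

static inline double propensity1(const Net& net, const std::vector<int>& x,
                                 int m) {
  const double c = net.rate[m];
  switch (net.order[m]) {
  case 0:
    return c;
  case 1:
    return c * x[net.s1[m]];
  default:
    if (net.dimer[m]) {
      const double xx = x[net.s1[m]];
      return c * xx * (xx - 1.0) / 2.0;
    }
    return c * (double)x[net.s1[m]] * (double)x[net.s2[m]];
  }
}

struct Event {
  int target;     // 0-based species index
  double theta;
  int sgn;        // sign(eta)
  int exact_hit;  // 1: Omega = {X_i == theta}; 0: first crossing
  double T;
  bool in_omega(const std::vector<int>& x) const {
    if (exact_hit) return x[target] == theta;
    return sgn * (x[target] - theta) >= 0;
  }
};

static Event make_event(const List& ev) {
  Event e;
  e.target = as<int>(ev["target"]);
  e.theta = as<double>(ev["theta"]);
  e.sgn = as<int>(ev["sgn"]);
  e.exact_hit = as<int>(ev["exact_hit"]);
  e.T = as<double>(ev["T"]);
  return e;
}

// scheme type codes
enum { SCH_NATURAL = 0, SCH_GAMMA = 1, SCH_GROUP = 2, SCH_SCALED = 3 };

struct Scheme {
  int type;
  std::vector<double> gamma;   // SCH_GAMMA
  std::vector<int> grp;        // SCH_GROUP: 0-based group per reaction
  std::vector<double> Q;       // SCH_GROUP: per-group target probability
  int G;
  std::vector<double> lambda;  // SCH_SCALED: per-reaction multiplier
  std::vector<int> slack;      // SCH_SCALED: 1 = slack-group member
};

static Scheme make_scheme(const List& sch) {
  Scheme sc;
  sc.type = as<int>(sch["type"]);
  if (sc.type == SCH_GAMMA) sc.gamma = as<std::vector<double> >(sch["gamma"]);
  if (sc.type == SCH_GROUP) {
    sc.grp = as<std::vector<int> >(sch["group"]);
    sc.Q = as<std::vector<double> >(sch["targets"]);
    sc.G = (int)sc.Q.size();
  }
  if (sc.type == SCH_SCALED) {
    sc.lambda = as<std::vector<double> >(sch["lambda"]);
    sc.slack = as<std::vector<int> >(sch["slack"]);
  }
  return sc;
}

// Biased per-reaction probabilities q (sum to 1 whenever a0 > 0).  For the
// group scheme, the target mass of any group whose total propensity is zero
// is redistributed over the live groups in proportion to their targets.
static void scheme_q(const Scheme& sc, const std::vector<double>& a, double a0,
                     std::vector<double>& q) {
  const int M = (int)a.size();
  switch (sc.type) {
  case SCH_NATURAL:
    for (int m = 0; m < M; ++m) q[m] = a[m] / a0;
    return;
  case SCH_GAMMA: {
    double b0 = 0.0;
    for (int m = 0; m < M; ++m) {
      q[m] = sc.gamma[m] * a[m];
      b0 += q[m];
    }
    for (int m = 0; m < M; ++m) q[m] /= b0;
    return;
  }
  case SCH_SCALED: {
    // directional reactions keep their natural state-conditional
    // probabilities scaled by a constant multiplier; the slack group
    // absorbs the remaining mass in proportion to its propensities
    double S = 0.0, slack_sum = 0.0;
    for (int m = 0; m < M; ++m) {
      if (sc.slack[m]) slack_sum += a[m];
      else S += sc.lambda[m] * a[m] / a0;
    }
    if (slack_sum > 0.0 && S < 1.0) {
      for (int m = 0; m < M; ++m)
        q[m] = sc.slack[m] ? (1.0 - S) * a[m] / slack_sum
                           : sc.lambda[m] * a[m] / a0;
    } else {
      // no live slack reaction (or overshoot): renormalize directly
      double b0 = 0.0;
      for (int m = 0; m < M; ++m) {
        q[m] = (sc.slack[m] ? 1.0 : sc.lambda[m]) * a[m];
        b0 += q[m];
      }
      for (int m = 0; m < M; ++m) q[m] /= b0;
    }
    return;
  }
  default: {
    std::vector<double> gs(sc.G, 0.0);
    for (int m = 0; m < M; ++m) gs[sc.grp[m]] += a[m];
    double qtot = 0.0;
    for (int g = 0; g < sc.G; ++g)
      if (gs[g] > 0.0) {
        if (sc.Q[g] <= 0.0)
          stop("bias scheme assigns zero probability to a group with positive propensity (absolute continuity violated)");
        qtot += sc.Q[g];
      }
    for (int m = 0; m < M; ++m) {
      const int g = sc.grp[m];
      q[m] = (gs[g] > 0.0) ? (sc.Q[g] / qtot) * a[m] / gs[g] : 0.0;
    }
    return;
  }
  }
}

// ---------------------------------------------------------------------------
// indexed priority queue: binary min-heap over putative firing times with
// ties broken by the lowest reaction index

struct IPQ {
  std::vector<int> heap, pos;
  const std::vector<double>* key;
  void init(const std::vector<double>& k) {
    key = &k;
    int M = (int)k.size();
    heap.resize(M);
    pos.resize(M);
    for (int i = 0; i < M; ++i) { heap[i] = i; pos[i] = i; }
    for (int i = M / 2 - 1; i >= 0; --i) sift_down(i);
  }
  bool less(int a, int b) const {
    const double ka = (*key)[a], kb = (*key)[b];
    if (ka != kb) return ka < kb;
    return a < b;
  }
  void swap_at(int i, int j) {
    std::swap(heap[i], heap[j]);
    pos[heap[i]] = i;
    pos[heap[j]] = j;
  }
  void sift_up(int i) {
    while (i > 0) {
      int p = (i - 1) / 2;
      if (less(heap[i], heap[p])) { swap_at(i, p); i = p; } else break;
    }
  }
  void sift_down(int i) {
    const int M = (int)heap.size();
    for (;;) {
      int l = 2 * i + 1, r = l + 1, s = i;
      if (l < M && less(heap[l], heap[s])) s = l;
      if (r < M && less(heap[r], heap[s])) s = r;
      if (s == i) break;
      swap_at(i, s);
      i = s;
    }
  }
  void update(int m) { sift_up(pos[m]); sift_down(pos[m]); }
  int top() const { return heap[0]; }
  int scan_min() const {  // full-scan oracle used by self-checks
    int best = 0;
    for (int m = 1; m < (int)heap.size(); ++m)
      if (less(m, best)) best = m;
    return best;
  }
};

// ---------------------------------------------------------------------------
// single-trajectory engines

struct RunOut {
  bool hit;
  double hit_time;
  double logw;
  double t_end;
  std::vector<int> Km;
};

struct StepLog {
  bool enabled = false;
  std::vector<double> t, a0, logw;
  std::vector<int> mu;
  std::vector<double> q;   // steps x M, row-major
  std::vector<int> x;      // steps x N, row-major (state after firing)
  bool heap_ok = true;
};

static inline double rexp_rate(double rate) {
  // ln(1/r)/rate with r ~ U(0,1); matches the printed inversion formula
  return std::log(1.0 / unif_rand()) / rate;
}

// DM / wSSA trajectory.  Draw order per step: r1 for tau, r2 for mu, so the
// natural-scheme weighted run is stream-identical to the plain SSA.
static RunOut dm_core(const Net& net, const Event& ev, const Scheme& sc,
                      std::vector<int> x, bool absorb, StepLog* log) {
  RunOut out;
  out.Km.assign(net.M, 0);
  out.logw = 0.0;
  out.hit = false;
  out.hit_time = NA_REAL;
  double t = 0.0;
  std::vector<double> a(net.M), q(net.M);
  for (;;) {
    if (absorb && ev.in_omega(x)) {
      out.hit = true;
      out.hit_time = t;
      break;
    }
    double a0 = 0.0;
    for (int m = 0; m < net.M; ++m) { a[m] = propensity1(net, x, m); a0 += a[m]; }
    if (a0 <= 0.0) { t = ev.T; break; }     // no-reaction signal: idle to T
    const double tau = rexp_rate(a0);
    t += tau;
    if (t > ev.T) { t = ev.T; break; }
    scheme_q(sc, a, a0, q);
    const double r2 = unif_rand();
    double cum = 0.0;
    int mu = net.M - 1;
    for (int m = 0; m < net.M; ++m) {
      cum += q[m];
      if (cum >= r2) { mu = m; break; }
    }
    if (q[mu] <= 0.0)
      stop("bias scheme assigns zero probability to a reaction with positive propensity (absolute continuity violated)");
    if (sc.type != SCH_NATURAL) out.logw += std::log(a[mu] / a0) - std::log(q[mu]);
    for (size_t k = 0; k < net.nu[mu].size(); ++k) x[net.nu[mu][k]] += net.nuv[mu][k];
    out.Km[mu]++;
    if (log && log->enabled) {
      log->t.push_back(t);
      log->mu.push_back(mu + 1);
      log->a0.push_back(a0);
      log->logw.push_back(out.logw);
      for (int m = 0; m < net.M; ++m) log->q.push_back(q[m]);
      for (int s = 0; s < net.N; ++s) log->x.push_back(x[s]);
    }
  }
  out.t_end = t;
  return out;
}

// NRM / wNRM trajectory with Gibson-Bruck reuse of putative times.
static RunOut nrm_core(const Net& net, const Event& ev, const Scheme& sc,
                       std::vector<int> x, bool absorb, StepLog* log,
                       bool check_heap) {
  RunOut out;
  out.Km.assign(net.M, 0);
  out.logw = 0.0;
  out.hit = false;
  out.hit_time = NA_REAL;
  double t = 0.0;
  const bool weighted = sc.type != SCH_NATURAL;
  std::vector<double> a(net.M), q(net.M), d(net.M), tau(net.M);
  double a0 = 0.0;
  for (int m = 0; m < net.M; ++m) { a[m] = propensity1(net, x, m); a0 += a[m]; }
  if (weighted && a0 > 0.0) {
    scheme_q(sc, a, a0, q);
    for (int m = 0; m < net.M; ++m) d[m] = q[m] * a0;
  } else {
    d = a;
  }
  for (int m = 0; m < net.M; ++m)
    tau[m] = d[m] > 0.0 ? rexp_rate(d[m]) : INF;
  IPQ pq;
  pq.init(tau);
  for (;;) {
    if (absorb && ev.in_omega(x)) {
      out.hit = true;
      out.hit_time = t;
      break;
    }
    const int mu = pq.top();
    if (check_heap && log && pq.scan_min() != mu) log->heap_ok = false;
    const double tmu = tau[mu];
    if (!(tmu <= ev.T)) { t = ev.T; break; }  // covers tau == Inf (all silent)
    if (weighted) out.logw += std::log(a[mu] / d[mu]);
    for (size_t k = 0; k < net.nu[mu].size(); ++k) x[net.nu[mu][k]] += net.nuv[mu][k];
    out.Km[mu]++;
    t = tmu;
    if (log && log->enabled) {
      log->t.push_back(t);
      log->mu.push_back(mu + 1);
      log->a0.push_back(a0);
      log->logw.push_back(out.logw);
      if (weighted) for (int m = 0; m < net.M; ++m) log->q.push_back(q[m]);
      for (int s = 0; s < net.N; ++s) log->x.push_back(x[s]);
    }
    // refresh propensities on the dependency set, then the putative rates
    for (size_t k = 0; k < net.dep[mu].size(); ++k) {
      const int m = net.dep[mu][k];
      const double anew = propensity1(net, x, m);
      a0 += anew - a[m];
      a[m] = anew;
    }
    if (a0 < 1e-12) {
      double chk = 0.0;
      for (int m = 0; m < net.M; ++m) chk += a[m];
      a0 = chk;
    }
    if (weighted) {
      // q_m depends on every propensity, so all putative rates change
      if (a0 > 0.0) {
        scheme_q(sc, a, a0, q);
        for (int m = 0; m < net.M; ++m) {
          const double dnew = q[m] * a0;
          if (m == mu) {
            tau[m] = dnew > 0.0 ? t + rexp_rate(dnew) : INF;
          } else if (d[m] > 0.0 && dnew > 0.0) {
            tau[m] = d[m] / dnew * (tau[m] - t) + t;
          } else if (dnew > 0.0) {
            tau[m] = t + rexp_rate(dnew);
          } else {
            tau[m] = INF;
          }
          d[m] = dnew;
          pq.update(m);
        }
      } else {
        for (int m = 0; m < net.M; ++m) { d[m] = 0.0; tau[m] = INF; pq.update(m); }
      }
    } else {
      for (size_t k = 0; k < net.dep[mu].size(); ++k) {
        const int m = net.dep[mu][k];
        const double dnew = a[m];
        if (m == mu) {
          tau[m] = dnew > 0.0 ? t + rexp_rate(dnew) : INF;
        } else if (d[m] > 0.0 && dnew > 0.0) {
          tau[m] = d[m] / dnew * (tau[m] - t) + t;
        } else if (dnew > 0.0) {
          tau[m] = t + rexp_rate(dnew);
        } else {
          tau[m] = INF;
        }
        d[m] = dnew;
        pq.update(m);
      }
    }
  }
  out.t_end = t;
  return out;
}

enum { M_SSA = 0, M_NRM = 1, M_WSSA = 2, M_WNRM = 3 };

static RunOut sim_run(const Net& net, const Event& ev, const Scheme& sc,
                      int method, const std::vector<int>& x0, bool absorb,
                      StepLog* log, bool check_heap) {
  if (method == M_SSA || method == M_WSSA)
    return dm_core(net, ev, sc, x0, absorb, log);
  return nrm_core(net, ev, sc, x0, absorb, log, check_heap);
}

static int method_code(const std::string& method) {
  if (method == "ssa") return M_SSA;
  if (method == "nrm") return M_NRM;
  if (method == "wssa") return M_WSSA;
  if (method == "wnrm") return M_WNRM;
  stop("unknown method '%s'", method.c_str());
}

// ---------------------------------------------------------------------------
// exported entry points

// [[Rcpp::export]]
List cpp_sim_batch(List sys, List ev, List sch, std::string method, int n,
                   bool absorb, bool record_runs, IntegerVector occ_species) {
  const Net net = make_net(sys);
  const Event event = make_event(ev);
  const Scheme scheme = make_scheme(sch);
  const int mcode = method_code(method);
  const std::vector<int> x0 = as<std::vector<int> >(sys["x0"]);

  double k1 = 0.0, k2 = 0.0;
  int hits = 0;
  NumericVector KT(n);
  NumericVector Km_sum(net.M);
  IntegerMatrix Km_runs;
  NumericVector w_runs, hit_time_runs;
  LogicalVector hit_runs;
  if (record_runs) {
    Km_runs = IntegerMatrix(n, net.M);
    w_runs = NumericVector(n);
    hit_runs = LogicalVector(n);
    hit_time_runs = NumericVector(n);
  }
  // optional occupancy tally: counts of reaction events by the joint pattern
  // of a small set of species (state at the moment the reaction fires)
  const bool do_occ = occ_species.size() > 0;
  std::map<std::vector<int>, double> occ;
  StepLog log;
  log.enabled = do_occ;

  for (int j = 0; j < n; ++j) {
    if (j % 4096 == 0) Rcpp::checkUserInterrupt();
    log.t.clear(); log.mu.clear(); log.a0.clear(); log.logw.clear();
    log.q.clear(); log.x.clear();
    RunOut out = sim_run(net, event, scheme, mcode, x0,
                         absorb, do_occ ? &log : nullptr, false);
    long kt = 0;
    for (int m = 0; m < net.M; ++m) {
      kt += out.Km[m];
      Km_sum[m] += out.Km[m];
    }
    KT[j] = (double)kt;
    double w = 0.0;
    if (out.hit) {
      w = std::exp(out.logw);
      k1 += w;
      k2 += w * w;
      hits++;
    }
    if (record_runs) {
      for (int m = 0; m < net.M; ++m) Km_runs(j, m) = out.Km[m];
      w_runs[j] = w;
      hit_runs[j] = out.hit;
      hit_time_runs[j] = out.hit_time;
    }
    if (do_occ) {
      // pattern of occ_species in the state in which each reaction fired
      const int S = (int)occ_species.size();
      std::vector<int> pat(S);
      const int nsteps = (int)log.mu.size();
      for (int i = 0; i < nsteps; ++i) {
        // state before step i is x0 for i == 0, else logged state i-1
        for (int s = 0; s < S; ++s)
          pat[s] = (i == 0) ? x0[occ_species[s]]
                            : log.x[(size_t)(i - 1) * net.N + occ_species[s]];
        occ[pat] += 1.0;
      }
    }
  }

  List res = List::create(
      _["n"] = n, _["k1"] = k1, _["k2"] = k2, _["hits"] = hits,
      _["KT"] = KT, _["Km_sum"] = Km_sum);
  if (record_runs) {
    res["Km_runs"] = Km_runs;
    res["w_runs"] = w_runs;
    res["hit_runs"] = hit_runs;
    res["hit_time_runs"] = hit_time_runs;
  }
  if (do_occ) {
    const int P = (int)occ.size();
    IntegerMatrix pats(P, (int)occ_species.size());
    NumericVector cnt(P);
    int i = 0;
    for (std::map<std::vector<int>, double>::const_iterator it = occ.begin();
         it != occ.end(); ++it, ++i) {
      for (int s = 0; s < (int)occ_species.size(); ++s) pats(i, s) = it->first[s];
      cnt[i] = it->second;
    }
    res["occ_patterns"] = pats;
    res["occ_counts"] = cnt;
  }
  return res;
}

// [[Rcpp::export]]
List cpp_sim_logged(List sys, List ev, List sch, std::string method,
                    bool absorb, bool check_heap) {
  const Net net = make_net(sys);
  const Event event = make_event(ev);
  const Scheme scheme = make_scheme(sch);
  const int mcode = method_code(method);
  const std::vector<int> x0 = as<std::vector<int> >(sys["x0"]);
  StepLog log;
  log.enabled = true;
  RunOut out = sim_run(net, event, scheme, mcode, x0, absorb, &log, check_heap);
  const int steps = (int)log.mu.size();
  NumericMatrix qmat(log.q.empty() ? 0 : steps, net.M);
  for (int i = 0; i < (int)qmat.nrow(); ++i)
    for (int m = 0; m < net.M; ++m) qmat(i, m) = log.q[(size_t)i * net.M + m];
  IntegerMatrix xmat(steps, net.N);
  for (int i = 0; i < steps; ++i)
    for (int s = 0; s < net.N; ++s) xmat(i, s) = log.x[(size_t)i * net.N + s];
  return List::create(
      _["hit"] = out.hit, _["hit_time"] = out.hit_time,
      _["w"] = std::exp(out.logw), _["t_end"] = out.t_end,
      _["Km"] = IntegerVector(out.Km.begin(), out.Km.end()),
      _["time"] = NumericVector(log.t.begin(), log.t.end()),
      _["mu"] = IntegerVector(log.mu.begin(), log.mu.end()),
      _["a0"] = NumericVector(log.a0.begin(), log.a0.end()),
      _["logw"] = NumericVector(log.logw.begin(), log.logw.end()),
      _["q"] = qmat, _["state"] = xmat, _["heap_ok"] = log.heap_ok);
}

// Apply a sequence of key updates to the indexed priority queue, reporting
// the minimum after each update (used by tests against a full-scan oracle).
// [[Rcpp::export]]
IntegerVector cpp_ipq_trace(NumericVector keys0, IntegerVector idx,
                            NumericVector newkey) {
  std::vector<double> keys = as<std::vector<double> >(keys0);
  IPQ pq;
  pq.init(keys);
  IntegerVector mins(idx.size() + 1);
  mins[0] = pq.top() + 1;
  for (int i = 0; i < idx.size(); ++i) {
    keys[idx[i] - 1] = newkey[i];
    pq.update(idx[i] - 1);
    mins[i + 1] = pq.top() + 1;
  }
  return mins;
}
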