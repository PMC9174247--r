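// Simulation core: homophilic preferential attachment (BAh) growth,
// Simple / Complex / Hybrid contagion to the absorbing state, and the
// Monte-Carlo ensembles built on them.  All randomness goes through R's
// RNG stream so that set.seed() makes every run reproducible.
//
// Conventions: nodes are 0-based here (wrappers convert to 1-based R ids);
// group codes 1 = minority, 0 = majority; state codes 0 = susceptible,
// 1 = informed, 2 = recovered.

#include <Rcpp.h>
#include <array>
#include <deque>
#include <vector>

using namespace Rcpp;

static inline int unif_index(int n) {
  return (int) R_unif_index((double) n);
}

static void shuffle_vec(std::vector<int>& v) {
  for (int i = (int) v.size() - 1; i > 0; --i) {
    int j = unif_index(i + 1);
    std::swap(v[i], v[j]);
  }
}

// ---------------------------------------------------------------------------
// BAh growth
// ---------------------------------------------------------------------------

// Grow a BAh network.  Seed: node 0 minority, node 1 majority, joined by an
// edge iff `bridged`.  Each arrival draws its group (minority w.p. fa), then
// attaches to m distinct existing nodes sampled from the kernel
//   w(j) = h * k_j        if same group
//        = (1 - h) * k_j  otherwise,
// renormalized after each pick (rejection sampling is equivalent).  Sampling
// is O(1) per draw via two degree-weighted bags (one per group).  If every
// kernel weight is zero, attachment falls back to a uniform pick among
// candidates whose group coefficient is positive (so h = 1 never creates a
// cross-group edge), then among all candidates; fallbacks are counted.
static void gen_bah(int n, int m, double fa, double h, bool bridged,
                    std::vector<std::array<int, 2> >& edges,
                    std::vector<int>& grp, int& fallback) {
  grp.assign(n, 0);
  grp[0] = 1;
  grp[1] = 0;
  std::vector<int> bag[2];       // node ids repeated once per degree unit
  std::vector<int> deg(n, 0);
  edges.clear();
  edges.reserve((size_t) (n - 2) * m + 1);
  fallback = 0;

  if (bridged) {
    edges.push_back({{0, 1}});
    bag[1].push_back(0);
    bag[0].push_back(1);
    deg[0] = deg[1] = 1;
  }

  std::vector<int> chosen;
  for (int i = 2; i < n; ++i) {
    int g = (unif_rand() < fa) ? 1 : 0;
    grp[i] = g;
    int mm = std::min(m, i);
    chosen.clear();

    for (int t = 0; t < mm; ++t) {
      int pick = -1;
      double wsame = h * (double) bag[g].size();
      double wcross = (1.0 - h) * (double) bag[1 - g].size();
      double tot = wsame + wcross;

      if (tot > 0.0) {
        for (int attempt = 0; attempt < 100000; ++attempt) {
          double u = unif_rand() * tot;
          int side = (u < wsame) ? g : (1 - g);
          if (bag[side].empty()) continue;
          int cand = bag[side][unif_index((int) bag[side].size())];
          bool dup = false;
          for (size_t c = 0; c < chosen.size(); ++c)
            if (chosen[c] == cand) { dup = true; break; }
          if (!dup) { pick = cand; break; }
        }
      }

      if (pick < 0) {
        // exact weighted enumeration over remaining candidates
        double totw = 0.0;
        std::vector<double> w(i, 0.0);
        for (int j = 0; j < i; ++j) {
          bool dup = false;
          for (size_t c = 0; c < chosen.size(); ++c)
            if (chosen[c] == j) { dup = true; break; }
          if (dup) continue;
          w[j] = (grp[j] == g ? h : 1.0 - h) * (double) deg[j];
          totw += w[j];
        }
        if (totw > 0.0) {
          double u = unif_rand() * totw, acc = 0.0;
          for (int j = 0; j < i; ++j) {
            acc += w[j];
            if (u < acc) { pick = j; break; }
          }
          if (pick < 0) pick = i - 1;  // numeric edge case
        }
      }

      if (pick < 0) {
        // degenerate: all kernel weights zero; uniform among candidates with
        // positive group coefficient, else among all remaining candidates
        std::vector<int> elig;
        for (int pass = 0; pass < 2 && elig.empty(); ++pass) {
          for (int j = 0; j < i; ++j) {
            bool dup = false;
            for (size_t c = 0; c < chosen.size(); ++c)
              if (chosen[c] == j) { dup = true; break; }
            if (dup) continue;
            double coef = (grp[j] == g ? h : 1.0 - h);
            if (pass == 1 || coef > 0.0) elig.push_back(j);
          }
        }
        if (elig.empty())
          stop("BAh generation failed at step %d: no eligible target", i);
        pick = elig[unif_index((int) elig.size())];
        ++fallback;
      }

      chosen.push_back(pick);
    }

    for (size_t c = 0; c < chosen.size(); ++c) {
      int j = chosen[c];
      edges.push_back({{i, j}});
      bag[g].push_back(i);
      bag[grp[j]].push_back(j);
      ++deg[i];
      ++deg[j];
    }
  }
}

// [[Rcpp::export]]
List cpp_generate_bah(int n, int m, double fa, double h, bool bridged) {
  std::vector<std::array<int, 2> > edges;
  std::vector<int> grp;
  int fallback = 0;
  gen_bah(n, m, fa, h, bridged, edges, grp, fallback);
  IntegerMatrix em((int) edges.size(), 2);
  for (int e = 0; e < (int) edges.size(); ++e) {
    em(e, 0) = edges[e][0];
    em(e, 1) = edges[e][1];
  }
  return List::create(_["edges"] = em,
                      _["groups"] = IntegerVector(grp.begin(), grp.end()),
                      _["fallback"] = fallback);
}

// [[Rcpp::export]]
List cpp_build_csr(int n, IntegerMatrix edges) {
  int E = edges.nrow();
  std::vector<int> deg(n, 0);
  for (int e = 0; e < E; ++e) {
    ++deg[edges(e, 0)];
    ++deg[edges(e, 1)];
  }
  IntegerVector ptr(n + 1);
  ptr[0] = 0;
  for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
  IntegerVector adj(2 * E);
  std::vector<int> pos(n, 0);
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[ptr[a] + pos[a]++] = b;
    adj[ptr[b] + pos[b]++] = a;
  }
  return List::create(_["ptr"] = ptr, _["adj"] = adj);
}

// ---------------------------------------------------------------------------
// Contagion dynamics
// ---------------------------------------------------------------------------

struct Net {
  int n;
  const int* ptr;
  const int* adj;
  const int* grp;
};

// One-shot SIR: FIFO over informed nodes; each informed node attempts its
// currently susceptible neighbors once (in random order), succeeding w.p.
// lambda, then recovers.  Returns number of processed informed nodes.
static int cascade_simple(const Net& net, int seed, double lambda,
                          std::vector<int>& state) {
  state.assign(net.n, 0);
  state[seed] = 1;
  std::deque<int> q;
  q.push_back(seed);
  int steps = 0;
  std::vector<int> nb;
  while (!q.empty()) {
    int i = q.front();
    q.pop_front();
    ++steps;
    nb.assign(net.adj + net.ptr[i], net.adj + net.ptr[i + 1]);
    shuffle_vec(nb);
    for (size_t k = 0; k < nb.size(); ++k) {
      int j = nb[k];
      if (state[j] == 0 && unif_rand() < lambda) {
        state[j] = 1;
        q.push_back(j);
      }
    }
    state[i] = 2;
  }
  return steps;
}

// Watts-style threshold dynamics: randomized sweeps over susceptible nodes;
// a node adopts iff its informed-or-recovered neighbor fraction strictly
// exceeds T.  Stops when a full sweep changes nothing (the strict-threshold
// update is monotone, so this is the unique absorbing state reached by the
// random sequential process with probability 1).  Returns sweep count.
static int cascade_complex(const Net& net, int seed, double T,
                           std::vector<int>& state) {
  state.assign(net.n, 0);
  state[seed] = 1;
  std::vector<int> cnt(net.n, 0);
  for (int k = net.ptr[seed]; k < net.ptr[seed + 1]; ++k) ++cnt[net.adj[k]];
  std::vector<int> sus;
  sus.reserve(net.n - 1);
  for (int i = 0; i < net.n; ++i)
    if (i != seed) sus.push_back(i);
  int sweeps = 0;
  bool changed = true;
  while (changed) {
    changed = false;
    ++sweeps;
    shuffle_vec(sus);
    for (size_t k = 0; k < sus.size();) {
      int i = sus[k];
      int deg = net.ptr[i + 1] - net.ptr[i];
      if (deg > 0 && (double) cnt[i] / (double) deg > T) {
        state[i] = 1;
        changed = true;
        for (int a = net.ptr[i]; a < net.ptr[i + 1]; ++a) ++cnt[net.adj[a]];
        sus[k] = sus.back();
        sus.pop_back();
      } else {
        ++k;
      }
    }
  }
  return sweeps;
}

// Hybrid: seed-group nodes follow Simple contagion with lambda = 1 (so a
// susceptible simple node adopts as soon as any neighbor is informed);
// other-group nodes follow the strict threshold rule.  Event-driven closure:
// every new adoption immediately cascades through simple neighbors, then
// complex nodes are re-evaluated in randomized sweeps until absorbing.
static int cascade_hybrid(const Net& net, int seed, double T,
                          int simple_group, std::vector<int>& state) {
  state.assign(net.n, 0);
  std::vector<int> cnt(net.n, 0);
  std::vector<int> q;

  state[seed] = 1;
  q.push_back(seed);
  // exhaust simple (lambda = 1) transmission from newly informed nodes
  auto closure = [&]() {
    while (!q.empty()) {
      int v = q.back();
      q.pop_back();
      for (int a = net.ptr[v]; a < net.ptr[v + 1]; ++a) {
        int u = net.adj[a];
        ++cnt[u];
        if (state[u] == 0 && net.grp[u] == simple_group) {
          state[u] = 1;
          q.push_back(u);
        }
      }
    }
  };
  closure();

  std::vector<int> sus_cx;
  for (int i = 0; i < net.n; ++i)
    if (state[i] == 0 && net.grp[i] != simple_group) sus_cx.push_back(i);

  int rounds = 0;
  bool changed = true;
  while (changed) {
    changed = false;
    ++rounds;
    shuffle_vec(sus_cx);
    for (size_t k = 0; k < sus_cx.size();) {
      int i = sus_cx[k];
      int deg = net.ptr[i + 1] - net.ptr[i];
      if (deg > 0 && (double) cnt[i] / (double) deg > T) {
        state[i] = 1;
        q.push_back(i);
        closure();
        changed = true;
        sus_cx[k] = sus_cx.back();
        sus_cx.pop_back();
      } else {
        ++k;
      }
    }
  }
  // simple-mechanism nodes have spent their one-shot attempts: recovered
  for (int i = 0; i < net.n; ++i)
    if (state[i] == 1 && net.grp[i] == simple_group) state[i] = 2;
  return rounds;
}

static int run_model(const Net& net, int model, int seed, double lambda,
                     double T, int simple_group, std::vector<int>& state) {
  if (model == 0) return cascade_simple(net, seed, lambda, state);
  if (model == 1) return cascade_complex(net, seed, T, state);
  int sg = (simple_group < 0) ? net.grp[seed] : simple_group;
  return cascade_hybrid(net, seed, T, sg, state);
}

// model: 0 simple, 1 complex, 2 hybrid; simple_group: -1 = seed's group
// [[Rcpp::export]]
List cpp_cascade(IntegerVector ptr, IntegerVector adj, IntegerVector grp,
                 int seed, int model, double lambda, double T,
                 int simple_group) {
  Net net;
  net.n = (int) ptr.size() - 1;
  net.ptr = INTEGER(ptr);
  net.adj = adj.size() ? INTEGER(adj) : NULL;
  net.grp = INTEGER(grp);
  if (seed < 0 || seed >= net.n) stop("seed node out of range");
  std::vector<int> state;
  int steps = run_model(net, model, seed, lambda, T, simple_group, state);
  return List::create(
      _["states"] = IntegerVector(state.begin(), state.end()),
      _["steps"] = steps);
}

// ---------------------------------------------------------------------------
// Monte-Carlo ensembles
// ---------------------------------------------------------------------------

static void densities(const Net& net, const std::vector<int>& state,
                      double& rho_all, double& rho_min, double& rho_maj) {
  int n_min = 0, n_maj = 0, i_min = 0, i_maj = 0;
  for (int i = 0; i < net.n; ++i) {
    bool inf = state[i] != 0;
    if (net.grp[i] == 1) {
      ++n_min;
      if (inf) ++i_min;
    } else {
      ++n_maj;
      if (inf) ++i_maj;
    }
  }
  rho_all = (double) (i_min + i_maj) / (double) net.n;
  rho_min = n_min ? (double) i_min / (double) n_min : NA_REAL;
  rho_maj = n_maj ? (double) i_maj / (double) n_maj : NA_REAL;
}

static int draw_seed(const Net& net, int source_group) {
  if (source_group < 0) return unif_index(net.n);
  std::vector<int> pool;
  for (int i = 0; i < net.n; ++i)
    if (net.grp[i] == source_group) pool.push_back(i);
  if (pool.empty()) return -1;
  return pool[unif_index((int) pool.size())];
}

// Fresh BAh network + fresh seed per realization.
// source_group: 1 minority, 0 majority, -1 any node.
// [[Rcpp::export]]
List cpp_ensemble_generated(int n, int m, double fa, double h, bool bridged,
                            int model, double lambda, double T,
                            int source_group, int n_real, int simple_group) {
  NumericVector rho_all(n_real), rho_min(n_real), rho_maj(n_real);
  IntegerVector seeds(n_real), steps(n_real);
  std::vector<std::array<int, 2> > edges;
  std::vector<int> grp, state;
  for (int r = 0; r < n_real; ++r) {
    int fallback = 0;
    gen_bah(n, m, fa, h, bridged, edges, grp, fallback);
    // local CSR
    std::vector<int> deg(n, 0), ptr(n + 1, 0), adj(2 * edges.size()), pos(n, 0);
    for (size_t e = 0; e < edges.size(); ++e) {
      ++deg[edges[e][0]];
      ++deg[edges[e][1]];
    }
    for (int i = 0; i < n; ++i) ptr[i + 1] = ptr[i] + deg[i];
    for (size_t e = 0; e < edges.size(); ++e) {
      int a = edges[e][0], b = edges[e][1];
      adj[ptr[a] + pos[a]++] = b;
      adj[ptr[b] + pos[b]++] = a;
    }
    Net net;
    net.n = n;
    net.ptr = ptr.data();
    net.adj = adj.data();
    net.grp = grp.data();
    int s = draw_seed(net, source_group);
    if (s < 0) stop("source group empty in generated network");
    steps[r] = run_model(net, model, s, lambda, T, simple_group, state);
    seeds[r] = s;
    densities(net, state, rho_all[r], rho_min[r], rho_maj[r]);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rho_all"] = rho_all, _["rho_minority"] = rho_min,
                      _["rho_majority"] = rho_maj, _["seed_node"] = seeds,
                      _["steps"] = steps);
}

// Fixed network; fresh seed (and dynamics randomness) per realization.
// fixed_seed >= 0 pins the seed node, otherwise drawn from source_group.
// [[Rcpp::export]]
List cpp_ensemble_fixed(IntegerVector ptr, IntegerVector adj,
                        IntegerVector grp, int model, double lambda, double T,
                        int source_group, int fixed_seed, int n_real,
                        int simple_group) {
  Net net;
  net.n = (int) ptr.size() - 1;
  net.ptr = INTEGER(ptr);
  net.adj = adj.size() ? INTEGER(adj) : NULL;
  net.grp = INTEGER(grp);
  NumericVector rho_all(n_real), rho_min(n_real), rho_maj(n_real);
  IntegerVector seeds(n_real), steps(n_real);
  std::vector<int> state;
  for (int r = 0; r < n_real; ++r) {
    int s = fixed_seed >= 0 ? fixed_seed : draw_seed(net, source_group);
    if (s < 0) stop("source group empty in network");
    steps[r] = run_model(net, model, s, lambda, T, simple_group, state);
    seeds[r] = s;
    densities(net, state, rho_all[r], rho_min[r], rho_maj[r]);
    if (r % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["rho_all"] = rho_all, _["rho_minority"] = rho_min,
                      _["rho_majority"] = rho_maj, _["seed_node"] = seeds,
                      _["steps"] = steps);
}

// Cross-group edge fraction of freshly generated BAh networks (one value
// per replicate); used by the simulation-matching homophily estimator.
// [[Rcpp::export]]
NumericVector cpp_cross_fractions(int n, int m, double fa, double h,
                                  bool bridged, int n_real) {
  NumericVector out(n_real);
  std::vector<std::array<int, 2> > edges;
  std::vector<int> grp;
  for (int r = 0; r < n_real; ++r) {
    int fallback = 0;
    gen_bah(n, m, fa, h, bridged, edges, grp, fallback);
    int cross = 0;
    for (size_t e = 0; e < edges.size(); ++e)
      if (grp[edges[e][0]] != grp[edges[e][1]]) ++cross;
    out[r] = edges.empty() ? NA_REAL : (double) cross / (double) edges.size();
  }
  return out;
}
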