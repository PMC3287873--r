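// Metropolis-Hastings structure sampler over constrained DAGs with
// linear-Gaussian node scores computed from the (standardized) moment matrix.
//
// DAGs are held as per-node parent bitmasks (hard cap of 64 nodes).  Node
// scores depend only on (node, parent set), so a move re-scores at most the
// two endpoints; an optional audit mode recomputes the full network score
// from scratch at every step and reports the largest discrepancy.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SIGMA2_FLOOR = 1e-16;

struct Move {
  int type; // 0 = add u->v, 1 = delete u->v, 2 = reverse u->v
  int u;
  int v;
};

static inline int popcount64(uint64_t x) {
#ifdef __GNUC__
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// children masks from parent masks
static void children_masks(const std::vector<uint64_t>& par, int V,
                           std::vector<uint64_t>& ch) {
  std::fill(ch.begin(), ch.end(), 0ULL);
  for (int v = 0; v < V; ++v) {
    uint64_t p = par[v];
    while (p) {
      int u = __builtin_ctzll(p);
      ch[u] |= (1ULL << v);
      p &= p - 1;
    }
  }
}

// reach[u] = all nodes reachable from u by >=1 edge
static void reachability(const std::vector<uint64_t>& ch, int V,
                         std::vector<uint64_t>& reach) {
  for (int u = 0; u < V; ++u) {
    uint64_t seen = ch[u];
    uint64_t frontier = ch[u];
    while (frontier) {
      uint64_t next = 0;
      uint64_t f = frontier;
      while (f) {
        int w = __builtin_ctzll(f);
        next |= ch[w];
        f &= f - 1;
      }
      next &= ~seen;
      seen |= next;
      frontier = next;
    }
    reach[u] = seen;
  }
}

// is there a path u ~> v that does not use the direct edge u->v?
static bool path_avoiding_direct(const std::vector<uint64_t>& ch, int V,
                                 int u, int v) {
  uint64_t start = ch[u] & ~(1ULL << v);
  uint64_t seen = start, frontier = start;
  while (frontier) {
    if ((seen >> v) & 1ULL) return true;
    uint64_t next = 0;
    uint64_t f = frontier;
    while (f) {
      int w = __builtin_ctzll(f);
      next |= ch[w];
      f &= f - 1;
    }
    next &= ~seen;
    seen |= next;
    frontier = next;
  }
  return (seen >> v) & 1ULL;
}

// enumerate every legal move of `par` under the banned matrix and parent cap
static void legal_moves(const std::vector<uint64_t>& par,
                        const std::vector<uint64_t>& banned_to, int V,
                        int max_parents, std::vector<Move>& out,
                        std::vector<uint64_t>& ch, std::vector<uint64_t>& reach) {
  out.clear();
  children_masks(par, V, ch);
  reachability(ch, V, reach);
  for (int v = 0; v < V; ++v) {
    int np = popcount64(par[v]);
    for (int u = 0; u < V; ++u) {
      if (u == v) continue;
      bool has = (par[v] >> u) & 1ULL;
      if (has) {
        out.push_back({1, u, v}); // delete always legal
        // reverse u->v  =>  add v->u
        if (!((banned_to[u] >> v) & 1ULL) &&
            popcount64(par[u]) < max_parents &&
            !path_avoiding_direct(ch, V, u, v)) {
          out.push_back({2, u, v});
        }
      } else {
        if (((banned_to[v] >> u) & 1ULL) || ((par[u] >> v) & 1ULL)) continue;
        if (np >= max_parents) continue;
        if ((reach[v] >> u) & 1ULL) continue; // u reachable from v -> cycle
        out.push_back({0, u, v});
      }
    }
  }
}

// Gaussian node score from moment matrix S (columns standardized, mean 0)
static double node_score_cpp(const arma::mat& S, double n, int v,
                             uint64_t parmask, bool bic) {
  int k = popcount64(parmask);
  double s2;
  if (k == 0) {
    s2 = S(v, v);
  } else {
    arma::uvec idx(k);
    uint64_t p = parmask;
    for (int j = 0; j < k; ++j) {
      idx(j) = (arma::uword)__builtin_ctzll(p);
      p &= p - 1;
    }
    arma::mat A = S.submat(idx, idx);
    arma::vec b(k);
    for (int j = 0; j < k; ++j) b(j) = S(idx(j), v);
    arma::vec beta;
    bool ok = arma::solve(beta, A, b, arma::solve_opts::no_approx);
    if (!ok) { // collinear parents: tiny ridge fallback
      A.diag() += 1e-8;
      arma::solve(beta, A, b);
    }
    s2 = S(v, v) - arma::dot(b, beta);
  }
  if (s2 < SIGMA2_FLOOR) s2 = SIGMA2_FLOOR;
  double ll = -0.5 * n * (std::log(2.0 * M_PI * s2) + 1.0);
  if (bic) ll -= 0.5 * (k + 2) * std::log(n);
  return ll;
}

static double dag_code(const std::vector<uint64_t>& par, int V) {
  // bit (v*V + u) set iff edge u->v; valid for V <= 7 (49 bits < 2^53)
  uint64_t code = 0;
  for (int v = 0; v < V; ++v) code |= par[v] << (uint64_t)(v * V);
  return (double)code;
}

// [[Rcpp::export(name = ".mcmc_core")]]
List mcmc_core(const arma::mat& S, double n, const LogicalMatrix& banned,
               const IntegerMatrix& init, int iterations, int max_parents,
               bool bic, bool hastings, int window, double tol, int thin,
               bool record_states, bool audit) {
  const int V = S.n_rows;
  if (V > 64) stop("at most 64 nodes supported");
  if (record_states && V > 7) stop("state recording supports at most 7 nodes");

  std::vector<uint64_t> banned_to(V, 0ULL); // banned_to[v] bit u: u->v banned
  for (int u = 0; u < V; ++u)
    for (int v = 0; v < V; ++v)
      if (banned(u, v) || u == v) banned_to[v] |= (1ULL << u);

  std::vector<uint64_t> par(V, 0ULL);
  for (int u = 0; u < V; ++u)
    for (int v = 0; v < V; ++v)
      if (init(u, v)) par[v] |= (1ULL << u);

  std::vector<double> sc(V);
  double total = 0.0;
  for (int v = 0; v < V; ++v) { sc[v] = node_score_cpp(S, n, v, par[v], bic); total += sc[v]; }

  std::vector<uint64_t> best_par = par;
  double best_total = total;

  std::vector<Move> moves, moves_prop;
  std::vector<uint64_t> ch(V), reach(V);
  std::vector<uint64_t> par_prop(V);

  std::vector<double> trace;
  trace.reserve(iterations / thin + 1);
  std::vector<double> states;
  if (record_states) states.reserve(iterations + 1);

  long accepted = 0;
  double audit_max = 0.0;
  double best_at_check = best_total;
  int steps_done = 0;

  for (int it = 1; it <= iterations; ++it) {
    legal_moves(par, banned_to, V, max_parents, moves, ch, reach);
    const int Ncur = (int)moves.size();
    if (Ncur > 0) {
      int idx = (int)(unif_rand() * Ncur);
      if (idx >= Ncur) idx = Ncur - 1;
      const Move m = moves[idx];

      par_prop = par;
      double delta = 0.0;
      double sc_v_new = 0.0, sc_u_new = 0.0;
      if (m.type == 0) {
        par_prop[m.v] |= (1ULL << m.u);
        sc_v_new = node_score_cpp(S, n, m.v, par_prop[m.v], bic);
        delta = sc_v_new - sc[m.v];
      } else if (m.type == 1) {
        par_prop[m.v] &= ~(1ULL << m.u);
        sc_v_new = node_score_cpp(S, n, m.v, par_prop[m.v], bic);
        delta = sc_v_new - sc[m.v];
      } else {
        par_prop[m.v] &= ~(1ULL << m.u);
        par_prop[m.u] |= (1ULL << m.v);
        sc_v_new = node_score_cpp(S, n, m.v, par_prop[m.v], bic);
        sc_u_new = node_score_cpp(S, n, m.u, par_prop[m.u], bic);
        delta = (sc_v_new - sc[m.v]) + (sc_u_new - sc[m.u]);
      }

      double logH = 0.0;
      if (hastings) {
        legal_moves(par_prop, banned_to, V, max_parents, moves_prop, ch, reach);
        const int Nnew = (int)moves_prop.size();
        logH = std::log((double)Ncur) - std::log((double)Nnew);
      }

      if (std::log(unif_rand()) < delta + logH) {
        par = par_prop;
        sc[m.v] = sc_v_new;
        if (m.type == 2) sc[m.u] = sc_u_new;
        total += delta;
        ++accepted;
        if (total > best_total) { best_total = total; best_par = par; }
      }
    }

    if (audit) {
      double fresh = 0.0;
      for (int v = 0; v < V; ++v) fresh += node_score_cpp(S, n, v, par[v], bic);
      double dev = std::fabs(fresh - total);
      if (dev > audit_max) audit_max = dev;
    }
    if (it % thin == 0) trace.push_back(total);
    if (record_states) states.push_back(dag_code(par, V));

    steps_done = it;
    if (window > 0 && it % window == 0) {
      double rel = std::fabs(best_total - best_at_check) /
                   (std::fabs(best_total) + 1e-12);
      if (rel < tol && it > window) break;
      best_at_check = best_total;
    }
  }

  IntegerMatrix amat(V, V);
  for (int v = 0; v < V; ++v) {
    uint64_t p = best_par[v];
    while (p) { int u = __builtin_ctzll(p); amat(u, v) = 1; p &= p - 1; }
  }

  return List::create(
    _["best_amat"] = amat,
    _["best_score"] = best_total,
    _["trace"] = NumericVector(trace.begin(), trace.end()),
    _["states"] = record_states
        ? NumericVector(states.begin(), states.end()) : NumericVector(0),
    _["accept_rate"] = steps_done > 0 ? (double)accepted / steps_done : 0.0,
    _["steps"] = steps_done,
    _["audit_max_dev"] = audit_max);
}

// [[Rcpp::export(name = ".node_score_cpp")]]
double node_score_export(const arma::mat& S, double n, int v,
                         const IntegerVector& parents, bool bic) {
  uint64_t mask = 0;
  for (int i = 0; i < parents.size(); ++i) mask |= (1ULL << parents[i]);
  return node_score_cpp(S, n, v, mask, bic);
}
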