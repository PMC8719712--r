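// Monte-Carlo engine for the decision-tree query task.
//
// Two inner loops live here because they dominate runtime: the rollout
// planner (15 x n_rollouts imagined playouts per action selection, each
// updating a copy of the belief state) and the heuristic-agent session
// simulator (detection-rule querying plus confidence-based blame, run for
// tens of thousands of trials when fitting omega or computing blame
// statistics). Everything uses R's RNG so results are reproducible from
// set.seed().
//
// Conventions (shared with the R code): spatial heap ids, internal nodes
// 1..7 with children 2i (left, d = -1) and 2i+1 (right, d = +1), leaves
// 8..15. Belief tables are 7 x 10; columns 0..4 are d = -1 over the five
// coherences (ascending), columns 5..9 are d = +1.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int NC = 5;          // coherence levels
static const int NK = 128;        // direction combinations

// 128 x 7 direction combinations (+1 bit) and each combination's target leaf
static bool combo_plus[NK][7];
static int combo_target[NK];
static bool combos_ready = false;

static void init_combos() {
  if (combos_ready) return;
  for (int k = 0; k < NK; ++k) {
    for (int i = 0; i < 7; ++i) combo_plus[k][i] = (k >> i) & 1;
    int node = 1;
    for (int s = 0; s < 3; ++s) node = 2 * node + (combo_plus[k][node - 1] ? 1 : 0);
    combo_target[k] = node;
  }
  combos_ready = true;
}

struct Sensory {
  double mu[NC];     // kappa * c * t for each coherence (d = +1)
  double sd[NC];     // sqrt(t * (1 + c * gamma))
};

static Sensory make_sensory(const NumericVector& coh, double kappa,
                            double gamma, double t) {
  Sensory s;
  for (int j = 0; j < NC; ++j) {
    s.mu[j] = kappa * coh[j] * t;
    s.sd[j] = std::sqrt(t * (1.0 + coh[j] * gamma));
  }
  return s;
}

static inline double dnorm0(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return std::exp(-0.5 * z * z) / sd;   // unnormalized is fine (ratios only)
}

// Bayes update of one node's 10-cell row with evidence e
static void update_row(double* row, double e, const Sensory& s) {
  double tot = 0.0;
  for (int j = 0; j < NC; ++j) {
    double lm = dnorm0(e, -s.mu[j], s.sd[j]);
    double lp = dnorm0(e, s.mu[j], s.sd[j]);
    row[j] *= lm; row[NC + j] *= lp;
    tot += row[j] + row[NC + j];
  }
  if (tot > 0) for (int j = 0; j < 2 * NC; ++j) row[j] /= tot;
}

// target beliefs from tables (7 x 10, row-major double[7][10]) and visited set
static void beliefs_B(const double tab[7][10], const bool visited[16],
                      double B[16]) {
  double mplus[7];
  for (int i = 0; i < 7; ++i) {
    double p = 0.0;
    for (int j = 0; j < NC; ++j) p += tab[i][NC + j];
    mplus[i] = p;
  }
  for (int T = 8; T <= 15; ++T) B[T] = 0.0;
  double tot = 0.0;
  for (int k = 0; k < NK; ++k) {
    if (visited[combo_target[k]]) continue;
    double pk = 1.0;
    for (int i = 0; i < 7; ++i)
      pk *= combo_plus[k][i] ? mplus[i] : (1.0 - mplus[i]);
    B[combo_target[k]] += pk;
    tot += pk;
  }
  if (tot > 0) for (int T = 8; T <= 15; ++T) B[T] /= tot;
}

// sample a joint state (direction + coherence index per node) from the
// posterior conditioned on visited leaves; returns the implied target
static int sample_state(const double tab[7][10], const bool visited[16],
                        int dir[7], int cidx[7]) {
  double mplus[7];
  for (int i = 0; i < 7; ++i) {
    double p = 0.0;
    for (int j = 0; j < NC; ++j) p += tab[i][NC + j];
    mplus[i] = p;
  }
  double pk[NK], tot = 0.0;
  for (int k = 0; k < NK; ++k) {
    if (visited[combo_target[k]]) { pk[k] = 0.0; continue; }
    double p = 1.0;
    for (int i = 0; i < 7; ++i)
      p *= combo_plus[k][i] ? mplus[i] : (1.0 - mplus[i]);
    pk[k] = p; tot += p;
  }
  double u = unif_rand() * tot, acc = 0.0;
  int kstar = NK - 1;
  for (int k = 0; k < NK; ++k) { acc += pk[k]; if (u <= acc) { kstar = k; break; } }
  for (int i = 0; i < 7; ++i) {
    dir[i] = combo_plus[kstar][i] ? 1 : -1;
    // coherence from P(c | d) at node i
    int off = dir[i] > 0 ? NC : 0;
    double cs = 0.0;
    for (int j = 0; j < NC; ++j) cs += tab[i][off + j];
    double v = unif_rand() * cs, a2 = 0.0;
    cidx[i] = NC - 1;
    for (int j = 0; j < NC; ++j) { a2 += tab[i][off + j]; if (v <= a2) { cidx[i] = j; break; } }
  }
  return combo_target[kstar];
}

// [[Rcpp::export]]
NumericVector cpp_target_beliefs(NumericMatrix tables, IntegerVector visited) {
  init_combos();
  double tab[7][10];
  for (int i = 0; i < 7; ++i) for (int j = 0; j < 10; ++j) tab[i][j] = tables(i, j);
  bool vis[16] = {false};
  for (int v = 0; v < visited.size(); ++v) vis[visited[v]] = true;
  double B[16];
  beliefs_B(tab, vis, B);
  NumericVector out(8);
  for (int T = 8; T <= 15; ++T) out[T - 8] = B[T];
  return out;
}

// Mean rollout cost (positive = points lost) for each of the 15 candidate
// next actions, given the current belief state. Each rollout samples a
// state from the posterior, executes the candidate action, then follows the
// constrained random policy (internal node w.p. 7/15 uniform; otherwise the
// highest-belief unvisited leaf) with imagined observations drawn from the
// sampled state, until the sampled target is found.
// [[Rcpp::export]]
NumericVector cpp_rollout_costs(NumericMatrix tables, IntegerVector visited,
                                NumericVector coherences, double kappa,
                                double gamma, double t, double q_cost,
                                double requery_cost, double wrong_cost,
                                double reward, int n_rollouts, int max_depth) {
  init_combos();
  Sensory sen = make_sensory(coherences, kappa, gamma, t);
  double tab0[7][10];
  for (int i = 0; i < 7; ++i) for (int j = 0; j < 10; ++j) tab0[i][j] = tables(i, j);
  bool vis0[16] = {false};
  for (int v = 0; v < visited.size(); ++v) vis0[visited[v]] = true;

  NumericVector mean_cost(15);
  double tab[7][10], B[16];
  bool vis[16];
  int dir[7], cidx[7];

  for (int a0 = 1; a0 <= 15; ++a0) {
    double total = 0.0;
    for (int r = 0; r < n_rollouts; ++r) {
      for (int i = 0; i < 7; ++i) for (int j = 0; j < 10; ++j) tab[i][j] = tab0[i][j];
      for (int i = 0; i < 16; ++i) vis[i] = vis0[i];
      int Tstar = sample_state(tab0, vis0, dir, cidx);
      double cost = 0.0;
      int action = a0, last = -1;
      bool dirtyB = true;
      for (int depth = 0; depth < max_depth; ++depth) {
        if (action <= 7) {
          cost += (action == last) ? requery_cost : q_cost;
          int i = action - 1;
          double e = norm_rand() * sen.sd[cidx[i]] + dir[i] * sen.mu[cidx[i]];
          update_row(tab[i], e, sen);
          dirtyB = true;
        } else if (action == Tstar) {
          cost -= reward;
          break;
        } else {
          if (!vis[action]) { vis[action] = true; dirtyB = true; }
          cost += wrong_cost;
        }
        last = action;
        if (unif_rand() < 7.0 / 15.0) {
          action = 1 + (int)(unif_rand() * 7.0);
          if (action > 7) action = 7;
        } else {
          if (dirtyB) { beliefs_B(tab, vis, B); dirtyB = false; }
          double best = -1.0; int nbest = 0, pick = -1;
          for (int T = 8; T <= 15; ++T) {
            if (vis[T]) continue;
            if (B[T] > best + 1e-12) { best = B[T]; nbest = 1; pick = T; }
            else if (B[T] > best - 1e-12) {
              ++nbest;
              if (unif_rand() < 1.0 / nbest) pick = T;
            }
          }
          action = pick;
        }
        if (depth == max_depth - 1) {
          // safeguard: charge the worst case for the remainder
          int u = 0;
          for (int T = 8; T <= 15; ++T) if (!vis[T] && T != Tstar) ++u;
          cost += wrong_cost * u - reward;
        }
      }
      total += cost;
    }
    mean_cost[a0 - 1] = total / n_rollouts;
  }
  return mean_cost;
}

// ---------------------------------------------------------------------------
// Heuristic-agent session simulator

static inline double conf_toward(double e, int req, const Sensory& s) {
  // P(d = req | e), uniform prior over the 10 (c, d) cells
  double num = 0.0, den = 0.0;
  for (int j = 0; j < NC; ++j) {
    double a = dnorm0(e, req * s.mu[j], s.sd[j]);
    double b = dnorm0(e, -req * s.mu[j], s.sd[j]);
    num += a; den += a + b;
  }
  return den > 0 ? num / den : 0.5;
}

// [[Rcpp::export]]
List cpp_heuristic_sessions(int n_trials, NumericVector coherences,
                            double kappa, double gamma, double t,
                            NumericVector phi, double lambda, double omega,
                            double q_cost, double wrong_cost, double reward,
                            bool full_log, int max_steps) {
  init_combos();
  Sensory sen = make_sensory(coherences, kappa, gamma, t);
  const int level_of[16] = {0, 1, 2, 2, 3, 3, 3, 3, 4, 4, 4, 4, 4, 4, 4, 4};

  // trial summaries
  NumericVector tr_reward(n_trials);
  IntegerMatrix tr_q(n_trials, 3);
  IntegerVector tr_err(n_trials), tr_err_synth(n_trials);

  // error records
  std::vector<int> er_trial, er_leaf_can, er_blamed, er_blamed_level,
      er_type, er_next_can, er_synth;
  std::vector<double> er_coh1, er_coh2, er_coh3, er_c1, er_c2, er_c3;
  std::vector<int> er_el1, er_el2, er_el3;

  // full query log
  std::vector<double> lg_trial, lg_step, lg_node, lg_canon, lg_level, lg_coh,
      lg_dir, lg_e, lg_nq, lg_q, lg_fb, lg_pts;
  auto log_row = [&](int trial, int step, int node, int canon, int lev,
                     double coh, int d, double e, int nq, int q, int fb,
                     double pts) {
    if (!full_log) return;
    lg_trial.push_back(trial); lg_step.push_back(step);
    lg_node.push_back(node); lg_canon.push_back(canon);
    lg_level.push_back(lev); lg_coh.push_back(coh); lg_dir.push_back(d);
    lg_e.push_back(e); lg_nq.push_back(nq); lg_q.push_back(q);
    lg_fb.push_back(fb); lg_pts.push_back(pts);
  };

  for (int tr = 0; tr < n_trials; ++tr) {
    int cix[8], dirn[8], canon[16];
    for (int i = 1; i <= 7; ++i) {
      cix[i] = (int)(unif_rand() * NC); if (cix[i] >= NC) cix[i] = NC - 1;
      dirn[i] = unif_rand() < 0.5 ? -1 : 1;
    }
    canon[1] = 1;
    for (int i = 1; i <= 7; ++i) {
      int hi = dirn[i] > 0 ? 2 * i + 1 : 2 * i;
      canon[hi] = 2 * canon[i] + 1;
      canon[hi ^ 1] = 2 * canon[i];
    }
    int target = 1;
    for (int s = 0; s < 3; ++s) target = dirn[target] > 0 ? 2 * target + 1 : 2 * target;

    double last_e[8]; bool has_e[8], eligible[8]; bool vis[16] = {false};
    for (int i = 1; i <= 7; ++i) { has_e[i] = false; eligible[i] = true; last_e[i] = 0.0; }
    double points = 0.0;
    int qlev[4] = {0, 0, 0, 0}, nerr = 0, nerr_synth = 0;
    int cur = 1, nq = 0, qord = 0, step = 0;
    bool done = false;
    int pending_leaf = 0;   // leaf selected without querying (off-path level-3 / fallback)

    while (!done && step < max_steps) {
      ++step;
      int leaf = 0;
      bool synthetic = false;
      if (pending_leaf) { leaf = pending_leaf; pending_leaf = 0; }
      else {
        // query internal node cur
        int lev = level_of[cur];
        double e = norm_rand() * sen.sd[cix[cur]] + dirn[cur] * sen.mu[cix[cur]];
        points -= q_cost; ++qlev[lev]; ++qord;
        last_e[cur] = e; has_e[cur] = true; eligible[cur] = true;
        log_row(tr + 1, step, cur, canon[cur], lev, coherences[cix[cur]],
                dirn[cur], e, nq, qord, 0, -q_cost);
        double Phi = phi[lev - 1] * (1.0 + std::exp(-lambda * nq));
        if (std::fabs(e) <= Phi) { ++nq; continue; }   // re-query
        int ch = e > 0 ? 2 * cur + 1 : 2 * cur;
        if (ch <= 7) { cur = ch; nq = 0; continue; }
        leaf = ch;
      }
      // leaf selection
      if (leaf == target) {
        points += reward; ++qord;
        log_row(tr + 1, step, leaf, canon[leaf], 4, NA_REAL, 0, NA_REAL, 0,
                qord, 2, reward);
        done = true;
        break;
      }
      if (vis[leaf]) {
        synthetic = true; ++nerr_synth;   // remembered error: no cost, no query
      } else {
        vis[leaf] = true; points -= wrong_cost; ++nerr; ++qord;
        log_row(tr + 1, step, leaf, canon[leaf], 4, NA_REAL, 0, NA_REAL, 0,
                qord, 1, -wrong_cost);
      }
      // blame assignment over the error path
      int anc[3] = {1, leaf / 4, leaf / 2};
      double cf[3]; int el[3];
      for (int a = 0; a < 3; ++a) {
        int nd = anc[a];
        int onchild = (a < 2) ? anc[a + 1] : leaf;
        int req = (onchild == 2 * nd + 1) ? 1 : -1;
        cf[a] = has_e[nd] ? conf_toward(last_e[nd], req, sen) : 0.5;
        el[a] = eligible[nd] ? 1 : 0;
      }
      int nlow = 0;
      for (int a = 0; a < 3; ++a) if (el[a] && cf[a] < omega) ++nlow;
      int blamed = 0, btype = 0, next_node = 0;
      if (el[0] + el[1] + el[2] == 0) {
        btype = 3;                       // fallback: random unvisited leaf
        int cand[8], ncand = 0;
        for (int T = 8; T <= 15; ++T) if (!vis[T]) cand[ncand++] = T;
        int pick = (int)(unif_rand() * ncand); if (pick >= ncand) pick = ncand - 1;
        next_node = cand[pick];
      } else if (nlow >= 2) {
        btype = 1;                       // on-path: highest-level eligible low-conf
        for (int a = 0; a < 3; ++a)
          if (el[a] && cf[a] < omega) { blamed = anc[a]; break; }
        next_node = blamed;
      } else {
        btype = 2;                       // off-path: least-confident eligible
        double cmin = 2.0;
        for (int a = 0; a < 3; ++a)
          if (el[a] && cf[a] < cmin) { cmin = cf[a]; blamed = anc[a]; }
        int onchild = (level_of[blamed] < 3)
          ? anc[level_of[blamed]]        // anc[] holds next on-path node
          : leaf;
        next_node = (2 * blamed + 1 == onchild) ? 2 * blamed : 2 * blamed + 1;
      }
      if (blamed) eligible[blamed] = false;
      er_trial.push_back(tr + 1); er_leaf_can.push_back(canon[leaf]);
      er_coh1.push_back(coherences[cix[anc[0]]]);
      er_coh2.push_back(coherences[cix[anc[1]]]);
      er_coh3.push_back(coherences[cix[anc[2]]]);
      er_c1.push_back(cf[0]); er_c2.push_back(cf[1]); er_c3.push_back(cf[2]);
      er_el1.push_back(el[0]); er_el2.push_back(el[1]); er_el3.push_back(el[2]);
      er_blamed.push_back(blamed ? canon[blamed] : 0);
      er_blamed_level.push_back(blamed ? level_of[blamed] : 0);
      er_type.push_back(btype);
      er_next_can.push_back(canon[next_node]);
      er_synth.push_back(synthetic ? 1 : 0);
      if (next_node <= 7) { cur = next_node; nq = 0; }
      else pending_leaf = next_node;
    }
    if (!done) {
      // safeguard: finish by random search over unvisited leaves
      while (true) {
        int cand[8], ncand = 0;
        for (int T = 8; T <= 15; ++T) if (!vis[T]) cand[ncand++] = T;
        int pick = cand[(int)(unif_rand() * ncand) % ncand];
        if (pick == target) { points += reward; break; }
        vis[pick] = true; points -= wrong_cost; ++nerr;
      }
    }
    tr_reward[tr] = points;
    tr_q(tr, 0) = qlev[1]; tr_q(tr, 1) = qlev[2]; tr_q(tr, 2) = qlev[3];
    tr_err[tr] = nerr; tr_err_synth[tr] = nerr_synth;
  }

  DataFrame trials = DataFrame::create(
      _["reward"] = tr_reward, _["q1"] = tr_q(_, 0), _["q2"] = tr_q(_, 1),
      _["q3"] = tr_q(_, 2), _["errors"] = tr_err,
      _["errors_synthetic"] = tr_err_synth);
  DataFrame errors = DataFrame::create(
      _["trial"] = er_trial, _["leaf"] = er_leaf_can,
      _["coh1"] = er_coh1, _["coh2"] = er_coh2, _["coh3"] = er_coh3,
      _["conf1"] = er_c1, _["conf2"] = er_c2, _["conf3"] = er_c3,
      _["elig1"] = er_el1, _["elig2"] = er_el2, _["elig3"] = er_el3,
      _["blamed"] = er_blamed, _["blamed_level"] = er_blamed_level,
      _["path_type"] = er_type, _["next_node"] = er_next_can,
      _["synthetic"] = er_synth);
  List out = List::create(_["trials"] = trials, _["errors"] = errors);
  if (full_log) {
    out["log"] = DataFrame::create(
        _["trial"] = lg_trial, _["step"] = lg_step, _["node"] = lg_node,
        _["node_canonical"] = lg_canon, _["level"] = lg_level,
        _["coh"] = lg_coh, _["dir"] = lg_dir, _["e"] = lg_e,
        _["n_q"] = lg_nq, _["q"] = lg_q, _["feedback"] = lg_fb,
        _["points"] = lg_pts);
  }
  return out;
}
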