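#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Strategy coding: 1 = cooperator (C), 0 = defector (D).
// Sites are addressed by 0-based linear index in R's column-major matrix
// layout: i = col*L + row.  Moore offsets in fixed order (dr, dc):
//   0:NW(-1,-1) 1:N(-1,0) 2:NE(-1,1) 3:W(0,-1) 4:E(0,1) 5:SW(1,-1) 6:S(1,0) 7:SE(1,1)
// Opposite of slot d is slot 7-d.  Each site owns the four edges towards
// slots 4..7 (E, SW, S, SE): edge id = 4*site + (d-4).  The edge towards
// slot d < 4 is stored at the neighbour: edge id = 4*neighbour + (3-d).
// Every undirected edge is therefore stored exactly once (4*N edges total)
// and both endpoints resolve to the same slot, which enforces weight
// symmetry structurally.
//
// RNG contract (one elementary step, draws taken from R's global stream):
//   u1 -> focal site x = floor(u1*N)
//   (focal utility + weight adjustment: no draws)
//   u2 -> neighbour slot j = floor(u2*8), y = Moore neighbour j of x
//   u3 -> drawn only if U_y > U_x; x copies s_y iff u3 < W
// This order is frozen so that pure-R reference implementations sharing
// set.seed() reproduce the kernel draw-for-draw.

static const int DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC[8] = {-1,  0,  1, -1, 1, -1, 0, 1};

static void build_tables(int L, std::vector<int>& nbr, std::vector<int>& edge) {
  const int N = L * L;
  nbr.assign(N * 8, 0);
  edge.assign(N * 8, 0);
  for (int c = 0; c < L; ++c) {
    for (int r = 0; r < L; ++r) {
      const int i = c * L + r;
      for (int d = 0; d < 8; ++d) {
        const int rr = (r + DR[d] + L) % L;
        const int cc = (c + DC[d] + L) % L;
        const int j = cc * L + rr;
        nbr[i * 8 + d] = j;
        edge[i * 8 + d] = (d >= 4) ? (4 * i + (d - 4)) : (4 * j + (3 - d));
      }
    }
  }
}

static inline double pd_payoff(int sx, int sy, double b) {
  // T=b, R=1, P=S=0
  return sx ? (sy ? 1.0 : 0.0) : (sy ? b : 0.0);
}

// One asynchronous elementary step; mutates s, w, ncoop in place.
static inline void elementary(std::vector<int>& s, std::vector<double>& w,
                              const std::vector<int>& nbr,
                              const std::vector<int>& edge,
                              const int N, const double b, const double Delta,
                              const double lo, const double hi,
                              const double Dk, int& ncoop) {
  int x = (int)(unif_rand() * N);
  if (x >= N) x = N - 1;
  const int* nx = &nbr[x * 8];
  const int* ex = &edge[x * 8];
  const int sx = s[x];

  double P[8];
  double praw = 0.0;
  for (int j = 0; j < 8; ++j) {
    const double p = pd_payoff(sx, s[nx[j]], b);
    P[j] = p;
    praw += p;
  }

  // reinforce links that paid above the focal player's mean pairwise
  // payoff, punish those below; an exact tie (possible only when all
  // eight payoffs are equal) discriminates nothing and leaves the link
  // unchanged
  if (Delta > 0.0) {
    const double avg = praw / 8.0;
    for (int j = 0; j < 8; ++j) {
      if (P[j] == avg) continue;
      double v = w[ex[j]] + (P[j] > avg ? Delta : -Delta);
      w[ex[j]] = v < lo ? lo : (v > hi ? hi : v);
    }
  }

  int jy = (int)(unif_rand() * 8);
  if (jy >= 8) jy = 7;
  const int y = nx[jy];

  // utilities for the imitation comparison use post-adjustment weights
  double Ux = 0.0;
  for (int j = 0; j < 8; ++j)
    Ux += w[ex[j]] * pd_payoff(sx, s[nx[j]], b);

  const int* ny = &nbr[y * 8];
  const int* ey = &edge[y * 8];
  const int sy = s[y];
  double Uy = 0.0;
  for (int j = 0; j < 8; ++j)
    Uy += w[ey[j]] * pd_payoff(sy, s[ny[j]], b);

  if (Uy > Ux) {
    double W = (Uy - Ux) / Dk;
    if (W > 1.0) W = 1.0;
    if (unif_rand() < W && sx != sy) {
      s[x] = sy;
      ncoop += sy ? 1 : -1;
    }
  }
}

static void weight_stats(const std::vector<double>& w, double& m, double& v) {
  const int M = (int)w.size();
  double sum = 0.0;
  for (int e = 0; e < M; ++e) sum += w[e];
  m = sum / M;
  double sum2 = 0.0;
  for (int e = 0; e < M; ++e) {
    const double d = w[e] - m;
    sum2 += d * d;
  }
  v = sum2 / M;  // population variance over all 4N edges
}

// [[Rcpp::export]]
List cpp_run_kernel(IntegerVector strat0, NumericVector wt0, int L, double b,
                    double delta, double Delta, int n_mcs,
                    IntegerVector snapshot_steps, bool record_weights,
                    bool stop_when_uniform, bool check_bounds) {
  const int N = L * L;
  if (strat0.size() != N) stop("strategy field has wrong length");
  if (wt0.size() != 4 * N) stop("weight field has wrong length");
  std::vector<int> nbr, edge;
  build_tables(L, nbr, edge);

  std::vector<int> s(strat0.begin(), strat0.end());
  std::vector<double> w(wt0.begin(), wt0.end());
  const double lo = 1.0 - delta, hi = 1.0 + delta, Dk = 8.0 * b;

  int ncoop = 0;
  for (int i = 0; i < N; ++i) ncoop += s[i];

  NumericVector rho(n_mcs + 1);
  rho[0] = (double)ncoop / N;
  NumericVector wmean(record_weights ? n_mcs + 1 : 0);
  NumericVector wvar(record_weights ? n_mcs + 1 : 0);
  if (record_weights) {
    double m, v;
    weight_stats(w, m, v);
    wmean[0] = m;
    wvar[0] = v;
  }

  std::vector<bool> want_snap(n_mcs + 1, false);
  int n_snap = 0;
  for (int k = 0; k < snapshot_steps.size(); ++k) {
    const int t = snapshot_steps[k];
    if (t >= 0 && t <= n_mcs && !want_snap[t]) {
      want_snap[t] = true;
      ++n_snap;
    }
  }
  List snaps(n_snap);
  CharacterVector snap_names(n_snap);
  int i_snap = 0;
  if (n_snap > 0 && want_snap[0]) {
    snaps[i_snap] = IntegerVector(s.begin(), s.end());
    snap_names[i_snap] = "0";
    ++i_snap;
  }

  bool bounds_ok = true;
  int absorbed_at = (ncoop == 0 || ncoop == N) ? 0 : -1;
  int stopped_at = n_mcs;

  for (int t = 1; t <= n_mcs; ++t) {
    for (int k = 0; k < N; ++k)
      elementary(s, w, nbr, edge, N, b, Delta, lo, hi, Dk, ncoop);
    rho[t] = (double)ncoop / N;
    if (record_weights) {
      double m, v;
      weight_stats(w, m, v);
      wmean[t] = m;
      wvar[t] = v;
    }
    if (check_bounds) {
      for (int e = 0; e < 4 * N; ++e)
        if (w[e] < lo || w[e] > hi) bounds_ok = false;
    }
    if (want_snap[t]) {
      snaps[i_snap] = IntegerVector(s.begin(), s.end());
      snap_names[i_snap] = std::to_string(t);
      ++i_snap;
    }
    const bool uniform = (ncoop == 0 || ncoop == N);
    if (uniform && absorbed_at < 0) absorbed_at = t;
    if (stop_when_uniform && uniform) {
      // strategies are absorbed: extend the trajectory as a constant
      for (int tt = t + 1; tt <= n_mcs; ++tt) {
        rho[tt] = rho[t];
        if (record_weights) {
          wmean[tt] = wmean[t];
          wvar[tt] = wvar[t];
        }
        if (want_snap[tt]) {
          snaps[i_snap] = IntegerVector(s.begin(), s.end());
          snap_names[i_snap] = std::to_string(tt);
          ++i_snap;
        }
      }
      stopped_at = t;
      break;
    }
    if (t % 256 == 0) Rcpp::checkUserInterrupt();
  }
  snaps.attr("names") = snap_names;

  return List::create(
      _["strategies"] = IntegerVector(s.begin(), s.end()),
      _["weights"] = NumericVector(w.begin(), w.end()),
      _["rho"] = rho, _["mean_weight"] = wmean, _["var_weight"] = wvar,
      _["snapshots"] = snaps, _["absorbed_at"] = absorbed_at,
      _["stopped_at"] = stopped_at, _["bounds_ok"] = bounds_ok);
}

// [[Rcpp::export]]
List cpp_elementary_steps(IntegerVector strat0, NumericVector wt0, int L,
                          double b, double delta, double Delta, int n_steps) {
  const int N = L * L;
  if (strat0.size() != N) stop("strategy field has wrong length");
  if (wt0.size() != 4 * N) stop("weight field has wrong length");
  std::vector<int> nbr, edge;
  build_tables(L, nbr, edge);
  std::vector<int> s(strat0.begin(), strat0.end());
  std::vector<double> w(wt0.begin(), wt0.end());
  const double lo = 1.0 - delta, hi = 1.0 + delta, Dk = 8.0 * b;
  int ncoop = 0;
  for (int i = 0; i < N; ++i) ncoop += s[i];
  for (int k = 0; k < n_steps; ++k)
    elementary(s, w, nbr, edge, N, b, Delta, lo, hi, Dk, ncoop);
  return List::create(_["strategies"] = IntegerVector(s.begin(), s.end()),
                      _["weights"] = NumericVector(w.begin(), w.end()));
}

// [[Rcpp::export]]
IntegerMatrix cpp_neighbor_table(int L) {
  const int N = L * L;
  std::vector<int> nbr, edge;
  build_tables(L, nbr, edge);
  IntegerMatrix out(N, 8);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 8; ++d) out(i, d) = nbr[i * 8 + d] + 1;  // 1-based
  return out;
}

// [[Rcpp::export]]
IntegerMatrix cpp_edge_table(int L) {
  const int N = L * L;
  std::vector<int> nbr, edge;
  build_tables(L, nbr, edge);
  IntegerMatrix out(N, 8);
  for (int i = 0; i < N; ++i)
    for (int d = 0; d < 8; ++d) out(i, d) = edge[i * 8 + d] + 1;  // 1-based
  return out;
}
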