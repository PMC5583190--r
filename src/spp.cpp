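#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Discrete-time Vicsek dynamics in a 2-D periodic box, with optional
// predator. Neighbor searches (metric radius or k-nearest) use a uniform
// cell grid with expanding-ring queries; correctness does not depend on the
// cell size, only speed does. All randomness goes through R's RNG so that
// set.seed() fully determines a run.

static inline double wrap_pos(double x, double L) {
  x -= L * std::floor(x / L);
  // guard against rounding right at the boundary
  if (x >= L) x -= L;
  if (x < 0) x = 0;
  return x;
}

// wrap angle into (-pi, pi]
static inline double wrap_angle(double t) {
  double r = t - 2.0 * M_PI * std::ceil((t - M_PI) / (2.0 * M_PI));
  if (r > M_PI) r = M_PI;
  if (r <= -M_PI) r += 2.0 * M_PI;
  return r;
}

// minimum-image signed displacement component (b - a), in [-L/2, L/2)
static inline double min_image(double d, double L) {
  d -= L * std::floor(d / L + 0.5);
  if (d >= L / 2.0) d -= L;
  if (d < -L / 2.0) d += L;
  return d;
}

// squared minimum-image distance; assumes both points already in [0, L)
static inline double pdist2(double ax, double ay, double bx, double by,
                            double L) {
  double dx = bx - ax;
  if (dx > L / 2.0) dx -= L; else if (dx < -L / 2.0) dx += L;
  double dy = by - ay;
  if (dy > L / 2.0) dy -= L; else if (dy < -L / 2.0) dy += L;
  return dx * dx + dy * dy;
}

// Cell grid over alive agents, counting-sorted into contiguous per-cell
// slices with position copies in cell order (cache-friendly queries).
struct CellGrid {
  int M;            // cells per side
  double cell;      // cell side length
  double L;
  std::vector<int> start;      // M*M + 1 prefix offsets
  std::vector<int> ids;        // agent index, cell-ordered
  std::vector<double> gx, gy;  // positions, cell-ordered
  std::vector<int> wrap_tab;   // wrapped cell index lookup
  std::vector<int> stamp;      // per-cell visited marker (kNN dedup)
  int stamp_val;
  std::vector<int> cellof, cur;
  int pad;

  inline int wrapc(int i) const { return wrap_tab[i + pad]; }

  void build(const std::vector<double>& x, const std::vector<double>& y,
             const std::vector<char>& alive, double L_, int n_alive) {
    L = L_;
    // fine cells (~1.5 agents each): expanding rings then terminate after
    // few candidates, which also adapts to the dense bands the ordered
    // phase develops
    int m = (int)std::floor(std::sqrt((double)std::max(n_alive, 1) / 1.5));
    M = std::max(1, std::min(m, 128));
    cell = L / M;
    pad = 2 * M + 2;
    wrap_tab.resize(M + 2 * pad);
    for (int i = -pad; i < M + pad; ++i)
      wrap_tab[i + pad] = ((i % M) + M) % M;
    int ncell = M * M;
    start.assign(ncell + 1, 0);
    stamp.assign(ncell, -1);
    stamp_val = 0;
    int n = (int)x.size();
    cellof.assign(n, -1);
    for (int i = 0; i < n; ++i) {
      if (!alive[i]) continue;
      int cx = std::min((int)(x[i] / cell), M - 1);
      int cy = std::min((int)(y[i] / cell), M - 1);
      cellof[i] = cy * M + cx;
      ++start[cellof[i] + 1];
    }
    for (int c = 0; c < ncell; ++c) start[c + 1] += start[c];
    ids.resize(start[ncell]);
    gx.resize(start[ncell]);
    gy.resize(start[ncell]);
    cur.assign(start.begin(), start.end() - 1);
    for (int i = 0; i < n; ++i) {
      if (cellof[i] < 0) continue;
      int t = cur[cellof[i]]++;
      ids[t] = i;
      gx[t] = x[i];
      gy[t] = y[i];
    }
  }
};

// Bounded "k best" selector: a max-heap on (d2, idx) so the current worst
// candidate sits at the root and most scanned points are rejected with one
// comparison. Ordering (d2, idx) lexicographic implements the tie rule:
// equal distances break toward the lower agent index.
struct KBest {
  int k;
  int size;
  std::vector<double> d2;
  std::vector<int> idx;

  void reset(int k_) {
    k = k_;
    size = 0;
    if ((int)d2.size() < k) {
      d2.resize(k);
      idx.resize(k);
    }
  }
  static inline bool worse(double ad2, int ai, double bd2, int bi) {
    return ad2 > bd2 || (ad2 == bd2 && ai > bi);
  }
  inline void sift_down(int i) {
    for (;;) {
      int l = 2 * i + 1, r = l + 1, w = i;
      if (l < size && worse(d2[l], idx[l], d2[w], idx[w])) w = l;
      if (r < size && worse(d2[r], idx[r], d2[w], idx[w])) w = r;
      if (w == i) break;
      std::swap(d2[i], d2[w]);
      std::swap(idx[i], idx[w]);
      i = w;
    }
  }
  inline void offer(double nd2, int ni) {
    if (size < k) {
      int i = size++;
      d2[i] = nd2;
      idx[i] = ni;
      while (i > 0) {  // sift up
        int p = (i - 1) / 2;
        if (!worse(d2[i], idx[i], d2[p], idx[p])) break;
        std::swap(d2[i], d2[p]);
        std::swap(idx[i], idx[p]);
        i = p;
      }
    } else if (worse(d2[0], idx[0], nd2, ni)) {
      d2[0] = nd2;
      idx[0] = ni;
      sift_down(0);
    }
  }
  // all k slots filled and every held distance strictly below `bound`
  inline bool settled(double bound2) const {
    return size == k && d2[0] < bound2;
  }
};

// k nearest alive agents to (px, py), excluding `self` (pass -1 for an
// external query point). Result left in `kb` (unordered heap contents).
static void knn_query(CellGrid& g, double px, double py, int self, int k,
                      KBest& kb) {
  kb.reset(k);
  if (k <= 0) return;
  ++g.stamp_val;
  int M = g.M;
  int cx = std::min((int)(px / g.cell), M - 1);
  int cy = std::min((int)(py / g.cell), M - 1);
  int total = M * M;
  int seen = 0;
  for (int m = 0; seen < total; ++m) {
    for (int dy = -m; dy <= m; ++dy) {
      int step = (m == 0 || std::abs(dy) == m) ? 1 : 2 * m;
      int uy = g.wrapc(cy + dy);
      for (int dx = -m; dx <= m; dx += step) {
        int ux = g.wrapc(cx + dx);
        int c = uy * M + ux;
        if (g.stamp[c] == g.stamp_val) continue;  // re-wrapped ring cell
        g.stamp[c] = g.stamp_val;
        ++seen;
        int lo = g.start[c], hi = g.start[c + 1];
        for (int t = lo; t < hi; ++t) {
          int j = g.ids[t];
          if (j == self) continue;
          kb.offer(pdist2(px, py, g.gx[t], g.gy[t], g.L), j);
        }
      }
    }
    // after ring m every point within distance m*cell has been scanned;
    // strict inequality in settled() keeps the lower-index tie rule exact
    double guar = (double)m * g.cell;
    if (kb.settled(guar * guar)) break;
  }
}

// metric query accumulating velocity sums directly (alignment hot path);
// returns the neighbor count (excluding self)
static int radius_sum(CellGrid& g, double px, double py, int self, double r,
                      const std::vector<double>& vx,
                      const std::vector<double>& vy, double& sx, double& sy) {
  int M = g.M;
  int cx = std::min((int)(px / g.cell), M - 1);
  int cy = std::min((int)(py / g.cell), M - 1);
  int mneed = (int)(r / g.cell) + 1;
  int count = 0;
  double r2 = r * r;
  if (2 * mneed + 1 >= M) {
    // neighborhood covers the whole grid: plain scan of every cell slice
    int nall = g.start[M * M];
    for (int t = 0; t < nall; ++t) {
      int j = g.ids[t];
      if (j == self) continue;
      if (pdist2(px, py, g.gx[t], g.gy[t], g.L) <= r2) {
        sx += vx[j];
        sy += vy[j];
        ++count;
      }
    }
    return count;
  }
  for (int dy = -mneed; dy <= mneed; ++dy) {
    int uy = g.wrapc(cy + dy);
    for (int dx = -mneed; dx <= mneed; ++dx) {
      int ux = g.wrapc(cx + dx);
      int c = uy * M + ux;
      int lo = g.start[c], hi = g.start[c + 1];
      for (int t = lo; t < hi; ++t) {
        int j = g.ids[t];
        if (j == self) continue;
        if (pdist2(px, py, g.gx[t], g.gy[t], g.L) <= r2) {
          sx += vx[j];
          sy += vy[j];
          ++count;
        }
      }
    }
  }
  return count;
}

// metric query collecting indices (exported neighbor lists; not hot)
static void radius_collect(CellGrid& g, double px, double py, int self,
                           double r, std::vector<int>& out) {
  out.clear();
  int M = g.M;
  int cx = std::min((int)(px / g.cell), M - 1);
  int cy = std::min((int)(py / g.cell), M - 1);
  int mneed = (int)(r / g.cell) + 1;
  double r2 = r * r;
  bool whole = (2 * mneed + 1 >= M);
  int dlim = whole ? M / 2 + 1 : mneed;
  std::vector<char> taken(g.start[M * M], 0);
  for (int dy = -dlim - 1; dy <= dlim + 1; ++dy) {
    int uy = g.wrapc(cy + dy);
    for (int dx = -dlim - 1; dx <= dlim + 1; ++dx) {
      int ux = g.wrapc(cx + dx);
      int c = uy * M + ux;
      int lo = g.start[c], hi = g.start[c + 1];
      for (int t = lo; t < hi; ++t) {
        if (taken[t]) continue;
        taken[t] = 1;
        int j = g.ids[t];
        if (j == self) continue;
        if (pdist2(px, py, g.gx[t], g.gy[t], g.L) <= r2) out.push_back(j);
      }
    }
  }
}

struct SwarmBuf {
  std::vector<double> x, y, th, th_new, vx, vy;
  std::vector<char> alive;
  int n;
  int n_alive;
};

static void buf_from_R(SwarmBuf& b, const NumericMatrix& pos,
                       const NumericVector& theta,
                       const LogicalVector& alive) {
  b.n = pos.nrow();
  b.x.resize(b.n);
  b.y.resize(b.n);
  b.th.resize(b.n);
  b.th_new.resize(b.n);
  b.vx.resize(b.n);
  b.vy.resize(b.n);
  b.alive.resize(b.n);
  b.n_alive = 0;
  for (int i = 0; i < b.n; ++i) {
    b.x[i] = pos(i, 0);
    b.y[i] = pos(i, 1);
    b.th[i] = theta[i];
    b.alive[i] = alive[i] ? 1 : 0;
    if (b.alive[i]) ++b.n_alive;
  }
}

// One synchronous alignment + streaming step. `flee` marks agents whose
// heading has already been overridden this step (predator evasion): they
// keep that heading instead of aligning, but still feed the alignment of
// others. Returns the summed neighbor count (excl. self) over alive agents.
// finish one agent's alignment once its neighbor velocity sum is known
static inline void finish_heading(SwarmBuf& b, int i, double sx, double sy,
                                  int nn) {
  if (std::sqrt(sx * sx + sy * sy) < 1e-12 * (double)(nn + 1)) {
    b.th_new[i] = b.th[i];  // zero resultant: keep previous heading
  } else {
    b.th_new[i] = std::atan2(sy, sx);
  }
}

static long long step_core(SwarmBuf& b, CellGrid& g, KBest& kb, double L,
                           double v0, double dt, double eta, bool topological,
                           int k, double r, const std::vector<char>* flee) {
  g.build(b.x, b.y, b.alive, L, b.n_alive);
  for (int i = 0; i < b.n; ++i) {
    if (!b.alive[i]) continue;
    b.vx[i] = std::cos(b.th[i]);
    b.vy[i] = std::sin(b.th[i]);
  }
  long long degree_sum = 0;
  int M = g.M;
  if (!topological) {
    for (int i = 0; i < b.n; ++i) {
      if (!b.alive[i]) continue;
      if (flee && (*flee)[i]) {
        b.th_new[i] = b.th[i];
        // fleeing agents still count toward the realized mean degree
        double sx0 = 0, sy0 = 0;
        degree_sum += radius_sum(g, b.x[i], b.y[i], i, r, b.vx, b.vy,
                                 sx0, sy0);
        continue;
      }
      double sx = b.vx[i], sy = b.vy[i];  // self included
      int nn = radius_sum(g, b.x[i], b.y[i], i, r, b.vx, b.vy, sx, sy);
      degree_sum += nn;
      finish_heading(b, i, sx, sy, nn);
    }
  } else {
    for (int i = 0; i < b.n; ++i) {
      if (!b.alive[i]) continue;
      knn_query(g, b.x[i], b.y[i], i, k, kb);
      degree_sum += kb.size;
      if (flee && (*flee)[i]) {
        b.th_new[i] = b.th[i];
        continue;
      }
      double sx = b.vx[i], sy = b.vy[i];
      for (int t = 0; t < kb.size; ++t) {
        sx += b.vx[kb.idx[t]];
        sy += b.vy[kb.idx[t]];
      }
      finish_heading(b, i, sx, sy, kb.size);
    }
  }
  // angular noise, drawn in agent-index order so the RNG stream does not
  // depend on the traversal order above
  for (int i = 0; i < b.n; ++i) {
    if (!b.alive[i]) continue;
    if (flee && (*flee)[i]) continue;
    double nt = b.th_new[i];
    if (eta > 0) nt += 2.0 * M_PI * R::runif(-eta / 2.0, eta / 2.0);
    b.th_new[i] = wrap_angle(nt);
  }
  // positions advance with the pre-update velocities
  for (int i = 0; i < b.n; ++i) {
    if (!b.alive[i]) continue;
    b.x[i] = wrap_pos(b.x[i] + dt * v0 * b.vx[i], L);
    b.y[i] = wrap_pos(b.y[i] + dt * v0 * b.vy[i], L);
    b.th[i] = b.th_new[i];
  }
  return degree_sum;
}

// [[Rcpp::export]]
List cpp_neighbor_lists(NumericMatrix pos, NumericVector theta,
                        LogicalVector alive, double L, bool topological,
                        int k, double r) {
  SwarmBuf b;
  buf_from_R(b, pos, theta, alive);
  CellGrid g;
  g.build(b.x, b.y, b.alive, L, b.n_alive);
  KBest kb;
  std::vector<int> found;
  List out(b.n);
  for (int i = 0; i < b.n; ++i) {
    if (!b.alive[i]) {
      out[i] = IntegerVector(0);
      continue;
    }
    if (topological) {
      knn_query(g, b.x[i], b.y[i], i, k, kb);
      found.assign(kb.idx.begin(), kb.idx.begin() + kb.size);
    } else {
      radius_collect(g, b.x[i], b.y[i], i, r, found);
    }
    IntegerVector v(found.size() + 1);
    v[0] = i + 1;
    for (size_t t = 0; t < found.size(); ++t) v[t + 1] = found[t] + 1;
    std::sort(v.begin(), v.end());
    out[i] = v;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_vicsek_step(NumericMatrix pos, NumericVector theta,
                     LogicalVector alive, double L, double v0, double dt,
                     double eta, bool topological, int k, double r) {
  SwarmBuf b;
  buf_from_R(b, pos, theta, alive);
  CellGrid g;
  KBest kb;
  step_core(b, g, kb, L, v0, dt, eta, topological, k, r, NULL);
  NumericMatrix np(b.n, 2);
  NumericVector nt(b.n);
  for (int i = 0; i < b.n; ++i) {
    np(i, 0) = b.x[i];
    np(i, 1) = b.y[i];
    nt[i] = b.th[i];
  }
  return List::create(_["pos"] = np, _["theta"] = nt);
}

// [[Rcpp::export]]
List cpp_run_swarm(NumericMatrix pos, NumericVector theta,
                   LogicalVector alive, double L, double v0, double dt,
                   double eta, bool topological, int k, double r,
                   int n_steps, IntegerVector sample_steps) {
  SwarmBuf b;
  buf_from_R(b, pos, theta, alive);
  CellGrid g;
  KBest kb;
  int ns = sample_steps.size();
  List spos(ns), sth(ns);
  int si = 0;
  for (int t = 1; t <= n_steps; ++t) {
    step_core(b, g, kb, L, v0, dt, eta, topological, k, r, NULL);
    if (si < ns && sample_steps[si] == t) {
      NumericMatrix p(b.n, 2);
      NumericVector th(b.n);
      for (int i = 0; i < b.n; ++i) {
        p(i, 0) = b.x[i];
        p(i, 1) = b.y[i];
        th[i] = b.th[i];
      }
      spos[si] = p;
      sth[si] = th;
      ++si;
    }
  }
  NumericMatrix np(b.n, 2);
  NumericVector nt(b.n);
  for (int i = 0; i < b.n; ++i) {
    np(i, 0) = b.x[i];
    np(i, 1) = b.y[i];
    nt[i] = b.th[i];
  }
  return List::create(_["pos"] = np, _["theta"] = nt,
                      _["sample_pos"] = spos, _["sample_theta"] = sth);
}

// Full predator run: plain Vicsek transient, then predator phase.
// Per iteration of the predator phase:
//   1. agents with min-image distance to the predator < r_detect have their
//      current heading replaced by the direction away from the predator
//      (this overridden heading is what neighbors align to);
//   2. non-fleeing agents perform the synchronous alignment update;
//   3. all alive agents advance one step with their current velocities;
//   4. the predator advances speed_factor*v0*dt toward the nearest alive
//      agent (positions as seen before the move);
//   5. alive agents now strictly within r_catch of the predator are removed
//      and logged with the current iteration index.
// [[Rcpp::export]]
List cpp_run_predator(NumericMatrix pos, NumericVector theta,
                      LogicalVector alive, double L, double v0, double dt,
                      double eta, bool topological, int k, double r,
                      double speed_factor, double r_detect, double r_catch,
                      int intro_step, int n_steps) {
  SwarmBuf b;
  buf_from_R(b, pos, theta, alive);
  CellGrid g;
  KBest kb;
  std::vector<int> catch_times;
  std::vector<int> catch_ids;
  long long degree_sum = 0;
  long long agent_steps = 0;
  double px = 0, py = 0;
  bool pred_active = false;
  std::vector<char> flee(b.n, 0);
  double rd2 = r_detect * r_detect;
  double rc2 = r_catch * r_catch;

  for (int t = 1; t <= n_steps; ++t) {
    if (b.n_alive == 0) break;
    if (!pred_active && t > intro_step) {
      px = R::runif(0.0, L);
      py = R::runif(0.0, L);
      pred_active = true;
    }
    if (!pred_active) {
      degree_sum += step_core(b, g, kb, L, v0, dt, eta, topological, k, r,
                              NULL);
      agent_steps += b.n_alive;
      continue;
    }
    // flee override replaces the current heading of detecting agents
    for (int i = 0; i < b.n; ++i) {
      flee[i] = 0;
      if (!b.alive[i]) continue;
      double d2 = pdist2(px, py, b.x[i], b.y[i], L);
      if (d2 < rd2) {
        if (d2 > 0) {
          double dx = min_image(b.x[i] - px, L);
          double dy = min_image(b.y[i] - py, L);
          b.th[i] = std::atan2(dy, dx);  // straight away from the predator
        }
        flee[i] = 1;  // exact overlap: keep heading; no alignment either
      }
    }
    // nearest alive agent seen by the predator, pre-move snapshot
    double best_d2 = -1, tx = 0, ty = 0;
    int best_i = -1;
    for (int i = 0; i < b.n; ++i) {
      if (!b.alive[i]) continue;
      double d2 = pdist2(px, py, b.x[i], b.y[i], L);
      if (best_i == -1 || d2 < best_d2) {
        best_d2 = d2;
        best_i = i;
        tx = b.x[i];
        ty = b.y[i];
      }
    }
    degree_sum += step_core(b, g, kb, L, v0, dt, eta, topological, k, r,
                            &flee);
    agent_steps += b.n_alive;
    if (best_i >= 0 && best_d2 > 0) {
      double dx = min_image(tx - px, L);
      double dy = min_image(ty - py, L);
      double d = std::sqrt(best_d2);
      px = wrap_pos(px + speed_factor * v0 * dt * dx / d, L);
      py = wrap_pos(py + speed_factor * v0 * dt * dy / d, L);
    }
    // catches after both predator and agents have moved
    for (int i = 0; i < b.n; ++i) {
      if (!b.alive[i]) continue;
      if (pdist2(px, py, b.x[i], b.y[i], L) < rc2) {
        b.alive[i] = 0;
        --b.n_alive;
        catch_times.push_back(t);
        catch_ids.push_back(i + 1);
      }
    }
  }

  NumericMatrix np(b.n, 2);
  NumericVector nt(b.n);
  LogicalVector na(b.n);
  for (int i = 0; i < b.n; ++i) {
    np(i, 0) = b.x[i];
    np(i, 1) = b.y[i];
    nt[i] = b.th[i];
    na[i] = (b.alive[i] != 0);
  }
  double mean_degree =
      agent_steps > 0 ? (double)degree_sum / (double)agent_steps : NA_REAL;
  return List::create(
      _["catch_times"] = wrap(catch_times), _["catch_ids"] = wrap(catch_ids),
      _["survivors"] = b.n_alive, _["mean_degree"] = mean_degree,
      _["pos"] = np, _["theta"] = nt, _["alive"] = na,
      _["pred_pos"] = NumericVector::create(px, py));
}
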