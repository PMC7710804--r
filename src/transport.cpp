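#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact solver for the balanced transportation problem
//   min sum_ij C_ij x_ij  s.t.  sum_j x_ij = a_i, sum_i x_ij = b_j, x >= 0
// by successive shortest augmenting paths with node potentials (Dijkstra on
// the residual bipartite graph). Masses are real-valued; each augmentation
// saturates a supply, a demand, or empties a residual arc, so the number of
// augmentations is O(m + n) in practice. Costs must be non-negative.
static double solve_transport(const std::vector<double>& C, int m, int n,
                              std::vector<double> a, std::vector<double> b,
                              bool& feasible) {
  const double EPS = 1e-13;
  std::vector<double> x(static_cast<size_t>(m) * n, 0.0);
  std::vector<double> ps(m, 0.0), pt(n, 0.0);
  double total = 0.0;
  for (double s : a) total += s;
  double flow = 0.0;
  const int N = m + n;
  std::vector<double> dist(N);
  std::vector<int> prev(N);
  std::vector<char> done(N);

  // Small non-negative integer costs (e.g. a hop ground metric) admit a
  // Dial bucket queue; potentials then stay integral and each Dijkstra is
  // linear in the number of arcs instead of quadratic in nodes.
  bool int_costs = true;
  for (double c : C)
    if (c < 0 || c > 4096 || c != std::floor(c)) { int_costs = false; break; }
  std::vector<std::vector<int>> buckets;

  while (total - flow > 1e-12) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    std::fill(prev.begin(), prev.end(), -1);
    std::fill(done.begin(), done.end(), 0);
    int tj = -1;       // first demand sink finalized = nearest one
    double dT = R_PosInf;

    // relax all residual arcs out of a finalized node u
    auto relax = [&](int u, auto push) {
      if (u < m) {
        const double* crow = &C[static_cast<size_t>(u) * n];
        for (int j = 0; j < n; j++) {
          double rc = crow[j] + ps[u] - pt[j];
          if (rc < 0) rc = 0;  // clamp fp noise; exact on basis arcs
          double nd = dist[u] + rc;
          if (nd < dist[m + j] && !done[m + j]) {
            dist[m + j] = nd; prev[m + j] = u; push(m + j, nd);
          }
        }
      } else {
        int j = u - m;
        for (int i = 0; i < m; i++) {
          if (x[static_cast<size_t>(i) * n + j] > EPS) {
            double rc = -C[static_cast<size_t>(i) * n + j] - ps[i] + pt[j];
            if (rc < 0) rc = 0;
            double nd = dist[u] + rc;
            if (nd < dist[i] && !done[i]) {
              dist[i] = nd; prev[i] = u; push(i, nd);
            }
          }
        }
      }
    };

    if (int_costs) {
      buckets.assign(1, {});
      for (int i = 0; i < m; i++)
        if (a[i] > EPS) { dist[i] = 0.0; buckets[0].push_back(i); }
      auto push = [&](int v, double nd) {
        size_t d = (size_t)nd;
        if (d >= buckets.size()) buckets.resize(d + 1);
        buckets[d].push_back(v);
      };
      for (size_t d = 0; d < buckets.size() && tj < 0; d++) {
        for (size_t q = 0; q < buckets[d].size(); q++) {
          int u = buckets[d][q];
          if (done[u] || dist[u] != (double)d) continue;  // stale entry
          done[u] = 1;
          if (u >= m && b[u - m] > EPS) { tj = u - m; dT = dist[u]; break; }
          relax(u, push);
        }
      }
    } else {
      for (int i = 0; i < m; i++) if (a[i] > EPS) dist[i] = 0.0;
      for (int it = 0; it < N; ++it) {
        int u = -1;
        double best = R_PosInf;
        for (int k = 0; k < N; k++)
          if (!done[k] && dist[k] < best) { best = dist[k]; u = k; }
        if (u < 0) break;
        done[u] = 1;
        if (u >= m && b[u - m] > EPS) { tj = u - m; dT = dist[u]; break; }
        relax(u, [](int, double) {});
      }
    }
    if (tj < 0) { feasible = false; return NA_REAL; }

    // bottleneck along the augmenting path
    double bot = b[tj];
    int cur = m + tj;
    while (prev[cur] >= 0) {
      int p = prev[cur];
      if (cur < m)  // backward arc (sink p-m) -> (source cur)
        bot = std::min(bot, x[static_cast<size_t>(cur) * n + (p - m)]);
      cur = p;
    }
    bot = std::min(bot, a[cur]);

    int c2 = m + tj;
    while (prev[c2] >= 0) {
      int p = prev[c2];
      if (c2 >= m) x[static_cast<size_t>(p) * n + (c2 - m)] += bot;
      else         x[static_cast<size_t>(c2) * n + (p - m)] -= bot;
      c2 = p;
    }
    a[c2] -= bot;
    b[tj] -= bot;
    flow += bot;

    // capped potential update (early-terminated Dijkstra): nodes beyond
    // the target keep reduced costs non-negative with the cap dT
    for (int i = 0; i < m; i++)
      ps[i] += R_FINITE(dist[i]) ? std::min(dist[i], dT) : dT;
    for (int j = 0; j < n; j++)
      pt[j] += R_FINITE(dist[m + j]) ? std::min(dist[m + j], dT) : dT;
  }

  double cost = 0.0;
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++)
      cost += x[static_cast<size_t>(i) * n + j] * C[static_cast<size_t>(i) * n + j];
  feasible = true;
  return cost;
}

// [[Rcpp::export(name = ".wasserstein1_cpp")]]
double wasserstein1_cpp(NumericMatrix cost, NumericVector a, NumericVector b) {
  int m = cost.nrow(), n = cost.ncol();
  if (a.size() != m || b.size() != n)
    stop("mass vectors do not match the cost matrix");
  std::vector<double> C(static_cast<size_t>(m) * n);
  for (int i = 0; i < m; i++)
    for (int j = 0; j < n; j++) {
      double c = cost(i, j);
      if (!R_FINITE(c)) {
        if (a[i] > 1e-13 && b[j] > 1e-13) stop("supports disconnected");
        c = 0.0;  // unreachable but massless: arc never used
      }
      C[static_cast<size_t>(i) * n + j] = c;
    }
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  bool ok = false;
  double w = solve_transport(C, m, n, av, bv, ok);
  if (!ok) stop("supports disconnected");
  return w;
}

// All-edge Ollivier-Ricci curvature for one weighted graph.
// W: symmetric non-negative weight matrix, zero diagonal.
// D: ground metric between nodes (hop counts or weighted geodesics).
// idleness: probability mass retained at the anchor node.
// Returns a matrix with columns (i, j, weight, kappa), i < j, 1-based ids.
// [[Rcpp::export(name = ".orc_edges_cpp")]]
NumericMatrix orc_edges_cpp(NumericMatrix W, NumericMatrix D, double idleness) {
  int N = W.nrow();
  std::vector<std::vector<int>> nbr(N);
  std::vector<double> strength(N, 0.0);
  for (int i = 0; i < N; i++)
    for (int j = 0; j < N; j++)
      if (W(i, j) > 0) { nbr[i].push_back(j); strength[i] += W(i, j); }

  int n_edges = 0;
  for (int i = 0; i < N; i++)
    for (int j = i + 1; j < N; j++) if (W(i, j) > 0) n_edges++;
  NumericMatrix out(n_edges, 4);

  int row = 0;
  std::vector<int> si, sj;
  std::vector<double> mi, mj, C;
  for (int i = 0; i < N; i++) {
    for (int j = i + 1; j < N; j++) {
      if (!(W(i, j) > 0)) continue;
      // lazy random-walk measures: idleness at anchor, rest ~ edge weights
      si.clear(); mi.clear();
      si.push_back(i); mi.push_back(idleness);
      for (int k : nbr[i]) {
        si.push_back(k);
        mi.push_back((1.0 - idleness) * W(i, k) / strength[i]);
      }
      sj.clear(); mj.clear();
      sj.push_back(j); mj.push_back(idleness);
      for (int k : nbr[j]) {
        sj.push_back(k);
        mj.push_back((1.0 - idleness) * W(j, k) / strength[j]);
      }
      // The ground cost is a graph metric, so mass shared between the two
      // measures can stay in place in some optimal plan:
      //   W1(mu, nu) = W1((mu - nu)+, (nu - mu)+).
      // Cancelling the overlap shrinks the LP dramatically on dense
      // graphs, where adjacent nodes share most of their neighbourhoods.
      {
        std::vector<double> residual_j(sj.size());
        for (size_t q = 0; q < sj.size(); q++) residual_j[q] = mj[q];
        for (size_t p = 0; p < si.size(); p++) {
          for (size_t q = 0; q < sj.size(); q++) {
            if (si[p] == sj[q]) {
              double o = std::min(mi[p], residual_j[q]);
              mi[p] -= o;
              residual_j[q] -= o;
              break;
            }
          }
        }
        size_t keep = 0;
        for (size_t p = 0; p < si.size(); p++)
          if (mi[p] > 1e-15) { si[keep] = si[p]; mi[keep] = mi[p]; keep++; }
        si.resize(keep); mi.resize(keep);
        keep = 0;
        for (size_t q = 0; q < sj.size(); q++)
          if (residual_j[q] > 1e-15) {
            sj[keep] = sj[q]; mj[keep] = residual_j[q]; keep++;
          }
        sj.resize(keep); mj.resize(keep);
      }
      double kappa = NA_REAL;
      if (si.empty() || sj.empty()) {
        kappa = 1.0;  // measures coincide: zero transport cost
      } else {
        // rebalance fp drift so both residuals carry identical mass
        double ma = 0.0, mb = 0.0;
        for (double v : mi) ma += v;
        for (double v : mj) mb += v;
        for (double& v : mi) v /= ma;
        for (double& v : mj) v /= mb;
        double scale = 0.5 * (ma + mb);
        int m = (int)si.size(), n = (int)sj.size();
        C.assign(static_cast<size_t>(m) * n, 0.0);
        bool disconnected = false;
        for (int p = 0; p < m && !disconnected; p++)
          for (int q = 0; q < n; q++) {
            double c = D(si[p], sj[q]);
            if (!R_FINITE(c)) { disconnected = true; break; }
            C[static_cast<size_t>(p) * n + q] = c;
          }
        if (!disconnected) {
          bool ok = false;
          std::vector<double> av(mi), bv(mj);
          double w1 = scale * solve_transport(C, m, n, av, bv, ok);
          if (ok) kappa = 1.0 - w1 / D(i, j);
        }
      }
      out(row, 0) = i + 1;
      out(row, 1) = j + 1;
      out(row, 2) = W(i, j);
      out(row, 3) = kappa;
      row++;
    }
  }
  return out;
}
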