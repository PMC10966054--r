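#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Exact solver for the balanced transportation problem
//   min sum_ij C_ij X_ij  s.t.  X 1 = a, X^T 1 = b, X >= 0,
// by the primal transportation simplex (u-v / MODI method) on a spanning-tree
// basis. Degeneracy is handled by keeping zero-flow basic arcs; anti-cycling
// falls back to Bland's rule if the pivot count grows unusually large.

namespace {

struct Basis {
  int m, n;
  std::vector<int> row, col;        // basic arc endpoints
  std::vector<double> flow;         // basic arc flows
  // adjacency: node -> indices of incident basic arcs (rows: 0..m-1, cols: m..m+n-1)
  std::vector<std::vector<int> > adj;

  Basis(int m_, int n_) : m(m_), n(n_), adj(m_ + n_) {}

  void add(int i, int j, double f) {
    row.push_back(i); col.push_back(j); flow.push_back(f);
    int k = (int)row.size() - 1;
    adj[i].push_back(k);
    adj[m + j].push_back(k);
  }
  void drop(int k) {
    int i = row[k], j = m + col[k];
    for (size_t t = 0; t < adj[i].size(); ++t)
      if (adj[i][t] == k) { adj[i].erase(adj[i].begin() + t); break; }
    for (size_t t = 0; t < adj[j].size(); ++t)
      if (adj[j][t] == k) { adj[j].erase(adj[j].begin() + t); break; }
  }
  void replace(int k, int i, int j, double f) {
    drop(k);
    row[k] = i; col[k] = j; flow[k] = f;
    adj[i].push_back(k);
    adj[m + j].push_back(k);
  }
};

} // namespace

// [[Rcpp::export]]
List transport_simplex_cpp(NumericMatrix cost, NumericVector a, NumericVector b,
                           double tol = 1e-11, int max_iter = -1) {
  const int m = a.size(), n = b.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match the marginals");
  if (max_iter < 0) max_iter = 4000 * (m + n) + 1000;

  Basis B(m, n);

  // North-west corner initial basic feasible solution: m+n-1 arcs.
  {
    std::vector<double> ra(a.begin(), a.end()), rb(b.begin(), b.end());
    int i = 0, j = 0;
    while (true) {
      double x = std::min(ra[i], rb[j]);
      B.add(i, j, x);
      ra[i] -= x; rb[j] -= x;
      if (i == m - 1 && j == n - 1) break;
      if (ra[i] <= tol && i < m - 1) ++i; else ++j;
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<char> seen(m + n);
  std::vector<int> par_arc(m + n), par_node(m + n);

  int iter = 0;
  bool bland = false;
  while (true) {
    if (++iter > max_iter)
      stop("transportation simplex failed to converge (degenerate cycling?)");
    if (iter > max_iter / 2) bland = true;

    // duals via BFS over the basis tree (u[0] = 0)
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> q;
    q.push(0); seen[0] = 1; u[0] = 0.0;
    while (!q.empty()) {
      int x = q.front(); q.pop();
      for (size_t t = 0; t < B.adj[x].size(); ++t) {
        int k = B.adj[x][t];
        int other = (x < m) ? (m + B.col[k]) : B.row[k];
        if (seen[other]) continue;
        seen[other] = 1;
        if (other >= m) v[other - m] = cost(B.row[k], B.col[k]) - u[B.row[k]];
        else            u[other]     = cost(B.row[k], B.col[k]) - v[B.col[k]];
        q.push(other);
      }
    }

    // entering arc: most negative reduced cost (Bland: first negative)
    int ei = -1, ej = -1; double best = -tol;
    for (int i = 0; i < m && !(bland && ei >= 0); ++i)
      for (int j = 0; j < n; ++j) {
        double rc = cost(i, j) - u[i] - v[j];
        if (rc < best) { best = rc; ei = i; ej = j; if (bland) break; }
      }
    if (ei < 0) break; // optimal

    // unique tree path from row node ei to col node (m+ej)
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> bq;
    bq.push(ei); seen[ei] = 1; par_arc[ei] = -1;
    while (!bq.empty()) {
      int x = bq.front(); bq.pop();
      if (x == m + ej) break;
      for (size_t t = 0; t < B.adj[x].size(); ++t) {
        int k = B.adj[x][t];
        int other = (x < m) ? (m + B.col[k]) : B.row[k];
        if (seen[other]) continue;
        seen[other] = 1; par_arc[other] = k; par_node[other] = x;
        bq.push(other);
      }
    }

    // walk back from col ej to row ei; arcs alternate -,+ starting with '-'
    std::vector<int> path;
    for (int x = m + ej; x != ei; x = par_node[x]) path.push_back(par_arc[x]);
    double theta = R_PosInf; int leave = -1;
    for (size_t t = 0; t < path.size(); t += 2) { // minus arcs
      int k = path[t];
      if (B.flow[k] < theta - 1e-15 || (leave >= 0 && std::abs(B.flow[k] - theta) <= 1e-15 && k < leave)) {
        theta = B.flow[k]; leave = k;
      }
    }
    for (size_t t = 0; t < path.size(); ++t)
      B.flow[path[t]] += (t % 2 == 0) ? -theta : theta;
    B.flow[leave] = 0.0;
    B.replace(leave, ei, ej, theta);
  }

  double total = 0.0;
  int nb = (int)B.row.size();
  IntegerVector ri(nb), ci(nb);
  NumericVector f(nb);
  for (int k = 0; k < nb; ++k) {
    double fk = B.flow[k] < 0 ? 0.0 : B.flow[k];
    ri[k] = B.row[k] + 1; ci[k] = B.col[k] + 1; f[k] = fk;
    total += cost(B.row[k], B.col[k]) * fk;
  }
  return List::create(_["cost"] = total, _["i"] = ri, _["j"] = ci,
                      _["mass"] = f, _["iterations"] = iter);
}
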