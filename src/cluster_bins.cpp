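#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Density-based clustering of one point subset given a precomputed full
// pairwise distance matrix. Core point: >= min_neighbors OTHER points within
// eps. Clusters: connected components of core points (core-core distance
// <= eps) plus border points attached to their nearest core. Points that are
// neither core nor border become singleton clusters -- no point is dropped.
static void cluster_one_bin(const NumericMatrix &dmat,
                            const std::vector<int> &idx, double eps,
                            int min_neighbors, List &out, int &pos) {
  const int nb = (int)idx.size();
  if (nb == 0) return;
  if (nb == 1) { out[pos++] = IntegerVector::create(idx[0] + 1); return; }

  std::vector<int> nnb(nb, 0);
  for (int i = 0; i < nb; ++i)
    for (int j = i + 1; j < nb; ++j)
      if (dmat(idx[i], idx[j]) <= eps) { ++nnb[i]; ++nnb[j]; }

  std::vector<char> core(nb);
  for (int i = 0; i < nb; ++i) core[i] = nnb[i] >= min_neighbors;

  std::vector<int> cl(nb, -1);
  int ncl = 0;
  // components of core points
  std::vector<int> stack;
  for (int s = 0; s < nb; ++s) {
    if (!core[s] || cl[s] >= 0) continue;
    cl[s] = ncl; stack.push_back(s);
    while (!stack.empty()) {
      int x = stack.back(); stack.pop_back();
      for (int j = 0; j < nb; ++j)
        if (core[j] && cl[j] < 0 && dmat(idx[x], idx[j]) <= eps) {
          cl[j] = ncl; stack.push_back(j);
        }
    }
    ++ncl;
  }
  // border points: nearest core within eps (ties: first core index)
  for (int i = 0; i < nb; ++i) {
    if (core[i] || cl[i] >= 0) continue;
    int best = -1; double bd = eps;
    for (int j = 0; j < nb; ++j)
      if (core[j] && dmat(idx[i], idx[j]) <= bd &&
          (best < 0 || dmat(idx[i], idx[j]) < bd)) {
        bd = dmat(idx[i], idx[j]); best = j;
      }
    if (best >= 0) cl[i] = cl[best];
  }
  // noise -> singleton clusters
  for (int i = 0; i < nb; ++i) if (cl[i] < 0) cl[i] = ncl++;

  std::vector<std::vector<int> > groups(ncl);
  for (int i = 0; i < nb; ++i) groups[cl[i]].push_back(idx[i] + 1);
  for (int g = 0; g < ncl; ++g)
    out[pos++] = IntegerVector(groups[g].begin(), groups[g].end());
}

// [[Rcpp::export]]
List cluster_bins_cpp(NumericMatrix dmat, List bins, double eps,
                      int min_neighbors) {
  int cap = 0;
  for (int b = 0; b < bins.size(); ++b)
    cap += ((IntegerVector)bins[b]).size();
  List out(cap == 0 ? 0 : cap);
  int pos = 0;
  for (int b = 0; b < bins.size(); ++b) {
    IntegerVector mem = bins[b];
    std::vector<int> idx(mem.size());
    for (int t = 0; t < mem.size(); ++t) idx[t] = mem[t] - 1;
    cluster_one_bin(dmat, idx, eps, min_neighbors, out, pos);
  }
  if (pos < out.size()) {
    List trimmed(pos);
    for (int t = 0; t < pos; ++t) trimmed[t] = out[t];
    return trimmed;
  }
  return out;
}
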