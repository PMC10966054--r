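#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
using namespace Rcpp;

// edges of the cluster-overlap (nerve) graph: an edge joins clusters u < v
// iff they share at least one frame; enumerated via each frame's cluster list
// [[Rcpp::export]]
IntegerMatrix overlap_edges_cpp(List clusters, int n_frames) {
  std::vector<std::vector<int> > frame_cl(n_frames);
  for (int c = 0; c < clusters.size(); ++c) {
    IntegerVector mem = clusters[c];
    for (int t = 0; t < mem.size(); ++t) {
      int f = mem[t] - 1;
      if (f < 0 || f >= n_frames) stop("frame index out of range");
      frame_cl[f].push_back(c + 1);
    }
  }
  std::set<std::pair<int,int> > edges;
  for (int f = 0; f < n_frames; ++f) {
    const std::vector<int> &cl = frame_cl[f];
    for (size_t a = 0; a < cl.size(); ++a)
      for (size_t b = a + 1; b < cl.size(); ++b) {
        int u = cl[a], v = cl[b];
        if (u > v) std::swap(u, v);
        if (u != v) edges.insert(std::make_pair(u, v));
      }
  }
  IntegerMatrix out(edges.size(), 2);
  int r = 0;
  for (std::set<std::pair<int,int> >::const_iterator it = edges.begin();
       it != edges.end(); ++it, ++r) {
    out(r, 0) = it->first;
    out(r, 1) = it->second;
  }
  return out;
}
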