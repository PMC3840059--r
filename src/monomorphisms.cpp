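// Subgraph monomorphism counting by backtracking.
//
// A monomorphism maps the pattern's vertices injectively into the host so
// that every pattern edge lands on a host edge (non-induced matching).
// Instances of a pattern as edge subsets of the host are monomorphisms
// divided by the pattern's automorphism count; multiplied by the pattern's
// covering-walk count this yields the factorized walk census.  Patterns
// here are tiny (<= 9 vertices for a length-8 walk), hosts are
// connectome-sized (hundreds of vertices), so a simple ordered backtracking
// search with O(1) adjacency checks is the right tool.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

struct Pattern {
  int np;                               // number of pattern vertices
  std::vector<int> order;               // visit order (BFS from max degree)
  std::vector<std::vector<int>> back;   // for order position i: earlier positions adjacent in pattern
};

Pattern plan_pattern(const IntegerMatrix& pedges, int np) {
  std::vector<std::vector<bool>> padj(np, std::vector<bool>(np, false));
  std::vector<int> pdeg(np, 0);
  for (int e = 0; e < pedges.nrow(); ++e) {
    int a = pedges(e, 0) - 1, b = pedges(e, 1) - 1;
    padj[a][b] = padj[b][a] = true;
    ++pdeg[a]; ++pdeg[b];
  }
  Pattern pl;
  pl.np = np;
  std::vector<bool> placed(np, false);
  int start = 0;
  for (int v = 1; v < np; ++v) if (pdeg[v] > pdeg[start]) start = v;
  pl.order.push_back(start); placed[start] = true;
  while ((int)pl.order.size() < np) {
    // next: unplaced vertex adjacent to the placed set with most placed neighbors
    int best = -1, bestc = -1;
    for (int v = 0; v < np; ++v) {
      if (placed[v]) continue;
      int c = 0;
      for (int u : pl.order) if (padj[v][u]) ++c;
      if (c > bestc) { bestc = c; best = v; }
    }
    pl.order.push_back(best); placed[best] = true;
  }
  pl.back.resize(np);
  for (int i = 1; i < np; ++i)
    for (int j = 0; j < i; ++j)
      if (padj[pl.order[i]][pl.order[j]]) pl.back[i].push_back(j);
  return pl;
}

double recurse(int pos, const Pattern& pl,
               const std::vector<std::vector<int>>& gadjlist,
               const std::vector<std::vector<bool>>& gadj,
               std::vector<int>& image, std::vector<bool>& used) {
  if (pos == pl.np) return 1.0;
  const std::vector<int>& anchors = pl.back[pos];
  // candidates: host neighbors of the first anchored image (pattern is
  // connected, so pos >= 1 always has an anchor)
  const std::vector<int>& cand = gadjlist[image[anchors[0]]];
  double total = 0.0;
  for (int g : cand) {
    if (used[g]) continue;
    bool ok = true;
    for (size_t k = 1; k < anchors.size(); ++k)
      if (!gadj[g][image[anchors[k]]]) { ok = false; break; }
    if (!ok) continue;
    used[g] = true; image[pos] = g;
    total += recurse(pos + 1, pl, gadjlist, gadj, image, used);
    used[g] = false;
  }
  return total;
}

} // namespace

// [[Rcpp::export]]
double count_monomorphisms_cpp(IntegerMatrix pat_edges, int n_pattern,
                               IntegerMatrix host_edges, int n_host) {
  if (pat_edges.nrow() == 0 || n_pattern < 2) stop("pattern must have at least one edge");
  std::vector<std::vector<bool>> gadj(n_host, std::vector<bool>(n_host, false));
  std::vector<std::vector<int>> gadjlist(n_host);
  for (int e = 0; e < host_edges.nrow(); ++e) {
    int a = host_edges(e, 0) - 1, b = host_edges(e, 1) - 1;
    if (!gadj[a][b]) {
      gadj[a][b] = gadj[b][a] = true;
      gadjlist[a].push_back(b);
      gadjlist[b].push_back(a);
    }
  }
  Pattern pl = plan_pattern(pat_edges, n_pattern);
  std::vector<int> image(n_pattern, -1);
  std::vector<bool> used(n_host, false);
  double total = 0.0;
  for (int g = 0; g < n_host; ++g) {
    used[g] = true; image[0] = g;
    total += recurse(1, pl, gadjlist, gadj, image, used);
    used[g] = false;
  }
  return total;
}
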