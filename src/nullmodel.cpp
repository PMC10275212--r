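#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sequential rank-matching reassignment of edge weights, preserving the
// binary topology (hence the degree sequence) and the weight multiset
// exactly while approximately preserving node strengths.
//
// Edges are visited in the supplied random order. At each step the visited
// edge receives the still-unassigned weight whose descending rank equals the
// rank of the edge's residual strength product max(s_i,0)*max(s_j,0) among
// all unassigned edges; the assigned weight is then subtracted from both
// endpoint residual strengths.
//
// ei, ej: 0-based endpoints per edge; w: observed weights per edge;
// s: original node strengths; order: 0-based processing order (a permutation
// of the edges). Returns the reassigned weight per edge.
// [[Rcpp::export]]
NumericVector strength_match_cpp(IntegerVector ei, IntegerVector ej,
                                 NumericVector w, NumericVector s,
                                 IntegerVector order) {
  const int E = ei.size();
  std::vector<double> pool(w.begin(), w.end());
  std::sort(pool.begin(), pool.end(), std::greater<double>());
  std::vector<double> sres(s.begin(), s.end());
  std::vector<char> assigned(E, 0);
  NumericVector out(E);

  for (int step = 0; step < E; ++step) {
    const int e = order[step];
    const double pi = std::max(sres[ei[e]], 0.0);
    const double pj = std::max(sres[ej[e]], 0.0);
    const double pe = pi * pj;
    int rank = 0;
    for (int f = 0; f < E; ++f) {
      if (assigned[f] || f == e) continue;
      double q = std::max(sres[ei[f]], 0.0) * std::max(sres[ej[f]], 0.0);
      if (q > pe || (q == pe && f < e)) ++rank;
    }
    const double wnew = pool[rank];
    pool.erase(pool.begin() + rank);
    out[e] = wnew;
    assigned[e] = 1;
    sres[ei[e]] -= wnew;
    sres[ej[e]] -= wnew;
  }
  return out;
}
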