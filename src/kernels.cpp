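#include <Rcpp.h>
#include <cstdlib>
using namespace Rcpp;

// Markov double-edge-swap rewiring shared by the randomized and latticized
// null models. Edges (a->b, c->d) become (a->d, c->b) when the swap creates
// no self-loop and no duplicate edge. In lattice mode a swap is additionally
// accepted only if it does not increase (strict: strictly decreases) the
// combined distance of the two edges from the diagonal of the connection
// matrix under the node ordering `ord`. Uses R's RNG so set.seed() governs
// reproducibility.
// [[Rcpp::export]]
List rewire_swaps_cpp(IntegerMatrix adjacency, int n_attempts, bool lattice,
                      IntegerVector ord, bool strict) {
  IntegerMatrix A = clone(adjacency);
  int n = A.nrow();
  std::vector<int> eu, ev;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (A(i, j)) { eu.push_back(i); ev.push_back(j); }
  int m = (int) eu.size();
  int accepted = 0;
  if (m < 2) {
    return List::create(_["adjacency"] = A, _["accepted"] = 0,
                        _["attempts"] = 0, _["n_edges"] = m);
  }
  for (int it = 0; it < n_attempts; ++it) {
    int i1 = (int) (unif_rand() * m);
    int i2 = (int) (unif_rand() * m);
    if (i1 == i2) continue;
    int a = eu[i1], b = ev[i1], c = eu[i2], d = ev[i2];
    // degenerate picks: nothing to swap, or swap would recreate the same edges
    if (a == c || b == d) continue;
    // self-loops a->d or c->b
    if (a == d || c == b) continue;
    // duplicate edges
    if (A(a, d) || A(c, b)) continue;
    if (lattice) {
      double oldcost = std::abs(ord[a] - ord[b]) + std::abs(ord[c] - ord[d]);
      double newcost = std::abs(ord[a] - ord[d]) + std::abs(ord[c] - ord[b]);
      if (strict ? (newcost >= oldcost) : (newcost > oldcost)) continue;
    }
    A(a, b) = 0; A(c, d) = 0;
    A(a, d) = 1; A(c, b) = 1;
    ev[i1] = d; ev[i2] = b;
    ++accepted;
  }
  return List::create(_["adjacency"] = A, _["accepted"] = accepted,
                      _["attempts"] = n_attempts, _["n_edges"] = m);
}

// Exact induced census of all connected 3-node subgraphs. `class_of_code`
// maps each 6-bit dyad configuration (bit order: i->j, j->i, i->k, k->i,
// j->k, k->j for the triple i<j<k) to a motif class 1..13, or 0 when the
// triple is not weakly connected. `apex_slot_of_code` gives, for apex
// classes, which of (i, j, k) = (0, 1, 2) sits at the apex, else -1.
// [[Rcpp::export]]
List triad_census_cpp(IntegerMatrix A, IntegerVector class_of_code,
                      IntegerVector apex_slot_of_code) {
  int n = A.nrow();
  IntegerVector counts(13);
  IntegerMatrix part(n, 13), apex(n, 13);
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 1; j < n - 1; ++j) {
      int bij = A(i, j), bji = A(j, i);
      for (int k = j + 1; k < n; ++k) {
        int code = bij | (bji << 1) | (A(i, k) << 2) | (A(k, i) << 3) |
                   (A(j, k) << 4) | (A(k, j) << 5);
        int cls = class_of_code[code];
        if (cls == 0) continue;
        counts[cls - 1] += 1;
        part(i, cls - 1) += 1;
        part(j, cls - 1) += 1;
        part(k, cls - 1) += 1;
        int slot = apex_slot_of_code[code];
        if (slot >= 0) {
          int node = (slot == 0) ? i : (slot == 1 ? j : k);
          apex(node, cls - 1) += 1;
        }
      }
    }
  }
  return List::create(_["class_count"] = counts, _["participation"] = part,
                      _["apex_count"] = apex);
}
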