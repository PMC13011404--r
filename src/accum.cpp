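#include <Rcpp.h>
using namespace Rcpp;

// Per-permutation counts of novel gene families discovered at each
// genome-addition step.  M is genomes x families (0/1); orders holds one
// 1-based genome permutation per row.  Returns an orders-rows x genomes
// matrix of new-family counts.
// [[Rcpp::export(name = ".accum_new_genes")]]
IntegerMatrix accum_new_genes(const IntegerMatrix& M,
                              const IntegerMatrix& orders) {
  const int G = M.nrow(), C = M.ncol(), P = orders.nrow();
  if (orders.ncol() != G)
    stop("orders must have one column per genome");

  // adjacency lists: families present in each genome
  std::vector< std::vector<int> > idx(G);
  for (int g = 0; g < G; ++g) {
    idx[g].reserve(64);
    for (int c = 0; c < C; ++c)
      if (M(g, c) != 0) idx[g].push_back(c);
  }

  IntegerMatrix out(P, G);
  std::vector<char> seen(C);
  for (int p = 0; p < P; ++p) {
    std::fill(seen.begin(), seen.end(), 0);
    for (int n = 0; n < G; ++n) {
      const int g = orders(p, n) - 1;
      if (g < 0 || g >= G) stop("order index out of range");
      int cnt = 0;
      const std::vector<int>& v = idx[g];
      for (size_t j = 0; j < v.size(); ++j) {
        if (!seen[v[j]]) { seen[v[j]] = 1; ++cnt; }
      }
      out(p, n) = cnt;
    }
  }
  return out;
}
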