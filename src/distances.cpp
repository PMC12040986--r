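#include <Rcpp.h>
using namespace Rcpp;

// Directed minimum Euclidean distances: for each row of `from` (N x 3,
// physical mm coordinates) the distance to the nearest row of `to` (M x 3).
// Plain exhaustive scan; surface sets from phantom-scale masks are small
// enough that no spatial index is needed.
// [[Rcpp::export(name = ".directed_min_dists")]]
NumericVector directed_min_dists(NumericMatrix from, NumericMatrix to) {
  const int n = from.nrow(), m = to.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double x = from(i, 0), y = from(i, 1), z = from(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      const double dx = x - to(j, 0), dy = y - to(j, 1), dz = z - to(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
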