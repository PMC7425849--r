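#include "meshtools.h"
using namespace Rcpp;
using namespace s3d;

// Closest points on a triangle mesh for a set of query points.
// Returns nearest surface points, distances and 0-based face indices.
// [[Rcpp::export(name = ".cpp_closest_points")]]
List cpp_closest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  TriGrid grid;
  grid.build(V, F);
  int n = Q.nrow();
  NumericMatrix P(n, 3);
  NumericVector d(n);
  IntegerVector face(n);
  for (int i = 0; i < n; ++i) {
    Vec3 p(Q(i, 0), Q(i, 1), Q(i, 2)), out;
    int f;
    double d2 = grid.query(p, out, f);
    P(i, 0) = out.x; P(i, 1) = out.y; P(i, 2) = out.z;
    d[i] = std::sqrt(d2);
    face[i] = f;
  }
  return List::create(_["point"] = P, _["distance"] = d, _["face"] = face);
}
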