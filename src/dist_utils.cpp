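#include <Rcpp.h>
using namespace Rcpp;

static inline double wrap(double d, double L) {
  if (L > 0.0) d -= L * std::round(d / L);
  return d;
}

// Histogram of minimum-image pair distances between group A rows and group B
// rows of a single frame. When `same_group` is true, A and B are the same
// set and each unordered pair is counted twice (observer convention of RDF).
// [[Rcpp::export(name = ".pair_dist_hist_cpp")]]
NumericVector pair_dist_hist_cpp(NumericMatrix a, NumericMatrix b,
                                 NumericVector box, double bin_width,
                                 double r_max, bool same_group) {
  const int na = a.nrow(), nb = b.nrow();
  const int nbins = (int)std::ceil(r_max / bin_width);
  NumericVector h(nbins);
  const double bx = box[0], by = box[1], bz = box[2];
  const double r2max = r_max * r_max;
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      if (same_group && i == j) continue;
      double dx = wrap(a(i, 0) - b(j, 0), bx);
      double dy = wrap(a(i, 1) - b(j, 1), by);
      double dz = wrap(a(i, 2) - b(j, 2), bz);
      double r2 = dx * dx + dy * dy + dz * dz;
      if (r2 >= r2max) continue;
      int bin = (int)(std::sqrt(r2) / bin_width);
      if (bin >= 0 && bin < nbins) h[bin] += 1.0;
    }
  }
  return h;
}

// Full minimum-image distance matrix between two coordinate sets.
// box of length 3 with zeros/negatives meaning non-periodic in that axis.
// [[Rcpp::export(name = ".min_image_dist_cpp")]]
NumericMatrix min_image_dist_cpp(NumericMatrix a, NumericMatrix b,
                                 NumericVector box) {
  const int na = a.nrow(), nb = b.nrow();
  NumericMatrix out(na, nb);
  const double bx = box[0], by = box[1], bz = box[2];
  for (int i = 0; i < na; ++i)
    for (int j = 0; j < nb; ++j) {
      double dx = wrap(a(i, 0) - b(j, 0), bx);
      double dy = wrap(a(i, 1) - b(j, 1), by);
      double dz = wrap(a(i, 2) - b(j, 2), bz);
      out(i, j) = std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  return out;
}
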