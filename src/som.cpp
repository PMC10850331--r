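#include <Rcpp.h>
using namespace Rcpp;

// Online SOM training on a square grid.
//
// x:      genes x samples data matrix
// w:      nodes x samples initial weight matrix (modified copy returned)
// coords: nodes x 2 grid coordinates (row, col)
// order:  epochs x genes matrix of 1-based gene presentation orders
// radius0/radius1, rate0/rate1: linear decay endpoints over all steps
//
// Returns list(weights, qe) where qe[e] is the mean squared distance of
// every gene to its best-matching node evaluated at the end of epoch e.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix x, NumericMatrix w, NumericMatrix coords,
                   IntegerMatrix order, double radius0, double radius1,
                   double rate0, double rate1) {
  const int ngene = x.nrow(), ns = x.ncol(), nnode = w.nrow();
  const int epochs = order.nrow();
  const double total = (double)epochs * ngene;
  NumericMatrix W = clone(w);
  NumericVector qe(epochs);
  long step = 0;

  for (int e = 0; e < epochs; ++e) {
    for (int t = 0; t < ngene; ++t, ++step) {
      const int g = order(e, t) - 1;
      const double frac = total > 1 ? step / (total - 1) : 0.0;
      const double radius = radius0 + (radius1 - radius0) * frac;
      const double rate = rate0 + (rate1 - rate0) * frac;

      // best-matching node
      int bmu = 0;
      double best = R_PosInf;
      for (int i = 0; i < nnode; ++i) {
        double d = 0;
        for (int j = 0; j < ns; ++j) {
          const double diff = W(i, j) - x(g, j);
          d += diff * diff;
        }
        if (d < best) { best = d; bmu = i; }
      }

      // gaussian neighbourhood update
      const double r2 = coords(bmu, 0), c2 = coords(bmu, 1);
      const double denom = 2.0 * radius * radius;
      for (int i = 0; i < nnode; ++i) {
        const double dr = coords(i, 0) - r2, dc = coords(i, 1) - c2;
        const double h = std::exp(-(dr * dr + dc * dc) / denom);
        const double a = rate * h;
        if (a < 1e-6) continue;
        for (int j = 0; j < ns; ++j)
          W(i, j) += a * (x(g, j) - W(i, j));
      }
    }

    // quantization error at epoch end
    double sum = 0;
    for (int g = 0; g < ngene; ++g) {
      double best = R_PosInf;
      for (int i = 0; i < nnode; ++i) {
        double d = 0;
        for (int j = 0; j < ns; ++j) {
          const double diff = W(i, j) - x(g, j);
          d += diff * diff;
        }
        if (d < best) best = d;
      }
      sum += best;
    }
    qe[e] = sum / ngene;
  }
  return List::create(_["weights"] = W, _["qe"] = qe);
}

// Nearest node (1-based) for every gene. Ties go to the lowest node index.
// [[Rcpp::export]]
IntegerVector som_assign_cpp(NumericMatrix x, NumericMatrix w) {
  const int ngene = x.nrow(), ns = x.ncol(), nnode = w.nrow();
  IntegerVector out(ngene);
  for (int g = 0; g < ngene; ++g) {
    int bmu = 0;
    double best = R_PosInf;
    for (int i = 0; i < nnode; ++i) {
      double d = 0;
      for (int j = 0; j < ns; ++j) {
        const double diff = w(i, j) - x(g, j);
        d += diff * diff;
      }
      if (d < best) { best = d; bmu = i; }
    }
    out[g] = bmu + 1;
  }
  return out;
}
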