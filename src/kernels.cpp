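#include <Rcpp.h>
using namespace Rcpp;

// Pairwise spatial kernels for mIHC fields. Fields hold at most a few
// thousand cells, but cohort-scale simulations evaluate hundreds of
// thousands of (field, phenotype-pair) combinations, so the inner loops
// live here. Identifier vectors carry integer codes; a pair is skipped when
// both codes are non-negative and equal (the same physical cell appearing
// in both the reference and the target set).

static inline bool same_cell(int a, int b) { return a >= 0 && a == b; }

// Within-radius neighbour counts per reference point. Planar distances use
// a cell-list grid with bin edge >= r (3x3 neighbourhood search); toroidal
// distances (used for edge-effect-free calibration) wrap both axes.
// [[Rcpp::export]]
IntegerVector cpp_count_within_radius(NumericVector xr, NumericVector yr,
                                      IntegerVector idr,
                                      NumericVector xt, NumericVector yt,
                                      IntegerVector idt,
                                      double r, bool torus,
                                      double width, double height) {
  const int nr = xr.size(), nt = xt.size();
  IntegerVector out(nr);
  const double r2 = r * r;

  if (torus) {
    for (int i = 0; i < nr; ++i) {
      int c = 0;
      for (int j = 0; j < nt; ++j) {
        if (same_cell(idr[i], idt[j])) continue;
        double dx = std::fabs(xr[i] - xt[j]);
        double dy = std::fabs(yr[i] - yt[j]);
        if (dx > 0.5 * width)  dx = width - dx;
        if (dy > 0.5 * height) dy = height - dy;
        if (dx * dx + dy * dy <= r2) ++c;
      }
      out[i] = c;
    }
    return out;
  }

  const int nbx = std::max(1, (int)std::floor(width / r));
  const int nby = std::max(1, (int)std::floor(height / r));
  const double bw = width / nbx, bh = height / nby;

  std::vector<int> bin(nt), start(nbx * nby + 1, 0), order(nt);
  for (int j = 0; j < nt; ++j) {
    int bx = std::min(nbx - 1, std::max(0, (int)(xt[j] / bw)));
    int by = std::min(nby - 1, std::max(0, (int)(yt[j] / bh)));
    bin[j] = by * nbx + bx;
    ++start[bin[j] + 1];
  }
  for (int b = 0; b < nbx * nby; ++b) start[b + 1] += start[b];
  {
    std::vector<int> cursor(start.begin(), start.end() - 1);
    for (int j = 0; j < nt; ++j) order[cursor[bin[j]]++] = j;
  }

  for (int i = 0; i < nr; ++i) {
    int bx = std::min(nbx - 1, std::max(0, (int)(xr[i] / bw)));
    int by = std::min(nby - 1, std::max(0, (int)(yr[i] / bh)));
    int c = 0;
    for (int gy = std::max(0, by - 1); gy <= std::min(nby - 1, by + 1); ++gy)
      for (int gx = std::max(0, bx - 1); gx <= std::min(nbx - 1, bx + 1); ++gx) {
        const int b = gy * nbx + gx;
        for (int k = start[b]; k < start[b + 1]; ++k) {
          const int j = order[k];
          if (same_cell(idr[i], idt[j])) continue;
          const double dx = xr[i] - xt[j], dy = yr[i] - yt[j];
          if (dx * dx + dy * dy <= r2) ++c;
        }
      }
    out[i] = c;
  }
  return out;
}

// One pass over all pairs for a radius sweep: accumulates, per radius, the
// edge-weighted indicator sum Sum_ij I(d_ij <= r) e_ij feeding the K
// estimator, and the per-reference neighbour counts feeding the proximity
// density. Translation correction: e_ij = W*H / ((W-|dx|)(H-|dy|)).
// [[Rcpp::export]]
List cpp_k_prox_sweep(NumericVector xr, NumericVector yr, IntegerVector idr,
                      NumericVector xt, NumericVector yt, IntegerVector idt,
                      NumericVector radii, bool translation,
                      double width, double height) {
  const int nr = xr.size(), nt = xt.size(), nrad = radii.size();
  NumericVector ksum(nrad);
  IntegerMatrix counts(nr, nrad);
  std::vector<double> r2(nrad);
  for (int k = 0; k < nrad; ++k) r2[k] = radii[k] * radii[k];
  const double rmax = radii[nrad - 1], rmax2 = r2[nrad - 1];

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nt; ++j) {
      if (same_cell(idr[i], idt[j])) continue;
      const double dx = std::fabs(xr[i] - xt[j]);
      if (dx > rmax) continue;
      const double dy = std::fabs(yr[i] - yt[j]);
      if (dy > rmax) continue;
      const double d2 = dx * dx + dy * dy;
      if (d2 > rmax2) continue;
      double w = 1.0;
      if (translation)
        w = (width * height) / ((width - dx) * (height - dy));
      for (int k = nrad - 1; k >= 0 && d2 <= r2[k]; --k) {
        ksum[k] += w;
        counts(i, k) += 1;
      }
    }
  }
  return List::create(_["ksum"] = ksum, _["counts"] = counts);
}
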