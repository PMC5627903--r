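#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// Bucketed nearest-seed lookup. Seeds and queries are in 0-based pixel
// coordinates (x = column, y = row). Bucket side ~ expected cell spacing so a
// query inspects a handful of candidates.
struct SeedGrid {
  double bx;          // bucket side, px
  int nbx, nby;       // bucket counts
  double x0, y0;      // origin
  std::vector<std::vector<int>> cells;
  const std::vector<double> *sx, *sy;

  void build(const std::vector<double> &x, const std::vector<double> &y,
             double xmin, double ymin, double xmax, double ymax, double bucket) {
    sx = &x; sy = &y;
    x0 = xmin; y0 = ymin;
    bx = bucket > 1e-9 ? bucket : 1.0;
    nbx = std::max(1, (int)std::ceil((xmax - xmin) / bx) + 1);
    nby = std::max(1, (int)std::ceil((ymax - ymin) / bx) + 1);
    cells.assign((size_t)nbx * nby, {});
    for (int i = 0; i < (int)x.size(); ++i) {
      int jx = std::min(nbx - 1, std::max(0, (int)((x[i] - x0) / bx)));
      int jy = std::min(nby - 1, std::max(0, (int)((y[i] - y0) / bx)));
      cells[(size_t)jy * nbx + jx].push_back(i);
    }
  }

  int nearest(double qx, double qy) const {
    int jx = std::min(nbx - 1, std::max(0, (int)((qx - x0) / bx)));
    int jy = std::min(nby - 1, std::max(0, (int)((qy - y0) / bx)));
    int best = -1;
    double bestd = R_PosInf;
    int maxring = std::max(nbx, nby);
    for (int k = 0; k <= maxring; ++k) {
      // once a candidate is found, rings whose closest possible point is
      // farther than the current best cannot improve it
      if (best >= 0 && (double)(k - 1) * bx > std::sqrt(bestd)) break;
      int xlo = jx - k, xhi = jx + k, ylo = jy - k, yhi = jy + k;
      for (int by = ylo; by <= yhi; ++by) {
        if (by < 0 || by >= nby) continue;
        for (int bxi = xlo; bxi <= xhi; ++bxi) {
          if (bxi < 0 || bxi >= nbx) continue;
          if (k > 0 && bxi != xlo && bxi != xhi && by != ylo && by != yhi) continue;
          const std::vector<int> &v = cells[(size_t)by * nbx + bxi];
          for (int idx : v) {
            double dx = (*sx)[idx] - qx, dy = (*sy)[idx] - qy;
            double d = dx * dx + dy * dy;
            if (d < bestd) { bestd = d; best = idx; }
          }
        }
      }
    }
    return best;
  }
};

// Lloyd relaxation of seeds toward the centroidal Voronoi tessellation of a
// disc, computed on a coarsened pixel grid, followed by a full-resolution
// assignment. Returns the label raster (1-based cell ids, 0 outside the
// disc), per-cell pixel areas and pixel centroids, and the relaxed seeds.
// [[Rcpp::export]]
List cpp_lloyd(NumericVector seed_x, NumericVector seed_y,
               int nrow, int ncol,
               double cx, double cy, double radius,
               int iters, int coarse) {
  int n = seed_x.size();
  if (coarse < 1) coarse = 1;
  std::vector<double> sx(seed_x.begin(), seed_x.end());
  std::vector<double> sy(seed_y.begin(), seed_y.end());
  double spacing = radius * std::sqrt(M_PI / std::max(1, n));
  double r2 = radius * radius;

  int cnx = (ncol + coarse - 1) / coarse;
  int cny = (nrow + coarse - 1) / coarse;
  std::vector<double> sumx(n), sumy(n);
  std::vector<int> cnt(n);

  SeedGrid grid;
  for (int it = 0; it < iters; ++it) {
    grid.build(sx, sy, 0, 0, ncol - 1, nrow - 1, spacing);
    std::fill(sumx.begin(), sumx.end(), 0.0);
    std::fill(sumy.begin(), sumy.end(), 0.0);
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int iy = 0; iy < cny; ++iy) {
      double py = iy * coarse + (coarse - 1) / 2.0;
      for (int ix = 0; ix < cnx; ++ix) {
        double px = ix * coarse + (coarse - 1) / 2.0;
        double dx = px - cx, dy = py - cy;
        if (dx * dx + dy * dy > r2) continue;
        int w = grid.nearest(px, py);
        if (w >= 0) { sumx[w] += px; sumy[w] += py; cnt[w]++; }
      }
    }
    for (int i = 0; i < n; ++i) {
      if (cnt[i] > 0) { sx[i] = sumx[i] / cnt[i]; sy[i] = sumy[i] / cnt[i]; }
    }
  }

  // full-resolution assignment
  grid.build(sx, sy, 0, 0, ncol - 1, nrow - 1, spacing);
  IntegerMatrix labels(nrow, ncol);
  std::fill(sumx.begin(), sumx.end(), 0.0);
  std::fill(sumy.begin(), sumy.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0);
  for (int iy = 0; iy < nrow; ++iy) {
    double dy = iy - cy;
    for (int ix = 0; ix < ncol; ++ix) {
      double dx = ix - cx;
      if (dx * dx + dy * dy > r2) { labels(iy, ix) = 0; continue; }
      int w = grid.nearest(ix, iy);
      labels(iy, ix) = w + 1;
      sumx[w] += ix; sumy[w] += iy; cnt[w]++;
    }
  }

  NumericVector area(n), centx(n), centy(n), outx(n), outy(n);
  for (int i = 0; i < n; ++i) {
    area[i] = cnt[i];
    centx[i] = cnt[i] > 0 ? sumx[i] / cnt[i] : NA_REAL;
    centy[i] = cnt[i] > 0 ? sumy[i] / cnt[i] : NA_REAL;
    outx[i] = sx[i]; outy[i] = sy[i];
  }
  return List::create(_["labels"] = labels, _["area_px"] = area,
                      _["centroid_x"] = centx, _["centroid_y"] = centy,
                      _["seed_x"] = outx, _["seed_y"] = outy);
}

// Assign every pixel of an nrow x ncol grid to its nearest seed (0-based
// pixel-center coordinates). Used for discrete Voronoi neighbour analysis.
// [[Rcpp::export]]
IntegerMatrix cpp_assign_grid(NumericVector seed_x, NumericVector seed_y,
                              int nrow, int ncol) {
  int n = seed_x.size();
  std::vector<double> sx(seed_x.begin(), seed_x.end());
  std::vector<double> sy(seed_y.begin(), seed_y.end());
  double spacing = std::sqrt((double)nrow * ncol / std::max(1, n));
  SeedGrid grid;
  grid.build(sx, sy, 0, 0, ncol - 1, nrow - 1, spacing);
  IntegerMatrix labels(nrow, ncol);
  for (int iy = 0; iy < nrow; ++iy)
    for (int ix = 0; ix < ncol; ++ix)
      labels(iy, ix) = grid.nearest(ix, iy) + 1;
  return labels;
}

// Shared-boundary adjacency of a label raster. Two cells are recorded as a
// candidate pair whenever a 4-neighbour pixel pair straddles them; callers
// threshold on the shared boundary length. Cells touching label 0 or the
// raster edge are flagged as boundary cells.
// [[Rcpp::export]]
List cpp_adjacency(IntegerMatrix labels, int nlab) {
  int nrow = labels.nrow(), ncol = labels.ncol();
  std::unordered_map<long long, int> pairs;
  LogicalVector boundary(nlab);
  for (int iy = 0; iy < nrow; ++iy) {
    for (int ix = 0; ix < ncol; ++ix) {
      int a = labels(iy, ix);
      if (a == 0) continue;
      if (iy == 0 || ix == 0 || iy == nrow - 1 || ix == ncol - 1)
        boundary[a - 1] = true;
      if (ix + 1 < ncol) {
        int b = labels(iy, ix + 1);
        if (b == 0) boundary[a - 1] = true;
        else if (b != a) {
          long long key = (long long)std::min(a, b) * (nlab + 1) + std::max(a, b);
          pairs[key]++;
        }
      }
      if (iy + 1 < nrow) {
        int b = labels(iy + 1, ix);
        if (b == 0) boundary[a - 1] = true;
        else if (b != a) {
          long long key = (long long)std::min(a, b) * (nlab + 1) + std::max(a, b);
          pairs[key]++;
        }
      }
    }
  }
  int m = pairs.size();
  IntegerVector pi(m), pj(m), shared(m);
  int k = 0;
  for (auto &kv : pairs) {
    pi[k] = (int)(kv.first / (nlab + 1));
    pj[k] = (int)(kv.first % (nlab + 1));
    shared[k] = kv.second;
    ++k;
  }
  return List::create(_["i"] = pi, _["j"] = pj, _["shared"] = shared,
                      _["boundary"] = boundary);
}

// Paint filled discs onto an image (used for nucleus rendering). Pixel
// centers within radius of the disc center take the disc value.
// [[Rcpp::export]]
NumericMatrix cpp_draw_discs(NumericMatrix img, NumericVector x, NumericVector y,
                             NumericVector r, NumericVector value) {
  NumericMatrix out = clone(img);
  int nrow = out.nrow(), ncol = out.ncol();
  for (int i = 0; i < x.size(); ++i) {
    double ri = r[i];
    int xlo = std::max(0, (int)std::floor(x[i] - ri));
    int xhi = std::min(ncol - 1, (int)std::ceil(x[i] + ri));
    int ylo = std::max(0, (int)std::floor(y[i] - ri));
    int yhi = std::min(nrow - 1, (int)std::ceil(y[i] + ri));
    double r2 = ri * ri;
    for (int iy = ylo; iy <= yhi; ++iy) {
      double dy = iy - y[i];
      for (int ix = xlo; ix <= xhi; ++ix) {
        double dx = ix - x[i];
        if (dx * dx + dy * dy <= r2) out(iy, ix) = value[i];
      }
    }
  }
  return out;
}
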