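#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// 8-connected component labelling by breadth-first flood fill.
// Returns integer labels 1..n in raster order (column-major input, but
// labels are assigned in row-major raster order of the first pixel to match
// the documented renumbering convention).
// [[Rcpp::export]]
IntegerMatrix cf_label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::queue<std::pair<int,int> > q;
  // raster order: row by row
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int,int> p = q.front(); q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            if (di == 0 && dj == 0) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (mask(ni, nj) && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  lab.attr("n") = next;
  return lab;
}

// Fill holes: any false region not 4-connected to the image border becomes
// true. 4-connectivity on the background is the dual of 8-connected
// foreground.
// [[Rcpp::export]]
LogicalMatrix cf_fill_holes(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix outside(nr, nc); // background reachable from border
  std::queue<std::pair<int,int> > q;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if ((i == 0 || j == 0 || i == nr - 1 || j == nc - 1) &&
          !mask(i, j) && !outside(i, j)) {
        outside(i, j) = true;
        q.push(std::make_pair(i, j));
      }
    }
  }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    std::pair<int,int> p = q.front(); q.pop();
    for (int k = 0; k < 4; ++k) {
      int ni = p.first + di[k], nj = p.second + dj[k];
      if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
      if (!mask(ni, nj) && !outside(ni, nj)) {
        outside(ni, nj) = true;
        q.push(std::make_pair(ni, nj));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      out(i, j) = mask(i, j) || !outside(i, j);
  return out;
}

// Grayscale erosion/dilation with a non-flat spherical ("ball") structuring
// element of the given radius: height(d) = sqrt(r^2 - d^2) over the disc
// d <= r. Erosion then dilation with this element gives the rolling-ball
// background (the upper envelope of a ball rolled beneath the surface).
static void ball_offsets(double radius, std::vector<int>& oi,
                         std::vector<int>& oj, std::vector<double>& oh) {
  int r = (int)std::floor(radius);
  for (int di = -r; di <= r; ++di) {
    for (int dj = -r; dj <= r; ++dj) {
      double d2 = (double)di * di + (double)dj * dj;
      if (d2 <= radius * radius) {
        oi.push_back(di);
        oj.push_back(dj);
        oh.push_back(std::sqrt(radius * radius - d2));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cf_ball_erode(const NumericMatrix& img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> oi, oj; std::vector<double> oh;
  ball_offsets(radius, oi, oj, oh);
  const int m = (int)oi.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_PosInf;
      for (int k = 0; k < m; ++k) {
        int ni = i + oi[k], nj = j + oj[k];
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        double cand = img(ni, nj) - oh[k];
        if (cand < v) v = cand;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cf_ball_dilate(const NumericMatrix& img, double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> oi, oj; std::vector<double> oh;
  ball_offsets(radius, oi, oj, oh);
  const int m = (int)oi.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = R_NegInf;
      for (int k = 0; k < m; ++k) {
        int ni = i + oi[k], nj = j + oj[k];
        if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
        double cand = img(ni, nj) + oh[k];
        if (cand > v) v = cand;
      }
      out(i, j) = v;
    }
  }
  return out;
}
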