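#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Separable convolution with a symmetric 1-D kernel, replicate padding.
// Applied along rows then columns; used for Gaussian smoothing.
// [[Rcpp::export]]
NumericMatrix cpp_sep_convolve(const NumericMatrix& img, const NumericVector& kernel) {
  const int nr = img.nrow(), nc = img.ncol();
  const int k = kernel.size();
  const int r = (k - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (horizontal pass)
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0;
        if (jj >= nc) jj = nc - 1;
        acc += img(i, jj) * kernel[t + r];
      }
      tmp(i, j) = acc;
    }
  }
  // along rows (vertical pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -r; t <= r; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0;
        if (ii >= nr) ii = nr - 1;
        acc += tmp(ii, j) * kernel[t + r];
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Rank filter over a disk neighbourhood: maximum = true gives grey dilation,
// false gives grey erosion. Binary masks (0/1) reduce to binary morphology.
// Border handled by ignoring out-of-image offsets (equivalent to replicate
// padding for binary use on images whose objects keep a margin).
// [[Rcpp::export]]
NumericMatrix cpp_disk_filter(const NumericMatrix& img, const double radius, const bool maximum) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> dr, dc;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)(a * a + b * b) <= radius * radius + 1e-9) { dr.push_back(a); dc.push_back(b); }
  const int m = dr.size();
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double best = maximum ? -1e300 : 1e300;
      for (int t = 0; t < m; ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        double v = img(ii, jj);
        if (maximum ? (v > best) : (v < best)) best = v;
      }
      out(i, j) = best;
    }
  }
  return out;
}

// Median filter over a disk neighbourhood; out-of-image offsets are
// ignored. Robust local level estimate: unaffected by bright foci that
// cover less than half the window.
// [[Rcpp::export]]
NumericMatrix cpp_disk_median(const NumericMatrix& img, const double radius) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r = (int)std::floor(radius);
  std::vector<int> dr, dc;
  for (int a = -r; a <= r; ++a)
    for (int b = -r; b <= r; ++b)
      if ((double)(a * a + b * b) <= radius * radius + 1e-9) { dr.push_back(a); dc.push_back(b); }
  const int m = dr.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve(m);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      buf.clear();
      for (int t = 0; t < m; ++t) {
        int ii = i + dr[t], jj = j + dc[t];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        buf.push_back(img(ii, jj));
      }
      size_t mid = buf.size() / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(i, j) = buf[mid];
    }
  }
  return out;
}

// Connected component labelling (8- or 4-connectivity) by breadth-first
// search. Returns an integer matrix of labels (0 = background, components
// 1..k in raster order of their first pixel).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask, const int connectivity = 8) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  const int nn = (connectivity == 4) ? 4 : 8;
  const int DR[8] = {-1, 0, 0, 1, -1, -1, 1, 1};
  const int DC[8] = {0, -1, 1, 0, -1, 1, -1, 1};
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int t = 0; t < nn; ++t) {
          int ii = p.first + DR[t], jj = p.second + DC[t];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) { lab(ii, jj) = next; q.push(std::make_pair(ii, jj)); }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing of the largest foreground component.
// Returns an n x 2 matrix of 1-based (row, col) contour coordinates in
// clockwise order. The caller guarantees a single 8-connected component.
// [[Rcpp::export]]
IntegerMatrix cpp_trace_contour(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  // clockwise Moore neighbourhood starting East
  const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  int si = -1, sj = -1;
  for (int i = 0; i < nr && si < 0; ++i)
    for (int j = 0; j < nc; ++j)
      if (mask(i, j)) { si = i; sj = j; break; }
  if (si < 0) return IntegerMatrix(0, 2);
  std::vector<int> ri, ci;
  int ci_ = si, cj_ = sj;
  // entered the start pixel moving East (from its empty West neighbour)
  int dir = 0;
  ri.push_back(ci_); ci.push_back(cj_);
  const int maxit = 4 * (nr * nc + 8);
  int it = 0;
  int first_dir = -1;
  while (it++ < maxit) {
    bool found = false;
    int start = (dir + 5) % 8; // neighbour after the backtrack, clockwise
    for (int t = 0; t < 8; ++t) {
      int d = (start + t) % 8;
      int ii = ci_ + DR[d], jj = cj_ + DC[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (mask(ii, jj)) {
        if (ci_ == si && cj_ == sj) {
          if (first_dir < 0) first_dir = d;
          else if (d == first_dir && ri.size() > 1) { found = false; break; }
        }
        ci_ = ii; cj_ = jj; dir = d; found = true;
        break;
      }
    }
    if (!found) break; // isolated pixel or closed loop
    if (ci_ == si && cj_ == sj) break;
    ri.push_back(ci_); ci.push_back(cj_);
  }
  IntegerMatrix out(ri.size(), 2);
  for (size_t t = 0; t < ri.size(); ++t) { out(t, 0) = ri[t] + 1; out(t, 1) = ci[t] + 1; }
  return out;
}
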