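#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// scipy-style "reflect" index: (d c b a | a b c d | d c b a)
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int k) {
  int H = img.nrow(), W = img.ncol();
  int h = k / 2;
  NumericMatrix out(H, W);
  std::vector<double> buf(k * k);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      int m = 0;
      for (int dy = -h; dy <= h; ++dy) {
        int yy = reflect_idx(y + dy, H);
        for (int dx = -h; dx <= h; ++dx) {
          buf[m++] = img(yy, reflect_idx(x + dx, W));
        }
      }
      std::nth_element(buf.begin(), buf.begin() + m / 2, buf.begin() + m);
      out(y, x) = buf[m / 2];
    }
  }
  return out;
}

// Separable Gaussian, kernel truncated at +/- ceil(3*sigma), reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(NumericMatrix img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  int rad = (int)std::ceil(3.0 * sigma);
  if (rad < 1) rad = 1;
  std::vector<double> w(2 * rad + 1);
  double s = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    w[i + rad] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += w[i + rad];
  }
  for (double& wi : w) wi /= s;

  NumericMatrix tmp(H, W), out(H, W);
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += w[i + rad] * img(y, reflect_idx(x + i, W));
      tmp(y, x) = acc;
    }
  for (int y = 0; y < H; ++y)
    for (int x = 0; x < W; ++x) {
      double acc = 0.0;
      for (int i = -rad; i <= rad; ++i)
        acc += w[i + rad] * tmp(reflect_idx(y + i, H), x);
      out(y, x) = acc;
    }
  return out;
}

// Sobel gradient magnitude with reflect padding.
// [[Rcpp::export]]
NumericMatrix cpp_sobel_magnitude(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int y = 0; y < H; ++y) {
    int ym = reflect_idx(y - 1, H), yp = reflect_idx(y + 1, H);
    for (int x = 0; x < W; ++x) {
      int xm = reflect_idx(x - 1, W), xp = reflect_idx(x + 1, W);
      double gx = img(ym, xp) + 2.0 * img(y, xp) + img(yp, xp)
                - img(ym, xm) - 2.0 * img(y, xm) - img(yp, xm);
      double gy = img(yp, xm) + 2.0 * img(yp, x) + img(yp, xp)
                - img(ym, xm) - 2.0 * img(ym, x) - img(ym, xp);
      out(y, x) = std::sqrt(gx * gx + gy * gy);
    }
  }
  return out;
}

// Circle Hough accumulator. votes[cy, cx, r - rmin] counts the edge pixels
// whose rounded Euclidean distance from center (cx, cy) equals r. Matrix rows
// are y (0-based), columns are x (0-based).
// [[Rcpp::export]]
IntegerVector cpp_hough_votes(LogicalMatrix edge, int rmin, int rmax) {
  int H = edge.nrow(), W = edge.ncol();
  int nr = rmax - rmin + 1;
  int D = 2 * rmax + 1;
  std::vector<int> lut(D * D);
  for (int dy = -rmax; dy <= rmax; ++dy)
    for (int dx = -rmax; dx <= rmax; ++dx)
      lut[(dy + rmax) * D + (dx + rmax)] =
        (int)std::lround(std::sqrt((double)(dx * dx + dy * dy)));
  IntegerVector votes(H * W * nr);
  for (int ey = 0; ey < H; ++ey) {
    for (int ex = 0; ex < W; ++ex) {
      if (!edge(ey, ex)) continue;
      int y0 = std::max(0, ey - rmax), y1 = std::min(H - 1, ey + rmax);
      int x0 = std::max(0, ex - rmax), x1 = std::min(W - 1, ex + rmax);
      for (int cx = x0; cx <= x1; ++cx) {
        int col = (cx - ex + rmax);
        for (int cy = y0; cy <= y1; ++cy) {
          int r = lut[(cy - ey + rmax) * D + col];
          if (r >= rmin && r <= rmax)
            votes[cy + cx * H + (r - rmin) * H * W]++;
        }
      }
    }
  }
  votes.attr("dim") = IntegerVector::create(H, W, nr);
  return votes;
}
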