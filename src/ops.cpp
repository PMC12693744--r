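#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// 3x3 median filter with edge replication.
// [[Rcpp::export]]
IntegerMatrix median_filter_3x3_cpp(IntegerMatrix img) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix out(h, w);
  int win[9];
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      int k = 0;
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          win[k++] = img(clampi(y + dy, 0, h - 1), clampi(x + dx, 0, w - 1));
      std::nth_element(win, win + 4, win + 9);
      out(y, x) = win[4];
    }
  }
  return out;
}

static NumericMatrix gaussian_blur(const NumericMatrix& img, double sigma) {
  int h = img.nrow(), w = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    ker[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + radius];
  }
  for (double& k : ker) k /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int x = 0; x < w; ++x)      // horizontal pass
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += ker[i + radius] * img(y, clampi(x + i, 0, w - 1));
      tmp(y, x) = acc;
    }
  for (int x = 0; x < w; ++x)      // vertical pass
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += ker[i + radius] * tmp(clampi(y + i, 0, h - 1), x);
      out(y, x) = acc;
    }
  return out;
}

// Canny edge detector: Gaussian smoothing, Sobel 3x3 gradients,
// 4-sector non-maximum suppression, double threshold with hysteresis
// (weak edges kept only when 8-connected to a strong edge).
// [[Rcpp::export]]
LogicalMatrix canny_cpp(NumericMatrix img, double sigma, double low, double high) {
  int h = img.nrow(), w = img.ncol();
  NumericMatrix sm = gaussian_blur(img, sigma);
  NumericMatrix mag(h, w);
  IntegerMatrix sector(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double gx = 0.0, gy = 0.0;
      // Sobel with replicated borders
      const int xm = clampi(x - 1, 0, w - 1), xp = clampi(x + 1, 0, w - 1);
      const int ym = clampi(y - 1, 0, h - 1), yp = clampi(y + 1, 0, h - 1);
      gx = (sm(ym, xp) + 2.0 * sm(y, xp) + sm(yp, xp))
         - (sm(ym, xm) + 2.0 * sm(y, xm) + sm(yp, xm));
      gy = (sm(yp, xm) + 2.0 * sm(yp, x) + sm(yp, xp))
         - (sm(ym, xm) + 2.0 * sm(ym, x) + sm(ym, xp));
      mag(y, x) = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) * 180.0 / M_PI;
      if (ang < 0) ang += 180.0;
      int sec;
      if (ang < 22.5 || ang >= 157.5) sec = 0;       // gradient ~horizontal
      else if (ang < 67.5) sec = 1;                  // ~45 degrees
      else if (ang < 112.5) sec = 2;                 // ~vertical
      else sec = 3;                                  // ~135 degrees
      sector(y, x) = sec;
    }
  }
  // Non-maximum suppression along the gradient direction. The comparison is
  // strict against the first neighbour and non-strict against the second so
  // that two-pixel plateaus (ideal steps) thin to a single pixel.
  LogicalMatrix strong(h, w), weak(h, w);
  static const int nx[4][2] = {{1, -1}, {1, -1}, {0, 0}, {-1, 1}};
  static const int ny[4][2] = {{0, 0}, {-1, 1}, {1, -1}, {-1, 1}};
  // sector 1: gradient at +45 deg (gx, gy same sign) -> neighbours (x+1,y+1),(x-1,y-1)
  // handled via the table below after correcting signs
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      double m = mag(y, x);
      if (m <= 0) { continue; }
      int sec = sector(y, x);
      int dx1, dy1, dx2, dy2;
      switch (sec) {
        case 0: dx1 = 1; dy1 = 0; dx2 = -1; dy2 = 0; break;
        case 1: dx1 = 1; dy1 = 1; dx2 = -1; dy2 = -1; break;
        case 2: dx1 = 0; dy1 = 1; dx2 = 0; dy2 = -1; break;
        default: dx1 = -1; dy1 = 1; dx2 = 1; dy2 = -1; break;
      }
      double m1 = mag(clampi(y + dy1, 0, h - 1), clampi(x + dx1, 0, w - 1));
      double m2 = mag(clampi(y + dy2, 0, h - 1), clampi(x + dx2, 0, w - 1));
      if (m >= m1 && m > m2) {
        if (m >= high) strong(y, x) = true;
        else if (m >= low) weak(y, x) = true;
      }
    }
  }
  (void)nx; (void)ny;
  // hysteresis: BFS from strong pixels through weak ones
  LogicalMatrix out(h, w);
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (strong(y, x)) { out(y, x) = true; q.push(std::make_pair(y, x)); }
  while (!q.empty()) {
    std::pair<int, int> p = q.front(); q.pop();
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int yy = p.first + dy, xx = p.second + dx;
        if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
        if (weak(yy, xx) && !out(yy, xx)) {
          out(yy, xx) = true;
          q.push(std::make_pair(yy, xx));
        }
      }
  }
  return out;
}

// 8-connected component labelling (BFS). Background = 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix img) {
  int h = img.nrow(), w = img.ncol();
  IntegerMatrix lab(h, w);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      if (!img(y, x) || lab(y, x) != 0) continue;
      lab(y, x) = ++next;
      q.push(std::make_pair(y, x));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int yy = p.first + dy, xx = p.second + dx;
            if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
            if (img(yy, xx) && lab(yy, xx) == 0) {
              lab(yy, xx) = next;
              q.push(std::make_pair(yy, xx));
            }
          }
      }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// Moore-neighbour boundary tracing of one labelled component, starting at
// its topmost-then-leftmost pixel with the backtrack to its west. Returns
// an n x 2 matrix of 0-based (x, y) boundary pixel coordinates in trace
// order. Clockwise ring scan; with the image y axis pointing down this
// walks the outer boundary keeping the component on its right.
static IntegerMatrix trace_one(const IntegerMatrix& lab, int target,
                               int sy, int sx) {
  int h = lab.nrow(), w = lab.ncol();
  // ring offsets, clockwise starting East
  static const int ox[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int oy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> xs, ys;
  int cy = sy, cx = sx;
  int back = 4;  // direction from current to backtrack pixel (West)
  xs.push_back(cx); ys.push_back(cy);
  // stop when about to repeat the first move out of the start pixel
  int second_y = -1, second_x = -1;
  long guard = 0, lim = 4L * (long)h * (long)w + 16;
  while (true) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (back + k) % 8;
      int yy = cy + oy[d], xx = cx + ox[d];
      bool fg = yy >= 0 && yy < h && xx >= 0 && xx < w && lab(yy, xx) == target;
      if (fg) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    int ny = cy + oy[found], nx = cx + ox[found];
    if (second_y >= 0 && cy == sy && cx == sx &&
        ny == second_y && nx == second_x) break;
    // backtrack becomes the ring position just before the found pixel
    int prev = (found + 7) % 8;
    int py = cy + oy[prev], px = cx + ox[prev];
    cy = ny; cx = nx;
    // direction from new current to that previous (background) pixel
    int nb = -1;
    for (int d = 0; d < 8; ++d)
      if (cy + oy[d] == py && cx + ox[d] == px) { nb = d; break; }
    if (nb < 0) nb = (found + 4) % 8;  // fall back to reverse direction
    back = nb;
    if (second_y < 0) { second_y = cy; second_x = cx; }
    xs.push_back(cx); ys.push_back(cy);
    if (++guard > lim) break;
  }
  // a closed trace re-enters the start just before terminating
  if (xs.size() > 1 && xs.back() == xs.front() && ys.back() == ys.front()) {
    xs.pop_back(); ys.pop_back();
  }
  IntegerMatrix out(xs.size(), 2);
  for (size_t i = 0; i < xs.size(); ++i) {
    out(i, 0) = xs[i];
    out(i, 1) = ys[i];
  }
  return out;
}

// [[Rcpp::export]]
List trace_contours_cpp(IntegerMatrix lab, int n_components) {
  int h = lab.nrow(), w = lab.ncol();
  std::vector<int> sy(n_components + 1, -1), sx(n_components + 1, -1);
  for (int y = 0; y < h; ++y)       // scan order: top row first, leftmost
    for (int x = 0; x < w; ++x) {
      int l = lab(y, x);
      if (l > 0 && sy[l] < 0) { sy[l] = y; sx[l] = x; }
    }
  List out(n_components);
  for (int l = 1; l <= n_components; ++l) {
    if (sy[l] < 0) { out[l - 1] = IntegerMatrix(0, 2); continue; }
    out[l - 1] = trace_one(lab, l, sy[l], sx[l]);
  }
  return out;
}
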