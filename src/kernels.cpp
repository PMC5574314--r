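#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Separable convolution of a 3-D array (dims y, x, z) along one axis with a
// 1-D kernel, reflecting at the borders so that a unit-sum kernel conserves
// total intensity on flat fields. axis: 0 = y (rows), 1 = x (cols), 2 = z.
// [[Rcpp::export(name = ".conv_axis")]]
NumericVector conv_axis(NumericVector arr, NumericVector kernel, int axis) {
  IntegerVector d = arr.attr("dim");
  int ny = d[0], nx = d[1], nz = (d.size() > 2) ? d[2] : 1;
  int kn = kernel.size();
  int kh = kn / 2;  // kernel assumed odd-length, centered
  NumericVector out(arr.size());
  out.attr("dim") = arr.attr("dim");

  int len = (axis == 0) ? ny : (axis == 1) ? nx : nz;
  long stride = (axis == 0) ? 1 : (axis == 1) ? (long)ny : (long)ny * nx;
  long nlines = (long)ny * nx * nz / len;

  const double *src = REAL(arr);
  double *dst = REAL(out);
  std::vector<double> kv(kernel.begin(), kernel.end());
  const double *kp = kv.data();

  std::vector<double> line(len);
  for (long l = 0; l < nlines; ++l) {
    // base index of this line
    long base;
    if (axis == 0) {
      long plane = l;          // over x*z
      base = plane * ny;
    } else if (axis == 1) {
      long z = l / ny, y = l % ny;
      base = z * (long)ny * nx + y;
    } else {
      base = l;                // over y*x
    }
    for (int i = 0; i < len; ++i) line[i] = src[base + (long)i * stride];
    const double *lp = line.data();
    int lo = std::min(kh, len), hi = std::max(len - kh, lo);
    for (int i = lo; i < hi; ++i) {          // interior: no boundary checks
      double acc = 0.0;
      const double *p = lp + i - kh;
      for (int k = 0; k < kn; ++k) acc += p[k] * kp[k];
      dst[base + (long)i * stride] = acc;
    }
    for (int half = 0; half < 2; ++half) {   // reflected borders
      int i0 = half ? hi : 0, i1 = half ? len : lo;
      for (int i = i0; i < i1; ++i) {
        double acc = 0.0;
        for (int k = 0; k < kn; ++k) {
          int j = i + k - kh;
          if (j < 0) j = -j - 1;             // reflect
          if (j >= len) j = 2 * len - j - 1;
          if (j < 0) j = 0;                  // very short axes
          if (j >= len) j = len - 1;
          acc += lp[j] * kp[k];
        }
        dst[base + (long)i * stride] = acc;
      }
    }
  }
  return out;
}

// 8-connected component labeling of a binary matrix. Returns an integer
// matrix with 0 = background and 1..n component labels, in raster order of
// first encounter.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  int next = 0;
  std::vector<int> sy, sx;
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      if (!mask(y, x) || lab(y, x)) continue;
      ++next;
      sy.clear(); sx.clear();
      sy.push_back(y); sx.push_back(x);
      lab(y, x) = next;
      while (!sy.empty()) {
        int cy = sy.back(), cx = sx.back();
        sy.pop_back(); sx.pop_back();
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dy && !dx) continue;
            int yy = cy + dy, xx = cx + dx;
            if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
            if (mask(yy, xx) && !lab(yy, xx)) {
              lab(yy, xx) = next;
              sy.push_back(yy); sx.push_back(xx);
            }
          }
        }
      }
    }
  }
  return lab;
}

static inline int nb(const LogicalMatrix &m, int y, int x) {
  if (y < 0 || y >= m.nrow() || x < 0 || x >= m.ncol()) return 0;
  return m(y, x) ? 1 : 0;
}

// Zhang-Suen thinning of a binary matrix down to a 1-pixel skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix m = clone(mask);
  bool changed = true;
  std::vector<int> dy_, dx_;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      dy_.clear(); dx_.clear();
      for (int x = 0; x < nx; ++x) {
        for (int y = 0; y < ny; ++y) {
          if (!m(y, x)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = nb(m, y - 1, x),     p3 = nb(m, y - 1, x + 1);
          int p4 = nb(m, y,     x + 1), p5 = nb(m, y + 1, x + 1);
          int p6 = nb(m, y + 1, x),     p7 = nb(m, y + 1, x - 1);
          int p8 = nb(m, y,     x - 1), p9 = nb(m, y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          dy_.push_back(y); dx_.push_back(x);
        }
      }
      for (size_t i = 0; i < dy_.size(); ++i) m(dy_[i], dx_[i]) = false;
      if (!dy_.empty()) changed = true;
    }
  }
  return m;
}

// Binary erosion with a 3x3 square structuring element, iterated n times.
// [[Rcpp::export(name = ".erode")]]
LogicalMatrix erode(LogicalMatrix mask, int n) {
  int ny = mask.nrow(), nx = mask.ncol();
  LogicalMatrix a = clone(mask), b(ny, nx);
  for (int it = 0; it < n; ++it) {
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) {
        bool keep = a(y, x);
        if (keep) {
          for (int dy = -1; dy <= 1 && keep; ++dy)
            for (int dx = -1; dx <= 1 && keep; ++dx) {
              int yy = y + dy, xx = x + dx;
              if (yy < 0 || yy >= ny || xx < 0 || xx >= nx) { keep = false; break; }
              if (!a(yy, xx)) keep = false;
            }
        }
        b(y, x) = keep;
      }
    }
    a = clone(b);
  }
  return a;
}
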