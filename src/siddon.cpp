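#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Ray traversal through an n x n pixel grid of pixel size ps (mm) centred on
// the origin, from (sx,sy) to (ex,ey), collecting exact intersection lengths
// per crossed pixel (Siddon-style incremental traversal).
//
// Pixel (row r, col c) of the R image matrix (0-based here) maps to
//   x in [x0 + c*ps, x0 + (c+1)*ps),  y in (y0 + (n-1-r)*ps, y0 + (n-r)*ps]
// with x0 = y0 = -n*ps/2: column index increases with x, row index
// increases downward (row 0 at the top, y maximal). Flat (column-major)
// index = c*n + r. Pixel intervals are half-open on the high edge so a ray
// exactly on a shared boundary is counted once.
static void trace_ray(double sx, double sy, double ex, double ey,
                      int n, double ps,
                      std::vector<int> &idx, std::vector<double> &len) {
  idx.clear();
  len.clear();
  const double x0 = -0.5 * n * ps;
  const double y0 = -0.5 * n * ps;
  const double x1 = x0 + n * ps;
  const double y1 = y0 + n * ps;
  const double rx = ex - sx, ry = ey - sy;
  const double L = std::sqrt(rx * rx + ry * ry);
  if (L <= 0.0) return;

  double tmin = 0.0, tmax = 1.0;
  if (std::fabs(rx) < 1e-14 * L) {
    if (sx < x0 || sx >= x1) return;
  } else {
    double t1 = (x0 - sx) / rx, t2 = (x1 - sx) / rx;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (std::fabs(ry) < 1e-14 * L) {
    if (sy < y0 || sy >= y1) return;
  } else {
    double t1 = (y0 - sy) / ry, t2 = (y1 - sy) / ry;
    if (t1 > t2) std::swap(t1, t2);
    tmin = std::max(tmin, t1);
    tmax = std::min(tmax, t2);
  }
  if (tmin >= tmax) return;

  // entry pixel: sample just inside the box
  const double teps = (tmax - tmin) * 1e-12;
  double px = sx + (tmin + teps) * rx;
  double py = sy + (tmin + teps) * ry;
  int ix = (int)std::floor((px - x0) / ps);
  int iy = (int)std::floor((py - y0) / ps);
  if (ix < 0) ix = 0; else if (ix > n - 1) ix = n - 1;
  if (iy < 0) iy = 0; else if (iy > n - 1) iy = n - 1;

  const int stepx = (rx > 0.0) ? 1 : ((rx < 0.0) ? -1 : 0);
  const int stepy = (ry > 0.0) ? 1 : ((ry < 0.0) ? -1 : 0);
  const double dtx = (stepx != 0) ? ps / std::fabs(rx) : R_PosInf;
  const double dty = (stepy != 0) ? ps / std::fabs(ry) : R_PosInf;
  double tx = R_PosInf, ty = R_PosInf;
  if (stepx > 0)      tx = ((x0 + (ix + 1) * ps) - sx) / rx;
  else if (stepx < 0) tx = ((x0 + ix * ps) - sx) / rx;
  if (stepy > 0)      ty = ((y0 + (iy + 1) * ps) - sy) / ry;
  else if (stepy < 0) ty = ((y0 + iy * ps) - sy) / ry;

  double t = tmin;
  const double tol = 1e-13;
  while (t < tmax - tol) {
    double tn = std::min(std::min(tx, ty), tmax);
    double seg = (tn - t) * L;
    if (seg > 0.0) {
      idx.push_back(ix * n + (n - 1 - iy));
      len.push_back(seg);
    }
    bool advanced = false;
    if (tx <= tn + tol) { ix += stepx; tx += dtx; advanced = true; }
    if (ty <= tn + tol) { iy += stepy; ty += dty; advanced = true; }
    t = tn;
    if (!advanced) break;                       // tn == tmax
    if (ix < 0 || ix >= n || iy < 0 || iy >= n) break;
  }
}

// [[Rcpp::export]]
NumericVector cpp_forward(NumericMatrix img, double ps,
                          NumericVector sx, NumericVector sy,
                          NumericVector ex, NumericVector ey) {
  const int n = img.nrow();
  const int m = sx.size();
  NumericVector out(m);
  const double *f = img.begin();
  std::vector<int> idx;
  std::vector<double> len;
  idx.reserve(4 * n);
  len.reserve(4 * n);
  for (int j = 0; j < m; ++j) {
    trace_ray(sx[j], sy[j], ex[j], ey[j], n, ps, idx, len);
    double acc = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) acc += f[idx[k]] * len[k];
    out[j] = acc;
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_back(NumericVector vals, int n, double ps,
                       NumericVector sx, NumericVector sy,
                       NumericVector ex, NumericVector ey) {
  const int m = sx.size();
  NumericMatrix out(n, n);
  double *f = out.begin();
  std::vector<int> idx;
  std::vector<double> len;
  for (int j = 0; j < m; ++j) {
    if (vals[j] == 0.0) continue;
    trace_ray(sx[j], sy[j], ex[j], ey[j], n, ps, idx, len);
    for (size_t k = 0; k < idx.size(); ++k) f[idx[k]] += vals[j] * len[k];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_row_norms(int n, double ps,
                            NumericVector sx, NumericVector sy,
                            NumericVector ex, NumericVector ey) {
  const int m = sx.size();
  NumericVector out(m);
  std::vector<int> idx;
  std::vector<double> len;
  for (int j = 0; j < m; ++j) {
    trace_ray(sx[j], sy[j], ex[j], ey[j], n, ps, idx, len);
    double acc = 0.0;
    for (size_t k = 0; k < len.size(); ++k) acc += len[k] * len[k];
    out[j] = acc;
  }
  return out;
}

// One full Kaczmarz (ART) pass over the rays listed in `order` (0-based ray
// ids). Rays with zero row norm are skipped. Returns a new image.
// [[Rcpp::export]]
NumericMatrix cpp_art_sweep(NumericMatrix img, NumericVector g,
                            IntegerVector order, double lambda, double ps,
                            NumericVector sx, NumericVector sy,
                            NumericVector ex, NumericVector ey) {
  const int n = img.nrow();
  NumericMatrix f = clone(img);
  double *fp = f.begin();
  std::vector<int> idx;
  std::vector<double> len;
  for (int jj = 0; jj < order.size(); ++jj) {
    const int j = order[jj];
    trace_ray(sx[j], sy[j], ex[j], ey[j], n, ps, idx, len);
    double val = 0.0, nrm = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) {
      val += fp[idx[k]] * len[k];
      nrm += len[k] * len[k];
    }
    if (nrm > 0.0) {
      const double corr = lambda * (g[j] - val) / nrm;
      for (size_t k = 0; k < idx.size(); ++k) fp[idx[k]] += corr * len[k];
    }
  }
  return f;
}

// Single-ray trace for sparse system-matrix assembly; 1-based pixel indices.
// [[Rcpp::export]]
List cpp_trace(double sx, double sy, double ex, double ey, int n, double ps) {
  std::vector<int> idx;
  std::vector<double> len;
  trace_ray(sx, sy, ex, ey, n, ps, idx, len);
  IntegerVector i(idx.size());
  NumericVector l(len.size());
  for (size_t k = 0; k < idx.size(); ++k) {
    i[k] = idx[k] + 1;
    l[k] = len[k];
  }
  return List::create(_["index"] = i, _["length"] = l);
}
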