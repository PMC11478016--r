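// Exact voxel traversal (Siddon / Amanatides-Woo), fan-beam forward
// projection onto material basis path lengths, equiangular backprojection,
// and exit-path attenuation marching. All distances in mm.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Traverse the segment p0 -> p1 through a regular grid.
// lower: coordinates of the grid's lower corner; dims: voxel counts.
// Appends (linear voxel index, intersection length) pairs.
static void traverseGrid(const double* p0, const double* p1,
                         const double* lower, const double* pitch,
                         const int* dims, int ndim,
                         std::vector<int>& idx, std::vector<double>& len) {
  double d[3], L2 = 0.0;
  for (int a = 0; a < ndim; ++a) { d[a] = p1[a] - p0[a]; L2 += d[a] * d[a]; }
  double L = std::sqrt(L2);
  if (L <= 0.0) stop("degenerate (zero-length) ray");

  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < ndim; ++a) {
    double lo = lower[a], hi = lower[a] + pitch[a] * dims[a];
    if (std::fabs(d[a]) < 1e-14) {
      if (p0[a] <= lo || p0[a] >= hi) return; // parallel and outside
    } else {
      double t1 = (lo - p0[a]) / d[a], t2 = (hi - p0[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmax <= tmin) return;

  // current voxel at entry (nudged inside)
  double tcur = tmin;
  double eps = 1e-12;
  int iv[3];
  for (int a = 0; a < ndim; ++a) {
    double s = p0[a] + (tmin + eps) * d[a];
    int i = (int)std::floor((s - lower[a]) / pitch[a]);
    if (i < 0) i = 0;
    if (i >= dims[a]) i = dims[a] - 1;
    iv[a] = i;
  }
  // parametric step per axis and next-crossing parameter
  double tDelta[3], tNext[3];
  int stepDir[3];
  for (int a = 0; a < ndim; ++a) {
    if (std::fabs(d[a]) < 1e-14) {
      stepDir[a] = 0; tDelta[a] = R_PosInf; tNext[a] = R_PosInf;
    } else {
      stepDir[a] = d[a] > 0 ? 1 : -1;
      tDelta[a] = pitch[a] / std::fabs(d[a]);
      int nextPlane = d[a] > 0 ? iv[a] + 1 : iv[a];
      double bound = lower[a] + pitch[a] * nextPlane;
      tNext[a] = (bound - p0[a]) / d[a];
      if (tNext[a] < tcur) tNext[a] += tDelta[a];
    }
  }
  int strides[3] = {1, dims[0], dims[0] * dims[1]};
  while (tcur < tmax - 1e-13) {
    int amin = 0;
    double tn = tNext[0];
    for (int a = 1; a < ndim; ++a) if (tNext[a] < tn) { tn = tNext[a]; amin = a; }
    if (tn > tmax) tn = tmax;
    double seg = (tn - tcur) * L;
    if (seg > 1e-13) {
      int lin = 0;
      for (int a = 0; a < ndim; ++a) lin += iv[a] * strides[a];
      idx.push_back(lin);
      len.push_back(seg);
    }
    tcur = tn;
    if (tcur >= tmax - 1e-13) break;
    iv[amin] += stepDir[amin];
    if (iv[amin] < 0 || iv[amin] >= dims[amin]) break;
    tNext[amin] += tDelta[amin];
  }
}

// [[Rcpp::export]]
List cpp_siddon(NumericVector p0, NumericVector p1, NumericVector lower,
                NumericVector pitch, IntegerVector dims) {
  int ndim = dims.size();
  std::vector<int> idx; std::vector<double> len;
  traverseGrid(p0.begin(), p1.begin(), lower.begin(), pitch.begin(),
               dims.begin(), ndim, idx, len);
  return List::create(_["index"] = wrap(idx), _["length"] = wrap(len));
}

// Forward projection of 2D basis density maps (host, gold): for each ray,
// accumulate mass thickness rho*l in (g/cm^3)*mm for both bases.
// [[Rcpp::export]]
NumericMatrix cpp_project_rays(NumericMatrix p0, NumericMatrix p1,
                               NumericMatrix host, NumericMatrix gold,
                               NumericVector lower, NumericVector pitch) {
  int nray = p0.nrow();
  int dims[2] = {(int)host.nrow(), (int)host.ncol()};
  NumericMatrix out(nray, 2);
  std::vector<int> idx; std::vector<double> len;
  const double* h = host.begin();
  const double* g = gold.begin();
  for (int r = 0; r < nray; ++r) {
    idx.clear(); len.clear();
    double a[2] = {p0(r, 0), p0(r, 1)};
    double b[2] = {p1(r, 0), p1(r, 1)};
    traverseGrid(a, b, lower.begin(), pitch.begin(), dims, 2, idx, len);
    double sh = 0.0, sg = 0.0;
    for (size_t k = 0; k < idx.size(); ++k) {
      sh += h[idx[k]] * len[k];
      sg += g[idx[k]] * len[k];
    }
    out(r, 0) = sh;
    out(r, 1) = sg;
  }
  return out;
}

// Equiangular fan-beam backprojection: q is (nChannels x nViews), already
// filtered, redundancy-weighted and scaled by the view increment. gamma0 is
// the angle of channel 1, dgamma the channel pitch. Returns the image as a
// vector over (pixX, pixY) pairs; weight 1/L^2 with L the source-pixel
// distance.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericMatrix q, NumericVector betas,
                              double gamma0, double dgamma, double sid,
                              NumericVector pixX, NumericVector pixY) {
  int npix = pixX.size(), nview = betas.size(), nch = q.nrow();
  NumericVector img(npix);
  for (int v = 0; v < nview; ++v) {
    double b = betas[v];
    double sx = sid * std::cos(b), sy = sid * std::sin(b);
    double cx = -std::cos(b), cy = -std::sin(b); // central ray direction
    const double* qv = &q(0, v);
    for (int p = 0; p < npix; ++p) {
      double vx = pixX[p] - sx, vy = pixY[p] - sy;
      double dot = vx * cx + vy * cy;
      if (dot <= 0) continue;
      double gam = std::atan2(cx * vy - cy * vx, dot);
      double u = (gam - gamma0) / dgamma;
      if (u < 0 || u > nch - 1) continue;
      int i0 = (int)std::floor(u);
      if (i0 >= nch - 1) i0 = nch - 2;
      double f = u - i0;
      double val = qv[i0] * (1 - f) + qv[i0 + 1] * f;
      double L2 = vx * vx + vy * vy;
      img[p] += val / L2;
    }
  }
  return img;
}

// Exit-path line integral: for every pixel centre of a 2D attenuation map
// (mu per mm), march along direction (dx, dy) to the grid edge with a fixed
// step, nearest-neighbour sampling. Returns the integral of mu dl.
// [[Rcpp::export]]
NumericMatrix cpp_exit_integral(NumericMatrix mu, NumericVector lower,
                                NumericVector pitch, double dx, double dy,
                                double step) {
  int nx = mu.nrow(), ny = mu.ncol();
  NumericMatrix out(nx, ny);
  double x0 = lower[0], y0 = lower[1], px = pitch[0], py = pitch[1];
  double xmax = x0 + nx * px, ymax = y0 + ny * py;
  for (int j = 0; j < ny; ++j) {
    double cy0 = y0 + (j + 0.5) * py;
    for (int i = 0; i < nx; ++i) {
      double cx0 = x0 + (i + 0.5) * px;
      double acc = 0.0;
      double x = cx0 + 0.5 * step * dx, y = cy0 + 0.5 * step * dy;
      while (x > x0 && x < xmax && y > y0 && y < ymax) {
        int ii = (int)((x - x0) / px), jj = (int)((y - y0) / py);
        if (ii >= 0 && ii < nx && jj >= 0 && jj < ny) acc += mu(ii, jj);
        x += step * dx; y += step * dy;
      }
      out(i, j) = acc * step;
    }
  }
  return out;
}
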