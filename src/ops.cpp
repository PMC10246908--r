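#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
using namespace Rcpp;

static const double DT_INF = 1e20;

// 1D squared distance transform of a sampled function f (Felzenszwalb &
// Huttenlocher lower-envelope algorithm). d receives the transform.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DT_INF;
  z[1] = DT_INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared Euclidean distance (in pixels) to the nearest TRUE pixel.
// Pixels are treated as lattice points; a mask with no TRUE pixel yields
// values >= DT_INF which the R wrapper maps to Inf.
// [[Rcpp::export]]
NumericMatrix edt_sq_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  NumericMatrix out(nr, nc);
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  // column pass
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? 0.0 : DT_INF;
    dt1d(f, d, nr);
    for (int i = 0; i < nr; ++i) out(i, j) = d[i];
  }
  // row pass
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = out(i, j);
    dt1d(f, d, nc);
    for (int j = 0; j < nc; ++j) out(i, j) = d[j];
  }
  return out;
}

// 8-connected component labelling by breadth-first search; labels are
// 1-based, background is 0.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop();
        for (int di = -1; di <= 1; ++di) {
          for (int dj = -1; dj <= 1; ++dj) {
            int ni = ci + di, nj = cj + dj;
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
  return lab;
}

// Intensity-only SLIC superpixels. img should be scaled to [0, 1];
// compactness m weights spatial against intensity distance. Labels 1-based.
// [[Rcpp::export]]
IntegerMatrix slic_cpp(NumericMatrix img, double step, double compactness,
                       int iters) {
  int nr = img.nrow(), nc = img.ncol();
  int gr = std::max(1, (int)std::floor(nr / step));
  int gc = std::max(1, (int)std::floor(nc / step));
  int k = gr * gc;
  std::vector<double> cr(k), cc(k), ci(k);
  int idx = 0;
  for (int a = 0; a < gr; ++a) {
    for (int b = 0; b < gc; ++b) {
      double r = (a + 0.5) * nr / gr, c = (b + 0.5) * nc / gc;
      if (r > nr - 1) r = nr - 1;
      if (c > nc - 1) c = nc - 1;
      cr[idx] = r;
      cc[idx] = c;
      ci[idx] = img((int)r, (int)c);
      ++idx;
    }
  }
  IntegerMatrix lab(nr, nc);
  NumericMatrix dist(nr, nc);
  for (int it = 0; it < iters; ++it) {
    std::fill(lab.begin(), lab.end(), 0);
    std::fill(dist.begin(), dist.end(), DT_INF);
    for (int s = 0; s < k; ++s) {
      int r0 = std::max(0, (int)(cr[s] - 2 * step));
      int r1 = std::min(nr - 1, (int)(cr[s] + 2 * step));
      int c0 = std::max(0, (int)(cc[s] - 2 * step));
      int c1 = std::min(nc - 1, (int)(cc[s] + 2 * step));
      for (int j = c0; j <= c1; ++j) {
        for (int i = r0; i <= r1; ++i) {
          double dc = img(i, j) - ci[s];
          double dsp = std::sqrt((i - cr[s]) * (i - cr[s]) +
                                 (j - cc[s]) * (j - cc[s])) / step;
          double D = dc * dc + compactness * compactness * dsp * dsp;
          if (D < dist(i, j)) {
            dist(i, j) = D;
            lab(i, j) = s + 1;
          }
        }
      }
    }
    std::vector<double> sr(k, 0), sc(k, 0), si(k, 0);
    std::vector<int> n(k, 0);
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int s = lab(i, j) - 1;
        if (s < 0) continue;
        sr[s] += i;
        sc[s] += j;
        si[s] += img(i, j);
        ++n[s];
      }
    }
    for (int s = 0; s < k; ++s) {
      if (n[s] > 0) {
        cr[s] = sr[s] / n[s];
        cc[s] = sc[s] / n[s];
        ci[s] = si[s] / n[s];
      }
    }
  }
  // any pixel left unassigned (possible for extreme step values) takes the
  // label of its nearest assigned neighbour in raster order
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) == 0) lab(i, j) = (j > 0) ? lab(i, j - 1)
                                    : (i > 0 ? lab(i - 1, j) : 1);
  return lab;
}

// Accumulate anti-aliased line segments of a given full width (pixels) into
// an image. Coordinates are 0-based (row, col) segment endpoints; per-pixel
// coverage ramps linearly over one pixel at the segment edge.
// [[Rcpp::export]]
NumericMatrix draw_segments_cpp(int nrow, int ncol, NumericVector r0,
                                NumericVector c0, NumericVector r1,
                                NumericVector c1, double width,
                                NumericVector intensity) {
  NumericMatrix out(nrow, ncol);
  double half = width / 2.0;
  int nseg = r0.size();
  for (int s = 0; s < nseg; ++s) {
    double ar = r0[s], ac = c0[s], br = r1[s], bc = c1[s];
    double vr = br - ar, vc = bc - ac;
    double len2 = vr * vr + vc * vc;
    int lo_r = std::max(0, (int)std::floor(std::min(ar, br) - half - 1));
    int hi_r = std::min(nrow - 1, (int)std::ceil(std::max(ar, br) + half + 1));
    int lo_c = std::max(0, (int)std::floor(std::min(ac, bc) - half - 1));
    int hi_c = std::min(ncol - 1, (int)std::ceil(std::max(ac, bc) + half + 1));
    for (int j = lo_c; j <= hi_c; ++j) {
      for (int i = lo_r; i <= hi_r; ++i) {
        double t = 0.0;
        if (len2 > 0) {
          t = ((i - ar) * vr + (j - ac) * vc) / len2;
          if (t < 0) t = 0;
          if (t > 1) t = 1;
        }
        double dr = i - (ar + t * vr), dc = j - (ac + t * vc);
        double d = std::sqrt(dr * dr + dc * dc);
        double cov = half + 0.5 - d;
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        out(i, j) += intensity[s] * cov;
      }
    }
  }
  return out;
}
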