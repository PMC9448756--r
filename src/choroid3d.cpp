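#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <queue>
using namespace Rcpp;

// Mirror-with-edge boundary (…, v[1], v[0] | v[0], v[1], …), the ndimage
// "reflect" convention; keeps filters unbiased near scan borders.
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - 1 - i;
  return i;
}

// 1D correlation of a 3D volume along one axis (0-based: 0=x, 1=y, 2=z).
// Kernel is centred (odd length). Axes 1 and 2 accumulate over contiguous
// x-runs / en-face planes so memory access stays sequential.
// [[Rcpp::export]]
NumericVector cpp_correlate1d(NumericVector vol, IntegerVector dims,
                              NumericVector kernel, int axis) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  const int klen = kernel.size();
  const int r = klen / 2;
  NumericVector out(vol.size());
  const double *v = vol.begin();
  const double *k = kernel.begin();
  double *o = out.begin();
  const long plane = (long)n0 * n1;

  if (axis == 0) {
    std::vector<double> buf(n0);
    const long nlines = (long)n1 * n2;
    for (long line = 0; line < nlines; ++line) {
      const long base = line * n0;
      for (int i = 0; i < n0; ++i) buf[i] = v[base + i];
      for (int i = 0; i < n0; ++i) {
        double acc = 0.0;
        if (i >= r && i + r < n0) {
          const double *b = &buf[i - r];
          for (int j = 0; j < klen; ++j) acc += b[j] * k[j];
        } else {
          for (int j = 0; j < klen; ++j)
            acc += buf[reflect_idx(i + j - r, n0)] * k[j];
        }
        o[base + i] = acc;
      }
    }
  } else if (axis == 1) {
    for (int z = 0; z < n2; ++z) {
      const double *vp = v + (long)z * plane;
      double *op = o + (long)z * plane;
      for (int y = 0; y < n1; ++y) {
        double *orow = op + (long)y * n0;
        std::fill(orow, orow + n0, 0.0);
        for (int j = 0; j < klen; ++j) {
          const int ys = reflect_idx(y + j - r, n1);
          const double kj = k[j];
          const double *vrow = vp + (long)ys * n0;
          for (int x = 0; x < n0; ++x) orow[x] += kj * vrow[x];
        }
      }
    }
  } else {
    for (int z = 0; z < n2; ++z) {
      double *op = o + (long)z * plane;
      std::fill(op, op + plane, 0.0);
      for (int j = 0; j < klen; ++j) {
        const int zs = reflect_idx(z + j - r, n2);
        const double kj = k[j];
        const double *vp = v + (long)zs * plane;
        for (long i = 0; i < plane; ++i) op[i] += kj * vp[i];
      }
    }
  }
  return out;
}

// Eigenvalues of a symmetric 3x3 matrix, ascending (analytic, Smith 1961).
static inline void eig_sym3(double a00, double a11, double a22,
                            double a01, double a02, double a12,
                            double out[3]) {
  const double p1 = a01 * a01 + a02 * a02 + a12 * a12;
  if (p1 == 0.0) {
    out[0] = a00; out[1] = a11; out[2] = a22;
    std::sort(out, out + 3);
    return;
  }
  const double q = (a00 + a11 + a22) / 3.0;
  const double b00 = a00 - q, b11 = a11 - q, b22 = a22 - q;
  const double p2 = b00 * b00 + b11 * b11 + b22 * b22 + 2.0 * p1;
  const double p = std::sqrt(p2 / 6.0);
  // det(B) / 2 with B = (A - qI) / p
  const double inv_p = 1.0 / p;
  const double c00 = b00 * inv_p, c11 = b11 * inv_p, c22 = b22 * inv_p;
  const double c01 = a01 * inv_p, c02 = a02 * inv_p, c12 = a12 * inv_p;
  double detb = c00 * (c11 * c22 - c12 * c12)
              - c01 * (c01 * c22 - c12 * c02)
              + c02 * (c01 * c12 - c11 * c02);
  double rr = detb / 2.0;
  if (rr < -1.0) rr = -1.0;
  if (rr > 1.0) rr = 1.0;
  const double phi = std::acos(rr) / 3.0;
  const double e1 = q + 2.0 * p * std::cos(phi);
  const double e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
  const double e2 = 3.0 * q - e1 - e3;
  out[0] = e3; out[1] = e2; out[2] = e1;  // ascending
}

// Frangi tubularity from the six Hessian components (already scale-
// normalized). Bright tubes: response 0 where lambda2 > 0 or lambda3 > 0
// (|l1| <= |l2| <= |l3|). The structureness cutoff c is c_frac times the
// maximum Frobenius norm over the volume at this scale.
// [[Rcpp::export]]
NumericVector cpp_frangi(NumericVector hxx, NumericVector hyy,
                         NumericVector hzz, NumericVector hxy,
                         NumericVector hxz, NumericVector hyz,
                         double alpha, double beta, double c_frac) {
  const R_xlen_t n = hxx.size();
  NumericVector out(n);
  std::vector<double> svol((size_t)n);
  double smax = 0.0;
  double lam[3];
  for (R_xlen_t i = 0; i < n; ++i) {
    eig_sym3(hxx[i], hyy[i], hzz[i], hxy[i], hxz[i], hyz[i], lam);
    // order by |lambda|: l1 smallest magnitude
    double a0 = std::fabs(lam[0]), a1 = std::fabs(lam[1]), a2 = std::fabs(lam[2]);
    double l1, l2, l3, m1, m2, m3;
    // lam ascending by value; sort by magnitude explicitly
    double vals[3] = {lam[0], lam[1], lam[2]};
    double mags[3] = {a0, a1, a2};
    int idx[3] = {0, 1, 2};
    if (mags[idx[0]] > mags[idx[1]]) std::swap(idx[0], idx[1]);
    if (mags[idx[1]] > mags[idx[2]]) std::swap(idx[1], idx[2]);
    if (mags[idx[0]] > mags[idx[1]]) std::swap(idx[0], idx[1]);
    l1 = vals[idx[0]]; l2 = vals[idx[1]]; l3 = vals[idx[2]];
    m1 = mags[idx[0]]; m2 = mags[idx[1]]; m3 = mags[idx[2]];
    const double s = std::sqrt(m1 * m1 + m2 * m2 + m3 * m3);
    svol[(size_t)i] = s;
    if (s > smax) smax = s;
    double t = 0.0;
    if (!(l2 > 0.0 || l3 > 0.0) && m3 > 0.0) {
      const double ra = m2 / m3;
      const double rb = m1 / std::sqrt(m2 * m3);
      t = (1.0 - std::exp(-(ra * ra) / (2.0 * alpha * alpha)))
        * std::exp(-(rb * rb) / (2.0 * beta * beta));
    }
    out[i] = t;  // structureness applied in second pass
  }
  if (smax <= 0.0) {
    std::fill(out.begin(), out.end(), 0.0);
    return out;
  }
  const double c = c_frac * smax;
  const double denom = 2.0 * c * c;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double s = svol[(size_t)i];
    out[i] *= 1.0 - std::exp(-(s * s) / denom);
  }
  return out;
}

// Surface model: foreground voxels with at least one 6-face background
// neighbour *inside* the scan domain. Exposure at the scan border does not
// count.
// [[Rcpp::export]]
LogicalVector cpp_surface6(LogicalVector vol, IntegerVector dims) {
  const int n0 = dims[0], n1 = dims[1], n2 = dims[2];
  LogicalVector out(vol.size());
  const int *v = LOGICAL(vol);
  int *o = LOGICAL(out);
  const long s0 = 1, s1 = n0, s2 = (long)n0 * n1;
  for (int z = 0; z < n2; ++z) {
    for (int y = 0; y < n1; ++y) {
      long base = (long)y * s1 + (long)z * s2;
      for (int x = 0; x < n0; ++x) {
        const long i = base + x;
        if (!v[i]) { o[i] = FALSE; continue; }
        bool edge = false;
        if (x > 0      && !v[i - s0]) edge = true;
        else if (x < n0 - 1 && !v[i + s0]) edge = true;
        else if (y > 0      && !v[i - s1]) edge = true;
        else if (y < n1 - 1 && !v[i + s1]) edge = true;
        else if (z > 0      && !v[i - s2]) edge = true;
        else if (z < n2 - 1 && !v[i + s2]) edge = true;
        o[i] = edge;
      }
    }
  }
  return out;
}

// ---- prominence-based 2D maxima (Fiji "Find Maxima" analogue) -------------
//
// A maximum is reported iff its topographic prominence is strictly greater
// than `prominence`; the global maximum's prominence is its height above the
// image minimum. One point per plateau, at the plateau centroid (half-values
// rounded toward the smaller index; if the centroid falls outside the
// plateau, the plateau pixel nearest to it, smaller linear index on ties).

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n, -1) {}
  int find(int x) {
    int root = x;
    while (parent[root] >= 0) root = parent[root];
    while (parent[x] >= 0) { int nxt = parent[x]; parent[x] = root; x = nxt; }
    return root;
  }
};

static inline long round_half_down(double m) {
  double fl = std::floor(m);
  double frac = m - fl;
  if (frac == 0.5) return (long)fl;
  return (long)std::floor(m + 0.5);
}

// [[Rcpp::export]]
LogicalMatrix cpp_prominence_maxima(NumericMatrix img, double prominence) {
  const int nr = img.nrow(), nc = img.ncol();
  const int n = nr * nc;
  LogicalMatrix out(nr, nc);
  if (n == 0) return out;
  const double *v = img.begin();

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&](int a, int b) {
    if (v[a] != v[b]) return v[a] > v[b];
    return a < b;
  });

  UF uf(n);
  std::vector<char> seen(n, 0);
  std::vector<double> peak_val(n, 0.0);
  std::vector<int> peak_pos(n, -1);
  std::vector<int> reported;
  double vmin = v[order[n - 1]];

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    const int pr = p % nr, pc = p / nr;
    int roots[8];
    int nroots = 0;
    for (int k = 0; k < 8; ++k) {
      const int qr = pr + dr[k], qc = pc + dc[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      const int q = qr + qc * nr;
      if (!seen[q]) continue;
      const int rt = uf.find(q);
      bool dup = false;
      for (int m = 0; m < nroots; ++m) if (roots[m] == rt) { dup = true; break; }
      if (!dup) roots[nroots++] = rt;
    }
    seen[p] = 1;
    if (nroots == 0) {
      peak_val[p] = v[p];
      peak_pos[p] = p;
      continue;
    }
    // component with highest peak survives (tie: smaller peak position)
    int best = roots[0];
    for (int m = 1; m < nroots; ++m) {
      if (peak_val[roots[m]] > peak_val[best] ||
          (peak_val[roots[m]] == peak_val[best] &&
           peak_pos[roots[m]] < peak_pos[best])) best = roots[m];
    }
    for (int m = 0; m < nroots; ++m) {
      const int r = roots[m];
      if (r == best) continue;
      const double prom = peak_val[r] - v[p];
      if (prom > prominence) reported.push_back(peak_pos[r]);
      uf.parent[r] = best;
    }
    uf.parent[p] = best;
  }
  // surviving components: prominence above the global minimum
  for (int i = 0; i < n; ++i) {
    if (uf.parent[i] < 0 && peak_pos[i] >= 0) {
      if (peak_val[i] - vmin > prominence) reported.push_back(peak_pos[i]);
    }
  }

  // plateau centroid placement
  std::vector<int> comp;
  std::vector<char> inplat(n, 0);
  for (size_t ri = 0; ri < reported.size(); ++ri) {
    const int p0 = reported[ri];
    const double h = v[p0];
    comp.clear();
    comp.push_back(p0);
    inplat[p0] = 1;
    double sum_r = 0.0, sum_c = 0.0;
    for (size_t head = 0; head < comp.size(); ++head) {
      const int q = comp[head];
      const int qr = q % nr, qc = q / nr;
      sum_r += qr; sum_c += qc;
      for (int k = 0; k < 8; ++k) {
        const int ur = qr + dr[k], uc = qc + dc[k];
        if (ur < 0 || ur >= nr || uc < 0 || uc >= nc) continue;
        const int u = ur + uc * nr;
        if (!inplat[u] && v[u] == h) { inplat[u] = 1; comp.push_back(u); }
      }
    }
    const double m = (double)comp.size();
    long cr = round_half_down(sum_r / m);
    long cc = round_half_down(sum_c / m);
    int target = -1;
    if (cr >= 0 && cr < nr && cc >= 0 && cc < nc &&
        inplat[cr + cc * nr]) {
      target = (int)(cr + cc * nr);
    } else {
      double bestd = -1.0;
      for (size_t j = 0; j < comp.size(); ++j) {
        const int q = comp[j];
        const double ddr = (q % nr) - (double)cr, ddc = (q / nr) - (double)cc;
        const double d = ddr * ddr + ddc * ddc;
        if (bestd < 0 || d < bestd || (d == bestd && q < target)) {
          bestd = d; target = q;
        }
      }
    }
    for (size_t j = 0; j < comp.size(); ++j) inplat[comp[j]] = 0;
    out[target] = TRUE;
  }
  return out;
}
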