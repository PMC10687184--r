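// Filter cores.
//
// All cores operate on a reflect-padded image (padding done in R) stored as
// an R column-major numeric array of dimension Hp x Wp x 3, and return the
// restored interior of size H x W x 3 plus diagnostics.  Intensities are
// real-valued in [0, 255].
//
// Geometry conventions (shared with the R level):
//  - patch radius s, side 2s+1, n = (2s+1)^2 pixels indexed v = 1..n
//    row-major (left-to-right, top-to-bottom); the symmetric index is
//    v_hat = n + 1 - v;
//  - block radius r, b = (2r+1)^2 candidate centers, row-major.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// row-major window offsets for radius rad, as (drow, dcol) pairs
inline void window_offsets(int rad, std::vector<int>& dr, std::vector<int>& dc) {
  const int side = 2 * rad + 1;
  dr.resize(side * side);
  dc.resize(side * side);
  int k = 0;
  for (int a = -rad; a <= rad; ++a)
    for (int b = -rad; b <= rad; ++b) {
      dr[k] = a;
      dc[k] = b;
      ++k;
    }
}

// copy the n patch pixels around (row, col) into out[n][3]
inline void load_patch(const double* x, int Hp, int plane, int row, int col,
                       const std::vector<int>& dr, const std::vector<int>& dc,
                       int n, std::vector<double>& out) {
  for (int u = 0; u < n; ++u) {
    const int base = (row + dr[u]) + Hp * (col + dc[u]);
    out[3 * u]     = x[base];
    out[3 * u + 1] = x[base + plane];
    out[3 * u + 2] = x[base + 2 * plane];
  }
}

// trimmed patch dissimilarity Delta(Wj, Wc) plus the trimmed-window
// membership of Wj (beta pixels with smallest R); returns Delta
inline double trimmed_delta(const std::vector<double>& jp,
                            const std::vector<double>& cp, int n, int alpha,
                            int beta, std::vector<double>& d2,
                            std::vector<double>& rv, std::vector<int>& ord,
                            std::vector<char>& sel) {
  for (int u = 0; u < n; ++u) {
    const double ur = jp[3 * u], ug = jp[3 * u + 1], ub = jp[3 * u + 2];
    for (int k = 0; k < n; ++k) {
      const double a = ur - cp[3 * k];
      const double b = ug - cp[3 * k + 1];
      const double c = ub - cp[3 * k + 2];
      d2[k] = a * a + b * b + c * c;
    }
    if (alpha < n)
      std::nth_element(d2.begin(), d2.begin() + alpha, d2.end());
    double s = 0.0;
    for (int k = 0; k < alpha; ++k) s += d2[k];
    rv[u] = s / alpha;
  }
  for (int u = 0; u < n; ++u) ord[u] = u;
  // stable: ties in R broken by ascending patch index
  std::stable_sort(ord.begin(), ord.end(),
                   [&rv](int a, int b) { return rv[a] < rv[b]; });
  std::fill(sel.begin(), sel.end(), 0);
  double dsum = 0.0;
  for (int k = 0; k < beta; ++k) {
    sel[ord[k]] = 1;
    dsum += rv[ord[k]];
  }
  return dsum / beta;
}

} // namespace

// MINOR filter core.  global = true: single pooled weighted average over all
// (v, j) contributions (MINOR_G); global = false: n per-offset estimates,
// each normalized separately, averaged over the non-empty ones (MINOR_S).
// Accumulation is center-major (c, then j, then v), deterministic.
// [[Rcpp::export]]
List minor_core(NumericVector padded, int H, int W, int s, int r, int alpha,
                int beta, double sigma, bool global, double tau) {
  const IntegerVector pd = padded.attr("dim");
  const int Hp = pd[0], Wp = pd[1];
  const int m = r + 2 * s; // margin used when padding
  const int side = 2 * s + 1, n = side * side;
  const int plane = Hp * Wp;
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double* x = padded.begin();

  std::vector<int> pdr, pdc, bdr, bdc;
  window_offsets(s, pdr, pdc);
  window_offsets(r, bdr, bdc);
  const int b = (int)bdr.size();

  const int nplanes = global ? 1 : n;
  std::vector<double> num((size_t)H * W * 3 * nplanes, 0.0);
  std::vector<double> den((size_t)H * W * nplanes, 0.0);

  std::vector<double> cp(3 * n), jp(3 * n), d2(n), rv(n);
  std::vector<int> ord(n);
  std::vector<char> sel(n);

  // centers c range over the interior dilated by s
  for (int cr = m - s; cr <= m + H - 1 + s; ++cr) {
    for (int cc = m - s; cc <= m + W - 1 + s; ++cc) {
      load_patch(x, Hp, plane, cr, cc, pdr, pdc, n, cp);
      for (int jb = 0; jb < b; ++jb) {
        const int jr = cr + bdr[jb], jc = cc + bdc[jb];
        load_patch(x, Hp, plane, jr, jc, pdr, pdc, n, jp);
        const double delta =
            trimmed_delta(jp, cp, n, alpha, beta, d2, rv, ord, sel);
        const double w = std::exp(-delta * inv_s2);
        if (w < tau) continue;
        // scatter: c is the offset-v neighbour of i, so i = c - offset_v;
        // the contributing pixel is patch position v_hat of Wj, gated on
        // membership of v_hat in the trimmed window Wj*
        for (int v = 0; v < n; ++v) {
          const int ir = cr - pdr[v], ic = cc - pdc[v];
          if (ir < m || ir >= m + H || ic < m || ic >= m + W) continue;
          const int vh = n - 1 - v;
          if (!sel[vh]) continue;
          const size_t ii = (size_t)(ir - m) + (size_t)H * (ic - m);
          const size_t pl = global ? 0 : (size_t)v;
          const int src = (jr + pdr[vh]) + Hp * (jc + pdc[vh]);
          double* np = &num[3 * (ii + (size_t)H * W * pl)];
          np[0] += w * x[src];
          np[1] += w * x[src + plane];
          np[2] += w * x[src + 2 * plane];
          den[ii + (size_t)H * W * pl] += w;
        }
      }
    }
  }

  NumericVector out((size_t)H * W * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  NumericVector zmap((size_t)H * W);
  zmap.attr("dim") = IntegerVector::create(H, W);
  int fallback = 0;
  const size_t HW = (size_t)H * W;
  for (size_t ii = 0; ii < HW; ++ii) {
    const int ir = (int)(ii % H) + m, ic = (int)(ii / H) + m;
    const int src = ir + Hp * ic;
    double rgb[3] = {0, 0, 0}, ztot = 0.0;
    int nv = 0;
    if (global) {
      if (den[ii] > 0.0) {
        for (int q = 0; q < 3; ++q) rgb[q] = num[3 * ii + q] / den[ii];
        ztot = den[ii];
        nv = 1;
      }
    } else {
      for (int v = 0; v < n; ++v) {
        const double z = den[ii + HW * v];
        if (z > 0.0) {
          for (int q = 0; q < 3; ++q)
            rgb[q] += num[3 * (ii + HW * v) + q] / z;
          ztot += z;
          ++nv;
        }
      }
      if (nv > 0)
        for (int q = 0; q < 3; ++q) rgb[q] /= nv;
    }
    if (nv == 0) { // empty contribution set: keep the input pixel
      ++fallback;
      for (int q = 0; q < 3; ++q) rgb[q] = x[src + q * plane];
    }
    for (int q = 0; q < 3; ++q) out[ii + HW * q] = rgb[q];
    zmap[ii] = ztot;
  }
  return List::create(_["image"] = out, _["z"] = zmap,
                      _["fallback"] = fallback);
}

// Classic NLM core.  mode: 0 = pixelwise, 1 = patchwise (blockwise,
// mean of n per-offset estimates with the symmetric index), 2 = global
// (single pooled average).  central: 0 = raw self-weight (1), 1 = replace
// the self-weight by the maximum weight among the other block members.
// [[Rcpp::export]]
List nlm_core(NumericVector padded, int H, int W, int s, int r, double sigma,
              int mode, int central, double tau) {
  const IntegerVector pd = padded.attr("dim");
  const int Hp = pd[0], Wp = pd[1];
  const int side = 2 * s + 1, n = side * side;
  const int plane = Hp * Wp;
  const double inv_s2 = 1.0 / (sigma * sigma);
  const double* x = padded.begin();

  std::vector<int> pdr, pdc, bdr, bdc;
  window_offsets(s, pdr, pdc);
  window_offsets(r, bdr, bdc);
  const int b = (int)bdr.size();
  const int jcenter = (b - 1) / 2; // row-major index of the block center

  NumericVector out((size_t)H * W * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  NumericVector zmap((size_t)H * W);
  zmap.attr("dim") = IntegerVector::create(H, W);
  int fallback = 0;
  const size_t HW = (size_t)H * W;

  std::vector<double> cp(3 * n), jp(3 * n), wbuf(b);

  if (mode == 0) { // pixelwise, margin r + s
    const int m = r + s;
    for (int ic = m; ic < m + W; ++ic) {
      for (int ir = m; ir < m + H; ++ir) {
        load_patch(x, Hp, plane, ir, ic, pdr, pdc, n, cp);
        double wmax = 0.0;
        for (int jb = 0; jb < b; ++jb) {
          load_patch(x, Hp, plane, ir + bdr[jb], ic + bdc[jb], pdr, pdc, n, jp);
          double D = 0.0;
          for (int k = 0; k < 3 * n; ++k) {
            const double d = jp[k] - cp[k];
            D += d * d;
          }
          wbuf[jb] = std::exp(-D * inv_s2);
          if (jb != jcenter && wbuf[jb] > wmax) wmax = wbuf[jb];
        }
        if (central == 1) wbuf[jcenter] = wmax;
        double rgb[3] = {0, 0, 0}, Z = 0.0;
        for (int jb = 0; jb < b; ++jb) {
          const double w = wbuf[jb];
          if (w < tau || w <= 0.0) continue;
          const int src = (ir + bdr[jb]) + Hp * (ic + bdc[jb]);
          rgb[0] += w * x[src];
          rgb[1] += w * x[src + plane];
          rgb[2] += w * x[src + 2 * plane];
          Z += w;
        }
        const size_t ii = (size_t)(ir - m) + (size_t)H * (ic - m);
        if (Z > 0.0) {
          for (int q = 0; q < 3; ++q) out[ii + HW * q] = rgb[q] / Z;
        } else {
          ++fallback;
          const int src = ir + Hp * ic;
          for (int q = 0; q < 3; ++q) out[ii + HW * q] = x[src + q * plane];
        }
        zmap[ii] = Z;
      }
    }
    return List::create(_["image"] = out, _["z"] = zmap,
                        _["fallback"] = fallback);
  }

  // patchwise / global: scatter over block centers, margin r + 2s
  const int m = r + 2 * s;
  const int nplanes = (mode == 2) ? 1 : n;
  std::vector<double> num((size_t)HW * 3 * nplanes, 0.0);
  std::vector<double> den((size_t)HW * nplanes, 0.0);

  for (int cr = m - s; cr <= m + H - 1 + s; ++cr) {
    for (int cc = m - s; cc <= m + W - 1 + s; ++cc) {
      load_patch(x, Hp, plane, cr, cc, pdr, pdc, n, cp);
      double wmax = 0.0;
      for (int jb = 0; jb < b; ++jb) {
        load_patch(x, Hp, plane, cr + bdr[jb], cc + bdc[jb], pdr, pdc, n, jp);
        double D = 0.0;
        for (int k = 0; k < 3 * n; ++k) {
          const double d = jp[k] - cp[k];
          D += d * d;
        }
        wbuf[jb] = std::exp(-D * inv_s2);
        if (jb != jcenter && wbuf[jb] > wmax) wmax = wbuf[jb];
      }
      if (central == 1) wbuf[jcenter] = wmax;
      for (int jb = 0; jb < b; ++jb) {
        const double w = wbuf[jb];
        if (w < tau || w <= 0.0) continue;
        const int jr = cr + bdr[jb], jc = cc + bdc[jb];
        for (int v = 0; v < n; ++v) {
          const int ir = cr - pdr[v], ic = cc - pdc[v];
          if (ir < m || ir >= m + H || ic < m || ic >= m + W) continue;
          const int vh = n - 1 - v;
          const size_t ii = (size_t)(ir - m) + (size_t)H * (ic - m);
          const size_t pl = (mode == 2) ? 0 : (size_t)v;
          const int src = (jr + pdr[vh]) + Hp * (jc + pdc[vh]);
          double* np = &num[3 * (ii + HW * pl)];
          np[0] += w * x[src];
          np[1] += w * x[src + plane];
          np[2] += w * x[src + 2 * plane];
          den[ii + HW * pl] += w;
        }
      }
    }
  }

  for (size_t ii = 0; ii < HW; ++ii) {
    const int ir = (int)(ii % H) + m, ic = (int)(ii / H) + m;
    double rgb[3] = {0, 0, 0}, ztot = 0.0;
    int nv = 0;
    if (mode == 2) {
      if (den[ii] > 0.0) {
        for (int q = 0; q < 3; ++q) rgb[q] = num[3 * ii + q] / den[ii];
        ztot = den[ii];
        nv = 1;
      }
    } else {
      for (int v = 0; v < n; ++v) {
        const double z = den[ii + HW * v];
        if (z > 0.0) {
          for (int q = 0; q < 3; ++q)
            rgb[q] += num[3 * (ii + HW * v) + q] / z;
          ztot += z;
          ++nv;
        }
      }
      if (nv > 0)
        for (int q = 0; q < 3; ++q) rgb[q] /= nv;
    }
    if (nv == 0) {
      ++fallback;
      const int src = ir + Hp * ic;
      for (int q = 0; q < 3; ++q) rgb[q] = x[src + q * plane];
    }
    for (int q = 0; q < 3; ++q) out[ii + HW * q] = rgb[q];
    zmap[ii] = ztot;
  }
  return List::create(_["image"] = out, _["z"] = zmap,
                      _["fallback"] = fallback);
}

// Bilateral filter core: weights combine spatial closeness (2D Euclidean
// distance between coordinates) and radiometric similarity (RGB distance).
// [[Rcpp::export]]
List bilateral_core(NumericVector padded, int H, int W, int r, double sigma_s,
                    double sigma_r) {
  const IntegerVector pd = padded.attr("dim");
  const int Hp = pd[0], Wp = pd[1];
  const int plane = Hp * Wp;
  const double inv_ss = 1.0 / (sigma_s * sigma_s);
  const double inv_sr = 1.0 / (sigma_r * sigma_r);
  const double* x = padded.begin();

  std::vector<int> bdr, bdc;
  window_offsets(r, bdr, bdc);
  const int b = (int)bdr.size();
  std::vector<double> wspat(b);
  for (int jb = 0; jb < b; ++jb) {
    const double rho2 = (double)bdr[jb] * bdr[jb] + (double)bdc[jb] * bdc[jb];
    wspat[jb] = std::exp(-rho2 * inv_ss);
  }

  NumericVector out((size_t)H * W * 3);
  out.attr("dim") = IntegerVector::create(H, W, 3);
  NumericVector zmap((size_t)H * W);
  zmap.attr("dim") = IntegerVector::create(H, W);
  const size_t HW = (size_t)H * W;
  const int m = r;

  for (int ic = m; ic < m + W; ++ic) {
    for (int ir = m; ir < m + H; ++ir) {
      const int ci = ir + Hp * ic;
      const double c0 = x[ci], c1 = x[ci + plane], c2 = x[ci + 2 * plane];
      double rgb[3] = {0, 0, 0}, Z = 0.0;
      for (int jb = 0; jb < b; ++jb) {
        const int src = (ir + bdr[jb]) + Hp * (ic + bdc[jb]);
        const double d0 = x[src] - c0, d1 = x[src + plane] - c1,
                     d2 = x[src + 2 * plane] - c2;
        const double w =
            wspat[jb] * std::exp(-(d0 * d0 + d1 * d1 + d2 * d2) * inv_sr);
        rgb[0] += w * x[src];
        rgb[1] += w * x[src + plane];
        rgb[2] += w * x[src + 2 * plane];
        Z += w;
      }
      const size_t ii = (size_t)(ir - m) + (size_t)H * (ic - m);
      for (int q = 0; q < 3; ++q) out[ii + HW * q] = rgb[q] / Z;
      zmap[ii] = Z;
    }
  }
  return List::create(_["image"] = out, _["z"] = zmap, _["fallback"] = 0);
}
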