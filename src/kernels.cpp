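#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Band-limited pulses evaluated analytically on the sample clock.
// PA: derivative-of-Gaussian (bipolar, N-shape-like), unit peak amplitude.
// US: Gaussian-windowed tone burst at the transducer center frequency.

static inline double dog_pulse(double t, double sigma) {
  // peak |value| of -(t/sigma) exp(-t^2/2sigma^2) is exp(-0.5) at |t| = sigma
  return -(t / sigma) * std::exp(-t * t / (2.0 * sigma * sigma)) / std::exp(-0.5);
}

static inline double tone_burst(double t, double sigma, double fc) {
  return std::cos(2.0 * M_PI * fc * t) * std::exp(-t * t / (2.0 * sigma * sigma));
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_pa(NumericVector src_x, NumericVector src_y,
                             NumericVector amp, NumericMatrix elem_xy,
                             double fs, double c, int n_t,
                             double sigma_us, double dist_floor) {
  const int n_src = src_x.size(), n_el = elem_xy.nrow();
  NumericMatrix out(n_t, n_el);
  const double half_support = 5.0 * sigma_us;
  for (int e = 0; e < n_el; ++e) {
    const double ex = elem_xy(e, 0), ey = elem_xy(e, 1);
    double* col = &out(0, e);
    for (int s = 0; s < n_src; ++s) {
      const double dx = src_x[s] - ex, dy = src_y[s] - ey;
      const double d = std::sqrt(dx * dx + dy * dy);
      const double t0 = d / c;
      const double a = amp[s] / std::max(d, dist_floor);
      int k0 = (int)std::ceil((t0 - half_support) * fs);
      int k1 = (int)std::floor((t0 + half_support) * fs);
      if (k0 < 0) k0 = 0;
      if (k1 > n_t - 1) k1 = n_t - 1;
      for (int k = k0; k <= k1; ++k)
        col[k] += a * dog_pulse(k / fs - t0, sigma_us);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_forward_us(NumericVector sc_x, NumericVector sc_y,
                             NumericVector refl,
                             double em_x, double em_y,
                             double em_nx, double em_ny,
                             double cos_half_angle,
                             NumericMatrix recv_xy,
                             double fs, double c, int n_t,
                             double sigma_env, double fc, double dist_floor) {
  const int n_sc = sc_x.size(), n_rx = recv_xy.nrow();
  NumericMatrix out(n_t, n_rx);
  const double half_support = 5.0 * sigma_env;
  for (int s = 0; s < n_sc; ++s) {
    const double dx = sc_x[s] - em_x, dy = sc_y[s] - em_y;
    const double de = std::sqrt(dx * dx + dy * dy);
    if (de <= 0) continue;
    // transmit diffraction cone gate around the emitter axis
    const double cos_ang = (dx * em_nx + dy * em_ny) / de;
    if (cos_ang < cos_half_angle) continue;
    const double de_f = std::max(de, dist_floor);
    for (int r = 0; r < n_rx; ++r) {
      const double rx = sc_x[s] - recv_xy(r, 0), ry = sc_y[s] - recv_xy(r, 1);
      const double dr = std::sqrt(rx * rx + ry * ry);
      const double t0 = (de + dr) / c;
      const double a = refl[s] / (de_f * std::max(dr, dist_floor));
      int k0 = (int)std::ceil((t0 - half_support) * fs);
      int k1 = (int)std::floor((t0 + half_support) * fs);
      if (k0 < 0) k0 = 0;
      if (k1 > n_t - 1) k1 = n_t - 1;
      double* col = &out(0, r);
      for (int k = k0; k <= k1; ++k)
        col[k] += a * tone_burst(k / fs - t0, sigma_env, fc);
    }
  }
  return out;
}

// Weighted delay-and-sum. apod: 0 none, 1 hann (cos^2), 2 cosine.
// mode: 0 bipolar s(tau); 1 unipolar signed s - kappa*ds/dt;
//       2 unipolar with per-contribution half-wave rectification.
// Returns pixel vector; attribute "truncated" counts out-of-window lookups.
// [[Rcpp::export]]
NumericVector cpp_das(NumericMatrix samples, NumericMatrix elem_xy,
                      NumericMatrix elem_norm,
                      NumericVector px, NumericVector py,
                      double fs, double c, double t0,
                      int apod, int mode, double kappa) {
  const int n_t = samples.nrow(), n_el = samples.ncol(), n_px = px.size();
  NumericVector out(n_px);
  long long truncated = 0;
  const bool deriv = mode != 0;
  std::vector<double> ds(deriv ? n_t : 0);
  for (int e = 0; e < n_el; ++e) {
    const double ex = elem_xy(e, 0), ey = elem_xy(e, 1);
    const double nx = elem_norm(e, 0), ny = elem_norm(e, 1);
    const double* s = &samples(0, e);
    if (deriv) {
      // central-difference time derivative, one-sided at the ends
      for (int k = 1; k < n_t - 1; ++k) ds[k] = (s[k + 1] - s[k - 1]) * fs / 2.0;
      ds[0] = (s[1] - s[0]) * fs;
      ds[n_t - 1] = (s[n_t - 1] - s[n_t - 2]) * fs;
    }
    for (int p = 0; p < n_px; ++p) {
      const double dx = px[p] - ex, dy = py[p] - ey;
      const double d = std::sqrt(dx * dx + dy * dy);
      double w = 1.0;
      if (apod != 0) {
        const double ca = (d > 0) ? (dx * nx + dy * ny) / d : 1.0;
        w = (ca > 0) ? (apod == 1 ? ca * ca : ca) : 0.0;
        if (w == 0.0) continue;
      }
      const double tau = (d / c - t0) * fs;
      const int k = (int)std::floor(tau);
      if (k < 0 || k >= n_t - 1) { ++truncated; continue; }
      const double fr = tau - k;
      double v = s[k] * (1.0 - fr) + s[k + 1] * fr;
      if (deriv) v -= kappa * (ds[k] * (1.0 - fr) + ds[k + 1] * fr);
      if (mode == 2 && v < 0) v = 0;
      out[p] += w * v;
    }
  }
  out.attr("truncated") = (double)truncated;
  return out;
}

// Per-frame complex synthetic-aperture DAS over gated receivers.
// re/im: analytic channel signal, n_t x n_recv (already subset to gated ones).
// [[Rcpp::export]]
List cpp_sa_das(NumericMatrix re, NumericMatrix im,
                double em_x, double em_y,
                NumericMatrix recv_xy,
                NumericVector px, NumericVector py,
                double fs, double c, double t0) {
  const int n_t = re.nrow(), n_rx = re.ncol(), n_px = px.size();
  NumericVector o_re(n_px), o_im(n_px);
  std::vector<double> d_em(n_px);
  for (int p = 0; p < n_px; ++p) {
    const double dx = px[p] - em_x, dy = py[p] - em_y;
    d_em[p] = std::sqrt(dx * dx + dy * dy);
  }
  long long truncated = 0;
  for (int r = 0; r < n_rx; ++r) {
    const double rx = recv_xy(r, 0), ry = recv_xy(r, 1);
    const double* sr = &re(0, r);
    const double* si = &im(0, r);
    for (int p = 0; p < n_px; ++p) {
      const double dx = px[p] - rx, dy = py[p] - ry;
      const double d = d_em[p] + std::sqrt(dx * dx + dy * dy);
      const double tau = (d / c - t0) * fs;
      const int k = (int)std::floor(tau);
      if (k < 0 || k >= n_t - 1) { ++truncated; continue; }
      const double fr = tau - k;
      o_re[p] += sr[k] * (1.0 - fr) + sr[k + 1] * fr;
      o_im[p] += si[k] * (1.0 - fr) + si[k + 1] * fr;
    }
  }
  return List::create(_["re"] = o_re, _["im"] = o_im,
                      _["truncated"] = (double)truncated);
}

// Zhang-Suen thinning of a binary image to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<char> a(nr * nc), b;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) a[i + (size_t)j * nr] = img(i, j) ? 1 : 0;
  b = a;
  auto at = [&](std::vector<char>& m, int i, int j) -> char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return m[i + (size_t)j * nr];
  };
  bool changed = true;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      std::vector<std::pair<int, int>> kill;
      for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
        if (!at(a, i, j)) continue;
        // 8-neighborhood clockwise from north: p2..p9
        char p2 = at(a, i - 1, j),     p3 = at(a, i - 1, j + 1);
        char p4 = at(a, i, j + 1),     p5 = at(a, i + 1, j + 1);
        char p6 = at(a, i + 1, j),     p7 = at(a, i + 1, j - 1);
        char p8 = at(a, i, j - 1),     p9 = at(a, i - 1, j - 1);
        int bsum = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (bsum < 2 || bsum > 6) continue;
        char seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
        int trans = 0;
        for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++trans;
        if (trans != 1) continue;
        if (pass == 0) {
          if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
        } else {
          if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
        }
        kill.push_back({i, j});
      }
      if (!kill.empty()) changed = true;
      for (auto& q : kill) a[q.first + (size_t)q.second * nr] = 0;
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = a[i + (size_t)j * nr] != 0;
  return out;
}

// 8-connected component labeling (iterative flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix img) {
  const int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int, int>> stack;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!img(i, j) || lab(i, j) != 0) continue;
    ++next;
    stack.push_back({i, j});
    lab(i, j) = next;
    while (!stack.empty()) {
      auto [ci, cj] = stack.back();
      stack.pop_back();
      for (int dj = -1; dj <= 1; ++dj) for (int di = -1; di <= 1; ++di) {
        const int ni = ci + di, nj = cj + dj;
        if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
        if (img(ni, nj) && lab(ni, nj) == 0) {
          lab(ni, nj) = next;
          stack.push_back({ni, nj});
        }
      }
    }
  }
  return lab;
}

// Stamp thick polylines (vessels) into an image: for each sample point,
// add value into all pixels within radius_px. Image modified in place.
// [[Rcpp::export]]
NumericMatrix cpp_stamp_discs(NumericMatrix img, NumericVector row,
                              NumericVector col, NumericVector radius_px,
                              NumericVector value) {
  const int nr = img.nrow(), nc = img.ncol(), n = row.size();
  for (int s = 0; s < n; ++s) {
    const double r = radius_px[s], rc = row[s], cc = col[s], v = value[s];
    const int i0 = std::max(0, (int)std::floor(rc - r)),
              i1 = std::min(nr - 1, (int)std::ceil(rc + r));
    const int j0 = std::max(0, (int)std::floor(cc - r)),
              j1 = std::min(nc - 1, (int)std::ceil(cc + r));
    for (int j = j0; j <= j1; ++j) for (int i = i0; i <= i1; ++i) {
      const double di = i - rc, dj = j - cc;
      if (di * di + dj * dj <= r * r && v > img(i, j)) img(i, j) = v;
    }
  }
  return img;
}
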