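// Cell-list force summation for the anisotropic particle model.
// Family codes: 1 = kc-like (alpha beta gamma eA eR cs_fa cl_fa),
// 2 = piecewise (alpha beta gamma eA eR cs_fa cl_fa c1 c2),
// 3 = oscillator (c cs cl es1 es2 el1 el2 as al).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double minimg(double d) { return d - std::floor(d + 0.5); }

static inline void axis_coeffs(int family, const double* p, double r,
                               double& fs, double& fl) {
  switch (family) {
  case 1: {
    double fR = (p[0] * r * r + p[1]) * std::exp(-p[4] * r);
    double fA = -p[2] * r * std::exp(-p[3] * r);
    fs = p[5] * fA + fR;
    fl = p[6] * fA + fR;
    break;
  }
  case 2: {
    double fR = (p[0] * r * r + p[1]) * std::exp(-p[4] * r);
    double fA = -p[2] * r * std::exp(-p[3] * r);
    fs = p[5] * fA + fR;
    double f1 = p[6] * fA + fR;  // f(r, 1) with the delta factor folded in
    double c1 = p[7], c2 = p[8];
    if (r < c1) {
      fl = f1;
    } else if (r > c2) {
      fl = -f1;
    } else {
      double fc1 = (p[6] * (-p[2] * c1 * std::exp(-p[3] * c1)) +
                    (p[0] * c1 * c1 + p[1]) * std::exp(-p[4] * c1));
      double fc2 = (p[6] * (-p[2] * c2 * std::exp(-p[3] * c2)) +
                    (p[0] * c2 * c2 + p[1]) * std::exp(-p[4] * c2));
      fl = fc1 + (r - c1) / (c2 - c1) * (-fc2 - fc1);
    }
    break;
  }
  case 3: {
    fs = p[0] * std::exp(p[3] * r) +
         p[1] * std::sin(M_PI * r / p[7]) * std::exp(p[4] * r);
    fl = p[0] * std::cos(M_PI * r / p[8]) * std::exp(p[5] * r) +
         p[2] * std::sin(M_PI * r / p[8]) * std::exp(p[6] * r);
    break;
  }
  default:
    fs = fl = 0.0;
  }
}

// accumulate the force that particle k exerts on particle j
static inline void add_pair(const double* px, const double* py,
                            const double* s1, const double* s2, int j, int k,
                            int family, const double* p, double cutoff,
                            double eta, double& vx, double& vy) {
  double dx = eta * minimg(px[j] - px[k]);
  double dy = eta * minimg(py[j] - py[k]);
  double r = std::sqrt(dx * dx + dy * dy);
  if (r >= cutoff || r == 0.0) return;
  double fs, fl;
  axis_coeffs(family, p, r, fs, fl);
  // frame of particle j: s = (s1, s2), l = (-s2, s1)
  double ps = dx * s1[j] + dy * s2[j];
  double pl = -dx * s2[j] + dy * s1[j];
  vx += fs * ps * s1[j] + fl * pl * (-s2[j]);
  vy += fs * ps * s2[j] + fl * pl * s1[j];
}

// [[Rcpp::export]]
NumericMatrix velocities_cpp(NumericMatrix pos, NumericMatrix S, int family,
                             NumericVector params, double cutoff, double eta,
                             int cells) {
  const int n = pos.nrow();
  NumericMatrix v(n, 2);
  std::vector<double> px(n), py(n), s1(n), s2(n);
  for (int j = 0; j < n; ++j) {
    px[j] = pos(j, 0); py[j] = pos(j, 1);
    s1[j] = S(j, 0);   s2[j] = S(j, 1);
  }
  const double* pp = params.begin();

  if (cells < 3) {
    // neighbourhood covers the torus: direct double loop
    for (int j = 0; j < n; ++j) {
      double vx = 0, vy = 0;
      for (int k = 0; k < n; ++k)
        if (k != j)
          add_pair(px.data(), py.data(), s1.data(), s2.data(), j, k, family,
                   pp, cutoff, eta, vx, vy);
      v(j, 0) = vx / n;
      v(j, 1) = vy / n;
    }
    return v;
  }

  // linked-cell lists
  const int nc = cells * cells;
  std::vector<int> head(nc, -1), nxt(n, -1);
  auto cell_of = [&](double x, double y) {
    int cx = (int)std::floor(x * cells); if (cx >= cells) cx = cells - 1; if (cx < 0) cx = 0;
    int cy = (int)std::floor(y * cells); if (cy >= cells) cy = cells - 1; if (cy < 0) cy = 0;
    return cy * cells + cx;
  };
  for (int j = 0; j < n; ++j) {
    int c = cell_of(px[j], py[j]);
    nxt[j] = head[c];
    head[c] = j;
  }
  for (int j = 0; j < n; ++j) {
    double vx = 0, vy = 0;
    int cx = (int)std::floor(px[j] * cells); if (cx >= cells) cx = cells - 1;
    int cy = (int)std::floor(py[j] * cells); if (cy >= cells) cy = cells - 1;
    for (int oy = -1; oy <= 1; ++oy) {
      int wy = (cy + oy + cells) % cells;
      for (int ox = -1; ox <= 1; ++ox) {
        int wx = (cx + ox + cells) % cells;
        for (int k = head[wy * cells + wx]; k != -1; k = nxt[k])
          if (k != j)
            add_pair(px.data(), py.data(), s1.data(), s2.data(), j, k, family,
                     pp, cutoff, eta, vx, vy);
      }
    }
    v(j, 0) = vx / n;
    v(j, 1) = vy / n;
  }
  return v;
}
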