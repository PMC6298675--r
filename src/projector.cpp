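#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix radon_cpp(NumericMatrix img, NumericVector angles, int nbins,
                        int supersample, bool nearest) {
  const int n = img.nrow(), na = angles.size(), k = supersample;
  NumericMatrix out(na, nbins);
  const int ic = n / 2;
  const double c0 = (nbins - 1) / 2.0;
  const double kk = (double)k * k;
  std::vector<double> offs(k);
  for (int i = 0; i < k; ++i) offs[i] = (i + 1 - (k + 1) / 2.0) / k;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      const double yproj = (j - ic) * st + c0;
      for (int i = 0; i < n; ++i) {
        const double v = img(i, j);
        if (v == 0.0) continue;
        const double rb = (i - ic) * ct + yproj;
        const double vv = v / kk;
        for (int dx = 0; dx < k; ++dx) {
          const double rx = rb + offs[dx] * ct;
          for (int dy = 0; dy < k; ++dy) {
            const double r = rx + offs[dy] * st;
            if (nearest) {
              long b = std::lround(r);
              if (b < 0) b = 0;
              if (b >= nbins) b = nbins - 1;
              out(a, b) += vv;
            } else {
              int b0 = (int)std::floor(r);
              const double w = r - b0;
              int bl = b0 < 0 ? 0 : (b0 >= nbins ? nbins - 1 : b0);
              int b1 = b0 + 1;
              int bh = b1 < 0 ? 0 : (b1 >= nbins ? nbins - 1 : b1);
              out(a, bl) += vv * (1.0 - w);
              out(a, bh) += vv * w;
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix backproject_cpp(NumericMatrix sino, NumericVector angles,
                              int out_size, bool nearest) {
  const int na = sino.nrow(), nb = sino.ncol(), n = out_size;
  NumericMatrix out(n, n);
  const int ic = n / 2;
  const double c0 = (nb - 1) / 2.0;
  const double dth = M_PI / na;
  for (int a = 0; a < na; ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    for (int j = 0; j < n; ++j) {
      const double yproj = (j - ic) * st + c0;
      for (int i = 0; i < n; ++i) {
        const double r = (i - ic) * ct + yproj;
        if (nearest) {
          const long b = std::lround(r);
          if (b >= 0 && b < nb) out(i, j) += sino(a, b) * dth;
        } else {
          const int b0 = (int)std::floor(r);
          double acc = 0.0;
          const double w = r - b0;
          if (b0 >= 0 && b0 < nb) acc += sino(a, b0) * (1.0 - w);
          if (b0 + 1 >= 0 && b0 + 1 < nb) acc += sino(a, b0 + 1) * w;
          out(i, j) += acc * dth;
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
IntegerMatrix trajectory_counts_cpp(int n, NumericVector angles) {
  IntegerMatrix cnt(n, n);
  const int c0 = n / 2;
  const int smax = (int)std::ceil(n * 0.7071067811865476) + 1;
  for (int a = 0; a < angles.size(); ++a) {
    const double ct = std::cos(angles[a]), st = std::sin(angles[a]);
    cnt(c0, c0) += 1;
    for (int dir = -1; dir <= 1; dir += 2) {
      for (int s = 1; s <= smax; ++s) {
        int i = c0 + (int)std::lround(dir * s * ct);
        int j = c0 + (int)std::lround(dir * s * st);
        // on even grids +Nyquist aliases to the unmatched -Nyquist row/col;
        // wrapping keeps the weight matrix Hermitian-symmetric
        if (n % 2 == 0) {
          if (i == n) i = 0;
          if (j == n) j = 0;
        }
        if (i < 0 || i >= n || j < 0 || j >= n) break;
        cnt(i, j) += 1;
      }
    }
  }
  return cnt;
}
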