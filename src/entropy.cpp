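#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Approximate entropy (Pincus): self-matches included, log of the mean
// match fraction averaged over the n - m + 1 templates of each length.
// One pass serves both template lengths, because the Chebyshev distance
// at length m + 1 is the length-m distance maxed with one extra term.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  if (n <= m + 1) stop("approximate entropy needs length(x) > m + 1");
  if (r <= 0) stop("tolerance r must be positive");
  const double* p = REAL(x);
  int nt2 = n - m + 1;      // templates of length m
  int nt3 = n - m;          // templates of length m + 1
  std::vector<int> c2(nt2, 1), c3(nt3, 1);  // self-matches
  for (int i = 0; i < nt2; ++i) {
    for (int j = i + 1; j < nt2; ++j) {
      double d = 0.0;
      for (int t = 0; t < m; ++t) {
        double a = std::fabs(p[i + t] - p[j + t]);
        if (a > d) d = a;
      }
      if (d <= r) { ++c2[i]; ++c2[j]; }
      if (i < nt3 && j < nt3) {
        double a = std::fabs(p[i + m] - p[j + m]);
        if (a > d) d = a;
        if (d <= r) { ++c3[i]; ++c3[j]; }
      }
    }
  }
  double phi2 = 0.0, phi3 = 0.0;
  for (int i = 0; i < nt2; ++i) phi2 += std::log((double)c2[i] / nt2);
  for (int i = 0; i < nt3; ++i) phi3 += std::log((double)c3[i] / nt3);
  return phi2 / nt2 - phi3 / nt3;
}

// Fuzzy entropy (Chen): templates baseline-removed, membership
// exp(-(d/r)^nexp), self-matches excluded; both template lengths use the
// first n - m starting points so the counts match.  nexp == 2 takes a
// pow-free path; terms with exponent argument above 60 (membership below
// ~9e-27, invisible at double precision next to any real sum) are skipped.
// [[Rcpp::export]]
double fuzzyen_cpp(NumericVector x, int m, double r, double nexp) {
  int n = x.size();
  if (n <= m + 1) stop("fuzzy entropy needs length(x) > m + 1");
  if (r <= 0) stop("tolerance r must be positive");
  if (nexp <= 0) stop("fuzzy exponent must be positive");
  const double* p = REAL(x);
  int nt = n - m;  // number of templates for both m and m + 1
  const bool sq = (nexp == 2.0);
  const double inv_r = 1.0 / r, inv_r2 = inv_r * inv_r;
  double phi[2];
  for (int s = 0; s < 2; ++s) {
    int mm = m + s;
    std::vector<double> tmpl((size_t)nt * mm);
    for (int i = 0; i < nt; ++i) {
      double mu = 0.0;
      for (int t = 0; t < mm; ++t) mu += p[i + t];
      mu /= mm;
      for (int t = 0; t < mm; ++t) tmpl[(size_t)i * mm + t] = p[i + t] - mu;
    }
    std::vector<double> rowsum(nt, 0.0);
    for (int i = 0; i < nt; ++i) {
      const double* ti = &tmpl[(size_t)i * mm];
      for (int j = i + 1; j < nt; ++j) {
        const double* tj = &tmpl[(size_t)j * mm];
        double d = 0.0;
        for (int t = 0; t < mm; ++t) {
          double a = std::fabs(ti[t] - tj[t]);
          if (a > d) d = a;
        }
        double w;
        if (sq) {
          double tt = d * d * inv_r2;
          if (tt > 60.0) continue;
          w = std::exp(-tt);
        } else {
          double tt = std::pow(d * inv_r, nexp);
          if (tt > 60.0) continue;
          w = std::exp(-tt);
        }
        rowsum[i] += w;
        rowsum[j] += w;
      }
    }
    double acc = 0.0;
    for (int i = 0; i < nt; ++i) acc += rowsum[i] / (double)(nt - 1);
    phi[s] = acc / (double)nt;
  }
  return std::log(phi[0]) - std::log(phi[1]);
}

// Information potential: mean pairwise Gaussian kernel
// B_sigma(u) = exp(-u^2 / (2 sigma^2)) / (sqrt(2 pi) sigma).
// [[Rcpp::export]]
double renyi_ip_cpp(NumericVector x, double sigma) {
  int n = x.size();
  if (n < 1) stop("empty input");
  if (sigma <= 0) stop("kernel width sigma must be positive");
  const double* p = REAL(x);
  const double norm = 1.0 / (std::sqrt(2.0 * M_PI) * sigma);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  // diagonal contributes n * B(0); off-diagonal pairs are symmetric
  double acc = (double)n;
  for (int j = 0; j < n; ++j) {
    for (int k = j + 1; k < n; ++k) {
      double u = p[k] - p[j];
      double t = u * u * inv2s2;
      if (t > 60.0) continue;
      acc += 2.0 * std::exp(-t);
    }
  }
  return norm * acc / ((double)n * (double)n);
}

// Higuchi fractal dimension, scales k = 1..kmax, least-squares slope of
// log(L(k)) on log(1/k).
// [[Rcpp::export]]
double higuchi_fd_cpp(NumericVector x, int kmax) {
  int n = x.size();
  if (kmax < 2) stop("kmax must be >= 2");
  if (n < kmax + 1) stop("series too short for requested kmax");
  const double* p = REAL(x);
  std::vector<double> lx, ly;
  lx.reserve(kmax);
  ly.reserve(kmax);
  for (int k = 1; k <= kmax; ++k) {
    double Lk = 0.0;
    int used = 0;
    for (int m = 0; m < k; ++m) {
      int nm = (n - 1 - m) / k;  // number of increments in this sub-series
      if (nm < 1) continue;
      double s = 0.0;
      for (int i = 1; i <= nm; ++i)
        s += std::fabs(p[m + i * k] - p[m + (i - 1) * k]);
      Lk += s * ((double)(n - 1) / ((double)nm * k)) / (double)k;
      ++used;
    }
    if (used == 0) continue;
    Lk /= (double)used;
    if (Lk <= 0) continue;  // flat sub-series: no curve length at this scale
    lx.push_back(std::log(1.0 / (double)k));
    ly.push_back(std::log(Lk));
  }
  size_t np = lx.size();
  if (np < 2) return 1.0;  // constant/degenerate signal: dimension of a line
  double mx = 0, my = 0;
  for (size_t i = 0; i < np; ++i) { mx += lx[i]; my += ly[i]; }
  mx /= np; my /= np;
  double sxy = 0, sxx = 0;
  for (size_t i = 0; i < np; ++i) {
    sxy += (lx[i] - mx) * (ly[i] - my);
    sxx += (lx[i] - mx) * (lx[i] - mx);
  }
  return sxy / sxx;
}
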