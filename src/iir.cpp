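#include <Rcpp.h>

using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi
// (length max(len(a), len(b)) - 1); a[0] must be 1.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nb = b.size(), na = a.size(), n = x.size();
  int nf = std::max(nb, na);
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < (int)z.size() && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double yi = bb[0] * x[i] + z[0];
    for (int k = 0; k < nf - 2; ++k)
      z[k] = bb[k + 1] * x[i] + z[k + 1] - aa[k + 1] * yi;
    z[nf - 2] = bb[nf - 1] * x[i] - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
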