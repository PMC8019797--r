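#include <Rcpp.h>
using namespace Rcpp;

// Mirror an out-of-range index back into [0, n): reflection about the border
// with the edge pixel repeated ( ... 1 0 | 0 1 ... n-1 | n-1 n-2 ... ).
static inline int reflect_index(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Pixelwise adaptive Wiener filter. Local first/second moments are accumulated
// in long double, column-major within the window, matching R's sum() over a
// column-major window extract so results are bit-identical to a per-pixel
// reference loop written in R.
// [[Rcpp::export]]
List wiener_filter_cpp(NumericMatrix img, int P, int Q, double eps) {
  const int M = img.nrow(), N = img.ncol();
  const int hp = P / 2, hq = Q / 2;
  const double npq = (double)P * (double)Q;
  NumericMatrix mu(M, N), sig2(M, N);

  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      long double s = 0.0L, s2 = 0.0L;
      for (int dq = -hq; dq <= hq; ++dq) {
        const int jj = reflect_index(j + dq, N);
        for (int dp = -hp; dp <= hp; ++dp) {
          const int ii = reflect_index(i + dp, M);
          const double v = img(ii, jj);
          s += (long double)v;
          const double vv = v * v;
          s2 += (long double)vv;
        }
      }
      const double sd = (double)s;   // round like R's sum() before dividing
      const double s2d = (double)s2;
      const double m = sd / npq;
      const double msq = m * m;
      const double q2 = s2d / npq;
      mu(i, j) = m;
      sig2(i, j) = q2 - msq;
    }
  }

  // Global noise variance: mean of the local variances (sum/n like R).
  long double acc = 0.0L;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < M; ++i)
      acc += (long double)sig2(i, j);
  const double nu2 = ((double)acc) / ((double)M * (double)N);

  NumericMatrix out(M, N);
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      const double s2v = sig2(i, j);
      double num = s2v - nu2;
      if (num < 0.0) num = 0.0;            // clamp: gain in [0, 1]
      const double den = (s2v > eps) ? s2v : eps;
      const double gain = num / den;
      out(i, j) = mu(i, j) + gain * (img(i, j) - mu(i, j));
    }
  }

  return List::create(_["filtered"] = out, _["mu"] = mu,
                      _["sigma2"] = sig2, _["nu2"] = nu2);
}
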