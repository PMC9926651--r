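#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Eight Haralick-style metrics from a symmetric, normalized co-occurrence
// tabulation held as sparse (code -> count) pairs.  Order is fixed:
// mean, variance, correlation, contrast, homogeneity, dissimilarity,
// asm, entropy.  correlation is defined as 0 when variance is 0.
static inline void metrics_from_counts(const std::vector<double> &cnt,
                                       const std::vector<int> &touched,
                                       int levels, double total,
                                       double out[8]) {
  double mean = 0, sumii = 0, cov = 0, contrast = 0, hom = 0, dis = 0,
         asm_ = 0, ent = 0;
  for (size_t t = 0; t < touched.size(); ++t) {
    int code = touched[t];
    double p = cnt[code] / total;
    int i = code / levels, j = code % levels;
    double d = (double)(i - j), d2 = d * d;
    mean += i * p;          // row marginal via full sum
    sumii += (double)i * i * p;
    cov += (double)i * j * p;
    contrast += d2 * p;
    hom += p / (1.0 + d2);
    dis += std::fabs(d) * p;
    asm_ += p * p;
    ent -= p * std::log(p); // p > 0 for touched codes
  }
  double var = sumii - mean * mean;
  if (var < 0) var = 0; // guard fp round-off
  double corr = (var > 0) ? (cov - mean * mean) / var : 0.0;
  out[0] = mean; out[1] = var; out[2] = corr; out[3] = contrast;
  out[4] = hom; out[5] = dis; out[6] = asm_; out[7] = ent;
}

// Moving-window GLCM texture metrics.
//   q:       quantized image, codes 0..levels-1, NA_INTEGER = nodata
//   window:  odd window edge in pixels; a border of one full window
//            width is trimmed to nodata
//   offsets: k x 2 integer matrix of (drow, dcol) unit displacements
// Per pixel and offset the co-occurrence tabulation is symmetric
// (pairs counted in both orders) and normalized; the 8 metrics are
// computed per offset and then averaged across the offsets that had at
// least one valid pair.  Returns an nr x nc x 8 array.
// [[Rcpp::export]]
NumericVector glcm_texture_cpp(IntegerMatrix q, int window, int levels,
                               IntegerMatrix offsets) {
  const int nr = q.nrow(), nc = q.ncol();
  const int half = window / 2;
  const int nmet = 8, noff = offsets.nrow();
  NumericVector out(Dimension(nr, nc, nmet));
  std::fill(out.begin(), out.end(), NA_REAL);

  std::vector<double> cnt((size_t)levels * levels, 0.0);
  std::vector<int> touched;
  touched.reserve((size_t)levels * levels);
  double met[8], acc[8];

  for (int c = window; c < nc - window; ++c) {
    for (int r = window; r < nr - window; ++r) {
      int nvalid_off = 0;
      for (int m = 0; m < nmet; ++m) acc[m] = 0.0;
      for (int o = 0; o < noff; ++o) {
        const int dr = offsets(o, 0), dc = offsets(o, 1);
        // clear only touched entries from the previous offset
        for (size_t t = 0; t < touched.size(); ++t) cnt[touched[t]] = 0.0;
        touched.clear();
        double total = 0.0;
        const int r0 = r - half, r1 = r + half;
        const int c0 = c - half, c1 = c + half;
        for (int cc = c0; cc <= c1; ++cc) {
          const int cc2 = cc + dc;
          if (cc2 < c0 || cc2 > c1) continue;
          for (int rr = r0; rr <= r1; ++rr) {
            const int rr2 = rr + dr;
            if (rr2 < r0 || rr2 > r1) continue;
            const int a = q(rr, cc), b = q(rr2, cc2);
            if (a == NA_INTEGER || b == NA_INTEGER) continue;
            const int code1 = a * levels + b, code2 = b * levels + a;
            if (cnt[code1] == 0.0) touched.push_back(code1);
            cnt[code1] += 1.0;
            if (code2 != code1) {
              if (cnt[code2] == 0.0) touched.push_back(code2);
              cnt[code2] += 1.0;
            } else {
              cnt[code1] += 1.0;
            }
            total += 2.0;
          }
        }
        if (total <= 0.0) continue;
        metrics_from_counts(cnt, touched, levels, total, met);
        for (int m = 0; m < nmet; ++m) acc[m] += met[m];
        ++nvalid_off;
      }
      if (nvalid_off > 0) {
        const size_t base = (size_t)r + (size_t)c * nr;
        for (int m = 0; m < nmet; ++m)
          out[base + (size_t)m * nr * nc] = acc[m] / nvalid_off;
      }
    }
  }
  return out;
}
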