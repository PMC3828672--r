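#include <Rcpp.h>
using namespace Rcpp;

// Single-level analysis step of the orthogonal DWT with half-point
// symmetric boundary extension. Output length floor((n + L - 1) / 2).
// out[i] = sum_k f[k] * ext[2i + 1 - k], with ext[j] = x[-j-1] for j < 0
// and ext[j] = x[2n-1-j] for j >= n.
// [[Rcpp::export(name = ".dwt_step")]]
List dwt_step(NumericVector x, NumericVector dec_lo, NumericVector dec_hi) {
  const int n = x.size();
  const int L = dec_lo.size();
  if (n < L - 1)
    stop("signal segment shorter than filter support (%d < %d)", n, L - 1);
  const int lc = (n + L - 1) / 2;
  NumericVector cA(lc), cD(lc);
  const double *px = x.begin(), *flo = dec_lo.begin(), *fhi = dec_hi.begin();

  // interior: all taps in range, i.e. 2i+1-(L-1) >= 0 and 2i+1 <= n-1
  const int i_lo = (L - 1) / 2;        // smallest i with 2i+1 >= L-1
  const int i_hi = (n - 2) / 2;        // largest i with 2i+1 <= n-1
  for (int i = i_lo; i <= i_hi; ++i) {
    const double *xe = px + (2 * i + 1);
    double sa = 0.0, sd = 0.0;
    for (int k = 0; k < L; ++k) {
      const double v = xe[-k];
      sa += flo[k] * v;
      sd += fhi[k] * v;
    }
    cA[i] = sa;
    cD[i] = sd;
  }
  // boundaries: reflect indices
  for (int i = 0; i < lc; ++i) {
    if (i >= i_lo && i <= i_hi) continue;
    double sa = 0.0, sd = 0.0;
    for (int k = 0; k < L; ++k) {
      int j = 2 * i + 1 - k;
      const int idx = j < 0 ? (-j - 1) : (j >= n ? (2 * n - 1 - j) : j);
      sa += flo[k] * px[idx];
      sd += fhi[k] * px[idx];
    }
    cA[i] = sa;
    cD[i] = sd;
  }
  return List::create(_["cA"] = cA, _["cD"] = cD);
}

// Single-level synthesis step: zero-upsample both coefficient bands,
// convolve with the reconstruction filters, drop the L-2 leading
// transient samples and return n_out samples (the length of the
// segment that was decomposed). Scatter form: coefficient t adds
// f[k] * c[t] to y[2t + k - (L-2)].
// [[Rcpp::export(name = ".idwt_step")]]
NumericVector idwt_step(NumericVector cA, NumericVector cD,
                        NumericVector rec_lo, NumericVector rec_hi,
                        int n_out) {
  const int lc = cA.size();
  const int L = rec_lo.size();
  if (cD.size() != lc) stop("coefficient bands differ in length");
  const int full_out = 2 * lc - L + 2;
  if (n_out > full_out || n_out < full_out - 1)
    stop("inconsistent reconstruction length");
  NumericVector y(n_out);
  double *py = y.begin();
  const double *pa = cA.begin(), *pd = cD.begin();
  const double *flo = rec_lo.begin(), *fhi = rec_hi.begin();
  const int off = L - 2;
  for (int t = 0; t < lc; ++t) {
    const double a = pa[t], d = pd[t];
    const int base = 2 * t - off;
    if (base >= 0 && base + L - 1 < n_out) {
      double *ye = py + base;
      for (int k = 0; k < L; ++k) ye[k] += flo[k] * a + fhi[k] * d;
    } else {
      for (int k = 0; k < L; ++k) {
        const int j = base + k;
        if (j >= 0 && j < n_out) py[j] += flo[k] * a + fhi[k] * d;
      }
    }
  }
  return y;
}

// Threshold-crossing spike scan. `v` is the polarity-transformed signal
// (e.g. absolute value); `thr` holds one threshold per consecutive window
// of `win` samples (the last window may be partial). A crossing is a
// below-to-above transition; the event index is the argmax of v within
// `search` samples of the crossing; events closer than `refr` samples to
// the previously kept event are discarded (earlier event wins).
// Returns 0-based event sample indices.
// [[Rcpp::export(name = ".detect_scan")]]
IntegerVector detect_scan(NumericVector v, NumericVector thr, int win,
                          int search, int refr) {
  const int n = v.size();
  const int nw = thr.size();
  std::vector<int> out;
  long last = -1 - (long)refr;
  bool above_prev = false;
  for (int i = 0; i < n; ++i) {
    int w = i / win;
    if (w >= nw) w = nw - 1;
    const bool above = v[i] > thr[w];
    if (above && !above_prev) {
      int p = i;
      double best = v[i];
      const int end = std::min(n, i + search);
      for (int j = i + 1; j < end; ++j)
        if (v[j] > best) { best = v[j]; p = j; }
      if ((long)p - last >= (long)refr) {
        out.push_back(p);
        last = p;
      }
    }
    above_prev = above;
  }
  return IntegerVector(out.begin(), out.end());
}

// Per-window adaptive thresholds: 4 * median(|x|) / 0.6745 over
// consecutive windows of `win` samples (trailing partial window uses
// its own samples). Median follows the usual convention: mean of the
// two middle order statistics for even counts.
// [[Rcpp::export(name = ".window_mad_thresholds")]]
NumericVector window_mad_thresholds(NumericVector x, int win) {
  const int n = x.size();
  const int nw = (n + win - 1) / win;
  NumericVector thr(nw);
  std::vector<double> buf;
  for (int w = 0; w < nw; ++w) {
    const int i0 = w * win;
    const int i1 = std::min(n, i0 + win);
    const int m = i1 - i0;
    buf.resize(m);
    for (int i = 0; i < m; ++i) buf[i] = std::fabs(x[i0 + i]);
    const int h = m / 2;
    std::nth_element(buf.begin(), buf.begin() + h, buf.end());
    double med = buf[h];
    if (m % 2 == 0) {
      const double lo = *std::max_element(buf.begin(), buf.begin() + h);
      med = (med + lo) / 2.0;
    }
    thr[w] = 4.0 * med / 0.6745;
  }
  return thr;
}
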