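#include <Rcpp.h>
using namespace Rcpp;

// 3x3 median filter with edge replication. Output extent equals input extent.
// [[Rcpp::export]]
IntegerMatrix median_filter3_cpp(const IntegerMatrix& img) {
  const int M = img.nrow(), N = img.ncol();
  IntegerMatrix out(M, N);
  int window[9];
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < M; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = j + dj;
        if (jj < 0) jj = 0; else if (jj >= N) jj = N - 1;
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di;
          if (ii < 0) ii = 0; else if (ii >= M) ii = M - 1;
          window[k++] = img(ii, jj);
        }
      }
      std::nth_element(window, window + 4, window + 9);
      out(i, j) = window[4];
    }
  }
  return out;
}

// Recursive quadtree split of a P x P (power-of-two) square: a block splits
// into four quadrants iff max - min of its pixels exceeds `thresh`.
// Emits final blocks as 0-based (top, left, size) rows.
static void qt_recurse(const IntegerMatrix& img, int top, int left, int size,
                       double thresh, std::vector<int>& acc) {
  if (size > 1) {
    int lo = img(top, left), hi = lo;
    for (int j = left; j < left + size; ++j)
      for (int i = top; i < top + size; ++i) {
        int v = img(i, j);
        if (v < lo) lo = v;
        if (v > hi) hi = v;
      }
    if (hi - lo > thresh) {
      int h = size / 2;
      qt_recurse(img, top,     left,     h, thresh, acc);
      qt_recurse(img, top,     left + h, h, thresh, acc);
      qt_recurse(img, top + h, left,     h, thresh, acc);
      qt_recurse(img, top + h, left + h, h, thresh, acc);
      return;
    }
  }
  acc.push_back(top);
  acc.push_back(left);
  acc.push_back(size);
}

// [[Rcpp::export]]
IntegerMatrix quadtree_blocks_cpp(const IntegerMatrix& img, double thresh) {
  if (img.nrow() != img.ncol())
    stop("quadtree requires a square image");
  std::vector<int> acc;
  qt_recurse(img, 0, 0, img.nrow(), thresh, acc);
  const int n = (int)acc.size() / 3;
  IntegerMatrix out(n, 3);
  for (int r = 0; r < n; ++r) {
    out(r, 0) = acc[3 * r];
    out(r, 1) = acc[3 * r + 1];
    out(r, 2) = acc[3 * r + 2];
  }
  return out;
}

// Bilinear sampling of `host` at (rows[k], cols[k]) in 0-based pixel-centre
// coordinates; values rounded half-up. Coordinates must lie inside
// [0, M-1] x [0, N-1] (caller checks; out-of-range here is an error).
// [[Rcpp::export]]
IntegerVector bilinear_sample_cpp(const IntegerMatrix& host,
                                  const NumericVector& rows,
                                  const NumericVector& cols) {
  const int M = host.nrow(), N = host.ncol(), n = rows.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    double r = rows[k], c = cols[k];
    if (r < 0 || c < 0 || r > M - 1 || c > N - 1)
      stop("bilinear sample point outside host image");
    int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
    if (r0 == M - 1) r0--;
    if (c0 == N - 1) c0--;
    double fr = r - r0, fc = c - c0;
    double v = (1 - fr) * (1 - fc) * host(r0, c0)
             + (1 - fr) * fc       * host(r0, c0 + 1)
             + fr       * (1 - fc) * host(r0 + 1, c0)
             + fr       * fc       * host(r0 + 1, c0 + 1);
    out[k] = (int)std::floor(v + 0.5);
  }
  return out;
}
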