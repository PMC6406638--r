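// Plug-in transfer entropy core.
//
// Symbol sequences are integer vectors in [0, B-1]. All probabilities are
// plug-in frequencies over the N-1 embedded triples (x[n+1], x[n], y[n]).
// Entropies are computed in bits through an integer log2 lookup table, so a
// full 14x14 surrogate-corrected matrix stays cheap even when called once
// per 20-s sliding window.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// Sum of c*log2(c) over a count array; lg[c] caches log2(c).
inline double clog_sum(const std::vector<int>& counts, const std::vector<double>& lg) {
  double s = 0.0;
  for (size_t k = 0; k < counts.size(); ++k) {
    int c = counts[k];
    if (c > 0) s += c * lg[c];
  }
  return s;
}

std::vector<double> log2_table(int n) {
  std::vector<double> lg(n + 1, 0.0);
  for (int c = 2; c <= n; ++c) lg[c] = std::log2((double)c);
  return lg;
}

} // namespace

// Transfer entropy TE_{y->x} in bits: I(x_{n+1}; y_n | x_n), plug-in.
// [[Rcpp::export]]
double cpp_te(IntegerVector x, IntegerVector y, int B) {
  int N = x.size();
  if (y.size() != N) stop("dimension error: sequences differ in length");
  int M = N - 1;
  if (M < 1) stop("sequences must have length >= 2");
  std::vector<int> c3(B * B * B, 0), c_x1x0(B * B, 0), c_x0y(B * B, 0), c_x0(B, 0);
  for (int n = 0; n < M; ++n) {
    int x1 = x[n + 1], x0 = x[n], y0 = y[n];
    ++c3[(x1 * B + x0) * B + y0];
    ++c_x1x0[x1 * B + x0];
    ++c_x0y[x0 * B + y0];
    ++c_x0[x0];
  }
  std::vector<double> lg = log2_table(M);
  // TE = H(x1,x0) + H(x0,y) - H(x0) - H(x1,x0,y); H = log2(M) - S/M
  double S3 = clog_sum(c3, lg), Sa = clog_sum(c_x1x0, lg),
         Sb = clog_sum(c_x0y, lg), Sx = clog_sum(c_x0, lg);
  double te = (S3 + Sx - Sa - Sb) / M;
  return te > 0 ? te : 0.0;
}

// H(x_{n+1} | x_n) in bits, plug-in pair counts.
// [[Rcpp::export]]
double cpp_cond_entropy(IntegerVector x, int B) {
  int N = x.size();
  int M = N - 1;
  if (M < 1) stop("sequence must have length >= 2");
  std::vector<int> cp(B * B, 0), c0(B, 0);
  for (int n = 0; n < M; ++n) {
    ++cp[x[n + 1] * B + x[n]];
    ++c0[x[n]];
  }
  std::vector<double> lg = log2_table(M);
  double h = (clog_sum(c0, lg) - clog_sum(cp, lg)) / M;
  return h > 0 ? h : 0.0;
}

// Surrogate-corrected NTE for one ordered pair. perms: 0-based index matrix
// (N rows, one column per surrogate); surrogate source s at time n is
// y[perms(n, s)].
// [[Rcpp::export]]
List cpp_nte_pair(IntegerVector x, IntegerVector y, int B, IntegerMatrix perms) {
  double te = cpp_te(x, y, B);
  double h = cpp_cond_entropy(x, B);
  int n_sh = perms.ncol();
  double acc = 0.0;
  IntegerVector ys(y.size());
  for (int s = 0; s < n_sh; ++s) {
    for (int n = 0; n < y.size(); ++n) ys[n] = y[perms(n, s)];
    acc += cpp_te(x, ys, B);
  }
  double bias = n_sh > 0 ? acc / n_sh : 0.0;
  double nte = h > 0 ? (te - bias) / h : 0.0;
  if (nte < 0) nte = 0.0;
  return List::create(_["te"] = te, _["te_shuffle_mean"] = bias,
                      _["h_cond"] = h, _["nte"] = nte);
}

// Full directed NTE matrix for one epoch. sym: channels x samples symbol
// matrix; perms as above, shared across pairs. Returns value[target, source].
// [[Rcpp::export]]
NumericMatrix cpp_nte_epoch(IntegerMatrix sym, int B, IntegerMatrix perms) {
  int C = sym.nrow(), N = sym.ncol(), M = N - 1;
  if (M < 1) stop("epoch must have length >= 2");
  int n_sh = perms.ncol();
  std::vector<double> lg = log2_table(M);

  // per-channel marginal terms
  std::vector<double> Sx0(C), Sx1x0(C), Hcond(C);
  std::vector<std::vector<int>> xs(C);
  for (int i = 0; i < C; ++i) {
    xs[i].resize(N);
    for (int n = 0; n < N; ++n) xs[i][n] = sym(i, n);
    std::vector<int> cp(B * B, 0), c0(B, 0);
    for (int n = 0; n < M; ++n) {
      ++cp[xs[i][n + 1] * B + xs[i][n]];
      ++c0[xs[i][n]];
    }
    Sx0[i] = clog_sum(c0, lg);
    Sx1x0[i] = clog_sum(cp, lg);
    double h = (Sx0[i] - Sx1x0[i]) / M;
    Hcond[i] = h > 0 ? h : 0.0;
  }

  // surrogate versions of every source channel (shared permutations), plus
  // the unshuffled source as variant 0
  int n_var = n_sh + 1;
  std::vector<std::vector<short>> ysur(C);
  for (int j = 0; j < C; ++j) {
    ysur[j].resize((size_t)n_var * M);
    for (int n = 0; n < M; ++n) ysur[j][n] = (short)xs[j][n];
  }
  for (int s = 0; s < n_sh; ++s)
    for (int n = 0; n < M; ++n) {
      int idx = perms(n, s);
      for (int j = 0; j < C; ++j) ysur[j][(size_t)(s + 1) * M + n] = (short)xs[j][idx];
    }

  // per-target combined key (x[n+1]*B + x[n])*B, so the inner count is a
  // single indexed increment; the (x_n, y_n) histogram is recovered as the
  // x_{n+1} marginal of the triple histogram instead of being counted
  std::vector<std::vector<short>> keyT(C);
  for (int i = 0; i < C; ++i) {
    keyT[i].resize(M);
    for (int n = 0; n < M; ++n)
      keyT[i][n] = (short)((xs[i][n + 1] * B + xs[i][n]) * B);
  }

  int B2 = B * B, B3 = B * B * B;
  NumericMatrix out(C, C);
  std::vector<int> c3(B3);
  for (int i = 0; i < C; ++i) {       // target
    if (Hcond[i] <= 0) { for (int j = 0; j < C; ++j) out(i, j) = 0.0; continue; }
    const short* key = keyT[i].data();
    for (int j = 0; j < C; ++j) {     // source
      if (i == j) continue;
      double te0 = 0.0, acc = 0.0;
      for (int v = 0; v < n_var; ++v) {
        const short* yp = ysur[j].data() + (size_t)v * M;
        std::fill(c3.begin(), c3.end(), 0);
        int n = 0;
        for (; n + 3 < M; n += 4) {   // unrolled; distinct cells collide rarely
          ++c3[key[n] + yp[n]];
          ++c3[key[n + 1] + yp[n + 1]];
          ++c3[key[n + 2] + yp[n + 2]];
          ++c3[key[n + 3] + yp[n + 3]];
        }
        for (; n < M; ++n) ++c3[key[n] + yp[n]];
        double S3 = 0.0, Scxy = 0.0;
        for (int k = 0; k < B2; ++k) { // branchless: lg[0] = 0
          int m = 0;
          for (int x1 = 0; x1 < B; ++x1) {
            int c = c3[x1 * B2 + k];
            S3 += c * lg[c];
            m += c;
          }
          Scxy += m * lg[m];
        }
        double te = (S3 + Sx0[i] - Sx1x0[i] - Scxy) / M;
        if (te < 0) te = 0.0;
        if (v == 0) te0 = te; else acc += te;
      }
      double bias = n_sh > 0 ? acc / n_sh : 0.0;
      double nte = (te0 - bias) / Hcond[i];
      out(i, j) = nte > 0 ? nte : 0.0;
    }
  }
  return out;
}

// Equiprobable (quantile-edge) binning with ties broken toward the lower
// bin: symbols = floor((rank_min - 1) * B / N).
// [[Rcpp::export]]
IntegerVector cpp_quantize(NumericVector v, int B) {
  int N = v.size();
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  std::stable_sort(idx.begin(), idx.end(),
                   [&](int a, int b) { return v[a] < v[b]; });
  IntegerVector out(N);
  int run_start = 0;
  for (int r = 0; r < N; ++r) {
    if (r > 0 && v[idx[r]] != v[idx[r - 1]]) run_start = r;
    out[idx[r]] = (int)(((long long)run_start * B) / N);
  }
  return out;
}
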