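#include <Rcpp.h>
using namespace Rcpp;

// Convolution + average-pooling block over stacked pair instances.
//
// A holds T instances of length `len` with C channels as a (T * len) x C
// column-major matrix (rows instance-major, position-fastest). The kernel
// spans two positions (valid padding, stride 1) over all C channels:
// weights W are (2C) x F (first C rows = kernel offset 0, next C = offset 1).
// ReLU is applied to the convolution output, then non-overlapping average
// pooling with window `pool_w` (remainder positions dropped). Positions
// beyond pool_w * floor((len-1)/pool_w) never reach the output and are not
// computed. Returns (T * l_pool) x F.
// [[Rcpp::export]]
NumericMatrix conv_pool_fwd(NumericMatrix A, NumericMatrix W, NumericVector b,
                            int t_inst, int pool_w) {
  const int n_rows = A.nrow();
  const int C = A.ncol();
  const int len = n_rows / t_inst;
  const int l_conv = len - 1;
  const int l_pool = l_conv / pool_w;
  const int F = W.ncol();
  const double *pa = A.begin();
  const double *pw = W.begin();
  const double *pb = b.begin();
  NumericMatrix out(t_inst * l_pool, F);
  double *po = out.begin();
  const int out_rows = t_inst * l_pool;

  std::vector<double> x(2 * C);
  std::vector<double> acc(F);
  for (int t = 0; t < t_inst; ++t) {
    const int base = t * len;
    for (int w = 0; w < l_pool; ++w) {
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int q = 0; q < pool_w; ++q) {
        const int p = base + w * pool_w + q;
        for (int c = 0; c < C; ++c) {
          x[c] = pa[(size_t)c * n_rows + p];
          x[C + c] = pa[(size_t)c * n_rows + p + 1];
        }
        for (int f = 0; f < F; ++f) {
          const double *wf = pw + (size_t)f * 2 * C;
          double s = pb[f];
          for (int c = 0; c < 2 * C; ++c) s += x[c] * wf[c];
          if (s > 0) acc[f] += s;
        }
      }
      const int orow = t * l_pool + w;
      for (int f = 0; f < F; ++f) {
        po[(size_t)f * out_rows + orow] = acc[f] / pool_w;
      }
    }
  }
  return out;
}

// Backward pass of conv_pool_fwd. Recomputes the pre-activations from A (the
// block input kept from the forward pass) instead of caching them, applies
// the ReLU mask, and accumulates the weight/bias gradients and the gradient
// with respect to A. dP is the gradient at the pooled output.
// [[Rcpp::export]]
List conv_pool_bwd(NumericMatrix A, NumericMatrix W, NumericVector b,
                   NumericMatrix dP, int t_inst, int pool_w,
                   bool need_da) {
  const int n_rows = A.nrow();
  const int C = A.ncol();
  const int len = n_rows / t_inst;
  const int l_conv = len - 1;
  const int l_pool = l_conv / pool_w;
  const int F = W.ncol();
  const double *pa = A.begin();
  const double *pw = W.begin();
  const double *pb = b.begin();
  const double *pdp = dP.begin();
  const int dp_rows = dP.nrow();

  NumericMatrix gW(2 * C, F);
  NumericVector gb(F);
  double *pgw = gW.begin();
  double *pgb = gb.begin();
  NumericMatrix dA(need_da ? n_rows : 1, need_da ? C : 1);
  double *pda = dA.begin();

  std::vector<double> x(2 * C);
  std::vector<double> dpre(F);
  for (int t = 0; t < t_inst; ++t) {
    const int base = t * len;
    for (int w = 0; w < l_pool; ++w) {
      const int orow = t * l_pool + w;
      for (int q = 0; q < pool_w; ++q) {
        const int p = base + w * pool_w + q;
        for (int c = 0; c < C; ++c) {
          x[c] = pa[(size_t)c * n_rows + p];
          x[C + c] = pa[(size_t)c * n_rows + p + 1];
        }
        for (int f = 0; f < F; ++f) {
          const double *wf = pw + (size_t)f * 2 * C;
          double s = pb[f];
          for (int c = 0; c < 2 * C; ++c) s += x[c] * wf[c];
          dpre[f] = (s > 0) ? pdp[(size_t)f * dp_rows + orow] / pool_w : 0.0;
        }
        for (int f = 0; f < F; ++f) {
          const double d = dpre[f];
          if (d == 0.0) continue;
          pgb[f] += d;
          double *gwf = pgw + (size_t)f * 2 * C;
          for (int c = 0; c < 2 * C; ++c) gwf[c] += x[c] * d;
        }
        if (need_da) {
          for (int c = 0; c < C; ++c) {
            double s0 = 0.0, s1 = 0.0;
            for (int f = 0; f < F; ++f) {
              const double d = dpre[f];
              if (d == 0.0) continue;
              s0 += pw[(size_t)f * 2 * C + c] * d;
              s1 += pw[(size_t)f * 2 * C + C + c] * d;
            }
            pda[(size_t)c * n_rows + p] += s0;
            pda[(size_t)c * n_rows + p + 1] += s1;
          }
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb, _["dA"] = dA);
}
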