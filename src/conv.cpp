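#include <Rcpp.h>
using namespace Rcpp;

// Multi-kernel 1D convolution over one-hot encoded protein sequences with
// global max pooling. Sequences are passed as integer residue-index vectors
// (1-based into the alphabet); positions beyond a sequence's length are
// zero padding and contribute nothing beyond the filter bias. Because the
// input is one-hot, the convolution at position t for filter f reduces to
//   b[f] + sum_j W[f, a[t+j], j]
// which is evaluated directly without materialising the one-hot tensor.

// [[Rcpp::export]]
List cnn_conv_forward(List seqs, List weights, List biases, int max_len) {
  const int n = seqs.size();
  const int n_kernels = weights.size();
  std::vector<NumericVector> W(n_kernels);
  std::vector<NumericVector> B(n_kernels);
  std::vector<int> F(n_kernels), A(n_kernels), K(n_kernels);
  int total_f = 0;
  for (int m = 0; m < n_kernels; ++m) {
    W[m] = as<NumericVector>(weights[m]);
    B[m] = as<NumericVector>(biases[m]);
    IntegerVector d = W[m].attr("dim");
    F[m] = d[0]; A[m] = d[1]; K[m] = d[2];
    total_f += F[m];
  }
  NumericMatrix pooled(n, total_f);
  IntegerMatrix argmax(n, total_f);
  for (int i = 0; i < n; ++i) {
    IntegerVector a = seqs[i];
    const int L = a.size();
    int col0 = 0;
    for (int m = 0; m < n_kernels; ++m) {
      const int f_n = F[m], alpha = A[m], k = K[m];
      const double *w = W[m].begin();
      const int n_pos = max_len - k + 1;
      for (int f = 0; f < f_n; ++f) {
        double best = R_NegInf;
        int best_t = 0;
        for (int t = 0; t < n_pos; ++t) {
          if (t >= L) { // window fully in padding: bias only, same for all t
            if (B[m][f] > best) { best = B[m][f]; best_t = t; }
            break;
          }
          double s = B[m][f];
          const int jmax = std::min(k, L - t);
          for (int j = 0; j < jmax; ++j) {
            const int res = a[t + j] - 1;
            s += w[f + (size_t)f_n * res + (size_t)f_n * alpha * j];
          }
          if (s > best) { best = s; best_t = t; }
        }
        pooled(i, col0 + f) = best;
        argmax(i, col0 + f) = best_t;
      }
      col0 += f_n;
    }
  }
  return List::create(_["pooled"] = pooled, _["argmax"] = argmax);
}

// Gradient of the pooled features with respect to the convolution weights
// and biases: only the argmax window of each (sequence, filter) receives
// gradient. grad is n x total_filters, aligned with cnn_conv_forward.

// [[Rcpp::export]]
List cnn_conv_backward(List seqs, List weights, IntegerMatrix argmax,
                       NumericMatrix grad, int max_len) {
  const int n = seqs.size();
  const int n_kernels = weights.size();
  List dW(n_kernels), dB(n_kernels);
  std::vector<NumericVector> dWv(n_kernels), dBv(n_kernels);
  std::vector<int> F(n_kernels), A(n_kernels), K(n_kernels);
  for (int m = 0; m < n_kernels; ++m) {
    NumericVector w = as<NumericVector>(weights[m]);
    IntegerVector d = w.attr("dim");
    F[m] = d[0]; A[m] = d[1]; K[m] = d[2];
    NumericVector g(w.size());
    g.attr("dim") = d;
    dWv[m] = g;
    dBv[m] = NumericVector(F[m]);
  }
  for (int i = 0; i < n; ++i) {
    IntegerVector a = seqs[i];
    const int L = a.size();
    int col0 = 0;
    for (int m = 0; m < n_kernels; ++m) {
      const int f_n = F[m], alpha = A[m], k = K[m];
      double *dw = dWv[m].begin();
      for (int f = 0; f < f_n; ++f) {
        const double g = grad(i, col0 + f);
        if (g == 0.0) continue;
        dBv[m][f] += g;
        const int t = argmax(i, col0 + f);
        const int jmax = std::min(k, L - t);
        for (int j = 0; j < jmax; ++j) {
          const int res = a[t + j] - 1;
          dw[f + (size_t)f_n * res + (size_t)f_n * alpha * j] += g;
        }
      }
      col0 += f_n;
    }
  }
  for (int m = 0; m < n_kernels; ++m) {
    dW[m] = dWv[m];
    dB[m] = dBv[m];
  }
  return List::create(_["dW"] = dW, _["dB"] = dB);
}
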