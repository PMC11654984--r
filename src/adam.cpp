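#include <Rcpp.h>
using namespace Rcpp;

// In-place Adam update of one parameter tensor. param, m and v are modified
// directly (they are private copies owned by the optimizer/model lists, made
// once per training run), avoiding six full-size temporaries per step in R.
// [[Rcpp::export(rng = false)]]
void adam_update_inplace(NumericVector param, NumericVector m, NumericVector v,
                         NumericVector grad, double lr, double beta1,
                         double beta2, double eps, double corr1,
                         double corr2) {
  const R_xlen_t n = param.size();
  if (m.size() != n || v.size() != n || grad.size() != n)
    stop("adam_update_inplace: length mismatch");
  for (R_xlen_t i = 0; i < n; ++i) {
    const double g = grad[i];
    m[i] = beta1 * m[i] + (1.0 - beta1) * g;
    v[i] = beta2 * v[i] + (1.0 - beta2) * g * g;
    param[i] -= lr * (m[i] / corr1) / (std::sqrt(v[i] / corr2) + eps);
  }
}

// y = x + row-broadcast bias (in place on x, which is a fresh matmul result).
// [[Rcpp::export(rng = false)]]
void add_bias_inplace(NumericMatrix x, NumericVector b) {
  const int nr = x.nrow(), nc = x.ncol();
  if (b.size() != nc) stop("add_bias_inplace: bias length mismatch");
  for (int j = 0; j < nc; ++j) {
    const double bj = b[j];
    double *col = &x(0, j);
    for (int i = 0; i < nr; ++i) col[i] += bj;
  }
}

// ELU forward (alpha = 1), returning a new matrix.
// [[Rcpp::export(rng = false)]]
NumericMatrix elu_forward(NumericMatrix x) {
  NumericMatrix y(x.nrow(), x.ncol());
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i)
    y[i] = x[i] > 0 ? x[i] : std::expm1(x[i]);
  return y;
}

// ELU backward: dy * (x > 0 ? 1 : y + 1), using the stored activation y.
// [[Rcpp::export(rng = false)]]
NumericMatrix elu_backward(NumericMatrix dy, NumericMatrix y) {
  NumericMatrix dx(dy.nrow(), dy.ncol());
  const R_xlen_t n = dy.size();
  if (y.size() != n) stop("elu_backward: shape mismatch");
  for (R_xlen_t i = 0; i < n; ++i)
    dx[i] = y[i] > 0 ? dy[i] : dy[i] * (y[i] + 1.0);
  return dx;
}
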