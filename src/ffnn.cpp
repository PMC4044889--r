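#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// One-hidden-layer feed-forward network, logistic sigmoid everywhere,
// full-batch gradient descent on total sum-of-squared-errors.
// Layout: W1 is h x p (hidden x input), W2 is q x h (output x hidden).

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Net {
  int p, h, q;
  std::vector<double> W1, b1, W2, b2; // row-major: W1[i*p + j]
};

static Net net_from(const NumericMatrix& W1, const NumericVector& b1,
                    const NumericMatrix& W2, const NumericVector& b2) {
  Net net;
  net.h = W1.nrow(); net.p = W1.ncol(); net.q = W2.nrow();
  net.W1.resize((size_t)net.h * net.p);
  net.W2.resize((size_t)net.q * net.h);
  net.b1.assign(b1.begin(), b1.end());
  net.b2.assign(b2.begin(), b2.end());
  for (int i = 0; i < net.h; ++i)
    for (int j = 0; j < net.p; ++j) net.W1[(size_t)i * net.p + j] = W1(i, j);
  for (int k = 0; k < net.q; ++k)
    for (int i = 0; i < net.h; ++i) net.W2[(size_t)k * net.h + i] = W2(k, i);
  return net;
}

static void forward_one(const Net& net, const double* x,
                        double* a1, double* out) {
  for (int i = 0; i < net.h; ++i) {
    double z = net.b1[i];
    const double* w = &net.W1[(size_t)i * net.p];
    for (int j = 0; j < net.p; ++j) z += w[j] * x[j];
    a1[i] = sigm(z);
  }
  for (int k = 0; k < net.q; ++k) {
    double z = net.b2[k];
    const double* w = &net.W2[(size_t)k * net.h];
    for (int i = 0; i < net.h; ++i) z += w[i] * a1[i];
    out[k] = sigm(z);
  }
}

// Accumulate the gradient of total SSE over the batch; returns the SSE of
// the weights the gradient was taken at.
static double batch_gradient(const Net& net,
                             const std::vector<double>& X, // n x p, row-major
                             const std::vector<double>& Y, // n x q, row-major
                             int n, Net& grad) {
  std::fill(grad.W1.begin(), grad.W1.end(), 0.0);
  std::fill(grad.b1.begin(), grad.b1.end(), 0.0);
  std::fill(grad.W2.begin(), grad.W2.end(), 0.0);
  std::fill(grad.b2.begin(), grad.b2.end(), 0.0);
  std::vector<double> a1(net.h), out(net.q), d2(net.q), d1(net.h);
  double sse = 0.0;
  for (int r = 0; r < n; ++r) {
    const double* x = &X[(size_t)r * net.p];
    forward_one(net, x, a1.data(), out.data());
    for (int k = 0; k < net.q; ++k) {
      double e = Y[(size_t)r * net.q + k] - out[k];
      sse += e * e;
      d2[k] = -2.0 * e * out[k] * (1.0 - out[k]);
    }
    for (int k = 0; k < net.q; ++k) {
      grad.b2[k] += d2[k];
      double* gw = &grad.W2[(size_t)k * net.h];
      for (int i = 0; i < net.h; ++i) gw[i] += d2[k] * a1[i];
    }
    for (int i = 0; i < net.h; ++i) {
      double s = 0.0;
      for (int k = 0; k < net.q; ++k) s += net.W2[(size_t)k * net.h + i] * d2[k];
      d1[i] = s * a1[i] * (1.0 - a1[i]);
    }
    for (int i = 0; i < net.h; ++i) {
      grad.b1[i] += d1[i];
      double* gw = &grad.W1[(size_t)i * net.p];
      for (int j = 0; j < net.p; ++j) gw[j] += d1[i] * x[j];
    }
  }
  return sse;
}

static double batch_sse(const Net& net, const std::vector<double>& X,
                        const std::vector<double>& Y, int n) {
  std::vector<double> a1(net.h), out(net.q);
  double sse = 0.0;
  for (int r = 0; r < n; ++r) {
    forward_one(net, &X[(size_t)r * net.p], a1.data(), out.data());
    for (int k = 0; k < net.q; ++k) {
      double e = Y[(size_t)r * net.q + k] - out[k];
      sse += e * e;
    }
  }
  return sse;
}

static std::vector<double> flatten_rows(const NumericMatrix& M) {
  std::vector<double> out((size_t)M.nrow() * M.ncol());
  for (int r = 0; r < M.nrow(); ++r)
    for (int c = 0; c < M.ncol(); ++c) out[(size_t)r * M.ncol() + c] = M(r, c);
  return out;
}

// [[Rcpp::export]]
List ffnn_train_cpp(NumericMatrix X, NumericMatrix Y,
                    NumericMatrix W1, NumericVector b1,
                    NumericMatrix W2, NumericVector b2,
                    double learning_rate, int max_epochs,
                    NumericMatrix Xhold, NumericMatrix Yhold, int eval_every,
                    int patience, double patience_tol) {
  int n = X.nrow();
  Net net = net_from(W1, b1, W2, b2);
  Net grad = net; // same shapes
  std::vector<double> Xf = flatten_rows(X), Yf = flatten_rows(Y);

  int m = Xhold.nrow();
  std::vector<double> Hf = m > 0 ? flatten_rows(Xhold) : std::vector<double>();
  std::vector<double> HYf = m > 0 ? flatten_rows(Yhold) : std::vector<double>();
  std::vector<double> hold_scores; // eval point-major, m per point
  std::vector<double> hold_sse;
  std::vector<int> eval_epochs;

  std::vector<double> sse_log;
  sse_log.reserve(max_epochs);
  double best = R_PosInf;
  int since_best = 0, epochs_run = 0, nan_epoch = 0;

  std::vector<double> a1(net.h), out(net.q);
  for (int e = 1; e <= max_epochs; ++e) {
    batch_gradient(net, Xf, Yf, n, grad);
    for (size_t i = 0; i < net.W1.size(); ++i) net.W1[i] -= learning_rate * grad.W1[i];
    for (size_t i = 0; i < net.b1.size(); ++i) net.b1[i] -= learning_rate * grad.b1[i];
    for (size_t i = 0; i < net.W2.size(); ++i) net.W2[i] -= learning_rate * grad.W2[i];
    for (size_t i = 0; i < net.b2.size(); ++i) net.b2[i] -= learning_rate * grad.b2[i];
    double sse = batch_sse(net, Xf, Yf, n);
    epochs_run = e;
    if (!std::isfinite(sse)) { nan_epoch = e; break; }
    sse_log.push_back(sse);
    if (m > 0 && eval_every > 0 && (e % eval_every == 0 || e == max_epochs)) {
      eval_epochs.push_back(e);
      double hsse = 0.0;
      for (int r = 0; r < m; ++r) {
        forward_one(net, &Hf[(size_t)r * net.p], a1.data(), out.data());
        hold_scores.push_back(out[0] - out[1]); // cancer minus healthy
        for (int k = 0; k < net.q; ++k) {
          double err = HYf[(size_t)r * net.q + k] - out[k];
          hsse += err * err;
        }
      }
      hold_sse.push_back(hsse);
    }
    if (patience > 0) {
      if (sse < best - patience_tol) { best = sse; since_best = 0; }
      else if (++since_best >= patience) break;
    }
  }

  NumericMatrix W1o(net.h, net.p), W2o(net.q, net.h);
  for (int i = 0; i < net.h; ++i)
    for (int j = 0; j < net.p; ++j) W1o(i, j) = net.W1[(size_t)i * net.p + j];
  for (int k = 0; k < net.q; ++k)
    for (int i = 0; i < net.h; ++i) W2o(k, i) = net.W2[(size_t)k * net.h + i];

  int n_eval = eval_epochs.size();
  NumericMatrix H(n_eval, m);
  for (int r = 0; r < n_eval; ++r)
    for (int c = 0; c < m; ++c) H(r, c) = hold_scores[(size_t)r * m + c];

  return List::create(
    _["W1"] = W1o, _["b1"] = NumericVector(net.b1.begin(), net.b1.end()),
    _["W2"] = W2o, _["b2"] = NumericVector(net.b2.begin(), net.b2.end()),
    _["sse_log"] = NumericVector(sse_log.begin(), sse_log.end()),
    _["epochs_run"] = epochs_run,
    _["nan_epoch"] = nan_epoch,
    _["eval_epochs"] = IntegerVector(eval_epochs.begin(), eval_epochs.end()),
    _["hold_scores"] = H,
    _["hold_sse"] = NumericVector(hold_sse.begin(), hold_sse.end()));
}

// [[Rcpp::export]]
List ffnn_grad_cpp(NumericMatrix X, NumericMatrix Y,
                   NumericMatrix W1, NumericVector b1,
                   NumericMatrix W2, NumericVector b2) {
  Net net = net_from(W1, b1, W2, b2);
  Net grad = net;
  std::vector<double> Xf = flatten_rows(X), Yf = flatten_rows(Y);
  double sse = batch_gradient(net, Xf, Yf, X.nrow(), grad);
  NumericMatrix gW1(net.h, net.p), gW2(net.q, net.h);
  for (int i = 0; i < net.h; ++i)
    for (int j = 0; j < net.p; ++j) gW1(i, j) = grad.W1[(size_t)i * net.p + j];
  for (int k = 0; k < net.q; ++k)
    for (int i = 0; i < net.h; ++i) gW2(k, i) = grad.W2[(size_t)k * net.h + i];
  return List::create(
    _["W1"] = gW1, _["b1"] = NumericVector(grad.b1.begin(), grad.b1.end()),
    _["W2"] = gW2, _["b2"] = NumericVector(grad.b2.begin(), grad.b2.end()),
    _["sse"] = sse);
}

// [[Rcpp::export]]
NumericMatrix ffnn_forward_cpp(NumericMatrix X,
                               NumericMatrix W1, NumericVector b1,
                               NumericMatrix W2, NumericVector b2) {
  Net net = net_from(W1, b1, W2, b2);
  int n = X.nrow();
  std::vector<double> Xf = flatten_rows(X);
  std::vector<double> a1(net.h), out(net.q);
  NumericMatrix O(n, net.q);
  for (int r = 0; r < n; ++r) {
    forward_one(net, &Xf[(size_t)r * net.p], a1.data(), out.data());
    for (int k = 0; k < net.q; ++k) O(r, k) = out[k];
  }
  return O;
}
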