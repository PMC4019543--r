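// Small feed-forward networks (one sigmoid hidden layer, sigmoid output,
// squared-error loss, full-batch gradient descent with momentum, early
// stopping on a validation subset). Used for per-transcript predictive
// ranking and for marker-interaction gradients.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct NetResult {
  double test_error;
  double best_val_error;
  int cycles;
  bool failed;
  std::vector<double> val_trace;
};

// Train a p-input / h-hidden / 1-output net. Parameter vector layout:
// w1 (h*p, input-major within each hidden unit), b1 (h), w2 (h), b2.
// Early stopping: training halts once the validation criterion has not
// improved for `patience` consecutive cycles; the test error is evaluated
// at the best-validation snapshot. With `maximize_val` the (non-default)
// reading that waits for the validation error to rise is used instead.
static NetResult train_net(const std::vector<std::vector<double>>& X,
                           const std::vector<double>& y,
                           const std::vector<int>& train_i,
                           const std::vector<int>& val_i,
                           const std::vector<int>& test_i,
                           std::vector<double> w, int h,
                           double lr, double momentum,
                           int patience, int max_cycles,
                           bool maximize_val, bool want_trace) {
  const int p = (int)X.size();       // inputs
  const int nw = h * p + h + h + 1;  // parameters
  std::vector<double> v(nw, 0.0), grad(nw), best_w(w);
  std::vector<double> act(h), delta_h(h);
  NetResult res;
  res.failed = false;

  auto forward = [&](int s) {
    double out_in = w[h * p + h + h]; // b2
    for (int u = 0; u < h; ++u) {
      double z = w[h * p + u]; // b1[u]
      for (int i = 0; i < p; ++i) z += w[u * p + i] * X[i][s];
      act[u] = sigmoid(z);
      out_in += w[h * p + h + u] * act[u];
    }
    return sigmoid(out_in);
  };
  auto subset_error = [&](const std::vector<int>& idx) {
    double e = 0.0;
    for (int s : idx) {
      double d = forward(s) - y[s];
      e += d * d;
    }
    return idx.empty() ? 0.0 : e / idx.size();
  };

  double best_val = maximize_val ? -1.0 : std::numeric_limits<double>::infinity();
  int stall = 0;
  int cycle = 0;
  for (cycle = 0; cycle < max_cycles; ++cycle) {
    std::fill(grad.begin(), grad.end(), 0.0);
    bool bad = false;
    for (int s : train_i) {
      double out = forward(s);
      double err = out - y[s];
      if (!std::isfinite(err)) { bad = true; break; }
      double dout = 2.0 * err * out * (1.0 - out) / train_i.size();
      grad[h * p + h + h] += dout; // b2
      for (int u = 0; u < h; ++u) {
        grad[h * p + h + u] += dout * act[u]; // w2
        double dh = dout * w[h * p + h + u] * act[u] * (1.0 - act[u]);
        grad[h * p + u] += dh; // b1
        for (int i = 0; i < p; ++i) grad[u * p + i] += dh * X[i][s];
      }
    }
    if (bad) { res.failed = true; break; }
    for (int j = 0; j < nw; ++j) {
      v[j] = momentum * v[j] - lr * grad[j];
      w[j] += v[j];
      if (!std::isfinite(w[j])) { res.failed = true; break; }
    }
    if (res.failed) break;
    double val_err = subset_error(val_i);
    if (want_trace) res.val_trace.push_back(val_err);
    bool improved = maximize_val ? (val_err > best_val) : (val_err < best_val);
    if (improved) {
      best_val = val_err;
      best_w = w;
      stall = 0;
    } else if (++stall >= patience) {
      ++cycle;
      break;
    }
  }
  res.cycles = cycle;
  if (res.failed) {
    res.test_error = NA_REAL;
    res.best_val_error = NA_REAL;
    return res;
  }
  w = best_w;
  res.best_val_error = best_val;
  res.test_error = subset_error(test_i);
  return res;
}

// Min-max scale `x` using the training subset's range; degenerate training
// ranges collapse to the constant 0.5 (an uninformative input).
static std::vector<double> minmax_scale(const std::vector<double>& x,
                                        const std::vector<int>& train_i) {
  double lo = std::numeric_limits<double>::infinity(), hi = -lo;
  for (int s : train_i) {
    if (x[s] < lo) lo = x[s];
    if (x[s] > hi) hi = x[s];
  }
  std::vector<double> out(x.size());
  if (!(hi > lo)) {
    std::fill(out.begin(), out.end(), 0.5);
    return out;
  }
  for (size_t s = 0; s < x.size(); ++s) out[s] = (x[s] - lo) / (hi - lo);
  return out;
}

static std::vector<int> which_code(const IntegerVector& codes, int code) {
  std::vector<int> out;
  for (int s = 0; s < codes.size(); ++s) if (codes[s] == code) out.push_back(s);
  return out;
}

// Train one single-input net and return (test_error, best_val, cycles,
// failed) plus the per-cycle validation trace.
// [[Rcpp::export]]
List cpp_train_single(NumericVector x, NumericVector y, IntegerVector codes,
                      NumericVector w0, int hidden, double lr,
                      double momentum, int patience, int max_cycles,
                      bool maximize_val) {
  std::vector<int> tr = which_code(codes, 0), va = which_code(codes, 1),
    te = which_code(codes, 2);
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::vector<double> xscaled = minmax_scale(xs, tr);
  std::vector<std::vector<double>> X{xscaled};
  std::vector<double> w(w0.begin(), w0.end());
  NetResult r = train_net(X, ys, tr, va, te, w, hidden, lr, momentum,
                          patience, max_cycles, maximize_val, true);
  return List::create(_["test_error"] = r.failed ? NA_REAL : r.test_error,
                      _["best_val_error"] = r.failed ? NA_REAL : r.best_val_error,
                      _["cycles"] = r.cycles,
                      _["failed"] = r.failed,
                      _["validation_trace"] = NumericVector(r.val_trace.begin(),
                                                            r.val_trace.end()));
}

// Batched ranking backend: one net per (transcript, resample). `splits` and
// `w0` have n_transcripts * n_resamples rows (resample-major within
// transcript); split codes are 0 train / 1 validation / 2 test.
// [[Rcpp::export]]
NumericVector cpp_rank_nets(NumericMatrix expr, NumericVector y,
                            IntegerMatrix splits, NumericMatrix w0,
                            int n_resamples, int hidden, double lr,
                            double momentum, int patience, int max_cycles,
                            bool maximize_val) {
  const int T = expr.nrow();
  const int S = expr.ncol();
  std::vector<double> ys(y.begin(), y.end());
  NumericVector errors(T * n_resamples);
  for (int t = 0; t < T; ++t) {
    std::vector<double> x(S);
    for (int s = 0; s < S; ++s) x[s] = expr(t, s);
    for (int r = 0; r < n_resamples; ++r) {
      int row = t * n_resamples + r;
      IntegerVector codes = splits.row(row);
      std::vector<int> tr = which_code(codes, 0), va = which_code(codes, 1),
        te = which_code(codes, 2);
      std::vector<std::vector<double>> X{minmax_scale(x, tr)};
      std::vector<double> w(w0.ncol());
      for (int j = 0; j < w0.ncol(); ++j) w[j] = w0(row, j);
      NetResult res = train_net(X, ys, tr, va, te, w, hidden, lr, momentum,
                                patience, max_cycles, maximize_val, false);
      errors[row] = res.failed ? NA_REAL : res.test_error;
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return errors;
}

// Train a net predicting marker `target` (0-based row of `expr`) from all
// other rows, on all samples, and return the mean over samples of the
// signed gradient of the output with respect to each input marker.
// `expr` must already be min-max scaled per row. Entry for the target
// itself is 0.
// [[Rcpp::export]]
NumericVector cpp_influence(NumericMatrix expr, int target, NumericVector w0,
                            int hidden, double lr, double momentum,
                            int max_cycles) {
  const int K = expr.nrow();
  const int S = expr.ncol();
  const int p = K - 1;
  std::vector<std::vector<double>> X(p, std::vector<double>(S));
  std::vector<int> input_rows;
  for (int i = 0; i < K; ++i) if (i != target) input_rows.push_back(i);
  for (int i = 0; i < p; ++i)
    for (int s = 0; s < S; ++s) X[i][s] = expr(input_rows[i], s);
  std::vector<double> y(S);
  for (int s = 0; s < S; ++s) y[s] = expr(target, s);
  NumericVector infl(K);
  // all samples train; the best-training-error snapshot is kept
  {
    const int nw = hidden * p + hidden + hidden + 1;
    std::vector<double> v(nw, 0.0), grad(nw), act(hidden);
    std::vector<double> ww(w0.begin(), w0.end());
    double best_err = std::numeric_limits<double>::infinity();
    std::vector<double> best_w(ww);
    for (int cycle = 0; cycle < max_cycles; ++cycle) {
      std::fill(grad.begin(), grad.end(), 0.0);
      double err_sum = 0.0;
      for (int s = 0; s < S; ++s) {
        double out_in = ww[hidden * p + hidden + hidden];
        for (int u = 0; u < hidden; ++u) {
          double z = ww[hidden * p + u];
          for (int i = 0; i < p; ++i) z += ww[u * p + i] * X[i][s];
          act[u] = sigmoid(z);
          out_in += ww[hidden * p + hidden + u] * act[u];
        }
        double out = sigmoid(out_in);
        double err = out - y[s];
        err_sum += err * err;
        double dout = 2.0 * err * out * (1.0 - out) / S;
        grad[hidden * p + hidden + hidden] += dout;
        for (int u = 0; u < hidden; ++u) {
          grad[hidden * p + hidden + u] += dout * act[u];
          double dh = dout * ww[hidden * p + hidden + u] * act[u] * (1.0 - act[u]);
          grad[hidden * p + u] += dh;
          for (int i = 0; i < p; ++i) grad[u * p + i] += dh * X[i][s];
        }
      }
      if (err_sum < best_err) { best_err = err_sum; best_w = ww; }
      for (int j = 0; j < nw; ++j) {
        v[j] = momentum * v[j] - lr * grad[j];
        ww[j] += v[j];
      }
    }
    ww = best_w;
    // mean signed input gradient over samples
    std::vector<double> g(p, 0.0);
    for (int s = 0; s < S; ++s) {
      double out_in = ww[hidden * p + hidden + hidden];
      for (int u = 0; u < hidden; ++u) {
        double z = ww[hidden * p + u];
        for (int i = 0; i < p; ++i) z += ww[u * p + i] * X[i][s];
        act[u] = sigmoid(z);
        out_in += ww[hidden * p + hidden + u] * act[u];
      }
      double out = sigmoid(out_in);
      double douts = out * (1.0 - out);
      for (int i = 0; i < p; ++i) {
        double acc = 0.0;
        for (int u = 0; u < hidden; ++u)
          acc += ww[hidden * p + hidden + u] * act[u] * (1.0 - act[u]) * ww[u * p + i];
        g[i] += douts * acc;
      }
    }
    for (int i = 0; i < p; ++i) infl[input_rows[i]] = g[i] / S;
  }
  infl[target] = 0.0;
  return infl;
}
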