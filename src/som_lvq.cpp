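#include <Rcpp.h>
using namespace Rcpp;

// Squared Euclidean distance between data row i and codebook row j.
static inline double sqdist_row(const NumericMatrix &a, int i,
                                const NumericMatrix &b, int j) {
  double s = 0.0;
  const int d = a.ncol();
  for (int c = 0; c < d; ++c) {
    const double diff = a(i, c) - b(j, c);
    s += diff * diff;
  }
  return s;
}

// Index of nearest codebook row (ties -> smallest index, via strict <).
static inline int nearest_row(const NumericMatrix &data, int i,
                              const NumericMatrix &codebook) {
  int best = 0;
  double bestd = sqdist_row(data, i, codebook, 0);
  for (int j = 1; j < codebook.nrow(); ++j) {
    const double d = sqdist_row(data, i, codebook, j);
    if (d < bestd) {
      bestd = d;
      best = j;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector bmu_cpp(NumericMatrix codebook, NumericMatrix data) {
  const int n = data.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = nearest_row(data, i, codebook);
  return out; // 0-based row-major neuron indices
}

// [[Rcpp::export]]
double quantization_error_cpp(NumericMatrix codebook, NumericMatrix data) {
  const int n = data.nrow();
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    const int b = nearest_row(data, i, codebook);
    total += std::sqrt(sqdist_row(data, i, codebook, b));
  }
  return total / n;
}

// Sequential Kohonen SOM with bubble neighborhood on a lat_rows x lat_cols
// lattice (codebook row r*lat_cols + c sits at lattice position (r, c)).
// Learning rate and radius both follow inverse-time decay
//   value(t) = value0 / (1 + t / (T/2)),
// and bubble membership is lattice Chebyshev distance <= current radius.
// sample_idx holds the 1-based data row drawn at each iteration so that
// all randomness stays under the caller's RNG.
// [[Rcpp::export]]
List som_train_cpp(NumericMatrix codebook, NumericMatrix data,
                   IntegerVector sample_idx, double lr0, double radius0,
                   int lat_rows, int lat_cols, int n_checkpoints) {
  NumericMatrix cb = clone(codebook);
  const int T = sample_idx.size();
  const int d = cb.ncol();
  const double tau = T / 2.0;

  std::vector<double> log_iter, log_qe;
  log_iter.push_back(0.0);
  log_qe.push_back(quantization_error_cpp(cb, data));
  const int step = std::max(1, T / n_checkpoints);

  for (int t = 0; t < T; ++t) {
    const double lr = lr0 / (1.0 + t / tau);
    const double radius = radius0 / (1.0 + t / tau);
    const int i = sample_idx[t] - 1;

    int bmu = 0;
    double bestd = sqdist_row(data, i, cb, 0);
    for (int j = 1; j < cb.nrow(); ++j) {
      const double dist = sqdist_row(data, i, cb, j);
      if (dist < bestd) {
        bestd = dist;
        bmu = j;
      }
    }
    const int br = bmu / lat_cols, bc = bmu % lat_cols;

    const int rad = (int)std::floor(radius);
    const int r0 = std::max(0, br - rad), r1 = std::min(lat_rows - 1, br + rad);
    const int c0 = std::max(0, bc - rad), c1 = std::min(lat_cols - 1, bc + rad);
    for (int r = r0; r <= r1; ++r) {
      for (int c = c0; c <= c1; ++c) {
        const int j = r * lat_cols + c;
        for (int k = 0; k < d; ++k) {
          const double upd = cb(j, k) + lr * (data(i, k) - cb(j, k));
          if (!std::isfinite(upd))
            stop("non-finite codebook update at iteration %d", t + 1);
          cb(j, k) = upd;
        }
      }
    }

    if ((t + 1) % step == 0 || t + 1 == T) {
      if (log_iter.back() != (double)(t + 1)) {
        log_iter.push_back((double)(t + 1));
        log_qe.push_back(quantization_error_cpp(cb, data));
      }
    }
  }

  return List::create(_["codebook"] = cb,
                      _["log_iteration"] = wrap(log_iter),
                      _["log_qe"] = wrap(log_qe));
}

// LVQ1: per epoch, visit samples in the caller-supplied shuffled order;
// the nearest prototype moves toward a same-class sample and away from a
// different-class sample by lr * (x - w). loss[e] is the training-set
// misclassification ratio evaluated after epoch e.
// orders: n x epochs matrix of 1-based sample visit orders.
// [[Rcpp::export]]
List lvq_train_cpp(NumericMatrix prototypes, IntegerVector proto_class,
                   NumericMatrix data, IntegerVector data_class,
                   IntegerMatrix orders, double lr) {
  NumericMatrix w = clone(prototypes);
  const int n = data.nrow(), d = data.ncol();
  const int epochs = orders.ncol();
  NumericVector loss(epochs);

  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s) {
      const int i = orders(s, e) - 1;
      int best = 0;
      double bestd = sqdist_row(data, i, w, 0);
      for (int j = 1; j < w.nrow(); ++j) {
        const double dist = sqdist_row(data, i, w, j);
        if (dist < bestd) {
          bestd = dist;
          best = j;
        }
      }
      const double sign = (proto_class[best] == data_class[i]) ? 1.0 : -1.0;
      for (int k = 0; k < d; ++k) {
        const double upd = w(best, k) + sign * lr * (data(i, k) - w(best, k));
        if (!std::isfinite(upd))
          stop("non-finite prototype update in epoch %d", e + 1);
        w(best, k) = upd;
      }
    }
    int wrong = 0;
    for (int i = 0; i < n; ++i) {
      const int b = nearest_row(data, i, w);
      if (proto_class[b] != data_class[i]) ++wrong;
    }
    loss[e] = (double)wrong / n;
  }

  return List::create(_["prototypes"] = w, _["loss"] = loss);
}
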