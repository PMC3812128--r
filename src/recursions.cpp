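#include <Rcpp.h>
using namespace Rcpp;

// Univariate structural-model recursions.
//
// Two state dimensions are supported:
//   order 0 : local level (random walk) -- state = level
//   order 1 : local linear trend        -- state = (level, slope),
//             G = [1 1; 0 1], observation picks the level.
// Observation noise variance v, level disturbance wl, slope disturbance wb.
// Missing observations (NA) skip the measurement update.
// Covariance updates use the Joseph form for numerical stability.
// The Gaussian log-likelihood follows the prediction-error decomposition,
// omitting the first `order + 1` observed terms, which are dominated by
// the (nearly) diffuse prior.

static const double LOG2PI = 1.8378770664093454836;

// [[Rcpp::export(name = ".dlm_filter_cpp")]]
List dlm_filter_cpp(NumericVector y, int order, double v, double wl, double wb,
                    double m0l, double m0b, double c0) {
  int M = y.size();
  int d = order + 1;
  NumericMatrix pred_mean(M, 2), filt_mean(M, 2);
  NumericMatrix pred_cov(M, 3), filt_cov(M, 3); // (c11, c12, c22)
  NumericVector f(M), Q(M), err(M);
  double loglik = 0.0;
  int n_obs_seen = 0, n_ll = 0;

  double ml = m0l, mb = (order == 1) ? m0b : 0.0;
  double c11 = c0, c12 = 0.0, c22 = (order == 1) ? c0 : 0.0;

  for (int t = 0; t < M; ++t) {
    // time update
    double al, ab, r11, r12, r22;
    if (order == 1) {
      al = ml + mb; ab = mb;
      r11 = c11 + 2.0 * c12 + c22 + wl;
      r12 = c12 + c22;
      r22 = c22 + wb;
    } else {
      al = ml; ab = 0.0;
      r11 = c11 + wl; r12 = 0.0; r22 = 0.0;
    }
    double ft = al, Qt = r11 + v;
    pred_mean(t, 0) = al; pred_mean(t, 1) = ab;
    pred_cov(t, 0) = r11; pred_cov(t, 1) = r12; pred_cov(t, 2) = r22;
    f[t] = ft; Q[t] = Qt;

    bool observed = !NumericVector::is_na(y[t]);
    if (observed) {
      double e = y[t] - ft;
      err[t] = e;
      double K1 = r11 / Qt;
      double K2 = (order == 1) ? r12 / Qt : 0.0;
      ml = al + K1 * e;
      mb = ab + K2 * e;
      double u = 1.0 - K1;
      if (order == 1) {
        double n11 = u * u * r11 + K1 * K1 * v;
        double n12 = u * (r12 - K2 * r11) + K1 * K2 * v;
        double n22 = K2 * K2 * r11 - 2.0 * K2 * r12 + r22 + K2 * K2 * v;
        c11 = n11; c12 = n12; c22 = n22;
      } else {
        c11 = u * u * r11 + K1 * K1 * v;
        c12 = 0.0; c22 = 0.0;
      }
      ++n_obs_seen;
      if (n_obs_seen > d) {
        loglik += -0.5 * (LOG2PI + std::log(Qt) + e * e / Qt);
        ++n_ll;
      }
    } else {
      err[t] = NA_REAL;
      ml = al; mb = ab;
      c11 = r11; c12 = r12; c22 = r22;
    }
    filt_mean(t, 0) = ml; filt_mean(t, 1) = mb;
    filt_cov(t, 0) = c11; filt_cov(t, 1) = c12; filt_cov(t, 2) = c22;
  }

  return List::create(
    _["pred_mean"] = pred_mean, _["pred_cov"] = pred_cov,
    _["filt_mean"] = filt_mean, _["filt_cov"] = filt_cov,
    _["forecast"] = f, _["forecast_var"] = Q, _["error"] = err,
    _["loglik"] = loglik, _["n_loglik_terms"] = n_ll,
    _["n_observed"] = n_obs_seen);
}

// Fast path for maximum-likelihood estimation: negative log-likelihood only.
// [[Rcpp::export(name = ".dlm_negloglik_cpp")]]
double dlm_negloglik_cpp(NumericVector y, int order, double v, double wl,
                         double wb, double m0l, double m0b, double c0) {
  int M = y.size();
  int d = order + 1;
  double loglik = 0.0;
  int n_obs_seen = 0;
  double ml = m0l, mb = (order == 1) ? m0b : 0.0;
  double c11 = c0, c12 = 0.0, c22 = (order == 1) ? c0 : 0.0;

  for (int t = 0; t < M; ++t) {
    double al, ab, r11, r12, r22;
    if (order == 1) {
      al = ml + mb; ab = mb;
      r11 = c11 + 2.0 * c12 + c22 + wl;
      r12 = c12 + c22;
      r22 = c22 + wb;
    } else {
      al = ml; ab = 0.0;
      r11 = c11 + wl; r12 = 0.0; r22 = 0.0;
    }
    double Qt = r11 + v;
    if (!NumericVector::is_na(y[t])) {
      double e = y[t] - al;
      double K1 = r11 / Qt;
      double K2 = (order == 1) ? r12 / Qt : 0.0;
      ml = al + K1 * e;
      mb = ab + K2 * e;
      double u = 1.0 - K1;
      if (order == 1) {
        double n11 = u * u * r11 + K1 * K1 * v;
        double n12 = u * (r12 - K2 * r11) + K1 * K2 * v;
        double n22 = K2 * K2 * r11 - 2.0 * K2 * r12 + r22 + K2 * K2 * v;
        c11 = n11; c12 = n12; c22 = n22;
      } else {
        c11 = u * u * r11 + K1 * K1 * v;
      }
      ++n_obs_seen;
      if (n_obs_seen > d)
        loglik += -0.5 * (LOG2PI + std::log(Qt) + e * e / Qt);
    } else {
      ml = al; mb = ab;
      c11 = r11; c12 = r12; c22 = r22;
    }
  }
  return -loglik;
}

// Rauch-Tung-Striebel backward pass. Takes the filter output matrices.
// A tiny diagonal jitter keeps the one-step-ahead covariance invertible in
// degenerate (zero-disturbance) limits.
// [[Rcpp::export(name = ".dlm_smoother_cpp")]]
List dlm_smoother_cpp(int order, NumericMatrix pred_mean, NumericMatrix pred_cov,
                      NumericMatrix filt_mean, NumericMatrix filt_cov) {
  int M = pred_mean.nrow();
  NumericMatrix s_mean(M, 2), s_cov(M, 3);

  s_mean(M - 1, 0) = filt_mean(M - 1, 0);
  s_mean(M - 1, 1) = filt_mean(M - 1, 1);
  s_cov(M - 1, 0) = filt_cov(M - 1, 0);
  s_cov(M - 1, 1) = filt_cov(M - 1, 1);
  s_cov(M - 1, 2) = filt_cov(M - 1, 2);

  for (int t = M - 2; t >= 0; --t) {
    double c11 = filt_cov(t, 0), c12 = filt_cov(t, 1), c22 = filt_cov(t, 2);
    double r11 = pred_cov(t + 1, 0), r12 = pred_cov(t + 1, 1),
           r22 = pred_cov(t + 1, 2);
    if (order == 1) {
      double jit = 1e-12 * (r11 + r22) + 1e-300;
      double a11 = r11 + jit, a22 = r22 + jit, a12 = r12;
      double det = a11 * a22 - a12 * a12;
      // B = C_t G' : G = [1 1; 0 1], G' = [1 0; 1 1]
      double b11 = c11 + c12, b12 = c12;
      double b21 = c12 + c22, b22 = c22;
      // J = B R^{-1}
      double j11 = (b11 * a22 - b12 * a12) / det;
      double j12 = (b12 * a11 - b11 * a12) / det;
      double j21 = (b21 * a22 - b22 * a12) / det;
      double j22 = (b22 * a11 - b21 * a12) / det;
      double dl = s_mean(t + 1, 0) - pred_mean(t + 1, 0);
      double db = s_mean(t + 1, 1) - pred_mean(t + 1, 1);
      s_mean(t, 0) = filt_mean(t, 0) + j11 * dl + j12 * db;
      s_mean(t, 1) = filt_mean(t, 1) + j21 * dl + j22 * db;
      // S_t = C_t + J (S_{t+1} - R_{t+1}) J'
      double d11 = s_cov(t + 1, 0) - r11;
      double d12 = s_cov(t + 1, 1) - r12;
      double d22 = s_cov(t + 1, 2) - r22;
      double m11 = j11 * d11 + j12 * d12;
      double m12 = j11 * d12 + j12 * d22;
      double m21 = j21 * d11 + j22 * d12;
      double m22 = j21 * d12 + j22 * d22;
      s_cov(t, 0) = c11 + m11 * j11 + m12 * j12;
      s_cov(t, 1) = c12 + m11 * j21 + m12 * j22;
      s_cov(t, 2) = c22 + m21 * j21 + m22 * j22;
    } else {
      double jit = 1e-12 * r11 + 1e-300;
      double j = c11 / (r11 + jit);
      s_mean(t, 0) = filt_mean(t, 0) + j * (s_mean(t + 1, 0) - pred_mean(t + 1, 0));
      s_cov(t, 0) = c11 + j * j * (s_cov(t + 1, 0) - r11);
      s_mean(t, 1) = 0.0; s_cov(t, 1) = 0.0; s_cov(t, 2) = 0.0;
    }
  }
  return List::create(_["smooth_mean"] = s_mean, _["smooth_cov"] = s_cov);
}

// One-step-ahead sum of squared errors for non-seasonal Holt-Winters.
// Initialization: level at the first observation; slope (trend variant)
// at y2 - y1. The SSE accumulates from the third observation onward, so
// the initialization itself is never rewarded. Missing values propagate
// the state forward without an update and contribute no error term.
// Leading NAs must be stripped by the caller.
// [[Rcpp::export(name = ".hw_sse_cpp")]]
List hw_sse_cpp(NumericVector y, double alpha, double beta, bool trend) {
  int M = y.size();
  double a = y[0];
  double b = 0.0;
  if (trend) {
    // first non-missing after position 0 defines the initial slope
    int j = 1;
    while (j < M && NumericVector::is_na(y[j])) ++j;
    b = (y[j] - y[0]) / (double)(j);
  }
  double sse = 0.0;
  int n = 0, seen = 1;
  for (int t = 1; t < M; ++t) {
    double f = a + b; // one-step forecast from state at t-1
    if (!NumericVector::is_na(y[t])) {
      ++seen;
      if (seen >= 3) { sse += (y[t] - f) * (y[t] - f); ++n; }
      double a_new = alpha * y[t] + (1.0 - alpha) * (a + b);
      double b_new = trend ? beta * (a_new - a) + (1.0 - beta) * b : 0.0;
      a = a_new; b = b_new;
    } else {
      a = a + b;
    }
  }
  return List::create(_["sse"] = sse, _["n"] = n,
                      _["level"] = a, _["slope"] = b);
}
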