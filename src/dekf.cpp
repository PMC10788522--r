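// Dual extended Kalman filter for time-varying MVAR estimation.
//
// Two coupled Kalman recursions run over the sample axis: a state filter
// tracks the signal in companion form given the current coefficient
// estimates, and a parameter filter treats the stacked MVAR coefficients as
// a random-walk state updated from the innovation of the state filter. The
// model is linear in both states, so the "extended" linearization is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// y: channels x samples; p: model order.
// qParam: parameter random-walk variance (per step, isotropic).
// p0Param: initial parameter covariance scale.
// obsNoiseFrac: observation-noise variance of the state filter as a
//   fraction of each channel's sample variance.
// Coefficients are stacked column-major as vec([A1 A2 ... Ap]) with
// B = [A1 ... Ap] (c x c*p), so y_t ~ B * [y_{t-1}; ...; y_{t-p}].
// [[Rcpp::export(name = ".dekfFitCpp")]]
Rcpp::List dekfFitCpp(const arma::mat& y, const int p,
                      const double qParam = 1e-4,
                      const double p0Param = 0.5,
                      const double obsNoiseFrac = 0.01) {
  const int c = y.n_rows;
  const int n = y.n_cols;
  const int cp = c * p;
  const int d = c * cp;
  if (n <= p + 1) Rcpp::stop("series too short for order %d", p);

  // measurement-noise scale from per-channel sample variance
  vec vy = var(y, 0, 1);
  vy.transform([](double v) { return v > 0.0 ? v : 1.0; });
  mat R = diagmat(vy);
  mat Robs = obsNoiseFrac * R;

  // parameter filter
  vec w(d, fill::zeros);
  mat Pw = p0Param * eye(d, d);
  const mat Qw = qParam * eye(d, d);

  // state filter (companion form)
  vec z(cp, fill::zeros);
  for (int r = 0; r < p; ++r) z.subvec(r * c, r * c + c - 1) = y.col(p - 1 - r);
  mat P1 = eye(cp, cp);
  mat Q1(cp, cp, fill::zeros);
  Q1.submat(0, 0, c - 1, c - 1) = R;
  if (cp > c) Q1.submat(c, c, cp - 1, cp - 1) = 1e-8 * eye(cp - c, cp - c);

  mat coeffs(d, n, fill::zeros);   // columns p..n-1 are filled
  mat resid(c, n, fill::zeros);
  mat B(c, cp, fill::zeros);

  mat F(cp, cp, fill::zeros);
  if (p > 1)
    F.submat(c, 0, cp - 1, cp - c - 1) = eye(cp - c, cp - c);

  for (int t = p; t < n; ++t) {
    // ---- parameter filter: predict
    Pw += Qw;

    // lagged regressors from the state filter's current estimate
    const vec xhat = z;                      // [y_{t-1}; ...; y_{t-p}]

    // ---- state filter: predict under current coefficients
    F.submat(0, 0, c - 1, cp - 1) = B;
    const vec zPred = F * z;
    mat P1pred = F * P1 * F.t() + Q1;

    // ---- parameter filter: measurement update (H = kron(xhat', I_c))
    mat H(c, d, fill::zeros);
    for (int k = 0; k < cp; ++k)
      H.submat(0, k * c, c - 1, k * c + c - 1) = xhat(k) * eye(c, c);
    const vec err = y.col(t) - B * xhat;
    resid.col(t) = err;
    mat PHt = Pw * H.t();                    // d x c
    mat S = H * PHt + R;
    mat K = PHt * inv_sympd(symmatu(S));     // d x c
    w += K * err;
    Pw -= K * (H * Pw);
    Pw = symmatu(Pw);
    if (!w.is_finite())
      Rcpp::stop("DEKF diverged (non-finite parameter state) at sample %d",
                 t + 1);

    // feed the updated coefficients back to the state filter
    B = reshape(w, c, cp);

    // ---- state filter: measurement update (C = [I 0])
    const vec innov = y.col(t) - zPred.subvec(0, c - 1);
    mat S1 = P1pred.submat(0, 0, c - 1, c - 1) + Robs;
    mat K1 = P1pred.cols(0, c - 1) * inv_sympd(symmatu(S1));  // cp x c
    z = zPred + K1 * innov;
    P1 = P1pred - K1 * P1pred.rows(0, c - 1);
    P1 = symmatu(P1);
    if (!z.is_finite())
      Rcpp::stop("DEKF diverged (non-finite signal state) at sample %d", t + 1);

    coeffs.col(t) = w;
  }

  return Rcpp::List::create(Rcpp::Named("coeffs") = coeffs,
                            Rcpp::Named("resid") = resid);
}
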