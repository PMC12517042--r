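// Per-window kernel for the dual-estimation loop:
//   1. extended Kalman filter over a window of observations (regime-indexed
//      effective connectivity W % Gamma_k, Jacobian linearization at the
//      current filtered state);
//   2. noise-free free-run prediction from the last filtered state;
//   3. full reverse-mode gradients of
//        L = sf * sum ||y_t - H f(xhat_{t-1})||^2  (filter window)
//          + sfr * sum ||H z_h - y_{L+h}||^2       (free run)
//      with respect to every model parameter AND the log-diagonal noise
//      covariances. The backward pass differentiates the complete filter
//      recursion -- state path, covariance propagation, innovation
//      covariance inverse and Kalman gain -- so the gradient matches a
//      central finite difference of the loss to numerical precision.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline vec act_phi(const vec& u, bool ident) {
  return ident ? u : tanh(u);
}
static inline vec act_dphi(const vec& u, bool ident) {
  if (ident) return ones<vec>(u.n_elem);
  vec th = tanh(u);
  return 1.0 - th % th;
}

// [[Rcpp::export(name = ".mm_window_kernel")]]
Rcpp::List mm_window_kernel(const arma::mat& W, const arma::cube& Gamma,
                            const arma::vec& S, const arma::vec& V,
                            const arma::vec& D, const arma::vec& C,
                            const arma::mat& H, const arma::vec& q,
                            const arma::vec& r, const arma::mat& Y,
                            const arma::ivec& regimes, const arma::vec& x0,
                            const arma::mat& P0, int window_len,
                            int freerun_len, int burnin, double sf,
                            double sfr, bool identity_act, double decay_sign,
                            bool want_grad) {
  const int n = W.n_rows, c = H.n_rows, m = Gamma.n_slices;
  const int L = window_len, F = freerun_len;
  if ((int)Y.n_rows < L + F) Rcpp::stop("window kernel: too few observations");
  if ((int)regimes.n_elem < L + F) Rcpp::stop("window kernel: too few labels");

  cube M(n, n, m);                 // per-regime effective connectivity
  for (int k = 0; k < m; ++k) M.slice(k) = W % Gamma.slice(k);

  // ---- forward: EKF over the window -------------------------------------
  mat Xhat(n, L + 1);              // filtered states, col 0 = x0
  mat Phi(n, L), Dphi(n, L), E(c, L), Ypred(c, L);
  cube Kk(n, c, L), Fk(n, n, L), Ppk(n, n, L), Sik(c, c, L), Pk(n, n, L + 1);
  Xhat.col(0) = x0;
  Pk.slice(0) = P0;
  mat Rm = diagmat(r), Qm = diagmat(q);
  double loss_f = 0.0;

  for (int t = 0; t < L; ++t) {
    int k = regimes(t) - 1;
    if (k < 0 || k >= m) Rcpp::stop("window kernel: regime label out of range");
    vec xprev = Xhat.col(t);
    vec u = S % xprev + V;
    vec phi = act_phi(u, identity_act), dphi = act_dphi(u, identity_act);
    vec xp = xprev + M.slice(k) * phi + decay_sign * (D % xprev) + C;
    mat Fj = eye(n, n) + M.slice(k) * diagmat(S % dphi) +
             diagmat(decay_sign * D);
    mat Pp = Fj * Pk.slice(t) * Fj.t() + Qm;
    Pp = 0.5 * (Pp + Pp.t());
    mat St = H * Pp * H.t() + Rm;
    St = 0.5 * (St + St.t());
    mat Sinv;
    if (!inv_sympd(Sinv, St))
      Rcpp::stop("singular innovation covariance at step %d", t + 1);
    mat K = Pp * H.t() * Sinv;
    vec e = Y.row(t).t() - H * xp;
    Xhat.col(t + 1) = xp + K * e;
    mat P = (eye(n, n) - K * H) * Pp;
    Pk.slice(t + 1) = 0.5 * (P + P.t());
    if (!Pk.slice(t + 1).is_finite() || !Xhat.col(t + 1).is_finite())
      Rcpp::stop("numerical failure in Kalman recursion at step %d", t + 1);

    Phi.col(t) = phi; Dphi.col(t) = dphi; E.col(t) = e;
    Ypred.col(t) = H * xp;
    Kk.slice(t) = K; Fk.slice(t) = Fj; Ppk.slice(t) = Pp; Sik.slice(t) = Sinv;
    if (t >= burnin) loss_f += dot(e, e);
  }

  // ---- forward: free run from the last filtered state -------------------
  mat Z(n, F + 1), PhiF(n, F), DphiF(n, F), Dres(c, F), Yfree(c, F);
  Z.col(0) = Xhat.col(L);
  double loss_fr = 0.0;
  for (int h = 0; h < F; ++h) {
    int k = regimes(L + h) - 1;
    if (k < 0 || k >= m) Rcpp::stop("window kernel: regime label out of range");
    vec zprev = Z.col(h);
    vec u = S % zprev + V;
    vec phi = act_phi(u, identity_act), dphi = act_dphi(u, identity_act);
    Z.col(h + 1) = zprev + M.slice(k) * phi + decay_sign * (D % zprev) + C;
    if (!Z.col(h + 1).is_finite())
      Rcpp::stop("free run diverged at step %d", h + 1);
    vec d = H * Z.col(h + 1) - Y.row(L + h).t();
    PhiF.col(h) = phi; DphiF.col(h) = dphi; Dres.col(h) = d;
    Yfree.col(h) = H * Z.col(h + 1);
    loss_fr += dot(d, d);
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss_filter") = loss_f,
      Rcpp::Named("loss_freerun") = loss_fr,
      Rcpp::Named("loss") = sf * loss_f + sfr * loss_fr,
      Rcpp::Named("states") = Xhat.cols(1, L).t(),
      Rcpp::Named("innovations") = E.t(),
      Rcpp::Named("pred_meas") = Ypred.t(),
      Rcpp::Named("freerun_pred") = Yfree.t());

  if (!want_grad) return out;

  // ---- backward ---------------------------------------------------------
  mat gW = zeros<mat>(n, n);
  cube gGamma = zeros<cube>(n, n, m);
  vec gS = zeros<vec>(n), gV = zeros<vec>(n), gD = zeros<vec>(n),
      gC = zeros<vec>(n), gq = zeros<vec>(n), gr = zeros<vec>(c);

  // free run: exact BPTT; adjoint of each M-application accumulated into
  // the parameter gradients through gM
  vec gz = zeros<vec>(n);
  for (int h = F - 1; h >= 0; --h) {
    int k = regimes(L + h) - 1;
    gz += 2.0 * sfr * (H.t() * Dres.col(h));
    vec phi = PhiF.col(h), dphi = DphiF.col(h), zprev = Z.col(h);
    mat gM = gz * phi.t();
    gW += gM % Gamma.slice(k);
    gGamma.slice(k) += gM % W;
    vec gu = (M.slice(k).t() * gz) % dphi;
    gS += gu % zprev;
    gV += gu;
    gD += decay_sign * (gz % zprev);
    gC += gz;
    // d z_h / d z_{h-1} = I + M diag(S dphi) + decay_sign diag(D)
    gz = gz + S % gu + decay_sign * (D % gz);
  }

  // filter: reverse the full recursion (state + covariance + gain)
  vec gx = gz;                       // adjoint of xhat_t
  mat gP = zeros<mat>(n, n);         // adjoint of P_t
  for (int t = L - 1; t >= 0; --t) {
    int k = regimes(t) - 1;
    vec xprev = Xhat.col(t);
    vec phi = Phi.col(t), dphi = Dphi.col(t), e = E.col(t);
    mat K = Kk.slice(t), Fj = Fk.slice(t), Pp = Ppk.slice(t),
        Sinv = Sik.slice(t);

    // P_t = (I - K H) Pp   (then symmetrised)
    gP = 0.5 * (gP + gP.t());
    mat gK = -gP * Pp * H.t();          // Pp symmetric
    mat gPp = (eye(n, n) - K * H).t() * gP;
    // x_t = xp + K e
    vec gxp = gx;
    gK += gx * e.t();
    vec ge = K.t() * gx;
    if (t >= burnin) ge += 2.0 * sf * e;
    gxp += -H.t() * ge;                 // e = y - H xp
    // K = Pp H' Sinv
    gPp += gK * (H.t() * Sinv).t();
    mat gSinv = (Pp * H.t()).t() * gK;
    // Sinv = inv(St)
    mat gSt = -Sinv * gSinv * Sinv;
    gSt = 0.5 * (gSt + gSt.t());
    // St = H Pp H' + R
    gPp += H.t() * gSt * H;
    gr += gSt.diag();
    // Pp = F P F' + Q  (then symmetrised)
    gPp = 0.5 * (gPp + gPp.t());
    mat gF = (gPp + gPp.t()) * Fj * Pk.slice(t);
    gP = Fj.t() * gPp * Fj;             // adjoint of P_{t-1}
    gq += gPp.diag();

    // F = I + M diag(S dphi) + decay_sign diag(D)
    mat gM = gF * diagmat(S % dphi);
    vec gdiagMF = diagvec(M.slice(k).t() * gF);
    // xp = xprev + M phi + decay_sign D xprev + C
    gM += gxp * phi.t();
    vec gphi = M.slice(k).t() * gxp;
    vec gu = gphi % dphi;
    if (!identity_act) {
      // dphi/du = -2 phi dphi  (tanh)
      gu += gdiagMF % S % (-2.0 * phi % dphi);
    }
    gW += gM % Gamma.slice(k);
    gGamma.slice(k) += gM % W;
    gS += gu % xprev + gdiagMF % dphi;
    gV += gu;
    gD += decay_sign * (gxp % xprev) + decay_sign * diagvec(gF);
    gC += gxp;
    // adjoint of xhat_{t-1}
    gx = gxp + S % gu + decay_sign * (D % gxp);
  }

  out["gW"] = gW;
  out["gGamma"] = gGamma;
  out["gS"] = gS; out["gV"] = gV; out["gD"] = gD; out["gC"] = gC;
  out["g_logq"] = gq % q;
  out["g_logr"] = gr % r;
  return out;
}
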