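# Small fixtures built in code.

# 1 excitatory + 1 inhibitory population, 1 channel, hand-picked weights
tiny_params <- function(m = 1, activation = "tanh") {
  W <- matrix(c(0.5, 0.3, -0.4, -0.6), 2, 2)   # [We->e, We->i; Wi->e, Wi->i]
  Gamma <- replicate(m, list(a = c(1, 1), b = c(1, 1)), simplify = FALSE)
  mindy_params(1, 1, W, Gamma, S = c(2.5, 1), V = c(0, 0),
               D = c(0.66, 0.81), C = c(0, 0), activation = activation)
}

tiny_obs <- function(q = 0.1, r = 0.05) {
  mindy_obs(matrix(c(1, 0), 1, 2), q * diag(2), r * diag(1), n_inh = 1)
}

# independent textbook Kalman filter for affine dynamics
# x' = A x + b + w, y = H x + v (written as a plain recursion; used as the
# oracle for the EKF under the identity-activation hook)
kf_oracle <- function(A, b, H, Q, R, Y, x0, P0) {
  L <- nrow(Y); n <- length(x0)
  states <- matrix(0, L, n)
  x <- x0; P <- P0
  for (t in seq_len(L)) {
    xp <- A %*% x + b
    Pp <- A %*% P %*% t(A) + Q
    St <- H %*% Pp %*% t(H) + R
    K <- Pp %*% t(H) %*% solve(St)
    x <- xp + K %*% (Y[t, ] - H %*% xp)
    P <- (diag(n) - K %*% H) %*% Pp
    states[t, ] <- x
  }
  states
}

# flat fit-state representation of a mindy_params (for kernel-level tests)
as_fit_state <- function(params, obs) {
  list(W = params$W, ga = params$gamma_a, gb = params$gamma_b,
       S = params$S, V = params$V, D = params$D, C = params$C,
       logq = log(diag(obs$process_cov)), logr = log(diag(obs$meas_cov)))
}
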