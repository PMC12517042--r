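# Ground-truth generator: random E/I models with sparse + low-rank
# connectivity, rank-1 near-unity modulation matrices, slow HMM regime
# switching, and forward simulation through the observation model.

#' Configuration for the synthetic ground-truth generator
#'
#' Defaults reproduce the generating distributions of the validation study:
#' sparse part of each excitatory-source block \eqn{(16/20)\,U(0,1)^3},
#' low-rank factors \eqn{U(0,1)^3 + 0.2\,U(0,1)}, slopes 2.5 (exc) / 1 (inh),
#' decays \eqn{0.65 + 0.02 U} (exc) and \eqn{0.8 + 0.02 U} (inh), zero offset
#' and drive, standard-normal lead field, measurement covariance `0.25 I`,
#' process covariance \eqn{(0.2 + 0.1U)\,I}, three modulation regimes with
#' near-unity rank-1 matrices, and a slow HMM with transition matrix
#' \eqn{0.999 I + (0.001/nS)(\mathbf{1}\mathbf{1}^\top - I)} (rows
#' renormalised to sum to one) and uniform initial distribution.
#'
#' @param c channel count (one excitatory + one inhibitory population per
#'   channel, so `n = 2c`).
#' @param nS number of modulation regimes.
#' @param T_steps timesteps to simulate (20000 = 80 s at 250 Hz).
#' @param A optional nS-by-nS HMM transition matrix (rows renormalised).
#' @param pi_init optional initial regime distribution (renormalised).
#' @param process_scale scalar multiplying the identity for the process-noise
#'   covariance; `NULL` (default) draws `0.2 + 0.1 U(0,1)` per model. Set
#'   explicitly for noise sweeps.
#' @param meas_scale measurement-noise variance per channel (default 0.25).
#' @param gamma_mu mean/sd of the Gaussian generating each regime's factor
#'   mean \eqn{\mu_i}.
#' @param gamma_sigma_uniform,gamma_sigma_normal mean/sd of the Gaussians
#'   generating the factor spread \eqn{\sigma_i} when the factor distribution
#'   is uniform resp. normal.
#' @param sparsity fraction of off-diagonal EE/EI entries zeroed (default
#'   0.75).
#' @param wii_dist,wie_dist functions `n -> magnitudes` for the diagonal
#'   inhibitory-source weights (negated internally). Defaults:
#'   `0.65 + 0.02 U(0,1)` for `W_ii`, `(16/20) U(0,1)^3 + 0.2` for `W_ie`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(c = 10, nS = 3, T_steps = 20000,
                             A = NULL, pi_init = NULL,
                             process_scale = NULL, meas_scale = 0.25,
                             gamma_mu = c(1, 0.1),
                             gamma_sigma_uniform = c(0.4, 0.1),
                             gamma_sigma_normal = c(0.05, 0.01),
                             sparsity = 0.75,
                             wii_dist = NULL, wie_dist = NULL) {
  if (nS < 1 || T_steps < 1) stop("nS and T_steps must be >= 1", call. = FALSE)
  if (is.null(A)) {
    A <- 0.999 * diag(nS) + (0.001 / nS) * (matrix(1, nS, nS) - diag(nS))
  }
  A <- A / rowSums(A)
  if (is.null(pi_init)) pi_init <- rep(1 / nS, nS)
  pi_init <- pi_init / sum(pi_init)
  if (is.null(wii_dist)) wii_dist <- function(n) 0.65 + 0.02 * runif(n)
  if (is.null(wie_dist)) wie_dist <- function(n) (16 / 20) * runif(n)^3 + 0.2
  structure(list(
    c = as.integer(c), nS = as.integer(nS), T_steps = as.integer(T_steps),
    A = A, pi_init = pi_init,
    process_scale = process_scale, meas_scale = meas_scale,
    gamma_mu = gamma_mu, gamma_sigma_uniform = gamma_sigma_uniform,
    gamma_sigma_normal = gamma_sigma_normal,
    sparsity = sparsity, wii_dist = wii_dist, wie_dist = wie_dist
  ), class = "synthetic_config")
}

#' Sample one excitatory-source connectivity block
#'
#' Builds a c-by-c nonnegative block as sparse + low-rank + diagonal,
#' \eqn{W_s + W_{l1} W_{l2}^\top + \mathrm{diag}(w)}, then zeroes a random
#' `sparsity` fraction of its off-diagonal entries. The low-rank factors are
#' c-by-floor(c/4). The applied mask is returned so it can serve as the
#' ground-truth support at fit time.
#'
#' @param c block size (must be >= 4 so the low-rank factors are nonempty).
#' @param sparsity off-diagonal zero fraction (default 0.75).
#' @return `list(W = c-by-c matrix, mask = c-by-c binary matrix)`.
#' @export
construct_connectivity_block <- function(c, sparsity = 0.75) {
  if (c < 4) stop("c must be >= 4 (low-rank factors are c x floor(c/4))",
                  call. = FALSE)
  r <- floor(c / 4)
  W_s <- matrix((16 / 20) * runif(c * c)^3, c, c)
  W_l1 <- matrix(runif(c * r)^3 + 0.2 * runif(c * r), c, r)
  W_l2 <- matrix(runif(c * r)^3 + 0.2 * runif(c * r), c, r)
  W <- W_s + tcrossprod(W_l1, W_l2) + diag((16 / 20) * runif(c)^3, c)
  off <- which(row(W) != col(W))
  nzero <- round(sparsity * length(off))
  zero_at <- sample(off, nzero)
  mask <- matrix(1, c, c)
  mask[zero_at] <- 0
  list(W = W * mask, mask = mask)
}

#' Sample one rank-1 modulation matrix
#'
#' Draws a regime mean \eqn{\mu_i \sim N(1, 0.1)}, picks uniform or normal
#' factor noise with equal probability, draws the spread \eqn{\sigma_i} from
#' the matching distribution, samples the length-n factor vector, clamps it
#' at zero, and returns its outer product with itself.
#'
#' @param n vector length (number of populations).
#' @param cfg a [synthetic_config()].
#' @return `list(vec = length-n factor, G = n-by-n rank-1 matrix)`.
#' @export
sample_modulation_matrix <- function(n, cfg = synthetic_config()) {
  mu <- rnorm(1, cfg$gamma_mu[1], cfg$gamma_mu[2])
  use_uniform <- runif(1) < 0.5
  if (use_uniform) {
    sig <- rnorm(1, cfg$gamma_sigma_uniform[1], cfg$gamma_sigma_uniform[2])
    sig <- abs(sig)
    v <- runif(n, mu - sig / 2, mu + sig / 2)
  } else {
    sig <- abs(rnorm(1, cfg$gamma_sigma_normal[1], cfg$gamma_sigma_normal[2]))
    v <- rnorm(n, mu, sig)
  }
  v <- pmax(v, 0)
  list(vec = v, G = tcrossprod(v))
}

#' Sample a complete ground-truth model
#'
#' Draws baseline connectivity (EE and EI blocks sparse + low-rank, IE and II
#' diagonal negative), slopes/decays/offsets per the generating table, `nS`
#' rank-1 modulation matrices, a standard-normal excitatory lead field and
#' diagonal noise covariances.
#'
#' @param cfg a [synthetic_config()].
#' @return `list(params = mindy_params, obs = mindy_obs)`.
#' @export
sample_ground_truth_model <- function(cfg = synthetic_config()) {
  c <- cfg$c; n <- 2L * c
  ee <- construct_connectivity_block(c, cfg$sparsity)
  ei <- construct_connectivity_block(c, cfg$sparsity)
  W <- matrix(0, n, n)
  e <- seq_len(c); i <- c + seq_len(c)
  W[e, e] <- ee$W
  W[i, e] <- ei$W
  W[e, i] <- diag(-cfg$wie_dist(c), c)
  W[i, i] <- diag(-cfg$wii_dist(c), c)
  mask <- matrix(0, n, n)
  mask[e, e] <- ee$mask
  mask[i, e] <- ei$mask
  mask[e, i][cbind(e, e)] <- 1
  mask[i, i][cbind(e, e)] <- 1
  Gamma <- lapply(seq_len(cfg$nS), function(k) {
    g <- sample_modulation_matrix(n, cfg)
    list(a = g$vec, b = g$vec)
  })
  S <- c(rep(2.5, c), rep(1, c))
  D <- c(0.65 + 0.02 * runif(c), 0.8 + 0.02 * runif(c))
  params <- mindy_params(c, c, W, Gamma, S = S, V = rep(0, n),
                         D = D, C = rep(0, n), mask = mask)
  H_exc <- matrix(rnorm(c * c), c, c)
  H <- cbind(H_exc, matrix(0, c, c))
  pscale <- if (is.null(cfg$process_scale)) 0.2 + 0.1 * runif(1) else
    cfg$process_scale
  obs <- mindy_obs(H, pscale * diag(n), cfg$meas_scale * diag(c), n_inh = c)
  list(params = params, obs = obs)
}

#' Sample an HMM regime-label sequence
#'
#' @param cfg a [synthetic_config()]; uses its transition matrix `A`,
#'   initial distribution, and `T_steps`.
#' @return Integer vector of length `T_steps` with values in `1..nS`.
#' @export
sample_regime_sequence <- function(cfg = synthetic_config()) {
  A <- cfg$A
  if (any(A < 0) || max(abs(rowSums(A) - 1)) > 1e-8) {
    stop("transition matrix rows must be nonnegative and sum to 1",
         call. = FALSE)
  }
  nS <- cfg$nS
  labs <- integer(cfg$T_steps)
  labs[1] <- sample.int(nS, 1, prob = cfg$pi_init)
  if (cfg$T_steps >= 2) {
    u <- runif(cfg$T_steps - 1)
    cumA <- t(apply(A, 1, cumsum))
    for (t in 2:cfg$T_steps) {
      labs[t] <- findInterval(u[t - 1], cumA[labs[t - 1], ],
                              left.open = TRUE) + 1L
    }
  }
  labs
}

#' Forward-simulate a model under a regime sequence
#'
#' Iterates [step_dynamics()] from the origin with i.i.d. Gaussian process
#' noise and maps each state through the lead field with Gaussian measurement
#' noise. Fails loudly (naming the step) if the state diverges.
#'
#' @param params a `mindy_params` object.
#' @param obs a `mindy_obs` object.
#' @param regimes integer regime label per timestep.
#' @param rate_hz nominal sampling rate attached to the output (default 250).
#' @param x0 initial state (default zero).
#' @return `list(latent = T-by-n matrix, recording = mindy_recording)`.
#' @export
simulate_recording <- function(params, obs, regimes, rate_hz = 250,
                               x0 = NULL) {
  n <- params$n_exc + params$n_inh
  c <- nrow(obs$H)
  T_steps <- length(regimes)
  if (any(regimes < 1 | regimes > params$m)) {
    stop("regime labels out of range", call. = FALSE)
  }
  if (is.null(x0)) x0 <- rep(0, n)
  q_sd <- sqrt(diag(obs$process_cov))
  r_sd <- sqrt(diag(obs$meas_cov))
  M <- lapply(seq_len(params$m), function(k) params$W * params$Gamma[[k]])
  act <- activation_fun(params)
  dsgn <- if (params$decay == "leak") -1 else 1
  X <- matrix(0, T_steps, n)
  Y <- matrix(0, T_steps, c)
  x <- x0
  Ht <- t(obs$H)
  for (t in seq_len(T_steps)) {
    eps <- rnorm(n) * q_sd
    x <- x + drop(M[[regimes[t]]] %*% act$phi(params$S * x + params$V)) +
      dsgn * params$D * x + params$C + eps
    if (any(!is.finite(x))) {
      stop(sprintf("simulation diverged at step %d", t), call. = FALSE)
    }
    X[t, ] <- x
    Y[t, ] <- drop(x %*% Ht) + rnorm(c) * r_sd
  }
  rec <- mindy_recording(Y, rate_hz = rate_hz, labels = regimes)
  list(latent = X, recording = rec)
}

#' Generate a complete labelled ground-truth dataset
#'
#' Convenience wrapper: seeds the RNG, samples a model, a regime sequence and
#' a simulated recording.
#'
#' @param cfg a [synthetic_config()].
#' @param seed optional integer seed.
#' @return `list(params, obs, regimes, latent, recording)`.
#' @export
generate_ground_truth <- function(cfg = synthetic_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mdl <- sample_ground_truth_model(cfg)
  regimes <- sample_regime_sequence(cfg)
  sim <- simulate_recording(mdl$params, mdl$obs, regimes)
  list(params = mdl$params, obs = mdl$obs, regimes = regimes,
       latent = sim$latent, recording = sim$recording)
}
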