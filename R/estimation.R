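# Dual estimation: extended Kalman filtering for the latent state on random
# data windows, free-run prediction, and NADAM learning of all parameters
# from gradients propagated through the filtering and free-run errors
# (compiled kernel in src/window_kernel.cpp).

#' Fitting configuration
#'
#' @param window_len Kalman-filter steps per window (default 20).
#' @param freerun_len free-run prediction steps per window (default 10).
#' @param burnin filter steps at the start of each window excluded from the
#'   loss (they still update the state estimate). Each window restarts the
#'   filter at the origin with unit covariance, so the first few innovations
#'   reflect the warm-up transient rather than model fit.
#' @param lr NADAM step size.
#' @param batch_windows windows whose gradients are averaged per NADAM step
#'   (default 1). Larger batches reduce gradient noise at proportional cost.
#' @param max_windows cap on optimiser steps.
#' @param tol relative smoothed-loss convergence tolerance.
#' @param patience plateau length (windows) for convergence.
#' @param fix_gamma1 force the first modulation matrix to all-ones (baseline
#'   regime convention for labelled real data).
#' @param learn_noise learn the log-diagonal process/measurement noise
#'   covariances from the innovation likelihood.
#' @param learn character vector of parameter groups to update; any subset of
#'   `c("W", "Gamma", "S", "V", "D", "C")`.
#' @param filter_weight,freerun_weight relative weights of the mean squared
#'   filter innovation and free-run errors in the training loss.
#' @param gamma_ridge strength of the quadratic pull of the modulation
#'   factor vectors toward 1. The Hadamard factorisation `W * (a b')` is
#'   invariant to rank-1 rescalings shared across regimes; this term damps
#'   stochastic drift along that unidentified direction without constraining
#'   the data-identified effective connectivity.
#' @param lr_decay `"cosine"` anneals the step size from `lr` to
#'   `lr_min` over `max_windows` (reduces the stochastic-gradient noise
#'   floor); `"none"` keeps it constant.
#' @param lr_min floor of the annealed step size.
#' @param beta1,beta2,eps NADAM moment decay rates and stabiliser.
#' @param ema smoothing factor for the convergence-tracking loss average.
#' @param average_tail fraction of the window budget over which the returned
#'   parameters are averaged (Polyak tail averaging; 0 disables). Averaging
#'   the stochastic-gradient iterates removes most of the residual
#'   window-to-window jitter.
#' @param init_w_sd,init_gamma_sd standard deviations of the random
#'   initialisation of `W` (half-normal magnitudes) and of the modulation
#'   factor vectors around 1.
#' @param init_wie,init_wii initial magnitudes of the diagonal
#'   inhibitory-to-excitatory and inhibitory self weights (negated). These
#'   start at typical physiological size so the unobserved inhibitory loops
#'   carry influence from the first window.
#' @param seed optional integer seed; all window selection and
#'   initialisation randomness flows from it.
#' @return A `fit_config` list.
#' @export
fit_config <- function(window_len = 20, freerun_len = 10, burnin = 0,
                       lr = 2e-3, batch_windows = 1,
                       max_windows = 10000, tol = 1e-6, patience = 5000,
                       fix_gamma1 = FALSE, learn_noise = TRUE,
                       learn = c("W", "Gamma", "S", "V", "D", "C"),
                       filter_weight = 1, freerun_weight = 0.1,
                       gamma_ridge = 0.1,
                       lr_decay = c("cosine", "none"), lr_min = 1e-4,
                       beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, ema = 0.02, average_tail = 0.25,
                       init_w_sd = 0.3, init_gamma_sd = 0.05,
                       init_wie = 0.4, init_wii = 0.66, seed = NULL) {
  lr_decay <- match.arg(lr_decay)
  stopifnot(window_len >= 2, freerun_len >= 1, lr > 0, tol > 0,
            burnin >= 0, burnin < window_len)
  structure(as.list(environment()), class = "fit_config")
}

#' Extended Kalman filter over a data window
#'
#' Standard EKF recursion for the modulated dynamics, with the Jacobian of
#' [step_dynamics()] evaluated at the current filtered state and the
#' regime-indexed effective connectivity selected per step from `labels`.
#'
#' @param params a `mindy_params` object.
#' @param obs a `mindy_obs` object (diagonal covariances).
#' @param segment L-by-c matrix of observations.
#' @param labels length-L regime labels.
#' @param x0 initial state mean (default zero).
#' @param P0 initial state covariance (default identity).
#' @return `list(states = L-by-n filtered means, innovations = L-by-c,
#'   pred_meas = L-by-c one-step predicted measurements, P = final covariance)`.
#' @export
ekf_window <- function(params, obs, segment, labels, x0 = NULL, P0 = NULL) {
  segment <- as.matrix(segment)
  L <- nrow(segment)
  n <- params$n_exc + params$n_inh
  c <- nrow(obs$H)
  if (length(labels) != L) stop("labels must align with the segment",
                                call. = FALSE)
  if (is.null(x0)) x0 <- rep(0, n)
  if (is.null(P0)) P0 <- diag(n)
  if (any(eigen(P0, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("P0 must be positive semi-definite", call. = FALSE)
  }
  H <- obs$H; Q <- obs$process_cov; R <- obs$meas_cov
  states <- matrix(0, L, n)
  innov <- matrix(0, L, c)
  pred <- matrix(0, L, c)
  x <- x0; P <- P0
  for (t in seq_len(L)) {
    xp <- step_dynamics(x, params, labels[t])
    Fj <- dynamics_jacobian(x, params, labels[t])
    Pp <- Fj %*% P %*% t(Fj) + Q
    St <- H %*% Pp %*% t(H) + R
    St <- (St + t(St)) / 2
    e <- segment[t, ] - drop(H %*% xp)
    Sinv <- tryCatch(chol2inv(chol(St)), error = function(err) {
      stop(sprintf("singular innovation covariance at step %d", t),
           call. = FALSE)
    })
    K <- Pp %*% t(H) %*% Sinv
    x <- xp + drop(K %*% e)
    P <- (diag(n) - K %*% H) %*% Pp
    P <- (P + t(P)) / 2
    if (any(!is.finite(x)) || any(!is.finite(P))) {
      stop(sprintf("numerical failure in Kalman recursion at step %d", t),
           call. = FALSE)
    }
    states[t, ] <- x
    innov[t, ] <- e
    pred[t, ] <- drop(H %*% xp)
  }
  list(states = states, innovations = innov, pred_meas = pred, P = P)
}

#' Noise-free forward prediction
#'
#' Iterates [step_dynamics()] without noise from `x0` for `horizon` steps and
#' maps each state through the lead field.
#'
#' @param params a `mindy_params` object.
#' @param obs a `mindy_obs` object.
#' @param x0 length-n start state.
#' @param horizon number of prediction steps.
#' @param labels length-`horizon` regime labels.
#' @return horizon-by-c matrix of predicted measurements.
#' @export
free_run <- function(params, obs, x0, horizon, labels) {
  stopifnot(horizon >= 1, length(labels) >= horizon)
  c <- nrow(obs$H)
  out <- matrix(0, horizon, c)
  x <- x0
  for (h in seq_len(horizon)) {
    x <- step_dynamics(x, params, labels[h])
    out[h, ] <- observe(x, obs)
  }
  out
}

#' Window training loss
#'
#' Sum of squared Kalman innovations over the filter window plus sum of
#' squared free-run prediction errors, with optional relative weights.
#'
#' @param innovations L-by-c innovation matrix.
#' @param freerun_pred F-by-c free-run predictions.
#' @param observed F-by-c observations aligned with the free run.
#' @param filter_weight,freerun_weight relative weights (default 1).
#' @return Nonnegative scalar; zero iff both residual sets are zero.
#' @export
training_loss <- function(innovations, freerun_pred, observed,
                          filter_weight = 1, freerun_weight = 1) {
  stopifnot(all(dim(freerun_pred) == dim(observed)))
  filter_weight * sum(innovations^2) +
    freerun_weight * sum((freerun_pred - observed)^2)
}

#' Draw a random window start index
#'
#' Uniform over all start indices such that `window_len + freerun_len`
#' consecutive samples fit inside one contiguous segment (fit windows never
#' cross recording-file boundaries).
#'
#' @param T_steps total number of timesteps.
#' @param window_len,freerun_len window and free-run lengths.
#' @param boundaries integer vector of segment start indices (default `1`).
#' @return A single start index (1-based).
#' @export
select_window <- function(T_steps, window_len, freerun_len, boundaries = 1L) {
  need <- window_len + freerun_len
  if (T_steps < need) stop("recording shorter than window + free run",
                           call. = FALSE)
  starts <- sort(unique(c(1L, as.integer(boundaries))))
  ends <- c(starts[-1] - 1L, T_steps)
  valid <- unlist(lapply(seq_along(starts), function(j) {
    hi <- ends[j] - need + 1L
    if (hi >= starts[j]) starts[j]:hi else integer(0)
  }))
  if (length(valid) == 0L) stop("no segment can hold window + free run",
                                call. = FALSE)
  valid[sample.int(length(valid), 1L)]
}

# ---- internal machinery -----------------------------------------------------

gamma_cube <- function(ga, gb) {
  n <- nrow(ga); m <- ncol(ga)
  arr <- array(0, c(n, n, m))
  for (k in seq_len(m)) arr[, , k] <- tcrossprod(ga[, k], gb[, k])
  arr
}

# Random initialisation of the fitted parameters: half-normal magnitudes
# with block signs for the excitatory-source blocks, factors near 1 for
# Gamma, decays at block midpoints, slopes at the generating values. The
# inhibitory-source diagonals start at typical physiological magnitudes
# (init_wie / init_wii): if an inhibitory loop starts near zero the filter
# assigns it no influence, its gradient vanishes and the population stays
# dead, so the inhibitory weights must be born alive.
init_fit_params <- function(n_exc, n_inh, m, mask, cfg) {
  n <- n_exc + n_inh
  e <- seq_len(n_exc); i <- n_exc + seq_len(n_inh)
  W <- matrix(abs(rnorm(n * n, 0, cfg$init_w_sd)), n, n)
  W[, i] <- 0
  W[e, i][cbind(seq_len(n_exc), seq_len(n_inh))] <-
    -abs(rnorm(n_inh, cfg$init_wie, 0.1))
  W[i, i][cbind(seq_len(n_inh), seq_len(n_inh))] <-
    -abs(rnorm(n_inh, cfg$init_wii, 0.1))
  W <- W * mask
  ga <- matrix(pmax(1 + rnorm(n * m, 0, cfg$init_gamma_sd), 0), n, m)
  gb <- matrix(pmax(1 + rnorm(n * m, 0, cfg$init_gamma_sd), 0), n, m)
  if (cfg$fix_gamma1) { ga[, 1] <- 1; gb[, 1] <- 1 }
  list(W = W, ga = ga, gb = gb,
       S = c(rep(2.5, n_exc), rep(1, n_inh)), V = rep(0, n),
       D = c(rep(0.66, n_exc), rep(0.81, n_inh)), C = rep(0, n))
}

nadam_new <- function(template) {
  list(m = lapply(template, function(x) x * 0),
       v = lapply(template, function(x) x * 0), t = 0L)
}

nadam_step <- function(state, theta, grads, cfg) {
  state$t <- state$t + 1L
  b1 <- cfg$beta1; b2 <- cfg$beta2
  bc1 <- 1 - b1^state$t; bc2 <- 1 - b2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- (b1 * mhat + (1 - b1) * g / bc1) / (sqrt(vhat) + cfg$eps)
    theta[[nm]] <- theta[[nm]] - cfg$lr * upd
  }
  list(state = state, theta = theta)
}

# projection of the flat fit state onto the constraint set (mirrors
# project_constraints() but operates on the fit representation)
project_fit_state <- function(th, n_exc, n_inh, mask, cfg) {
  n <- n_exc + n_inh
  e <- seq_len(n_exc); i <- n_exc + seq_len(n_inh)
  W <- th$W
  W[, e][W[, e] < 0] <- 0
  W[, i][W[, i] > 0] <- 0
  ie <- W[e, i, drop = FALSE]; ie[row(ie) != col(ie)] <- 0
  ii <- W[i, i, drop = FALSE]; ii[row(ii) != col(ii)] <- 0
  W[e, i] <- ie; W[i, i] <- ii
  th$W <- W * mask
  th$ga[th$ga < 0] <- 0
  th$gb[th$gb < 0] <- 0
  if (cfg$fix_gamma1) { th$ga[, 1] <- 1; th$gb[, 1] <- 1 }
  eps <- 1e-6
  th$D <- pmin(pmax(th$D, eps), 1 - eps)
  th$S <- pmax(th$S, eps)
  th
}

# single-window loss + gradients at the current fit state (used by fit_mindy
# and by the finite-difference tests)
window_gradients <- function(th, H, Y, labels, cfg, n_exc, n_inh,
                             identity_act = FALSE, decay_sign = -1,
                             want_grad = TRUE) {
  n <- n_exc + n_inh
  L <- cfg$window_len; F <- cfg$freerun_len
  b <- cfg$burnin
  sf <- cfg$filter_weight / ((L - b) * nrow(H))
  sfr <- cfg$freerun_weight / (F * nrow(H))
  .mm_window_kernel(th$W, gamma_cube(th$ga, th$gb), th$S, th$V, th$D, th$C,
                    H, exp(th$logq), exp(th$logr), Y,
                    as.integer(labels), rep(0, n), diag(n),
                    L, F, b, sf, sfr, identity_act, decay_sign,
                    want_grad)
}

#' Fit a modulated neural-mass model
#'
#' Dual estimation loop: repeatedly select a random data window, run the
#' extended Kalman filter over it, free-run the model forward, and take one
#' NADAM step on all unfrozen parameters using reverse-mode gradients of the
#' combined filter + free-run squared error (the Kalman gains are recomputed
#' every window and held fixed within each backward pass). Noise covariances,
#' when learned, follow the gradient of the Gaussian innovation likelihood.
#' After every step the parameters are projected back onto the constraint
#' set (sign blocks, mask support, nonnegative rank-1 modulation factors).
#'
#' The lead field `H` is taken from `obs` and treated as known; the noise
#' covariances in `obs` initialise the learned covariances.
#'
#' @param recording a `mindy_recording` (or T-by-c matrix).
#' @param labels per-timestep regime labels; defaults to the recording's
#'   labels, or all-ones (single regime) when absent.
#' @param obs a `mindy_obs` with the known lead field and initial noise
#'   covariances.
#' @param cfg a [fit_config()].
#' @param init optional `mindy_params` to start from (otherwise random
#'   initialisation).
#' @param mask n-by-n support mask applied to `W` during fitting. For
#'   synthetic data pass the ground-truth mask; if `NULL`, a random mask
#'   zeroing 75% of the EE/EI off-diagonals is drawn once from the seed.
#' @return `list(params, obs, diagnostics)` where `diagnostics` holds the
#'   per-window loss trace, convergence flag, window count and final
#'   covariance diagonals.
#' @export
fit_mindy <- function(recording, labels = NULL, obs, cfg = fit_config(),
                      init = NULL, mask = NULL) {
  if (inherits(recording, "mindy_recording")) {
    Ydata <- recording$data
    if (is.null(labels)) labels <- recording$labels
    boundaries <- recording$boundaries
  } else {
    Ydata <- as.matrix(recording)
    boundaries <- 1L
  }
  T_steps <- nrow(Ydata)
  if (is.null(labels)) labels <- rep(1L, T_steps)
  labels <- as.integer(labels)
  if (length(labels) != T_steps) stop("labels must align with the recording",
                                      call. = FALSE)
  m <- max(labels)
  c <- ncol(Ydata)
  n <- ncol(obs$H)
  n_inh <- obs$n_inh
  n_exc <- n - n_inh
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (is.null(mask)) mask <- random_support_mask(n_exc, n_inh)
  identity_act <- FALSE; decay_sign <- -1
  if (!is.null(init)) {
    identity_act <- init$activation == "identity"
    decay_sign <- if (init$decay == "leak") -1 else 1
    ga <- init$gamma_a; gb <- init$gamma_b
    if (is.null(ga)) {
      ga <- matrix(1, n, init$m); gb <- matrix(1, n, init$m)
      for (k in seq_len(init$m)) {
        sv <- svd(init$Gamma[[k]])
        ga[, k] <- sv$u[, 1] * sqrt(sv$d[1])
        gb[, k] <- sv$v[, 1] * sqrt(sv$d[1])
        if (mean(ga[, k]) < 0) { ga[, k] <- -ga[, k]; gb[, k] <- -gb[, k] }
      }
    }
    th <- list(W = init$W, ga = ga, gb = gb, S = init$S, V = init$V,
               D = init$D, C = init$C)
    m <- init$m
  } else {
    th <- init_fit_params(n_exc, n_inh, m, mask, cfg)
  }
  th$logq <- log(pmax(diag(obs$process_cov), 1e-8))
  th$logr <- log(pmax(diag(obs$meas_cov), 1e-8))

  grad_names <- character(0)
  if ("W" %in% cfg$learn) grad_names <- c(grad_names, "W")
  if ("Gamma" %in% cfg$learn && !(m == 1 && cfg$fix_gamma1)) {
    grad_names <- c(grad_names, "ga", "gb")
  }
  for (nm in c("S", "V", "D", "C")) {
    if (nm %in% cfg$learn) grad_names <- c(grad_names, nm)
  }
  if (cfg$learn_noise) grad_names <- c(grad_names, "logq", "logr")

  opt <- nadam_new(th[grad_names])
  need <- cfg$window_len + cfg$freerun_len
  loss_trace <- matrix(NA_real_, cfg$max_windows, 2,
                       dimnames = list(NULL, c("filter", "freerun")))
  smoothed <- rep(NA_real_, cfg$max_windows)
  converged <- FALSE
  w <- 0L
  avg_from <- if (cfg$average_tail > 0) {
    max(1L, ceiling((1 - cfg$average_tail) * cfg$max_windows))
  } else Inf
  th_avg <- NULL; n_avg <- 0L
  e_rows <- seq_len(n_exc); i_rows <- n_exc + seq_len(n_inh)
  B <- max(1L, as.integer(cfg$batch_windows))
  while (w < cfg$max_windows) {
    w <- w + 1L
    res <- NULL
    for (b in seq_len(B)) {
      s <- select_window(T_steps, cfg$window_len, cfg$freerun_len, boundaries)
      idx <- s:(s + need - 1L)
      res_b <- window_gradients(th, obs$H, Ydata[idx, , drop = FALSE],
                                labels[idx], cfg, n_exc, n_inh,
                                identity_act, decay_sign)
      if (is.null(res)) {
        res <- res_b
      } else {
        for (nm in c("loss_filter", "loss_freerun", "loss", "gW", "gGamma",
                     "gS", "gV", "gD", "gC", "g_logq", "g_logr")) {
          res[[nm]] <- res[[nm]] + res_b[[nm]]
        }
      }
    }
    if (B > 1L) {
      for (nm in c("loss_filter", "loss_freerun", "loss", "gW", "gGamma",
                   "gS", "gV", "gD", "gC", "g_logq", "g_logr")) {
        res[[nm]] <- res[[nm]] / B
      }
    }
    if (!is.finite(res$loss)) {
      stop(sprintf("training loss diverged at step %d", w), call. = FALSE)
    }
    loss_trace[w, ] <- c(res$loss_filter, res$loss_freerun)
    grads <- list()
    if ("W" %in% grad_names) {
      gW <- res$gW * mask
      ie <- gW[e_rows, i_rows, drop = FALSE]
      ie[row(ie) != col(ie)] <- 0
      ii <- gW[i_rows, i_rows, drop = FALSE]
      ii[row(ii) != col(ii)] <- 0
      gW[e_rows, i_rows] <- ie; gW[i_rows, i_rows] <- ii
      grads$W <- gW
    }
    if ("ga" %in% grad_names) {
      gG <- res$gGamma
      ga_g <- matrix(0, n, m); gb_g <- matrix(0, n, m)
      for (k in seq_len(m)) {
        if (cfg$fix_gamma1 && k == 1L) next
        ga_g[, k] <- gG[, , k] %*% th$gb[, k] +
          cfg$gamma_ridge * (th$ga[, k] - 1)
        gb_g[, k] <- crossprod(gG[, , k], th$ga[, k]) +
          cfg$gamma_ridge * (th$gb[, k] - 1)
      }
      grads$ga <- ga_g; grads$gb <- gb_g
    }
    for (nm in c("S", "V", "D", "C")) {
      if (nm %in% grad_names) grads[[nm]] <- drop(res[[paste0("g", nm)]])
    }
    if (cfg$learn_noise) {
      grads$logq <- drop(res$g_logq)
      grads$logr <- drop(res$g_logr)
    }
    cfg_w <- cfg
    if (cfg$lr_decay == "cosine") {
      frac <- w / cfg$max_windows
      cfg_w$lr <- cfg$lr_min + 0.5 * (cfg$lr - cfg$lr_min) *
        (1 + cos(pi * frac))
    }
    st <- nadam_step(opt, th, grads, cfg_w)
    opt <- st$state; th <- st$theta
    th <- project_fit_state(th, n_exc, n_inh, mask, cfg)

    if (w >= avg_from) {
      n_avg <- n_avg + 1L
      if (is.null(th_avg)) {
        th_avg <- th
      } else {
        for (nm in names(th)) {
          th_avg[[nm]] <- th_avg[[nm]] + (th[[nm]] - th_avg[[nm]]) / n_avg
        }
      }
    }

    tot <- res$loss
    smoothed[w] <- if (w == 1L) tot else
      cfg$ema * tot + (1 - cfg$ema) * smoothed[w - 1L]
    if (w > cfg$patience) {
      ref <- smoothed[w - cfg$patience]
      if (is.finite(ref) && ref > 0 &&
          abs(smoothed[w] - ref) / ref < cfg$tol) {
        converged <- TRUE
        break
      }
    }
  }

  if (!is.null(th_avg)) {
    th <- project_fit_state(th_avg, n_exc, n_inh, mask, cfg)
  }
  Gamma <- lapply(seq_len(m), function(k) list(a = th$ga[, k], b = th$gb[, k]))
  params <- mindy_params(n_exc, n_inh, th$W, Gamma, th$S, th$V, th$D, th$C,
                         mask = mask,
                         activation = if (identity_act) "identity" else "tanh",
                         decay = if (decay_sign < 0) "leak" else "literal")
  obs_out <- mindy_obs(obs$H, diag(exp(th$logq), n), diag(exp(th$logr), c),
                       n_inh = n_inh)
  diagnostics <- list(
    loss_trace = loss_trace[seq_len(w), , drop = FALSE],
    converged = converged, windows_used = w,
    process_var = exp(th$logq), meas_var = exp(th$logr)
  )
  list(params = params, obs = obs_out, diagnostics = diagnostics)
}

#' Random 75% support mask for unknown true sparsity
#'
#' When fitting real data the true zero pattern is unknown; a random 75% of
#' the off-diagonal EE and EI entries is zeroed once (seeded by the caller)
#' and shared across subjects.
#'
#' @param n_exc,n_inh population counts.
#' @param sparsity off-diagonal zero fraction (default 0.75).
#' @return n-by-n binary mask (inhibitory-source blocks diagonal-only).
#' @export
random_support_mask <- function(n_exc, n_inh, sparsity = 0.75) {
  n <- n_exc + n_inh
  e <- seq_len(n_exc); i <- n_exc + seq_len(n_inh)
  mask <- matrix(0, n, n)
  for (rows in list(e, i)) {
    blk <- matrix(1, length(rows), n_exc)
    off <- which(row(blk) != col(blk))
    blk[sample(off, round(sparsity * length(off)))] <- 0
    mask[rows, e] <- blk
  }
  mask[e, i][cbind(seq_len(n_exc), seq_len(n_inh))] <- 1
  mask[i, i][cbind(seq_len(n_inh), seq_len(n_inh))] <- 1
  mask
}
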