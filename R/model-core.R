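# Core model objects and pure dynamical operations.
#
# Population ordering is excitatory-then-inhibitory everywhere. W is stored
# with source populations on columns, so the block layout is
#   [ W_ee  W_ie ]   rows 1..n_exc        (targets: excitatory)
#   [ W_ei  W_ii ]   rows n_exc+1..n      (targets: inhibitory)
# Excitatory-source columns (left blocks) are >= 0, inhibitory-source columns
# (right blocks) are <= 0 and diagonal within their block.

#' Construct a modulated neural-mass parameter set
#'
#' Bundles the baseline connectivity `W`, the regime-specific modulation
#' matrices `Gamma`, the activation slope/offset `S`/`V`, the per-step decay
#' `D`, the baseline drive `C` and the sparsity `mask` into a validated
#' `mindy_params` object.
#'
#' The dynamics of the model are
#' \deqn{x_{t+1} = x_t + (W \odot \Gamma_i)\,\tanh(S \odot x_t + V) - D \odot x_t + C + \epsilon_t,}
#' where \eqn{i} is the active modulation regime at time \eqn{t}. Each
#' \eqn{\Gamma_i} is a nonnegative rank-1 matrix, stored both as the full
#' matrix and (optionally) as its two factor vectors `a`, `b` with
#' \eqn{\Gamma_i = a b^\top}.
#'
#' @param n_exc,n_inh counts of excitatory and inhibitory populations;
#'   `n = n_exc + n_inh`.
#' @param W n-by-n baseline connectivity (signed E/I block structure).
#' @param Gamma list of `m` n-by-n nonnegative rank-1 modulation matrices, or
#'   a list of `list(a =, b =)` factor pairs from which the matrices are built.
#' @param S,V length-n activation slope (positive) and offset.
#' @param D length-n per-step decay in (0, 1).
#' @param C length-n baseline drive.
#' @param mask n-by-n binary support matrix (1 = connection allowed). Defaults
#'   to all ones.
#' @param activation `"tanh"` (model) or `"identity"` (linear test hook).
#' @param decay `"leak"` applies `- D * x` (default); `"literal"` applies
#'   `+ D * x`, the unstabilised sign variant, retained as a switch.
#' @param validate validate invariants on construction (default `TRUE`).
#'
#' @return An object of class `mindy_params`.
#' @seealso [project_constraints()], [step_dynamics()],
#'   [effective_connectivity()]
#' @export
mindy_params <- function(n_exc, n_inh, W, Gamma, S, V, D, C,
                         mask = NULL, activation = c("tanh", "identity"),
                         decay = c("leak", "literal"), validate = TRUE) {
  activation <- match.arg(activation)
  decay <- match.arg(decay)
  n <- n_exc + n_inh
  if (is.null(mask)) mask <- matrix(1, n, n)
  gamma_a <- gamma_b <- NULL
  if (length(Gamma) > 0L && is.list(Gamma[[1L]])) {
    gamma_a <- vapply(Gamma, function(g) as.numeric(g$a), numeric(n))
    gamma_b <- vapply(Gamma, function(g) as.numeric(g$b), numeric(n))
    gamma_a <- matrix(gamma_a, nrow = n)
    gamma_b <- matrix(gamma_b, nrow = n)
    Gamma <- lapply(seq_along(Gamma), function(i) {
      tcrossprod(gamma_a[, i], gamma_b[, i])
    })
  }
  p <- structure(
    list(
      n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
      m = length(Gamma),
      W = W, Gamma = Gamma, gamma_a = gamma_a, gamma_b = gamma_b,
      S = as.numeric(S), V = as.numeric(V),
      D = as.numeric(D), C = as.numeric(C),
      mask = mask, activation = activation, decay = decay
    ),
    class = "mindy_params"
  )
  if (validate) validate_params(p)
  p
}

#' @export
print.mindy_params <- function(x, ...) {
  cat(sprintf(
    "<mindy_params> %d exc + %d inh populations, %d regime(s), activation=%s\n",
    x$n_exc, x$n_inh, x$m, x$activation
  ))
  free <- sum(x$mask != 0)
  cat(sprintf("  W: %dx%d (%d unmasked entries); decay in [%.3f, %.3f]\n",
              nrow(x$W), ncol(x$W), free, min(x$D), max(x$D)))
  invisible(x)
}

exc_idx <- function(p) seq_len(p$n_exc)
inh_idx <- function(p) p$n_exc + seq_len(p$n_inh)

#' Validate a `mindy_params` object
#'
#' Checks the block sign structure of `W`, diagonality of the
#' inhibitory-source blocks, mask consistency, nonnegativity and rank of every
#' modulation matrix, and the ranges of `D` and `S`. Called by the constructor
#' and after fitting.
#'
#' @param p a `mindy_params` object.
#' @param tol numerical tolerance for the checks.
#' @return `p`, invisibly; signals an error describing the first violated
#'   invariant otherwise.
#' @export
validate_params <- function(p, tol = 1e-10) {
  n <- p$n_exc + p$n_inh
  stopifnot(is.matrix(p$W), all(dim(p$W) == n), all(dim(p$mask) == n))
  for (v in c("S", "V", "D", "C")) {
    if (length(p[[v]]) != n) {
      stop(sprintf("parameter '%s' must have length %d, got %d",
                   v, n, length(p[[v]])), call. = FALSE)
    }
  }
  e <- exc_idx(p); i <- inh_idx(p)
  if (any(p$W[, e] < -tol)) {
    stop("excitatory-source columns of W must be nonnegative", call. = FALSE)
  }
  if (any(p$W[, i] > tol)) {
    stop("inhibitory-source columns of W must be nonpositive", call. = FALSE)
  }
  for (blk in list(p$W[e, i, drop = FALSE], p$W[i, i, drop = FALSE])) {
    offd <- blk; diag(offd) <- 0
    if (any(abs(offd) > tol)) {
      stop("W_ie and W_ii blocks must be diagonal", call. = FALSE)
    }
  }
  if (any(abs(p$W[p$mask == 0]) > tol)) {
    stop("W must be zero where mask is zero", call. = FALSE)
  }
  if (length(p$Gamma) != p$m) stop("length(Gamma) != m", call. = FALSE)
  for (k in seq_len(p$m)) {
    G <- p$Gamma[[k]]
    if (any(G < -tol)) {
      stop(sprintf("Gamma[[%d]] must be entrywise nonnegative", k),
           call. = FALSE)
    }
    if (n >= 2) {
      sv <- svd(G, nu = 0, nv = 0)$d
      if (sv[2] > max(tol, 1e-8 * sv[1])) {
        stop(sprintf("Gamma[[%d]] must have rank <= 1", k), call. = FALSE)
      }
    }
  }
  if (any(p$D <= 0 | p$D >= 1)) {
    stop("D entries must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (any(p$S <= 0)) stop("S entries must be positive", call. = FALSE)
  invisible(p)
}

#' Construct an observation model
#'
#' @param H c-by-n lead field; the columns over inhibitory populations must be
#'   zero (inhibitory populations do not generate measurable fields).
#' @param process_cov n-by-n process-noise covariance (maintained diagonal).
#' @param meas_cov c-by-c measurement-noise covariance (maintained diagonal).
#' @param n_inh number of inhibitory populations (trailing columns of `H`
#'   checked to be zero).
#' @return A `mindy_obs` object.
#' @export
mindy_obs <- function(H, process_cov, meas_cov, n_inh) {
  stopifnot(is.matrix(H))
  n <- ncol(H)
  if (n_inh > 0) {
    if (any(H[, (n - n_inh + 1):n] != 0)) {
      stop("inhibitory columns of the lead field must be zero", call. = FALSE)
    }
  }
  for (Cv in list(process_cov, meas_cov)) {
    if (max(abs(Cv - t(Cv))) > 1e-12 || any(diag(Cv) < 0)) {
      stop("noise covariances must be symmetric PSD", call. = FALSE)
    }
  }
  structure(list(H = H, process_cov = process_cov, meas_cov = meas_cov,
                 n_inh = as.integer(n_inh)),
            class = "mindy_obs")
}

#' @export
print.mindy_obs <- function(x, ...) {
  cat(sprintf("<mindy_obs> lead field %dx%d, %d inhibitory columns zeroed\n",
              nrow(x$H), ncol(x$H), x$n_inh))
  invisible(x)
}

#' Effective connectivity in a given regime
#'
#' Returns the modulated connectivity \eqn{W \odot \Gamma_i} active in regime
#' `regime`. Because every \eqn{\Gamma_i} is nonnegative, the sign pattern and
#' structural zeros of `W` are preserved.
#'
#' @param params a `mindy_params` object.
#' @param regime regime index in `1..m`.
#' @return n-by-n numeric matrix.
#' @export
effective_connectivity <- function(params, regime) {
  check_regime(params, regime)
  params$W * params$Gamma[[regime]]
}

check_regime <- function(params, regime) {
  if (length(regime) != 1L || is.na(regime) ||
      regime < 1L || regime > params$m || regime != as.integer(regime)) {
    stop(sprintf("regime must be an integer in 1..%d, got %s",
                 params$m, format(regime)), call. = FALSE)
  }
  invisible(TRUE)
}

activation_fun <- function(params) {
  if (params$activation == "identity") {
    list(phi = identity, dphi = function(u) rep(1, length(u)))
  } else {
    list(phi = tanh, dphi = function(u) 1 - tanh(u)^2)
  }
}

#' One step of the modulated dynamics
#'
#' Advances the latent state one timestep under the regime-`regime`
#' effective connectivity:
#' \deqn{x_{t+1} = x_t + (W \odot \Gamma_i)\,\tanh(Sx_t + V) - D x_t + C + \epsilon_t.}
#'
#' @param x length-n current state.
#' @param params a `mindy_params` object.
#' @param regime active regime index.
#' @param process_noise optional length-n additive noise vector.
#' @return length-n next state.
#' @export
step_dynamics <- function(x, params, regime, process_noise = NULL) {
  check_regime(params, regime)
  n <- params$n_exc + params$n_inh
  if (length(x) != n) {
    stop(sprintf("state has length %d, model has %d populations",
                 length(x), n), call. = FALSE)
  }
  act <- activation_fun(params)
  M <- params$W * params$Gamma[[regime]]
  dsgn <- if (params$decay == "leak") -1 else 1
  out <- x + drop(M %*% act$phi(params$S * x + params$V)) +
    dsgn * params$D * x + params$C
  if (!is.null(process_noise)) {
    if (length(process_noise) != n) {
      stop("process_noise has wrong length", call. = FALSE)
    }
    out <- out + process_noise
  }
  out
}

#' Jacobian of the one-step dynamics map
#'
#' @inheritParams step_dynamics
#' @return n-by-n Jacobian of [step_dynamics()] (noise-free) at `x`.
#' @export
dynamics_jacobian <- function(x, params, regime) {
  check_regime(params, regime)
  act <- activation_fun(params)
  M <- params$W * params$Gamma[[regime]]
  dsgn <- if (params$decay == "leak") -1 else 1
  n <- length(x)
  diag(n) + M * rep(params$S * act$dphi(params$S * x + params$V),
                    each = n) + diag(dsgn * params$D, n)
}

#' Map a latent state to a measurement
#'
#' @param x length-n latent state.
#' @param obs a `mindy_obs` observation model.
#' @param meas_noise optional length-c additive noise.
#' @return length-c measurement `H x (+ noise)`; independent of all
#'   inhibitory state entries because the inhibitory lead-field block is zero.
#' @export
observe <- function(x, obs, meas_noise = NULL) {
  if (length(x) != ncol(obs$H)) {
    stop(sprintf("state length %d does not match lead field columns %d",
                 length(x), ncol(obs$H)), call. = FALSE)
  }
  y <- drop(obs$H %*% x)
  if (!is.null(meas_noise)) {
    if (length(meas_noise) != nrow(obs$H)) {
      stop("meas_noise has wrong length", call. = FALSE)
    }
    y <- y + meas_noise
  }
  y
}

#' Project a parameter set onto its constraint set
#'
#' Clamps excitatory-source entries of `W` below at zero and
#' inhibitory-source entries above at zero, zeroes the off-diagonals of the
#' `W_ie`/`W_ii` blocks and every masked entry, and clamps the modulation
#' factor vectors below at zero (rebuilding each rank-1 \eqn{\Gamma_i}).
#' Idempotent; a no-op on already-feasible parameters. Degenerate `D`/`S`
#' values are nudged into their open ranges.
#'
#' @param params a `mindy_params` object (possibly infeasible, e.g. after a
#'   gradient step).
#' @return A feasible `mindy_params` object.
#' @export
project_constraints <- function(params) {
  p <- params
  e <- exc_idx(p); i <- inh_idx(p)
  p$W[, e][p$W[, e] < 0] <- 0
  p$W[, i][p$W[, i] > 0] <- 0
  # inhibitory-source blocks are diagonal
  keep_ie <- p$W[e, i, drop = FALSE]; keep_ie[row(keep_ie) != col(keep_ie)] <- 0
  keep_ii <- p$W[i, i, drop = FALSE]; keep_ii[row(keep_ii) != col(keep_ii)] <- 0
  p$W[e, i] <- keep_ie
  p$W[i, i] <- keep_ii
  p$W[p$mask == 0] <- 0
  if (!is.null(p$gamma_a)) {
    p$gamma_a[p$gamma_a < 0] <- 0
    p$gamma_b[p$gamma_b < 0] <- 0
    p$Gamma <- lapply(seq_len(p$m), function(k) {
      tcrossprod(p$gamma_a[, k], p$gamma_b[, k])
    })
  } else {
    p$Gamma <- lapply(p$Gamma, function(G) {
      G[G < 0] <- 0
      G
    })
  }
  eps <- 1e-6
  p$D <- pmin(pmax(p$D, eps), 1 - eps)
  p$S <- pmax(p$S, eps)
  p
}

#' Assemble a lead field and default noise covariances
#'
#' Builds the observation model for `c` channels over `2c` populations (one
#' excitatory and one inhibitory population per channel, excitatory first).
#' The inhibitory half of the lead field is always zero.
#'
#' @param c channel count.
#' @param variant `"eeg"` uses the spatially smoothed identity
#'   \eqn{H_{exc} = I - 0.05\,\mathbf{1}\mathbf{1}^\top} with process
#'   covariance `1.2 I` and measurement covariance `0.25 I`; `"synthetic"`
#'   draws `H_exc` i.i.d. standard normal with measurement covariance
#'   `0.25 I` and process covariance `(0.2 + 0.1 U(0,1)) I`.
#' @param seed optional RNG seed for the `"synthetic"` variant.
#' @return A `mindy_obs` object.
#' @export
assemble_lead_field <- function(c, variant = c("synthetic", "eeg"),
                                seed = NULL) {
  variant <- match.arg(variant)
  if (c < 1) stop("c must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (variant == "eeg") {
    H_exc <- diag(c) - 0.05 * matrix(1, c, c)
    process_cov <- 1.2 * diag(2 * c)
    meas_cov <- 0.25 * diag(c)
  } else {
    H_exc <- matrix(rnorm(c * c), c, c)
    process_cov <- (0.2 + 0.1 * runif(1)) * diag(2 * c)
    meas_cov <- 0.25 * diag(c)
  }
  H <- cbind(H_exc, matrix(0, c, c))
  mindy_obs(H, process_cov, meas_cov, n_inh = c)
}

#' Construct a recording
#'
#' @param data T-by-c numeric matrix of measurements.
#' @param rate_hz sampling rate in Hz.
#' @param channels channel names (defaults to `ch1..chc`).
#' @param labels optional length-T integer regime labels.
#' @param boundaries optional integer vector of segment start indices
#'   (fit windows never cross them); defaults to `1`.
#' @return A `mindy_recording` object.
#' @export
mindy_recording <- function(data, rate_hz, channels = NULL, labels = NULL,
                            boundaries = 1L) {
  data <- as.matrix(data)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(data)))
  if (length(channels) != ncol(data)) {
    stop("length(channels) must equal ncol(data)", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(data)) {
      stop("labels length must equal the number of timesteps", call. = FALSE)
    }
  }
  if (any(!is.finite(data))) {
    stop("recording contains non-finite values", call. = FALSE)
  }
  structure(list(data = data, rate_hz = rate_hz,
                 channels = as.character(channels), labels = labels,
                 boundaries = as.integer(boundaries)),
            class = "mindy_recording")
}

#' @export
print.mindy_recording <- function(x, ...) {
  cat(sprintf("<mindy_recording> %d steps x %d channels @ %g Hz%s\n",
              nrow(x$data), ncol(x$data), x$rate_hz,
              if (is.null(x$labels)) "" else
                sprintf(", %d regime(s)", length(unique(x$labels)))))
  invisible(x)
}
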