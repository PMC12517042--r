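# Model persistence. A fitted or ground-truth model is stored as a single
# RDS file holding named components (W, Gamma, S, V, D, C, mask, H,
# process_cov, meas_cov) plus the integer attributes n_exc, n_inh, m.
# RDS round-trips doubles exactly, which the recovery tests rely on.

#' Write a model (parameters + observation model) to disk
#'
#' @param params a `mindy_params` object.
#' @param obs a `mindy_obs` object.
#' @param path output file path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_mindy_model <- function(params, obs, path) {
  payload <- list(
    format = "modmindy-model", version = 1L,
    n_exc = params$n_exc, n_inh = params$n_inh, m = params$m,
    W = params$W, Gamma = params$Gamma,
    gamma_a = params$gamma_a, gamma_b = params$gamma_b,
    S = params$S, V = params$V, D = params$D, C = params$C,
    mask = params$mask, activation = params$activation, decay = params$decay,
    H = obs$H, process_cov = obs$process_cov, meas_cov = obs$meas_cov
  )
  saveRDS(payload, path)
  invisible(path)
}

#' Read a model written by [write_mindy_model()]
#'
#' @param path file path.
#' @return `list(params =, obs =)` with exact round-trip of every field.
#' @export
read_mindy_model <- function(path) {
  z <- readRDS(path)
  if (!identical(z$format, "modmindy-model")) {
    stop(sprintf("'%s' is not a modmindy model file", path), call. = FALSE)
  }
  Gamma <- if (!is.null(z$gamma_a)) {
    lapply(seq_len(z$m), function(k) list(a = z$gamma_a[, k], b = z$gamma_b[, k]))
  } else {
    z$Gamma
  }
  params <- mindy_params(z$n_exc, z$n_inh, z$W, Gamma, z$S, z$V, z$D, z$C,
                         mask = z$mask, activation = z$activation,
                         decay = z$decay, validate = FALSE)
  # preserve exact matrices (factor product may round differently)
  params$Gamma <- z$Gamma
  obs <- mindy_obs(z$H, z$process_cov, z$meas_cov, n_inh = z$n_inh)
  list(params = params, obs = obs)
}
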