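# Quantitative validation: truth-masked recovery correlations, noise sweeps,
# split-half reliability, and modulation analyses.

#' Zero the entries of a fitted connectivity outside the true support
#'
#' When ground truth is known, the fitted `W` is masked with the true zero
#' pattern before correlation, so that structural zeros enforced during
#' fitting do not mix with genuinely absent connections.
#'
#' @param W_fit n-by-n fitted connectivity.
#' @param truth_mask n-by-n binary support matrix.
#' @return Masked copy of `W_fit`; idempotent.
#' @export
apply_truth_mask <- function(W_fit, truth_mask) {
  if (!all(dim(W_fit) == dim(truth_mask))) {
    stop("W_fit and truth_mask dimensions differ", call. = FALSE)
  }
  W_fit * (truth_mask != 0)
}

block_indices <- function(params, block) {
  e <- seq_len(params$n_exc)
  i <- params$n_exc + seq_len(params$n_inh)
  switch(block,
    W = list(rows = c(e, i), cols = c(e, i)),
    W_ee = list(rows = e, cols = e),
    W_ei = list(rows = i, cols = e),
    stop(sprintf("unknown block '%s'", block), call. = FALSE)
  )
}

#' Pearson correlation between fitted and true parameter blocks
#'
#' Vectorises the requested block of both parameter sets (after truth
#' masking, for `W` blocks) and returns the Pearson correlation over all
#' entries of the block. Modulation blocks are addressed as
#' `"Gamma<k>_EE"` / `"Gamma<k>_EI"` (e.g. `"Gamma2_EE"`).
#'
#' @param fit_params,true_params `mindy_params` objects of equal structure.
#' @param block one of `"W"`, `"W_ee"`, `"W_ei"`, `"Gamma<k>_EE"`,
#'   `"Gamma<k>_EI"`.
#' @param mask truth support mask (defaults to `true_params$mask`).
#' @return Pearson r in `[-1, 1]`.
#' @export
recovery_correlation <- function(fit_params, true_params, block = "W",
                                 mask = NULL) {
  if (is.null(mask)) mask <- true_params$mask
  gm <- regmatches(block, regexec("^Gamma([0-9]+)_(EE|EI)$", block))[[1]]
  if (length(gm)) {
    k <- as.integer(gm[2])
    if (k < 1 || k > true_params$m) {
      stop(sprintf("no modulation regime %d", k), call. = FALSE)
    }
    e <- seq_len(true_params$n_exc)
    rows <- if (gm[3] == "EE") e else true_params$n_exc +
      seq_len(true_params$n_inh)
    f <- as.vector(fit_params$Gamma[[k]][rows, e])
    t <- as.vector(true_params$Gamma[[k]][rows, e])
  } else {
    idx <- block_indices(true_params, block)
    Wf <- apply_truth_mask(fit_params$W, mask)
    f <- as.vector(Wf[idx$rows, idx$cols])
    t <- as.vector(true_params$W[idx$rows, idx$cols])
  }
  if (sd(f) == 0 || sd(t) == 0) {
    stop(sprintf("block '%s' is constant; correlation undefined", block),
         call. = FALSE)
  }
  cor(f, t)
}

summarise_r <- function(x) {
  x <- x[is.finite(x)]
  q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  c(median = q[2], q1 = q[1], q3 = q[3])
}

#' Ground-truth recovery experiment
#'
#' Repeats the full validation pipeline: sample a ground-truth model,
#' simulate a labelled recording, fit from random initialisation (lead field
#' and noise covariances initialised at their true values, connectivity
#' masked with the true support), and correlate fitted against true
#' parameter blocks. The unmodulated variant generates single-regime data
#' with the modulation fixed at all-ones and fits the baseline model.
#'
#' @param n_models number of replicate models.
#' @param cfg a [synthetic_config()].
#' @param fitcfg a [fit_config()].
#' @param seed integer seed; replicate `i` uses `seed + i` for its model and
#'   an independent stream for its fit.
#' @param modulated fit the modulated architecture (default) or the
#'   single-regime baseline.
#' @return A `recovery_report`: list with `per_model` (data.frame of per-block
#'   r), `summary` (median and IQR per block), and `failures` (count of
#'   propagated fit failures).
#' @export
recovery_experiment <- function(n_models, cfg = synthetic_config(),
                                fitcfg = fit_config(), seed = 1,
                                modulated = TRUE) {
  stopifnot(n_models >= 1)
  if (!modulated) {
    cfg$nS <- 1L
    cfg$A <- matrix(1, 1, 1)
    cfg$pi_init <- 1
  }
  blocks <- c("W", "W_ee", "W_ei")
  if (modulated) {
    blocks <- c(blocks, as.vector(outer(
      paste0("Gamma", seq_len(cfg$nS)), c("EE", "EI"), paste, sep = "_")))
  }
  rows <- vector("list", n_models)
  failures <- 0L
  for (rep in seq_len(n_models)) {
    set.seed(seed + rep)
    mdl <- sample_ground_truth_model(cfg)
    if (!modulated) {
      n <- 2L * cfg$c
      mdl$params$Gamma[[1]] <- matrix(1, n, n)
      mdl$params$gamma_a <- matrix(1, n, 1)
      mdl$params$gamma_b <- matrix(1, n, 1)
    }
    regimes <- sample_regime_sequence(cfg)
    sim <- simulate_recording(mdl$params, mdl$obs, regimes)
    fc <- fitcfg
    fc$seed <- seed * 1000L + rep
    fc$fix_gamma1 <- !modulated
    fit <- tryCatch(
      fit_mindy(sim$recording, regimes, mdl$obs, fc, mask = mdl$params$mask),
      error = function(e) e
    )
    if (inherits(fit, "error")) {
      failures <- failures + 1L
      next
    }
    r <- vapply(blocks, function(b) {
      tryCatch(recovery_correlation(fit$params, mdl$params, b),
               error = function(e) NA_real_)
    }, numeric(1))
    rows[[rep]] <- as.data.frame(as.list(r))
  }
  per_model <- do.call(rbind, rows)
  summary <- t(vapply(blocks, function(b) summarise_r(per_model[[b]]),
                      numeric(3)))
  structure(list(per_model = per_model, summary = summary,
                 failures = failures, modulated = modulated),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("<recovery_report> %d model(s), %d failure(s), %s fits\n",
              nrow(x$per_model), x$failures,
              if (x$modulated) "modulated" else "unmodulated"))
  s <- round(x$summary, 4)
  for (b in rownames(s)) {
    cat(sprintf("  %-10s median r = %.4f (IQR %.4f-%.4f)\n",
                b, s[b, 1], s[b, 2], s[b, 3]))
  }
  invisible(x)
}

#' Recovery as a function of measurement-noise level
#'
#' Repeats [recovery_experiment()] with the generator's measurement-noise
#' covariance set to `level * I` for each level. Recovery is insensitive to
#' raising the process noise (which only excites the latent dynamics); it is
#' the measurement noise that masks the signal, so that is the axis swept.
#'
#' @param levels vector of covariance scales
#'   (default `c(0.05, 0.25, 0.5, 0.75, 1, 5, 10)`).
#' @param n_models replicates per level.
#' @param cfg,fitcfg,seed as in [recovery_experiment()].
#' @return A data.frame with one row per level: median and IQR of r for the
#'   `W`, `W_ee` and `W_ei` blocks.
#' @export
noise_sweep <- function(levels = c(0.05, 0.25, 0.5, 0.75, 1, 5, 10),
                        n_models = 5, cfg = synthetic_config(),
                        fitcfg = fit_config(), seed = 1) {
  stopifnot(length(levels) >= 1)
  out <- lapply(seq_along(levels), function(j) {
    cfg$meas_scale <- levels[j]
    rep <- recovery_experiment(n_models, cfg, fitcfg,
                               seed = seed + 100L * j)
    s <- rep$summary
    data.frame(level = levels[j],
               W_median = s["W", 1], W_q1 = s["W", 2], W_q3 = s["W", 3],
               W_ee_median = s["W_ee", 1], W_ei_median = s["W_ei", 1],
               failures = rep$failures)
  })
  do.call(rbind, out)
}

#' Split a labelled recording in half within each regime block
#'
#' Within every contiguous run of a single regime label, the first half of
#' the samples goes to the first output and the second half to the second,
#' preserving label proportions to within one sample per run. Session
#' boundaries are retained so windows never span the split points.
#'
#' @param rec a `mindy_recording` with labels.
#' @return `list(first =, second =)` of `mindy_recording`s.
#' @export
split_half <- function(rec) {
  if (is.null(rec$labels)) stop("split_half needs regime labels",
                                call. = FALSE)
  labs <- rec$labels
  runs <- rle(labs)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  idx1 <- integer(0); idx2 <- integer(0)
  b1 <- integer(0); b2 <- integer(0)
  for (j in seq_along(starts)) {
    half <- floor(runs$lengths[j] / 2)
    b1 <- c(b1, length(idx1) + 1L)
    b2 <- c(b2, length(idx2) + 1L)
    idx1 <- c(idx1, starts[j]:(starts[j] + half - 1L))
    idx2 <- c(idx2, (starts[j] + half):ends[j])
  }
  list(
    first = mindy_recording(rec$data[idx1, , drop = FALSE], rec$rate_hz,
                            rec$channels, labs[idx1], boundaries = b1),
    second = mindy_recording(rec$data[idx2, , drop = FALSE], rec$rate_hz,
                             rec$channels, labs[idx2], boundaries = b2)
  )
}

#' Reliability statistics for within- vs across-subject correlations
#'
#' Medians and IQRs of both samples plus a one-sided Wilcoxon rank-sum test
#' of within > across (exact when both samples are small and tie-free).
#'
#' @param within_r,across_r numeric vectors of split-half correlations.
#' @param exact force the exact test (default: automatic).
#' @return list with `within` and `across` summaries and `p_value`.
#' @export
reliability_stats <- function(within_r, across_r, exact = NULL) {
  if (!length(within_r) || !length(across_r)) {
    stop("both correlation lists must be nonempty", call. = FALSE)
  }
  # ties force the normal approximation; that switch is expected, not a fault
  wt <- suppressWarnings(
    wilcox.test(within_r, across_r, alternative = "greater", exact = exact))
  list(within = summarise_r(within_r), across = summarise_r(across_r),
       p_value = wt$p.value)
}

#' Impact of a modulation transition on the effective connectivity
#'
#' The connection-wise change between two regimes scaled by the baseline
#' weights, \eqn{W \odot (\Gamma_j - \Gamma_i)}. Positive entries flag
#' strengthened connections in regime `j` relative to regime `i`, negative
#' entries weakened ones.
#'
#' @param params a `mindy_params` object.
#' @param i,j regime indices (`i` before `j`).
#' @return n-by-n impact matrix (zero wherever the mask is zero).
#' @export
modulation_impact <- function(params, i, j) {
  check_regime(params, i); check_regime(params, j)
  params$W * (params$Gamma[[j]] - params$Gamma[[i]])
}

#' Per-target summary of excitatory-block modulation
#'
#' For each excitatory target (row of the EE block), the mean of the matrix
#' entries over that row's mask support — a "post-synaptic" summary of the
#' modulation arriving at each excitatory population.
#'
#' @param mat n-by-n matrix (e.g. a modulation or impact matrix).
#' @param params a `mindy_params` object providing mask and block structure.
#' @return Length-`n_exc` vector; `NA` where a row has empty support.
#' @export
postsynaptic_summary <- function(mat, params) {
  e <- seq_len(params$n_exc)
  vapply(e, function(r) {
    supp <- which(params$mask[r, e] != 0)
    if (!length(supp)) return(NA_real_)
    mean(mat[r, e][supp])
  }, numeric(1))
}

#' Pooled distribution statistics of modulation values
#'
#' @param Gammas list of modulation matrices (one per regime).
#' @param breaks histogram breaks passed to [graphics::hist()].
#' @return list with per-regime `histogram` objects and `fraction_above_one`
#'   (exact fraction of entries strictly greater than 1).
#' @export
gamma_distribution_stats <- function(Gammas, breaks = "Sturges") {
  hists <- lapply(Gammas, function(G) {
    graphics::hist(as.vector(G), breaks = breaks, plot = FALSE)
  })
  frac <- vapply(Gammas, function(G) mean(as.vector(G) > 1), numeric(1))
  list(histogram = hists, fraction_above_one = frac)
}

#' Two-way ANOVA of post-synaptic modulation values
#'
#' Fixed-effects two-way ANOVA with interaction of channel location and
#' regime (sedation state) on per-subject post-synaptic modulation values.
#' Requires a balanced complete design; the baseline (first) regime is
#' expected to be excluded by the caller since its modulation is fixed at 1.
#'
#' @param values data.frame with numeric `value` and factors (or coercibles)
#'   `channel`, `state`, `subject`.
#' @return data.frame with rows channel, state, channel:state, residual and
#'   columns `sum_sq`, `df`, `F`, `p`.
#' @export
anova_postsynaptic <- function(values) {
  stopifnot(all(c("value", "channel", "state", "subject") %in% names(values)))
  values$channel <- factor(values$channel)
  values$state <- factor(values$state)
  counts <- table(values$channel, values$state)
  if (length(unique(as.vector(counts))) != 1L) {
    stop("design must be balanced (equal subjects per channel x state cell)",
         call. = FALSE)
  }
  fit <- aov(value ~ channel * state, data = values)
  s <- summary(fit)[[1]]
  out <- data.frame(
    term = trimws(rownames(s)),
    sum_sq = s[["Sum Sq"]],
    df = s[["Df"]],
    F = s[["F value"]],
    p = s[["Pr(>F)"]]
  )
  out$term[out$term == "Residuals"] <- "residual"
  rownames(out) <- NULL
  out
}
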