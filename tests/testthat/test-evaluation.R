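test_that("truth masking is the entrywise product with the support", {
  W <- matrix(1:4, 2, 2)
  expect_equal(apply_truth_mask(W, matrix(1, 2, 2)), W)
  expect_equal(apply_truth_mask(W, matrix(0, 2, 2)), matrix(0, 2, 2))
  m <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(apply_truth_mask(W, m), W * m)
  expect_equal(apply_truth_mask(apply_truth_mask(W, m), m),
               apply_truth_mask(W, m))
  expect_error(apply_truth_mask(W, matrix(1, 3, 3)), "dimensions")
})

test_that("recovery correlation reproduces the Pearson formula and its invariances", {
  set.seed(7)
  cfg <- synthetic_config(c = 5, T_steps = 1)
  truth <- sample_ground_truth_model(cfg)$params
  # identical parameters give r = 1 on every block
  for (b in c("W", "W_ee", "W_ei", "Gamma2_EE", "Gamma1_EI")) {
    expect_equal(recovery_correlation(truth, truth, b), 1)
  }

  # 3x3 toy checked against the hand-written Pearson formula
  f <- c(0.2, 0.5, 0.1, 0.9, 0.4, 0.3, 0.8, 0.6, 0.7)
  t0 <- c(0.1, 0.6, 0.2, 0.8, 0.5, 0.2, 0.9, 0.5, 0.6)
  r_hand <- sum((f - mean(f)) * (t0 - mean(t0))) /
    sqrt(sum((f - mean(f))^2) * sum((t0 - mean(t0))^2))
  fp <- mindy_params(3, 0, matrix(f, 3, 3),
                     list(list(a = rep(1, 3), b = rep(1, 3))),
                     S = rep(1, 3), V = rep(0, 3), D = rep(0.5, 3),
                     C = rep(0, 3))
  tp <- fp; tp$W <- matrix(t0, 3, 3)
  expect_equal(recovery_correlation(fp, tp, "W"), r_hand, tolerance = 1e-12)

  # exact invariance under the Hadamard scaling ambiguity (gW, Gamma/g)
  g <- 2.9
  fit2 <- truth
  fit2$W <- g * truth$W
  fit2$Gamma <- lapply(truth$Gamma, function(G) G / g)
  expect_equal(recovery_correlation(fit2, truth, "W"),
               recovery_correlation(truth, truth, "W"))
  expect_equal(recovery_correlation(fit2, truth, "W"), 1)

  # constant blocks are flagged, not silently NaN
  cp <- fp; cp$W <- matrix(1, 3, 3)
  expect_error(recovery_correlation(cp, cp, "W"), "constant")
})

test_that("recovery_experiment aggregates per-model correlations", {
  cfg <- synthetic_config(c = 5, T_steps = 1200)
  fc <- fit_config(max_windows = 60, patience = 60, tol = 1e-12)
  rep1 <- recovery_experiment(1, cfg, fc, seed = 3)
  # a single replicate: median equals the value, IQR degenerate
  expect_equal(nrow(rep1$per_model), 1L)
  expect_equal(unname(rep1$summary["W", "median"]),
               rep1$per_model$W)
  expect_equal(unname(rep1$summary["W", "q1"]),
               unname(rep1$summary["W", "q3"]))
  expect_true(all(abs(rep1$per_model) <= 1, na.rm = TRUE))
  expect_equal(rep1$failures, 0L)
  # modulated run reports all Gamma blocks
  expect_true(all(c("Gamma1_EE", "Gamma3_EI") %in%
                    colnames(rep1$per_model)))
})

test_that("split_half halves every regime run and preserves order", {
  labs <- c(rep(1L, 11), rep(2L, 8), rep(1L, 6))
  rec <- mindy_recording(matrix(seq_len(25 * 2), 25, 2), 250,
                         labels = labs)
  h <- split_half(rec)
  # lengths differ by at most one sample per run
  expect_lte(abs(nrow(h$first$data) - nrow(h$second$data)), 3)
  expect_equal(nrow(h$first$data) + nrow(h$second$data), 25)
  # each regime present in both halves
  expect_setequal(unique(h$first$labels), c(1L, 2L))
  expect_setequal(unique(h$second$labels), c(1L, 2L))
  # samples within each run stay ordered and re-concatenate to the original
  runs <- rle(labs)
  ends <- cumsum(runs$lengths); starts <- c(1L, head(ends, -1L) + 1L)
  rebuilt <- integer(0)
  i1 <- 1L; i2 <- 1L
  for (j in seq_along(starts)) {
    half <- floor(runs$lengths[j] / 2)
    rebuilt <- c(rebuilt,
                 h$first$data[i1:(i1 + half - 1L), 1],
                 h$second$data[i2:(i2 + (runs$lengths[j] - half) - 1L), 1])
    i1 <- i1 + half; i2 <- i2 + runs$lengths[j] - half
  }
  expect_equal(rebuilt, rec$data[, 1])
  expect_error(split_half(mindy_recording(matrix(0, 5, 1), 250)), "labels")
})

test_that("reliability statistics use the exact rank-sum tail", {
  # clearly separated samples: p equals the exhaustive permutation tail
  within <- c(0.9, 0.91, 0.92)
  across <- c(0.1, 0.11, 0.12)
  rs <- reliability_stats(within, across, exact = TRUE)
  # brute-force: probability that a random 3-subset of the 6 pooled values
  # has rank sum >= the observed one
  pooled <- c(within, across)
  combos <- combn(6, 3)
  obs_stat <- sum(rank(pooled)[1:3])
  tail_count <- sum(apply(combos, 2, function(ix)
    sum(rank(pooled)[ix]) >= obs_stat))
  expect_equal(rs$p_value, tail_count / ncol(combos), tolerance = 1e-12)

  # identical samples: one-sided p of 0.5-ish (no evidence of ordering)
  same <- reliability_stats(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_gt(same$p_value, 0.3)

  # invariant to within-list ordering
  rs2 <- reliability_stats(rev(within), sample(across), exact = TRUE)
  expect_equal(rs2$p_value, rs$p_value)
  expect_error(reliability_stats(numeric(0), across), "nonempty")
})

test_that("modulation impact is W-scaled regime differencing", {
  p <- tiny_params(m = 2)
  p$Gamma[[2]] <- p$Gamma[[1]]
  expect_equal(modulation_impact(p, 1, 2), matrix(0, 2, 2))

  # 2x2 hand case
  W <- matrix(c(1, 0, 2, 1), 2, 2)
  dG <- matrix(c(0.1, 0.2, -0.1, 0), 2, 2)
  p2 <- mindy_params(2, 0, W, list(list(a = c(1, 1), b = c(1, 1)),
                                   list(a = c(1, 1), b = c(1, 1))),
                     S = c(1, 1), V = c(0, 0), D = c(0.5, 0.5), C = c(0, 0))
  p2$Gamma[[2]] <- p2$Gamma[[1]] + dG
  expect_equal(modulation_impact(p2, 1, 2),
               matrix(c(0.1, 0, -0.2, 0), 2, 2))
  # positive entries mark strengthened connections
  expect_gt(modulation_impact(p2, 1, 2)[1, 1], 0)
  expect_lt(modulation_impact(p2, 1, 2)[1, 2], 0)
  expect_error(modulation_impact(p2, 1, 5), "regime")
})

test_that("postsynaptic summaries average over each row's support", {
  set.seed(10)
  cfg <- synthetic_config(c = 5, T_steps = 1)
  p <- sample_ground_truth_model(cfg)$params
  # all-ones matrix summarises to 1 everywhere; constants propagate
  expect_equal(postsynaptic_summary(matrix(1, 10, 10), p), rep(1, 5))
  expect_equal(postsynaptic_summary(matrix(3.5, 10, 10), p), rep(3.5, 5))

  # 3x3 masked toy by hand
  m3 <- matrix(c(1, 1, 1, 0, 1, 1, 1, 0, 1), 3, 3)
  p3 <- mindy_params(3, 0, 0.5 * m3,
                     list(list(a = rep(1, 3), b = rep(1, 3))),
                     S = rep(1, 3), V = rep(0, 3), D = rep(0.5, 3),
                     C = rep(0, 3), mask = m3)
  M <- matrix(1:9, 3, 3)
  expect_equal(postsynaptic_summary(M, p3),
               c(mean(c(1, 7)), mean(c(2, 5)), mean(c(3, 6, 9))))
})

test_that("modulation distribution statistics count strict exceedances", {
  expect_equal(gamma_distribution_stats(list(matrix(0.5, 3, 3)))$
                 fraction_above_one, 0)
  expect_equal(gamma_distribution_stats(list(matrix(1, 3, 3)))$
                 fraction_above_one, 0)     # boundary not counted
  G <- matrix(c(1.2, 0.9, 1.01, 0.5, 2, 0.3, 0.8, 0.7, 0.99, 0.2), 2, 5)
  expect_equal(gamma_distribution_stats(list(G))$fraction_above_one, 0.3)
})

test_that("two-way ANOVA reproduces the balanced-design degrees of freedom", {
  set.seed(11)
  des <- expand.grid(channel = paste0("ch", 1:20), state = 2:4,
                     subject = 1:20)
  des$value <- rnorm(nrow(des))
  tab <- anova_postsynaptic(des)
  expect_equal(tab$df, c(19, 2, 38, 1140))
  expect_equal(tab$term, c("channel", "state", "channel:state", "residual"))

  # pure noise: F statistics near 1
  expect_lt(tab$F[1], 2)
  expect_gt(tab$p[1], 1e-4)

  # an injected channel main effect moves only the channel F
  des2 <- des
  bump <- rnorm(20, 0, 2)[as.integer(des2$channel)]
  des2$value <- des2$value + bump
  tab2 <- anova_postsynaptic(des2)
  expect_gt(tab2$F[1], 10)
  expect_lt(tab2$F[2], 5)

  # unbalanced designs are refused
  expect_error(anova_postsynaptic(des[-1, ]), "balanced")
})
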