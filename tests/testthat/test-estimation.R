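test_that("EKF with identity activation matches a textbook Kalman filter", {
  # 2-channel affine-linear system: x' = A x + b with
  # A = I + M diag(S) - diag(D), b = M V + C
  set.seed(3)
  W <- matrix(0, 4, 4)
  W[1, 1] <- 0.3; W[1, 2] <- 0.2; W[2, 1] <- 0.1; W[2, 2] <- 0.4
  W[3, 1] <- 0.25; W[4, 2] <- 0.15
  W[1, 3] <- -0.5; W[2, 4] <- -0.3
  W[3, 3] <- -0.6; W[4, 4] <- -0.4
  p <- mindy_params(2, 2, W,
                    Gamma = list(list(a = rep(1, 4), b = rep(1, 4))),
                    S = c(1.2, 0.8, 1, 1), V = c(0.1, -0.1, 0, 0),
                    D = c(0.5, 0.6, 0.7, 0.8), C = c(0.05, 0, 0, 0),
                    activation = "identity")

  H <- matrix(rnorm(8), 2, 4)
  H[, 3:4] <- 0
  obs <- mindy_obs(H, 0.3 * diag(4), 0.2 * diag(2), n_inh = 2)

  A <- diag(4) + W %*% diag(p$S) - diag(p$D)
  b <- drop(W %*% p$V) + p$C
  Y <- matrix(rnorm(200), 100, 2)

  oracle <- kf_oracle(A, b, H, obs$process_cov, obs$meas_cov, Y,
                      x0 = rep(0, 4), P0 = diag(4))
  got <- ekf_window(p, obs, Y, rep(1, 100))
  expect_lt(max(abs(got$states - oracle)), 1e-8)

  # the compiled kernel filters identically to the R recursion
  th <- as_fit_state(p, obs)
  fc <- fit_config(window_len = 100, freerun_len = 1)
  Yk <- rbind(Y, 0)
  k <- modmindy:::window_gradients(th, H, Yk, rep(1, 101), fc, 2, 2,
                                   identity_act = TRUE)
  expect_lt(max(abs(k$states - oracle)), 1e-8)

  # repeat call is bit-identical
  got2 <- ekf_window(p, obs, Y, rep(1, 100))
  expect_identical(got$states, got2$states)
})

test_that("EKF pins the state to the data in the zero-measurement-noise limit", {
  set.seed(4)
  p <- mindy_params(2, 0, matrix(abs(rnorm(4, 0, 0.3)), 2, 2),
                    list(list(a = c(1, 1), b = c(1, 1))),
                    S = c(1, 1), V = c(0, 0), D = c(0.5, 0.5), C = c(0, 0))
  H <- matrix(c(1, 0.2, -0.1, 1), 2, 2)    # invertible square lead field
  obs <- mindy_obs(H, diag(2), 1e-14 * diag(2), n_inh = 0)
  Y <- matrix(rnorm(60), 30, 2)
  f <- ekf_window(p, obs, Y, rep(1, 30))
  expect_lt(max(abs(f$states %*% t(H) - Y)), 1e-5)
})

test_that("free_run composes noise-free steps through the observation map", {
  p <- tiny_params()
  obs <- tiny_obs()
  x0 <- c(0.3, -0.1)
  pred <- free_run(p, obs, x0, 3, rep(1, 3))
  x <- x0
  for (h in 1:3) {
    x <- step_dynamics(x, p, 1)
    expect_equal(pred[h, ], observe(x, obs))
  }

  # scalar hand-iterated case, two steps
  ps <- mindy_params(1, 0, matrix(0.5), list(list(a = 1, b = 1)),
                     S = 2, V = 0, D = 0.4, C = 0.1)
  obs_s <- mindy_obs(matrix(1), diag(1), diag(1), n_inh = 0)
  x1 <- 0.2 + 0.5 * tanh(0.4) - 0.4 * 0.2 + 0.1
  x2 <- x1 + 0.5 * tanh(2 * x1) - 0.4 * x1 + 0.1
  expect_equal(drop(free_run(ps, obs_s, 0.2, 2, c(1, 1))), c(x1, x2),
               tolerance = 1e-12)

  # a fixed point with zero offsets yields constant predictions
  expect_true(all(free_run(p, obs, c(0, 0), 4, rep(1, 4)) == 0))
})

test_that("training loss is the weighted sum of squared residuals", {
  expect_equal(training_loss(matrix(0, 3, 2), matrix(0, 2, 2),
                             matrix(0, 2, 2)), 0)
  expect_equal(training_loss(matrix(c(3, 4), 1, 2),
                             matrix(c(3, 4), 1, 2), matrix(0, 1, 2)), 50)
  set.seed(8)
  inn <- matrix(rnorm(10), 5, 2)
  fp <- matrix(rnorm(6), 3, 2); ob <- matrix(rnorm(6), 3, 2)
  expect_equal(training_loss(inn, fp, ob, 2, 0.5),
               2 * sum(inn^2) + 0.5 * sum((fp - ob)^2))
})

test_that("select_window draws uniformly within contiguous segments", {
  expect_equal(select_window(30, 20, 10), 1L)
  expect_error(select_window(20, 15, 10), "shorter")

  set.seed(12)
  draws <- replicate(20000, select_window(59, 20, 10))
  # valid starts 1..30, uniform
  expect_equal(sort(unique(draws)), 1:30)
  expect_gt(chisq.test(table(factor(draws, levels = 1:30)))$p.value, 1e-4)

  # windows never straddle a segment boundary
  set.seed(13)
  d2 <- replicate(5000, select_window(100, 10, 5, boundaries = c(1L, 51L)))
  expect_true(all(d2 <= 36 | (d2 >= 51 & d2 <= 86)))

  set.seed(14); a <- replicate(50, select_window(100, 10, 5))
  set.seed(14); b <- replicate(50, select_window(100, 10, 5))
  expect_identical(a, b)
})

test_that("kernel gradients match central finite differences of the loss", {
  set.seed(20)
  cfg <- synthetic_config(c = 4, T_steps = 300)
  gt <- generate_ground_truth(cfg, seed = 2)
  fc <- fit_config(window_len = 12, freerun_len = 5)
  seg <- gt$recording$data[1:17, ]
  labs <- gt$regimes[1:17]
  th <- as_fit_state(gt$params, gt$obs)
  k <- modmindy:::window_gradients(th, gt$obs$H, seg, labs, fc, 4, 4)
  lossfun <- function(th2) {
    modmindy:::window_gradients(th2, gt$obs$H, seg, labs, fc, 4, 4,
                                want_grad = FALSE)$loss
  }
  h <- 1e-6
  for (nm in c("W", "S", "D", "C", "logq", "logr")) {
    g_an <- switch(nm, W = k$gW, S = drop(k$gS), D = drop(k$gD),
                   C = drop(k$gC), logq = drop(k$g_logq),
                   logr = drop(k$g_logr))
    n_chk <- min(8, length(th[[nm]]))
    pick <- seq_len(n_chk)
    g_fd <- vapply(pick, function(ii) {
      tp <- th; tp[[nm]][ii] <- tp[[nm]][ii] + h
      tm <- th; tm[[nm]][ii] <- tm[[nm]][ii] - h
      (lossfun(tp) - lossfun(tm)) / (2 * h)
    }, numeric(1))
    denom <- max(abs(g_fd), 1e-8)
    expect_lt(max(abs(as.vector(g_an)[pick] - g_fd)) / denom, 1e-3)
  }
})

test_that("a NADAM step moves the loss in the descent direction", {
  set.seed(22)
  cfg <- synthetic_config(c = 4, T_steps = 300)
  gt <- generate_ground_truth(cfg, seed = 5)
  fc <- fit_config(window_len = 12, freerun_len = 5)
  seg <- gt$recording$data[1:17, ]; labs <- gt$regimes[1:17]
  th <- as_fit_state(gt$params, gt$obs)
  # perturb away from the optimum so the gradient is informative
  th$W <- th$W * 1.3
  k <- modmindy:::window_gradients(th, gt$obs$H, seg, labs, fc, 4, 4)
  lossfun <- function(th2) {
    modmindy:::window_gradients(th2, gt$obs$H, seg, labs, fc, 4, 4,
                                want_grad = FALSE)$loss
  }
  step <- 1e-5
  th2 <- th
  th2$W <- th$W - step * k$gW
  th2$D <- th$D - step * drop(k$gD)
  expect_lt(lossfun(th2), k$loss)
})

test_that("a single free parameter is recovered on clean data", {
  # scalar model: everything known except the drive C
  set.seed(30)
  truth <- mindy_params(1, 0, matrix(0.5), list(list(a = 1, b = 1)),
                        S = 2, V = 0, D = 0.4, C = 0.3)
  obs <- mindy_obs(matrix(1), 1e-4 * diag(1), 1e-4 * diag(1), n_inh = 0)
  regimes <- rep(1L, 3000)
  sim <- simulate_recording(truth, obs, regimes)
  init <- truth
  init$C <- 0
  # each window restarts the filter at the origin; the first innovations
  # reflect that transient, so they are excluded from the loss
  fc <- fit_config(window_len = 20, freerun_len = 5, burnin = 3, lr = 5e-3,
                   learn = "C", learn_noise = FALSE, fix_gamma1 = TRUE,
                   max_windows = 2000, patience = 2000, tol = 1e-12,
                   lr_decay = "cosine", seed = 7)
  fit <- fit_mindy(sim$recording, regimes, obs, fc, init = init,
                   mask = truth$mask)
  expect_equal(fit$params$C, truth$C, tolerance = 1e-3)
  expect_equal(fit$params$W, truth$W)   # frozen groups untouched
})

test_that("fit_mindy honours constraints, the regime convention and determinism", {
  cfg <- synthetic_config(c = 5, T_steps = 1500)
  gt <- generate_ground_truth(cfg, seed = 6)
  fc <- fit_config(max_windows = 120, patience = 120, tol = 1e-12,
                   fix_gamma1 = TRUE, seed = 19)
  fit <- fit_mindy(gt$recording, gt$regimes, gt$obs, fc,
                   mask = gt$params$mask)
  p <- fit$params
  # output is a fixed point of the constraint projection
  expect_equal(project_constraints(p)$W, p$W)
  expect_equal(project_constraints(p)$Gamma, p$Gamma)
  expect_no_error(validate_params(p))
  # first modulation pinned to all-ones
  expect_equal(p$Gamma[[1]], matrix(1, 10, 10))
  # every other modulation matrix nonnegative rank-1
  for (k in 2:3) {
    sv <- svd(p$Gamma[[k]])$d
    expect_lt(sv[2], 1e-8 * max(sv[1], 1))
    expect_true(all(p$Gamma[[k]] >= 0))
  }
  # sparsity respected exactly
  expect_true(all(p$W[gt$params$mask == 0] == 0))
  # same config, same result
  fit2 <- fit_mindy(gt$recording, gt$regimes, gt$obs, fc,
                    mask = gt$params$mask)
  expect_identical(fit$params$W, fit2$params$W)
  expect_true(all(is.finite(fit$diagnostics$loss_trace)))
})
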