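test_that("draw_action samples the rebuilt covariance deterministically", {
  # degenerate spectrum: the draw is always the mean
  st0 <- generative_state(diag(4), task_dim = 2, mean = c(1, 2, 3, 4),
                          lambda_reg = rep(0, 4))
  set.seed(1)
  expect_equal(draw_action(st0), c(1, 2, 3, 4))
  # determinism contract
  st <- generative_state(diag(8), task_dim = 2)
  set.seed(5); q1 <- draw_action(st)
  set.seed(5); q2 <- draw_action(st)
  expect_identical(q1, q2)
  # law of large numbers: isotropic state, 50k draws
  set.seed(6)
  Q <- t(replicate(50000, draw_action(st)))
  S <- cov(Q)
  expect_lt(norm(S - diag(8), "F"), 0.05 * norm(diag(8), "F"))
})

test_that("the ARMA smoother follows its closed forms", {
  sm <- smoothing_state(rep(0, 3), alpha = 0.99, beta = 0.15)
  v <- c(1, -2, 3)
  sm1 <- smooth_step(sm, v)
  expect_equal(sm1$s, 0.15 * v)
  # geometric decay with zero input
  sm2 <- smoothing_state(c(1, 1), alpha = 0.99, beta = 0.15)
  for (k in 1:50) sm2 <- smooth_step(sm2, c(0, 0))
  expect_equal(sm2$s, 0.99^50 * c(1, 1), tolerance = 1e-12)
  # fixed point under constant input: s* = beta c / (1 - alpha) = 15 c
  smf <- smoothing_state(15 * v, alpha = 0.99, beta = 0.15)
  smf <- smooth_step(smf, v)
  expect_equal(smf$s, 15 * v, tolerance = 1e-12)
  expect_error(smoothing_state(0, alpha = 1), "alpha")
  expect_error(smooth_step(sm, 1:2), "mismatch")
})

test_that("reward is the transmitted power fraction, bounded in [0, 1]", {
  B <- interface_map(rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)))
  expect_equal(reward(project(B, c(0, 0, 2, -1)), c(0, 0, 2, -1)), 0)
  expect_equal(reward(project(B, c(3, -4, 0, 0)), c(3, -4, 0, 0)), 1)
  expect_equal(reward(project(B, c(1, 1, 1, 1)), c(1, 1, 1, 1)), 0.5)
  expect_equal(reward(numeric(2), numeric(4)), 0)   # no feedback, no reward
})

test_that("the effective learning rate scales with reward", {
  expect_equal(effective_rate(0.01, 0), 0)
  expect_equal(effective_rate(0.01, 1), 0.01)
  expect_equal(effective_rate(0.01, 0.5), 0.005)
  expect_error(effective_rate(0.01, 1.2), "reward")
  expect_error(effective_rate(0.01, -0.2), "reward")
})

test_that("mean and component updates follow the printed recursions", {
  st <- generative_state(diag(4), task_dim = 2)
  v <- c(1, 0, -1, 2)
  expect_equal(update_mean(st, v, 0.1)$mean, 0.1 * v)
  expect_equal(update_mean(st, v, 0)$mean, rep(0, 4))
  # repeated constant input converges geometrically with ratio (1 - eta)
  stm <- st
  for (k in 1:30) stm <- update_mean(stm, v, 0.2)
  expect_equal(stm$mean, (1 - 0.8^30) * v, tolerance = 1e-12)

  # aligned input: w1 = (2*0.9 + 0.1) e1
  W <- diag(4); W[1, 1] <- 2
  sta <- generative_state(W, task_dim = 2)
  sta1 <- update_components(sta, c(1, 0, 0, 0), 0.1)
  expect_equal(sta1$components[, 1], c(1.9, 0, 0, 0))
  # orthogonal input: pure shrinkage of w1
  sta2 <- update_components(sta, c(0, 0, 1, 0), 0.1)
  expect_equal(sta2$components[, 1], c(1.8, 0, 0, 0))
  # eta_k = 0 leaves the eigenstructure untouched
  expect_equal(update_components(sta, rnorm(4), 0)$components, sta$components)
  stbad <- sta
  stbad$components[, 3] <- 1e-14
  expect_error(update_components(stbad, rnorm(4), 0.1), "degenerate")
})

test_that("incremental component tracking converges to the batch eigenbasis", {
  set.seed(41)
  truth <- make_covariance(8, target_planarity = 0.75)
  A <- truth$vectors %*% diag(sqrt(truth$values))
  X <- matrix(rnorm(40000 * 8), 40000, 8) %*% t(A)
  set.seed(42)
  st <- generative_state(matrix(rnorm(64), 8, 8), task_dim = 2)
  # time-averaged first-component projector filters the constant-rate jitter
  P1 <- matrix(0, 8, 8)
  for (k in seq_len(nrow(X))) {
    st <- update_components(st, X[k, ], 5e-3)
    if (k > nrow(X) - 5000) {
      v1 <- state_eigenvectors(st)[, 1]
      P1 <- P1 + tcrossprod(v1)
    }
  }
  e <- eigen(cov(X), symmetric = TRUE)     # batch oracle on the same stream
  v1bar <- eigen(P1 / 5000, symmetric = TRUE)$vectors[, 1]
  ang <- acos(min(abs(sum(v1bar * e$vectors[, 1])), 1)) * 180 / pi
  expect_lt(ang, 5)
  expect_lt(abs(state_eigenvalues(st)[1] - e$values[1]) / e$values[1], 0.2)
})

test_that("variance regularization conserves task-dimension vigor", {
  lam0 <- c(4, 2, 1, 0.5, 0.25)
  V <- diag(5)
  st <- generative_state(V %*% diag(lam0), task_dim = 2)
  # already satisfying, zero noise: spectrum unchanged
  st1 <- regularize_variance(st, 0)
  expect_equal(st1$lambda_reg, lam0, tolerance = 1e-12)
  # drifted first-m (halved): restored exactly
  W <- V %*% diag(c(2, 1, 1, 0.5, 0.25))
  std <- generative_state(W, task_dim = 2, initial_spectrum = lam0)
  std1 <- regularize_variance(std, 0)
  expect_equal(sum(std1$lambda_reg[1:2]), sum(lam0[1:2]), tolerance = 1e-12)
  expect_equal(std1$lambda_reg[1:2], lam0[1:2], tolerance = 1e-12)
  # inflated tail: fraction constraint enforced with equality or better
  Wi <- V %*% diag(c(4, 2, 5, 3, 2))
  sti <- generative_state(Wi, task_dim = 2, initial_spectrum = lam0)
  sti1 <- regularize_variance(sti, 0)
  f0 <- sum(lam0[1:2]) / sum(lam0)
  f1 <- sum(sti1$lambda_reg[1:2]) / sum(sti1$lambda_reg)
  expect_gte(f1, f0 - 1e-12)
  expect_true(all(sti1$lambda_reg >= 0))
  # with noise: conservation still exact, all entries non-negative
  set.seed(51)
  for (i in 1:50) {
    st2 <- regularize_variance(std, 1e-4)
    expect_equal(sum(st2$lambda_reg[1:2]), sum(lam0[1:2]), tolerance = 1e-9)
    expect_true(all(st2$lambda_reg >= 0))
  }
})

test_that("the rebuilt covariance is symmetric PSD and eigen-consistent", {
  expect_equal(state_covariance(generative_state(diag(c(3, 2, 1)), task_dim = 2)),
               diag(c(3, 2, 1)))
  set.seed(61)
  truth <- make_covariance(6, target_planarity = 0.6)
  st <- generative_state(truth$vectors %*% diag(truth$values), task_dim = 2)
  S <- state_covariance(st)
  expect_equal(S, t(S), tolerance = 1e-12)
  e <- eigen(S, symmetric = TRUE)
  expect_true(all(e$values > -1e-9))
  # round trip: eigendecomposition recovers the spectrum and basis (up to sign)
  expect_equal(e$values, sort(st$lambda_reg, decreasing = TRUE), tolerance = 1e-8)
  for (i in 1:6) {
    j <- order(st$lambda_reg, decreasing = TRUE)[i]
    expect_equal(abs(sum(e$vectors[, i] * state_eigenvectors(st)[, j])), 1,
                 tolerance = 1e-8)
  }
})

test_that("expected reward matches its Monte-Carlo estimate and closed forms", {
  B <- interface_map(rand_orthonormal_rows(2, 8))
  iso <- generative_state(diag(8), task_dim = 2)
  expect_equal(expected_reward(B, iso), 2 / 8, tolerance = 1e-12)
  # all variance in the row space: maximum reward (remaining components are
  # padded with tiny orthogonal directions carrying zero regularized variance)
  comp <- svd(t(B$rows), nu = 8)$u[, 3:8] * 1e-8
  strow <- generative_state(cbind(t(B$rows) %*% diag(c(2, 1)), comp), task_dim = 2)
  strow$lambda_reg <- c(2, 1, rep(0, 6))
  expect_equal(expected_reward(B, strow), 1, tolerance = 1e-9)
  # Monte-Carlo oracle with a non-zero mean
  set.seed(71)
  truth <- make_covariance(8, target_planarity = 0.6)
  st <- generative_state(truth$vectors %*% diag(truth$values), task_dim = 2,
                         mean = rnorm(8, sd = 0.3))
  er <- expected_reward(B, st)
  N <- 100000
  Z <- matrix(rnorm(N * 8), N, 8)
  Q <- sweep(Z %*% (sqrt(st$lambda_reg) * t(state_eigenvectors(st))), 2,
             st$mean, "+")
  P <- Q %*% t(B$rows)
  # the expectation is a ratio of transmitted to total power
  expect_lt(abs(sum(P^2) / sum(Q^2) - er), 0.005)
  # the mean per-sample power ratio approximates it (the ratio of means and
  # the mean of ratios coincide only approximately for anisotropic states)
  rs <- rowSums(P^2) / rowSums(Q^2)
  expect_lt(abs(mean(rs) - er), 0.02)
  expect_true(er >= 0 && er <= 1)
  stz <- st; stz$lambda_reg <- rep(0, 8); stz$mean <- rep(0, 8)
  expect_error(expected_reward(B, stz), "zero total power")
})

test_that("the exponential filter time constant follows its closed form", {
  expect_equal(time_constant(1 - exp(-1)), 1, tolerance = 1e-12)
  expect_equal(time_constant(1e-6), 1 / 1e-6, tolerance = 1e-3 * 1e6 * 1e-6)
  expect_equal(time_constant(0.0013), -1 / log(1 - 0.0013), tolerance = 1e-12)
  expect_equal(time_constant(0.1, T = 2), -2 / log(0.9), tolerance = 1e-12)
  expect_error(time_constant(1), "eta")
  expect_error(time_constant(0.5, T = 0), "T")
})

test_that("generative state serialization round-trips losslessly", {
  set.seed(81)
  st <- generative_state(matrix(rnorm(36), 6, 6), task_dim = 2,
                         mean = rnorm(6), lambda_reg = runif(6),
                         initial_spectrum = runif(6))
  f <- tempfile(fileext = ".txt")
  write_generative_state(st, f)
  st2 <- read_generative_state(f)
  expect_equal(st2$components, st$components, tolerance = 1e-15)
  expect_equal(st2$mean, st$mean, tolerance = 1e-15)
  expect_equal(st2$lambda_reg, st$lambda_reg, tolerance = 1e-15)
  expect_equal(st2$initial_spectrum, st$initial_spectrum, tolerance = 1e-15)
  expect_identical(st2$task_dim, st$task_dim)
})
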