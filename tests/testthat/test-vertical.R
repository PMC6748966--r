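test_that("reversed regression matches the normal-equations oracle", {
  set.seed(11)
  Xpc <- matrix(rnorm(30 * 10), 30, 10)
  W <- matrix(rnorm(10 * 5), 10, 5)
  # noiseless recovery
  Z <- Xpc %*% W
  expect_equal(reverse_regress(Z, Xpc), W, tolerance = 1e-10,
               ignore_attr = TRUE)
  # orthogonal response -> zero coefficients
  Zo <- qr.resid(qr(Xpc), matrix(rnorm(30 * 3), 30, 3))
  expect_equal(reverse_regress(Zo, Xpc), matrix(0, 10, 3),
               tolerance = 1e-10, ignore_attr = TRUE)
  # pseudo-inverse oracle on noisy data
  Zn <- Z + matrix(rnorm(30 * 5), 30, 5)
  oracle <- solve(crossprod(Xpc)) %*% crossprod(Xpc, Zn)
  expect_equal(reverse_regress(Zn, Xpc), oracle, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(reverse_regress(Zn[1:10, ], Xpc), "rows")
})

test_that("residualization subtracts the fitted overlap exactly", {
  set.seed(12)
  Xpc <- matrix(rnorm(25 * 4), 25, 4)
  Z <- matrix(rnorm(25 * 6), 25, 6)
  W <- reverse_regress(Z, Xpc)
  R <- residualize(Z, Xpc, W)
  # least-squares residuals are orthogonal to the scores
  expect_lt(max(abs(crossprod(Xpc, R))), 1e-8)
  # omega = 0 leaves Z untouched; noiseless case leaves nothing
  expect_identical(residualize(Z, Xpc, matrix(0, 4, 6)), Z)
  expect_equal(residualize(Xpc %*% W, Xpc, W),
               matrix(0, 25, 6), tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(residualize(Z, Xpc, matrix(0, 3, 6)), "shapes")
})

test_that("variant A1 with omega forced to zero coincides with A2", {
  sim <- simulate_vertical_data(n = 60, p = 16, seed = 13)
  f0 <- fit_vertical(sim$dataset, "A1", force_omega_zero = TRUE)
  f2 <- fit_vertical(sim$dataset, "A2")
  expect_identical(f0$theta_x, f2$theta_x)
  expect_identical(f0$theta_z, f2$theta_z)
  expect_identical(f0$alpha, f2$alpha)
})

test_that("variants carry the blocks the design requires", {
  sim <- simulate_vertical_data(n = 50, p = 12, seed = 14)
  f1 <- fit_vertical(sim$dataset, "A1")
  expect_false(is.null(f1$expr_spca))
  expect_false(is.null(f1$omega_hat))
  expect_false(is.null(f1$resid_spca))
  f3 <- fit_vertical(sim$dataset, "A3")
  expect_null(f3$theta_z)
  f4 <- fit_vertical(sim$dataset, "A4")
  expect_null(f4$theta_x)
  # determinism: identical inputs give identical fits
  g1 <- fit_vertical(sim$dataset, "A1")
  expect_identical(f1$theta_x, g1$theta_x)
  expect_identical(f1$omega_hat, g1$omega_hat)
})

test_that("prediction reuses training centering and loadings", {
  sim <- simulate_vertical_data(n = 60, p = 12, seed = 15)
  d <- sim$dataset
  fit <- fit_vertical(d, "A1")
  # training data reproduce the in-sample fitted probabilities
  expect_equal(predict(fit, d), fit$fitted, tolerance = 1e-12,
               ignore_attr = TRUE)
  # a sample at the training mean has zero scores -> plogis(alpha)
  dm <- omics_dataset(X = rbind(colMeans(d$X)), Z = rbind(colMeans(d$Z)),
                      y = NULL, gene_ids = d$gene_ids)
  expect_equal(unname(predict(fit, dm)), unname(plogis(fit$alpha)),
               tolerance = 1e-10)
  # gene mismatch is an error
  dbad <- omics_dataset(X = d$X[, 1:6], Z = d$Z[, 1:6], y = d$y)
  expect_error(predict(fit, dbad), "gene")
})

test_that("null data give calibrated likelihood-ratio statistics", {
  # permuted labels: LRT of the 20-score model vs intercept-only should
  # stay below the chi-square(20) 95% quantile in most replicates
  n <- 300
  p <- 30
  hits <- 0
  nsim <- 30
  for (s in seq_len(nsim)) {
    set.seed(1000 + s)
    X <- matrix(rnorm(n * p), n, p)
    Z <- matrix(rnorm(n * p), n, p)
    y <- rbinom(n, 1, 0.5)
    d <- omics_dataset(X = X, Z = Z, y = y)
    fit <- fit_vertical(d, "A1")
    ll0 <- sum(y * qlogis(mean(y)) - log1p(exp(qlogis(mean(y)))))
    lrt <- 2 * (fit$loglik - ll0)
    if (lrt < qchisq(0.95, 20)) hits <- hits + 1
  }
  expect_gte(hits / nsim, 0.9)
})

test_that("an outcome driven by one expression factor dominates theta_x", {
  sim <- simulate_vertical_data(n = 200, p = 24,
                                independent_cnv_effect = 0,
                                beta_expr = 2, seed = 16)
  fit <- fit_vertical(sim$dataset, "A3")
  # the top component aligned with the causal factor carries the largest
  # coefficient in magnitude
  cors <- abs(cor(fit$expr_spca$scores, sim$truth$f1))
  expect_equal(unname(which.max(abs(fit$theta_x))), unname(which.max(cors)))
})
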