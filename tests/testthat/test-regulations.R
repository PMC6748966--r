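test_that("zero fusion decouples into per-disease per-gene lasso", {
  r1 <- make_regulation_dataset(n = 30, p = 5, seed = 41)
  r2 <- make_regulation_dataset(n = 30, p = 5, seed = 42,
                                group = "schizophrenia")
  for (pen in c("magnitude", "sign")) {
    joint <- solve_penalized_regulation(r1$dataset, r2$dataset, 0.05, 0,
                                        penalty = pen, tol = 1e-9)
    s1 <- fit_lasso_regulation(r1$dataset, 0.05, tol = 1e-9)
    s2 <- fit_lasso_regulation(r2$dataset, 0.05, tol = 1e-9)
    expect_equal(joint$eta[[1]], s1$eta[[1]], tolerance = 1e-6)
    expect_equal(joint$eta[[2]], s2$eta[[1]], tolerance = 1e-6)
  }
})

test_that("noiseless sparse truth is support-recovered on a 50x10 design", {
  set.seed(43)
  n <- 50; p <- 10
  Z <- matrix(rnorm(n * p), n, p)
  W <- matrix(0, p, p)
  for (j in seq_len(p)) W[j, sample(p, 3)] <- runif(3, 0.8, 1.5)
  X <- Z %*% t(W)
  colnames(X) <- colnames(Z) <- paste0("g", 1:p)
  d1 <- omics_dataset(X = X, Z = Z)
  fit <- fit_lasso_regulation(d1, 0.02, tol = 1e-8)
  expect_identical(unname(fit$eta[[1]] != 0), W != 0)
})

test_that("huge and zero lasso levels hit their limits", {
  r <- make_regulation_dataset(n = 40, p = 4, seed = 44)
  # huge lambda3 -> empty matrix
  f <- fit_lasso_regulation(r$dataset, 10)
  expect_true(all(f$eta[[1]] == 0))
  # lambda3 = 0, n > p -> per-gene OLS on standardized/centered data
  f0 <- fit_lasso_regulation(r$dataset, 0, tol = 1e-10, max_sweeps = 5000)
  Zs <- scale(r$dataset$Z)
  Xc <- scale(r$dataset$X, scale = FALSE)
  ols <- t(solve(crossprod(Zs)) %*% crossprod(Zs, Xc))
  expect_equal(f0$eta[[1]], ols, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("coordinate descent attains the quadratic-programming oracle", {
  set.seed(45)
  n <- 20; p <- 4
  mk <- function(seed, group) {
    set.seed(seed)
    Z <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("g", 1:p)))
    X <- Z %*% t(matrix(c(1, 0.8, 0, 0,
                          0, 1.2, 0, 0,
                          0, 0, 0, 0.9,
                          0.7, 0, 0, 0), p, p, byrow = TRUE)) +
      matrix(rnorm(n * p, sd = 0.4), n, p)
    colnames(X) <- paste0("g", 1:p)
    omics_dataset(X = X, Z = Z, group_label = group)
  }
  d1 <- mk(46, "bipolar")
  d2 <- mk(47, "schizophrenia")
  l3 <- 0.06; l4 <- 0.3
  fit <- solve_penalized_regulation(d1, d2, l3, l4, "magnitude",
                                    tol = 1e-10)
  # check gene by gene against an orthant-constrained smooth minimization
  for (j in 1:p) {
    Z1 <- scale(d1$Z); x1 <- scale(d1$X, scale = FALSE)[, j]
    Z2 <- scale(d2$Z); x2 <- scale(d2$X, scale = FALSE)[, j]
    obj <- function(b1, b2) {
      sum((x1 - Z1 %*% b1)^2) / (2 * n) + sum((x2 - Z2 %*% b2)^2) / (2 * n) +
        l3 * (sum(abs(b1)) + sum(abs(b2))) +
        (l4 / 2) * magnitude_penalty(b1, b2)
    }
    b1 <- fit$eta[[1]][j, ]; b2 <- fit$eta[[2]][j, ]
    sg1 <- sign(b1); sg2 <- sign(b2)
    nf <- c(sum(sg1 != 0), sum(sg2 != 0))
    if (sum(nf) == 0) next
    fn <- function(par) {
      v1 <- numeric(p); v1[sg1 != 0] <- par[seq_len(nf[1])]
      v2 <- numeric(p); v2[sg2 != 0] <- par[nf[1] + seq_len(nf[2])]
      obj(v1, v2)
    }
    lower <- c(ifelse(sg1[sg1 != 0] > 0, 0, -Inf),
               ifelse(sg2[sg2 != 0] > 0, 0, -Inf))
    upper <- c(ifelse(sg1[sg1 != 0] > 0, Inf, 0),
               ifelse(sg2[sg2 != 0] > 0, Inf, 0))
    o <- optim(c(b1[sg1 != 0], b2[sg2 != 0]), fn, method = "L-BFGS-B",
               lower = lower, upper = upper,
               control = list(maxit = 2000, factr = 1e3))
    expect_lt(abs(obj(b1, b2) - o$value), 1e-6)
  }
})

test_that("genes decouple: perturbing one response leaves others intact", {
  r1 <- make_regulation_dataset(n = 25, p = 5, seed = 48)
  r2 <- make_regulation_dataset(n = 25, p = 5, seed = 49,
                                group = "schizophrenia")
  f <- solve_penalized_regulation(r1$dataset, r2$dataset, 0.05, 0.2,
                                  "magnitude")
  d1b <- r1$dataset
  d1b$X[, 2] <- rnorm(25)
  f2 <- solve_penalized_regulation(d1b, r2$dataset, 0.05, 0.2,
                                   "magnitude")
  expect_identical(f$eta[[1]][-2, ], f2$eta[[1]][-2, ])
  expect_identical(f$eta[[2]][-2, ], f2$eta[[2]][-2, ])
})

test_that("a zero-variance CNV column is pinned at zero with a warning", {
  r <- make_regulation_dataset(n = 20, p = 4, seed = 50)
  d <- r$dataset
  d$Z[, 3] <- 1
  expect_warning(f <- fit_lasso_regulation(d, 0.01), "zero-variance")
  expect_true(all(f$eta[[1]][, 3] == 0))
})

test_that("distance measures match their naive double-loop definitions", {
  expect_equal(dist_matrices(diag(3), diag(3)), 0)
  A <- matrix(0, 3, 3); B <- A; B[2, 3] <- 2
  expect_equal(dist_matrices(A, B), 4)
  expect_equal(signdist_matrices(matrix(1, 2, 2), matrix(1, 2, 2)), 0)
  C <- matrix(0, 2, 2); D <- C; C[1, 1] <- 1; D[1, 1] <- -1
  expect_equal(signdist_matrices(C, D), 4)
  set.seed(51)
  E <- matrix(rnorm(16) * rbinom(16, 1, 0.5), 4, 4)
  F <- matrix(rnorm(16) * rbinom(16, 1, 0.5), 4, 4)
  loop_d <- 0; loop_s <- 0
  for (j in 1:4) for (l in 1:4) {
    loop_d <- loop_d + (E[j, l] - F[j, l])^2
    loop_s <- loop_s + (sign(E[j, l]) - sign(F[j, l]))^2
  }
  expect_equal(dist_matrices(E, F), loop_d)
  expect_equal(signdist_matrices(E, F), loop_s)
  expect_error(dist_matrices(E, matrix(0, 3, 3)), "shape")
})

test_that("tuning selection honours a single-point grid and null data", {
  r1 <- make_regulation_dataset(n = 25, p = 4, seed = 52)
  r2 <- make_regulation_dataset(n = 25, p = 4, seed = 53,
                                group = "schizophrenia")
  sel <- select_tuning_regulations(r1$dataset, r2$dataset, "magnitude",
                                   lambda3_grid = 0.08,
                                   lambda4_grid = 0.2)
  direct <- solve_penalized_regulation(r1$dataset, r2$dataset, 0.08, 0.2,
                                       "magnitude")
  expect_equal(sel$eta, direct$eta, tolerance = 1e-10)
  # pure noise: the selected model is (near) empty most of the time
  nulls <- 0
  nsim <- 10
  for (s in seq_len(nsim)) {
    set.seed(600 + s)
    Z <- matrix(rnorm(30 * 4), 30, 4)
    X <- matrix(rnorm(30 * 4), 30, 4)
    colnames(X) <- colnames(Z) <- paste0("g", 1:4)
    d <- omics_dataset(X = X, Z = Z)
    f <- select_tuning_lasso_regulation(d)
    if (sum(f$eta[[1]] != 0) == 0) nulls <- nulls + 1
  }
  expect_gte(nulls / nsim, 0.8)
})
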