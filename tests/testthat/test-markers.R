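test_that("fusion penalty values match direct evaluation of their sums", {
  # magnitude: identical same-sign vectors incur nothing
  expect_equal(magnitude_penalty(c(1, -2), c(1, -2)), 0)
  # opposite signs: s = 0 in both directions
  expect_equal(magnitude_penalty(1, -1), 2)
  # same-sign difference counted over both ordered pairs
  expect_equal(magnitude_penalty(c(2, 1), c(1, 1)), 2)
  # sign penalty
  expect_equal(sign_penalty(c(3, 0.1), c(0.2, 5)), 0)
  expect_equal(sign_penalty(1, -1), 8)
  expect_equal(sign_penalty(1, 0), 2)
  expect_error(magnitude_penalty(1:2, 1:3), "length")
  expect_error(sign_penalty(1:2, 1:3), "length")
})

test_that("single-disease lasso agrees with glmnet on standardized data", {
  skip_if_not_installed("glmnet")
  d <- make_logistic_dataset(n = 60, p = 8, seed = 21)
  lam <- 0.05
  fit <- fit_lasso_logistic(d, lam, tol = 1e-9)
  g <- glmnet::glmnet(scale(d$X), d$y, family = "binomial", lambda = lam,
                      standardize = FALSE, thresh = 1e-14)
  expect_equal(fit$beta[[1]], as.numeric(g$beta), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit$intercepts[1], as.numeric(g$a0), tolerance = 1e-6)
})

test_that("lambda1 = 0 on a well-conditioned problem matches the MLE", {
  d <- make_logistic_dataset(n = 80, p = 3, seed = 22)
  fit <- fit_lasso_logistic(d, 0, tol = 1e-10, max_sweeps = 5000)
  ml <- glm.fit(cbind(1, scale(d$X)), d$y,
                family = binomial())$coefficients
  expect_equal(c(fit$intercepts[1], fit$beta[[1]]), ml, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("full shrinkage at lambda_max leaves only class-frequency fits", {
  d1 <- make_logistic_dataset(n = 40, p = 6, seed = 23)
  d2 <- make_logistic_dataset(n = 50, p = 6, seed = 24,
                              group = "schizophrenia")
  lmax <- lambda_max_markers(list(d1, d2))
  for (pen in c("magnitude", "sign")) {
    fit <- solve_penalized_logistic(d1, d2, lmax, 0.7, penalty = pen)
    expect_true(all(fit$beta[[1]] == 0) && all(fit$beta[[2]] == 0))
    expect_equal(fit$intercepts,
                 c(qlogis(mean(d1$y)), qlogis(mean(d2$y))),
                 tolerance = 1e-6)
  }
  # just below lambda_max something enters
  fit <- solve_penalized_logistic(d1, d2, 0.9 * lmax, 0, "none")
  expect_gt(sum(fit$beta[[1]] != 0) + sum(fit$beta[[2]] != 0), 0)
})

test_that("zero fusion reduces to two independent lasso problems", {
  d1 <- make_logistic_dataset(n = 45, p = 7, seed = 25)
  d2 <- make_logistic_dataset(n = 55, p = 7, seed = 26,
                              group = "schizophrenia")
  for (pen in c("magnitude", "sign")) {
    joint <- solve_penalized_logistic(d1, d2, 0.04, 0, penalty = pen,
                                      tol = 1e-9)
    s1 <- fit_lasso_logistic(d1, 0.04, tol = 1e-9)
    s2 <- fit_lasso_logistic(d2, 0.04, tol = 1e-9)
    expect_equal(joint$beta[[1]], s1$beta[[1]], tolerance = 1e-6)
    expect_equal(joint$beta[[2]], s2$beta[[1]], tolerance = 1e-6)
  }
})

test_that("coordinate descent attains the orthant-oracle objective", {
  d1 <- make_logistic_dataset(n = 20, p = 4, seed = 27)
  d2 <- make_logistic_dataset(n = 20, p = 4, seed = 28,
                              group = "schizophrenia")
  fit <- solve_penalized_logistic(d1, d2, 0.08, 0.4, "magnitude",
                                  tol = 1e-9)
  f_cd <- marker_objective(fit$beta[[1]], fit$beta[[2]],
                           fit$intercepts[1], fit$intercepts[2],
                           scale(d1$X), d1$y, scale(d2$X), d2$y,
                           0.08, 0.4, "magnitude")
  f_star <- orthant_oracle_logistic(fit, d1, d2, 0.08, 0.4, "magnitude")
  expect_lt(abs(f_cd - f_star), 1e-4)
})

test_that("swapping the datasets swaps the coefficient vectors", {
  d1 <- make_logistic_dataset(n = 36, p = 5, seed = 29)
  d2 <- make_logistic_dataset(n = 44, p = 5, seed = 30,
                              group = "schizophrenia")
  for (pen in c("magnitude", "sign")) {
    f12 <- solve_penalized_logistic(d1, d2, 0.05, 0.3, penalty = pen)
    f21 <- solve_penalized_logistic(d2, d1, 0.05, 0.3, penalty = pen)
    expect_identical(f12$beta[[1]], f21$beta[[2]])
    expect_identical(f12$beta[[2]], f21$beta[[1]])
  }
})

test_that("stronger magnitude fusion draws same-sign estimates together", {
  set.seed(31)
  p <- 6
  X1 <- matrix(rnorm(60 * p), 60, p)
  X2 <- matrix(rnorm(60 * p), 60, p)
  beta <- c(1.5, 1, -1.2, 0, 0, 0)
  y1 <- rbinom(60, 1, plogis(X1 %*% beta))
  y2 <- rbinom(60, 1, plogis(X2 %*% (beta * 1.6)))
  d1 <- omics_dataset(X = X1, y = y1)
  d2 <- omics_dataset(X = X2, y = y2)
  gaps <- vapply(c(0, 0.3, 1, 4, 16), function(l2) {
    f <- solve_penalized_logistic(d1, d2, 0.02, l2, "magnitude",
                                  tol = 1e-8, max_sweeps = 5000)
    max(abs(f$beta[[1]] - f$beta[[2]]))
  }, numeric(1))
  expect_true(all(diff(gaps) <= 1e-6))
  expect_lt(gaps[length(gaps)], 0.1 * gaps[1])
})

test_that("tuning selection returns the only candidate of a 1-point grid", {
  d1 <- make_logistic_dataset(n = 30, p = 5, seed = 32)
  d2 <- make_logistic_dataset(n = 30, p = 5, seed = 33,
                              group = "schizophrenia")
  sel <- select_tuning_markers(d1, d2, "magnitude", lambda1_grid = 0.06,
                               lambda2_grid = 0.2)
  direct <- solve_penalized_logistic(d1, d2, 0.06, 0.2, "magnitude")
  expect_equal(sel$beta, direct$beta, tolerance = 1e-8)
  expect_equal(sel$lambda1, 0.06)
  expect_equal(sel$lambda2, 0.2)
})

test_that("cross-validated and joint-search tuning run and validate folds", {
  d1 <- make_logistic_dataset(n = 40, p = 6, seed = 201)
  d2 <- make_logistic_dataset(n = 40, p = 6, seed = 202,
                              group = "schizophrenia")
  f_cv <- select_tuning_markers(d1, d2, "magnitude", criterion = "cv",
                                seed = 1, nlambda1 = 5,
                                lambda2_grid = c(0, 0.3))
  expect_s3_class(f_cv, "marker_fit")
  expect_true(f_cv$lambda2 %in% c(0, 0.3))
  f_j <- select_tuning_markers(d1, d2, "sign", search = "joint",
                               nlambda1 = 5, lambda2_grid = c(0, 0.3))
  expect_s3_class(f_j, "marker_fit")
  f_lcv <- select_tuning_lasso_logistic(d1, criterion = "cv", seed = 3,
                                        nlambda1 = 5)
  expect_s3_class(f_lcv, "marker_fit")
  # degenerate folds are rejected
  d_small <- make_logistic_dataset(n = 8, p = 4, seed = 203)
  expect_error(select_tuning_markers(d_small, d_small, "none",
                                     criterion = "cv", nfolds = 5,
                                     seed = 1),
               "degenerate")
})

test_that("pure-noise data mostly select the empty model under (E)BIC", {
  nulls <- 0
  nsim <- 25
  for (s in seq_len(nsim)) {
    set.seed(500 + s)
    X <- matrix(rnorm(40 * 20), 40, 20)
    y <- rbinom(40, 1, 0.5)
    d <- omics_dataset(X = X, y = y)
    fit <- select_tuning_lasso_logistic(d)
    if (sum(fit$beta[[1]] != 0) == 0) nulls <- nulls + 1
  }
  expect_gte(nulls / nsim, 0.8)
})

test_that("fusion strength is selected when the diseases truly match", {
  picks <- vapply(1:10, function(s) {
    ms <- simulate_marker_scenario(
      marker_scenario_spec("I", p = 40), seed = 700 + s)
    select_tuning_markers(ms$d1, ms$d2, "magnitude", nlambda1 = 8)$lambda2
  }, numeric(1))
  expect_gt(mean(picks > 0), 0.5)
})

test_that("coefficients transform correctly back to the original scale", {
  d <- make_logistic_dataset(n = 50, p = 4, seed = 34)
  fit <- fit_lasso_logistic(d, 0.03, tol = 1e-9)
  co <- coef(fit, scale = "original")
  eta_std <- fit$intercepts[1] + drop(scale(d$X) %*% fit$beta[[1]])
  eta_orig <- co[1, 1] + drop(d$X %*% co[-1, 1])
  expect_equal(eta_std, eta_orig, tolerance = 1e-10)
})
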