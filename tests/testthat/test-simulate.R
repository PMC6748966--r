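test_that("built-in scenarios reproduce the stated mean vectors", {
  p <- 100
  mu1 <- c(-1, -1, -1, -1, 2, 2, 2, 2, rep(0, p - 8))
  expect_equal(marker_scenario_spec("I")$mu1, mu1)
  expect_equal(marker_scenario_spec("I")$mu2, mu1)
  expect_equal(marker_scenario_spec("II")$mu2,
               c(-1, -1, -4, -4, 2, 2, 4, 4, rep(0, p - 8)))
  expect_equal(marker_scenario_spec("III")$mu2,
               c(-2, -2, -0.5, -0.5, 3, 3, 1, 1, rep(0, p - 8)))
  expect_equal(marker_scenario_spec("IV")$mu2,
               c(2, 2, -0.5, -0.5, 3, 3, -1, -1, rep(0, p - 8)))
  expect_error(marker_scenario_spec("I", rho = 1), "positive-definite")
})

test_that("marker simulation matches its law at large n", {
  spec <- marker_scenario_spec("I", n_per_group = 5000)
  sim <- simulate_marker_scenario(spec, seed = 61)
  cases <- sim$d1$X[sim$d1$y == 1, ]
  # sample means of the important case columns near mu
  expect_lt(max(abs(colMeans(cases)[1:8] - spec$mu1[1:8])), 0.05)
  # AR(0.3) within the important block
  expect_lt(abs(cor(cases[, 1], cases[, 2]) - 0.3), 0.02)
  expect_lt(abs(cor(cases[, 1], cases[, 3]) - 0.09), 0.02)
  # blocks independent
  expect_lt(abs(cor(cases[, 8], cases[, 9])), 0.05)
  # shared controls between the two disease datasets
  expect_identical(sim$d1$X[sim$d1$y == 0, ], sim$d2$X[sim$d2$y == 0, ])
  expect_identical(sim$truth, 1:8)
})

test_that("simulation draws are seed-deterministic and seed-sensitive", {
  spec <- marker_scenario_spec("II", n_per_group = 10, p = 12)
  a <- simulate_marker_scenario(spec, seed = 62)
  b <- simulate_marker_scenario(spec, seed = 62)
  cc <- simulate_marker_scenario(spec, seed = 63)
  expect_identical(a$d1$X, b$d1$X)
  expect_false(identical(a$d1$X, cc$d1$X))
})

test_that("surrogate CNV matrices match the AR design", {
  Z <- simulate_cnv_matrix(5000, 6, seed = 64)
  expect_equal(dim(Z), c(5000, 6))
  expect_lt(abs(cor(Z[, 1], Z[, 2]) - 0.3), 0.03)
  Zd <- simulate_cnv_matrix(100, 4, discretize = TRUE, seed = 65)
  expect_true(all(Zd %in% c(-1, 0, 1)))
  expect_identical(simulate_cnv_matrix(20, 3, seed = 66),
                   simulate_cnv_matrix(20, 3, seed = 66))
})

test_that("regulation simulation builds the stated sharing structure", {
  spec <- regulation_sim_spec()
  Z1 <- simulate_cnv_matrix(50, 100, seed = 67)
  Z2 <- simulate_cnv_matrix(50, 100, seed = 68)
  sim <- simulate_regulation_data(spec, Z1, Z2, seed = 69)
  for (j in 1:100) {
    s1 <- which(sim$eta1[j, ] != 0)
    s2 <- which(sim$eta2[j, ] != 0)
    # support size 10% of p, exactly 6 shared, matching signs on shared
    expect_length(s1, 10)
    expect_length(s2, 10)
    shared <- intersect(s1, s2)
    expect_identical(shared, sim$shared[[j]])
    expect_true(all(sign(sim$eta1[j, shared]) ==
                      sign(sim$eta2[j, shared])))
    # coefficient laws: positive in [0.6, 1.2], negative in [-1.2, -0.6]
    vals <- sim$eta1[j, s1]
    expect_true(all((vals >= 0.6 & vals <= 1.2) |
                      (vals >= -1.2 & vals <= -0.6)))
    expect_equal(sum(vals > 0), 5)
  }
  # infeasible sharing is rejected
  expect_error(simulate_regulation_data(spec, Z1[, 1:20], Z2[, 1:20],
                                        seed = 70),
               "incompatible")
})

test_that("zero regulation noise reproduces the linear model exactly", {
  spec <- regulation_sim_spec(noise_sd = 0)
  Z1 <- simulate_cnv_matrix(20, 60, seed = 71)
  Z2 <- simulate_cnv_matrix(20, 60, seed = 72)
  sim <- simulate_regulation_data(spec, Z1, Z2, seed = 73)
  expect_equal(sim$d1$X, Z1 %*% t(sim$eta1), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("regulation refits at n >> p recover the truth to within error", {
  spec <- regulation_sim_spec()
  p <- 60
  Z1 <- simulate_cnv_matrix(2000, p, seed = 74)
  Z2 <- simulate_cnv_matrix(2000, p, seed = 75)
  sim <- simulate_regulation_data(spec, Z1, Z2, seed = 76)
  ok <- 0; tot <- 0
  for (j in seq_len(10)) {
    co <- lm.fit(Z1, sim$d1$X[, j])$coefficients
    se <- sqrt(diag(chol2inv(chol(crossprod(Z1)))) *
                 sum(lm.fit(Z1, sim$d1$X[, j])$residuals^2) / (2000 - p))
    hit <- abs(co - sim$eta1[j, ]) <= 3 * se
    ok <- ok + sum(hit); tot <- tot + p
  }
  expect_gte(ok / tot, 0.95)
})

test_that("vertical generator honours its structural switches", {
  # fraction of (centered) CNV variance removed by the reversed
  # regression: near the chance level K/n without overlap, substantial
  # with it
  zr2 <- function(overlap) {
    sim <- simulate_vertical_data(n = 400, p = 16,
                                  overlap_strength = overlap, seed = 77)
    f <- fit_vertical(sim$dataset, "A1")
    Zc <- scale(sim$dataset$Z, scale = FALSE)
    R <- residualize(Zc, f$expr_spca$scores, f$omega_hat)
    1 - sum(R^2) / sum(Zc^2)
  }
  expect_lt(zr2(0), 0.1)
  expect_gt(zr2(0.7), 3 * zr2(0))
  # determinism
  a <- simulate_vertical_data(n = 30, p = 8, seed = 78)
  b <- simulate_vertical_data(n = 30, p = 8, seed = 78)
  expect_identical(a$dataset$X, b$dataset$X)
  expect_identical(a$dataset$y, b$dataset$y)
})
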