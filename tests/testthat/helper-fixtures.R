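# Fixtures are generated in code; seeds fixed per test for reproducibility.

# one case-control expression dataset with a sparse logistic signal
make_logistic_dataset <- function(n = 40, p = 6, beta = NULL, seed = 1,
                                  group = "bipolar") {
  set.seed(seed)
  if (is.null(beta)) beta <- c(1.2, -1, 0.8, rep(0, p - 3))
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
  y <- rbinom(n, 1, plogis(drop(X %*% beta)))
  if (length(unique(y)) < 2) y[1:2] <- c(0L, 1L)
  omics_dataset(X = X, y = y, group_label = group)
}

# paired expression+CNV dataset with known sparse regulation matrix
make_regulation_dataset <- function(n = 30, p = 5, seed = 1,
                                    noise_sd = 0.3, group = "bipolar") {
  set.seed(seed)
  Z <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:p)))
  eta <- matrix(0, p, p)
  for (j in seq_len(p)) eta[j, sample(p, 2)] <- runif(2, 0.5, 1.5)
  X <- Z %*% t(eta) + matrix(rnorm(n * p, sd = noise_sd), n, p)
  colnames(X) <- colnames(Z)
  list(dataset = omics_dataset(X = X, Z = Z, group_label = group),
       eta = eta)
}

# exact objective of the cross-disease penalized logistic problem on
# standardized predictors (independent of the solver)
marker_objective <- function(b1, b2, a1, a2, S1, y1, S2, y2, lambda1,
                             lambda2, penalty) {
  nll <- function(S, y, b, a) {
    eta <- a + drop(S %*% b)
    mean(log1p(exp(eta)) - y * eta)
  }
  rho <- switch(penalty,
                magnitude = magnitude_penalty(b1, b2),
                sign = sign_penalty(b1, b2),
                none = 0)
  nll(S1, y1, b1, a1) + nll(S2, y2, b2, a2) +
    lambda1 * (sum(abs(b1)) + sum(abs(b2))) + (lambda2 / 2) * rho
}

# orthant-restricted numerical minimization with the sign pattern (and the
# fusion indicator) frozen at a reference solution; used as an independent
# oracle for the coordinate-descent fits
orthant_oracle_logistic <- function(fit, d1, d2, lambda1, lambda2,
                                    penalty) {
  S1 <- scale(d1$X)
  S2 <- scale(d2$X)
  sg1 <- sign(fit$beta[[1]])
  sg2 <- sign(fit$beta[[2]])
  n1 <- sum(sg1 != 0)
  n2 <- sum(sg2 != 0)
  par0 <- c(fit$beta[[1]][sg1 != 0], fit$beta[[2]][sg2 != 0],
            fit$intercepts)
  expand <- function(par) {
    b1 <- numeric(length(sg1)); b1[sg1 != 0] <- par[seq_len(n1)]
    b2 <- numeric(length(sg2)); b2[sg2 != 0] <- par[n1 + seq_len(n2)]
    list(b1 = b1, b2 = b2, a1 = par[n1 + n2 + 1], a2 = par[n1 + n2 + 2])
  }
  fn <- function(par) {
    q <- expand(par)
    marker_objective(q$b1, q$b2, q$a1, q$a2, S1, d1$y, S2, d2$y, lambda1,
                     lambda2, penalty)
  }
  lower <- c(ifelse(sg1[sg1 != 0] > 0, 0, -Inf),
             ifelse(sg2[sg2 != 0] > 0, 0, -Inf), -Inf, -Inf)
  upper <- c(ifelse(sg1[sg1 != 0] > 0, Inf, 0),
             ifelse(sg2[sg2 != 0] > 0, Inf, 0), Inf, Inf)
  o <- optim(par0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
             control = list(maxit = 2000, factr = 1e4))
  o$value
}

expect_monotone_trace <- function(trace, tol = 1e-10) {
  expect_true(all(diff(trace) <= tol))
}
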