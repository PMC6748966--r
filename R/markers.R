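#' Magnitude-based fusion penalty
#'
#' Cross-disease contrast penalty
#' \deqn{\sum_j \sum_{k \ne k'} (\beta_j^{(k)} - s_j^{(kk')}
#'   \beta_j^{(k')})^2}
#' with \eqn{s_j^{(kk')} = 1} when the two coefficients share the same sign
#' (`Sgn(0) = 0`) and 0 otherwise: value differences of same-sign effects
#' are shrunk toward zero, promoting quantitative similarity.
#'
#' @param beta1,beta2 equal-length coefficient vectors.
#' @return the (non-negative) penalty value summed over both ordered pairs.
#' @export
magnitude_penalty <- function(beta1, beta2) {
  if (length(beta1) != length(beta2))
    stop("beta1 and beta2 must have equal length")
  s <- as.numeric(sign(beta1) == sign(beta2))
  sum((beta1 - s * beta2)^2 + (beta2 - s * beta1)^2)
}

#' Sign-based fusion penalty
#'
#' Cross-disease contrast penalty
#' \deqn{\sum_j \sum_{k \ne k'} ({\rm Sgn}(\beta_j^{(k)}) -
#'   {\rm Sgn}(\beta_j^{(k')}))^2}
#' shrinking sign disagreements: qualitative similarity between diseases.
#'
#' @inheritParams magnitude_penalty
#' @return the penalty value summed over both ordered pairs.
#' @export
sign_penalty <- function(beta1, beta2) {
  if (length(beta1) != length(beta2))
    stop("beta1 and beta2 must have equal length")
  2 * sum((sign(beta1) - sign(beta2))^2)
}

# internal: map penalty name to the integer code of the C++ core
penalty_code <- function(penalty) {
  match(penalty, c("none", "magnitude", "sign")) - 1L
}

# internal: standardize a feature matrix; zero-variance columns get scale 1
# (their coefficients can never leave zero anyway once the column is
# constant at 0 after centering)
standardize_block <- function(M) {
  ctr <- colMeans(M)
  scl <- apply(M, 2, sd)
  zero <- scl == 0
  scl[zero] <- 1
  Ms <- sweep(sweep(M, 2, ctr), 2, scl, "/")
  list(M = Ms, center = ctr, scale = scl, zero_var = zero)
}

#' Smallest lasso penalty with an all-zero solution
#'
#' For the cross-disease penalized logistic objective, the smallest
#' `lambda1` at which both coefficient vectors are exactly zero (with
#' intercepts at the logit class frequencies):
#' \eqn{\max_{j,k} |x_j^T (y - \bar y)| / n_k} on standardized predictors.
#'
#' @param datasets list of one or two `omics_dataset` objects.
#' @param feature which block to use.
#' @param normalize_likelihood whether the log-likelihoods are scaled by
#'   `1/n_k` (the solver default).
#' @return the critical value.
#' @export
lambda_max_markers <- function(datasets, feature = c("expression", "cnv"),
                               normalize_likelihood = TRUE) {
  feature <- match.arg(feature)
  mx <- 0
  for (d in datasets) {
    M <- standardize_block(feature_block(d, feature))$M
    y <- d$y
    cf <- if (normalize_likelihood) 1 / length(y) else 1
    g <- abs(drop(crossprod(M, y - mean(y)))) * cf
    mx <- max(mx, g)
  }
  # tiny safety factor so floating-point ties at the threshold still give
  # an exactly zero fit
  mx * (1 + 1e-10)
}

#' Cross-disease penalized logistic regression
#'
#' Minimizes
#' \deqn{-l(\beta^{(1)}) - l(\beta^{(2)}) + \lambda_1 \sum_k
#'   \|\beta^{(k)}\|_1 + \frac{\lambda_2}{2}\rho(\beta^{(1)},\beta^{(2)})}
#' by cyclic coordinate descent, where \eqn{\rho} is the magnitude- or
#' sign-based fusion penalty ([magnitude_penalty()], [sign_penalty()]).
#' Each sweep majorizes the logistic losses by their 1/4-curvature quadratic
#' bound and updates the coefficient pair of each gene jointly: exactly over
#' the sign branches for the magnitude penalty, and through the smooth
#' surrogate `Sgn(x) ~ x / sqrt(x^2 + sign_tau)` with per-sweep frozen
#' denominators (plus a descent safeguard) for the sign penalty. The
#' recorded objective trace -- using the smoothed sign surrogate when
#' `penalty = "sign"` -- is non-increasing. By default each log-likelihood
#' is scaled by `1/n_k`, making tuning values comparable across sample
#' sizes.
#'
#' Predictors are standardized internally; coefficients are returned on the
#' standardized scale with the centering/scaling vectors attached (see
#' [coef.marker_fit()] for the original scale).
#'
#' @param d1,d2 `omics_dataset` objects for the two diseases, sharing gene
#'   identifiers for the chosen block.
#' @param lambda1 non-negative lasso penalty.
#' @param lambda2 non-negative fusion penalty.
#' @param penalty `"magnitude"`, `"sign"` or `"none"`.
#' @param feature `"expression"` or `"cnv"`.
#' @param init optional warm start: list with `beta` (list of 2 vectors)
#'   and `intercepts`.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_sweeps sweep cap; non-convergence yields a warning and a
#'   fit flagged `converged = FALSE`.
#' @param sign_tau smoothing constant of the sign surrogate
#'   `Sgn(x) ~ x / sqrt(x^2 + sign_tau)` used by the solver for
#'   `penalty = "sign"` (reported penalty values use exact signs).
#' @param normalize_likelihood scale each log-likelihood by `1/n_k`
#'   (`FALSE` restores the literal unnormalized sum).
#' @return object of class `marker_fit`: `beta` (list of two standardized
#'   coefficient vectors), `intercepts`, `objective_trace`, `n_sweeps`,
#'   `loglik` (unnormalized, per dataset), supports via [support()].
#' @export
solve_penalized_logistic <- function(d1, d2, lambda1, lambda2,
                                     penalty = c("magnitude", "sign",
                                                 "none"),
                                     feature = c("expression", "cnv"),
                                     init = NULL, tol = 1e-5,
                                     max_sweeps = 1000, sign_tau = 1e-2,
                                     normalize_likelihood = TRUE) {
  penalty <- match.arg(penalty)
  feature <- match.arg(feature)
  stopifnot(lambda1 >= 0, lambda2 >= 0)
  if (!identical(d1$gene_ids, d2$gene_ids))
    stop("the two datasets must share gene identifiers")
  s1 <- standardize_block(feature_block(d1, feature))
  s2 <- standardize_block(feature_block(d2, feature))
  p <- ncol(s1$M)
  b1 <- if (is.null(init)) rep(0, p) else init$beta[[1]]
  b2 <- if (is.null(init)) rep(0, p) else init$beta[[2]]
  a1 <- if (is.null(init)) qlogis(mean(d1$y)) else init$intercepts[1]
  a2 <- if (is.null(init)) qlogis(mean(d2$y)) else init$intercepts[2]
  res <- cd_fused_logistic_cpp(s1$M, as.numeric(d1$y), s2$M,
                               as.numeric(d2$y), lambda1, lambda2,
                               penalty_code(penalty), sign_tau,
                               normalize_likelihood, b1, b2, a1, a2, tol,
                               as.integer(max_sweeps), TRUE)
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_sweeps,
            " sweeps")
  new_marker_fit(res, list(s1, s2), list(d1, d2), lambda1, lambda2, penalty,
                 feature)
}

# internal constructor shared by the two- and one-dataset fitters
new_marker_fit <- function(res, stands, datasets, lambda1, lambda2, penalty,
                           feature) {
  two <- length(datasets) == 2
  genes <- datasets[[1]]$gene_ids
  beta <- list(structure(res$beta1, names = genes))
  intercepts <- res$alpha1
  if (two) {
    beta[[2]] <- structure(res$beta2, names = genes)
    intercepts <- c(intercepts, res$alpha2)
  }
  loglik <- vapply(seq_along(datasets), function(k) {
    eta <- intercepts[k] + drop(stands[[k]]$M %*% beta[[k]])
    sum(datasets[[k]]$y * eta - ifelse(eta > 35, eta, log1p(exp(eta))))
  }, numeric(1))
  structure(list(
    beta = beta, intercepts = intercepts, lambda1 = lambda1,
    lambda2 = lambda2, penalty = penalty, feature = feature,
    objective_trace = res$objective_trace, n_sweeps = res$n_sweeps,
    converged = res$converged, loglik = loglik,
    center = lapply(stands, `[[`, "center"),
    scale = lapply(stands, `[[`, "scale"),
    n = vapply(datasets, function(d) length(d$y), numeric(1)),
    groups = vapply(datasets, `[[`, character(1), "group_label"),
    gene_ids = genes), class = "marker_fit")
}

#' Single-disease lasso logistic regression
#'
#' The separate-analysis baseline: one lasso-penalized logistic regression
#' per disease, i.e. the cross-disease objective with `lambda2 = 0` and a
#' single dataset.
#'
#' @inheritParams solve_penalized_logistic
#' @param d an `omics_dataset`.
#' @return a `marker_fit` with a single coefficient vector.
#' @export
fit_lasso_logistic <- function(d, lambda1, feature = c("expression", "cnv"),
                               init = NULL, tol = 1e-5, max_sweeps = 1000,
                               normalize_likelihood = TRUE) {
  feature <- match.arg(feature)
  stopifnot(lambda1 >= 0)
  s1 <- standardize_block(feature_block(d, feature))
  p <- ncol(s1$M)
  b1 <- if (is.null(init)) rep(0, p) else init$beta[[1]]
  a1 <- if (is.null(init)) qlogis(mean(d$y)) else init$intercepts[1]
  dummy <- matrix(0, 1, p)
  res <- cd_fused_logistic_cpp(s1$M, as.numeric(d$y), dummy, 0, lambda1, 0,
                               0L, 1e-2, normalize_likelihood, b1,
                               rep(0, p), a1, 0, tol,
                               as.integer(max_sweeps), FALSE)
  if (!res$converged)
    warning("coordinate descent did not converge in ", max_sweeps,
            " sweeps")
  new_marker_fit(res, list(s1), list(d), lambda1, 0, "none", feature)
}

#' @export
print.marker_fit <- function(x, ...) {
  cat("marker_fit (", x$penalty, "penalty,", x$feature, "):",
      length(x$beta), "dataset(s)\n")
  cat("  lambda1 =", signif(x$lambda1, 4), " lambda2 =",
      signif(x$lambda2, 4), "\n")
  for (k in seq_along(x$beta))
    cat("  dataset", k, "(", x$groups[k], "): ", sum(x$beta[[k]] != 0),
        "nonzero of", length(x$beta[[k]]), "\n")
  invisible(x)
}

#' Extract coefficients from a marker fit
#'
#' @param object a `marker_fit`.
#' @param scale `"standardized"` (solver scale, the default) or
#'   `"original"` (coefficients divided by the predictor standard
#'   deviations, intercept adjusted).
#' @param ... unused.
#' @return matrix with one column per dataset plus a first intercept row.
#' @export
coef.marker_fit <- function(object, scale = c("standardized", "original"),
                            ...) {
  scale <- match.arg(scale)
  out <- sapply(seq_along(object$beta), function(k) {
    b <- object$beta[[k]]
    a <- object$intercepts[k]
    if (scale == "original") {
      b <- b / object$scale[[k]]
      a <- a - sum(b * object$center[[k]])
    }
    c(`(Intercept)` = a, b)
  })
  colnames(out) <- object$groups
  out
}

#' Nonzero-coefficient supports of a fit
#'
#' @param object a `marker_fit` or `regulation_fit`.
#' @return for marker fits, a list of integer index vectors (one per
#'   dataset); for regulation fits, a list of logical p x p support
#'   matrices.
#' @export
support <- function(object) UseMethod("support")

#' @export
support.marker_fit <- function(object) {
  lapply(object$beta, function(b) which(b != 0))
}

# internal: held-out deviance of a marker fit on standardized-by-training
# predictors
marker_deviance <- function(fit, datasets) {
  sum(vapply(seq_along(datasets), function(k) {
    d <- datasets[[k]]
    M <- sweep(sweep(feature_block(d, fit$feature), 2, fit$center[[k]]),
               2, fit$scale[[k]], "/")
    eta <- fit$intercepts[k] + drop(M %*% fit$beta[[k]])
    -2 * sum(d$y * eta - ifelse(eta > 35, eta, log1p(exp(eta))))
  }, numeric(1)))
}

# internal: fusion-aware effective degrees of freedom. The lasso part
# contributes 1 per nonzero coefficient (the usual lasso df); the quadratic
# fusion part shrinks pairs toward each other, so each active pair
# contributes tr((H + P)^{-1} H) with H the (approximate) loss curvatures
# and P the fusion Hessian -- between 1 (fully fused) and 2 (no fusion).
fused_effective_df <- function(beta1, beta2, v1, v2, lambda2, penalty,
                               tau = 1e-2) {
  if (penalty == "none" || lambda2 == 0)
    return(sum(beta1 != 0) + sum(beta2 != 0))
  df <- 0
  for (j in seq_along(beta1)) {
    b1 <- beta1[j]
    b2 <- beta2[j]
    nz1 <- b1 != 0
    nz2 <- b2 != 0
    if (!nz1 && !nz2) next
    if (penalty == "magnitude") {
      if (nz1 && nz2 && sign(b1) == sign(b2)) {
        H <- diag(c(v1[j], v2[j]))
        P <- 2 * lambda2 * matrix(c(1, -1, -1, 1), 2)
        df <- df + sum(diag(solve(H + P, H)))
      } else {
        if (nz1) df <- df + v1[j] / (v1[j] + lambda2)
        if (nz2) df <- df + v2[j] / (v2[j] + lambda2)
      }
    } else {
      d1 <- sqrt(b1^2 + tau)
      d2 <- sqrt(b2^2 + tau)
      if (nz1 && nz2) {
        H <- diag(c(v1[j], v2[j]))
        P <- 2 * lambda2 *
          matrix(c(1 / d1^2, -1 / (d1 * d2), -1 / (d1 * d2), 1 / d2^2), 2)
        df <- df + sum(diag(solve(H + P, H)))
      } else {
        if (nz1) df <- df + v1[j] / (v1[j] + 2 * lambda2 / d1^2)
        if (nz2) df <- df + v2[j] / (v2[j] + 2 * lambda2 / d2^2)
      }
    }
  }
  df
}

# internal: choose a grid index by minimum score or by the one-standard-
# error rule (sparsest qualifying model: largest lambda1, then smallest
# lambda2)
pick_from_grid <- function(grid, score, se, criterion, cv_rule) {
  imin <- which.min(score)
  if (criterion != "cv" || cv_rule == "min") return(imin)
  thr <- score[imin] + se[imin]
  ok <- which(score <= thr)
  ok[order(-grid$lambda1[ok], grid$lambda2[ok])][1]
}

# internal: stratified fold assignment
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  fold
}

# internal: subset an omics_dataset by sample index
dataset_rows <- function(d, idx) {
  omics_dataset(X = if (!is.null(d$X)) d$X[idx, , drop = FALSE],
                Z = if (!is.null(d$Z)) d$Z[idx, , drop = FALSE],
                y = d$y[idx], sample_ids = d$sample_ids[idx],
                gene_ids = d$gene_ids, group_label = d$group_label)
}

#' Tuning-parameter selection for cross-disease marker identification
#'
#' Two search strategies over `(lambda1, lambda2)`:
#'
#' * `"profiled"` (default): for every fusion level `lambda2`, the lasso
#'   level `lambda1` is selected along a warm-started path by BIC,
#'   \eqn{-2(l_1 + l_2) + \log(n_1 + n_2)\,\mathrm{df}} with unnormalized
#'   log-likelihoods and `df` the plain nonzero count (or by
#'   cross-validated deviance), keeping sparsity tightly controlled at
#'   every fusion level; the fusion level is then chosen among the
#'   profiled candidates by BIC with fusion-aware effective degrees of
#'   freedom, in which an actively fused coefficient pair counts as
#'   between one and two parameters, so the comparison across fusion
#'   levels does not double-count what the penalty ties together.
#' * `"joint"`: full grid search under a single criterion (effective-df
#'   BIC or cross-validated deviance).
#'
#' Ties are broken toward the sparser model (larger `lambda1`, then
#' smaller `lambda2`).
#'
#' @inheritParams solve_penalized_logistic
#' @param lambda1_grid descending lasso grid; default log-spaced over
#'   `[0.05, 1] * lambda_max` of length `nlambda1`.
#' @param lambda2_grid fusion grid; default `c(0, 0.1, 0.3, 1)`.
#' @param criterion `"bic"` (default) or `"cv"` (5-fold stratified
#'   held-out deviance).
#' @param search `"profiled"` (default) or `"joint"`.
#' @param cv_rule for `"cv"`: `"1se"` (sparsest model within one standard
#'   error of the minimum, the usual parsimony rule) or `"min"`.
#' @param nlambda1 default lasso grid length.
#' @param nfolds folds for `criterion = "cv"`.
#' @param seed optional RNG seed for fold assignment.
#' @param ebic_gamma weight of the extended-BIC term
#'   \eqn{2\gamma \sum_k \log \binom{p}{df_k}} added to every BIC score
#'   (0 recovers plain BIC; 0.5 is the usual high-dimensional default).
#' @return the selected `marker_fit`, with the search record in `$path`.
#' @export
select_tuning_markers <- function(d1, d2,
                                  penalty = c("magnitude", "sign", "none"),
                                  lambda1_grid = NULL, lambda2_grid = NULL,
                                  criterion = c("bic", "cv"),
                                  search = c("profiled", "joint"),
                                  cv_rule = c("1se", "min"),
                                  feature = c("expression", "cnv"),
                                  nlambda1 = 10, nfolds = 5, seed = NULL,
                                  ebic_gamma = 0.5, tol = 1e-5,
                                  max_sweeps = 1000,
                                  normalize_likelihood = TRUE) {
  penalty <- match.arg(penalty)
  criterion <- match.arg(criterion)
  search <- match.arg(search)
  cv_rule <- match.arg(cv_rule)
  feature <- match.arg(feature)
  if (is.null(lambda1_grid)) {
    lmax <- lambda_max_markers(list(d1, d2), feature, normalize_likelihood)
    lambda1_grid <- exp(seq(log(lmax), log(0.05 * lmax),
                            length.out = nlambda1))
  }
  lambda1_grid <- sort(lambda1_grid, decreasing = TRUE)
  if (is.null(lambda2_grid))
    lambda2_grid <- if (penalty == "none") 0 else c(0, 0.1, 0.3, 1)
  if (!length(lambda1_grid) || !length(lambda2_grid))
    stop("empty tuning grid")
  if (!is.null(seed)) set.seed(seed)

  folds <- NULL
  if (criterion == "cv") {
    folds <- list(stratified_folds(d1$y, nfolds),
                  stratified_folds(d2$y, nfolds))
    for (k in 1:2) {
      tab <- table(folds[[k]], list(d1$y, d2$y)[[k]])
      if (any(tab == 0) || nrow(tab) < nfolds)
        stop("degenerate cross-validation folds (a class is missing from ",
             "a fold); reduce nfolds")
    }
  }

  fit_one <- function(dd1, dd2, l1, l2, init) {
    suppressWarnings(solve_penalized_logistic(
      dd1, dd2, l1, l2, penalty = penalty, feature = feature, init = init,
      tol = tol, max_sweeps = max_sweeps,
      normalize_likelihood = normalize_likelihood))
  }
  cv_score <- function(l1, l2, cv_inits) {
    folddev <- vapply(seq_len(nfolds), function(f) {
      cvfit <- fit_one(dataset_rows(d1, folds[[1]] != f),
                       dataset_rows(d2, folds[[2]] != f), l1, l2,
                       cv_inits[[f]])
      cv_inits[[f]] <<- list(beta = cvfit$beta,
                             intercepts = cvfit$intercepts)
      marker_deviance(cvfit, list(dataset_rows(d1, folds[[1]] == f),
                                  dataset_rows(d2, folds[[2]] == f)))
    }, numeric(1))
    c(mean(folddev), sd(folddev) / sqrt(nfolds))
  }
  # approximate per-coordinate loss curvatures for the effective df
  vcurv <- lapply(list(d1, d2), function(d) {
    M <- standardize_block(feature_block(d, feature))$M
    cf <- if (normalize_likelihood) 1 / nrow(M) else 1
    0.25 * cf * colSums(M^2)
  })
  bic_eff <- function(fit, l2) {
    dfe <- fused_effective_df(fit$beta[[1]], fit$beta[[2]], vcurv[[1]],
                              vcurv[[2]], l2, penalty)
    p <- length(fit$beta[[1]])
    dfk <- vapply(fit$beta, function(b) sum(b != 0), numeric(1))
    -2 * sum(fit$loglik) + log(sum(fit$n)) * dfe +
      2 * ebic_gamma * sum(lchoose(p, dfk))
  }

  if (search == "profiled") {
    cand_fits <- vector("list", length(lambda2_grid))
    cand_score <- numeric(length(lambda2_grid))
    path <- NULL
    for (h in seq_along(lambda2_grid)) {
      l2 <- lambda2_grid[h]
      score1 <- numeric(length(lambda1_grid))
      se1 <- rep(NA_real_, length(lambda1_grid))
      fits1 <- vector("list", length(lambda1_grid))
      init <- NULL
      cv_inits <- vector("list", nfolds)
      for (g in seq_along(lambda1_grid)) {
        l1 <- lambda1_grid[g]
        fit <- fit_one(d1, d2, l1, l2, init)
        init <- list(beta = fit$beta, intercepts = fit$intercepts)
        fits1[[g]] <- fit
        if (criterion == "bic") {
          dfk <- vapply(fit$beta, function(b) sum(b != 0), numeric(1))
          score1[g] <- -2 * sum(fit$loglik) +
            log(sum(fit$n)) * sum(dfk) +
            2 * ebic_gamma * sum(lchoose(length(fit$beta[[1]]), dfk))
        } else {
          sc <- cv_score(l1, l2, cv_inits)
          score1[g] <- sc[1]
          se1[g] <- sc[2]
        }
      }
      g1 <- pick_from_grid(data.frame(lambda1 = lambda1_grid,
                                      lambda2 = l2),
                           score1, se1, criterion, cv_rule)
      cand_fits[[h]] <- fits1[[g1]]
      cand_score[h] <- bic_eff(fits1[[g1]], l2)
      path <- rbind(path, data.frame(lambda1 = lambda1_grid, lambda2 = l2,
                                     score = score1,
                                     selected = seq_along(lambda1_grid) ==
                                       g1))
    }
    h_star <- which.min(cand_score)  # ascending lambda2: ties keep weaker
    best <- cand_fits[[h_star]]
    best$path <- path
    best$fusion_scores <- data.frame(lambda2 = lambda2_grid,
                                     bic_eff = cand_score)
    best$criterion <- criterion
    return(best)
  }

  # joint grid search
  grid <- expand.grid(lambda1 = lambda1_grid, lambda2 = lambda2_grid)
  grid <- grid[order(grid$lambda2, -grid$lambda1), ]
  fits <- vector("list", nrow(grid))
  score <- numeric(nrow(grid))
  se <- rep(NA_real_, nrow(grid))
  g <- 0
  for (l2 in lambda2_grid) {
    init <- NULL
    cv_inits <- vector("list", nfolds)
    for (l1 in lambda1_grid) {
      g <- g + 1
      fit <- fit_one(d1, d2, l1, l2, init)
      init <- list(beta = fit$beta, intercepts = fit$intercepts)
      fits[[g]] <- fit
      if (criterion == "bic") {
        score[g] <- bic_eff(fit, l2)
      } else {
        sc <- cv_score(l1, l2, cv_inits)
        score[g] <- sc[1]
        se[g] <- sc[2]
      }
    }
  }
  pick <- pick_from_grid(grid, score, se, criterion, cv_rule)
  best <- fits[[pick]]
  best$path <- cbind(grid, score = score, se = se)
  best$criterion <- criterion
  best
}

#' Tuning-parameter selection for a single-disease lasso logistic fit
#'
#' The separate-analysis counterpart of [select_tuning_markers()]: one
#' disease, `lambda2 = 0`, same criteria.
#'
#' @inheritParams select_tuning_markers
#' @param d an `omics_dataset`.
#' @return the selected single-dataset `marker_fit` with `$path`.
#' @export
select_tuning_lasso_logistic <- function(d, lambda1_grid = NULL,
                                         criterion = c("bic", "cv"),
                                         cv_rule = c("1se", "min"),
                                         feature = c("expression", "cnv"),
                                         nlambda1 = 10, nfolds = 5,
                                         seed = NULL, ebic_gamma = 0.5,
                                         tol = 1e-5, max_sweeps = 1000,
                                         normalize_likelihood = TRUE) {
  criterion <- match.arg(criterion)
  cv_rule <- match.arg(cv_rule)
  feature <- match.arg(feature)
  if (is.null(lambda1_grid)) {
    lmax <- lambda_max_markers(list(d), feature, normalize_likelihood)
    lambda1_grid <- exp(seq(log(lmax), log(0.05 * lmax),
                            length.out = nlambda1))
  }
  lambda1_grid <- sort(lambda1_grid, decreasing = TRUE)
  if (!is.null(seed)) set.seed(seed)
  folds <- NULL
  if (criterion == "cv") {
    folds <- stratified_folds(d$y, nfolds)
    tab <- table(folds, d$y)
    if (any(tab == 0) || nrow(tab) < nfolds)
      stop("degenerate cross-validation folds; reduce nfolds")
  }
  fits <- vector("list", length(lambda1_grid))
  df <- numeric(length(lambda1_grid))
  score <- numeric(length(lambda1_grid))
  se <- rep(NA_real_, length(lambda1_grid))
  init <- NULL
  cv_inits <- vector("list", if (criterion == "cv") nfolds else 0)
  for (g in seq_along(lambda1_grid)) {
    l1 <- lambda1_grid[g]
    fit <- suppressWarnings(fit_lasso_logistic(
      d, l1, feature = feature, init = init, tol = tol,
      max_sweeps = max_sweeps,
      normalize_likelihood = normalize_likelihood))
    init <- list(beta = fit$beta, intercepts = fit$intercepts)
    fits[[g]] <- fit
    df[g] <- sum(fit$beta[[1]] != 0)
    if (criterion == "bic") {
      score[g] <- -2 * fit$loglik + log(fit$n) * df[g] +
        2 * ebic_gamma * lchoose(length(fit$beta[[1]]), df[g])
    } else {
      folddev <- vapply(seq_len(nfolds), function(f) {
        cvfit <- suppressWarnings(fit_lasso_logistic(
          dataset_rows(d, folds != f), l1, feature = feature,
          init = cv_inits[[f]], tol = tol, max_sweeps = max_sweeps,
          normalize_likelihood = normalize_likelihood))
        cv_inits[[f]] <<- list(beta = cvfit$beta,
                               intercepts = cvfit$intercepts)
        marker_deviance(cvfit, list(dataset_rows(d, folds == f)))
      }, numeric(1))
      score[g] <- mean(folddev)
      se[g] <- sd(folddev) / sqrt(nfolds)
    }
  }
  pick <- pick_from_grid(data.frame(lambda1 = lambda1_grid, lambda2 = 0),
                         score, se, criterion, cv_rule)
  best <- fits[[pick]]
  best$path <- data.frame(lambda1 = lambda1_grid, df = df, score = score,
                          se = se)
  best$criterion <- criterion
  best
}
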