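#' Reversed regression of CNV on expression components
#'
#' Least-squares fit of every CNV column on the expression PC scores,
#' \eqn{Z = X_{pc} \omega + \epsilon}. This "reversed" direction is used to
#' split CNV into a component overlapping with expression and an
#' independent remainder. A small ridge penalty is added automatically when
#' the score matrix is rank deficient.
#'
#' @param Z n x p CNV matrix.
#' @param Xpc n x K expression score matrix.
#' @param ridge ridge penalty used only on rank deficiency.
#' @return K x p coefficient matrix `omega_hat`.
#' @export
reverse_regress <- function(Z, Xpc, ridge = 1e-6) {
  Z <- as.matrix(Z)
  Xpc <- as.matrix(Xpc)
  if (nrow(Z) != nrow(Xpc))
    stop("Z has ", nrow(Z), " rows but Xpc has ", nrow(Xpc))
  G <- crossprod(Xpc)
  if (qr(Xpc)$rank < ncol(Xpc)) {
    warning("rank-deficient score matrix; using ridge-regularized ",
            "least squares")
    G <- G + ridge * diag(ncol(Xpc))
  }
  omega <- solve(G, crossprod(Xpc, Z))
  dimnames(omega) <- list(colnames(Xpc), colnames(Z))
  omega
}

#' CNV residual after removing the expression-overlapping component
#'
#' @param Z n x p CNV matrix.
#' @param Xpc n x K expression score matrix.
#' @param omega_hat K x p coefficients from [reverse_regress()].
#' @return n x p residual matrix `Z - Xpc %*% omega_hat`; when `omega_hat`
#'   is the least-squares solution the residual is orthogonal to the
#'   scores.
#' @export
residualize <- function(Z, Xpc, omega_hat) {
  Z <- as.matrix(Z)
  Xpc <- as.matrix(Xpc)
  omega_hat <- as.matrix(omega_hat)
  if (nrow(Z) != nrow(Xpc) || ncol(Xpc) != nrow(omega_hat) ||
      ncol(omega_hat) != ncol(Z))
    stop("non-conforming shapes: Z ", nrow(Z), "x", ncol(Z), ", Xpc ",
         nrow(Xpc), "x", ncol(Xpc), ", omega_hat ", nrow(omega_hat), "x",
         ncol(omega_hat))
  Z - Xpc %*% omega_hat
}

# internal unpenalized (or ridge-stabilized) logistic regression by IRLS
fit_logistic_irls <- function(S, y, ridge = 0, maxit = 100, tol = 1e-8) {
  S <- as.matrix(S)
  n <- nrow(S)
  D <- cbind(`(Intercept)` = 1, S)
  q <- ncol(D)
  pen <- diag(c(0, rep(ridge, q - 1)), q)
  coefs <- rep(0, q)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(D %*% coefs)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zr <- eta + (y - mu) / w
    H <- crossprod(D, w * D) + pen
    new <- tryCatch(drop(solve(H, crossprod(D, w * zr))),
                    error = function(e) NULL)
    if (is.null(new)) break
    delta <- max(abs(new - coefs))
    coefs <- new
    if (!all(is.finite(coefs))) break
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(D %*% coefs)
  loglik <- sum(y * eta - ifelse(eta > 35, eta, log1p(exp(eta))))
  list(alpha = coefs[1], theta = coefs[-1], loglik = loglik,
       converged = converged && all(is.finite(coefs)) &&
         max(abs(coefs[-1])) < 1e3,
       fitted = plogis(eta))
}

#' Vertical integrative outcome model
#'
#' Fits one of four outcome-model variants for a single disease-vs-control
#' dataset carrying expression (`X`) and CNV (`Z`) blocks:
#'
#' * `A1` (integrative): sparse PCA of `X`; reversed regression of `Z` on
#'   the expression scores; sparse PCA of the CNV residual; logistic model
#'   on the combined expression and residual-CNV scores.
#' * `A2`: sparse PCA of `X` and of `Z` separately, scores stacked (no
#'   decomposition).
#' * `A3` / `A4`: sparse PCA of `X` only / `Z` only.
#'
#' Coefficients are estimated by unpenalized maximum likelihood; on
#' separation or non-convergence a ridge-stabilized fit (penalty `1e-4`) is
#' used with a warning.
#'
#' @param dataset an `omics_dataset` with outcome `y` and the blocks the
#'   variant needs.
#' @param variant `"A1"`, `"A2"`, `"A3"` or `"A4"`.
#' @param n_components components per block (truncated to
#'   `min(n_components, n - 1, p)`).
#' @param sparsity L1 bound for sparse PCA; default `sqrt(p)/2` per block.
#' @param scale. scale columns before sparse PCA.
#' @param force_omega_zero diagnostic switch: fixes the reversed-regression
#'   coefficients at zero, making `A1` coincide with `A2`.
#' @return object of class `vertical_fit` with elements `expr_spca`,
#'   `omega_hat`, `resid_spca`, `theta_x`, `theta_z`, `alpha`, `loglik`,
#'   `fitted`.
#' @export
fit_vertical <- function(dataset, variant = c("A1", "A2", "A3", "A4"),
                         n_components = 10, sparsity = NULL, scale. = FALSE,
                         force_omega_zero = FALSE) {
  variant <- match.arg(variant)
  stopifnot(inherits(dataset, "omics_dataset"))
  y <- dataset$y
  if (is.null(y) || length(unique(y)) < 2)
    stop("dataset must contain both outcome classes")
  n <- length(y)
  need_x <- variant %in% c("A1", "A2", "A3")
  need_z <- variant %in% c("A1", "A2", "A4")
  if (need_x && is.null(dataset$X)) stop("variant ", variant, " needs X")
  if (need_z && is.null(dataset$Z)) stop("variant ", variant, " needs Z")

  expr_spca <- NULL
  omega_hat <- NULL
  resid_spca <- NULL
  Sx <- NULL
  Sz <- NULL

  if (need_x) {
    p <- ncol(dataset$X)
    K <- min(n_components, n - 1, p)
    cx <- if (is.null(sparsity)) sqrt(p) / 2 else sparsity
    expr_spca <- sparse_pca(dataset$X, K = K, c = cx, scale. = scale.)
    Sx <- expr_spca$scores
  }
  if (need_z) {
    p <- ncol(dataset$Z)
    K <- min(n_components, n - 1, p)
    cz <- if (is.null(sparsity)) sqrt(p) / 2 else sparsity
    if (variant == "A1") {
      omega_hat <- if (force_omega_zero) {
        matrix(0, ncol(Sx), p, dimnames = list(colnames(Sx),
                                               colnames(dataset$Z)))
      } else reverse_regress(dataset$Z, Sx)
      R <- residualize(dataset$Z, Sx, omega_hat)
      resid_spca <- sparse_pca(R, K = K, c = cz, scale. = scale.)
      Sz <- resid_spca$scores
    } else {
      resid_spca <- sparse_pca(dataset$Z, K = K, c = cz, scale. = scale.)
      Sz <- resid_spca$scores
    }
  }

  S <- cbind(Sx, Sz)
  fit <- fit_logistic_irls(S, y)
  if (!fit$converged) {
    warning("maximum-likelihood logistic did not converge (possible ",
            "separation); refitting with ridge stabilization 1e-4")
    fit <- fit_logistic_irls(S, y, ridge = 1e-4)
  }
  kx <- if (is.null(Sx)) 0 else ncol(Sx)
  kz <- if (is.null(Sz)) 0 else ncol(Sz)
  structure(list(
    variant = variant, expr_spca = expr_spca, omega_hat = omega_hat,
    resid_spca = resid_spca,
    theta_x = if (kx) fit$theta[seq_len(kx)] else NULL,
    theta_z = if (kz) fit$theta[kx + seq_len(kz)] else NULL,
    alpha = fit$alpha, loglik = fit$loglik, fitted = fit$fitted,
    gene_ids = dataset$gene_ids, n = n), class = "vertical_fit")
}

#' @export
print.vertical_fit <- function(x, ...) {
  cat("vertical_fit (", x$variant, "): n =", x$n, "\n")
  cat("  components:",
      if (!is.null(x$theta_x)) paste0(length(x$theta_x), " expression"),
      if (!is.null(x$theta_z)) paste0(length(x$theta_z), " CNV"), "\n")
  cat("  log-likelihood:", signif(x$loglik, 6), "\n")
  invisible(x)
}

#' Predict case probabilities from a vertical fit
#'
#' New samples are centered with the training centering, projected on the
#' training loadings and (for `A1`) residualized with the training
#' `omega_hat`; no refitting occurs, as required for honest resampled
#' prediction.
#'
#' @param object a `vertical_fit`.
#' @param newdata an `omics_dataset` with the same genes as training.
#' @param ... unused.
#' @return vector of case probabilities in (0, 1).
#' @export
predict.vertical_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "omics_dataset"))
  if (!identical(newdata$gene_ids, object$gene_ids))
    stop("gene identifiers of newdata do not match the training data")
  Sx <- NULL
  Sz <- NULL
  if (!is.null(object$expr_spca))
    Sx <- predict(object$expr_spca, newdata$X)
  if (!is.null(object$resid_spca)) {
    if (object$variant == "A1") {
      R <- residualize(newdata$Z, Sx, object$omega_hat)
      Sz <- predict(object$resid_spca, R)
    } else {
      Sz <- predict(object$resid_spca, newdata$Z)
    }
  }
  eta <- object$alpha
  if (!is.null(Sx)) eta <- eta + drop(Sx %*% object$theta_x)
  if (!is.null(Sz)) eta <- eta + drop(Sz %*% object$theta_z)
  plogis(eta)
}

#' @rdname predict.vertical_fit
#' @param fit a `vertical_fit`.
#' @param dataset an `omics_dataset` to score.
#' @export
predict_vertical <- function(fit, dataset) predict(fit, dataset)
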