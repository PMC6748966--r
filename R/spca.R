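#' Rank-one penalized matrix decomposition
#'
#' Alternating maximization of \eqn{u^T A v} subject to \eqn{\|u\|_2 \le 1},
#' \eqn{\|v\|_2 \le 1}, \eqn{\|v\|_1 \le c}: the rank-one step of sparse PCA
#' by penalized matrix decomposition. The v-update soft-thresholds
#' \eqn{A^T u} and rescales to unit norm, with the threshold found by
#' bisection so the L1 bound is met.
#'
#' @param A numeric n x p matrix, assumed column-centered.
#' @param c L1 bound on v; must satisfy `c >= 1` (with `c = sqrt(p)` the
#'   constraint is vacuous and v is the leading right singular vector).
#' @param tol convergence tolerance on the change in d.
#' @param max_iter maximum alternations.
#' @return list with unit vectors `u` (length n) and sparse `v` (length p),
#'   the value `d = t(u) %*% A %*% v`, the per-iteration objective trace,
#'   and the iteration count. `v` is sign-normalized so its
#'   largest-magnitude entry is positive.
#' @export
pmd_rank_one <- function(A, c, tol = 1e-7, max_iter = 200) {
  A <- as.matrix(A)
  if (c < 1) stop("c must be >= 1 (no unit vector has L1 norm below 1)")
  if (all(A == 0)) stop("A is all zero")
  v <- svd(A, nu = 0, nv = 1)$v[, 1]
  v <- l1_project_unit(v, c)
  d_old <- -Inf
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    Av <- drop(A %*% v)
    nu <- sqrt(sum(Av^2))
    if (nu == 0) break
    u <- Av / nu
    sv <- drop(crossprod(A, u))
    v <- l1_project_unit(sv, c)
    d <- sum(u * drop(A %*% v))
    trace <- c(trace, d)
    if (is.finite(d_old) && abs(d - d_old) < tol) break
    d_old <- d
  }
  imax <- which.max(abs(v))
  if (v[imax] < 0) { v <- -v; u <- -u }
  d <- sum(u * drop(A %*% v))
  list(u = u, d = d, v = v, objective_trace = trace, iterations = it)
}

# soft-threshold x and rescale to unit L2 norm such that the result has
# L1 norm <= c; the threshold is found by bisection (smaller thresholds
# preferred on ties).
l1_project_unit <- function(x, c) {
  ax <- abs(x)
  nx <- sqrt(sum(ax * ax))
  if (nx == 0) return(x)
  if (sum(ax) <= c * nx * (1 + 1e-12)) return(x / nx)
  lo <- 0
  hi <- max(ax)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    w <- ax - mid
    w[w < 0] <- 0
    nw <- sqrt(sum(w * w))
    if (sum(w) > c * nw) lo <- mid else hi <- mid
  }
  w <- ax - hi
  w[w < 0] <- 0
  if (all(w == 0)) w[which.max(ax)] <- 1  # degenerate boundary: c ~ 1
  # drop numerical dust left by the bisection boundary
  w[w < 1e-9 * max(w)] <- 0
  v <- sign(x) * w
  v / sqrt(sum(v * v))
}

#' Sparse principal component analysis
#'
#' Extracts `K` sparse components by repeated rank-one penalized matrix
#' decomposition with rank-one deflation (`A <- A - d u v'` after each
#' component). Columns are mean-centered first (optionally scaled); scores
#' are the centered input projected on the sparse loadings.
#'
#' @param A numeric n x p data matrix (samples in rows).
#' @param K number of components; must satisfy `K <= min(n - 1, p)`.
#' @param c L1 sparsity bound passed to [pmd_rank_one()]; the default
#'   `sqrt(p)/2` gives moderately sparse loadings.
#' @param center,scale. center/scale columns before decomposition.
#' @param tol,max_iter convergence controls for each rank-one fit.
#' @return object of class `sparse_pca`: `loadings` (p x K, unit-norm
#'   columns), `scores` (n x K), `d` (non-increasing), `center`, `scale`,
#'   `sparsity_bound`.
#' @export
sparse_pca <- function(A, K, c = sqrt(ncol(A)) / 2, center = TRUE,
                       scale. = FALSE, tol = 1e-7, max_iter = 200) {
  A <- as.matrix(A)
  n <- nrow(A)
  p <- ncol(A)
  if (K > min(n - 1, p))
    stop("K = ", K, " exceeds min(n - 1, p) = ", min(n - 1, p))
  ctr <- if (center) colMeans(A) else rep(0, p)
  scl <- if (scale.) apply(A, 2, sd) else rep(1, p)
  scl[scl == 0] <- 1
  Ac <- sweep(sweep(A, 2, ctr), 2, scl, "/")
  loadings <- matrix(0, p, K)
  d <- numeric(K)
  Awork <- Ac
  for (k in seq_len(K)) {
    fit <- pmd_rank_one(Awork, c, tol = tol, max_iter = max_iter)
    loadings[, k] <- fit$v
    d[k] <- fit$d
    Awork <- Awork - fit$d * tcrossprod(fit$u, fit$v)
  }
  ord <- order(d, decreasing = TRUE)
  loadings <- loadings[, ord, drop = FALSE]
  d <- d[ord]
  scores <- Ac %*% loadings
  dimnames(loadings) <- list(colnames(A), paste0("PC", seq_len(K)))
  dimnames(scores) <- list(rownames(A), paste0("PC", seq_len(K)))
  structure(list(loadings = loadings, scores = scores, d = d, center = ctr,
                 scale = scl, sparsity_bound = c),
            class = "sparse_pca")
}

#' @export
print.sparse_pca <- function(x, ...) {
  nz <- colSums(x$loadings != 0)
  cat("sparse_pca:", ncol(x$loadings), "components,",
      nrow(x$loadings), "variables\n")
  cat("  nonzero loadings per component:", paste(nz, collapse = " "), "\n")
  cat("  d:", paste(signif(x$d, 4), collapse = " "), "\n")
  invisible(x)
}

#' Project new samples on fitted sparse components
#'
#' @param object a `sparse_pca` fit.
#' @param newdata matrix with the same columns as the training data.
#' @param ... unused.
#' @return n x K score matrix using the training centering/scaling.
#' @export
predict.sparse_pca <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$loadings))
    stop("newdata has ", ncol(newdata), " columns, expected ",
         nrow(object$loadings))
  Ac <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  Ac %*% object$loadings
}

#' Choose the sparsity bound from a target support size
#'
#' Convenience bisection on the L1 bound `c` of [pmd_rank_one()] so that the
#' first component has approximately `target_nonzero` nonzero loadings.
#'
#' @param A centered data matrix.
#' @param target_nonzero desired nonzero count of the leading loadings.
#' @param tol bisection tolerance on `c`.
#' @return the chosen bound.
#' @export
tune_sparsity_bound <- function(A, target_nonzero, tol = 1e-3) {
  p <- ncol(A)
  stopifnot(target_nonzero >= 1, target_nonzero <= p)
  lo <- 1
  hi <- sqrt(p)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    nz <- sum(pmd_rank_one(A, mid)$v != 0)
    if (nz < target_nonzero) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
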