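#' Cross-disease penalized regulation estimation
#'
#' Estimates the expression-on-CNV regulation coefficient matrices
#' \eqn{\eta^{(k)}} of the linear model \eqn{x_{ij}^{(k)} = z_i^{(k)}
#' \eta_j^{(k)} + \delta_{ij}^{(k)}} for two diseases jointly, minimizing
#' \deqn{\sum_k \frac{1}{2 n^{(k)}} \sum_j \sum_i (x_{ij}^{(k)} - z_i^{(k)}
#'   \eta_j^{(k)})^2 + \lambda_3 \sum_{k,j,l} |\eta_{jl}^{(k)}| + \lambda_4
#'   \sum_j \rho(\eta_j^{(1)}, \eta_j^{(2)})}
#' where \eqn{\rho} is the magnitude- or sign-based fusion penalty. The
#' problem decouples over genes and is solved as p independent fused
#' regressions by exact coordinate descent. Cis (diagonal) entries are
#' penalized like any other.
#'
#' Expression responses are centered and CNV predictors standardized per
#' dataset; coefficients are returned on the standardized-predictor scale
#' with the scaling attached. A zero-variance CNV column has its
#' coefficients fixed at 0 with a warning.
#'
#' @param d1,d2 `omics_dataset` objects carrying both `X` and `Z` over the
#'   same genes.
#' @param lambda3 non-negative lasso penalty.
#' @param lambda4 non-negative fusion penalty.
#' @param penalty `"magnitude"`, `"sign"` or `"none"`.
#' @param tol,max_sweeps coordinate-descent controls (per gene).
#' @return object of class `regulation_fit`: `eta` (list of two p x p
#'   matrices, row j = coefficients of all CNVs on expression j),
#'   `objective_trace` (summed over genes, padded to a common length),
#'   `gene_traces`, `lambda3`, `lambda4`, `penalty`.
#' @export
solve_penalized_regulation <- function(d1, d2, lambda3, lambda4,
                                       penalty = c("magnitude", "sign",
                                                   "none"),
                                       tol = 1e-5, max_sweeps = 1000,
                                       sign_tau = 1e-2) {
  penalty <- match.arg(penalty)
  stopifnot(lambda3 >= 0, lambda4 >= 0)
  datasets <- list(d1, d2)
  if (!identical(d1$gene_ids, d2$gene_ids))
    stop("the two datasets must share gene identifiers")
  for (d in datasets)
    if (is.null(d$X) || is.null(d$Z))
      stop("both X and Z blocks are required")
  fit_regulation_core(datasets, lambda3, lambda4, penalty, tol, max_sweeps,
                      sign_tau)
}

# internal: shared core for one- and two-dataset regulation fits
fit_regulation_core <- function(datasets, lambda3, lambda4, penalty, tol,
                                max_sweeps, sign_tau = 1e-2) {
  two <- length(datasets) == 2
  genes <- datasets[[1]]$gene_ids
  p <- length(genes)
  prep <- lapply(datasets, function(d) {
    s <- standardize_block(d$Z)
    if (any(s$zero_var))
      warning("zero-variance CNV column(s) ",
              paste(genes[s$zero_var], collapse = ", "),
              "; their coefficients are fixed at 0")
    s$M[, s$zero_var] <- 0  # curvature 0 => coefficient pinned at 0
    s$Xc <- scale(d$X, center = TRUE, scale = FALSE)
    s
  })
  eta <- lapply(seq_along(datasets),
                function(k) matrix(0, p, p, dimnames = list(genes, genes)))
  gene_traces <- vector("list", p)
  dummy <- matrix(0, 1, p)
  for (j in seq_len(p)) {
    if (two) {
      res <- cd_fused_gaussian_cpp(prep[[1]]$M, prep[[1]]$Xc[, j],
                                   prep[[2]]$M, prep[[2]]$Xc[, j],
                                   lambda3, lambda4,
                                   penalty_code(penalty), sign_tau,
                                   rep(0, p), rep(0, p), tol,
                                   as.integer(max_sweeps), TRUE)
      eta[[2]][j, ] <- res$beta2
    } else {
      res <- cd_fused_gaussian_cpp(prep[[1]]$M, prep[[1]]$Xc[, j], dummy,
                                   0, lambda3, 0, 0L, 1e-2, rep(0, p),
                                   rep(0, p), tol, as.integer(max_sweeps),
                                   FALSE)
    }
    eta[[1]][j, ] <- res$beta1
    gene_traces[[j]] <- res$objective_trace
  }
  len <- max(vapply(gene_traces, length, integer(1)))
  padded <- vapply(gene_traces, function(tr) {
    c(tr, rep(tr[length(tr)], len - length(tr)))
  }, numeric(len))
  total_trace <- if (len == 1) sum(padded) else rowSums(padded)
  rss <- vapply(seq_along(datasets), function(k) {
    sum((prep[[k]]$Xc - tcrossprod(prep[[k]]$M, eta[[k]]))^2)
  }, numeric(1))
  structure(list(
    eta = eta, lambda3 = lambda3, lambda4 = lambda4, penalty = penalty,
    objective_trace = total_trace, gene_traces = gene_traces, rss = rss,
    center = lapply(prep, `[[`, "center"),
    scale = lapply(prep, `[[`, "scale"),
    n = vapply(datasets, function(d) length(d$sample_ids), numeric(1)),
    groups = vapply(datasets, `[[`, character(1), "group_label"),
    gene_ids = genes), class = "regulation_fit")
}

#' Single-group lasso regulation estimation
#'
#' Per-gene lasso regressions of expression on all CNVs for one group (the
#' separate-analysis baseline, also used for the normal group).
#'
#' @inheritParams solve_penalized_regulation
#' @param d an `omics_dataset` with both blocks.
#' @return a `regulation_fit` with a single coefficient matrix.
#' @export
fit_lasso_regulation <- function(d, lambda3, tol = 1e-5,
                                 max_sweeps = 1000) {
  stopifnot(lambda3 >= 0)
  if (is.null(d$X) || is.null(d$Z))
    stop("both X and Z blocks are required")
  fit_regulation_core(list(d), lambda3, 0, "none", tol, max_sweeps)
}

#' @export
print.regulation_fit <- function(x, ...) {
  cat("regulation_fit (", x$penalty, "penalty ):", length(x$eta),
      "group(s),", length(x$gene_ids), "genes\n")
  cat("  lambda3 =", signif(x$lambda3, 4), " lambda4 =",
      signif(x$lambda4, 4), "\n")
  for (k in seq_along(x$eta))
    cat("  group", k, "(", x$groups[k], "): ", sum(x$eta[[k]] != 0),
        "regulations\n")
  invisible(x)
}

#' @export
support.regulation_fit <- function(object) {
  lapply(object$eta, function(e) e != 0)
}

#' Squared-difference distance between regulation matrices
#'
#' \deqn{{\rm Dist} = \sum_j \sum_l (\eta_{jl}^{A} - \eta_{jl}^{B})^2,}
#' the magnitude-and-sign sensitive distance between two estimated
#' regulation coefficient matrices, summed over genes.
#'
#' @param etaA,etaB p x p coefficient matrices.
#' @return non-negative scalar.
#' @export
dist_matrices <- function(etaA, etaB) {
  if (!identical(dim(etaA), dim(etaB)))
    stop("matrices must have identical shape")
  sum((etaA - etaB)^2)
}

#' Sign-difference distance between regulation matrices
#'
#' \deqn{{\rm SignDist} = \sum_j \sum_l ({\rm Sgn}(\eta_{jl}^{A}) -
#'   {\rm Sgn}(\eta_{jl}^{B}))^2,}
#' sensitive only to the directions of regulation (`Sgn(0) = 0`).
#'
#' @inheritParams dist_matrices
#' @return non-negative scalar.
#' @export
signdist_matrices <- function(etaA, etaB) {
  if (!identical(dim(etaA), dim(etaB)))
    stop("matrices must have identical shape")
  sum((sign(etaA) - sign(etaB))^2)
}

#' Pairwise regulation distances for disease and normal groups
#'
#' Convenience summary of [dist_matrices()] and [signdist_matrices()] over
#' all group pairs, in the usual disease-disease vs disease-normal layout.
#'
#' @param fits named list of `regulation_fit` objects (single-matrix fits
#'   or the two matrices of a joint fit are expanded by group label).
#' @return data.frame with columns `pair`, `dist`, `signdist`.
#' @export
regulation_distances <- function(fits) {
  mats <- list()
  for (f in fits)
    for (k in seq_along(f$eta)) mats[[f$groups[k]]] <- f$eta[[k]]
  nms <- names(mats)
  pairs <- utils::combn(nms, 2)
  data.frame(
    pair = apply(pairs, 2, paste, collapse = "-"),
    dist = apply(pairs, 2, function(pr)
      dist_matrices(mats[[pr[1]]], mats[[pr[2]]])),
    signdist = apply(pairs, 2, function(pr)
      signdist_matrices(mats[[pr[1]]], mats[[pr[2]]])))
}

#' Smallest lasso penalty giving all-zero regulation matrices
#'
#' @param datasets list of `omics_dataset` objects with both blocks.
#' @return max over genes, CNVs and datasets of
#'   `|z_l' x_j| / n` on standardized predictors and centered responses.
#' @export
lambda_max_regulations <- function(datasets) {
  mx <- 0
  for (d in datasets) {
    Zs <- standardize_block(d$Z)$M
    Xc <- scale(d$X, center = TRUE, scale = FALSE)
    mx <- max(mx, max(abs(crossprod(Zs, Xc))) / nrow(Zs))
  }
  mx * (1 + 1e-10)
}

#' Tuning-parameter selection for regulation estimation
#'
#' Grid search over a global `(lambda3, lambda4)` pair shared across
#' genes, scored by BIC summed over genes and datasets: per gene and
#' dataset, \eqn{n \log({\rm RSS}/n) + \log(n)\,\mathrm{df}}. The default
#' `"bic_fused"` uses fusion-aware effective degrees of freedom (an
#' actively fused pair of regulation coefficients counts as between one
#' and two parameters); `"bic"` counts nonzeros. A per-gene variant
#' selecting `lambda3` independently per gene is available.
#'
#' @inheritParams solve_penalized_regulation
#' @param lambda3_grid descending lasso grid; default log-spaced over
#'   `[0.05, 1] * lambda_max` of length `nlambda3`.
#' @param lambda4_grid fusion grid; default `c(0, 0.1, 0.5, 2)`.
#' @param criterion `"bic_fused"` (default) or `"bic"`.
#' @param nlambda3 default lasso grid length.
#' @param ebic_gamma weight of the extended-BIC term (0 recovers plain
#'   per-gene BIC; 0.5 is the usual high-dimensional default).
#' @param per_gene select `lambda3` per gene (with `lambda4` still global).
#' @return the selected `regulation_fit` with the grid record in `$path`.
#' @export
select_tuning_regulations <- function(d1, d2,
                                      penalty = c("magnitude", "sign",
                                                  "none"),
                                      lambda3_grid = NULL,
                                      lambda4_grid = NULL,
                                      criterion = c("bic_fused", "bic"),
                                      nlambda3 = 10, ebic_gamma = 0.5,
                                      per_gene = FALSE, tol = 1e-5,
                                      max_sweeps = 1000) {
  penalty <- match.arg(penalty)
  criterion <- match.arg(criterion)
  if (is.null(lambda3_grid)) {
    lmax <- lambda_max_regulations(list(d1, d2))
    lambda3_grid <- exp(seq(log(lmax), log(0.05 * lmax),
                            length.out = nlambda3))
  }
  lambda3_grid <- sort(lambda3_grid, decreasing = TRUE)
  if (is.null(lambda4_grid))
    lambda4_grid <- if (penalty == "none") 0 else c(0, 0.1, 0.5, 2)
  if (!length(lambda3_grid) || !length(lambda4_grid))
    stop("empty tuning grid")
  p <- length(d1$gene_ids)

  # per-coordinate curvatures of the (1/2n)RSS losses, for effective df
  vcurv <- lapply(list(d1, d2), function(d) {
    Zs <- standardize_block(d$Z)$M
    colSums(Zs^2) / nrow(Zs)
  })
  # per-gene BIC contributions, one column per dataset; under "bic_fused"
  # the df of gene j is the effective df of its fused coefficient pair
  pergene_bic <- function(fit) {
    dfm <- vapply(seq_len(p), function(j) {
      if (criterion == "bic_fused") {
        dfe <- fused_effective_df(fit$eta[[1]][j, ], fit$eta[[2]][j, ],
                                  vcurv[[1]], vcurv[[2]], fit$lambda4,
                                  fit$penalty)
        # split the pair df evenly between the two datasets
        c(dfe / 2, dfe / 2)
      } else {
        c(sum(fit$eta[[1]][j, ] != 0), sum(fit$eta[[2]][j, ] != 0))
      }
    }, numeric(2))
    vapply(seq_along(fit$eta), function(k) {
      n <- fit$n[k]
      Xc <- scale(if (k == 1) d1$X else d2$X, center = TRUE, scale = FALSE)
      Zs <- sweep(sweep(if (k == 1) d1$Z else d2$Z, 2, fit$center[[k]]),
                  2, fit$scale[[k]], "/")
      rss_j <- colSums((Xc - tcrossprod(Zs, fit$eta[[k]]))^2)
      df_nz <- rowSums(fit$eta[[k]] != 0)
      n * log(pmax(rss_j, 1e-12) / n) + log(n) * dfm[k, ] +
        2 * ebic_gamma * lchoose(p, df_nz)
    }, numeric(p))
  }

  path <- NULL
  best <- NULL
  best_score <- Inf
  for (l4 in lambda4_grid) {
    fits_l4 <- vector("list", length(lambda3_grid))
    scores_l4 <- matrix(NA_real_, p, length(lambda3_grid))
    for (gi in seq_along(lambda3_grid)) {
      l3 <- lambda3_grid[gi]
      fit <- suppressWarnings(solve_penalized_regulation(
        d1, d2, l3, l4, penalty = penalty, tol = tol,
        max_sweeps = max_sweeps))
      gs <- rowSums(pergene_bic(fit))
      fits_l4[[gi]] <- fit
      scores_l4[, gi] <- gs
      path <- rbind(path, data.frame(lambda3 = l3, lambda4 = l4,
                                     df = sum(fit$eta[[1]] != 0) +
                                       sum(fit$eta[[2]] != 0),
                                     score = sum(gs)))
      if (!per_gene && sum(gs) < best_score) {
        best_score <- sum(gs)
        best <- fit
      }
    }
    if (per_gene) {
      pick <- apply(scores_l4, 1, which.min)
      total <- sum(scores_l4[cbind(seq_len(p), pick)])
      if (total < best_score) {
        best_score <- total
        best <- fits_l4[[1]]
        for (j in seq_len(p)) {
          src <- fits_l4[[pick[j]]]
          best$eta[[1]][j, ] <- src$eta[[1]][j, ]
          best$eta[[2]][j, ] <- src$eta[[2]][j, ]
        }
        best$lambda3 <- lambda3_grid[pick]
        best$lambda4 <- l4
      }
    }
  }
  best$path <- path
  best$criterion <- criterion
  best
}

#' Tuning-parameter selection for single-group lasso regulation
#'
#' BIC-selected `lambda3` for [fit_lasso_regulation()] (the separate
#' baseline and the normal group).
#'
#' @inheritParams fit_lasso_regulation
#' @param lambda3_grid descending grid; default as in
#'   [select_tuning_regulations()].
#' @param nlambda3 default grid length.
#' @param per_gene select `lambda3` per gene.
#' @return the selected `regulation_fit`.
#' @export
select_tuning_lasso_regulation <- function(d, lambda3_grid = NULL,
                                           nlambda3 = 10,
                                           ebic_gamma = 0.5,
                                           per_gene = FALSE, tol = 1e-5,
                                           max_sweeps = 1000) {
  if (is.null(lambda3_grid)) {
    lmax <- lambda_max_regulations(list(d))
    lambda3_grid <- exp(seq(log(lmax), log(0.05 * lmax),
                            length.out = nlambda3))
  }
  lambda3_grid <- sort(lambda3_grid, decreasing = TRUE)
  p <- length(d$gene_ids)
  n <- length(d$sample_ids)
  Xc <- scale(d$X, center = TRUE, scale = FALSE)
  fits <- lapply(lambda3_grid, function(l3)
    suppressWarnings(fit_lasso_regulation(d, l3, tol = tol,
                                          max_sweeps = max_sweeps)))
  score <- vapply(fits, function(fit) {
    Zs <- sweep(sweep(d$Z, 2, fit$center[[1]]), 2, fit$scale[[1]], "/")
    resid <- Xc - tcrossprod(Zs, fit$eta[[1]])
    rss_j <- colSums(resid^2)
    df_j <- rowSums(fit$eta[[1]] != 0)
    sum(n * log(pmax(rss_j, 1e-12) / n) + log(n) * df_j +
          2 * ebic_gamma * lchoose(p, df_j))
  }, numeric(1))
  if (!per_gene) return(fits[[which.min(score)]])
  per_gene_score <- vapply(fits, function(fit) {
    Zs <- sweep(sweep(d$Z, 2, fit$center[[1]]), 2, fit$scale[[1]], "/")
    resid <- Xc - tcrossprod(Zs, fit$eta[[1]])
    df_j <- rowSums(fit$eta[[1]] != 0)
    n * log(pmax(colSums(resid^2), 1e-12) / n) + log(n) * df_j +
      2 * ebic_gamma * lchoose(p, df_j)
  }, numeric(p))
  pick <- apply(per_gene_score, 1, which.min)
  best <- fits[[1]]
  for (j in seq_len(p)) best$eta[[1]][j, ] <- fits[[pick[j]]]$eta[[1]][j, ]
  best$lambda3 <- lambda3_grid[pick]
  best
}
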