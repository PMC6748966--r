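# AR(1) correlation matrix rho^|j-k|
ar1_cor <- function(p, rho) rho^abs(outer(seq_len(p), seq_len(p), "-"))

# draw n samples from N(mu, Sigma) given a precomputed upper Cholesky
mvn_chol <- function(n, mu, R) {
  p <- length(mu)
  sweep(matrix(rnorm(n * p), n, p) %*% R, 2, mu, "+")
}

#' Specification of a cross-disease marker simulation scenario
#'
#' Case-control gene-expression design with two diseases and a shared
#' normal group: disease-k cases drawn from \eqn{N(\mu_k, \Sigma)},
#' controls from \eqn{N(0, \Sigma)}, where \eqn{\Sigma} is block-diagonal
#' over the important and unimportant variables with AR(1) blocks
#' \eqn{\rho^{|j-k|}}. The four built-in scenarios vary the similarity of
#' the two disease mean vectors over the eight important variables:
#'
#' * `I`: identical means, `mu1 = mu2 = (-1,-1,-1,-1, 2, 2, 2, 2, 0, ...)`.
#' * `II`: same signs, different magnitudes,
#'   `mu2 = (-1,-1,-4,-4, 2, 2, 4, 4, 0, ...)`.
#' * `III`: same signs, different magnitudes,
#'   `mu2 = (-2,-2,-0.5,-0.5, 3, 3, 1, 1, 0, ...)`.
#' * `IV`: conflicting signs, `mu2 = (2, 2,-0.5,-0.5, 3, 3,-1,-1, 0, ...)`.
#'
#' @param scenario `"I"`, `"II"`, `"III"`, `"IV"` or `"custom"` (supply
#'   `mu1`/`mu2`).
#' @param n_per_group samples per group (two diseases + one control pool).
#' @param p number of variables.
#' @param mu1,mu2 custom mean vectors (length p), ignored for the built-in
#'   scenarios.
#' @param rho AR(1) correlation of each covariance block.
#' @param n_important number of disease-associated leading variables.
#' @return list of class `marker_scenario_spec`.
#' @export
marker_scenario_spec <- function(scenario = c("I", "II", "III", "IV",
                                              "custom"),
                                 n_per_group = 40, p = 100, mu1 = NULL,
                                 mu2 = NULL, rho = 0.3, n_important = 8) {
  scenario <- match.arg(scenario)
  if (abs(rho) >= 1) stop("|rho| must be < 1 for a positive-definite AR ",
                          "covariance")
  base1 <- c(-1, -1, -1, -1, 2, 2, 2, 2)
  base2 <- switch(scenario,
                  I = base1,
                  II = c(-1, -1, -4, -4, 2, 2, 4, 4),
                  III = c(-2, -2, -0.5, -0.5, 3, 3, 1, 1),
                  IV = c(2, 2, -0.5, -0.5, 3, 3, -1, -1),
                  custom = NULL)
  if (scenario == "custom") {
    if (is.null(mu1) || is.null(mu2))
      stop("custom scenario needs mu1 and mu2")
    stopifnot(length(mu1) == p, length(mu2) == p)
  } else {
    if (n_important != length(base1))
      stop("built-in scenarios define ", length(base1),
           " important variables")
    if (p < n_important) stop("p must be >= n_important")
    mu1 <- c(base1, rep(0, p - n_important))
    mu2 <- c(base2, rep(0, p - n_important))
  }
  structure(list(scenario = scenario, n_per_group = n_per_group, p = p,
                 mu1 = mu1, mu2 = mu2, rho = rho,
                 n_important = n_important),
            class = "marker_scenario_spec")
}

#' Simulate a cross-disease marker-identification dataset
#'
#' Draws the two disease groups and one shared control group according to a
#' [marker_scenario_spec()]; each returned dataset pairs one disease's
#' cases with the (shared) controls. Expression is stored in the `X` block.
#'
#' @param spec a `marker_scenario_spec`.
#' @param seed optional integer seed.
#' @return list with `omics_dataset`s `d1`, `d2` and `truth`, the indices
#'   of the important variables.
#' @export
simulate_marker_scenario <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "marker_scenario_spec"))
  if (!is.null(seed)) set.seed(seed)
  p <- spec$p
  m <- spec$n_important
  Sigma <- matrix(0, p, p)
  Sigma[seq_len(m), seq_len(m)] <- ar1_cor(m, spec$rho)
  if (p > m)
    Sigma[(m + 1):p, (m + 1):p] <- ar1_cor(p - m, spec$rho)
  R <- chol(Sigma)
  n <- spec$n_per_group
  cases1 <- mvn_chol(n, spec$mu1, R)
  cases2 <- mvn_chol(n, spec$mu2, R)
  controls <- mvn_chol(n, rep(0, p), R)
  genes <- paste0("g", seq_len(p))
  mk <- function(cases, label, tag) {
    X <- rbind(cases, controls)
    rownames(X) <- c(paste0(tag, seq_len(n)), paste0("ctl", seq_len(n)))
    colnames(X) <- genes
    omics_dataset(X = X, y = rep(c(1L, 0L), each = n), group_label = label)
  }
  list(d1 = mk(cases1, "bipolar", "bd"),
       d2 = mk(cases2, "schizophrenia", "sz"),
       truth = seq_len(m))
}

#' Simulate a surrogate CNV matrix
#'
#' Multivariate-normal draw with AR(1) column correlation, optionally
#' discretized by tertiles to copy-number-like levels \eqn{\{-1, 0, 1\}}.
#' A synthetic stand-in for observed CNV measurements, not a model of any
#' particular platform.
#'
#' @param n,p dimensions.
#' @param rho AR(1) correlation.
#' @param discretize map to \{-1, 0, 1\} by within-column tertiles.
#' @param seed optional integer seed.
#' @return n x p numeric matrix.
#' @export
simulate_cnv_matrix <- function(n, p, rho = 0.3, discretize = FALSE,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- chol(ar1_cor(p, rho))
  Z <- mvn_chol(n, rep(0, p), R)
  if (discretize) {
    Z <- apply(Z, 2, function(z) {
      q <- quantile(z, c(1 / 3, 2 / 3))
      ifelse(z <= q[1], -1, ifelse(z <= q[2], 0, 1))
    })
  }
  dimnames(Z) <- list(paste0("s", seq_len(n)), paste0("g", seq_len(p)))
  Z
}

#' Specification of the regulation simulation
#'
#' Sparse linear expression-on-CNV model with partially shared supports
#' across two diseases: each gene is regulated by `regulated_fraction` of
#' the CNVs; positive coefficients are drawn from
#' `Uniform(coef_pos[1], coef_pos[2])` and negative ones from
#' `Uniform(coef_neg[1], coef_neg[2])` (half of the support each); for every
#' gene the two diseases share `n_shared` regulating CNVs whose
#' coefficients have the same signs.
#'
#' @param regulated_fraction fraction of CNVs regulating each gene.
#' @param coef_pos,coef_neg ranges of the positive and negative
#'   coefficients.
#' @param n_shared number of per-gene regulators shared across diseases.
#' @param noise_sd standard deviation of the N(0, sd^2) errors.
#' @return list of class `regulation_sim_spec`.
#' @export
regulation_sim_spec <- function(regulated_fraction = 0.10,
                                coef_pos = c(0.6, 1.2),
                                coef_neg = c(-1.2, -0.6), n_shared = 6,
                                noise_sd = 1.0) {
  structure(list(regulated_fraction = regulated_fraction,
                 coef_pos = coef_pos, coef_neg = coef_neg,
                 n_shared = n_shared, noise_sd = noise_sd),
            class = "regulation_sim_spec")
}

# draw one gene's regulation coefficients: support of size m over p CNVs
# containing the given shared indices, with signs fixed for the shared
# part; `avoid` excludes the other disease's specific regulators so the
# designated sharing is exact
draw_gene_coefs <- function(p, m, shared_idx, shared_signs, spec,
                            avoid = integer(0)) {
  extra <- sample(setdiff(seq_len(p), c(shared_idx, avoid)),
                  m - length(shared_idx))
  n_pos <- floor(m / 2)
  n_neg <- m - n_pos
  pos_left <- n_pos - sum(shared_signs > 0)
  neg_left <- n_neg - sum(shared_signs < 0)
  sv <- c(rep(1, pos_left), rep(-1, neg_left))
  extra_signs <- sv[sample.int(length(sv))]
  idx <- c(shared_idx, extra)
  sgns <- c(shared_signs, extra_signs)
  coefs <- numeric(p)
  coefs[idx] <- ifelse(sgns > 0,
                       runif(m, spec$coef_pos[1], spec$coef_pos[2]),
                       runif(m, spec$coef_neg[1], spec$coef_neg[2]))
  coefs
}

#' Simulate paired expression/CNV data with known regulations
#'
#' Given CNV matrices for two diseases (observed or from
#' [simulate_cnv_matrix()]), builds ground-truth regulation matrices per
#' the [regulation_sim_spec()] construction, computes expression as
#' `X = Z %*% t(eta) + noise`, and returns the completed datasets with the
#' truth. Supports are re-drawn per gene; the shared regulators (common to
#' both diseases, same signs) are also drawn per gene. Optionally a third,
#' normal-group dataset with independently drawn regulations is produced
#' for dysregulation contrasts.
#'
#' @param spec a `regulation_sim_spec`.
#' @param Z1,Z2 n x p CNV matrices for the two diseases.
#' @param Z_normal optional CNV matrix for a normal group whose regulation
#'   structure is drawn independently of the diseases.
#' @param seed optional integer seed.
#' @return list with `omics_dataset`s `d1`, `d2` (and `d_normal` when
#'   `Z_normal` is given), truth matrices `eta1`, `eta2` (`eta_normal`),
#'   each p x p with row j holding the regulators of gene j, and `shared`,
#'   the per-gene indices of the designated shared regulators.
#' @export
simulate_regulation_data <- function(spec, Z1, Z2, Z_normal = NULL,
                                     seed = NULL) {
  stopifnot(inherits(spec, "regulation_sim_spec"))
  if (!is.null(seed)) set.seed(seed)
  Z1 <- as.matrix(Z1)
  Z2 <- as.matrix(Z2)
  p <- ncol(Z1)
  if (ncol(Z2) != p) stop("Z1 and Z2 must have the same column count")
  m <- round(spec$regulated_fraction * p)
  ns <- spec$n_shared
  if (m < ns || m > p)
    stop("support size ", m, " incompatible with ", ns,
         " shared regulators (p = ", p, ")")
  n_pos <- floor(m / 2)
  if (ns > m || min(n_pos, m - n_pos) < ceiling(ns / 2))
    stop("cannot split ", ns, " shared same-sign coefficients into the ",
         "positive/negative halves of a support of size ", m)
  if (2 * m - ns > p)
    stop("p too small for two supports of size ", m, " sharing only ",
         ns, " regulators")
  genes <- paste0("g", seq_len(p))
  eta1 <- matrix(0, p, p, dimnames = list(genes, genes))
  eta2 <- matrix(0, p, p, dimnames = list(genes, genes))
  shared <- vector("list", p)
  for (j in seq_len(p)) {
    shared_idx <- sample(seq_len(p), ns)
    ssv <- c(rep(1, floor(ns / 2)), rep(-1, ceiling(ns / 2)))
    shared_signs <- ssv[sample.int(ns)]
    eta1[j, ] <- draw_gene_coefs(p, m, shared_idx, shared_signs, spec)
    # disease-2 extras avoid disease-1's support: sharing is exactly ns
    eta2[j, ] <- draw_gene_coefs(p, m, shared_idx, shared_signs, spec,
                                 avoid = which(eta1[j, ] != 0))
    shared[[j]] <- sort(shared_idx)
  }
  make_d <- function(Z, eta, label) {
    X <- Z %*% t(eta) +
      matrix(rnorm(nrow(Z) * p, sd = spec$noise_sd), nrow(Z), p)
    colnames(X) <- genes
    colnames(Z) <- genes
    omics_dataset(X = X, Z = Z, group_label = label)
  }
  out <- list(d1 = make_d(Z1, eta1, "bipolar"),
              d2 = make_d(Z2, eta2, "schizophrenia"),
              eta1 = eta1, eta2 = eta2, shared = shared)
  if (!is.null(Z_normal)) {
    Z_normal <- as.matrix(Z_normal)
    etaN <- matrix(0, p, p, dimnames = list(genes, genes))
    for (j in seq_len(p)) {
      shared_idx <- sample(seq_len(p), ns)
      ssv <- c(rep(1, floor(ns / 2)), rep(-1, ceiling(ns / 2)))
      shared_signs <- ssv[sample.int(ns)]
      etaN[j, ] <- draw_gene_coefs(p, m, shared_idx, shared_signs, spec)
    }
    out$d_normal <- make_d(Z_normal, etaN, "control")
    out$eta_normal <- etaN
  }
  out
}

#' Simulate paired data for the vertical pipeline
#'
#' Latent-factor construction: expression is driven by two sparse factors;
#' CNV carries a scaled copy of those factors (the expression-overlapping
#' component) plus two independent factors of its own; the outcome follows
#' a logistic model on one expression factor and one independent CNV
#' factor. With `independent_cnv_effect = 0` the CNV block adds no outcome
#' information beyond expression; with `overlap_strength = 0` the reversed
#' regression has nothing to remove.
#'
#' @param n samples.
#' @param p genes (split into four equal factor blocks).
#' @param overlap_strength scale of the expression-driven CNV component.
#' @param independent_cnv_effect outcome coefficient of the independent
#'   CNV factor.
#' @param beta_expr outcome coefficient of the first expression factor.
#' @param noise_sd residual standard deviation of both omics blocks.
#' @param seed optional integer seed.
#' @return list with the `omics_dataset` and the truth (factor scores and
#'   block memberships).
#' @export
simulate_vertical_data <- function(n = 120, p = 40, overlap_strength = 0.7,
                                   independent_cnv_effect = 1.5,
                                   beta_expr = 1.5, noise_sd = 0.5,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(p >= 8)
  blocks <- split(seq_len(p), cut(seq_len(p), 4, labels = FALSE))
  f1 <- rnorm(n); f2 <- rnorm(n)  # expression factors
  g1 <- rnorm(n); g2 <- rnorm(n)  # independent CNV factors
  lx1 <- numeric(p); lx1[blocks[[1]]] <- 1
  lx2 <- numeric(p); lx2[blocks[[2]]] <- 1
  lz1 <- numeric(p); lz1[blocks[[3]]] <- 1
  lz2 <- numeric(p); lz2[blocks[[4]]] <- 1
  X <- tcrossprod(f1, lx1) + tcrossprod(f2, lx2) +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
  Z <- overlap_strength * (tcrossprod(f1, lx1) + tcrossprod(f2, lx2)) +
    tcrossprod(g1, lz1) + tcrossprod(g2, lz2) +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
  eta <- beta_expr * f1 + independent_cnv_effect * g1
  y <- rbinom(n, 1, plogis(eta))
  genes <- paste0("g", seq_len(p))
  colnames(X) <- genes
  colnames(Z) <- genes
  list(dataset = omics_dataset(X = X, Z = Z, y = y,
                               group_label = "bipolar"),
       truth = list(f1 = f1, f2 = f2, g1 = g1, g2 = g2, blocks = blocks))
}
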