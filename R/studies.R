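# Simulation-study drivers: the replicate loops used to compare the
# integrative methods (fusion penalties) against their separate-analysis
# baselines under the synthetic designs. Comparisons are made at matched
# model size: the baseline's information-criterion fit sets the support
# size, and the fused fits are taken from a fine regularization path at
# the size closest to it, so that identification accuracy (not sparsity
# calibration) is what is being compared.

#' Cross-disease marker fit at a matched support size
#'
#' Fits the fused penalized logistic model along a fine `lambda1` path for
#' each (strictly positive) fusion level and returns, per level, the fit
#' whose total support size (summed over the two diseases) is closest to
#' `target_size` with the best joint log-likelihood; across fusion levels
#' the candidate minimizing BIC with fusion-aware effective degrees of
#' freedom wins. Ties prefer the sparser fit.
#'
#' @inheritParams select_tuning_markers
#' @param target_size desired total number of nonzero coefficients.
#' @return a `marker_fit`.
#' @export
fit_markers_size_matched <- function(d1, d2,
                                     penalty = c("magnitude", "sign"),
                                     target_size,
                                     lambda2_grid = c(0.15, 0.5, 1.5),
                                     feature = c("expression", "cnv"),
                                     nlambda1 = 25, tol = 1e-5,
                                     max_sweeps = 1000) {
  penalty <- match.arg(penalty)
  feature <- match.arg(feature)
  lmax <- lambda_max_markers(list(d1, d2), feature)
  lambda1_grid <- exp(seq(log(lmax), log(0.02 * lmax),
                          length.out = nlambda1))
  vcurv <- lapply(list(d1, d2), function(d) {
    M <- standardize_block(feature_block(d, feature))$M
    0.25 * colSums(M^2) / nrow(M)
  })
  best <- NULL
  best_score <- Inf
  for (l2 in lambda2_grid) {
    cand <- NULL
    cand_key <- c(Inf, Inf)  # (|size - target|, -loglik) within the level
    init <- NULL
    for (l1 in lambda1_grid) {
      fit <- suppressWarnings(solve_penalized_logistic(
        d1, d2, l1, l2, penalty = penalty, feature = feature,
        init = init, tol = tol, max_sweeps = max_sweeps))
      init <- list(beta = fit$beta, intercepts = fit$intercepts)
      size <- sum(vapply(fit$beta, function(b) sum(b != 0), numeric(1)))
      key <- c(abs(size - target_size), -sum(fit$loglik))
      if (key[1] < cand_key[1] ||
          (key[1] == cand_key[1] && key[2] < cand_key[2])) {
        cand_key <- key
        cand <- fit
      }
      if (size > target_size + 10) break  # past the target
    }
    dfe <- fused_effective_df(cand$beta[[1]], cand$beta[[2]], vcurv[[1]],
                              vcurv[[2]], l2, penalty)
    score <- -2 * sum(cand$loglik) + log(sum(cand$n)) * dfe
    if (score < best_score) {
      best_score <- score
      best <- cand
    }
  }
  best
}

#' Marker-identification simulation study
#'
#' Runs the four-group case-control simulation for one scenario and
#' compares the two integrative approaches (magnitude- and sign-fused
#' penalized logistic regression) with the separate lasso baseline. Per
#' replicate, the baseline is tuned by extended BIC per disease; the fused
#' fits are size-matched to the baseline's total support
#' ([fit_markers_size_matched()]), so TPR/FPR differences reflect the
#' quality of marker ranking rather than different sparsity levels.
#'
#' @param scenario scenario name passed to [marker_scenario_spec()].
#' @param n_reps number of replicates.
#' @param seed integer; replicate r uses seed `seed + r`.
#' @param n_per_group,p,rho generator settings (defaults as in
#'   [marker_scenario_spec()]).
#' @param lambda2_grid fusion levels searched by the size-matched fits.
#' @return data.frame with one row per replicate and method (`B1` =
#'   magnitude, `B2` = sign, `B3` = separate lasso): columns `tpr`, `fpr`
#'   averaged over the two diseases.
#' @export
marker_simulation_study <- function(scenario, n_reps = 30, seed = 1,
                                    n_per_group = 40, p = 100, rho = 0.3,
                                    lambda2_grid = c(0.15, 0.5, 1.5)) {
  spec <- marker_scenario_spec(scenario, n_per_group = n_per_group, p = p,
                               rho = rho)
  out <- NULL
  for (r in seq_len(n_reps)) {
    ms <- simulate_marker_scenario(spec, seed = seed + r)
    b3 <- lapply(list(ms$d1, ms$d2), select_tuning_lasso_logistic)
    target <- sum(vapply(b3, function(f) sum(f$beta[[1]] != 0),
                         numeric(1)))
    sel <- list(
      B1 = support(fit_markers_size_matched(ms$d1, ms$d2, "magnitude",
                                            target,
                                            lambda2_grid = lambda2_grid)),
      B2 = support(fit_markers_size_matched(ms$d1, ms$d2, "sign", target,
                                            lambda2_grid = lambda2_grid)),
      B3 = list(support(b3[[1]])[[1]], support(b3[[2]])[[1]]))
    for (m in names(sel)) {
      mets <- lapply(sel[[m]], selection_metrics, truth = ms$truth, p = p)
      out <- rbind(out, data.frame(
        replicate = r, method = m,
        tpr = mean(vapply(mets, `[[`, numeric(1), "tpr")),
        fpr = mean(vapply(mets, `[[`, numeric(1), "fpr"))))
    }
  }
  out
}

#' Cross-disease regulation fit at a matched support size
#'
#' Regulation counterpart of [fit_markers_size_matched()]: fused per-gene
#' regressions along a `lambda3` path, returning the fit whose total
#' regulation count is closest to `target_size`.
#'
#' @inheritParams select_tuning_regulations
#' @param target_size desired total number of nonzero coefficients over
#'   both diseases.
#' @param nlambda3 path length.
#' @return a `regulation_fit`.
#' @export
fit_regulations_size_matched <- function(d1, d2,
                                         penalty = c("magnitude", "sign"),
                                         target_size,
                                         lambda4_grid = c(0.15, 0.5, 1.5),
                                         nlambda3 = 15, tol = 1e-5,
                                         max_sweeps = 1000) {
  penalty <- match.arg(penalty)
  lmax <- lambda_max_regulations(list(d1, d2))
  lambda3_grid <- exp(seq(log(lmax), log(0.02 * lmax),
                          length.out = nlambda3))
  best <- NULL
  best_key <- c(Inf, Inf)
  for (l4 in lambda4_grid) {
    for (l3 in lambda3_grid) {
      fit <- suppressWarnings(solve_penalized_regulation(
        d1, d2, l3, l4, penalty = penalty, tol = tol,
        max_sweeps = max_sweeps))
      size <- sum(fit$eta[[1]] != 0) + sum(fit$eta[[2]] != 0)
      key <- c(abs(size - target_size), sum(fit$rss))
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_key <- key
        best <- fit
      }
      if (size > target_size * 1.5 + 20) break
    }
  }
  best
}

#' Regulation-identification simulation study
#'
#' Sparse expression-on-CNV regulation simulation with partially shared
#' supports across two diseases: compares the fused approaches (`C1` =
#' magnitude, `C2` = sign) against separate per-disease lasso (`C3`),
#' size-matched to the `C3` support chosen by per-gene BIC.
#'
#' @param n_reps number of replicates.
#' @param seed integer; replicate r derives its seeds from `seed + r`.
#' @param n samples per group.
#' @param p number of genes (= number of CNVs).
#' @param spec a [regulation_sim_spec()]; by default the shared-regulator
#'   count is scaled with the support size (roughly half the support, at
#'   most the full-scale value of 6) so that scaled-down problem sizes
#'   keep the same sharing ratio.
#' @param lambda4_grid fusion levels searched.
#' @return data.frame with one row per replicate and method: `tpr`, `fpr`
#'   over regulation coefficients, averaged over the two diseases.
#' @export
regulation_simulation_study <- function(n_reps = 20, seed = 1, n = 40,
                                        p = 40, spec = NULL,
                                        lambda4_grid = c(0.15, 0.5, 1.5)) {
  if (is.null(spec)) {
    m <- round(0.1 * p)
    spec <- regulation_sim_spec(n_shared = min(6, max(2, floor(m / 2))))
  }
  out <- NULL
  for (r in seq_len(n_reps)) {
    base <- 1000 * (seed + r)
    Z1 <- simulate_cnv_matrix(n, p, seed = base + 1)
    Z2 <- simulate_cnv_matrix(n, p, seed = base + 2)
    sim <- simulate_regulation_data(spec, Z1, Z2, seed = base + 3)
    c3 <- lapply(list(sim$d1, sim$d2), select_tuning_lasso_regulation,
                 per_gene = TRUE)
    target <- sum(vapply(c3, function(f) sum(f$eta[[1]] != 0),
                         numeric(1)))
    fits <- list(
      C1 = fit_regulations_size_matched(sim$d1, sim$d2, "magnitude",
                                        target,
                                        lambda4_grid = lambda4_grid),
      C2 = fit_regulations_size_matched(sim$d1, sim$d2, "sign", target,
                                        lambda4_grid = lambda4_grid))
    sel <- list(C1 = support(fits$C1), C2 = support(fits$C2),
                C3 = list(c3[[1]]$eta[[1]] != 0, c3[[2]]$eta[[1]] != 0))
    truths <- list(sim$eta1 != 0, sim$eta2 != 0)
    for (m in names(sel)) {
      mets <- lapply(1:2, function(k)
        selection_metrics(which(sel[[m]][[k]]), which(truths[[k]]),
                          p * p))
      out <- rbind(out, data.frame(
        replicate = r, method = m,
        tpr = mean(vapply(mets, `[[`, numeric(1), "tpr")),
        fpr = mean(vapply(mets, `[[`, numeric(1), "fpr"))))
    }
  }
  out
}

#' Regulation-distance study (disease-disease vs disease-normal)
#'
#' Simulates two diseases with partially shared regulation structure plus
#' an independent normal group, estimates regulations by the fused
#' approaches (and lasso for the normal group), and records the
#' squared-difference and sign-difference distances between the estimated
#' coefficient matrices for every group pair. With shared disease
#' structure the disease-disease distances are expected to fall below the
#' disease-normal ones.
#'
#' @inheritParams regulation_simulation_study
#' @return data.frame with one row per replicate, method and measure
#'   (`dist`, `signdist`): columns `bd_sz`, `bd_n`, `sz_n`.
#' @export
regulation_distance_study <- function(n_reps = 25, seed = 1, n = 40,
                                      p = 30, spec = NULL) {
  if (is.null(spec)) {
    m <- round(0.1 * p)
    spec <- regulation_sim_spec(n_shared = min(6, max(2, floor(m / 2))))
  }
  out <- NULL
  for (r in seq_len(n_reps)) {
    base <- 2000 * (seed + r)
    Z1 <- simulate_cnv_matrix(n, p, seed = base + 1)
    Z2 <- simulate_cnv_matrix(n, p, seed = base + 2)
    Zn <- simulate_cnv_matrix(n, p, seed = base + 3)
    sim <- simulate_regulation_data(spec, Z1, Z2, Z_normal = Zn,
                                    seed = base + 4)
    cn <- select_tuning_lasso_regulation(sim$d_normal, per_gene = TRUE)
    target <- 2 * sum(cn$eta[[1]] != 0)
    for (m in c("C1", "C2")) {
      pen <- if (m == "C1") "magnitude" else "sign"
      fit <- fit_regulations_size_matched(sim$d1, sim$d2, pen, target)
      for (meas in c("dist", "signdist")) {
        fn <- if (meas == "dist") dist_matrices else signdist_matrices
        out <- rbind(out, data.frame(
          replicate = r, method = m, measure = meas,
          bd_sz = fn(fit$eta[[1]], fit$eta[[2]]),
          bd_n = fn(fit$eta[[1]], cn$eta[[1]]),
          sz_n = fn(fit$eta[[2]], cn$eta[[1]])))
      }
    }
  }
  out
}
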