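#' True- and false-positive rates of a selected support
#'
#' \eqn{{\rm TPR} = |S \cap T| / |T|}, \eqn{{\rm FPR} = |S \setminus T| /
#' (p - |T|)} for a selected index set S against the true support T.
#'
#' @param selected integer indices of selected variables.
#' @param truth integer indices of truly important variables (non-empty).
#' @param p total number of variables.
#' @return list of class `selection_metrics`: `tpr`, `fpr`, `n_true`,
#'   `n_selected`.
#' @export
selection_metrics <- function(selected, truth, p) {
  selected <- unique(as.integer(selected))
  truth <- unique(as.integer(truth))
  if (!length(truth)) stop("empty truth set: TPR undefined")
  if (length(c(selected, truth)) && max(c(selected, truth, 1)) > p)
    stop("indices exceed p")
  tp <- length(intersect(selected, truth))
  fp <- length(setdiff(selected, truth))
  structure(list(tpr = tp / length(truth),
                 fpr = if (p > length(truth)) fp / (p - length(truth))
                       else 0,
                 n_true = length(truth), n_selected = length(selected)),
            class = "selection_metrics")
}

#' @export
print.selection_metrics <- function(x, ...) {
  cat(sprintf("TPR = %.3f, FPR = %.3f (%d selected, %d true)\n", x$tpr,
              x$fpr, x$n_selected, x$n_true))
  invisible(x)
}

#' Corrected prediction ratio
#'
#' Prediction score for binary outcomes at a probability threshold. The
#' default is balanced accuracy, `(sensitivity + specificity) / 2`, which
#' corrects for class imbalance: a useless classifier scores 0.5 on any
#' class mix and perfect prediction scores 1. Ties (`p_hat == threshold`)
#' deterministically predict class 0.
#'
#' @param y_true binary outcome vector.
#' @param p_hat predicted case probabilities.
#' @param threshold classification threshold.
#' @param type `"balanced"` (default) or raw `"accuracy"`.
#' @return scalar in \[0, 1\].
#' @export
cpr <- function(y_true, p_hat, threshold = 0.5,
                type = c("balanced", "accuracy")) {
  type <- match.arg(type)
  stopifnot(length(y_true) == length(p_hat))
  pred <- as.integer(p_hat > threshold)
  if (type == "accuracy") return(mean(pred == y_true))
  sens <- if (any(y_true == 1)) mean(pred[y_true == 1] == 1) else NA_real_
  spec <- if (any(y_true == 0)) mean(pred[y_true == 0] == 0) else NA_real_
  mean(c(sens, spec), na.rm = TRUE)
}

#' Resampled prediction evaluation
#'
#' Repeated stratified train/test splits: the model (including any
#' dimension reduction and decomposition steps) is refit on each training
#' set only, and the corrected prediction ratio is computed on the held-out
#' samples.
#'
#' @param dataset an `omics_dataset` with a binary outcome.
#' @param fit_fun function taking a training `omics_dataset` and returning
#'   a fitted object.
#' @param predict_fun function `(fit, dataset) -> probabilities`; defaults
#'   to [predict()].
#' @param n_splits number of random splits.
#' @param train_fraction fraction of each class assigned to training.
#' @param threshold,type passed to [cpr()].
#' @param seed optional integer seed.
#' @return list of class `cpr_summary`: `mean`, `sd`, `n_splits`,
#'   `per_split`.
#' @export
evaluate_cpr_resampling <- function(dataset, fit_fun,
                                    predict_fun = predict,
                                    n_splits = 200, train_fraction = 0.75,
                                    threshold = 0.5, type = "balanced",
                                    seed = NULL) {
  stopifnot(inherits(dataset, "omics_dataset"), !is.null(dataset$y))
  if (!is.null(seed)) set.seed(seed)
  y <- dataset$y
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  n1 <- max(1, round(train_fraction * length(idx1)))
  n0 <- max(1, round(train_fraction * length(idx0)))
  if (n1 >= length(idx1) || n0 >= length(idx0))
    stop("too few samples for a stratified split at train_fraction = ",
         train_fraction)
  vals <- vapply(seq_len(n_splits), function(s) {
    tr <- c(idx1[sample.int(length(idx1), n1)],
            idx0[sample.int(length(idx0), n0)])
    fit <- fit_fun(dataset_rows(dataset, tr))
    phat <- predict_fun(fit, dataset_rows(dataset, -tr))
    cpr(y[-tr], phat, threshold = threshold, type = type)
  }, numeric(1))
  structure(list(mean = mean(vals), sd = sd(vals), n_splits = n_splits,
                 per_split = vals), class = "cpr_summary")
}

#' @export
print.cpr_summary <- function(x, ...) {
  cat(sprintf("CPR over %d splits: %.2f (%.2f)\n", x$n_splits, x$mean,
              x$sd))
  invisible(x)
}
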