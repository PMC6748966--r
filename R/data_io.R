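#' Construct a paired expression/CNV case-control dataset
#'
#' Container for one disease-versus-control contrast: a samples-by-genes
#' expression matrix `X`, an aligned CNV matrix `Z`, and a binary outcome
#' `y` (0 = control, 1 = case). Either omics block may be absent (`NULL`)
#' for single-block analyses.
#'
#' @param X numeric n x p expression matrix (samples in rows) or `NULL`.
#' @param Z numeric n x p CNV matrix (samples in rows) or `NULL`.
#' @param y binary outcome vector of length n, or `NULL` when the dataset is
#'   used without an outcome (e.g. the normal group in regulation analysis).
#' @param sample_ids,gene_ids identifiers; defaults taken from dimnames.
#' @param group_label character tag for the case group, e.g. `"bipolar"`.
#' @return An object of class `omics_dataset`.
#' @export
omics_dataset <- function(X = NULL, Z = NULL, y = NULL, sample_ids = NULL,
                          gene_ids = NULL, group_label = NA_character_) {
  if (is.null(X) && is.null(Z))
    stop("at least one of X and Z must be supplied")
  ref <- if (!is.null(X)) X else Z
  if (is.null(sample_ids)) sample_ids <- rownames(ref)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(ref)))
  if (is.null(gene_ids)) gene_ids <- colnames(ref)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(ref)))
  n <- length(sample_ids)
  p <- length(gene_ids)
  for (nm in c("X", "Z")) {
    M <- get(nm)
    if (is.null(M)) next
    M <- as.matrix(M)
    if (!is.numeric(M)) stop(nm, " must be numeric")
    if (nrow(M) != n || ncol(M) != p)
      stop(nm, " has dimensions ", nrow(M), "x", ncol(M),
           " but expected ", n, "x", p)
    if (any(!is.finite(M)))
      stop("non-finite values in ", nm,
           "; missing values are not supported")
    dimnames(M) <- list(sample_ids, gene_ids)
    assign(nm, M)
  }
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (!is.null(y)) {
    if (length(y) != n) stop("y has length ", length(y), ", expected ", n)
    if (!all(y %in% c(0, 1))) stop("y must contain only 0/1")
    y <- as.integer(y)
  }
  structure(list(X = X, Z = Z, y = y, sample_ids = sample_ids,
                 gene_ids = gene_ids, group_label = group_label),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", length(x$sample_ids), "samples x",
      length(x$gene_ids), "genes\n")
  cat("  blocks:", paste(c("X", "Z")[!c(is.null(x$X), is.null(x$Z))],
                         collapse = ", "), "\n")
  if (!is.null(x$y))
    cat("  outcome:", sum(x$y == 1), "cases /", sum(x$y == 0),
        "controls (", x$group_label, ")\n")
  invisible(x)
}

#' @export
dim.omics_dataset <- function(x) {
  c(length(x$sample_ids), length(x$gene_ids))
}

#' Read a TSV omics matrix
#'
#' Reads a tab-separated matrix with one header row and a leading identifier
#' column. Omics distribution files conventionally store features in rows;
#' the matrix is returned in samples-by-features orientation regardless.
#'
#' @param path file path.
#' @param orientation `"features_in_rows"` (default, transposed on read) or
#'   `"samples_in_rows"`.
#' @return numeric matrix, samples in rows, with dimnames.
#' @export
load_matrix <- function(path,
                        orientation = c("features_in_rows",
                                        "samples_in_rows")) {
  orientation <- match.arg(orientation)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expected an identifier column plus data columns")
  row_ids <- df[[1]]
  if (anyDuplicated(row_ids))
    stop("duplicate row identifiers: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  col_ids <- colnames(df)[-1]
  if (anyDuplicated(col_ids))
    stop("duplicate column identifiers: ",
         paste(unique(col_ids[duplicated(col_ids)]), collapse = ", "))
  M <- matrix(NA_real_, nrow(df), length(col_ids),
              dimnames = list(row_ids, col_ids))
  for (j in seq_along(col_ids)) {
    vals <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(vals))
    if (length(bad))
      stop("non-numeric value \"", df[[j + 1]][bad[1]], "\" at row \"",
           row_ids[bad[1]], "\", column \"", col_ids[j], "\" of ", path)
    M[, j] <- vals
  }
  if (orientation == "features_in_rows") M <- t(M)
  M
}

#' Write a matrix as TSV
#'
#' Inverse of [load_matrix()]: values are formatted with full double
#' precision so that a read/write round trip is bit-identical.
#'
#' @param mat numeric matrix, samples in rows.
#' @param path output file path.
#' @param orientation file orientation, as in [load_matrix()].
#' @param id_column header name of the identifier column.
#' @export
write_matrix <- function(mat, path,
                         orientation = c("features_in_rows",
                                         "samples_in_rows"),
                         id_column = "id") {
  orientation <- match.arg(orientation)
  if (orientation == "features_in_rows") mat <- t(mat)
  body <- apply(mat, 2, function(col) sprintf("%.17g", col))
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(mat))
  out <- cbind(rownames(mat), body)
  colnames(out) <- c(id_column, colnames(mat))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`; the description is
#' discarded.
#'
#' @param path GMT file path.
#' @return named list of character vectors of gene identifiers.
#' @export
load_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(structure(list(), names = character(0)))
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("GMT line ", i, " has ", length(fields),
           " fields; at least 3 required (name, description, members)")
    nms[i] <- fields[1]
    members <- unique(fields[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("GMT line ", i, ": set has no members")
    sets[[i]] <- members
  }
  if (anyDuplicated(nms))
    stop("duplicate gene-set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  names(sets) <- nms
  sets
}

#' Assemble the two disease-versus-control contrasts
#'
#' Splits jointly measured samples into one case-control dataset per
#' disease. The single control pool is shared between the two contrasts by
#' default, matching a design with one normal group.
#'
#' @param X,Z samples-by-genes expression and CNV matrices (either may be
#'   `NULL`); rows aligned with `labels`.
#' @param labels character vector of group labels, one per sample, or a
#'   data.frame with columns `sample_id` and `group`.
#' @param groups length-3 character vector naming the two case groups and
#'   the control group, in that order.
#' @param split_controls if `TRUE`, controls are partitioned disjointly
#'   (alternating) between the contrasts instead of shared.
#' @return list of two `omics_dataset` objects, named by disease.
#' @export
assemble_contrasts <- function(X, Z, labels,
                               groups = c("bipolar", "schizophrenia",
                                          "control"),
                               split_controls = FALSE) {
  ref <- if (!is.null(X)) X else Z
  if (is.null(ref)) stop("at least one of X and Z must be supplied")
  if (is.data.frame(labels)) {
    if (!all(c("sample_id", "group") %in% names(labels)))
      stop("labels data.frame needs columns sample_id and group")
    ids <- rownames(ref)
    if (!is.null(ids)) {
      m <- match(ids, labels$sample_id)
      if (any(is.na(m))) stop("samples without labels: ",
                              paste(ids[is.na(m)], collapse = ", "))
      labels <- labels$group[m]
    } else labels <- labels$group
  }
  labels <- as.character(labels)
  if (length(labels) != nrow(ref))
    stop("labels length ", length(labels), " != sample count ", nrow(ref))
  unknown <- setdiff(unique(labels), groups)
  if (length(unknown))
    stop("unknown group label(s): ", paste(unknown, collapse = ", "))
  ctrl_idx <- which(labels == groups[3])
  if (!length(ctrl_idx)) stop("no control samples")
  ctrl_split <- if (split_controls) {
    list(ctrl_idx[seq_along(ctrl_idx) %% 2 == 1],
         ctrl_idx[seq_along(ctrl_idx) %% 2 == 0])
  } else list(ctrl_idx, ctrl_idx)
  out <- vector("list", 2)
  for (k in 1:2) {
    case_idx <- which(labels == groups[k])
    if (!length(case_idx)) stop("no cases for group ", groups[k])
    idx <- c(case_idx, ctrl_split[[k]])
    y <- c(rep(1L, length(case_idx)), rep(0L, length(ctrl_split[[k]])))
    out[[k]] <- omics_dataset(
      X = if (!is.null(X)) X[idx, , drop = FALSE],
      Z = if (!is.null(Z)) Z[idx, , drop = FALSE],
      y = y, group_label = groups[k])
  }
  names(out) <- groups[1:2]
  out
}

#' Restrict a dataset to a gene set
#'
#' Keeps the columns of both omics blocks whose identifiers fall in `genes`,
#' preserving the original column order; pathway prescreening ahead of the
#' penalized analyses.
#'
#' @param dataset an `omics_dataset`.
#' @param genes character vector of gene identifiers (e.g. one entry of
#'   [load_gene_sets()]).
#' @return the restricted `omics_dataset`; warns about `genes` absent from
#'   the data, errors when the intersection is empty.
#' @export
subset_to_gene_set <- function(dataset, genes) {
  stopifnot(inherits(dataset, "omics_dataset"))
  missing <- setdiff(genes, dataset$gene_ids)
  if (length(missing))
    warning("gene set members absent from data: ",
            paste(missing, collapse = ", "))
  keep <- dataset$gene_ids %in% genes
  if (!any(keep)) stop("no overlap between gene set and dataset genes")
  omics_dataset(
    X = if (!is.null(dataset$X)) dataset$X[, keep, drop = FALSE],
    Z = if (!is.null(dataset$Z)) dataset$Z[, keep, drop = FALSE],
    y = dataset$y, sample_ids = dataset$sample_ids,
    gene_ids = dataset$gene_ids[keep], group_label = dataset$group_label)
}

# internal: pull the chosen feature block, erroring when absent
feature_block <- function(dataset, feature = c("expression", "cnv")) {
  feature <- match.arg(feature)
  M <- if (feature == "expression") dataset$X else dataset$Z
  if (is.null(M)) stop("dataset has no ", feature, " block")
  M
}
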