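test_that("matrix TSV round trip preserves values and orientation", {
  M <- matrix(1:6, 3, 2, dimnames = list(paste0("s", 1:3), c("gA", "gB")))
  storage.mode(M) <- "double"
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(M, f)  # features-in-rows file
  expect_identical(load_matrix(f), M)
  # opposite orientation reads the transpose
  expect_identical(load_matrix(f, "samples_in_rows"), t(M))
  # bit-identical round trip on irrational values
  set.seed(3)
  R <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("s", 1:5), paste0("g", 1:4)))
  write_matrix(R, f)
  expect_identical(load_matrix(f), R)
})

test_that("non-numeric cells and duplicate ids are rejected with context", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "gA\t1\tNA", "gB\t3\t4"), f)
  expect_error(load_matrix(f), "NA.*gA.*s2|s2.*gA")
  writeLines(c("id\ts1\ts2", "gA\t1\t2", "gA\t3\t4"), f)
  expect_error(load_matrix(f), "duplicate")
})

test_that("GMT parsing follows the standard line format", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("UMP\tdesc\tA\tB", "TRP\turl\tC"), f)
  sets <- load_gene_sets(f)
  expect_identical(sets, list(UMP = c("A", "B"), TRP = "C"))
  # empty file -> empty collection
  writeLines(character(0), f)
  expect_length(load_gene_sets(f), 0)
  # short line and duplicate names are errors
  writeLines("UMP\tonlydesc", f)
  expect_error(load_gene_sets(f), "line 1")
  writeLines(c("UMP\td\tA", "UMP\td\tB"), f)
  expect_error(load_gene_sets(f), "duplicate")
})

test_that("contrast assembly pairs each disease with the shared controls", {
  set.seed(1)
  n <- 23 + 24 + 24
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(paste0("s", 1:n), paste0("g", 1:3)))
  labels <- rep(c("bipolar", "schizophrenia", "control"), c(23, 24, 24))
  out <- assemble_contrasts(X, NULL, labels)
  expect_equal(dim(out$bipolar), c(47, 3))
  expect_equal(dim(out$schizophrenia), c(48, 3))
  expect_equal(sum(out$bipolar$y), 23)
  expect_equal(sum(out$schizophrenia$y), 24)
  # order invariance of the counts
  perm <- sample(n)
  out2 <- assemble_contrasts(X[perm, ], NULL, labels[perm])
  expect_equal(dim(out2$bipolar), c(47, 3))
  # controls shared: same control sample ids in both contrasts
  expect_setequal(out$bipolar$sample_ids[out$bipolar$y == 0],
                  out$schizophrenia$sample_ids[out$schizophrenia$y == 0])
  # split controls option makes them disjoint
  out3 <- assemble_contrasts(X, NULL, labels, split_controls = TRUE)
  expect_length(intersect(out3$bipolar$sample_ids[out3$bipolar$y == 0],
                          out3$schizophrenia$sample_ids[
                            out3$schizophrenia$y == 0]), 0)
  # error cases
  expect_error(assemble_contrasts(X, NULL, rep("control", n)), "no cases")
  expect_error(assemble_contrasts(X, NULL, c("odd", labels[-1])),
               "unknown group")
  # minimal valid input
  Y <- X[1:4, ]
  lab <- c("bipolar", "schizophrenia", "control", "control")
  mini <- assemble_contrasts(Y, NULL, lab)
  expect_equal(dim(mini$bipolar)[1], 3)
})

test_that("gene-set subsetting preserves order, warns, and errors", {
  d <- make_logistic_dataset(n = 10, p = 4, seed = 2)
  expect_warning(sub <- subset_to_gene_set(d, c("g2", "g3", "gZ")), "gZ")
  expect_identical(sub$gene_ids, c("g2", "g3"))
  expect_identical(sub$X, d$X[, 2:3])
  # identity
  expect_identical(subset_to_gene_set(d, d$gene_ids)$X, d$X)
  # disjoint
  expect_error(suppressWarnings(subset_to_gene_set(d, "nope")),
               "no overlap")
})

test_that("dataset construction enforces the invariants", {
  X <- matrix(1:6, 3, 2)
  expect_error(omics_dataset(X = X, y = c(0, 1)), "length")
  expect_error(omics_dataset(X = X, y = c(0, 1, 2)), "0/1")
  expect_error(omics_dataset(X = matrix(c(1, NA, 3, 4, 5, 6), 3, 2)),
               "non-finite")
  expect_error(omics_dataset(X = X, gene_ids = c("a", "a")), "unique")
})
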