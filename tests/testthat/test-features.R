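toy_matrix <- function(n = 300, seed = 1) {
  # three classes; pos1 mirrors the class label, pos2-3 are noise, pos4 is
  # constant (an all-pad position)
  withr::with_seed(seed, {
    y <- factor(rep(c("a", "b", "c"), length.out = n))
    X <- cbind(
      pos1 = as.integer(y),
      pos2 = sample(1:9, n, replace = TRUE),
      pos3 = sample(1:9, n, replace = TRUE),
      pos4 = 0L
    )
    list(X = X, y = y)
  })
}

test_that("correlation handles self, copies and constant columns", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(5, 5, 5, 5))
  cm <- correlation_matrix(X)
  expect_identical(unname(diag(cm)), c(1, 1, 1))
  expect_equal(cm["a", "b"], 1)
  expect_equal(cm["a", "c"], 0) # constant column: 0 by convention
  expect_identical(cm, t(cm))
  expect_error(correlation_matrix(X[1, , drop = FALSE]), "at least 2 rows")
})

test_that("Gini importance is zero for constants and maximal for the label copy", {
  toy <- toy_matrix()
  imp <- gini_importance(toy$X, toy$y, seed = 7)
  expect_true(all(imp >= 0))
  expect_identical(unname(imp["pos4"]), 0)
  expect_identical(names(which.max(imp)), "pos1")
  expect_gt(imp["pos1"], 5 * max(imp[c("pos2", "pos3")]))
  expect_identical(imp, gini_importance(toy$X, toy$y, seed = 7))
  expect_error(gini_importance(toy$X, rep("a", nrow(toy$X))), "2 classes")
})

test_that("selection drops low-importance and redundant features", {
  imp <- c(pos1 = 1, pos2 = 0.5, pos3 = 0.004, pos4 = 0)
  corr <- diag(4)
  dimnames(corr) <- list(names(imp), names(imp))
  rep0 <- list(corr = corr, importance = imp)
  expect_identical(select_features(rep0, 0, 1), 1:4) # zero thresholds keep all
  expect_identical(select_features(rep0, 0.01, 0.95), 1:2)
  # a highly correlated pair loses its lower-importance member
  corr2 <- corr
  corr2["pos1", "pos2"] <- corr2["pos2", "pos1"] <- 0.99
  expect_identical(select_features(list(corr = corr2, importance = imp), 0.01, 0.95), 1L)
  expect_error(select_features(rep0, -0.1, 0.95), "\\[0, 1\\]")
})

test_that("selection is monotone in the importance fraction and never empty", {
  toy <- toy_matrix()
  rep1 <- feature_report(
    structure(list(X = toy$X, y = toy$y, encoding = default_encoding(),
      ids = NULL), class = "encoded_ids"),
    seed = 3
  )
  fractions <- c(0, 0.01, 0.1, 0.5, 1)
  kept <- lapply(fractions, function(f) select_features(rep1, f, 0.95))
  for (i in seq_len(length(kept) - 1L)) {
    expect_true(all(kept[[i + 1L]] %in% kept[[i]]))
  }
  expect_gte(length(kept[[length(kept)]]), 1L)
})

test_that("permuting feature order permutes but does not change the kept set", {
  imp <- c(pos1 = 1, pos2 = 0.6, pos3 = 0.002)
  corr <- diag(3)
  dimnames(corr) <- list(names(imp), names(imp))
  perm <- c(3L, 1L, 2L)
  kept <- select_features(list(corr = corr, importance = imp), 0.01, 0.95)
  kept_p <- select_features(
    list(corr = corr[perm, perm], importance = imp[perm]), 0.01, 0.95
  )
  expect_setequal(names(imp)[kept], names(imp[perm])[kept_p])
})

test_that("trailing pad-dominated positions are filtered on a synthetic corpus", {
  # two classes distinguished only by their first character; digit tails of
  # random length leave the trailing positions pad-dominated and uninformative
  reg <- id_registry()
  reg <- register_pattern(reg, id_pattern_spec("alpha", "^A\\d{4,9}$",
    list(hint_seg("A", literal = TRUE), hint_seg(DIGITS, 4, 9))))
  reg <- register_pattern(reg, id_pattern_spec("beta", "^B\\d{4,9}$",
    list(hint_seg("B", literal = TRUE), hint_seg(DIGITS, 4, 9))))
  tab <- generate_dataset(reg, c(alpha = 400, beta = 400), seed = 6)
  enc <- encode_ids(tab)
  rep2 <- feature_report(enc, seed = 6)
  expect_true(1L %in% rep2$kept)
  expect_false(10L %in% rep2$kept)
  expect_lt(length(rep2$kept), ncol(enc$X))
})

test_that("feature reports export rectangular tables", {
  toy <- toy_matrix()
  rep3 <- feature_report(
    structure(list(X = toy$X, y = toy$y, encoding = default_encoding(),
      ids = NULL), class = "encoded_ids"),
    seed = 2
  )
  dir <- withr::local_tempdir()
  export_feature_report(rep3, dir)
  imp_tab <- readr::read_tsv(file.path(dir, "feature_importance.tsv"),
    show_col_types = FALSE)
  expect_identical(nrow(imp_tab), 4L)
  corr_tab <- readr::read_tsv(file.path(dir, "feature_correlation.tsv"),
    show_col_types = FALSE)
  expect_identical(dim(corr_tab), c(4L, 5L))
})
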