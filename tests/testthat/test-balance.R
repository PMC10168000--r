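make_encoded <- function(profile, seed = 1) {
  tab <- generate_dataset(builtin_registry(), profile, seed = seed)
  encode_ids(tab)
}

test_that("stratified split holds out the complement of the rounded 70%", {
  enc <- make_encoded(c("Rfam" = 58, "ChEMBL" = 10))
  sp <- stratified_split(enc, 0.3, seed = 1)
  counts <- table(sp$test$y)
  expect_identical(as.integer(counts[["Rfam"]]), 17L) # 58 - round(40.6)
  expect_identical(as.integer(counts[["ChEMBL"]]), 3L)
  expect_identical(as.integer(table(sp$train$y)[["Rfam"]]), 41L)
  # the realized split always agrees with the closed-form plan
  enc45 <- make_encoded(c("Rfam" = 45))
  plan45 <- balance_plan(c(Rfam = 45))
  expect_identical(
    as.numeric(table(stratified_split(enc45, 0.3, seed = 1)$test$y)[["Rfam"]]),
    plan45$test
  )
  expect_error(balance_config(test_fraction = 0), "between 0 and 1")
  expect_error(balance_config(test_fraction = 1), "between 0 and 1")
})

test_that("split partitions are disjoint original rows", {
  enc <- make_encoded(c("Rfam" = 20, "ChEMBL" = 20))
  sp <- stratified_split(enc, 0.3, seed = 2)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0L)
  expect_setequal(c(sp$train$ids, sp$test$ids), enc$ids)
})

test_that("the closed-form plan reproduces the reference balanced counts", {
  plan <- balance_plan(reference_profile())
  expect_identical(plan$train_balanced, reference_balanced_counts())
})

test_that("SMOTE rows are rounded convex combinations of class neighbours", {
  X <- matrix(c(1L, 3L, 1L, 5L), nrow = 2, byrow = TRUE,
    dimnames = list(NULL, c("pos1", "pos2")))
  expect_identical(nrow(smote_class(X, 0, seed = 1)), 0L)
  syn <- smote_class(X, 50, k = 5, seed = 1)
  expect_identical(nrow(syn), 50L)
  expect_true(all(syn[, "pos1"] == 1L)) # both parents agree coordinate-wise
  expect_true(all(syn[, "pos2"] >= 3L & syn[, "pos2"] <= 5L))
  expect_true(is.integer(syn))
  # identical parents can only yield themselves
  same <- smote_class(matrix(c(2L, 7L, 2L, 7L), 2, byrow = TRUE), 5, seed = 1)
  expect_true(all(same[, 1] == 2L & same[, 2] == 7L))
  # determinism
  expect_identical(smote_class(X, 10, seed = 9), smote_class(X, 10, seed = 9))
})

test_that("a single-row class is balanced by duplication with a warning", {
  X <- matrix(c(4L, 4L), 1, 2)
  expect_warning(syn <- smote_class(X, 3, seed = 1), "duplication")
  expect_identical(nrow(syn), 3L)
  expect_true(all(syn == 4L))
})

test_that("balancing realizes the plan and keeps the test side original", {
  enc <- make_encoded(c("Rfam" = 12, "ChEMBL" = 40, "HGNC" = 80))
  cfg <- balance_config() # target = ceiling(mean) = 44
  sp <- balance_dataset(enc, cfg, seed = 3)
  plan <- sp$plan
  # n = 12: test 4, original train 8, plus (44 - 12) synthetic = 40
  expect_identical(plan$train_balanced[plan$class == "Rfam"], 40)
  got <- table(sp$train$y)
  expect_identical(as.numeric(got[plan$class]), plan$train_balanced)
  expect_identical(as.numeric(table(sp$test$y)[plan$class]), plan$test)
  # synthetic rows live only in the training partition and are flagged
  expect_identical(sum(sp$train$synthetic), as.integer(sum(plan$synthetic)))
  expect_true(all(sp$test$ids %in% enc$ids))
  # imbalance strictly reduced
  expect_lt(
    max(plan$train_balanced) / min(plan$train_balanced),
    max(plan$n) / min(plan$n)
  )
})

test_that("optional undersampling caps majority training partitions", {
  enc <- make_encoded(c("Rfam" = 10, "ChEMBL" = 120))
  cfg <- balance_config(target = 20, undersample = TRUE, undersample_ratio = 1)
  sp <- balance_dataset(enc, cfg, seed = 4)
  expect_true(all(table(sp$train$y) <= 20))
})

test_that("boundary class at the target gets no synthesis", {
  enc <- make_encoded(c("Rfam" = 10, "ChEMBL" = 10))
  cfg <- balance_config(target = 10)
  sp <- balance_dataset(enc, cfg, seed = 5)
  expect_identical(sum(sp$train$synthetic), 0L)
  expect_true(all(table(sp$train$y) == 7))
})
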