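#' Balancing configuration
#'
#' Controls the per-class train/test split and SMOTE oversampling. The
#' per-class total target `target` defaults to the ceiling of the mean class
#' count, the unique constant under which the closed-form balanced training
#' counts reproduce the reference corpus arithmetic (see [balance_plan()]).
#'
#' @param test_fraction fraction of each class held out as the test set
#'   (default 0.3). Test rows are always original, never synthetic.
#' @param target per-class total target `T`; classes smaller than `T` are
#'   oversampled up to it. `NULL` (default) means ceiling of the mean
#'   original class count.
#' @param smote_k number of nearest same-class neighbours used by SMOTE
#'   (default 5); reduced automatically for classes smaller than `k + 1`.
#' @param undersample cap majority-class training partitions at
#'   `undersample_ratio * target` by random deletion (default off: the
#'   reference corpus arithmetic corresponds to no undersampling).
#' @param undersample_ratio cap ratio `r` when `undersample` is on.
#' @return A list of class `balance_config`.
#' @export
balance_config <- function(test_fraction = 0.3, target = NULL, smote_k = 5L,
                           undersample = FALSE, undersample_ratio = 1) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stopf("test_fraction must lie strictly between 0 and 1")
  }
  if (!is.null(target) && target < 1) stopf("target must be >= 1")
  if (smote_k < 1) stopf("smote_k must be >= 1")
  structure(
    list(
      test_fraction = test_fraction, target = target, smote_k = as.integer(smote_k),
      undersample = undersample, undersample_ratio = undersample_ratio
    ),
    class = "balance_config"
  )
}

#' Closed-form balancing arithmetic
#'
#' For a class of original size `n`, the original training count is
#' `round((1 - test_fraction) * n)` (R's `round()`, i.e. half-to-even at
#' exact midpoints) and the held-out test count the remainder; when `n` is
#' below the per-class target `T`, `T - n` synthetic rows are added to the
#' training side, giving a balanced training count of
#' `round((1 - f) * n) + max(0, T - n)`. With `T = ceiling(mean(n))` this
#' reproduces the reference corpus's published per-class balanced counts
#' exactly (all 39 classes).
#'
#' @param counts named numeric vector of original per-class counts.
#' @param config a [balance_config()].
#' @return A tibble with one row per class: `class`, `n`, `test`,
#'   `train_original`, `synthetic`, `train_balanced`.
#' @examples
#' balance_plan(reference_profile())
#' @export
balance_plan <- function(counts, config = balance_config()) {
  stopifnot(is.numeric(counts))
  target <- config$target %||% ceiling(mean(counts))
  test <- split_test_count(counts, config$test_fraction)
  train0 <- counts - test
  synth <- pmax(0, target - counts)
  train_bal <- train0 + synth
  if (config$undersample) {
    cap <- round(config$undersample_ratio * target)
    train_bal <- pmin(train_bal, cap)
  }
  tibble::tibble(
    class = if (is.null(names(counts))) as.character(seq_along(counts)) else names(counts),
    n = as.numeric(counts), test = as.numeric(test),
    train_original = as.numeric(train0), synthetic = as.numeric(synth),
    train_balanced = as.numeric(train_bal)
  )
}

#' Stratified train/test split
#'
#' Holds out `n - round((1 - test_fraction) * n)` rows per class, sampled
#' uniformly under the seed; the remainder is the training partition.
#'
#' @param data a labelled `encoded_ids` object.
#' @param test_fraction held-out fraction per class.
#' @param seed integer seed.
#' @return List with `train` and `test` (`encoded_ids`), plus `test_idx`, the
#'   row indices of `data` that went to the test side.
#' @export
stratified_split <- function(data, test_fraction = 0.3, seed = 1L) {
  stopifnot(inherits(data, "encoded_ids"))
  if (is.null(data$y)) stopf("stratified_split requires labelled data")
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stopf("test_fraction must lie strictly between 0 and 1")
  }
  idx_by_class <- split(seq_along(data$y), data$y)
  test_idx <- with_seed(seed, {
    unlist(lapply(idx_by_class, function(ix) {
      k <- split_test_count(length(ix), test_fraction)
      if (k == 0L) integer(0) else sort(sample(ix, k))
    }), use.names = FALSE)
  })
  test_idx <- sort(test_idx)
  take <- function(ix) {
    new_encoded_ids(
      data$X[ix, , drop = FALSE], droplevels_keep(data$y[ix], data$y),
      data$encoding, data$ids[ix]
    )
  }
  train_idx <- setdiff(seq_along(data$y), test_idx)
  list(train = take(train_idx), test = take(test_idx), test_idx = test_idx)
}

# keep the full level set so per-class tables stay rectangular even when a
# partition misses a class
droplevels_keep <- function(y, ref) factor(y, levels = levels(ref))

#' SMOTE synthesis for one class
#'
#' Each synthetic row interpolates between a real row and one of its `k`
#' nearest same-class neighbours (Euclidean distance on the integer codes):
#' `base + u * (neighbour - base)` with `u ~ U(0, 1)`, every coordinate then
#' rounded to the nearest integer so synthetic rows stay on the code grid.
#' Degenerate classes fall back gracefully: `k` is reduced to `size - 1`, and
#' a single-row class is balanced by duplication with a warning.
#'
#' @param X integer matrix of the class's training rows.
#' @param n_synthetic number of synthetic rows to produce.
#' @param k neighbour count.
#' @param seed integer seed.
#' @return Integer matrix with `n_synthetic` rows.
#' @export
smote_class <- function(X, n_synthetic, k = 5L, seed = 1L) {
  stopifnot(is.matrix(X))
  n_synthetic <- as.integer(n_synthetic)
  if (n_synthetic <= 0L) {
    return(X[integer(0), , drop = FALSE])
  }
  n <- nrow(X)
  if (n == 0L) stopf("cannot oversample an empty class")
  if (n == 1L) {
    warnf("class has a single training row; balancing by duplication")
    return(X[rep(1L, n_synthetic), , drop = FALSE])
  }
  k <- min(k, n - 1L)
  with_seed(seed, {
    base_idx <- sample.int(n, n_synthetic, replace = TRUE)
    out <- matrix(0L, nrow = n_synthetic, ncol = ncol(X),
      dimnames = list(NULL, colnames(X)))
    # neighbour lists computed lazily per distinct base row
    nn_cache <- vector("list", n)
    for (j in seq_len(n_synthetic)) {
      b <- base_idx[j]
      if (is.null(nn_cache[[b]])) {
        d <- rowSums((X - matrix(X[b, ], n, ncol(X), byrow = TRUE))^2)
        d[b] <- Inf
        nn_cache[[b]] <- order(d)[seq_len(k)]
      }
      nb <- X[sample(nn_cache[[b]], 1L), ]
      u <- stats::runif(1)
      out[j, ] <- as.integer(round(X[b, ] + u * (nb - X[b, ])))
    }
    out
  })
}

#' Balance an encoded dataset
#'
#' Splits each class into train/test per [stratified_split()], then raises
#' every minority class's training partition to the target `T` with SMOTE
#' rows (majority classes are left alone unless `undersample` is on). The
#' test side only ever contains original rows.
#'
#' @param data labelled `encoded_ids`.
#' @param config a [balance_config()].
#' @param seed integer seed.
#' @return A list of class `split_dataset`: `train` and `test`
#'   (`encoded_ids`; `train$synthetic` flags SMOTE rows), and `plan` — the
#'   realized per-class count table of [balance_plan()].
#' @export
balance_dataset <- function(data, config = balance_config(), seed = 1L) {
  stopifnot(inherits(data, "encoded_ids"))
  if (is.null(data$y)) stopf("balance_dataset requires labelled data")
  counts <- table(data$y)
  plan <- balance_plan(stats::setNames(as.numeric(counts), names(counts)), config)
  sp <- stratified_split(data, config$test_fraction, seed = stage_seed(seed, "split"))
  train <- sp$train
  synthetic <- rep(FALSE, nrow(train$X))

  add_X <- list()
  add_y <- character(0)
  for (i in seq_len(nrow(plan))) {
    cl <- plan$class[i]
    n_syn <- plan$synthetic[i]
    if (n_syn > 0) {
      rows <- which(train$y == cl)
      syn <- smote_class(train$X[rows, , drop = FALSE], n_syn,
        k = config$smote_k, seed = stage_seed(seed, paste0("smote:", cl))
      )
      add_X[[cl]] <- syn
      add_y <- c(add_y, rep(cl, n_syn))
    }
  }
  if (length(add_X)) {
    train$X <- rbind(train$X, do.call(rbind, add_X))
    train$y <- factor(c(as.character(train$y), add_y), levels = levels(data$y))
    train$ids <- c(train$ids, rep(NA_character_, length(add_y)))
    synthetic <- c(synthetic, rep(TRUE, length(add_y)))
  }

  if (config$undersample) {
    cap <- round(config$undersample_ratio *
      (config$target %||% ceiling(mean(counts))))
    keep <- with_seed(stage_seed(seed, "undersample"), {
      unlist(lapply(levels(train$y), function(cl) {
        rows <- which(train$y == cl)
        if (length(rows) > cap) sort(sample(rows, cap)) else rows
      }), use.names = FALSE)
    })
    keep <- sort(keep)
    train$X <- train$X[keep, , drop = FALSE]
    train$y <- factor(train$y[keep], levels = levels(data$y))
    train$ids <- train$ids[keep]
    synthetic <- synthetic[keep]
  }

  train$synthetic <- synthetic
  structure(list(train = train, test = sp$test, plan = plan),
    class = "split_dataset"
  )
}

#' @export
print.split_dataset <- function(x, ...) {
  cat("<split_dataset> train ", nrow(x$train$X), " (",
    sum(x$train$synthetic), " synthetic), test ", nrow(x$test$X), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write the per-class balance report
#'
#' @param split a `split_dataset` from [balance_dataset()].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
write_balance_report <- function(split, path) {
  plan <- split$plan
  plan$ratio_before <- max(plan$n) / min(plan$n)
  plan$ratio_after <- max(plan$train_balanced) / min(plan$train_balanced)
  readr::write_tsv(plan, path)
  invisible(path)
}
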