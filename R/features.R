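#' Pearson correlation between positional features
#'
#' Integer character codes are treated as numeric (they are ordinal at best;
#' the correlation screen is a redundancy heuristic, not an inference). A
#' constant column — typically an all-pad trailing position — has undefined
#' correlation; by convention it gets 0 off-diagonal so that padding columns
#' are judged by importance alone, and 1 on the diagonal.
#'
#' @param X numeric matrix with at least 2 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(X) {
  if (nrow(X) < 2L) stopf("correlation requires at least 2 rows")
  suppressWarnings(cm <- stats::cor(X))
  cm[is.na(cm)] <- 0
  diag(cm) <- 1
  cm
}

#' Gini-impurity feature importance
#'
#' Mean decrease in Gini impurity per feature, from a seeded random forest.
#' A constant column can never split and scores 0; identical seeds give
#' identical vectors.
#'
#' @param X integer/numeric feature matrix.
#' @param y class label factor.
#' @param n_trees number of trees (default 100; importance stabilizes well
#'   before the forest used for classification is this large).
#' @param seed integer seed.
#' @return Named non-negative numeric vector, one entry per column of `X`.
#' @export
gini_importance <- function(X, y, n_trees = 100L, seed = 1L) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) stopf("importance requires at least 2 classes")
  df <- as.data.frame(X)
  df$.class <- droplevels(y)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = n_trees, importance = "impurity",
    seed = as.integer(seed), num.threads = 1L
  )
  imp <- fit$variable.importance[colnames(X)]
  pmax(imp, 0)
}

#' Select informative positional features
#'
#' Two-stage threshold rule. Stage 1 drops features whose importance falls
#' below `importance_fraction * max(importance)` — this is what removes the
#' low-information trailing pad positions. Stage 2 walks the survivors in
#' decreasing importance and drops any feature whose absolute correlation
#' with an already-kept feature exceeds `corr_threshold` (the
#' lower-importance member of each redundant pair goes). At least one
#' feature always survives.
#'
#' @param report a `feature_report` from [feature_report()], or a list with
#'   elements `corr` and `importance`.
#' @param importance_fraction importance cut as a fraction of the maximum,
#'   in `[0, 1]` (default 0.01).
#' @param corr_threshold absolute-correlation cut in `[0, 1]` (default 0.95).
#' @return Sorted integer vector of kept column indices.
#' @export
select_features <- function(report, importance_fraction = 0.01,
                            corr_threshold = 0.95) {
  if (importance_fraction < 0 || importance_fraction > 1 ||
    corr_threshold < 0 || corr_threshold > 1) {
    stopf("thresholds must lie in [0, 1]")
  }
  imp <- report$importance
  corr <- report$corr
  cut <- importance_fraction * max(imp)
  surv <- which(imp >= cut)
  if (!length(surv)) surv <- which.max(imp)
  kept <- integer(0)
  for (j in surv[order(imp[surv], decreasing = TRUE)]) {
    if (!length(kept) || all(abs(corr[j, kept]) <= corr_threshold)) {
      kept <- c(kept, j)
    }
  }
  sort(kept)
}

#' Feature redundancy report
#'
#' Bundles the correlation matrix, Gini importance vector and the kept
#' feature set for a labelled encoded dataset.
#'
#' @param data labelled `encoded_ids`.
#' @param importance_fraction,corr_threshold passed to [select_features()].
#' @param n_trees,seed passed to [gini_importance()].
#' @return An object of class `feature_report`: list with `corr`,
#'   `importance`, `kept`, and `thresholds`.
#' @export
feature_report <- function(data, importance_fraction = 0.01,
                           corr_threshold = 0.95, n_trees = 100L, seed = 1L) {
  stopifnot(inherits(data, "encoded_ids"))
  if (is.null(data$y)) stopf("feature_report requires labelled data")
  corr <- correlation_matrix(data$X)
  imp <- gini_importance(data$X, data$y, n_trees = n_trees, seed = seed)
  rep <- structure(
    list(
      corr = corr, importance = imp, kept = integer(0),
      thresholds = c(
        importance_fraction = importance_fraction,
        corr_threshold = corr_threshold
      )
    ),
    class = "feature_report"
  )
  rep$kept <- select_features(rep, importance_fraction, corr_threshold)
  rep
}

#' @export
print.feature_report <- function(x, ...) {
  cat("<feature_report> ", length(x$importance), " features, ",
    length(x$kept), " kept\n", sep = "")
  invisible(x)
}

#' Restrict an encoded dataset to the kept features
#'
#' @param data an `encoded_ids` object.
#' @param kept integer indices of the columns to keep (e.g. the `kept` set
#'   of a [feature_report()]).
#' @return An `encoded_ids` with the reduced feature matrix.
#' @export
keep_features <- function(data, kept) {
  stopifnot(inherits(data, "encoded_ids"))
  new_encoded_ids(data$X[, kept, drop = FALSE], data$y, data$encoding, data$ids)
}

#' Export a feature report as delimited text and figures
#'
#' Writes the correlation matrix and importance table as TSV, plus (best
#' effort, skipped with a warning on device-less systems) a correlation heat
#' map and an importance bar chart.
#'
#' @param report a `feature_report`.
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_feature_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corr_path <- file.path(dir, "feature_correlation.tsv")
  ct <- tibble::as_tibble(report$corr, .name_repair = "minimal")
  ct <- dplyr::bind_cols(tibble::tibble(feature = colnames(report$corr)), ct)
  readr::write_tsv(ct, corr_path)
  imp_path <- file.path(dir, "feature_importance.tsv")
  readr::write_tsv(tibble::tibble(
    feature = names(report$importance),
    importance = unname(report$importance),
    kept = seq_along(report$importance) %in% report$kept
  ), imp_path)
  files <- c(corr_path, imp_path)
  files <- c(files, save_plot_quietly(
    plot_correlation_heatmap(report), file.path(dir, "feature_correlation.png")
  ))
  files <- c(files, save_plot_quietly(
    plot_importance(report), file.path(dir, "feature_importance.png")
  ))
  invisible(files)
}

#' Plot helpers for feature reports
#'
#' @param report a `feature_report`.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(report) {
  cm <- report$corr
  df <- expand.grid(
    f1 = factor(colnames(cm), levels = colnames(cm)),
    f2 = factor(colnames(cm), levels = colnames(cm))
  )
  df$corr <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(.data$f1, .data$f2, fill = .data$corr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Pearson r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname plot_correlation_heatmap
#' @export
plot_importance <- function(report) {
  df <- tibble::tibble(
    feature = factor(names(report$importance), levels = rev(names(report$importance))),
    importance = unname(report$importance),
    kept = seq_along(report$importance) %in% report$kept
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$importance, .data$feature, fill = .data$kept)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Gini impurity decrease", y = NULL, fill = "kept") +
    ggplot2::theme_minimal()
}

save_plot_quietly <- function(plot, path, width = 7, height = 6) {
  ok <- tryCatch(
    {
      suppressMessages(ggplot2::ggsave(path, plot, width = width, height = height, dpi = 96))
      TRUE
    },
    error = function(e) {
      warnf("could not write figure '%s': %s", path, conditionMessage(e))
      FALSE
    }
  )
  if (ok) path else character(0)
}
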