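#' Confusion matrix
#'
#' Counts of true class (rows) versus predicted class (columns) over a fixed
#' class ordering, so matrices from different models are directly comparable.
#'
#' @param truth,predicted equal-length character/factor vectors whose values
#'   all appear in `classes`.
#' @param classes class ordering for rows and columns.
#' @return Square integer matrix, `sum(cm) == length(truth)`.
#' @export
confusion <- function(truth, predicted, classes) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted differ in length (%d vs %d)",
      length(truth), length(predicted))
  }
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) stopf("label(s) outside the class set: %s", paste(bad, collapse = ", "))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  unclass(table(truth = tf, predicted = pf))
}

#' Per-class and aggregate classification metrics
#'
#' Reduces the confusion matrix one-vs-rest per class: `TP` the diagonal
#' cell, `FP` the rest of the column, `FN` the rest of the row, `TN` the
#' remainder, so `TP + FP + TN + FN` equals the sample total for every
#' class. Then
#' `Acc = (TP + TN) / (TP + FN + FP + TN)`,
#' `Pre = TP / (TP + FP)`, `Rec = TP / (TP + FN)`, and
#' `F1 = 2 TP / (2 TP + FN + FP)` (the harmonic mean of precision and
#' recall). An undefined `0/0` ratio is reported as 0 and flagged in the
#' `undefined` column rather than dropped, keeping the table rectangular.
#'
#' @param cm square confusion matrix from [confusion()].
#' @return List with `per_class` (tibble: `class`, `TP`, `FP`, `FN`, `TN`,
#'   `Acc`, `Pre`, `Rec`, `F1`, `undefined`), `overall_accuracy`
#'   (`trace / total`) and `macro_f1` (unweighted mean of per-class F1).
#' @export
prf_metrics <- function(cm) {
  if (length(cm) == 0L || sum(cm) == 0) stopf("empty confusion matrix")
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  pre <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * tp, 2 * tp + fn + fp)
  per_class <- tibble::tibble(
    class = rownames(cm),
    TP = as.numeric(tp), FP = as.numeric(fp), FN = as.numeric(fn),
    TN = as.numeric(tn),
    Acc = unname((tp + tn) / total), Pre = unname(pre), Rec = unname(rec),
    F1 = unname(f1),
    undefined = unname((tp + fp == 0) | (tp + fn == 0))
  )
  list(
    per_class = per_class,
    overall_accuracy = sum(tp) / total,
    macro_f1 = mean(f1)
  )
}

#' Confusion-matrix heat map
#'
#' @param cm square confusion matrix.
#' @param title plot title.
#' @return A ggplot object.
#' @export
plot_confusion_heatmap <- function(cm, title = NULL) {
  df <- expand.grid(
    truth = factor(rownames(cm), levels = rev(rownames(cm))),
    predicted = factor(colnames(cm), levels = colnames(cm))
  )
  df$count <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
    fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = title, x = "predicted", y = "truth") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Export evaluation reports
#'
#' Writes, under one directory: a per-class metrics TSV and a confusion
#' heat-map figure per model, the same pair for the ensemble, and a summary
#' TSV of overall accuracy and macro-F1. Deterministic for fixed inputs
#' (rerunning yields byte-identical TSVs).
#'
#' @param bundles named list of `model_bundle`s.
#' @param ensemble_eval optional result of [evaluate_ensemble()].
#' @param dir output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_report <- function(bundles, ensemble_eval = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  summary_rows <- list()
  write_one <- function(name, metrics, cm, accuracy, macro_f1) {
    mpath <- file.path(dir, paste0("metrics_", name, ".tsv"))
    readr::write_tsv(metrics, mpath)
    cpath <- file.path(dir, paste0("confusion_", name, ".tsv"))
    ct <- dplyr::bind_cols(
      tibble::tibble(truth = rownames(cm)),
      tibble::as_tibble(as.data.frame.matrix(cm), .name_repair = "minimal")
    )
    readr::write_tsv(ct, cpath)
    fig <- save_plot_quietly(plot_confusion_heatmap(cm, title = name),
      file.path(dir, paste0("confusion_", name, ".png")))
    summary_rows[[name]] <<- tibble::tibble(
      model = name, accuracy = accuracy, macro_f1 = macro_f1
    )
    c(mpath, cpath, fig)
  }
  for (nm in names(bundles)) {
    b <- bundles[[nm]]
    files <- c(files, write_one(nm, b$metrics, b$cm, b$accuracy, b$macro_f1))
  }
  if (!is.null(ensemble_eval)) {
    files <- c(files, write_one("ensemble", ensemble_eval$metrics,
      ensemble_eval$cm, ensemble_eval$accuracy, ensemble_eval$macro_f1))
  }
  spath <- file.path(dir, "summary.tsv")
  readr::write_tsv(dplyr::bind_rows(summary_rows), spath)
  invisible(c(files, spath))
}
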