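#' Build a unified four-model ensemble
#'
#' Bundles the four evaluated models with the constant `c` that controls how
#' strongly the other models' held-out misclassification behaviour sways a
#' model's score when votes disagree. The model order fixes deterministic
#' tie-breaking; the conventional order `rf, xgb, mlp, cart` is used when the
#' bundles are supplied unnamed.
#'
#' @param bundles named list of `model_bundle`s (see [evaluate_learner()]),
#'   all evaluated on the same class set.
#' @param c_influence influence constant in `[0, 1]` (default 0.5). At
#'   `c = 1` the other models have no influence and a model's score is its
#'   per-class F1; at `c = 0` the score is fully discounted by the others'
#'   misclassification probabilities.
#' @param encoding,pad_len,kept optional preprocessing context stored for
#'   [predict_batch()] on raw identifier strings.
#' @return An object of class `ensemble_model`.
#' @export
ensemble_model <- function(bundles, c_influence = 0.5, encoding = NULL,
                           pad_len = NULL, kept = NULL) {
  stopifnot(is.list(bundles), length(bundles) >= 2L)
  lapply(bundles, function(b) stopifnot(inherits(b, "model_bundle")))
  if (c_influence < 0 || c_influence > 1) stopf("c_influence must lie in [0, 1]")
  classes <- bundles[[1]]$classes
  for (b in bundles) {
    if (!identical(b$classes, classes)) {
      stopf("all bundles must share one class set")
    }
  }
  if (is.null(names(bundles))) {
    names(bundles) <- vapply(bundles, function(b) b$spec$kind, character(1))
  }
  structure(
    list(
      bundles = bundles, c_influence = c_influence, classes = classes,
      encoding = encoding, pad_len = pad_len, kept = kept
    ),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("<ensemble_model> ", length(x$bundles), " models (",
    paste(names(x$bundles), collapse = ", "), "), c = ", x$c_influence,
    "\n", sep = "")
  invisible(x)
}

#' Score one model's disagreeing vote
#'
#' The score of model `N` voting class `x` is its held-out F1 for `x`,
#' multiplied for every other model `R` (voting `y`) by
#' `c + (1 - c) * P_R(y | x)` — the probability, estimated from `R`'s
#' held-out confusion matrix, that a sample truly of class `x` is predicted
#' `y` by `R`. A disagreeing model that often confuses `x` with its own vote
#' barely discounts the score; one that never does discounts it toward
#' `c`-fold per model. The score is affine and non-decreasing in each
#' `P_R(y | x)`, and collapses to the bare F1 at `c = 1`.
#'
#' @param model name of the voting model in `ensemble$bundles`.
#' @param x the class it voted.
#' @param others named character vector: the other models' votes.
#' @param ensemble an [ensemble_model()].
#' @return Numeric score in `[0, 1]`.
#' @export
score_model <- function(model, x, others, ensemble) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  b <- ensemble$bundles[[model]]
  if (is.null(b)) stopf("unknown model '%s'", model)
  if (!x %in% ensemble$classes) stopf("class '%s' not covered by the ensemble", x)
  cc <- ensemble$c_influence
  score <- unname(b$f1[x])
  for (r in names(others)) {
    y <- others[[r]]
    P <- ensemble$bundles[[r]]$misclass
    if (!y %in% colnames(P)) stopf("class '%s' not covered by model '%s'", y, r)
    score <- score * (cc + (1 - cc) * P[x, y])
  }
  score
}

#' Unify one set of votes
#'
#' A label voted by at least three of the four models wins outright
#' (majority path). Otherwise — a 2-2 or 2-1-1 split, the "scattered
#' opinions" case — every model's vote is scored with [score_model()] and
#' the vote of the highest-scoring model wins (scored path). Score ties are
#' broken by the tied models' macro-F1, then by ensemble model order, so the
#' result is deterministic.
#'
#' @param votes named character vector: one vote per ensemble model.
#' @param ensemble an [ensemble_model()].
#' @return List with `label`, `path` (`"majority"` or `"scored"`), and
#'   `scores` (named numeric, present on the scored path only).
#' @export
ensemble_vote <- function(votes, ensemble) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  if (length(votes) != length(ensemble$bundles) ||
    !setequal(names(votes), names(ensemble$bundles))) {
    stopf("need exactly one vote per ensemble model")
  }
  votes <- votes[names(ensemble$bundles)]
  tab <- table(votes)
  # "majority" = more than half the models back one label (>= 3 of 4);
  # a 2-2 or 2-1-1 split counts as scattered and goes to scoring
  if (max(tab) * 2 > length(votes)) {
    return(list(label = names(tab)[which.max(tab)], path = "majority",
      scores = NULL))
  }
  scores <- vapply(names(votes), function(nm) {
    score_model(nm, votes[[nm]], votes[setdiff(names(votes), nm)], ensemble)
  }, numeric(1))
  macro <- vapply(ensemble$bundles, function(b) b$macro_f1, numeric(1))
  ord <- order(-scores, -macro[names(votes)], seq_along(votes))
  winner <- names(votes)[ord[1]]
  list(label = votes[[winner]], path = "scored", scores = scores)
}

#' Predict classes for a batch of identifiers
#'
#' Encodes the identifiers with the ensemble's stored training encoding
#' (identifiers longer than the training pad length are truncated and
#' characters outside the training inventory map to the pad code, each with
#' a warning), collects each model's vote, and unifies votes row by row.
#' Output rows follow input order.
#'
#' @param ensemble an [ensemble_model()] holding its preprocessing context.
#' @param ids character vector of identifiers, or a table with an `id`
#'   column.
#' @return A tibble with `id`, the final `class`, the decision `path`, one
#'   `vote_<model>` column per member, and `score` (the winning score on the
#'   scored path, `NA` on the majority path).
#' @export
predict_batch <- function(ensemble, ids) {
  stopifnot(inherits(ensemble, "ensemble_model"))
  if (is.data.frame(ids)) ids <- ids$id
  ids <- as.character(ids)
  nm <- names(ensemble$bundles)
  if (length(ids) == 0L) {
    out <- tibble::tibble(id = character(0), class = character(0),
      path = character(0))
    for (m in nm) out[[paste0("vote_", m)]] <- character(0)
    out$score <- numeric(0)
    return(out)
  }
  if (is.null(ensemble$encoding) || is.null(ensemble$pad_len)) {
    stopf("ensemble carries no preprocessing context; rebuild with encoding and pad_len")
  }
  enc <- encode_ids(tibble::tibble(id = ids), ensemble$encoding,
    len = ensemble$pad_len, unknown = "pad")
  X <- enc$X
  if (!is.null(ensemble$kept)) X <- X[, ensemble$kept, drop = FALSE]

  vote_mat <- vapply(nm, function(m) {
    as.character(stats::predict(ensemble$bundles[[m]]$fit, X)$label)
  }, character(length(ids)))
  vote_mat <- matrix(vote_mat, nrow = length(ids),
    dimnames = list(NULL, nm))

  label <- character(length(ids))
  path <- character(length(ids))
  score <- rep(NA_real_, length(ids))
  for (i in seq_len(length(ids))) {
    v <- stats::setNames(vote_mat[i, ], nm)
    res <- ensemble_vote(v, ensemble)
    label[i] <- res$label
    path[i] <- res$path
    if (!is.null(res$scores)) score[i] <- max(res$scores)
  }
  out <- tibble::tibble(id = ids, class = label, path = path)
  for (m in nm) out[[paste0("vote_", m)]] <- unname(vote_mat[, m])
  out$score <- score
  out
}

#' Evaluate the unified ensemble on labelled data
#'
#' @param ensemble an [ensemble_model()].
#' @param test labelled `encoded_ids` (on the full training feature set; the
#'   ensemble applies its own kept-feature subset).
#' @return List with `predictions` (per-row tibble as in [predict_batch()]
#'   but on encoded rows), `cm`, `metrics`, `accuracy` and `macro_f1`.
#' @export
evaluate_ensemble <- function(ensemble, test) {
  stopifnot(inherits(ensemble, "ensemble_model"), inherits(test, "encoded_ids"))
  if (is.null(test$y)) stopf("evaluation requires labelled data")
  nm <- names(ensemble$bundles)
  X <- test$X
  if (!is.null(ensemble$kept)) X <- X[, ensemble$kept, drop = FALSE]
  vote_mat <- vapply(nm, function(m) {
    as.character(stats::predict(ensemble$bundles[[m]]$fit, X)$label)
  }, character(nrow(X)))
  vote_mat <- matrix(vote_mat, nrow = nrow(X), dimnames = list(NULL, nm))
  label <- character(nrow(X))
  path <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    res <- ensemble_vote(stats::setNames(vote_mat[i, ], nm), ensemble)
    label[i] <- res$label
    path[i] <- res$path
  }
  cm <- confusion(as.character(test$y), label, ensemble$classes)
  met <- prf_metrics(cm)
  preds <- tibble::tibble(
    id = test$ids %||% rep(NA_character_, nrow(X)),
    truth = as.character(test$y), class = label, path = path
  )
  for (m in nm) preds[[paste0("vote_", m)]] <- unname(vote_mat[, m])
  list(
    predictions = preds, cm = cm, metrics = met$per_class,
    accuracy = met$overall_accuracy, macro_f1 = met$macro_f1
  )
}
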