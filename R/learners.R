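#' Learner specifications
#'
#' A `learner_spec` names one of the four classifier kinds and carries its
#' hyperparameters. Defaults are the tuned operating points of the reference
#' configuration:
#'
#' * `cart` — decision tree (rpart): complexity 0.00053, max depth 24,
#'   minimum node size 4, no internal cross-validation, 3 competitor splits.
#' * `rf` — random forest (ranger): 385 trees, max depth 368, Gini split
#'   criterion, minprop 0.017, impurity importance, out-of-bag evaluation.
#' * `xgb` — gradient boosting (xgboost, gbtree booster): eta 0.29, max
#'   depth 8, subsample 0.84, minimum loss split (gamma) 0, weight
#'   regularization (lambda) 0.92, 10 boosting rounds, column sampling 0.99,
#'   L1 regularization factor (alpha) 0.014.
#' * `mlp` — neural network: two hidden layers of 40 (ReLU), softmax output,
#'   Adam, categorical cross-entropy, 64 epochs, batch size 128.
#'
#' @param kind one of `"cart"`, `"rf"`, `"xgb"`, `"mlp"`.
#' @param ... hyperparameter overrides (must name known parameters).
#' @return An object of class `learner_spec`.
#' @examples
#' learner_spec("xgb", eta = 0.1)
#' @export
learner_spec <- function(kind = c("cart", "rf", "xgb", "mlp"), ...) {
  kind <- match.arg(kind)
  defaults <- switch(kind,
    cart = list(cp = 0.00053, maxdepth = 24L, minsplit = 4L, xval = 0L,
      maxcompete = 3L),
    rf = list(num.trees = 385L, max.depth = 368L, splitrule = "gini",
      minprop = 0.017, importance = "impurity"),
    xgb = list(eta = 0.29, max_depth = 8L, subsample = 0.84,
      booster = "gbtree", gamma = 0, lambda = 0.92, nrounds = 10L,
      colsample_bytree = 0.99, alpha = 0.014),
    mlp = list(epochs = 64L, batch_size = 128L, hidden = c(40L, 40L),
      lr = 1e-3)
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stopf("unknown %s hyperparameter(s): %s", kind, paste(unknown, collapse = ", "))
  }
  params <- utils::modifyList(defaults, overrides)
  structure(list(kind = kind, params = params), class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  cat("<learner_spec:", x$kind, "> ",
    paste(names(x$params), vapply(x$params, function(p) paste(p, collapse = ","),
      character(1)), sep = "=", collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Train one classifier
#'
#' Fits the learner described by `spec` on a labelled encoded dataset.
#' Training is deterministic given the seed (all backends run
#' single-threaded).
#'
#' @param spec a [learner_spec()].
#' @param data labelled `encoded_ids` (at least two classes present).
#' @param seed integer seed.
#' @return An object of class `fitted_learner`: list with `spec`, the opaque
#'   backend `fit`, `classes` and `feature_names`.
#' @export
train_learner <- function(spec, data, seed = 1L) {
  stopifnot(inherits(spec, "learner_spec"), inherits(data, "encoded_ids"))
  if (is.null(data$y)) stopf("train_learner requires labelled data")
  y <- droplevels(data$y)
  if (nlevels(y) < 2L) stopf("training requires at least 2 classes")
  X <- data$X
  p <- spec$params
  fit <- switch(spec$kind,
    cart = {
      df <- as.data.frame(X)
      df$.class <- y
      with_seed(seed, rpart::rpart(.class ~ ., data = df, method = "class",
        control = rpart::rpart.control(
          cp = p$cp, maxdepth = min(p$maxdepth, 30L), minsplit = p$minsplit,
          xval = p$xval, maxcompete = p$maxcompete
        )))
    },
    rf = {
      df <- as.data.frame(X)
      df$.class <- y
      ranger::ranger(
        dependent.variable.name = ".class", data = df, probability = TRUE,
        num.trees = p$num.trees, max.depth = p$max.depth,
        splitrule = p$splitrule, minprop = p$minprop,
        importance = p$importance, seed = as.integer(seed), num.threads = 1L
      )
    },
    xgb = {
      dtrain <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1L)
      params <- list(
        objective = "multi:softprob", num_class = nlevels(y),
        eta = p$eta, max_depth = p$max_depth, subsample = p$subsample,
        booster = p$booster, gamma = p$gamma, lambda = p$lambda,
        colsample_bytree = p$colsample_bytree, alpha = p$alpha,
        nthread = 1L, seed = as.integer(seed)
      )
      xgboost::xgb.train(params = params, data = dtrain, nrounds = p$nrounds,
        verbose = 0)
    },
    mlp = mlp_train(X, y, hidden = p$hidden, epochs = p$epochs,
      batch_size = p$batch_size, lr = p$lr, seed = seed)
  )
  structure(
    list(spec = spec, fit = fit, classes = levels(y),
      feature_names = colnames(X)),
    class = "fitted_learner"
  )
}

#' Predict labels and class probabilities
#'
#' @param object a `fitted_learner`.
#' @param newdata integer feature matrix over the training feature set.
#' @param ... unused.
#' @return List with `prob` (n x K probability matrix, columns in training
#'   class order) and `label` (factor; ties broken by class order).
#' @export
predict.fitted_learner <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata))
  newdata <- newdata[, object$feature_names, drop = FALSE]
  K <- length(object$classes)
  prob <- switch(object$spec$kind,
    cart = {
      pr <- stats::predict(object$fit, as.data.frame(newdata), type = "prob")
      pr[, object$classes, drop = FALSE]
    },
    rf = {
      pr <- stats::predict(object$fit, as.data.frame(newdata),
        num.threads = 1L)$predictions
      pr[, object$classes, drop = FALSE]
    },
    xgb = {
      pr <- stats::predict(object$fit,
        xgboost::xgb.DMatrix(newdata, nthread = 1L))
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = K, byrow = TRUE)
      colnames(pr) <- object$classes
      pr
    },
    mlp = stats::predict(object$fit, newdata)[, object$classes, drop = FALSE]
  )
  label <- factor(object$classes[max.col(prob, ties.method = "first")],
    levels = object$classes)
  list(prob = prob, label = label)
}

#' Evaluate a fitted learner on held-out data
#'
#' Computes the confusion matrix, per-class F1, the row-normalized
#' misclassification-probability matrix `P(y|x)` (the estimated chance that a
#' sample of true class `x` is predicted `y`), and aggregate accuracy. A true
#' class absent from the test partition has an undefined misclassification
#' row; it is filled with the uniform distribution and flagged (attribute
#' `"uniform_rows"`) with a warning, since downstream ensemble scoring needs
#' every row defined.
#'
#' @param fit a `fitted_learner`.
#' @param test labelled `encoded_ids` whose classes are a subset of the
#'   training classes.
#' @return An object of class `model_bundle`: list with `spec`, `fit`,
#'   `classes`, `cm`, `metrics` (per-class table; see [prf_metrics()]), `f1`
#'   (named per-class vector), `misclass`, `accuracy` and `macro_f1`.
#' @export
evaluate_learner <- function(fit, test) {
  stopifnot(inherits(fit, "fitted_learner"), inherits(test, "encoded_ids"))
  if (is.null(test$y)) stopf("evaluation requires labelled test data")
  extra <- setdiff(unique(as.character(test$y)), fit$classes)
  if (length(extra)) {
    stopf("test set contains class(es) unseen in training: %s",
      paste(extra, collapse = ", "))
  }
  pred <- stats::predict(fit, test$X)
  cm <- confusion(as.character(test$y), as.character(pred$label), fit$classes)
  met <- prf_metrics(cm)
  structure(
    list(
      spec = fit$spec, fit = fit, classes = fit$classes, cm = cm,
      metrics = met$per_class,
      f1 = stats::setNames(met$per_class$F1, met$per_class$class),
      misclass = misclass_matrix(cm),
      accuracy = met$overall_accuracy, macro_f1 = met$macro_f1
    ),
    class = "model_bundle"
  )
}

#' @export
print.model_bundle <- function(x, ...) {
  cat("<model_bundle:", x$spec$kind, "> accuracy ",
    sprintf("%.4f", x$accuracy), ", macro-F1 ",
    sprintf("%.4f", x$macro_f1), "\n", sep = "")
  invisible(x)
}

#' Row-normalized misclassification probabilities
#'
#' @param cm square confusion matrix (true classes in rows).
#' @return Matrix whose row `x` estimates `P(predicted = y | true = x)`.
#'   Rows for classes absent from the evaluation are uniform and recorded in
#'   the `"uniform_rows"` attribute.
#' @export
misclass_matrix <- function(cm) {
  rs <- rowSums(cm)
  out <- cm / ifelse(rs == 0, 1, rs)
  empty <- which(rs == 0)
  if (length(empty)) {
    warnf("class(es) absent from evaluation get uniform misclassification rows: %s",
      paste(rownames(cm)[empty], collapse = ", "))
    out[empty, ] <- 1 / ncol(cm)
  }
  attr(out, "uniform_rows") <- rownames(cm)[empty]
  out
}
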