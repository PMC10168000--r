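#' Default hyperparameter search spaces
#'
#' Bounded boxes around each learner's default operating point, sampled
#' uniformly (log-uniformly for the CART complexity parameter). The neural
#' network is not tuned this way: its architecture is fixed and Adam adapts
#' its learning rates.
#'
#' @param kind `"cart"`, `"rf"` or `"xgb"`.
#' @return A named list of parameter descriptors
#'   (`list(type, lower, upper)`).
#' @export
learner_space <- function(kind = c("cart", "rf", "xgb")) {
  kind <- match.arg(kind)
  num <- function(lower, upper) list(type = "num", lower = lower, upper = upper)
  int <- function(lower, upper) list(type = "int", lower = lower, upper = upper)
  lognum <- function(lower, upper) list(type = "lognum", lower = lower, upper = upper)
  switch(kind,
    cart = list(cp = lognum(1e-4, 1e-2), maxdepth = int(8L, 30L),
      minsplit = int(2L, 16L)),
    rf = list(num.trees = int(100L, 500L), max.depth = int(50L, 500L),
      minprop = num(0.005, 0.1)),
    xgb = list(eta = num(0.05, 0.5), max_depth = int(3L, 12L),
      subsample = num(0.5, 1), colsample_bytree = num(0.5, 1),
      lambda = num(0.5, 1.5), alpha = num(0, 0.1))
  )
}

sample_config <- function(space, kind) {
  vals <- lapply(space, function(d) {
    switch(d$type,
      num = stats::runif(1, d$lower, d$upper),
      int = sample(seq(d$lower, d$upper), 1L),
      lognum = exp(stats::runif(1, log(d$lower), log(d$upper)))
    )
  })
  do.call(learner_spec, c(list(kind = kind), vals))
}

# stratified row subsample keeping every class represented
subsample_fraction <- function(data, fraction, seed) {
  if (fraction >= 1) {
    return(data)
  }
  idx <- with_seed(seed, {
    unlist(lapply(split(seq_along(data$y), data$y), function(ix) {
      k <- max(1L, ceiling(fraction * length(ix)))
      sample(ix, min(k, length(ix)))
    }), use.names = FALSE)
  })
  idx <- sort(idx)
  new_encoded_ids(data$X[idx, , drop = FALSE],
    factor(data$y[idx], levels = levels(data$y)), data$encoding, data$ids[idx])
}

#' Hyperband hyperparameter tuning
#'
#' Races randomly sampled configurations on growing training budgets. With
#' halving factor `eta` and `stages` stages the maximum resource is
#' `R = eta^(stages - 1)`; bracket `s = stages-1, ..., 0` starts
#' `ceiling(stages / (s + 1) * eta^s)` configurations at resource
#' `R * eta^-s`, and after every stage only the lowest-loss
#' `floor(n / eta)` configurations advance to an `eta`-fold larger budget
#' (ties broken by sampling order). The resource unit is the fraction
#' `r / R` of training rows used for the fit. With `eta = 3` and four stages
#' this samples 49 configurations in total.
#'
#' The default objective fits the learner on a stratified subsample of an
#' 80% tuning partition and scores classification error on the held-out 20%
#' (both fixed by the seed). Supply `objective` to tune against anything
#' else — e.g. a stub for testing the bracket arithmetic.
#'
#' @param kind learner kind (`"cart"`, `"rf"`, `"xgb"`).
#' @param data labelled `encoded_ids` (not needed when `objective` is given).
#' @param eta halving factor, at least 2 (default 3).
#' @param stages number of stages per full bracket (default 4).
#' @param seed integer seed.
#' @param objective optional `function(spec, fraction)` returning a loss.
#' @param space search space from [learner_space()].
#' @return An object of class `hyperband_result`: `best_spec` (lowest loss
#'   over all evaluations), `best_loss`, `n_configs` (distinct
#'   configurations sampled), and `schedule` — a tibble with one row per
#'   evaluation (`bracket`, `stage`, `config`, `resource`, `loss`).
#' @examples
#' hb <- hyperband_tune("cart", objective = function(spec, fraction) spec$params$cp)
#' hb$n_configs
#' @export
hyperband_tune <- function(kind = c("cart", "rf", "xgb"), data = NULL,
                           eta = 3, stages = 4, seed = 1L, objective = NULL,
                           space = NULL) {
  kind <- match.arg(kind)
  if (eta < 2) stopf("eta must be at least 2")
  if (stages < 1) stopf("need at least one stage")
  space <- space %||% learner_space(kind)
  if (!length(space)) stopf("empty search space")
  if (is.null(objective)) {
    if (is.null(data)) stopf("either data or an objective is required")
    sp <- stratified_split(data, 0.2, seed = stage_seed(seed, "tune-split"))
    tune_train <- sp$train
    tune_val <- sp$test
    objective <- function(spec, fraction) {
      sub <- subsample_fraction(tune_train, fraction,
        seed = stage_seed(seed, sprintf("tune-sub:%f", fraction)))
      fit <- train_learner(spec, sub, seed = stage_seed(seed, "tune-fit"))
      pred <- stats::predict(fit, tune_val$X)
      mean(as.character(pred$label) != as.character(tune_val$y))
    }
  }

  s_max <- stages - 1
  R <- eta^s_max
  schedule <- list()
  configs <- list()
  next_id <- 1L

  with_seed(seed, {
    for (s in s_max:0) {
      n <- ceiling(stages / (s + 1) * eta^s)
      r0 <- R * eta^(-s)
      ids <- next_id:(next_id + n - 1L)
      for (i in ids) configs[[i]] <- sample_config(space, kind)
      next_id <- next_id + n
      active <- ids
      for (i in 0:s) {
        r_i <- r0 * eta^i
        frac <- r_i / R
        stage_loss <- vapply(active, function(cid) {
          objective(configs[[cid]], frac)
        }, numeric(1))
        schedule[[length(schedule) + 1L]] <- tibble::tibble(
          bracket = s, stage = i, config = active,
          resource = frac, loss = stage_loss
        )
        keep <- floor(length(active) / eta)
        if (i < s && keep >= 1L) {
          active <- active[order(stage_loss)[seq_len(keep)]]
        } else if (i < s) {
          active <- active[order(stage_loss)[1L]]
        }
      }
    }
  })

  sched <- dplyr::bind_rows(schedule)
  # best = lowest loss over all evaluations; ties go to the earliest
  best_row <- sched[order(sched$loss, sched$config), ][1, ]
  structure(
    list(
      best_spec = configs[[best_row$config]], best_loss = best_row$loss,
      n_configs = length(configs), schedule = sched, eta = eta, stages = stages
    ),
    class = "hyperband_result"
  )
}

#' @export
print.hyperband_result <- function(x, ...) {
  cat("<hyperband_result> ", x$n_configs, " configurations, best loss ",
    sprintf("%.5f", x$best_loss), "\n", sep = "")
  invisible(x)
}

#' Tuning-stage plot
#'
#' Loss of every configuration across the stages of each bracket; surviving
#' configurations form the descending polylines.
#'
#' @param result a `hyperband_result`.
#' @return A ggplot object.
#' @export
plot_tuning_stages <- function(result) {
  df <- result$schedule
  df$bracket <- factor(df$bracket)
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$loss,
    group = .data$config, colour = .data$bracket)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "stage", y = "validation loss", colour = "bracket") +
    ggplot2::theme_minimal()
}
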