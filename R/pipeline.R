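#' Pipeline run configuration
#'
#' Bundles every knob of the end-to-end workflow so that a run is
#' reproducible from `(config, seed)` alone.
#'
#' @param registry an [id_registry()]; default [builtin_registry()].
#' @param profile named per-class generation counts; default 200 identifiers
#'   for every registered class (ignored by [fit_pipeline()], which takes an
#'   existing table).
#' @param balance a [balance_config()].
#' @param importance_fraction,corr_threshold feature-filter thresholds (see
#'   [select_features()]).
#' @param specs named list of [learner_spec()]s in ensemble (tie-break)
#'   order; default `rf, xgb, mlp, cart` with their standard settings.
#' @param tune run hyperband tuning for the tree-based learners before
#'   training (default off: the default specs already are tuned operating
#'   points).
#' @param eta,stages hyperband geometry used when `tune = TRUE`.
#' @param c_influence ensemble scoring constant (see [ensemble_model()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(registry = builtin_registry(),
                       profile = NULL,
                       balance = balance_config(),
                       importance_fraction = 0.01, corr_threshold = 0.95,
                       specs = NULL, tune = FALSE, eta = 3, stages = 4,
                       c_influence = 0.5) {
  if (is.null(profile)) {
    profile <- stats::setNames(
      rep(200, length(registry$specs)), names(registry$specs)
    )
  }
  if (is.null(specs)) {
    specs <- list(
      rf = learner_spec("rf"), xgb = learner_spec("xgb"),
      mlp = learner_spec("mlp"), cart = learner_spec("cart")
    )
  }
  structure(
    list(
      registry = registry, profile = profile, balance = balance,
      importance_fraction = importance_fraction,
      corr_threshold = corr_threshold, specs = specs, tune = tune,
      eta = eta, stages = stages, c_influence = c_influence
    ),
    class = "run_config"
  )
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Fit the classification pipeline on a labelled identifier table
#'
#' Executes clean -> encode -> balance -> filter -> (tune) -> train (four
#' learners) -> evaluate -> ensemble -> report, persisting every stage's
#' artifact under `out_dir`. Randomness is fanned out from `seed` with
#' stable per-stage derived seeds, so reruns with the same config and seed
#' produce identical outputs.
#'
#' @param table identifier table with `id` and `class` columns.
#' @param config a [run_config()].
#' @param out_dir run directory (created if needed).
#' @param seed integer master seed.
#' @return An object of class `pipeline_result`: list with `ensemble` (an
#'   [ensemble_model()]), `bundles`, `ensemble_eval`, `split`, `report`
#'   (feature report), `pad_len` and `out_dir`.
#' @export
fit_pipeline <- function(table, config = run_config(), out_dir = tempfile("idrun"),
                         seed = 42L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message(sprintf(...))

  tab <- run_stage("clean", clean_table(table))
  log_msg("clean: %d rows, %d classes", nrow(tab), length(unique(tab$class)))

  encoding <- default_encoding()
  enc <- run_stage("encode", encode_ids(tab, encoding))
  len <- ncol(enc$X)
  write_encoding(encoding, file.path(out_dir, "encoding.json"))
  log_msg("encode: pad length %d", len)

  split <- run_stage("balance",
    balance_dataset(enc, config$balance, seed = stage_seed(seed, "balance")))
  write_balance_report(split, file.path(out_dir, "balance_report.tsv"))
  log_msg("balance: train %d (%d synthetic), test %d",
    nrow(split$train$X), sum(split$train$synthetic), nrow(split$test$X))

  report <- run_stage("filter", feature_report(split$train,
    importance_fraction = config$importance_fraction,
    corr_threshold = config$corr_threshold,
    seed = stage_seed(seed, "importance")))
  export_feature_report(report, file.path(out_dir, "features"))
  kept <- report$kept
  log_msg("filter: kept %d of %d positions", length(kept), len)

  train <- keep_features(split$train, kept)
  test <- keep_features(split$test, kept)

  specs <- config$specs
  if (config$tune) {
    for (kind in intersect(names(specs), c("cart", "rf", "xgb"))) {
      hb <- run_stage(paste0("tune:", kind), hyperband_tune(
        kind, train, eta = config$eta, stages = config$stages,
        seed = stage_seed(seed, paste0("tune:", kind))
      ))
      readr::write_tsv(hb$schedule,
        file.path(out_dir, paste0("tuning_", kind, ".tsv")))
      save_plot_quietly(plot_tuning_stages(hb),
        file.path(out_dir, paste0("tuning_", kind, ".png")))
      specs[[kind]] <- hb$best_spec
      log_msg("tune %s: %d configurations, best loss %.5f",
        kind, hb$n_configs, hb$best_loss)
    }
  }

  bundles <- list()
  for (nm in names(specs)) {
    fit <- run_stage(paste0("train:", nm),
      train_learner(specs[[nm]], train, seed = stage_seed(seed, paste0("train:", nm))))
    bundles[[nm]] <- run_stage(paste0("evaluate:", nm),
      evaluate_learner(fit, test))
    log_msg("train %s: held-out accuracy %.4f", nm, bundles[[nm]]$accuracy)
  }

  ens <- ensemble_model(bundles, c_influence = config$c_influence,
    encoding = encoding, pad_len = len, kept = kept)
  ens_eval <- run_stage("ensemble", evaluate_ensemble(ens, split$test))
  log_msg("ensemble: held-out accuracy %.4f", ens_eval$accuracy)

  run_stage("report", {
    export_report(bundles, ens_eval, file.path(out_dir, "reports"))
    readr::write_tsv(ens_eval$predictions, file.path(out_dir, "predictions.tsv"))
  })
  saveRDS(ens, file.path(out_dir, "model.rds"))

  manifest <- list(
    seed = seed, pad_len = len, kept = kept,
    classes = ens$classes, c_influence = config$c_influence,
    n_train = nrow(train$X), n_test = nrow(test$X),
    accuracy = list(
      ensemble = ens_eval$accuracy,
      models = lapply(bundles, function(b) b$accuracy)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA)

  structure(
    list(
      ensemble = ens, bundles = bundles, ensemble_eval = ens_eval,
      split = split, report = report, pad_len = len, out_dir = out_dir
    ),
    class = "pipeline_result"
  )
}

#' Run the full workflow from a generation profile
#'
#' Generates the seeded synthetic corpus described by the config's profile,
#' then hands it to [fit_pipeline()].
#'
#' @inheritParams fit_pipeline
#' @return A `pipeline_result` (see [fit_pipeline()]); the generated corpus
#'   is persisted as `dataset.tsv` in the run directory.
#' @examples
#' \donttest{
#' cfg <- run_config(profile = c(ChEMBL = 60, Rfam = 60, HGNC = 60))
#' res <- run_pipeline(cfg, seed = 1)
#' res$ensemble_eval$accuracy
#' }
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("idrun"),
                         seed = 42L) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- run_stage("generate",
    generate_dataset(config$registry, config$profile,
      seed = stage_seed(seed, "generate")))
  write_id_table(tab, file.path(out_dir, "dataset.tsv"))
  fit_pipeline(tab, config, out_dir = out_dir, seed = seed)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> ensemble held-out accuracy ",
    sprintf("%.4f", x$ensemble_eval$accuracy), "; run dir: ", x$out_dir,
    "\n", sep = "")
  invisible(x)
}
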