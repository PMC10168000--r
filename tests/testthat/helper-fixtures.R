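# Shared fixtures. Everything is generated in code at test time; the only
# expensive object (a small trained pipeline) is built once per run and
# memoized in this environment.

.fixture_env <- new.env(parent = emptyenv())

# four easily separable classes, small counts: fast to train yet exercises
# every pipeline stage
fixture_profile <- function() {
  c("ChEMBL" = 60, "Ensembl gene" = 60, "HGNC" = 60, "Rfam" = 60)
}

fixture_config <- function() {
  run_config(
    profile = fixture_profile(),
    specs = list(
      rf = learner_spec("rf", num.trees = 60L),
      xgb = learner_spec("xgb"),
      mlp = learner_spec("mlp", epochs = 8L),
      cart = learner_spec("cart")
    )
  )
}

fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    dir <- file.path(tempdir(), "idsleuth-fixture-run")
    .fixture_env$pipeline <- suppressMessages(
      run_pipeline(fixture_config(), out_dir = dir, seed = 42)
    )
  }
  .fixture_env$pipeline
}

# hand-built model bundles with chosen F1 / misclassification tables, for
# exact ensemble-scoring oracles
fake_bundle <- function(kind, classes, f1, misclass, macro_f1 = mean(f1)) {
  cm <- matrix(0L, length(classes), length(classes),
    dimnames = list(classes, classes))
  structure(
    list(
      spec = learner_spec(kind), fit = NULL, classes = classes, cm = cm,
      metrics = NULL, f1 = stats::setNames(f1, classes),
      misclass = misclass, accuracy = NA_real_, macro_f1 = macro_f1
    ),
    class = "model_bundle"
  )
}

uniform_misclass <- function(classes) {
  k <- length(classes)
  matrix(1 / k, k, k, dimnames = list(classes, classes))
}

# the published per-class corpus sizes and balanced training counts used as
# the closed-form reference
reference_balanced_counts <- function() {
  c(
    60736, 68390, 69342, 139545, 596934, 50146, 63673, 70444, 58617, 162747,
    63418, 65267, 70317, 69997, 56079, 68572, 70282, 70266, 70106, 343233,
    69802, 51937, 65803, 53386, 70534, 70113, 62810, 70287, 70532, 70245,
    70217, 70373, 158752, 63554, 64420, 63104, 52020, 64765, 63673
  )
}
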