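three_model_ensemble <- function(c_influence, classes = c("x", "y1", "y2")) {
  # model "n" votes x; misclassification rows of the OTHER two models are
  # chosen to make the score an exact hand computation
  P_r1 <- uniform_misclass(classes)
  P_r1["x", ] <- c(0.8, 0.2, 0) # P_r1(y1 | x) = 0.2
  P_r2 <- uniform_misclass(classes)
  P_r2["x", ] <- c(1, 0, 0) # P_r2(y2 | x) = 0
  bundles <- list(
    n = fake_bundle("rf", classes, f1 = c(0.9, 0.7, 0.6), uniform_misclass(classes)),
    r1 = fake_bundle("xgb", classes, f1 = c(0.8, 0.8, 0.8), P_r1),
    r2 = fake_bundle("cart", classes, f1 = c(0.7, 0.7, 0.7), P_r2)
  )
  ensemble_model(bundles, c_influence = c_influence)
}

test_that("the disagreement score matches the hand oracle", {
  ens <- three_model_ensemble(0.5)
  s <- score_model("n", "x", c(r1 = "y1", r2 = "y2"), ens)
  expect_equal(s, 0.9 * (0.5 + 0.5 * 0.2) * (0.5 + 0.5 * 0)) # = 0.27
  expect_equal(s, 0.27)
})

test_that("at c = 1 the score collapses to the model's per-class F1", {
  ens <- three_model_ensemble(1)
  expect_equal(score_model("n", "x", c(r1 = "y1", r2 = "y2"), ens), 0.9)
  # and agreement with perfectly self-consistent peers changes nothing
  ens2 <- three_model_ensemble(0.5)
  ens2$bundles$r1$misclass["x", ] <- c(1, 0, 0)
  ens2$bundles$r2$misclass["x", ] <- c(1, 0, 0)
  expect_equal(score_model("n", "x", c(r1 = "x", r2 = "x"), ens2), 0.9)
})

test_that("the score is affine and non-decreasing in each misclassification term", {
  classes <- c("x", "y1", "y2")
  probe <- function(p) {
    ens <- three_model_ensemble(0.5, classes)
    ens$bundles$r1$misclass["x", ] <- c(1 - p, p, 0)
    score_model("n", "x", c(r1 = "y1", r2 = "y2"), ens)
  }
  ps <- seq(0, 1, by = 0.25)
  scores <- vapply(ps, probe, numeric(1))
  expect_true(all(diff(scores) > 0))
  slopes <- diff(scores) / diff(ps)
  # slope = F1 * (1 - c) * (other factor) = 0.9 * 0.5 * 0.5
  expect_equal(unname(slopes), rep(0.9 * 0.5 * 0.5, 4))
  expect_true(all(scores >= 0 & scores <= 1))
})

test_that("a three-of-four majority wins outright; splits go to scoring", {
  classes <- c("A", "B", "C")
  bundles <- list(
    rf = fake_bundle("rf", classes, c(0.9, 0.9, 0.9), uniform_misclass(classes)),
    xgb = fake_bundle("xgb", classes, c(0.9, 0.9, 0.9), uniform_misclass(classes)),
    mlp = fake_bundle("mlp", classes, c(0.9, 0.9, 0.9), uniform_misclass(classes)),
    cart = fake_bundle("cart", classes, c(0.9, 0.9, 0.9), uniform_misclass(classes))
  )
  ens <- ensemble_model(bundles, 0.5)
  v <- function(...) c(rf = ..1, xgb = ..2, mlp = ..3, cart = ..4)
  r <- ensemble_vote(v("A", "A", "A", "B"), ens)
  expect_identical(r$label, "A")
  expect_identical(r$path, "majority")
  expect_null(r$scores)
  expect_identical(ensemble_vote(v("A", "A", "A", "A"), ens)$label, "A")
  r22 <- ensemble_vote(v("A", "A", "B", "B"), ens)
  expect_identical(r22$path, "scored")
  expect_length(r22$scores, 4L)
  expect_true(r22$label %in% c("A", "B"))
  r211 <- ensemble_vote(v("A", "A", "B", "C"), ens)
  expect_identical(r211$path, "scored")
  expect_error(ensemble_vote(c(rf = "A", xgb = "A"), ens), "one vote per")
})

test_that("the scored path picks the highest-scoring model's vote", {
  classes <- c("A", "B")
  # rf votes A with high F1; cart votes B with low F1; peers indifferent
  bundles <- list(
    rf = fake_bundle("rf", classes, c(0.95, 0.5), uniform_misclass(classes)),
    xgb = fake_bundle("xgb", classes, c(0.95, 0.5), uniform_misclass(classes)),
    mlp = fake_bundle("mlp", classes, c(0.4, 0.4), uniform_misclass(classes)),
    cart = fake_bundle("cart", classes, c(0.4, 0.4), uniform_misclass(classes))
  )
  ens <- ensemble_model(bundles, 0.5)
  r <- ensemble_vote(c(rf = "A", xgb = "B", mlp = "B", cart = "A"), ens)
  expect_identical(r$path, "scored")
  expect_identical(r$label, "A") # rf's F1 for A dominates
  expect_identical(names(which.max(r$scores)), "rf")
})

test_that("score ties break by macro-F1, then by fixed model order", {
  classes <- c("A", "B")
  mk <- function(kind, macro) {
    fake_bundle(kind, classes, c(0.8, 0.8), uniform_misclass(classes),
      macro_f1 = macro)
  }
  bundles <- list(rf = mk("rf", 0.7), xgb = mk("xgb", 0.9),
    mlp = mk("mlp", 0.7), cart = mk("cart", 0.7))
  ens <- ensemble_model(bundles, 1) # all scores equal the common F1 = 0.8
  r <- ensemble_vote(c(rf = "A", xgb = "B", mlp = "A", cart = "B"), ens)
  expect_identical(r$label, "B") # xgb has the highest macro-F1
  bundles2 <- list(rf = mk("rf", 0.7), xgb = mk("xgb", 0.7),
    mlp = mk("mlp", 0.7), cart = mk("cart", 0.7))
  ens2 <- ensemble_model(bundles2, 1)
  r2 <- ensemble_vote(c(rf = "A", xgb = "B", mlp = "A", cart = "B"), ens2)
  expect_identical(r2$label, "A") # full tie: first model in ensemble order
})

test_that("batch prediction preserves order and handles empty input", {
  ens <- fixture_pipeline()$ensemble
  empty <- predict_batch(ens, character(0))
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("id", "class", "path", "vote_rf", "score") %in% names(empty)))
  ids <- generate_ids(builtin_registry(), "ChEMBL", 20, seed = 99)
  out <- predict_batch(ens, ids)
  expect_identical(out$id, ids)
  expect_true(all(out$class == "ChEMBL"))
  expect_true(all(out$path %in% c("majority", "scored")))
})
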