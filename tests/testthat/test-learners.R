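sep_toy <- function(n_per = 40, seed = 1) {
  # two linearly separable classes in two coded positions
  withr::with_seed(seed, {
    X <- rbind(
      cbind(pos1 = sample(1:5, n_per, TRUE), pos2 = sample(1:5, n_per, TRUE)),
      cbind(pos1 = sample(20:25, n_per, TRUE), pos2 = sample(20:25, n_per, TRUE))
    )
    y <- factor(rep(c("low", "high"), each = n_per))
    structure(list(X = X, y = y, encoding = default_encoding(), ids = NULL),
      class = "encoded_ids")
  })
}

test_that("learner specs carry the standard settings and reject unknowns", {
  expect_equal(learner_spec("cart")$params$cp, 0.00053)
  expect_equal(learner_spec("rf")$params$num.trees, 385L)
  expect_equal(learner_spec("xgb")$params$eta, 0.29)
  expect_equal(learner_spec("mlp")$params$hidden, c(40L, 40L))
  expect_equal(learner_spec("xgb", eta = 0.1)$params$eta, 0.1)
  expect_error(learner_spec("cart", bogus = 1), "unknown cart")
})

test_that("training is deterministic under a fixed seed", {
  toy <- sep_toy()
  for (kind in c("cart", "rf", "xgb", "mlp")) {
    spec <- if (kind == "mlp") learner_spec("mlp", epochs = 3L) else learner_spec(kind)
    f1 <- train_learner(spec, toy, seed = 5)
    f2 <- train_learner(spec, toy, seed = 5)
    expect_identical(
      predict(f1, toy$X)$prob, predict(f2, toy$X)$prob,
      label = paste(kind, "determinism")
    )
  }
})

test_that("separable classes are learned perfectly by the forest", {
  toy <- sep_toy()
  fit <- train_learner(learner_spec("rf"), toy, seed = 1)
  pred <- predict(fit, toy$X)
  expect_identical(as.character(pred$label), as.character(toy$y))
  expect_identical(colnames(pred$prob), fit$classes)
  expect_equal(unname(rowSums(pred$prob)), rep(1, nrow(toy$X)), tolerance = 1e-8)
})

test_that("the neural network's training loss decreases", {
  toy <- sep_toy(n_per = 120)
  fit <- train_learner(learner_spec("mlp", epochs = 40L, batch_size = 32L),
    toy, seed = 2)
  hist <- fit$fit$loss_history
  expect_length(hist, 40L)
  expect_lt(hist[40], hist[1])
  b <- evaluate_learner(fit, toy)
  expect_gt(b$accuracy, 0.9)
})

test_that("training refuses unlabelled or single-class data", {
  toy <- sep_toy()
  toy1 <- toy
  toy1$y <- factor(rep("low", length(toy$y)))
  expect_error(train_learner(learner_spec("cart"), toy1, seed = 1), "2 classes")
  toy2 <- toy
  toy2$y <- NULL
  expect_error(train_learner(learner_spec("cart"), toy2, seed = 1), "labelled")
})

test_that("evaluation produces conserved confusion matrices and valid F1", {
  toy <- sep_toy()
  fit <- train_learner(learner_spec("cart"), toy, seed = 1)
  b <- evaluate_learner(fit, toy)
  expect_identical(sum(b$cm), length(toy$y))
  expect_identical(as.integer(rowSums(b$cm)), as.integer(table(toy$y)[fit$classes]))
  expect_true(all(b$f1 >= 0 & b$f1 <= 1))
  expect_true(b$macro_f1 >= 0 && b$macro_f1 <= 1)
  expect_equal(unname(rowSums(b$misclass)), rep(1, 2))
})

test_that("a test class unseen in training is rejected", {
  toy <- sep_toy()
  fit <- train_learner(learner_spec("cart"), toy, seed = 1)
  bad <- toy
  bad$y <- factor(rep(c("low", "other"), length.out = length(toy$y)))
  expect_error(evaluate_learner(fit, bad), "unseen in training")
})

test_that("a class missing from the test partition gets a flagged uniform row", {
  cm <- matrix(c(5L, 0L, 0L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(mc <- misclass_matrix(cm), "uniform")
  expect_equal(unname(mc["b", ]), c(0.5, 0.5))
  expect_identical(attr(mc, "uniform_rows"), "b")
})

test_that("hyperband brackets follow the halving geometry", {
  stub <- function(spec, fraction) spec$params$cp / fraction
  hb <- hyperband_tune("cart", objective = stub, eta = 3, stages = 4, seed = 1)
  expect_identical(hb$n_configs, 49L)
  first_stage <- table(hb$schedule$bracket[hb$schedule$stage == 0])
  expect_identical(as.integer(first_stage[c("3", "2", "1", "0")]), c(27L, 12L, 6L, 4L))
  # survivors per stage are the lowest-loss floor(n / eta)
  b3 <- hb$schedule[hb$schedule$bracket == 3, ]
  expect_identical(as.integer(table(b3$stage)), c(27L, 9L, 3L, 1L))
  s0 <- b3[b3$stage == 0, ]
  s1 <- b3[b3$stage == 1, ]
  expect_setequal(s1$config, s0$config[order(s0$loss)][1:9])
  # the total configuration count matches the bracket formula for any geometry
  for (geom in list(c(2, 3), c(3, 3), c(4, 2))) {
    eta <- geom[1]; stages <- geom[2]
    hb2 <- hyperband_tune("cart", objective = stub, eta = eta, stages = stages,
      seed = 2)
    expected <- sum(vapply((stages - 1):0, function(s) {
      ceiling(stages / (s + 1) * eta^s)
    }, numeric(1)))
    expect_identical(hb2$n_configs, as.integer(expected))
  }
})

test_that("hyperband's default objective tunes on real data", {
  toy <- sep_toy(n_per = 60)
  hb <- hyperband_tune("cart", data = toy, eta = 2, stages = 2, seed = 3)
  expect_s3_class(hb$best_spec, "learner_spec")
  expect_true(all(hb$schedule$loss >= 0 & hb$schedule$loss <= 1))
  expect_lte(hb$best_loss, max(hb$schedule$loss))
})
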