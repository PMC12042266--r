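# Training loop, prediction contract, evaluation metrics and checkpoints.

small_config <- function(...) {
  model_config(embedding = 16L, conv_layers = 2L, pooling = "mean",
               head_hidden = 16L, lr = 3e-3, batch_size = 16L,
               val_fraction = 0.2, ...)
}

test_that("a short training run produces finite history and honours epochs", {
  gs <- cached_graphs(20, seed = 41)
  m <- train(gs, small_config(epochs = 2L, patience = 5L, seed = 2L))
  expect_equal(nrow(m$history), 2L)
  expect_true(all(is.finite(m$history$train_loss)))
  expect_true(all(is.finite(m$history$val_loss)))
  expect_s3_class(m, "hydro_model")
})

test_that("training is deterministic under the seed", {
  gs <- cached_graphs(20, seed = 41)
  m1 <- train(gs, small_config(epochs = 4L, patience = 5L, seed = 9L))
  m2 <- train(gs, small_config(epochs = 4L, patience = 5L, seed = 9L))
  expect_identical(m1$history, m2$history)
  expect_identical(predict_dg(m1, gs), predict_dg(m2, gs))
  m3 <- train(gs, small_config(epochs = 4L, patience = 5L, seed = 10L))
  expect_false(identical(m1$history$train_loss, m3$history$train_loss))
})

test_that("training errors are typed and informative", {
  expect_error(train(list()), class = "hydro_training_error")
  gs <- cached_graphs(5, seed = 41)
  gs[[2]]$dG <- NA_real_
  expect_error(train(gs, small_config(epochs = 1L)),
               class = "hydro_training_error")
})

test_that("predictions are reproducible and invariant to relabeling", {
  gs <- cached_graphs(15, seed = 41)
  m <- train(gs, small_config(epochs = 3L, patience = 5L, seed = 4L))
  p1 <- predict_dg(m, gs)
  p2 <- predict_dg(m, gs)
  expect_identical(p1, p2)               # bitwise-identical repeat calls
  for (k in 1:3) {
    perm <- lapply(seq_along(gs), function(i) permute_graph(gs[[i]], seed = 100 + k * i))
    expect_equal(predict_dg(m, perm), p1, tolerance = 1e-10)
  }
  expect_length(predict_dg(m, gs[[1]]), 1L)   # single reaction input
})

test_that("evaluation metrics follow their standard definitions", {
  y <- c(-3.2, 1.5, 0.7, -8.1, 12)
  yhat <- c(-2.0, 2.5, -0.3, -8.1, 6)
  fg <- c("urea", "urea", "amide", "amide", "amide")
  ev <- eval_metrics(y, yhat, fg)
  err <- yhat - y
  expect_equal(ev$mae, mean(abs(err)))
  expect_equal(ev$rmse, sqrt(mean(err^2)))
  expect_equal(ev$r2, 1 - sum(err^2) / sum((y - mean(y))^2))
  expect_equal(ev$sign_accuracy, 100 * 4 / 5)  # signs: -,+,+,-,+ vs -,+,-,-,+
  expect_equal(unname(ev$error_bins), c(4L, 0L, 1L, 0L))
  expect_equal(sum(ev$error_bins), length(y))
  urea_mae <- ev$per_fg_mae$mae[ev$per_fg_mae$fg_id == "urea"]
  expect_equal(urea_mae, mean(abs(err[1:2])))

  # perfect predictor
  evp <- eval_metrics(y, y, fg)
  expect_equal(evp$mae, 0); expect_equal(evp$rmse, 0)
  expect_equal(evp$r2, 1); expect_equal(evp$sign_accuracy, 100)

  # constant predictor at the label mean has R^2 = 0
  evc <- eval_metrics(y, rep(mean(y), 5), fg)
  expect_equal(evc$r2, 0)
})

test_that("MAE never exceeds RMSE on real evaluations", {
  gs <- cached_graphs(30, seed = 41)
  m <- train(gs, small_config(epochs = 3L, patience = 5L, seed = 6L))
  ev <- evaluate(m, gs)
  expect_lte(ev$mae, ev$rmse)
  expect_equal(sum(ev$error_bins), ev$n)
  expect_setequal(ev$per_fg_mae$fg_id,
                  unique(vapply(gs, `[[`, character(1), "fg_id")))
})

test_that("checkpoints round trip through JSON with identical predictions", {
  gs <- cached_graphs(12, seed = 41)
  m <- train(gs, small_config(epochs = 3L, patience = 5L, seed = 8L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(m2$label_mean, m$label_mean)
  expect_equal(predict_dg(m2, gs), predict_dg(m, gs), tolerance = 1e-12)
  expect_identical(m2$schema, feature_schema_version())
})
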