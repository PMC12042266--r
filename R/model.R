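# Model API: configuration, seeded training with Adam and early stopping,
# prediction, evaluation reports and text checkpoints.

#' Model configuration
#'
#' @param embedding node embedding size shared by atom, bond and global
#'   nodes.
#' @param conv_layers number of gated graph-convolution layers (2-4
#'   typical).
#' @param pooling one of `"mean"`, `"weighted_mean"`, `"self_attention"`,
#'   `"set2set"`.
#' @param head_hidden integer vector of dense head hidden sizes.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction fraction of the training set held out for
#'   validation/early stopping.
#' @param loss `"mse"` (default) or `"mae"`; MAE is always reported.
#' @param seed random seed controlling initialization, the train/val split
#'   and batch shuffling.
#' @return A `hydro_config` list.
#' @export
model_config <- function(embedding = 64L, conv_layers = 3L,
                         pooling = c("mean", "weighted_mean", "self_attention", "set2set"),
                         head_hidden = c(64L), lr = 1e-3, batch_size = 128L,
                         epochs = 200L, patience = 30L, val_fraction = 0.1,
                         loss = c("mse", "mae"), seed = 1L) {
  pooling <- match.arg(pooling)
  loss <- match.arg(loss)
  stopifnot(embedding > 0L, conv_layers >= 1L, all(head_hidden > 0L),
            lr > 0, batch_size > 0L, epochs > 0L, patience > 0L,
            val_fraction >= 0, val_fraction < 1)
  structure(list(embedding = as.integer(embedding),
                 conv_layers = as.integer(conv_layers),
                 pooling = pooling, head_hidden = as.integer(head_hidden),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 val_fraction = val_fraction, loss = loss,
                 seed = as.integer(seed)),
            class = "hydro_config")
}

training_error <- function(msg) {
  stop(structure(class = c("hydro_training_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

as_graphs <- function(dataset) {
  if (length(dataset) == 0L) return(list())
  if (inherits(dataset[[1]], "hydro_rxn_graph")) return(dataset)
  lapply(dataset, build_reaction_graph)
}

#' Train the reaction-graph network
#'
#' Standardizes labels to zero mean / unit variance on the training split,
#' minimizes the configured loss with Adam, applies early stopping on a
#' seeded validation split, and returns the parameters of the best
#' validation epoch.
#'
#' @param dataset list of labelled `hydro_reaction` or `hydro_rxn_graph`.
#' @param config a [model_config()].
#' @param quiet suppress per-epoch stderr logging.
#' @param log_file optional path receiving per-epoch log lines.
#' @return A `hydro_model`: parameters, config, feature schema version,
#'   label scaling, and per-epoch `history` (train/val loss).
#' @export
train <- function(dataset, config = model_config(), quiet = TRUE,
                  log_file = NULL) {
  graphs <- as_graphs(dataset)
  if (length(graphs) == 0L) training_error("empty training dataset")
  y <- vapply(graphs, function(g) g$dG, numeric(1))
  if (anyNA(y)) training_error("training requires a dG label on every reaction")
  bad <- vapply(graphs, function(g) !identical(g$schema, feature_schema_version()),
                logical(1))
  if (any(bad)) schema_error("graph schema does not match current featurization")

  set.seed(config$seed)
  n <- length(graphs)
  n_val <- max(if (config$val_fraction > 0) 1L else 0L,
               floor(config$val_fraction * n))
  if (n_val >= n) n_val <- n - 1L
  idx <- sample.int(n)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)

  mu <- mean(y[tr_idx]); sdv <- stats::sd(y[tr_idx])
  if (!is.finite(sdv) || sdv < 1e-8) sdv <- 1
  scale_y <- function(v) (v - mu) / sdv
  tr_graphs <- graphs[tr_idx]; va_graphs <- graphs[val_idx]

  dims <- feature_dims()
  params <- init_params(config, dims$atom, dims$bond + 3L, dims$global)
  skel <- param_skeleton(params)
  flat <- flatten_params(params)
  m <- v <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L

  va_batch <- if (length(va_graphs) > 0L) batch_graphs(va_graphs) else NULL
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best_val <- Inf; best_flat <- flat; best_epoch <- 0L; stall <- 0L
  log_line <- function(txt) {
    if (!quiet) message(txt)
    if (!is.null(log_file)) cat(txt, "\n", file = log_file, append = TRUE)
  }

  eval_loss <- function(flat_params, batch) {
    p <- unflatten_params(flat_params, skel)
    fw <- nn_forward(p, batch, config)
    err <- fw$yhat - scale_y(batch$y)
    if (config$loss == "mse") mean(err^2) else mean(abs(err))
  }

  for (epoch in seq_len(config$epochs)) {
    # cosine decay from lr to lr/30 across the epoch budget
    lr_now <- config$lr * (1 / 30 + (1 - 1 / 30) *
                           (1 + cos(pi * (epoch - 1) / config$epochs)) / 2)
    ord <- sample(seq_along(tr_graphs))
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (bi in batches) {
      batch <- batch_graphs(tr_graphs[bi])
      p <- unflatten_params(flat, skel)
      fw <- nn_forward(p, batch, config)
      err <- fw$yhat - scale_y(batch$y)
      nb <- length(bi)
      if (config$loss == "mse") {
        loss <- mean(err^2); dy <- 2 * err / nb
      } else {
        loss <- mean(abs(err)); dy <- sign(err) / nb
      }
      if (!is.finite(loss))
        training_error(sprintf("non-finite loss at epoch %d", epoch))
      gr <- nn_backward(p, batch, config, fw, dy)
      gflat <- flatten_params(gr)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * gflat
      v <- b2 * v + (1 - b2) * gflat^2
      mhat <- m / (1 - b1^step); vhat <- v / (1 - b2^step)
      flat <- flat - lr_now * mhat / (sqrt(vhat) + eps)
      ep_loss <- ep_loss + loss * nb
    }
    ep_loss <- ep_loss / length(tr_graphs)
    val_loss <- if (!is.null(va_batch)) eval_loss(flat, va_batch) else ep_loss
    history <- rbind(history, data.frame(epoch = epoch, train_loss = ep_loss,
                                         val_loss = val_loss))
    log_line(sprintf("epoch %3d  train %.5f  val %.5f", epoch, ep_loss, val_loss))
    if (val_loss < best_val - 1e-9) {
      best_val <- val_loss; best_flat <- flat; best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) {
        log_line(sprintf("early stop at epoch %d (best %d)", epoch, best_epoch))
        break
      }
    }
  }
  structure(list(params = unflatten_params(best_flat, skel),
                 config = config,
                 schema = feature_schema_version(),
                 label_mean = mu, label_sd = sdv,
                 best_epoch = best_epoch,
                 history = history),
            class = "hydro_model")
}

#' @export
print.hydro_model <- function(x, ...) {
  cat(sprintf("<model: %d conv layers, embedding %d, %s pooling, %d epochs trained (best %d)>\n",
              x$config$conv_layers, x$config$embedding, x$config$pooling,
              nrow(x$history), x$best_epoch))
  invisible(x)
}

#' Predict hydrolysis free energies (kcal/mol)
#'
#' @param model a trained `hydro_model`.
#' @param dataset one reaction/graph or a list of them.
#' @return Numeric vector of predicted reaction free energies.
#' @export
predict_dg <- function(model, dataset) {
  if (inherits(dataset, c("hydro_reaction", "hydro_rxn_graph")))
    dataset <- list(dataset)
  graphs <- as_graphs(dataset)
  if (length(graphs) == 0L) return(numeric(0))
  if (!all(vapply(graphs, function(g) identical(g$schema, model$schema), logical(1))))
    schema_error("feature schema of input does not match the trained model")
  batch <- batch_graphs(graphs)
  fw <- nn_forward(model$params, batch, model$config)
  fw$yhat * model$label_sd + model$label_mean
}

#' Evaluate a model on a labelled dataset
#'
#' Computes MAE and RMSE (kcal/mol), the coefficient of determination
#' R-squared, the endergonic/exergonic sign-classification accuracy (% of
#' reactions whose predicted free-energy sign matches the label sign), the
#' absolute-error bin counts (<2, 2-5, 5-10, >10 kcal/mol) and a
#' per-functional-group MAE table.
#'
#' @inheritParams predict_dg
#' @return An `hydro_eval` list.
#' @export
evaluate <- function(model, dataset) {
  graphs <- as_graphs(dataset)
  if (length(graphs) == 0L) training_error("empty evaluation dataset")
  y <- vapply(graphs, function(g) g$dG, numeric(1))
  if (anyNA(y)) training_error("evaluation requires labels")
  yhat <- predict_dg(model, graphs)
  fg <- vapply(graphs, `[[`, character(1), "fg_id")
  eval_metrics(y, yhat, fg)
}

#' Regression metrics for predicted vs labelled free energies
#'
#' Standard definitions: MAE, RMSE, R-squared (1 - SS_res/SS_tot),
#' sign-classification accuracy in percent, absolute-error bin counts and
#' the per-group MAE table.
#'
#' @param y label vector (kcal/mol).
#' @param yhat prediction vector.
#' @param fg functional-group id per reaction.
#' @return An `hydro_eval` list.
#' @export
eval_metrics <- function(y, yhat, fg = rep("carboxylic acid ester", length(y))) {
  stopifnot(length(y) == length(yhat), length(fg) == length(y))
  err <- yhat - y
  ae <- abs(err)
  per_fg <- stats::aggregate(ae, list(fg_id = fg), mean)
  names(per_fg)[2] <- "mae"
  per_fg$n <- as.integer(table(fg)[per_fg$fg_id])
  ss_res <- sum(err^2); ss_tot <- sum((y - mean(y))^2)
  bins <- c(`<2` = sum(ae < 2),
            `2-5` = sum(ae >= 2 & ae < 5),
            `5-10` = sum(ae >= 5 & ae < 10),
            `>10` = sum(ae >= 10))
  structure(list(mae = mean(ae),
                 rmse = sqrt(mean(err^2)),
                 r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
                 sign_accuracy = 100 * mean(sign(yhat) == sign(y)),
                 n = length(y),
                 error_bins = bins,
                 per_fg_mae = per_fg),
            class = "hydro_eval")
}

#' @export
print.hydro_eval <- function(x, ...) {
  cat(sprintf("n=%d  MAE %.3f  RMSE %.3f  R2 %.3f  sign acc %.1f%%\n",
              x$n, x$mae, x$rmse, x$r2, x$sign_accuracy))
  cat("error bins (kcal/mol):",
      paste(names(x$error_bins), x$error_bins, sep = ": ", collapse = "  "), "\n")
  df <- x$per_fg_mae
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-28s MAE %.3f (n=%d)\n", df$fg_id[i], df$mae[i], df$n[i]))
  invisible(x)
}

#' Save / load a model checkpoint (JSON text)
#'
#' The checkpoint embeds the configuration, the feature schema version and
#' the label scaling alongside the parameters; loading refuses a schema
#' mismatch.
#'
#' @param model a `hydro_model`.
#' @param path checkpoint file.
#' @return `path` ([save_model()]); a `hydro_model` ([load_model()]).
#' @export
save_model <- function(model, path) {
  flat <- unlist(model$params)
  out <- list(schema = model$schema,
              config = unclass(model$config),
              label_mean = model$label_mean, label_sd = model$label_sd,
              best_epoch = model$best_epoch,
              history = model$history,
              param_names = names(flat),
              param_values = as.numeric(flat),
              skeleton = skeleton_spec(model$params))
  jsonlite::write_json(out, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

skeleton_spec <- function(params) {
  # record matrix shapes so the flat vector can be restored
  rapply(params, function(x) if (is.matrix(x)) dim(x) else length(x),
         how = "list")
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, feature_schema_version()))
    schema_error(sprintf("checkpoint schema '%s' does not match '%s'",
                         raw$schema, feature_schema_version()))
  cfg <- do.call(model_config, raw$config[setdiff(names(raw$config), character(0))])
  dims <- feature_dims()
  set.seed(cfg$seed)
  skel <- init_params(cfg, dims$atom, dims$bond + 3L, dims$global)
  sk <- param_skeleton(skel)
  if (sk$total != length(raw$param_values))
    schema_error("checkpoint parameter count does not match configuration")
  params <- unflatten_params(as.numeric(raw$param_values), sk)
  structure(list(params = params, config = cfg, schema = raw$schema,
                 label_mean = raw$label_mean, label_sd = raw$label_sd,
                 best_epoch = raw$best_epoch,
                 history = as.data.frame(raw$history)),
            class = "hydro_model")
}
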