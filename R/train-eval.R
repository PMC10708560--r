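#' Training protocol configuration
#'
#' The reference protocol trains every model for 60 epochs with batch size
#' 64 under Adam; regression minimizes root-mean-squared error at learning
#' rate 0.001, classification minimizes categorical cross-entropy at
#' 0.0001. There is no early stopping or schedule: the final-epoch weights
#' are returned. `NULL` entries are resolved per task at [train()] time.
#'
#' @param epochs Training epochs (default 60).
#' @param batch_size Mini-batch size (default 64).
#' @param lr Adam learning rate; default 0.001 (regression) or 0.0001
#'   (classification).
#' @param loss `"rmse"` or `"categorical_cross_entropy"`; default chosen by
#'   task.
#' @param seed Training seed (shuffling, dropout).
#' @param n_test_repeats Repeats used by [repeated_evaluation()].
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 60L, batch_size = 64L, lr = NULL,
                         loss = NULL, seed = 1L, n_test_repeats = 10L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (!is.null(lr) && lr <= 0) stop("lr must be positive")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr, loss = loss,
                 seed = as.integer(seed),
                 n_test_repeats = as.integer(n_test_repeats)),
            class = "train_config")
}

resolve_cfg <- function(cfg, task) {
  cfg$lr <- cfg$lr %||% if (task == "regression") 1e-3 else 1e-4
  cfg$loss <- cfg$loss %||%
    if (task == "regression") "rmse" else "categorical_cross_entropy"
  cfg
}

# loss functions return the scalar loss and the gradient w.r.t. the
# network output (logits for cross-entropy; see nn-layers.R)
loss_eval <- function(loss, pred, y) {
  if (loss == "rmse") {
    r <- pred - y
    list(value = sqrt(mean(r^2)), grad = 2 * r / length(r))
  } else {
    list(value = -mean(rowSums(y * log(pmax(pred, 1e-12)))),
         grad = (pred - y) / nrow(y))
  }
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / bc1) / (sqrt(state$v[[k]] / bc2) + eps)
  }
  list(state = state, params = params)
}

#' Convert dataset records to network inputs and targets
#'
#' Builds the `(time, channels, batch)` input array: in `"iq"` mode the
#' in-phase and quadrature components form two channels, centered by the
#' record's complex mean and scaled by one common factor (preserving the
#' phasor geometry); in `"phase"` mode the single channel is the unwrapped, detrended,
#' z-scored baseband phase. Regression targets are `(fc, fr)` in Hz;
#' classification targets are one-hot over drowsiness/normal/stress.
#'
#' @param ds A `signal_dataset`.
#' @param indices Record indices (default all).
#' @param input_mode `"iq"` or `"phase"`.
#' @param task Target type; defaults to the dataset task
#'   (`"generalization"` datasets yield regression targets).
#' @return List with `x` (array) and `y` (matrix).
#' @export
dataset_to_input <- function(ds, indices = seq_len(n_records(ds)),
                             input_mode = "iq", task = NULL) {
  task <- task %||% if (ds$task == "classification") "classification"
                    else "regression"
  z_rows <- function(m) {
    mu <- rowMeans(m)
    s <- sqrt(rowMeans((m - mu)^2))
    s[s < 1e-12] <- 1
    (m - mu) / s
  }
  iq <- ds$iq[indices, , drop = FALSE]
  t_len <- ncol(iq)
  if (input_mode == "iq") {
    # joint normalization: one complex mean and one common scale per
    # record, so the circular phasor geometry (where the rate information
    # lives) is preserved; independent per-channel z-scores would shear
    # the I/Q circle
    ctr <- iq - rowMeans(iq)
    s <- sqrt(rowMeans(Mod(ctr)^2) / 2)
    s[s < 1e-12] <- 1
    ctr <- ctr / s
    x <- array(0, c(t_len, 2L, length(indices)))
    x[, 1L, ] <- t(Re(ctr))
    x[, 2L, ] <- t(Im(ctr))
  } else {
    ph <- t(apply(iq, 1, phase_demodulate))
    x <- array(t(z_rows(ph)), c(t_len, 1L, length(indices)))
  }
  y <- if (task == "classification") {
    one_hot(ds$labels$state[indices], ds$class_levels)
  } else {
    cbind(fc = ds$labels$fc_hz[indices], fr = ds$labels$fr_hz[indices])
  }
  list(x = x, y = y)
}

split_indices <- function(ds, split) {
  if (is.null(ds$split)) stop("dataset has no split assignments; call split_dataset()")
  which(ds$split == split)
}

#' Train a model on a split dataset
#'
#' Mini-batch Adam for `cfg$epochs` epochs with per-epoch training and
#' validation loss recorded; the final-epoch weights are kept (no early
#' stopping). The run is a pure function of (model, dataset, cfg):
#' shuffling and dropout draw from `cfg$seed`.
#'
#' @param model A `vr_model` whose task matches the dataset.
#' @param dataset A `signal_dataset` with split assignments.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return An object of class `vr_fit`: `model` (trained), `history`
#'   (data frame epoch/train_loss/val_loss), `cfg`.
#' @export
train <- function(model, dataset, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(model, "vr_model"), inherits(dataset, "signal_dataset"))
  task <- model$spec$task
  ds_task <- if (dataset$task == "classification") "classification"
             else "regression"
  if (task != ds_task)
    stop(sprintf("model task '%s' does not match dataset task '%s'",
                 task, dataset$task))
  if (ncol(dataset$iq) != model$spec$n_samples)
    stop("record length does not match the model's input length")
  cfg <- resolve_cfg(cfg, task)
  tr <- dataset_to_input(dataset, split_indices(dataset, "train"),
                         model$spec$input_mode, task)
  va <- dataset_to_input(dataset, split_indices(dataset, "val"),
                         model$spec$input_mode, task)
  target_scale <- NULL
  if (task == "regression") {
    # standardize the two rate targets so the narrow respiration range is
    # not swamped by the heart-rate range in the joint loss
    target_scale <- list(mu = colMeans(tr$y),
                         sd = pmax(apply(tr$y, 2, stats::sd), 1e-12))
    tr$y <- scale_targets(tr$y, target_scale)
    va$y <- scale_targets(va$y, target_scale)
  }
  n_tr <- dim(tr$x)[3]
  net <- model$net
  params <- flatten_params(net)
  opt <- adam_init(params)
  history <- data.frame(epoch = seq_len(cfg$epochs), train_loss = NA_real_,
                        val_loss = NA_real_)
  set.seed(cfg$seed)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1, n_tr, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, n_tr)]
      fw <- net_forward(net, tr$x[, , idx, drop = FALSE], training = TRUE)
      net <- fw$node
      l <- loss_eval(cfg$loss, fw$y, tr$y[idx, , drop = FALSE])
      bw <- net_backward(net, fw$cache, l$grad)
      grads <- flatten_grads(net, bw$grads)
      upd <- adam_step(opt, params, grads, cfg$lr)
      opt <- upd$state
      params <- upd$params
      net <- assign_params(net, params)
      ep_loss <- ep_loss + l$value
      n_batches <- n_batches + 1L
    }
    model$net <- net
    val_pred <- predict.vr_model(model, va$x, cfg$batch_size)
    history$train_loss[ep] <- ep_loss / n_batches
    history$val_loss[ep] <- loss_eval(cfg$loss, val_pred, va$y)$value
    if (verbose)
      message(sprintf("epoch %3d  train %.5f  val %.5f", ep,
                      history$train_loss[ep], history$val_loss[ep]))
  }
  structure(list(model = model, history = history, cfg = cfg,
                 target_scale = target_scale),
            class = "vr_fit")
}

scale_targets <- function(y, sc) sweep(sweep(y, 2, sc$mu, "-"), 2, sc$sd, "/")
unscale_targets <- function(y, sc) sweep(sweep(y, 2, sc$sd, "*"), 2, sc$mu, "+")

#' @export
print.vr_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("<vr_fit> %s/%s after %d epochs: train %.4g, val %.4g\n",
              x$model$spec$family, x$model$spec$task, nrow(x$history),
              last$train_loss, last$val_loss))
  invisible(x)
}

#' Evaluate a fit on one split of a dataset
#'
#' @param fit A `vr_fit` (or bare `vr_model`).
#' @param dataset A `signal_dataset` with splits (or without, when
#'   `split = NULL` evaluates all records).
#' @param split `"train"`, `"val"`, `"test"`, or `NULL` for all records.
#' @return For regression: list with `pred`, `truth`, and
#'   [regression_metrics()] per target. For classification: list with
#'   `prob`, predicted/true classes, and [classification_metrics()].
#' @export
evaluate <- function(fit, dataset, split = "test") {
  model <- if (inherits(fit, "vr_fit")) fit$model else fit
  idx <- if (is.null(split)) seq_len(n_records(dataset))
         else split_indices(dataset, split)
  task <- model$spec$task
  inp <- dataset_to_input(dataset, idx, model$spec$input_mode, task)
  pred <- predict.vr_model(model, inp$x)
  if (task == "regression" && inherits(fit, "vr_fit") &&
      !is.null(fit$target_scale))
    pred <- unscale_targets(pred, fit$target_scale)
  if (task == "regression") {
    list(pred = pred, truth = inp$y,
         metrics = list(fc = regression_metrics(inp$y[, 1], pred[, 1]),
                        fr = regression_metrics(inp$y[, 2], pred[, 2])),
         indices = idx)
  } else {
    true_cls <- max.col(inp$y, ties.method = "first")
    pred_cls <- max.col(pred, ties.method = "first")
    list(prob = pred, pred_class = pred_cls, true_class = true_cls,
         metrics = classification_metrics(true_cls, pred_cls, n_classes = 3),
         indices = idx)
  }
}

#' Repeated training/evaluation protocol
#'
#' Trains and evaluates `n_repeats` times with distinct training seeds on a
#' fixed split, and reports each metric's mean and standard deviation over
#' the repeats (the "ten test compilations" layout: RMSE/MAE/R2 per target
#' for regression, accuracy/precision/recall/F1 for classification).
#'
#' @param spec A [model_spec()].
#' @param dataset A split `signal_dataset`.
#' @param cfg A [train_config()]; `cfg$n_test_repeats` is used unless
#'   `n_repeats` is given.
#' @param n_repeats Number of repeats.
#' @param split Evaluation split (default `"test"`).
#' @return List with `per_repeat` (data frame, one row per repeat),
#'   `summary` (mean and sd per metric), and `fits` (the last fit).
#' @export
repeated_evaluation <- function(spec, dataset, cfg = train_config(),
                                n_repeats = NULL, split = "test") {
  cfg <- resolve_cfg(cfg, spec$task)
  n_repeats <- n_repeats %||% cfg$n_test_repeats
  if (n_repeats < 1) stop("n_repeats must be >= 1")
  rows <- vector("list", n_repeats)
  fit <- NULL
  for (r in seq_len(n_repeats)) {
    rcfg <- cfg
    rcfg$seed <- make_seed(cfg$seed, paste0("repeat", r))
    rspec <- spec
    rspec$seed <- make_seed(cfg$seed, paste0("init", r))
    fit <- train(build_model(rspec), dataset, rcfg)
    ev <- evaluate(fit, dataset, split)
    rows[[r]] <- if (spec$task == "regression") {
      data.frame(repeat_id = r,
                 rmse_fc = ev$metrics$fc$rmse, rmse_fr = ev$metrics$fr$rmse,
                 mae_fc = ev$metrics$fc$mae, mae_fr = ev$metrics$fr$mae,
                 r2_fc = ev$metrics$fc$r2, r2_fr = ev$metrics$fr$r2)
    } else {
      m <- ev$metrics
      data.frame(repeat_id = r, accuracy = m$accuracy,
                 precision = m$precision_macro, recall = m$recall_macro,
                 f1 = m$f1_macro)
    }
  }
  per_repeat <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_repeat), "repeat_id")
  summary <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(k) mean(per_repeat[[k]]), 0),
    sd = vapply(metric_cols, function(k)
      if (n_repeats == 1) 0 else stats::sd(per_repeat[[k]]), 0))
  list(per_repeat = per_repeat, summary = summary, fit = fit)
}

#' Per-state generalization report (adapted R2*)
#'
#' Groups a generalization dataset by physiological state and scores a
#' trained regression model with the adapted [r2_star()] statistic per
#' state and per target, in percent — the layout used to probe how models
#' trained on normal-range subjects extrapolate to drowsiness and stress.
#'
#' @param fit A trained regression `vr_fit` (or `vr_model`).
#' @param generalization_set A `signal_dataset` carrying both continuous
#'   and state labels.
#' @return Data frame with columns `state`, `r2star_fc_pct`,
#'   `r2star_fr_pct`.
#' @export
state_r2star_report <- function(fit, generalization_set) {
  ds <- generalization_set
  if (all(is.na(ds$labels$state))) stop("dataset carries no state labels")
  ev <- evaluate(fit, ds, split = NULL)
  states <- state_levels()
  out <- lapply(states, function(st) {
    sel <- which(ds$labels$state[ev$indices] == st)
    if (length(sel) == 0)
      return(data.frame(state = st, r2star_fc_pct = NA_real_,
                        r2star_fr_pct = NA_real_))
    data.frame(state = st,
               r2star_fc_pct = 100 * r2_star(ev$truth[sel, 1], ev$pred[sel, 1]),
               r2star_fr_pct = 100 * r2_star(ev$truth[sel, 2], ev$pred[sel, 2]))
  })
  do.call(rbind, out)
}
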