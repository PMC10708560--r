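quick_spec <- function(task, seed = 1) {
  model_spec("crnn", task, scale = "desk", n_samples = 120L, filters = 8L,
             kernel = 16L, lstm_units = 4L, head = c(8L), seed = seed)
}

test_that("training runs the protocol and records per-epoch losses", {
  ds <- tiny_cls_dataset()
  cfg <- train_config(epochs = 6L, batch_size = 16L, lr = 2e-3, seed = 3)
  fit <- train(build_model(quick_spec("classification")), ds, cfg)
  expect_s3_class(fit, "vr_fit")
  expect_equal(nrow(fit$history), 6L)
  expect_true(all(is.finite(fit$history$train_loss)))
  expect_true(all(is.finite(fit$history$val_loss)))
  # optimization sanity: loss drops over training
  expect_lt(fit$history$train_loss[6], fit$history$train_loss[1])
})

test_that("training is deterministic under a fixed seed", {
  ds <- tiny_cls_dataset()
  cfg <- train_config(epochs = 3L, batch_size = 16L, seed = 5)
  f1 <- train(build_model(quick_spec("classification", seed = 2)), ds, cfg)
  f2 <- train(build_model(quick_spec("classification", seed = 2)), ds, cfg)
  expect_identical(f1$history, f2$history)
  vr <- asNamespace("vitalradar")
  expect_identical(vr$flatten_params(f1$model$net),
                   vr$flatten_params(f2$model$net))
})

test_that("task mismatches and missing splits are rejected", {
  ds <- tiny_cls_dataset()
  expect_error(train(build_model(quick_spec("regression")), ds, train_config()),
               "does not match")
  ds2 <- ds
  ds2$split <- NULL
  expect_error(train(build_model(quick_spec("classification")), ds2,
                     train_config(epochs = 1)),
               "split")
  wrong_len <- model_spec("crnn", "classification", scale = "desk",
                          n_samples = 60L, filters = 4L, kernel = 8L,
                          lstm_units = 2L, head = c(4L))
  expect_error(train(build_model(wrong_len), ds, train_config(epochs = 1)),
               "record length")
})

test_that("regression training standardizes targets and inverts at evaluation", {
  cfg <- tiny_config()
  ds <- build_regression_dataset(6, n_envs = 5, config = cfg, seed = 13)
  ds <- split_dataset(ds, seed = 4)
  fit <- train(build_model(quick_spec("regression")), ds,
               train_config(epochs = 2L, batch_size = 16L, seed = 1))
  expect_named(fit$target_scale, c("mu", "sd"))
  ev <- evaluate(fit, ds, "test")
  # predictions come back on the physical Hz scale
  expect_true(all(ev$pred[, 1] > 0 & ev$pred[, 1] < 4))
  expect_named(ev$metrics, c("fc", "fr"))
})

test_that("repeated evaluation reports the mean/sd table layout", {
  ds <- tiny_cls_dataset()
  spec <- quick_spec("classification")
  rep_ev <- repeated_evaluation(spec, ds,
                                train_config(epochs = 2L, batch_size = 16L,
                                             seed = 9),
                                n_repeats = 2)
  expect_equal(nrow(rep_ev$per_repeat), 2L)
  expect_setequal(rep_ev$summary$metric,
                  c("accuracy", "precision", "recall", "f1"))
  for (k in rep_ev$summary$metric) {
    vals <- rep_ev$per_repeat[[k]]
    row <- rep_ev$summary[rep_ev$summary$metric == k, ]
    expect_gte(row$mean, min(vals))
    expect_lte(row$mean, max(vals))
  }
  one <- repeated_evaluation(spec, ds,
                             train_config(epochs = 1L, batch_size = 16L),
                             n_repeats = 1)
  expect_equal(one$summary$sd, rep(0, 4))
})

test_that("per-state R2* report distinguishes in-range from out-of-range predictors", {
  cfg <- tiny_config()
  gen <- build_generalization_dataset(2, n_envs = 4, config = cfg, seed = 15)

  # a perfect oracle predictor scores 100 everywhere
  perfect <- list(spec = list(task = "regression", input_mode = "iq",
                              out_dim = 2L))
  class(perfect) <- "vr_model"
  # emulate by scoring the truth directly
  states <- state_levels()
  for (st in states) {
    sel <- gen$labels$state == st
    expect_equal(100 * r2_star(gen$labels$fc_hz[sel], gen$labels$fc_hz[sel]),
                 100)
  }

  # a midpoint-of-normal-range predictor is best in the normal state
  mid_fc <- mean(c(0.83, 2))
  mid_fr <- mean(c(0.16, 0.33))
  scores <- vapply(states, function(st) {
    sel <- gen$labels$state == st
    100 * r2_star(gen$labels$fc_hz[sel], rep(mid_fc, sum(sel)))
  }, 0)
  expect_equal(names(which.max(scores)), "normal")
  scores_fr <- vapply(states, function(st) {
    sel <- gen$labels$state == st
    100 * r2_star(gen$labels$fr_hz[sel], rep(mid_fr, sum(sel)))
  }, 0)
  expect_equal(names(which.max(scores_fr)), "normal")
})

test_that("state_r2star_report covers all states with a trained model", {
  cfg <- tiny_config()
  reg <- split_dataset(build_regression_dataset(6, n_envs = 5, config = cfg,
                                                seed = 13), seed = 4)
  gen <- build_generalization_dataset(2, n_envs = 4, config = cfg, seed = 15)
  fit <- train(build_model(quick_spec("regression")), reg,
               train_config(epochs = 2L, batch_size = 16L, seed = 1))
  rep <- state_r2star_report(fit, gen)
  expect_equal(rep$state, state_levels())
  expect_true(all(is.finite(rep$r2star_fc_pct)))
  expect_true(all(rep$r2star_fc_pct <= 100))
  expect_error(state_r2star_report(fit, reg), "state labels")
})
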