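families <- c("cnn1d", "tcn", "bilstm", "crnn")

small_spec <- function(family, task, seed = 1) {
  model_spec(family, task, scale = "desk", n_samples = 200L, filters = 8L,
             kernel = 16L, lstm_units = 4L, tcn_filters = 6L,
             tcn_dilations = c(1L, 2L, 4L), head = c(8L), seed = seed)
}

test_that("all families satisfy the forward shape contract for both tasks", {
  set.seed(1)
  x <- array(stats::rnorm(200 * 2 * 4), c(200, 2, 4))
  for (fam in families) {
    for (task in c("regression", "classification")) {
      m <- build_model(small_spec(fam, task))
      out <- predict(m, x)
      expect_equal(dim(out), c(4L, if (task == "regression") 2L else 3L),
                   label = paste(fam, task))
      expect_true(all(is.finite(out)))
      if (task == "classification") {
        expect_equal(rowSums(out), rep(1, 4), tolerance = 1e-6)
        expect_true(all(out >= 0))
      }
    }
  }
})

test_that("TCN activations are strictly causal", {
  # impulse probe in inference mode: perturbing sample t must not change
  # any pre-pooling activation before t
  spec <- small_spec("tcn", "regression")
  m <- build_model(spec)
  conv_stack <- m$net
  conv_stack$layers <- conv_stack$layers[
    vapply(conv_stack$layers, function(l) l$type == "residual", TRUE)]
  vr <- asNamespace("vitalradar")
  set.seed(2)
  x <- array(stats::rnorm(200 * 2), c(200, 2, 1))
  base <- vr$net_forward(conv_stack, x, FALSE)$y
  for (t_hit in c(1, 50, 150)) {
    xp <- x
    xp[t_hit, , 1] <- xp[t_hit, , 1] + 5
    pert <- vr$net_forward(conv_stack, xp, FALSE)$y
    changed <- which(apply(abs(pert - base)[, , 1, drop = FALSE], 1, max)
                     > 1e-9)
    expect_gte(min(changed), t_hit)
  }
})

test_that("TCN receptive field matches the dilated-convolution formula", {
  # two kernel-3 convs per block over dilations 1..32:
  # 1 + 2*(3-1)*(1+2+4+8+16+32) = 253
  expect_equal(1 + 2 * (3 - 1) * sum(c(1, 2, 4, 8, 16, 32)), 253)
  # impulse-response probe: an input spike at t reaches exactly the next
  # 253 positions of the final block's output
  spec <- model_spec("tcn", "regression", scale = "desk", n_samples = 400L,
                     tcn_filters = 4L, head = c(4L), seed = 3)
  m <- build_model(spec)
  stack <- m$net
  stack$layers <- stack$layers[
    vapply(stack$layers, function(l) l$type == "residual", TRUE)]
  vr <- asNamespace("vitalradar")
  x0 <- array(0, c(400, 2, 1))
  xi <- x0
  xi[100, , 1] <- 1
  base <- vr$net_forward(stack, x0, FALSE)$y
  pert <- vr$net_forward(stack, xi, FALSE)$y
  changed <- which(apply(abs(pert - base)[, , 1, drop = FALSE], 1, max)
                   > 1e-12)
  expect_equal(min(changed), 100)
  expect_lte(max(changed), 100 + 253 - 1)
})

test_that("Bi-LSTM output is sensitive to time reversal", {
  m <- build_model(small_spec("bilstm", "regression"))
  set.seed(4)
  x <- array(stats::rnorm(200 * 2), c(200, 2, 1))
  xr <- x[200:1, , , drop = FALSE]
  expect_gt(max(abs(predict(m, x) - predict(m, xr))), 1e-8)
})

test_that("seeded builds are reproducible", {
  for (fam in families) {
    m1 <- build_model(small_spec(fam, "classification", seed = 42))
    m2 <- build_model(small_spec(fam, "classification", seed = 42))
    vr <- asNamespace("vitalradar")
    expect_identical(vr$flatten_params(m1$net), vr$flatten_params(m2$net))
    m3 <- build_model(small_spec(fam, "classification", seed = 43))
    expect_false(identical(vr$flatten_params(m1$net),
                           vr$flatten_params(m3$net)))
  }
})

test_that("parameter budgets partition and order as expected", {
  # a single dense layer 10 -> 3 with bias
  vr <- asNamespace("vitalradar")
  set.seed(1)
  d <- vr$nn_dense(10, 3)
  expect_equal(sum(lengths(d$params)), 33L)

  counts <- vapply(families, function(fam) {
    count_parameters(build_model(model_spec(fam, "classification",
                                            scale = "full")))$total
  }, 0)
  # reference-scale ordering: CNN > TCN > Bi-LSTM > CRNN
  expect_true(counts["cnn1d"] > counts["tcn"])
  expect_true(counts["tcn"] > counts["bilstm"])
  expect_true(counts["bilstm"] > counts["crnn"])

  for (fam in families) {
    p <- count_parameters(build_model(model_spec(fam, "classification",
                                                 scale = "full")))
    expect_equal(p$total, p$trainable + p$non_trainable)
  }
})

test_that("classification and regression budgets differ by head_width + 1 per extra output", {
  for (fam in families) {
    spec_r <- model_spec(fam, "regression", scale = "full")
    spec_c <- model_spec(fam, "classification", scale = "full")
    diff <- count_parameters(build_model(spec_c))$trainable -
      count_parameters(build_model(spec_r))$trainable
    last_width <- utils::tail(spec_r$head, 1)
    expect_equal(diff, (last_width + 1) * (3 - 2), label = fam)
  }
})

test_that("every family can overfit a 12-record toy classification set", {
  # capacity/plumbing check: 2 subjects per state x 2 SNR levels
  ds <- build_classification_dataset(2, 2, 2, n_envs = 2,
                                     config = tiny_config(), seed = 5)
  ds$split <- factor(rep("train", n_records(ds)),
                     levels = c("train", "val", "test"))
  ds$split[c(1, 12)] <- "val"   # train() needs a non-empty validation set
  for (fam in families) {
    spec <- model_spec(fam, "classification", scale = "desk",
                       n_samples = 120L, filters = 12L, kernel = 16L,
                       lstm_units = 8L, tcn_filters = 8L,
                       tcn_dilations = c(1L, 2L, 4L), head = c(16L),
                       dropout = 0, seed = 7)
    fit <- train(build_model(spec), ds,
                 train_config(epochs = 200L, batch_size = 10L, lr = 3e-3,
                              seed = 7))
    ev <- evaluate(fit, ds, "train")
    expect_gte(ev$metrics$accuracy, 0.99)
  }
})
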