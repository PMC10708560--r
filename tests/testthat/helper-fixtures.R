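# Shared fixtures, built once per test run. The desk-scale datasets follow
# the reduced study conditions: records synthesized at the reference rate
# (100 Hz, 5001 samples) and decimated to 10 Hz with the package's
# anti-aliased resampler, which preserves the band-limited SNR structure.

.fixtures <- new.env(parent = emptyenv())

get_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

desk_cls_dataset <- function() get_fixture("cls_desk", function() {
  ds <- build_classification_dataset(8, 7, 7, n_envs = 50, seed = 11)
  ds <- decimate_dataset(ds, 10)
  split_dataset(ds, seed = 4)
})

desk_reg_dataset <- function() get_fixture("reg_desk", function() {
  # 15 subjects kept at the reference 100-environment SNR sweep: nuisance
  # diversity per subject is what regression generalization feeds on
  ds <- build_regression_dataset(15, n_envs = 100, seed = 21)
  ds <- decimate_dataset(ds, 10)
  split_dataset(ds, seed = 4)
})

desk_gen_dataset <- function() get_fixture("gen_desk", function() {
  ds <- build_generalization_dataset(5, n_envs = 30, seed = 31)
  decimate_dataset(ds, 10)
})

# small quick dataset for smoke tests (short records, few subjects)
tiny_config <- function() radar_config(fs_hz = 10, n_samples = 120)

tiny_cls_dataset <- function(seed = 5) {
  ds <- build_classification_dataset(3, 3, 3, n_envs = 6,
                                     config = tiny_config(), seed = seed)
  split_dataset(ds, seed = 4)
}

# finite-difference gradient checker against the backward pass (MSE loss)
check_gradients <- function(net, x, y, training = TRUE, seed = 42,
                            eps = 1e-5) {
  force(net)
  ns <- asNamespace("vitalradar")
  net_forward <- ns$net_forward
  net_backward <- ns$net_backward
  flatten_params <- ns$flatten_params
  flatten_grads <- ns$flatten_grads
  assign_params <- ns$assign_params
  lossfn <- function(n, xx) {
    set.seed(seed)
    fw <- net_forward(n, xx, training)
    mean((fw$y - y)^2)
  }
  set.seed(seed)
  fw <- net_forward(net, x, training)
  bw <- net_backward(fw$node, fw$cache, 2 * (fw$y - y) / length(fw$y))
  ga <- flatten_grads(fw$node, bw$grads)
  params <- flatten_params(net)
  worst <- 0
  scale <- max(abs(unlist(lapply(ga, as.numeric)))) + 1e-8
  for (k in names(params)) {
    gn <- params[[k]]
    for (i in seq_along(gn)) {
      pp <- params
      pp[[k]][i] <- pp[[k]][i] + eps
      lp <- lossfn(assign_params(net, pp), x)
      pp[[k]][i] <- pp[[k]][i] - 2 * eps
      lm <- lossfn(assign_params(net, pp), x)
      gn[i] <- (lp - lm) / (2 * eps)
    }
    worst <- max(worst, max(abs(gn - as.numeric(ga[[k]]))) / scale)
  }
  gx <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    gx[i] <- (lossfn(net, xp) - lossfn(net, xm)) / (2 * eps)
  }
  max(worst, max(abs(gx - bw$dx)) / scale)
}
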