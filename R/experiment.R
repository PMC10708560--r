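#' Write a dataset to disk
#'
#' Layout: `labels.csv` (one row per record: subject, rates, state, SNR,
#' seed, split), `config.json` (radar config, task, builder seed), and the
#' I/Q samples as `iq.parquet` (long format: record, i, q) when the arrow
#' package is available, else `iq.csv`.
#'
#' @param ds A `signal_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_signal_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "signal_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lab <- ds$labels
  lab$split <- if (is.null(ds$split)) NA_character_ else as.character(ds$split)
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  meta <- list(task = ds$task, seed = ds$seed, class_levels = ds$class_levels,
               config = unclass(ds$config), n_records = nrow(ds$iq),
               n_samples = ncol(ds$iq))
  jsonlite::write_json(meta, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  long <- data.frame(record = rep(seq_len(nrow(ds$iq)), each = ncol(ds$iq)),
                     i = as.vector(t(Re(ds$iq))),
                     q = as.vector(t(Im(ds$iq))))
  if (requireNamespace("arrow", quietly = TRUE)) {
    arrow::write_parquet(long, file.path(dir, "iq.parquet"))
  } else {
    utils::write.csv(long, file.path(dir, "iq.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a dataset written by [write_signal_dataset()]
#' @param dir Dataset directory.
#' @return A `signal_dataset`.
#' @export
read_signal_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  pq <- file.path(dir, "iq.parquet")
  long <- if (file.exists(pq)) as.data.frame(arrow::read_parquet(pq))
          else utils::read.csv(file.path(dir, "iq.csv"))
  iq <- matrix(complex(real = long$i, imaginary = long$q),
               nrow = meta$n_records, ncol = meta$n_samples, byrow = TRUE)
  cfg <- meta$config
  config <- radar_config(cfg$carrier_hz, cfg$d0_m, cfg$fs_hz, cfg$n_samples,
                         cfg$modulation_mode)
  split <- if (all(is.na(lab$split))) NULL
           else factor(lab$split, levels = c("train", "val", "test"))
  lab$split <- NULL
  structure(list(iq = iq, labels = lab, task = meta$task, config = config,
                 split = split, seed = meta$seed,
                 class_levels = meta$class_levels),
            class = "signal_dataset")
}

#' Save / load a trained model
#'
#' Checkpoints use the package's native serialized form (`.rds`) with a
#' JSON sidecar carrying the spec and parameter budget for inspection.
#'
#' @param fit A `vr_fit` or `vr_model`.
#' @param path Path to the `.rds` checkpoint.
#' @return `path`, invisibly.
#' @export
save_model <- function(fit, path) {
  model <- if (inherits(fit, "vr_fit")) fit$model else fit
  saveRDS(fit, path)
  sidecar <- list(spec = unclass(model$spec),
                  parameter_budget = count_parameters(model))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)

#' Experiment configuration
#'
#' Bundles everything one reproducible run needs: which dataset to build,
#' which model family/task to train, the training protocol, and a single
#' global seed that fans out deterministically to the build / split /
#' train stages via [make_seed()].
#'
#' @param task `"regression"` or `"classification"`.
#' @param family Model family.
#' @param out_dir Run directory.
#' @param seed Global seed.
#' @param n_subjects Subjects for regression (single count) or
#'   classification (length-3 normal/drowsy/stress).
#' @param n_envs SNR levels per subject.
#' @param scale Model size preset; `"desk"` also decimates records to
#'   `desk_fs_hz`.
#' @param desk_fs_hz Working sampling rate at desk scale (Hz).
#' @param epochs,batch_size,lr Training protocol (NULL = task defaults).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(task = "classification", family = "crnn",
                              out_dir = "vitalradar-run", seed = 1L,
                              n_subjects = NULL, n_envs = NULL,
                              scale = "desk", desk_fs_hz = 10,
                              epochs = NULL, batch_size = 64L, lr = NULL) {
  if (!is.numeric(seed) || seed < 0) stop("seed must be a non-negative integer")
  n_subjects <- n_subjects %||%
    if (task == "classification") c(8L, 7L, 7L) else 20L
  n_envs <- n_envs %||% if (scale == "desk") 50L else 100L
  epochs <- epochs %||% if (scale == "desk") 40L else 60L
  structure(list(task = task, family = family, out_dir = out_dir,
                 seed = as.integer(seed), n_subjects = n_subjects,
                 n_envs = n_envs, scale = scale, desk_fs_hz = desk_fs_hz,
                 epochs = epochs, batch_size = batch_size, lr = lr),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' The file holds the fields of [experiment_config()] (unknown fields are
#' rejected), e.g.:
#' ```yaml
#' task: classification
#' family: crnn
#' seed: 7
#' n_subjects: [8, 7, 7]
#' n_envs: 50
#' epochs: 40
#' ```
#' @param path YAML file path.
#' @return An [experiment_config()].
#' @export
experiment_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  do.call(experiment_config, vals)
}

build_for_experiment <- function(cfg) {
  seed <- make_seed(cfg$seed, "build")
  ds <- if (cfg$task == "classification") {
    build_classification_dataset(cfg$n_subjects[1], cfg$n_subjects[2],
                                 cfg$n_subjects[3], n_envs = cfg$n_envs,
                                 seed = seed)
  } else {
    build_regression_dataset(cfg$n_subjects[1], n_envs = cfg$n_envs,
                             seed = seed)
  }
  if (cfg$scale == "desk") ds <- decimate_dataset(ds, cfg$desk_fs_hz)
  split_dataset(ds, seed = 4)
}

#' Run one end-to-end experiment
#'
#' Build data, split, train, evaluate, and write a self-describing run
#' directory: the dataset, the checkpoint, `history.csv`, `metrics.json`,
#' per-record test predictions, and `manifest.json` with the configuration,
#' derived stage seeds and content hashes so a rerun can be verified
#' bit-for-bit on its deterministic stages.
#'
#' @param cfg An [experiment_config()].
#' @param write_dataset Also serialize the full dataset (can be large).
#' @return List with the fit, evaluation, dataset and manifest (invisibly).
#' @export
run_experiment <- function(cfg, write_dataset = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(cfg$out_dir, 2) != 0) stop("output directory not writable")
  t0 <- Sys.time()
  ds <- build_for_experiment(cfg)
  msg_stage <- function(what, t) sprintf("%s: %.1fs", what,
    as.numeric(difftime(Sys.time(), t, units = "secs")))
  log_lines <- c(msg_stage(sprintf("build (%d records)", n_records(ds)), t0))
  spec <- model_spec(cfg$family, cfg$task, scale = cfg$scale,
                     n_samples = ncol(ds$iq),
                     seed = make_seed(cfg$seed, "init"))
  t1 <- Sys.time()
  fit <- train(build_model(spec), ds,
               train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                            lr = cfg$lr, seed = make_seed(cfg$seed, "train")))
  log_lines <- c(log_lines, msg_stage("train", t1))
  ev <- evaluate(fit, ds, "test")
  utils::write.csv(fit$history, file.path(cfg$out_dir, "history.csv"),
                   row.names = FALSE)
  save_model(fit, file.path(cfg$out_dir, "model.rds"))
  metrics <- if (cfg$task == "regression") {
    list(fc = ev$metrics$fc[c("rmse", "mae", "r2")],
         fr = ev$metrics$fr[c("rmse", "mae", "r2")])
  } else {
    m <- ev$metrics
    list(accuracy = m$accuracy, precision_macro = m$precision_macro,
         recall_macro = m$recall_macro, f1_macro = m$f1_macro,
         confusion = m$confusion)
  }
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  if (cfg$task == "classification") {
    utils::write.csv(as.data.frame(ev$metrics$confusion),
                     file.path(cfg$out_dir, "confusion.csv"),
                     row.names = FALSE)
  }
  if (write_dataset) write_signal_dataset(ds, file.path(cfg$out_dir, "data"))
  manifest <- list(
    config = unclass(cfg),
    stage_seeds = list(build = make_seed(cfg$seed, "build"),
                       split = 4,
                       init = make_seed(cfg$seed, "init"),
                       train = make_seed(cfg$seed, "train")),
    hashes = list(labels = content_hash(c(ds$labels$fc_hz, ds$labels$fr_hz,
                                          ds$labels$snr_db)),
                  iq = content_hash(c(Re(ds$iq[1, ]), Im(ds$iq[1, ])))),
    package_version = as.character(utils::packageVersion("vitalradar")),
    r_version = R.version.string,
    log = log_lines)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(fit = fit, evaluation = ev, dataset = ds,
                 manifest = manifest))
}

#' Reproduce the benchmark tables on simulated data
#'
#' Runs all four families through the evaluation protocol and writes three
#' tables: regression metrics with repeat mean/sd ("table4"),
#' classification metrics ("table5"), and the per-state generalization R2*
#' report ("table6"). `scale = "desk"` uses the reduced study conditions
#' (fewer subjects and SNR levels, 10 Hz records, smaller networks, fewer
#' epochs and repeats); `scale = "full"` uses the reference conditions
#' (3000/5300/1500 records, 60 epochs, 10 repeats) and takes many CPU
#' hours.
#'
#' @param scale `"desk"` or `"full"`.
#' @param out_dir Directory for the three CSV files.
#' @param seed Global seed.
#' @param families Model families to include.
#' @param overrides Named list overriding individual study-condition values
#'   (`reg_subjects`, `cls_subjects`, `gen_per_state`, `n_envs`,
#'   `gen_envs`, `epochs`, `repeats`), e.g. for smoke runs.
#' @return List of the three tables (also written as CSV), invisibly.
#' @export
reproduce_paper_tables <- function(scale = c("desk", "full"),
                                   out_dir = "vitalradar-tables", seed = 1L,
                                   families = c("cnn1d", "tcn", "bilstm",
                                                "crnn"),
                                   overrides = list()) {
  scale <- match.arg(scale)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- if (scale == "full") {
    list(reg_subjects = 30L, cls_subjects = c(20L, 16L, 17L),
         gen_per_state = 5L, n_envs = 100L, epochs = 60L, repeats = 10L,
         gen_envs = 100L)
  } else {
    list(reg_subjects = 15L, cls_subjects = c(6L, 5L, 5L),
         gen_per_state = 4L, n_envs = 40L, epochs = 25L, repeats = 2L,
         gen_envs = 25L)
  }
  p[names(overrides)] <- overrides
  prep <- function(ds) {
    if (scale == "desk") ds <- decimate_dataset(ds, 10)
    split_dataset(ds, seed = 4)
  }
  reg <- prep(build_regression_dataset(p$reg_subjects, p$n_envs,
                                       seed = make_seed(seed, "reg")))
  cls <- prep(build_classification_dataset(p$cls_subjects[1],
                                           p$cls_subjects[2],
                                           p$cls_subjects[3], p$n_envs,
                                           seed = make_seed(seed, "cls")))
  gen <- build_generalization_dataset(p$gen_per_state, p$gen_envs,
                                      seed = make_seed(seed, "gen"))
  if (scale == "desk") gen <- decimate_dataset(gen, 10)
  mscale <- if (scale == "full") "full" else "desk"
  t4 <- list()
  t5 <- list()
  t6 <- list()
  for (fam in families) {
    rspec <- model_spec(fam, "regression", scale = mscale,
                        n_samples = ncol(reg$iq))
    rep_ev <- repeated_evaluation(
      rspec, reg,
      train_config(epochs = p$epochs, seed = make_seed(seed, fam)),
      n_repeats = p$repeats)
    s <- rep_ev$summary
    t4[[fam]] <- data.frame(family = fam, metric = s$metric, mean = s$mean,
                            sd = s$sd)
    cspec <- model_spec(fam, "classification", scale = mscale,
                        n_samples = ncol(cls$iq),
                        seed = make_seed(seed, paste0(fam, "c")))
    cfit <- train(build_model(cspec), cls,
                  train_config(epochs = p$epochs,
                               lr = if (scale == "desk") 5e-4 else NULL,
                               seed = make_seed(seed, paste0(fam, "ct"))))
    cev <- evaluate(cfit, cls, "test")
    t5[[fam]] <- data.frame(family = fam, accuracy = cev$metrics$accuracy,
                            precision = cev$metrics$precision_macro,
                            recall = cev$metrics$recall_macro,
                            f1 = cev$metrics$f1_macro)
    gtab <- state_r2star_report(rep_ev$fit, gen)
    gtab$family <- fam
    t6[[fam]] <- gtab
  }
  tables <- list(regression = do.call(rbind, t4),
                 classification = do.call(rbind, t5),
                 generalization = do.call(rbind, t6))
  for (nm in names(tables)) {
    tables[[nm]]$scale <- scale
    utils::write.csv(tables[[nm]],
                     file.path(out_dir, paste0(nm, "_table.csv")),
                     row.names = FALSE)
  }
  invisible(tables)
}
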