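#' Equally spaced SNR grid
#'
#' The noise "environments": `n_levels` equally spaced SNR values including
#' both endpoints. The reference sweep is 100 levels over \[-10, 10\] dB.
#'
#' @param n_levels Number of levels (>= 2).
#' @param lo_db,hi_db Endpoints in dB, `lo_db < hi_db`.
#' @return Numeric vector of length `n_levels`.
#' @examples
#' snr_grid(3, -10, 10)
#' @export
snr_grid <- function(n_levels = 100, lo_db = -10, hi_db = 10) {
  if (!is.numeric(n_levels) || n_levels < 2) stop("n_levels must be >= 2")
  if (lo_db >= hi_db) stop("lo_db must be below hi_db")
  seq(lo_db, hi_db, length.out = as.integer(n_levels))
}

#' Per-state sampling bands for the physiological classes
#'
#' Normal: rates inside the adult resting ranges. Drowsiness/fatigue: both
#' rates below the normal range. Stress: both above. The out-of-range band
#' edges are plausible physiological margins and are configurable.
#'
#' @param normal_fc,normal_fr,drowsy_fc,drowsy_fr,stress_fc,stress_fr
#'   Length-2 numeric ranges in Hz.
#' @return Named list of per-state `(fc, fr)` ranges.
#' @export
state_bands <- function(normal_fc = c(0.83, 2), normal_fr = c(0.16, 0.33),
                        drowsy_fc = c(0.55, 0.83), drowsy_fr = c(0.10, 0.16),
                        stress_fc = c(2, 2.5), stress_fr = c(0.33, 0.50)) {
  list(normal = list(fc = normal_fc, fr = normal_fr),
       drowsiness = list(fc = drowsy_fc, fr = drowsy_fr),
       stress = list(fc = stress_fc, fr = stress_fr))
}

#' @export
state_levels <- function() c("drowsiness", "normal", "stress")

draw_pairs <- function(n, band) {
  data.frame(fc_hz = stats::runif(n, band$fc[1], band$fc[2]),
             fr_hz = stats::runif(n, band$fr[1], band$fr[2]))
}

# Synthesize one record per (subject pair x SNR level). Amplitudes, phases
# and standoff distance are nuisance parameters drawn fresh per record from
# their physiological/geometric ranges; SNR is the labeled environmental
# variable. All randomness flows from the single `seed`.
assemble_dataset <- function(pairs, states, snrs, config, seed, task) {
  set.seed(seed)
  n_sub <- nrow(pairs)
  n_env <- length(snrs)
  n_rec <- n_sub * n_env
  iq <- matrix(complex(real = 0), nrow = n_rec, ncol = config$n_samples)
  lab <- data.frame(record = seq_len(n_rec),
                    subject = rep(seq_len(n_sub), each = n_env),
                    fc_hz = rep(pairs$fc_hz, each = n_env),
                    fr_hz = rep(pairs$fr_hz, each = n_env),
                    state = if (is.null(states)) NA_character_ else
                      rep(states, each = n_env),
                    snr_db = rep(snrs, times = n_sub))
  lab$seed <- sample.int(.Machine$integer.max - 1L, n_rec)
  # nuisance draws happen up front: synthesize_baseband() reseeds the RNG
  # per record, so interleaving would entangle the streams
  nuis <- data.frame(ac_m = stats::runif(n_rec, 2e-4, 5e-4),
                     ar_m = stats::runif(n_rec, 4e-3, 12e-3),
                     phase_c = stats::runif(n_rec, 0, 2 * pi),
                     phase_r = stats::runif(n_rec, 0, 2 * pi),
                     d0_m = stats::runif(n_rec, 0.6, 1))
  for (r in seq_len(n_rec)) {
    p <- vital_sign_params(
      fc_hz = lab$fc_hz[r], fr_hz = lab$fr_hz[r],
      ac_m = nuis$ac_m[r], ar_m = nuis$ar_m[r],
      phase_c_rad = nuis$phase_c[r], phase_r_rad = nuis$phase_r[r])
    cfg <- config
    cfg$d0_m <- nuis$d0_m[r]
    iq[r, ] <- synthesize_baseband(p, cfg, snr_db = lab$snr_db[r],
                                   seed = lab$seed[r])$iq
  }
  structure(list(iq = iq, labels = lab, task = task, config = config,
                 split = NULL, seed = seed,
                 class_levels = state_levels()),
            class = "signal_dataset")
}

#' @export
print.signal_dataset <- function(x, ...) {
  cat(sprintf("<signal_dataset> %d records x %d samples, task = %s\n",
              nrow(x$iq), ncol(x$iq), x$task))
  if (!is.null(x$split)) print(table(x$split))
  invisible(x)
}

#' Number of records in a dataset
#' @param ds A `signal_dataset`.
#' @export
n_records <- function(ds) nrow(ds$iq)

#' Build the regression dataset (normal-state subjects)
#'
#' Draws `n_subjects` (fc, fr) pairs uniformly inside the normal ranges and
#' synthesizes one record per pair per SNR level of a sweep over
#' \[-10, 10\] dB. At the reference scale (30 subjects x 100 environments)
#' this yields 3000 records labeled with their continuous rates.
#'
#' @param n_subjects Number of subjects (default 30).
#' @param n_envs Number of SNR levels (default 100).
#' @param config A [radar_config()].
#' @param seed Integer seed; the dataset is a pure function of its arguments.
#' @param bands A [state_bands()] list (only the `normal` entry is used).
#' @return A `signal_dataset` with `task = "regression"`.
#' @export
build_regression_dataset <- function(n_subjects = 30, n_envs = 100,
                                     config = radar_config(), seed = 101,
                                     bands = state_bands()) {
  set.seed(seed)
  pairs <- draw_pairs(n_subjects, bands$normal)
  assemble_dataset(pairs, NULL, snr_grid(n_envs), config,
                   seed = make_seed(seed, "signals"), task = "regression")
}

#' Build the 3-class physiological-state dataset
#'
#' Per-class (fc, fr) pairs are drawn from the [state_bands()]: normal pairs
#' inside the resting ranges, drowsiness pairs below them, stress pairs
#' above. One record per pair per SNR level; at the reference scale
#' (20 + 16 + 17 subjects x 100 environments) this yields 5300 records.
#'
#' @param n_normal,n_drowsy,n_stress Subjects per class (defaults 20/16/17).
#' @inheritParams build_regression_dataset
#' @return A `signal_dataset` with `task = "classification"`; labels carry
#'   both the state class and the underlying continuous rates.
#' @export
build_classification_dataset <- function(n_normal = 20, n_drowsy = 16,
                                         n_stress = 17, n_envs = 100,
                                         config = radar_config(), seed = 202,
                                         bands = state_bands()) {
  set.seed(seed)
  pairs <- rbind(draw_pairs(n_normal, bands$normal),
                 draw_pairs(n_drowsy, bands$drowsiness),
                 draw_pairs(n_stress, bands$stress))
  states <- rep(c("normal", "drowsiness", "stress"),
                c(n_normal, n_drowsy, n_stress))
  assemble_dataset(pairs, states, snr_grid(n_envs), config,
                   seed = make_seed(seed, "signals"), task = "classification")
}

#' Build the generalization dataset (unseen subjects, all three states)
#'
#' `n_per_state` fresh subjects per physiological state, disjoint (by exact
#' pair comparison, via rejection) from any `exclude_pairs` such as the
#' regression-set subjects. Records carry both continuous and class labels,
#' so regression models trained on normal-state data can be scored per
#' state. Reference scale: 5 per state x 100 environments = 1500 records.
#'
#' @param n_per_state Subjects per state (default 5).
#' @param exclude_pairs Optional data frame with `fc_hz`, `fr_hz` columns.
#' @inheritParams build_regression_dataset
#' @return A `signal_dataset` with `task = "generalization"`.
#' @export
build_generalization_dataset <- function(n_per_state = 5, n_envs = 100,
                                         config = radar_config(), seed = 303,
                                         bands = state_bands(),
                                         exclude_pairs = NULL) {
  set.seed(seed)
  draw_disjoint <- function(n, band) {
    out <- draw_pairs(n, band)
    if (!is.null(exclude_pairs)) {
      for (i in seq_len(n)) {
        while (any(out$fc_hz[i] == exclude_pairs$fc_hz &
                   out$fr_hz[i] == exclude_pairs$fr_hz)) {
          redo <- draw_pairs(1, band)
          out[i, ] <- redo
        }
      }
    }
    out
  }
  pairs <- rbind(draw_disjoint(n_per_state, bands$drowsiness),
                 draw_disjoint(n_per_state, bands$normal),
                 draw_disjoint(n_per_state, bands$stress))
  states <- rep(c("drowsiness", "normal", "stress"), each = n_per_state)
  assemble_dataset(pairs, states, snr_grid(n_envs), config,
                   seed = make_seed(seed, "signals"), task = "generalization")
}

#' Assign train/validation/test splits
#'
#' Seeded shuffle followed by contiguous partition into the given fractions
#' (reference protocol: 64/16/20 with random state 4). Classification and
#' generalization datasets are stratified by class so per-class proportions
#' are preserved to within one record.
#'
#' @param ds A `signal_dataset`.
#' @param fractions Length-3 fractions summing to 1 (train, val, test).
#' @param seed Shuffle seed (default 4).
#' @return The dataset with a `split` factor (`train`/`val`/`test`).
#' @export
split_dataset <- function(ds, fractions = c(0.64, 0.16, 0.20), seed = 4) {
  stopifnot(inherits(ds, "signal_dataset"))
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  n <- n_records(ds)
  split <- rep(NA_character_, n)
  assign_group <- function(idx) {
    m <- length(idx)
    n_tr <- round(fractions[1] * m)
    n_va <- round(fractions[2] * m)
    if (n_tr < 1 || n_va < 1 || n_tr + n_va >= m)
      stop("too few records in a stratum for the requested fractions")
    shuffled <- idx[sample.int(m)]
    split[shuffled[seq_len(n_tr)]] <<- "train"
    split[shuffled[n_tr + seq_len(n_va)]] <<- "val"
    split[shuffled[(n_tr + n_va + 1):m]] <<- "test"
  }
  set.seed(seed)
  if (ds$task %in% c("classification", "generalization") &&
      !all(is.na(ds$labels$state))) {
    for (st in unique(ds$labels$state)) assign_group(which(ds$labels$state == st))
  } else {
    assign_group(seq_len(n))
  }
  ds$split <- factor(split, levels = c("train", "val", "test"))
  ds
}

#' Resample and segment an externally recorded baseband signal
#'
#' Generic preprocessor for long I/Q recordings captured at a higher rate:
#' anti-aliased rational resampling to `fs_out` (polyphase FIR, applied to
#' the real and imaginary parts), then non-overlapping consecutive windows
#' of exactly `window` samples; any trailing remainder is dropped.
#'
#' @param iq Complex (or numeric) input series.
#' @param fs_in Input sampling rate in Hz (>= `fs_out`).
#' @param fs_out Output rate in Hz (default 100).
#' @param window Window length in samples (default 5001).
#' @return List of complex vectors of length `window`; empty list if the
#'   resampled signal is shorter than one window.
#' @examples
#' segs <- resample_and_segment(complex(real = rnorm(4000)), 2000, 100, 150)
#' length(segs)  # floor(200 / 150) = 1
#' @export
resample_and_segment <- function(iq, fs_in, fs_out = 100, window = 5001) {
  if (fs_out <= 0 || fs_in < fs_out) stop("need fs_in >= fs_out > 0")
  if (fs_in == fs_out) {
    y <- iq
  } else {
    frac <- rational_factors(fs_out / fs_in)
    y <- complex(real = signal::resample(Re(iq), frac$p, frac$q),
                 imaginary = signal::resample(Im(iq), frac$p, frac$q))
  }
  n_win <- floor(length(y) / window)
  if (n_win == 0) return(list())
  lapply(seq_len(n_win), function(k) y[((k - 1) * window + 1):(k * window)])
}

#' Decimate every record of a dataset
#'
#' Anti-aliased resampling of all records to a lower rate, keeping labels
#' and split assignments. Because the resampler low-passes before
#' decimating, out-of-band noise is removed and the band-limited
#' signal-to-noise structure of the original records is preserved; this is
#' how reduced-rate working copies of the reference datasets are made
#' without changing the difficulty of the estimation task.
#'
#' @param ds A `signal_dataset`.
#' @param fs_out Target rate in Hz (at most the dataset's rate; all rate
#'   bands must stay below `fs_out / 2`).
#' @return The dataset with shorter records and an updated config.
#' @export
decimate_dataset <- function(ds, fs_out) {
  stopifnot(inherits(ds, "signal_dataset"))
  fs_in <- ds$config$fs_hz
  if (fs_out == fs_in) return(ds)
  if (fs_out > fs_in) stop("decimate_dataset only lowers the rate")
  frac <- rational_factors(fs_out / fs_in)
  n_out <- floor(ncol(ds$iq) * frac$p / frac$q)
  iq <- matrix(complex(real = 0), nrow(ds$iq), n_out)
  for (r in seq_len(nrow(ds$iq))) {
    iq[r, ] <- complex(real = signal::resample(Re(ds$iq[r, ]), frac$p, frac$q),
                       imaginary = signal::resample(Im(ds$iq[r, ]), frac$p,
                                                    frac$q))
  }
  ds$iq <- iq
  ds$config$fs_hz <- fs_out
  ds$config$n_samples <- n_out
  ds
}

rational_factors <- function(ratio, max_den = 10000) {
  # smallest p/q = ratio with integer p, q
  for (q in seq_len(max_den)) {
    p <- ratio * q
    if (abs(p - round(p)) < 1e-9) return(list(p = as.integer(round(p)), q = q))
  }
  stop("sampling-rate ratio is not a simple rational number")
}
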