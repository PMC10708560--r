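#' Vital-sign parameters for one simulated subject
#'
#' Bundles the ground-truth physiology driving the chest-motion model: the
#' heart (cardiac) rate `fc_hz`, the respiration rate `fr_hz`, the
#' corresponding displacement amplitudes (metres), the initial phases of the
#' two oscillations, and an optional random body-motion component.
#'
#' Normal adult ranges are roughly 0.83--2 Hz for the heart rate and
#' 0.16--0.33 Hz for respiration; heartbeat chest displacement is
#' 0.2--0.5 mm while respiration moves the chest wall by 4--12 mm, an order
#' of magnitude more.
#'
#' @param fc_hz Heart rate in Hz (> 0).
#' @param fr_hz Respiration rate in Hz (> 0).
#' @param ac_m Heartbeat displacement amplitude in metres (>= 0).
#' @param ar_m Respiration displacement amplitude in metres (>= 0).
#' @param phase_c_rad,phase_r_rad Initial phases in radians.
#' @param body_motion A [body_motion_spec()], or `NULL` for none.
#' @return An object of class `vital_sign_params`.
#' @examples
#' vital_sign_params(fc_hz = 1.2, fr_hz = 0.25)
#' @export
vital_sign_params <- function(fc_hz, fr_hz, ac_m = 3.5e-4, ar_m = 8e-3,
                              phase_c_rad = 0, phase_r_rad = 0,
                              body_motion = NULL) {
  if (!is.finite(fc_hz) || !is.finite(fr_hz) || fc_hz <= 0 || fr_hz <= 0)
    stop("rates fc_hz and fr_hz must be finite and positive")
  if (!is.finite(ac_m) || !is.finite(ar_m) || ac_m < 0 || ar_m < 0)
    stop("displacement amplitudes must be finite and non-negative")
  if (!is.null(body_motion) && !inherits(body_motion, "body_motion_spec"))
    stop("body_motion must be a body_motion_spec() or NULL")
  structure(list(fc_hz = fc_hz, fr_hz = fr_hz, ac_m = ac_m, ar_m = ar_m,
                 phase_c_rad = phase_c_rad, phase_r_rad = phase_r_rad,
                 body_motion = body_motion),
            class = "vital_sign_params")
}

#' Random body-motion specification
#'
#' Chest displacement unrelated to heartbeat or respiration. `kind = "none"`
#' (the default everywhere) contributes exactly zero; `kind = "random_walk"`
#' adds a Gaussian random walk with per-sample step standard deviation
#' `step_std_m`, useful for robustness experiments.
#'
#' @param kind `"none"` or `"random_walk"`.
#' @param step_std_m Per-sample displacement step std in metres (>= 0).
#' @return An object of class `body_motion_spec`.
#' @export
body_motion_spec <- function(kind = c("none", "random_walk"), step_std_m = 0) {
  kind <- match.arg(kind)
  if (!is.finite(step_std_m) || step_std_m < 0)
    stop("step_std_m must be finite and non-negative")
  structure(list(kind = kind, step_std_m = step_std_m),
            class = "body_motion_spec")
}

#' Continuous-wave radar configuration
#'
#' Carrier and sampling geometry of the simulated radar. The wavelength is
#' derived from the carrier (`c / carrier_hz`); `d0_m` is the standoff
#' distance between antenna and chest, which only contributes a constant
#' phase offset to the baseband return.
#'
#' `modulation_mode` selects how chest displacement maps to baseband phase:
#' `"physical"` uses the modulation index beta = 4*pi*amplitude/lambda
#' implied by the two-way path-length change of the echo, while
#' `"paper_literal"` fixes both indices to exactly 1 (a simplified
#' exponential form in which the displacement amplitudes and the wavelength
#' scaling are dropped from the phase terms).
#'
#' @param carrier_hz Carrier frequency in Hz (default 24 GHz).
#' @param d0_m Standoff distance in metres (typically 0.6--1).
#' @param fs_hz Baseband sampling rate in Hz (default 100).
#' @param n_samples Record length in samples (default 5001, i.e. 50 s of
#'   increments at 100 Hz).
#' @param modulation_mode `"physical"` or `"paper_literal"`.
#' @return An object of class `radar_config` with a derived `wavelength_m`.
#' @examples
#' cfg <- radar_config()
#' cfg$wavelength_m  # ~12.5 mm at 24 GHz
#' @export
radar_config <- function(carrier_hz = 24e9, d0_m = 0.8, fs_hz = 100,
                         n_samples = 5001,
                         modulation_mode = c("physical", "paper_literal")) {
  modulation_mode <- match.arg(modulation_mode)
  if (!is.finite(carrier_hz) || carrier_hz <= 0) stop("carrier_hz must be positive")
  if (!is.finite(fs_hz) || fs_hz <= 0) stop("fs_hz must be positive")
  if (!is.finite(n_samples) || n_samples < 2) stop("n_samples must be >= 2")
  if (!is.finite(d0_m) || d0_m < 0) stop("d0_m must be non-negative")
  structure(list(carrier_hz = carrier_hz,
                 wavelength_m = 299792458 / carrier_hz,
                 d0_m = d0_m, fs_hz = fs_hz, n_samples = as.integer(n_samples),
                 modulation_mode = modulation_mode),
            class = "radar_config")
}

#' Time axis of a radar record
#' @param config A [radar_config()].
#' @return Numeric vector of sampling instants starting at t = 0.
#' @export
record_times <- function(config) {
  seq(0, by = 1 / config$fs_hz, length.out = config$n_samples)
}

#' Chest-wall displacement
#'
#' Superposition of the respiration and heartbeat oscillations plus any
#' random body motion:
#' `x(t) = ar*cos(2*pi*fr*t + phi_r) + ac*cos(2*pi*fc*t + phi_c) + xm(t)`.
#'
#' @param params A [vital_sign_params()].
#' @param times Uniformly spaced, increasing sampling instants (seconds).
#' @return Displacement in metres at each instant.
#' @examples
#' p <- vital_sign_params(1.2, 0.25, ac_m = 0, ar_m = 0.01, phase_r_rad = 0)
#' chest_displacement(p, 0)      # = ar
#' @export
chest_displacement <- function(params, times) {
  stopifnot(inherits(params, "vital_sign_params"))
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0) || diff(range(dt)) > 1e-9 * max(dt))
      stop("times must be increasing and uniformly spaced")
  }
  x <- params$ar_m * cos(2 * pi * params$fr_hz * times + params$phase_r_rad) +
       params$ac_m * cos(2 * pi * params$fc_hz * times + params$phase_c_rad)
  bm <- params$body_motion
  if (!is.null(bm) && bm$kind == "random_walk" && bm$step_std_m > 0)
    x <- x + cumsum(stats::rnorm(length(times), 0, bm$step_std_m))
  x
}

body_motion_displacement <- function(params, n) {
  bm <- params$body_motion
  if (is.null(bm) || bm$kind == "none" || bm$step_std_m == 0) return(rep(0, n))
  cumsum(stats::rnorm(n, 0, bm$step_std_m))
}

#' Synthesize a complex baseband radar record
#'
#' The noiseless return is a pure phase modulation of the carrier by chest
#' displacement,
#' `B(t) = Ab * s(t) * exp(1i*br*cos(2*pi*fr*t + phi_r))
#'              * exp(1i*bc*cos(2*pi*fc*t + phi_c))`,
#' where `Ab = exp(1i*4*pi*d0/lambda)` carries the standoff phase (received
#' amplitude fixed to 1) and `s(t) = exp(1i*4*pi*xm(t)/lambda)` carries any
#' random body motion. In `"physical"` mode the modulation indices are
#' `br = 4*pi*ar/lambda` and `bc = 4*pi*ac/lambda`; in `"paper_literal"`
#' mode both are 1. A finite `snr_db` then adds circularly symmetric complex
#' Gaussian noise via [add_noise()].
#'
#' @param params A [vital_sign_params()].
#' @param config A [radar_config()].
#' @param snr_db Target signal-to-noise ratio in dB, or `Inf` for noiseless.
#' @param seed Optional integer; when given, the record is a pure function
#'   of `(params, config, snr_db, seed)`.
#' @return An object of class `baseband_record`: list with complex vector
#'   `iq`, `labels` (fc/fr and optional state), `snr_db`, `seed`, `config`.
#' @examples
#' rec <- synthesize_baseband(vital_sign_params(1.2, 0.25), radar_config(),
#'                            snr_db = Inf)
#' sd(Mod(rec$iq))  # ~0: constant modulus
#' @export
synthesize_baseband <- function(params, config = radar_config(),
                                snr_db = Inf, seed = NULL) {
  stopifnot(inherits(params, "vital_sign_params"),
            inherits(config, "radar_config"))
  if (!is.numeric(snr_db) || length(snr_db) != 1 || is.na(snr_db))
    stop("snr_db must be a finite dB value or Inf")
  if (!is.null(seed)) set.seed(seed)
  t <- record_times(config)
  lam <- config$wavelength_m
  if (config$modulation_mode == "physical") {
    br <- 4 * pi * params$ar_m / lam
    bc <- 4 * pi * params$ac_m / lam
  } else {
    br <- 1
    bc <- 1
  }
  xm <- body_motion_displacement(params, length(t))
  ab <- exp(1i * 4 * pi * config$d0_m / lam)
  s_t <- exp(1i * 4 * pi * xm / lam)
  iq <- ab * s_t *
    exp(1i * br * cos(2 * pi * params$fr_hz * t + params$phase_r_rad)) *
    exp(1i * bc * cos(2 * pi * params$fc_hz * t + params$phase_c_rad))
  if (is.finite(snr_db)) iq <- add_noise(iq, snr_db)
  structure(list(iq = iq,
                 labels = list(fc_hz = params$fc_hz, fr_hz = params$fr_hz,
                               state = NULL),
                 snr_db = snr_db, seed = seed, params = params,
                 config = config),
            class = "baseband_record")
}

#' Add complex Gaussian noise at a target SNR
#'
#' Adds circularly symmetric complex Gaussian noise with total variance
#' `signal_power / 10^(snr_db/10)`, split equally between the in-phase and
#' quadrature components. Signal power is the mean squared magnitude of the
#' input (which should be the noiseless record).
#'
#' @param iq Complex signal vector with nonzero power.
#' @param snr_db Finite target SNR in dB.
#' @return Complex vector of the same length.
#' @export
add_noise <- function(iq, snr_db) {
  if (!is.finite(snr_db)) stop("snr_db must be finite (use Inf upstream to skip noise)")
  p_sig <- mean(Mod(iq)^2)
  if (p_sig == 0) stop("all-zero input: SNR undefined")
  sigma2 <- p_sig / 10^(snr_db / 10)
  n <- length(iq)
  iq + complex(real = stats::rnorm(n, 0, sqrt(sigma2 / 2)),
               imaginary = stats::rnorm(n, 0, sqrt(sigma2 / 2)))
}

#' Unwrapped, detrended baseband phase
#'
#' Demodulates a complex baseband record to its phase: argument, unwrapped,
#' with the best-fit linear trend removed. In the noiseless motion-free case
#' this recovers `br*cos(2*pi*fr*t) + bc*cos(2*pi*fc*t)` up to a constant.
#'
#' @param iq Complex vector.
#' @return Numeric phase vector in radians.
#' @export
phase_demodulate <- function(iq) {
  ph <- signal::unwrap(Arg(iq))
  n <- length(ph)
  tt <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, tt), ph)
  ph - fit$fitted.values
}

#' FFT-based respiration/heart rate estimation
#'
#' The non-neural oracle used to validate the simulator and dataset labels:
#' the record is phase-demodulated ([phase_demodulate()]), Hann-windowed,
#' Fourier-transformed, and the frequency of the largest spectral magnitude
#' inside each search band is returned. A Hann window is used so that
#' leakage from the (much stronger) respiration line cannot mask the heart
#' line when the two bands are close. Frequency granularity is `fs/N`,
#' i.e. about 0.02 Hz for a 50 s record.
#'
#' @param record A `baseband_record`, or a complex vector (then `fs_hz` must
#'   be supplied).
#' @param fr_band,fc_band Numeric length-2 search bands in Hz, within
#'   `(0, fs/2)`.
#' @param fs_hz Sampling rate, taken from the record's config by default.
#' @return Named list `fr_hz`, `fc_hz` of peak frequencies.
#' @examples
#' rec <- synthesize_baseband(vital_sign_params(1.5, 0.2), radar_config())
#' estimate_rates_fft(rec)
#' @export
estimate_rates_fft <- function(record, fr_band = c(0.08, 0.52),
                               fc_band = c(0.55, 2.6), fs_hz = NULL) {
  if (inherits(record, "baseband_record")) {
    iq <- record$iq
    fs_hz <- record$config$fs_hz
  } else {
    iq <- record
    if (is.null(fs_hz)) stop("fs_hz required when passing a bare vector")
  }
  n <- length(iq)
  if (n < 2) stop("record too short")
  ph <- phase_demodulate(iq)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))  # Hann
  mag <- Mod(stats::fft(ph * w))
  freqs <- (seq_len(n) - 1) * fs_hz / n
  peak_in <- function(band) {
    if (any(!is.finite(band)) || band[1] >= band[2] ||
        band[1] <= 0 || band[2] >= fs_hz / 2)
      stop("band must lie within (0, fs/2)")
    sel <- which(freqs >= band[1] & freqs <= band[2])
    if (length(sel) == 0) stop("empty band after discretization")
    freqs[sel[which.max(mag[sel])]]
  }
  list(fr_hz = peak_in(fr_band), fc_hz = peak_in(fc_band))
}
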