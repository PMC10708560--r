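test_that("chest displacement follows the two-tone motion model", {
  p0 <- vital_sign_params(1.2, 0.25, ac_m = 0, ar_m = 0)
  t <- seq(0, 10, by = 0.01)
  expect_equal(chest_displacement(p0, t), rep(0, length(t)))

  p1 <- vital_sign_params(1.2, 0.2, ac_m = 0, ar_m = 0.010, phase_r_rad = 0)
  expect_equal(chest_displacement(p1, 0), 0.010)
  expect_lt(abs(chest_displacement(p1, 1.25)), 1e-12)  # quarter period

  # brute-force bound over a full grid: |x| <= ar + ac
  p2 <- vital_sign_params(1.2, 0.25, ac_m = 4e-4, ar_m = 8e-3,
                          phase_c_rad = 0.7, phase_r_rad = 1.1)
  tg <- seq(0, 50, by = 0.01)
  x <- chest_displacement(p2, tg)
  expect_lte(max(abs(x)), 8.4e-3)
  expect_gte(min(x), -8.4e-3)
})

test_that("parameter validation rejects bad physiology", {
  expect_error(vital_sign_params(-1, 0.2), "positive")
  expect_error(vital_sign_params(1, Inf), "finite")
  expect_error(vital_sign_params(1, 0.2, ac_m = -1e-4), "non-negative")
  expect_error(chest_displacement(vital_sign_params(1, 0.2), c(0, 1, 1.5)),
               "uniformly spaced")
  expect_error(body_motion_spec("random_walk", -1), "non-negative")
})

test_that("noiseless baseband has constant modulus and the standoff phase", {
  p <- vital_sign_params(1.3, 0.22)
  cfg <- radar_config(d0_m = 0.8)
  rec <- synthesize_baseband(p, cfg, snr_db = Inf)
  expect_s3_class(rec, "baseband_record")
  expect_length(rec$iq, cfg$n_samples)
  expect_lt(diff(range(Mod(rec$iq))), 1e-9)

  p0 <- vital_sign_params(1.3, 0.22, ac_m = 0, ar_m = 0)
  rec0 <- synthesize_baseband(p0, cfg, snr_db = Inf)
  ab <- exp(1i * 4 * pi * cfg$d0_m / cfg$wavelength_m)
  expect_equal(rec0$iq, rep(ab, cfg$n_samples))
})

test_that("physical modulation index is 4*pi*amplitude/wavelength", {
  cfg <- radar_config()  # 24 GHz
  expect_equal(cfg$wavelength_m, 299792458 / 24e9)
  beta_r <- 4 * pi * 0.006 / cfg$wavelength_m
  expect_equal(beta_r, 6.036, tolerance = 1e-3)
})

test_that("single-tone spectrum carries Bessel-function line magnitudes", {
  # on-bin tone, rectangular window: DFT line k has magnitude |J_k(beta)|
  cfg <- radar_config(fs_hz = 100, n_samples = 5000, d0_m = 0)
  p <- vital_sign_params(fc_hz = 1, fr_hz = 0.2, ac_m = 0, ar_m = 0.006,
                         phase_r_rad = 0)
  rec <- synthesize_baseband(p, cfg, snr_db = Inf)
  beta <- 4 * pi * p$ar_m / cfg$wavelength_m
  mag <- Mod(stats::fft(rec$iq)) / cfg$n_samples
  k <- 0:5
  lines <- mag[1 + k * p$fr_hz * cfg$n_samples / cfg$fs_hz]
  expect_equal(lines, abs(besselJ(beta, k)), tolerance = 0.02)
})

test_that("paper_literal mode uses unit modulation indices", {
  cfg <- radar_config(modulation_mode = "paper_literal", d0_m = 0)
  p <- vital_sign_params(1.5, 0.25, phase_c_rad = 0, phase_r_rad = 0)
  rec <- synthesize_baseband(p, cfg, snr_db = Inf)
  t10 <- record_times(cfg)[sample.int(cfg$n_samples, 10)]
  idx <- round(t10 * cfg$fs_hz) + 1
  expected <- exp(1i * cos(2 * pi * p$fr_hz * t10)) *
    exp(1i * cos(2 * pi * p$fc_hz * t10))
  expect_equal(rec$iq[idx], expected, tolerance = 1e-12)
})

test_that("additive noise hits the requested SNR on average", {
  p <- vital_sign_params(1.2, 0.25)
  clean <- synthesize_baseband(p, radar_config(), snr_db = Inf)$iq
  set.seed(1)
  for (snr in c(0, -10)) {
    ratio <- mean(vapply(1:100, function(i) {
      noisy <- add_noise(clean, snr)
      mean(Mod(clean)^2) / mean(Mod(noisy - clean)^2)
    }, 0))
    expect_equal(10 * log10(ratio), snr, tolerance = 0.5)
  }
})

test_that("noise handling rejects degenerate input and Inf bypasses it", {
  expect_error(add_noise(complex(real = numeric(5)), 0), "all-zero")
  expect_error(add_noise(complex(real = rnorm(5)), Inf), "finite")
  expect_error(synthesize_baseband(vital_sign_params(1, 0.2),
                                   radar_config(), snr_db = NA),
               "snr_db")
  rec <- synthesize_baseband(vital_sign_params(1, 0.2), radar_config(),
                             snr_db = Inf)
  expect_lt(diff(range(Mod(rec$iq))), 1e-9)  # no noise was added
})

test_that("records are bit-identical under the same seed", {
  p <- vital_sign_params(1.4, 0.3,
                         body_motion = body_motion_spec("random_walk", 1e-5))
  r1 <- synthesize_baseband(p, radar_config(), snr_db = 3, seed = 99)
  r2 <- synthesize_baseband(p, radar_config(), snr_db = 3, seed = 99)
  expect_identical(r1$iq, r2$iq)
  r3 <- synthesize_baseband(p, radar_config(), snr_db = 3, seed = 100)
  expect_false(identical(r1$iq, r3$iq))
})

test_that("FFT oracle recovers both rates from noiseless records", {
  cfg <- radar_config()
  rec <- synthesize_baseband(vital_sign_params(1.5, 0.20), cfg, Inf)
  est <- estimate_rates_fft(rec)
  expect_lt(abs(est$fr_hz - 0.20), 0.02)
  expect_lt(abs(est$fc_hz - 1.50), 0.02)

  rec2 <- synthesize_baseband(vital_sign_params(1.5, 0.25, ac_m = 0),
                              cfg, Inf)
  expect_lt(abs(estimate_rates_fft(rec2)$fr_hz - 0.25), 0.02)
})

test_that("FFT oracle tolerates 10 dB noise in most draws", {
  cfg <- radar_config()
  hits <- 0L
  for (s in 1:50) {
    fr <- 0.16 + 0.17 * (s / 51)
    rec <- synthesize_baseband(vital_sign_params(1.2, fr), cfg,
                               snr_db = 10, seed = 1000 + s)
    if (abs(estimate_rates_fft(rec)$fr_hz - fr) <= 0.02) hits <- hits + 1L
  }
  expect_gte(hits, 45L)  # >= 90%
})

test_that("FFT oracle validates its band arguments", {
  rec <- synthesize_baseband(vital_sign_params(1.2, 0.25), radar_config())
  expect_error(estimate_rates_fft(rec, fr_band = c(0.5, 0.1)), "band")
  expect_error(estimate_rates_fft(rec, fc_band = c(0.6, 60)), "band")
  expect_error(estimate_rates_fft(rec$iq), "fs_hz")
})
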