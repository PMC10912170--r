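with_seed_noise <- function(s) {
  set.seed(s)
  n <- rnorm(1800, 0, 0.02)
  attr(n, "fs") <- 7.5
  n
}

test_that("calcium simulation matches its design", {
  # rate 0, no noise -> constant baseline
  x0 <- simulate_calcium(rate = 0, noise_sd = 0, seed = 1)
  expect_true(all(x0 == 1))
  # 4 min at 7.5 Hz -> 1800 samples
  x <- simulate_calcium(rate = 3, fs = 7.5, duration = 240, seed = 2)
  expect_identical(length(x), 1800L)
  # planted event count within the Poisson 95% band for lambda = 12
  counts <- vapply(1:20, function(s) {
    length(attr(simulate_calcium(rate = 3, duration = 240, seed = s),
                "event_times"))
  }, numeric(1))
  band <- qpois(c(0.025, 0.975), 12)
  expect_gt(mean(counts >= band[1] & counts <= band[2]), 0.85)
  expect_error(simulate_calcium(rate = 1, fs = 0), "fs")
})

test_that("dF/F normalisation is exact on constructed traces", {
  x <- rep(2, 600); attr(x, "fs") <- 10
  expect_true(all(abs(dff(x)) < 1e-12))
  # step x2 after a long baseline: dff ~ 1 right after the step
  xs <- c(rep(1, 400), rep(2, 200)); attr(xs, "fs") <- 10
  d <- dff(xs, baseline_window_s = 30)
  expect_equal(d[420], 1, tolerance = 1e-6)
  expect_error(dff(rep(1, 10), fs = 1, baseline_window_s = 30), "window")
  xneg <- rep(-1, 600); attr(xneg, "fs") <- 10
  expect_error(dff(xneg), "positive")
})

test_that("transient detection recovers planted events", {
  # noiseless: exactly the planted count
  x <- simulate_calcium(rate = 3, duration = 240, fs = 7.5,
                        noise_sd = 0.004, amp = 0.5, seed = 4)
  d <- dff(x)
  ev <- detect_transients(d, k_sd = 3)
  expect_identical(nrow(ev), length(attr(x, "event_times")))
  # peak amplitudes near the planted amplitude
  expect_equal(median(ev$amplitude), 0.5, tolerance = 0.1)
  # pure noise at k_sd = 5: false positives < 0.2/min over 40 seeds
  fp <- vapply(1:40, function(s) {
    n <- with_seed_noise(s)
    attr(detect_transients(n, fs = 7.5, k_sd = 5), "frequency_per_min")
  }, numeric(1))
  expect_lt(mean(fp), 0.2)
  expect_error(detect_transients(numeric(0), fs = 1), "empty")
})

test_that("transient frequency is unbiased across rates at high SNR", {
  for (rate in c(2, 6, 10)) {
    est <- planted <- c()
    for (s in 1:6) {
      x <- simulate_calcium(rate = rate, duration = 240, fs = 7.5,
                            noise_sd = 0.01, amp = 0.5, seed = 50 + s)
      ev <- detect_transients(dff(x))
      est <- c(est, nrow(ev))
      planted <- c(planted, length(attr(x, "event_times")))
    }
    # mean error within the Poisson sampling scale of the planted count
    expect_lt(abs(mean(est - planted)), 2 * sqrt(mean(planted) / 6) + 1)
  }
})

test_that("PSD locates a pure tone and is flat for white noise", {
  fs <- 1000
  t <- seq(0, 20, by = 1 / fs)[-1]
  x <- sin(2 * pi * 40 * t)
  p <- lfp_psd(x, fs)
  expect_equal(p$freqs[which.max(p$psd)], 40, tolerance = 0.5)
  # Parseval: band-integrated power ~ variance for in-band content
  expect_equal(as.numeric(band_power(p, band = c(0.5, 100))), var(x),
               tolerance = 0.05)
  set.seed(9)
  w <- rnorm(fs * 120)
  pw <- lfp_psd(w, fs)
  gsel <- pw$freqs >= 30 & pw$freqs <= 100
  flat <- pw$psd[gsel] / mean(pw$psd[gsel])
  # smoothed-by-averaging periodogram flat within 20% across 30-100 Hz
  expect_lt(max(abs(tapply(flat, cut(pw$freqs[gsel], 7), mean) - 1)), 0.2)
  expect_error(lfp_psd(w, fs = 100), "too low")
  expect_error(lfp_psd(w[1:1000], fs), ">= 4 s")
})

test_that("band power normalisation behaves as a ratio", {
  base <- simulate_lfp(fs = 1000, duration = 30, gamma_power = 0, seed = 3)
  p <- lfp_psd(base, 1000)
  expect_equal(as.numeric(band_power(p, baseline = p)), 1)
  expect_error(band_power(p, band = c(150, 200)), "outside")
  expect_error(simulate_lfp(fs = 1000, gamma_band = c(30, 600)), "Nyquist|inside")
})

test_that("injected gamma power is recovered across the planted ratios", {
  fs <- 1000
  base <- simulate_lfp(fs = fs, duration = 60, gamma_power = 0, seed = 70)
  bg <- attr(base, "background_band_power")
  p0 <- lfp_psd(base, fs)
  est <- c()
  for (k in c(0.5, 1, 2, 4)) {
    r <- vapply(1:5, function(s) {
      x <- simulate_lfp(fs = fs, duration = 60, gamma_power = k * bg,
                        seed = 200 + 10 * k + s)
      as.numeric(band_power(lfp_psd(x, fs), baseline = p0))
    }, numeric(1))
    est <- c(est, mean(r))
  }
  planted <- 1 + c(0.5, 1, 2, 4)
  expect_true(all(abs(est / planted - 1) < 0.1))
  expect_true(all(diff(est) > 0))  # monotone in injected power
})

test_that("fixed seeds reproduce traces exactly", {
  a <- simulate_lfp(fs = 500, duration = 10, gamma_power = 1, seed = 5)
  b <- simulate_lfp(fs = 500, duration = 10, gamma_power = 1, seed = 5)
  expect_identical(as.numeric(a), as.numeric(b))
  ca <- simulate_calcium(rate = 2, seed = 8)
  cb <- simulate_calcium(rate = 2, seed = 8)
  expect_identical(as.numeric(ca), as.numeric(cb))
})
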