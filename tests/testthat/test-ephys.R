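test_that("CAR subtraction zeroes the channel mean at every sample", {
  # identical channels cancel completely
  x <- sin(seq(0, 10, length.out = 1000))
  rec <- ephys_recording(rbind(x, x, x), 30000)
  expect_true(all(car_subtract(rec)$signal == 0))
  # antisymmetric pair is unchanged
  rec2 <- ephys_recording(rbind(x, -x), 30000)
  expect_equal(car_subtract(rec2)$signal, rec2$signal)
  # random array: per-sample channel mean is numerically zero
  withr::with_seed(2, {
    sig <- matrix(rnorm(16 * 1000), nrow = 16)
  })
  out <- car_subtract(ephys_recording(sig, 30000))$signal
  expect_lt(max(abs(colMeans(out))), 1e-10)
  expect_error(car_subtract(ephys_recording(sig[1, , drop = FALSE], 30000)),
               "2 channels")
})

test_that("spike band-pass preserves in-band tones and rejects DC and >10 kHz", {
  fs <- 48828
  t <- seq_len(fs) / fs
  tone <- sin(2 * pi * 2000 * t)
  rec <- ephys_recording(rbind(tone, tone), fs)
  out <- bandpass_spike(rec)$signal[1, ]
  # FFT amplitude at 2 kHz preserved within 5%
  core <- (fs %/% 4):(3 * fs %/% 4)
  expect_lt(abs(sd(out[core]) / sd(tone[core]) - 1), 0.05)

  dc <- matrix(100, 2, fs)
  out_dc <- bandpass_spike(ephys_recording(dc, fs))$signal[1, ]
  expect_lt(abs(mean(out_dc[core])), 0.1)

  hi <- sin(2 * pi * 12000 * t)
  out_hi <- bandpass_spike(ephys_recording(rbind(hi, hi), fs))$signal[1, ]
  expect_lt(sd(out_hi[core]) / sd(hi[core]), 0.01)  # >= 40 dB
})

test_that("impulse response energy matches the analytic magnitude response", {
  fs <- 48828
  n <- 2^14
  imp <- c(rep(0, n / 2), 1, rep(0, n / 2 - 1))
  h <- peritract:::spike_bandpass_filter(imp, fs)
  # energy via Parseval against |H(f)|^2 of the zero-phase cascade
  bf <- signal::butter(4, c(500, 6000) / (fs / 2), type = "pass")
  f <- seq(0, fs / 2, length.out = 4096)
  H <- signal::freqz(bf$b, bf$a, n = 4096, Fs = fs)
  mag4 <- abs(H$h)^4  # filtfilt applies the magnitude twice
  energy_analytic <- sum(mag4) / length(mag4)
  expect_lt(abs(sum(h^2) - energy_analytic) / energy_analytic, 0.01)
})

test_that("snippet extraction matches a brute-force scan on Gaussian noise", {
  fs <- 48828
  withr::with_seed(5, x <- rnorm(1e6))
  sn <- detect_snippets(x, fs)
  # supra-threshold fraction ~ 2 * pnorm(-3.5)
  frac <- mean(abs(x) > sn$threshold_uv)
  expect_lt(abs(frac - 2 * pnorm(-3.5)) / (2 * pnorm(-3.5)), 0.2)
  # windows are non-overlapping, odd-length, centred at the absolute minimum
  win <- round(0.0024 * fs) + (1 - round(0.0024 * fs) %% 2)
  expect_true(all(sn$windows$end - sn$windows$start + 1 == win))
  if (nrow(sn$windows) > 1) {
    expect_true(all(diff(sn$windows$start) >= win))
  }
  # every extracted window contains a supra-threshold sample
  has_crossing <- vapply(seq_len(nrow(sn$windows)), function(i) {
    any(abs(x[sn$windows$start[i]:sn$windows$end[i]]) > sn$threshold_uv)
  }, logical(1))
  expect_true(all(has_crossing))
  # window union + noise set partitions the trace
  covered <- sum(sn$windows$end - sn$windows$start + 1)
  expect_equal(covered + length(sn$noise_idx), length(x))
  # brute-force: every excursion beyond threshold intersects a window
  over <- which(abs(x) > sn$threshold_uv)
  in_any <- unlist(mapply(seq, sn$windows$start, sn$windows$end,
                          SIMPLIFY = FALSE))
  expect_true(all(over %in% in_any |
                  vapply(over, function(i) any(abs(i - sn$centers) <= win),
                         logical(1))))

  # zero signal: no snippets, everything is noise
  z <- detect_snippets(rep(0, 5000), fs)
  expect_equal(length(z$p2p_uv), 0L)
  expect_equal(z$noise_idx, seq_len(5000))
  expect_error(detect_snippets(rep(0, 10), fs), "longer")
})

test_that("a planted template is detected once and aligned to its minimum", {
  fs <- 48828
  tpl <- peritract:::default_template(fs, 100)
  withr::with_seed(6, x <- rnorm(fs, sd = 0.1))
  at <- 20000
  x[at:(at + length(tpl) - 1)] <- x[at:(at + length(tpl) - 1)] + tpl
  sn <- detect_snippets(x, fs)
  expect_equal(length(sn$p2p_uv), 1L)
  true_min <- at + which.min(tpl) - 1
  expect_lte(abs(sn$centers[1] - true_min), 1)
})

test_that("channel inclusion uses inclusive 0.3-2x bounds on the array mean", {
  expect_true(all(channel_inclusion(rep(3, 16))))
  rms <- c(rep(1, 15), 3)
  expect_equal(unname(channel_inclusion(rms)[16]), FALSE)
  expect_true(all(channel_inclusion(rms)[1:15]))
  # boundary: exactly 2x the mean is included
  m <- mean(c(rep(1, 3), 2 * mean(c(1, 1, 1, 1))))
  rms2 <- c(1, 1, 1, 1)
  rms2 <- c(rms2, 2 * mean(c(rms2, NA), na.rm = TRUE))  # construct iteratively
  # direct construction: x such that x = 2 * mean(c(1,1,1,x)) -> x = 3
  rms3 <- c(1, 1, 1, 3)
  expect_true(channel_inclusion(rms3)[4])
  # and just above the bound is excluded
  rms4 <- c(1, 1, 1, 3.05)
  expect_false(channel_inclusion(rms4)[4])
})

test_that("channel SNR follows mean P2P over six noise SDs", {
  sn <- structure(list(p2p_uv = c(60, 60), noise_idx = 1:1000),
                  class = "snippet_set")
  withr::with_seed(7, x <- rnorm(1000))
  x <- x / sd(x) * 2  # noise SD exactly 2
  expect_equal(channel_snr(sn, x), 60 / (6 * 2))
  # zero snippets and zero-SD noise are undefined
  sn0 <- structure(list(p2p_uv = numeric(0), noise_idx = 1:10),
                   class = "snippet_set")
  expect_true(is.na(channel_snr(sn0, x)))
  snz <- structure(list(p2p_uv = 5, noise_idx = 1:10),
                   class = "snippet_set")
  expect_true(is.na(channel_snr(snz, rep(0, 10))))
})

test_that("MUA amplitude matches loop oracle and truncated-normal closed form", {
  # symmetric spikes: brute-force set means
  withr::with_seed(8, x <- rnorm(10000))
  s <- sd(x)
  x[1:20] <- 10 * s
  x[21:40] <- -10 * s
  mua <- channel_mua(x)
  s2 <- sd(x)
  pos <- x[x > 3.5 * s2]; neg <- x[x < -3.5 * s2]
  expect_equal(mua, mean(pos) - mean(neg))

  # pure Gaussian noise: 2 * E[X | X > 3.5] = 2 * dnorm(3.5)/pnorm(-3.5)
  withr::with_seed(9, g <- rnorm(1e7))
  closed <- 2 * dnorm(3.5) / pnorm(-3.5)
  expect_lt(abs(channel_mua(g) - closed) / closed, 0.05)

  # no sample beyond threshold: missing
  expect_true(is.na(channel_mua(seq(-1, 1, length.out = 100))))
})

test_that("LFP amplitude recovers 6 SD of a band-limited component and notches 60 Hz", {
  fs <- 48828
  cfg <- ephys_sim_config(duration_s = 4, n_channels = 1, spike_rate_hz = 0,
                          noise_sd_uv = 0, lfp_sd_uv = 40, seed = 10)
  rec <- simulate_recording(cfg)
  amp <- channel_lfp_amplitude(rec$signal[1, ], fs)
  expect_lt(abs(amp - 6 * 40) / (6 * 40), 0.02)

  # pure 60 Hz sinusoid of amplitude 100 is strongly attenuated
  t <- seq_len(10 * fs) / fs
  line <- 100 * sin(2 * pi * 60 * t)
  expect_lt(channel_lfp_amplitude(line, fs), 10)

  expect_equal(channel_lfp_amplitude(rep(0, 1000), 2000), 0)
  expect_error(channel_lfp_amplitude(rnorm(100), 500), "600")
})

test_that("implant metrics average included channels and are deterministic", {
  cfg <- ephys_sim_config(duration_s = 2, n_channels = 16,
                          template_p2p_uv = 100, noise_sd_uv = 3,
                          lfp_sd_uv = 40, seed = 11)
  rec <- simulate_recording(cfg)
  m1 <- implant_metrics(rec)
  m2 <- implant_metrics(rec)
  expect_identical(m1$implant, m2$implant)
  inc <- m1$channels[m1$channels$included, ]
  expect_equal(m1$implant$snr_avg, mean(inc$snr, na.rm = TRUE))
  expect_equal(m1$implant$n_included, sum(m1$channels$included))
  # tidy/glance accessors expose the tables
  expect_equal(nrow(tidy(m1)), 16)
  expect_equal(nrow(glance(m1)), 1)
})

test_that("a dead channel is excluded and averages recompute over the rest", {
  cfg <- ephys_sim_config(duration_s = 2, n_channels = 16,
                          template_p2p_uv = 80, noise_sd_uv = 3,
                          lfp_sd_uv = 30, seed = 13)
  rec <- simulate_recording(cfg)
  rec$signal[4, ] <- rec$signal[4, ] * 0.01  # nearly dead site
  m <- implant_metrics(rec)
  expect_false(m$channels$included[4])
  inc <- m$channels[m$channels$included, ]
  expect_equal(m$implant$mua_avg_uv, mean(inc$mua_uv, na.rm = TRUE))
  expect_equal(m$implant$n_included, 15)
})

test_that("metrics are invariant to channel order and constant offsets", {
  cfg <- ephys_sim_config(duration_s = 1, n_channels = 4,
                          template_p2p_uv = 80, noise_sd_uv = 3,
                          lfp_sd_uv = 30, seed = 14)
  rec <- simulate_recording(cfg)
  m <- implant_metrics(rec)
  perm <- c(3, 1, 4, 2)
  rec_p <- ephys_recording(rec$signal[perm, ], rec$fs_hz)
  m_p <- implant_metrics(rec_p)
  expect_equal(m_p$implant$snr_avg, m$implant$snr_avg, tolerance = 1e-10)
  expect_equal(m_p$implant$lfp_avg_uv, m$implant$lfp_avg_uv,
               tolerance = 1e-10)
  # constant offset is removed by the filters
  rec_o <- ephys_recording(rec$signal + 50, rec$fs_hz)
  m_o <- implant_metrics(rec_o)
  expect_equal(m_o$implant$snr_avg, m$implant$snr_avg, tolerance = 1e-6)
  expect_equal(m_o$implant$mua_avg_uv, m$implant$mua_avg_uv,
               tolerance = 1e-6)
})
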