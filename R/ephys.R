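#' Construct an extracellular recording object
#'
#' @param signal Numeric matrix, channels x samples, microvolts.
#' @param fs_hz Sampling rate in Hz.
#' @param channels Optional channel identifiers.
#' @return An `ephys_recording`.
#' @export
ephys_recording <- function(signal, fs_hz, channels = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    abort("`signal` must be a numeric matrix (channels x samples).")
  }
  if (!all(is.finite(signal))) abort("`signal` must be finite throughout.")
  assert_positive_scalar(fs_hz, "fs_hz")
  if (is.null(channels)) channels <- seq_len(nrow(signal))
  if (length(channels) != nrow(signal)) {
    abort("`channels` must match the number of signal rows.")
  }
  structure(list(signal = signal, fs_hz = fs_hz, channels = channels),
            class = "ephys_recording")
}

#' Common average reference subtraction
#'
#' Subtracts the across-channel mean from every channel at each sample,
#' removing signal components common to the whole array.
#'
#' @param rec An `ephys_recording` (>= 2 channels).
#' @return The recording with the common average removed.
#' @export
car_subtract <- function(rec) {
  check_recording(rec)
  if (nrow(rec$signal) < 2L) {
    abort("CAR subtraction requires at least 2 channels.")
  }
  rec$signal <- sweep(rec$signal, 2, colMeans(rec$signal), "-")
  rec
}

check_recording <- function(rec) {
  if (!inherits(rec, "ephys_recording")) {
    abort("Expected an `ephys_recording` object.")
  }
  invisible(rec)
}

# Spike-band filter core: order-4 Butterworth prototype (8-pole band-pass),
# applied forward-backward for zero net phase.
spike_bandpass_filter <- function(x, fs_hz, band = c(500, 6000)) {
  if (band[2] >= fs_hz / 2) {
    abort("Band edge at or above Nyquist; increase the sampling rate.")
  }
  bf <- signal::butter(4, band / (fs_hz / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Spike-band (500-6000 Hz) band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass applied per channel.
#'
#' @param rec An `ephys_recording` with `fs_hz` > 12 kHz.
#' @return The filtered recording.
#' @export
bandpass_spike <- function(rec) {
  check_recording(rec)
  if (rec$fs_hz <= 12000) abort("`fs_hz` must exceed 12 kHz.")
  rec$signal <- t(apply(rec$signal, 1, spike_bandpass_filter, fs_hz = rec$fs_hz))
  rec
}

#' Threshold snippet extraction from a filtered channel
#'
#' The threshold is `k` times the SD of the full filtered trace. Scanning
#' left to right, at the first supra-threshold sample of an excursion the
#' absolute minimum within half a window on either side is located, a 2.4 ms
#' window centred on that minimum is extracted, and the scan resumes past the
#' window end. Samples in no window form the noise set.
#'
#' @param x Numeric vector, one filtered channel.
#' @param fs_hz Sampling rate.
#' @param k Threshold multiplier (default 3.5).
#' @param window_ms Snippet window length (default 2.4).
#' @return A `snippet_set`: list with `snippets` (matrix, one row per
#'   snippet), `centers` (alignment sample indices), `p2p_uv`, `windows`
#'   (start/end tibble), `noise_idx`, `threshold_uv`, `n_samples`.
#' @export
detect_snippets <- function(x, fs_hz, k = 3.5, window_ms = 2.4) {
  if (!is.numeric(x) || length(x) < 2L) abort("`x` must be a numeric vector.")
  win <- round(window_ms / 1000 * fs_hz)
  if (win %% 2 == 0) win <- win + 1L  # odd length so the centre is a sample
  if (win > length(x)) abort("Snippet window longer than the trace.")
  half <- (win - 1L) %/% 2L
  thr <- k * sd(x)
  n <- length(x)
  over <- which(abs(x) > thr)
  centers <- integer(0)
  starts <- integer(0)
  i_ptr <- 1L
  guard <- 0L
  while (i_ptr <= length(over)) {
    i <- over[i_ptr]
    if (i <= guard) { i_ptr <- i_ptr + 1L; next }
    # search for the excursion minimum within half a window of the crossing;
    # the aligned window must start after the previous one ends (greedy
    # left-to-right overlap resolution)
    lo <- max(1L, i - half, guard + half + 1L)
    hi <- min(n, i + half)
    m <- lo + which.min(x[lo:hi]) - 1L
    s <- m - half
    e <- m + half
    if (s >= 1L && e <= n) {
      centers <- c(centers, m)
      starts <- c(starts, s)
      guard <- e
    } else {
      # window would overrun the trace edge: skip past the excursion
      guard <- hi
    }
    i_ptr <- i_ptr + 1L
  }
  if (length(centers)) {
    snips <- t(vapply(starts, function(s) x[s:(s + win - 1L)], numeric(win)))
    p2p <- apply(snips, 1, function(v) max(v) - min(v))
    in_window <- unlist(lapply(starts, function(s) s:(s + win - 1L)))
    noise_idx <- setdiff(seq_len(n), in_window)
    windows <- tibble::tibble(start = starts, end = starts + win - 1L)
  } else {
    snips <- matrix(numeric(0), ncol = win)
    p2p <- numeric(0)
    noise_idx <- seq_len(n)
    windows <- tibble::tibble(start = integer(0), end = integer(0))
  }
  structure(
    list(snippets = snips, centers = centers, p2p_uv = p2p,
         windows = windows, noise_idx = noise_idx, threshold_uv = thr,
         n_samples = n),
    class = "snippet_set"
  )
}

#' @export
print.snippet_set <- function(x, ...) {
  cat(sprintf("<snippet_set> %d snippets, threshold %.2f uV\n",
              length(x$p2p_uv), x$threshold_uv))
  invisible(x)
}

#' Noise-floor channel inclusion
#'
#' A channel is included when its noise RMS lies between 0.3 and 2 times the
#' array-average noise RMS (inclusive bounds); this screens out damaged or
#' dead sites.
#'
#' @param noise_rms Numeric vector of per-channel noise-floor RMS values.
#' @return Logical inclusion mask.
#' @export
channel_inclusion <- function(noise_rms) {
  if (!is.numeric(noise_rms) || !all(is.finite(noise_rms))) {
    abort("`noise_rms` must be finite numeric.")
  }
  m <- mean(noise_rms)
  noise_rms >= 0.3 * m & noise_rms <= 2 * m
}

#' Channel SNR from a snippet set
#'
#' Mean snippet peak-to-peak amplitude divided by six times the SD of the
#' noise-floor samples. Undefined (NA) when the channel has no snippets or a
#' degenerate (zero-SD) noise floor.
#'
#' @param snips A `snippet_set`, together with the filtered trace it was
#'   extracted from.
#' @param x The filtered channel the snippets came from.
#' @return SNR (dimensionless) or NA.
#' @export
channel_snr <- function(snips, x) {
  if (!inherits(snips, "snippet_set")) abort("`snips` must be a snippet_set.")
  if (length(snips$p2p_uv) == 0L) return(NA_real_)
  noise <- x[snips$noise_idx]
  s <- sd(noise)
  if (!is.finite(s) || s == 0) return(NA_real_)
  mean(snips$p2p_uv) / (6 * s)
}

#' Channel multi-unit activity amplitude
#'
#' Mean of the supra-threshold positive deflections minus mean of the
#' sub-threshold negative deflections of the filtered trace (threshold
#' `k` SD of the full trace). Missing when either deflection set is empty.
#'
#' @param x Filtered channel trace.
#' @param k Threshold multiplier (default 3.5).
#' @return MUA amplitude in microvolts, or NA.
#' @export
channel_mua <- function(x, k = 3.5) {
  s <- sd(x)
  pos <- x[x > k * s]
  neg <- x[x < -k * s]
  if (!length(pos) || !length(neg)) return(NA_real_)
  mean(pos) - mean(neg)
}

# FFT brick-wall low-pass + integer decimation. The 1-300 Hz band-pass is
# numerically unstable in direct form at ~48.8 kHz (poles crowd z = 1), so
# LFP filtering runs at a ~1 kHz decimated rate.
decimate_for_lfp <- function(x, fs_hz, target_fs = 1000) {
  m <- max(1L, floor(fs_hz / target_fs))
  if (m == 1L) return(list(x = x, fs = fs_hz))
  fsd <- fs_hz / m
  n <- length(x)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)
  X[f > fsd / 2 * 0.98] <- 0
  xl <- Re(fft(X, inverse = TRUE)) / n
  list(x = xl[seq(1, n, by = m)], fs = fsd)
}

# Direct-form II transposed IIR with explicit initial state.
iir_df2t <- function(b, a, x, zi) {
  nf <- max(length(b), length(a))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  z <- zi
  y <- numeric(length(x))
  for (i in seq_along(x)) {
    xi <- x[i]
    yi <- b[1] * xi + z[1]
    z <- c(z[-1], 0) + b[-1] * xi - a[-1] * yi
    y[i] <- yi
  }
  y
}

# Steady-state initial filter state for unit step input (per-sample state
# scaled by the boundary value), eliminating start-up transients.
filter_zi <- function(b, a) {
  nf <- max(length(b), length(a))
  b <- c(b, rep(0, nf - length(b))) / a[1]
  a <- c(a, rep(0, nf - length(a))) / a[1]
  n1 <- nf - 1L
  A <- diag(1, n1) - cbind(-a[2:nf], rbind(diag(1, n1 - 1), rep(0, n1 - 1)))
  solve(A, b[2:nf] - b[1] * a[2:nf])
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# matched initial conditions, so boundary transients vanish even for
# narrow-band (high-Q) filters.
filtfilt_zi <- function(b, a, x) {
  nf <- max(length(b), length(a))
  nfact <- 3L * (nf - 1L)
  n <- length(x)
  if (n <= nfact + 1L) abort("Signal too short for zero-phase filtering.")
  zi <- filter_zi(b, a)
  xt <- c(2 * x[1] - x[(nfact + 1):2], x, 2 * x[n] - x[(n - 1):(n - nfact)])
  y <- iir_df2t(b, a, xt, zi * xt[1])
  y <- rev(y)
  y <- iir_df2t(b, a, y, zi * y[1])
  rev(y)[(nfact + 1):(nfact + n)]
}

# Autoregressive (Burg) signal extension: pads both ends with linear
# predictions so narrow-band content continues smoothly across the
# boundary. Keeps the high-Q notch and the 1 Hz band edge from ringing at
# the data edges (reflection padding leaves a DC/phase discontinuity there).
ar_extend <- function(x, np, order = 30) {
  n <- length(x)
  if (var(x) < .Machine$double.eps) {
    return(c(rep(x[1], np), x, rep(x[n], np)))
  }
  order <- min(order, n - 1L)
  fit_r <- stats::ar(x, aic = FALSE, order.max = order, method = "burg")
  right <- as.numeric(stats::predict(fit_r, n.ahead = np, se.fit = FALSE))
  fit_l <- stats::ar(rev(x), aic = FALSE, order.max = order, method = "burg")
  left <- rev(as.numeric(stats::predict(fit_l, n.ahead = np,
                                        se.fit = FALSE)))
  c(left, x, right)
}

# 60 Hz biquad notch (RBJ), quality factor Q.
notch_coefficients <- function(fs_hz, f0 = 60, q = 30) {
  w0 <- 2 * pi * f0 / fs_hz
  al <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + al)
  a <- c(1, -2 * cos(w0) / (1 + al), (1 - al) / (1 + al))
  list(b = b, a = a)
}

#' Channel LFP amplitude
#'
#' The raw (not CAR-subtracted) channel is passed through a 60 Hz notch
#' (2nd-order IIR, Q = 30) and a 1-300 Hz 4th-order Butterworth band-pass,
#' both applied forward-backward; the LFP amplitude is six times the SD of
#' the filtered trace. Filtering runs at a ~1 kHz decimated rate (see
#' Details in the package vignette) with an FFT anti-alias stage.
#'
#' @param x Raw channel trace (uV).
#' @param fs_hz Sampling rate (must be >= 600 Hz).
#' @return LFP amplitude in microvolts.
#' @export
channel_lfp_amplitude <- function(x, fs_hz) {
  if (fs_hz < 600) abort("`fs_hz` must be at least 600 Hz for the LFP band.")
  if (all(x == 0)) return(0)
  dec <- decimate_for_lfp(x, fs_hz)
  n <- length(dec$x)
  np <- min(n - 1L, 2000L)
  xp <- ar_extend(dec$x, np)
  nc <- notch_coefficients(dec$fs)
  xn <- filtfilt_zi(nc$b, nc$a, xp)
  bf <- signal::butter(4, c(1, 300) / (dec$fs / 2), type = "pass")
  xf <- filtfilt_zi(bf$b, bf$a, xn)[(np + 1):(np + n)]
  6 * sd(xf)
}

#' Per-implant recording-quality metrics
#'
#' Runs the full per-channel algorithm — CAR subtraction, 500-6000 Hz
#' band-pass, +/-3.5 SD snippet detection, noise-floor RMS channel inclusion
#' (0.3-2x array mean), SNR and MUA amplitude per channel, and the 1-300 Hz
#' LFP amplitude on the raw signal — then averages SNR, MUA, and LFP across
#' included channels with defined values.
#'
#' @param rec An `ephys_recording` (full array).
#' @param k Detection threshold multiplier (default 3.5).
#' @return An `implant_metrics` object: list with `channels` (per-channel
#'   tibble: channel, noise_rms_uv, included, n_snippets, snr, mua_uv,
#'   lfp_uv) and `implant` (one-row tibble: snr_avg, mua_avg_uv, lfp_avg_uv,
#'   n_included).
#' @export
implant_metrics <- function(rec, k = 3.5) {
  check_recording(rec)
  raw <- rec$signal
  filt <- bandpass_spike(car_subtract(rec))$signal
  nch <- nrow(raw)
  res <- purrr::map(seq_len(nch), function(ch) {
    x <- filt[ch, ]
    snips <- detect_snippets(x, rec$fs_hz, k = k)
    noise <- x[snips$noise_idx]
    tibble::tibble(
      channel = rec$channels[ch],
      noise_rms_uv = sqrt(mean(noise^2)),
      n_snippets = length(snips$p2p_uv),
      snr = channel_snr(snips, x),
      mua_uv = channel_mua(x, k = k),
      lfp_uv = channel_lfp_amplitude(raw[ch, ], rec$fs_hz)
    )
  })
  channels <- dplyr::bind_rows(res)
  channels$included <- channel_inclusion(channels$noise_rms_uv)
  channels <- dplyr::relocate(channels, "included", .after = "noise_rms_uv")
  if (!any(channels$included)) {
    abort("All channels excluded by the noise-floor inclusion rule.")
  }
  inc <- channels[channels$included, , drop = FALSE]
  implant <- tibble::tibble(
    snr_avg = mean(inc$snr, na.rm = TRUE),
    mua_avg_uv = mean(inc$mua_uv, na.rm = TRUE),
    lfp_avg_uv = mean(inc$lfp_uv, na.rm = TRUE),
    n_included = sum(channels$included)
  )
  structure(list(channels = channels, implant = implant),
            class = "implant_metrics")
}

#' @export
print.implant_metrics <- function(x, ...) {
  cat(sprintf(
    "<implant_metrics> %d/%d channels included; SNR %.2f, MUA %.1f uV, LFP %.1f uV\n",
    x$implant$n_included, nrow(x$channels), x$implant$snr_avg,
    x$implant$mua_avg_uv, x$implant$lfp_avg_uv))
  invisible(x)
}

#' @export
tidy.implant_metrics <- function(x, ...) x$channels

#' @export
glance.implant_metrics <- function(x, ...) x$implant
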