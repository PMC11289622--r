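#' Simulation configuration for a spot dataset
#'
#' Describes a Visium-like rectangular spot lattice with a planted tract.
#' Counts are negative-binomially distributed with per-spot expected depth
#' drawn lognormally around `mean_depth` (coefficient of variation
#' `depth_cv`), emulating the severalfold spread of total UMI counts across
#' capture spots at high sequencing depth.
#'
#' @param grid_shape Integer pair, spots per axis (rows, cols).
#' @param spot_pitch_um Center-to-center spacing in micrometres (default 100,
#'   the lattice pitch the annular bin width matches).
#' @param tract_center_um Planar tract coordinate; defaults to the lattice
#'   spot nearest the grid center.
#' @param mean_depth Expected UMI per spot (default 50000, the recommended
#'   sequencing-depth benchmark).
#' @param depth_cv Coefficient of variation of per-spot expected depth
#'   (default 0.4).
#' @param dispersion Negative-binomial dispersion phi >= 0 (variance
#'   m + phi m^2); 0 means Poisson. Default 0.02.
#' @param seed RNG seed; identical seeds give identical outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(grid_shape = c(30, 30), spot_pitch_um = 100,
                       tract_center_um = NULL, mean_depth = 5e4,
                       depth_cv = 0.4, dispersion = 0.02, seed = 1) {
  if (length(grid_shape) != 2L || any(grid_shape < 1) ||
      any(grid_shape != round(grid_shape))) {
    abort("`grid_shape` must be two positive integers.")
  }
  assert_positive_scalar(spot_pitch_um, "spot_pitch_um")
  assert_positive_scalar(mean_depth, "mean_depth")
  assert_nonneg_scalar(dispersion, "dispersion")
  assert_nonneg_scalar(depth_cv, "depth_cv")
  if (is.null(tract_center_um)) {
    tract_center_um <- (floor((grid_shape - 1) / 2)) * spot_pitch_um
    tract_center_um <- rev(tract_center_um)  # (x from cols, y from rows)
  }
  if (length(tract_center_um) != 2L || !all(is.finite(tract_center_um))) {
    abort("`tract_center_um` must be a finite length-2 coordinate.")
  }
  structure(
    list(grid_shape = as.integer(grid_shape), spot_pitch_um = spot_pitch_um,
         tract_center_um = as.numeric(tract_center_um),
         mean_depth = mean_depth, depth_cv = depth_cv,
         dispersion = dispersion, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Gene panel specification
#'
#' Each gene has a baseline expression proportion (its expected fraction of a
#' spot's UMIs far from the tract), a multiplicative fold change at the tract
#' (`effect_amplitude`, 1 for no radial effect), an exponential decay length
#' of the radial effect, and a role. The radial proportion is
#' `baseline_prop * (1 + (effect_amplitude - 1) * exp(-d / decay_um))`,
#' renormalized per spot so proportions sum to 1 at every distance.
#'
#' The default panel carries the field's canonical markers: `Gfap`
#' (astrocyte reactivity, strongly up-regulated at the tract), `Snap25`
#' (neuronal, down-regulated), a handful of inflammation-associated
#' up-markers, the housekeeping pair `Gapdh`/`Actb`, and neutral filler genes
#' with a long-tailed baseline-abundance distribution.
#'
#' @param n_genes Panel size (default 200).
#' @param up_amplitude Fold change of the lead up-marker (default 8).
#' @param down_amplitude Fold change of the lead down-marker (default 0.4).
#' @param decay_um Radial decay length (default 150).
#' @return A tibble with columns `gene`, `baseline_prop`, `effect_amplitude`,
#'   `decay_um`, `role`; baseline proportions sum to 1.
#' @export
gene_panel <- function(n_genes = 200, up_amplitude = 8, down_amplitude = 0.4,
                       decay_um = 150) {
  if (n_genes < 10) abort("`n_genes` must be at least 10.")
  named <- tibble::tibble(
    gene = c("Gfap", "Hspb1", "Lcn2", "C3", "Snap25", "Syp", "Gapdh", "Actb"),
    effect_amplitude = c(up_amplitude, 6, 5, 4, down_amplitude, 0.5, 1, 1),
    decay_um = decay_um,
    role = c("up_marker", "up_marker", "up_marker", "up_marker",
             "down_marker", "down_marker", "housekeeping", "housekeeping")
  )
  n_neutral <- n_genes - nrow(named)
  neutral <- tibble::tibble(
    gene = sprintf("Gene%04d", seq_len(n_neutral)),
    effect_amplitude = 1,
    decay_um = decay_um,
    role = "neutral"
  )
  panel <- dplyr::bind_rows(named, neutral)
  # long-tailed but deterministic baseline abundances (Zipf-like)
  w <- 1 / (seq_len(n_genes) + 10)
  # housekeeping genes get high abundance, as in tissue
  w[panel$role == "housekeeping"] <- max(w) * 3
  panel$baseline_prop <- w / sum(w)
  validate_panel(panel)
}

validate_panel <- function(panel) {
  if (!is.data.frame(panel) ||
      !all(c("gene", "baseline_prop", "effect_amplitude", "decay_um",
             "role") %in% names(panel))) {
    abort(paste("`panel` must have columns gene, baseline_prop,",
                "effect_amplitude, decay_um, role."))
  }
  if (nrow(panel) == 0L) abort("`panel` must be non-empty.")
  if (anyDuplicated(panel$gene)) abort("Panel gene names must be unique.")
  with(panel, {
    if (any(!is.finite(baseline_prop)) || any(baseline_prop <= 0)) {
      abort("`baseline_prop` must be positive and finite.")
    }
    if (sum(baseline_prop) > 1 + 1e-8) {
      abort("Panel baseline proportions sum to more than 1.")
    }
    if (any(!is.finite(effect_amplitude)) || any(effect_amplitude < 0)) {
      abort("`effect_amplitude` must be non-negative and finite.")
    }
    if (any(!is.finite(decay_um)) || any(decay_um <= 0)) {
      abort("`decay_um` must be positive.")
    }
  })
  if (any(panel$role == "housekeeping" & panel$effect_amplitude != 1)) {
    abort("Housekeeping genes must have effect_amplitude = 1.")
  }
  tibble::as_tibble(panel)
}

# Per-spot expression proportions for a panel at distances d (genes x spots),
# renormalized so columns sum to 1.
panel_proportions <- function(panel, d) {
  amp <- outer(panel$effect_amplitude - 1, exp(-d / panel$decay_um[1]))
  # per-gene decay lengths: recompute row-wise when they differ
  if (length(unique(panel$decay_um)) > 1L) {
    amp <- (panel$effect_amplitude - 1) *
      exp(-outer(1 / panel$decay_um, d, function(a, b) a * b))
  }
  p <- panel$baseline_prop * (1 + amp)
  p[p < 0] <- 0
  p <- sweep(p, 2, colSums(p), "/")
  rownames(p) <- panel$gene
  p
}

#' Simulate a spot-level spatial expression dataset
#'
#' Generates a rectangular spot lattice, plants radial expression effects
#' around the tract according to the gene panel, and draws UMI counts from a
#' negative-binomial law `NB(mean = depth_j * p_g(d_j), dispersion phi)`.
#' Housekeeping counts therefore have expectation proportional to spot depth.
#'
#' @param cfg A [sim_config()].
#' @param panel A gene panel (see [gene_panel()]).
#' @return A `spot_dataset`: list with sparse `counts` (genes x spots),
#'   `spots` tibble (`barcode`, `x_um`, `y_um`, `in_tissue`, `artifact`,
#'   `row`, `col`), `tract` ([tract_geometry()]), and a `truth` list
#'   (panel, per-spot expected depth, expected proportion matrix, and the
#'   per-gene true radial mean function `radial_mean(gene, d)`).
#' @export
simulate_spot_dataset <- function(cfg, panel = gene_panel()) {
  if (!inherits(cfg, "sim_config")) abort("`cfg` must be a sim_config.")
  panel <- validate_panel(panel)
  nr <- cfg$grid_shape[1]; nc <- cfg$grid_shape[2]
  grid <- expand.grid(row = seq_len(nr) - 1L, col = seq_len(nc) - 1L)
  spots <- tibble::tibble(
    barcode = sprintf("SPOT-%05d", seq_len(nrow(grid))),
    row = grid$row, col = grid$col,
    x_um = grid$col * cfg$spot_pitch_um,
    y_um = grid$row * cfg$spot_pitch_um,
    in_tissue = TRUE, artifact = FALSE
  )
  tract <- tract_geometry(cfg$tract_center_um)
  d <- sqrt((spots$x_um - tract$center_um[1])^2 +
            (spots$y_um - tract$center_um[2])^2)
  p <- panel_proportions(panel, d)
  counts <- with_seed(cfg$seed, {
    if (cfg$depth_cv > 0) {
      sdlog <- sqrt(log(1 + cfg$depth_cv^2))
      depth <- rlnorm(nrow(spots), log(cfg$mean_depth) - sdlog^2 / 2, sdlog)
    } else {
      depth <- rep(cfg$mean_depth, nrow(spots))
    }
    m <- sweep(p, 2, depth, "*")
    k <- if (cfg$dispersion == 0) {
      rpois(length(m), lambda = m)
    } else {
      rnbinom(length(m), mu = m, size = 1 / cfg$dispersion)
    }
    list(depth = depth,
         mat = matrix(k, nrow = nrow(panel),
                      dimnames = list(panel$gene, spots$barcode)))
  })
  radial_mean <- local({
    pan <- panel; md <- cfg$mean_depth
    function(gene, dist_um) {
      i <- match(gene, pan$gene)
      if (is.na(i)) abort(sprintf("Gene '%s' not in panel.", gene))
      pp <- panel_proportions(pan, dist_um)
      md * pp[i, ]
    }
  })
  structure(
    list(
      counts = Matrix(counts$mat, sparse = TRUE),
      spots = spots,
      tract = tract,
      truth = list(panel = panel, depth = counts$depth, proportions = p,
                   radial_mean = radial_mean)
    ),
    class = "spot_dataset"
  )
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("<spot_dataset> %d genes x %d spots; tract at (%.0f, %.0f) um\n",
              nrow(x$counts), ncol(x$counts),
              x$tract$center_um[1], x$tract$center_um[2]))
  invisible(x)
}

#' Ephys simulation configuration
#'
#' Each channel is composed of spikes at Poisson times (a planted biphasic
#' template), spike-band Gaussian noise, a 60 Hz line sinusoid, a band-limited
#' low-frequency (LFP) component, and an optional common-mode artifact
#' injected identically on all channels.
#'
#' `noise_sd_uv` is the spike-band (500-6000 Hz) noise-floor standard
#' deviation: white noise is shaped with the spike band-pass and rescaled to
#' this SD exactly, so the planted value is the quantity the SNR denominator
#' estimates. The LFP component is brick-wall band-limited to 5-150 Hz, the
#' band where cortical LFP power concentrates, and rescaled to `lfp_sd_uv`
#' exactly.
#'
#' @param fs_hz Sampling rate (default 48828, ~48 kHz).
#' @param duration_s Recording length in seconds.
#' @param n_channels Number of channels (default 16).
#' @param spike_rate_hz Poisson multi-unit event rate per channel
#'   (default 20, typical of aggregate multi-unit activity near a site).
#' @param template Biphasic waveform samples (uV); default is a band-limited
#'   biphasic of ~1 ms scaled to `template_p2p_uv`.
#' @param template_p2p_uv Peak-to-peak amplitude of the default template.
#' @param noise_sd_uv Spike-band noise SD (default 3).
#' @param line_amp_uv 60 Hz sinusoid amplitude (default 0).
#' @param lfp_sd_uv SD of the 5-150 Hz band-limited component (default 50).
#' @param common_artifact_uv Amplitude of a common-mode sinusoidal artifact
#'   shared across channels (default 0).
#' @param seed RNG seed.
#' @return An `ephys_sim_config` list.
#' @export
ephys_sim_config <- function(fs_hz = 48828, duration_s = 10, n_channels = 16,
                             spike_rate_hz = 20, template = NULL,
                             template_p2p_uv = 100, noise_sd_uv = 3,
                             line_amp_uv = 0, lfp_sd_uv = 50,
                             common_artifact_uv = 0, seed = 1) {
  assert_positive_scalar(fs_hz, "fs_hz")
  if (fs_hz <= 12000) abort("`fs_hz` must exceed 12 kHz (band edge 6 kHz).")
  assert_positive_scalar(duration_s, "duration_s")
  if (n_channels < 1) abort("`n_channels` must be >= 1.")
  assert_nonneg_scalar(spike_rate_hz, "spike_rate_hz")
  assert_nonneg_scalar(noise_sd_uv, "noise_sd_uv")
  assert_nonneg_scalar(line_amp_uv, "line_amp_uv")
  assert_nonneg_scalar(lfp_sd_uv, "lfp_sd_uv")
  assert_nonneg_scalar(common_artifact_uv, "common_artifact_uv")
  if (is.null(template)) {
    template <- default_template(fs_hz, template_p2p_uv)
  }
  win <- round(0.0024 * fs_hz)
  if (length(template) >= win) {
    abort("`template` must be shorter than the 2.4 ms snippet window.")
  }
  # expected ISI must exceed two template lengths; warn and clamp otherwise
  max_rate <- fs_hz / (2 * length(template))
  if (spike_rate_hz > max_rate) {
    warn(sprintf("spike_rate_hz clamped from %g to %g (ISI constraint).",
                 spike_rate_hz, max_rate))
    spike_rate_hz <- max_rate
  }
  structure(
    list(fs_hz = fs_hz, duration_s = duration_s, n_channels = n_channels,
         spike_rate_hz = spike_rate_hz, template = template,
         noise_sd_uv = noise_sd_uv, line_amp_uv = line_amp_uv,
         lfp_sd_uv = lfp_sd_uv, common_artifact_uv = common_artifact_uv,
         seed = as.integer(seed)),
    class = "ephys_sim_config"
  )
}

# Biphasic template (~0.8 ms): a 2 kHz Gabor (sine under a Gaussian
# envelope), which concentrates the waveform's energy mid-band so its
# peak-to-peak amplitude is essentially invariant under the 500-6000 Hz
# band-pass (refiltering changes P2P by <0.5%). Pre-shaped with one
# zero-phase pass and rescaled to the requested P2P.
default_template <- function(fs_hz, p2p_uv) {
  n <- round(0.0008 * fs_hz)
  t <- ((seq_len(n) - 1) / fs_hz - 0.0004) * 1e3  # ms, centred
  shape <- sin(2 * pi * 2 * t) * exp(-(t / 0.15)^2)
  pad <- round(0.01 * fs_hz)
  x <- c(rep(0, pad), shape, rep(0, pad))
  xf <- spike_bandpass_filter(x, fs_hz)
  xf <- xf[(pad + 1):(pad + n)]
  xf * p2p_uv / (max(xf) - min(xf))
}

# Brick-wall band-limited Gaussian noise via FFT, rescaled to exact SD.
bandlimited_noise <- function(n, fs_hz, f_lo, f_hi, sd_target) {
  if (sd_target == 0) return(rep(0, n))
  x <- rnorm(n)
  X <- fft(x)
  f <- (seq_len(n) - 1) * fs_hz / n
  f <- pmin(f, fs_hz - f)  # two-sided frequency axis
  X[f < f_lo | f > f_hi] <- 0
  y <- Re(fft(X, inverse = TRUE)) / n
  y * sd_target / sd(y)
}

#' Simulate a multichannel extracellular recording
#'
#' @param cfg An [ephys_sim_config()].
#' @return An `ephys_recording` with `signal` (channels x samples, uV),
#'   `fs_hz`, `channels`, and a `truth` list: per-channel spike sample
#'   indices, the planted template, its peak-to-peak amplitude, and the
#'   per-channel spike-band noise SD.
#' @export
simulate_recording <- function(cfg) {
  if (!inherits(cfg, "ephys_sim_config")) {
    abort("`cfg` must be an ephys_sim_config.")
  }
  n <- round(cfg$duration_s * cfg$fs_hz)
  tpl <- cfg$template
  ntpl <- length(tpl)
  with_seed(cfg$seed, {
    common <- if (cfg$common_artifact_uv > 0) {
      cfg$common_artifact_uv *
        sin(2 * pi * 7 * seq_len(n) / cfg$fs_hz + runif(1, 0, 2 * pi))
    } else rep(0, n)
    sig <- matrix(0, nrow = cfg$n_channels, ncol = n)
    spike_idx <- vector("list", cfg$n_channels)
    noise_sd <- numeric(cfg$n_channels)
    for (ch in seq_len(cfg$n_channels)) {
      x <- rep(0, n)
      # Poisson spike times, kept clear of the edges
      n_spk <- rpois(1, cfg$spike_rate_hz * cfg$duration_s)
      idx <- sort(sample.int(n - 2L * ntpl, n_spk)) + ntpl
      # enforce minimum separation of one template length
      if (length(idx) > 1L) idx <- idx[c(TRUE, diff(idx) > ntpl)]
      for (i in idx) x[i:(i + ntpl - 1L)] <- x[i:(i + ntpl - 1L)] + tpl
      spike_idx[[ch]] <- idx
      if (cfg$noise_sd_uv > 0) {
        nz <- spike_bandpass_filter(rnorm(n), cfg$fs_hz)
        nz <- nz * cfg$noise_sd_uv / sd(nz)
      } else nz <- rep(0, n)
      noise_sd[ch] <- cfg$noise_sd_uv
      lfp <- bandlimited_noise(n, cfg$fs_hz, 5, 150, cfg$lfp_sd_uv)
      line <- if (cfg$line_amp_uv > 0) {
        cfg$line_amp_uv * sin(2 * pi * 60 * seq_len(n) / cfg$fs_hz)
      } else 0
      sig[ch, ] <- x + nz + lfp + line + common
    }
    structure(
      list(signal = sig, fs_hz = cfg$fs_hz,
           channels = seq_len(cfg$n_channels),
           truth = list(spike_idx = spike_idx, template = tpl,
                        template_p2p_uv = max(tpl) - min(tpl),
                        noise_sd_uv = noise_sd)),
      class = "ephys_recording"
    )
  })
}

#' @export
print.ephys_recording <- function(x, ...) {
  cat(sprintf("<ephys_recording> %d channels x %d samples at %.0f Hz\n",
              nrow(x$signal), ncol(x$signal), x$fs_hz))
  invisible(x)
}

#' Simulate an IHC sample: neuron centroids and a GFAP intensity field
#'
#' Neuron centroids follow an inhomogeneous Poisson process with intensity
#' `density_far * (1 - exp(-d / suppression_radius_um))` (cell loss near the
#' tract); the intensity field is
#' `gfap_baseline + gfap_peak * exp(-d / gfap_decay_um)` plus Gaussian pixel
#' noise (elevated astrocyte reactivity at the interface).
#'
#' @param tract A [tract_geometry()].
#' @param density_far Far-field neuronal density, neurons/mm^2 (default 1500).
#' @param suppression_radius_um Decay length of neuronal suppression
#'   (default 100).
#' @param gfap_baseline Baseline intensity (default 100, arbitrary units).
#' @param gfap_peak Peak intensity elevation at the tract (default 150).
#' @param gfap_decay_um Intensity decay length (default 100).
#' @param noise_sd Pixel noise SD (default 10).
#' @param extent_um Half-width of the square field around the tract
#'   (default 500).
#' @param pixel_um Pixel pitch of the intensity field (default 5).
#' @param seed RNG seed.
#' @return List with `points` (tibble `x_um`, `y_um`) and `field` (tibble
#'   `x_um`, `y_um`, `intensity`).
#' @export
simulate_ihc_sample <- function(tract, density_far = 1500,
                                suppression_radius_um = 100,
                                gfap_baseline = 100, gfap_peak = 150,
                                gfap_decay_um = 100, noise_sd = 10,
                                extent_um = 500, pixel_um = 5, seed = 1) {
  assert_positive_scalar(density_far, "density_far")
  assert_positive_scalar(suppression_radius_um, "suppression_radius_um")
  assert_positive_scalar(gfap_decay_um, "gfap_decay_um")
  assert_nonneg_scalar(gfap_peak, "gfap_peak")
  assert_nonneg_scalar(noise_sd, "noise_sd")
  cx <- tract$center_um[1]; cy <- tract$center_um[2]
  with_seed(seed, {
    # homogeneous Poisson at density_far over the window, thinned by the
    # radial suppression profile
    area_mm2 <- (2 * extent_um / 1e3)^2
    n0 <- rpois(1, density_far * area_mm2)
    px <- runif(n0, cx - extent_um, cx + extent_um)
    py <- runif(n0, cy - extent_um, cy + extent_um)
    d <- point_distances(px, py, tract)
    keep <- runif(n0) < (1 - exp(-d / suppression_radius_um))
    points <- tibble::tibble(x_um = px[keep], y_um = py[keep])
    gx <- seq(cx - extent_um + pixel_um / 2, cx + extent_um, by = pixel_um)
    gy <- seq(cy - extent_um + pixel_um / 2, cy + extent_um, by = pixel_um)
    g <- expand.grid(x_um = gx, y_um = gy)
    gd <- point_distances(g$x_um, g$y_um, tract)
    field <- tibble::tibble(
      x_um = g$x_um, y_um = g$y_um,
      intensity = gfap_baseline + gfap_peak * exp(-gd / gfap_decay_um) +
        rnorm(nrow(g), 0, noise_sd)
    )
    list(points = points, field = field)
  })
}

#' Cohort ground-truth specification
#'
#' Defines the planted linear relationships between electrode-site gene
#' expression and the recording-quality / histology metrics:
#' `metric = alpha + sum(beta_g * x_g) + eps`, where `x_g` is the planted
#' electrode-site MNA of gene `g` for that sample.
#'
#' @param betas Tibble with columns `gene`, `metric`
#'   (one of MUA, LFP, SNR, GFAP, ND), `beta`.
#' @param alpha Named numeric of intercepts per metric (defaults chosen at
#'   realistic scales: MUA ~60 uV, LFP ~300 uV, SNR ~4, GFAP ~150 a.u.,
#'   ND ~1200 mm^-2).
#' @param noise_sd Named numeric of metric noise SDs (defaults ~5% of alpha).
#' @param amp_cv Lognormal coefficient of variation of per-sample marker
#'   effect amplitudes, the between-animal variability that makes site
#'   expression an informative regressor (default 0.5).
#' @param shared_latent Optional character vector of genes whose per-sample
#'   amplitude scatter is driven by one common draw per sample, modelling
#'   correlated markers of the same underlying foreign-body-response
#'   severity.
#' @return A `cohort_truth_spec` list.
#' @export
cohort_truth_spec <- function(betas = NULL,
                              alpha = c(MUA = 60, LFP = 300, SNR = 4,
                                        GFAP = 150, ND = 1200),
                              noise_sd = NULL, amp_cv = 0.5,
                              shared_latent = NULL) {
  metrics <- c("MUA", "LFP", "SNR", "GFAP", "ND")
  if (is.null(betas)) {
    betas <- tibble::tibble(gene = character(), metric = character(),
                            beta = numeric())
  }
  betas <- tibble::as_tibble(betas)
  if (nrow(betas) && !all(betas$metric %in% metrics)) {
    abort("`betas$metric` must be one of MUA, LFP, SNR, GFAP, ND.")
  }
  if (is.null(noise_sd)) noise_sd <- 0.05 * abs(alpha)
  if (!all(metrics %in% names(alpha)) || !all(metrics %in% names(noise_sd))) {
    abort("`alpha` and `noise_sd` must name all five metrics.")
  }
  structure(list(betas = betas, alpha = alpha, noise_sd = noise_sd,
                 amp_cv = amp_cv, shared_latent = shared_latent),
            class = "cohort_truth_spec")
}

#' Simulate a multi-sample cohort with planted gene-metric relationships
#'
#' Implanted samples (default 9: 3 per timepoint at 24 h, 1 week, 6 weeks)
#' each get a simulated spot dataset whose marker effect amplitudes vary
#' between animals, plus metric values generated from the planted linear
#' model on the expected electrode-site MNA values. Naive samples have no
#' tract effect and carry no recording metrics.
#'
#' @param n_implanted Number of implanted samples (>= 3; default 9).
#' @param n_naive Number of naive samples (default 3).
#' @param panel Gene panel.
#' @param truth_spec A [cohort_truth_spec()].
#' @param cfg Template [sim_config()] (per-sample seeds are derived from its
#'   seed).
#' @param rmax_um Electrode-site radius used for the planted site MNA
#'   (default 300).
#' @param timepoint_effect Named multipliers applied to the log-scale tract
#'   effect per timepoint, emulating the resolution of differential
#'   expression over the post-implantation time course (default 24h = 1,
#'   1wk = 0.7, 6wk = 0.4).
#' @return A `cohort`: list with `samples` (list of per-sample lists:
#'   `dataset`, `timepoint`, `implanted`, `site`), `metrics` tibble (sample,
#'   timepoint, MUA, LFP, SNR, GFAP, ND; NA for naive), and `truth` (planted
#'   site MNA matrix `x` genes x samples, the spec, per-sample amplitudes).
#' @export
simulate_cohort <- function(n_implanted = 9, n_naive = 3,
                            panel = gene_panel(),
                            truth_spec = cohort_truth_spec(),
                            cfg = sim_config(grid_shape = c(10, 10)),
                            rmax_um = 300,
                            timepoint_effect = c("24h" = 1, "1wk" = 0.7,
                                                 "6wk" = 0.4)) {
  if (n_implanted < 3) abort("`n_implanted` must be >= 3.")
  panel <- validate_panel(panel)
  if (!inherits(truth_spec, "cohort_truth_spec")) {
    abort("`truth_spec` must be a cohort_truth_spec.")
  }
  missing_genes <- setdiff(c(truth_spec$betas$gene,
                             truth_spec$shared_latent), panel$gene)
  if (length(missing_genes)) {
    abort(sprintf("truth_spec names genes absent from panel: %s.",
                  paste(missing_genes, collapse = ", ")))
  }
  timepoints <- rep(c("24h", "1wk", "6wk"), length.out = n_implanted)
  metrics <- c("MUA", "LFP", "SNR", "GFAP", "ND")
  sdlog <- sqrt(log(1 + truth_spec$amp_cv^2))
  samples <- list()
  x_list <- list()
  amp_list <- list()
  met_rows <- list()
  variable <- panel$role %in% c("up_marker", "down_marker")
  for (i in seq_len(n_implanted)) {
    seed_i <- cfg$seed + 1000L * i
    pan_i <- panel
    amp_mult <- with_seed(seed_i + 1L, {
      m <- rep(1, nrow(panel))
      m[variable] <- rlnorm(sum(variable), -sdlog^2 / 2, sdlog)
      if (!is.null(truth_spec$shared_latent)) {
        shared <- panel$gene %in% truth_spec$shared_latent
        m[shared] <- rlnorm(1, -sdlog^2 / 2, sdlog)
      }
      m
    })
    # amplitude scatter and the timepoint decay act on the fold effect,
    # preserving direction
    tp_scale <- timepoint_effect[[timepoints[i]]] %||% 1
    pan_i$effect_amplitude <- 1 +
      (panel$effect_amplitude - 1) * amp_mult * tp_scale
    pan_i$effect_amplitude[pan_i$effect_amplitude < 0.01] <- 0.01
    cfg_i <- cfg
    cfg_i$seed <- seed_i
    ds <- simulate_spot_dataset(cfg_i, pan_i)
    site <- select_cluster(ds$spots, ds$tract, rmax_um = rmax_um,
                           name = sprintf("sample%02d_site", i))
    # planted site MNA: expected depth times mean cluster proportion
    sp <- spot_distances(ds$spots, ds$tract)
    in_site <- sp$barcode %in% site$barcodes
    x_g <- cfg$mean_depth * rowMeans(ds$truth$proportions[, in_site,
                                                          drop = FALSE])
    x_list[[i]] <- x_g
    amp_list[[i]] <- pan_i$effect_amplitude
    eps <- with_seed(seed_i + 2L,
                     rnorm(length(metrics), 0, truth_spec$noise_sd[metrics]))
    names(eps) <- metrics
    mvals <- vapply(metrics, function(m) {
      b <- truth_spec$betas[truth_spec$betas$metric == m, , drop = FALSE]
      contrib <- if (nrow(b)) sum(b$beta * x_g[b$gene]) else 0
      truth_spec$alpha[[m]] + contrib + eps[[m]]
    }, numeric(1))
    samples[[i]] <- list(dataset = ds, timepoint = timepoints[i],
                         implanted = TRUE, site = site)
    met_rows[[i]] <- tibble::tibble(
      sample = sprintf("implant%02d", i), timepoint = timepoints[i],
      MUA = mvals[["MUA"]], LFP = mvals[["LFP"]], SNR = mvals[["SNR"]],
      GFAP = mvals[["GFAP"]], ND = mvals[["ND"]]
    )
  }
  for (j in seq_len(n_naive)) {
    pan_n <- panel
    pan_n$effect_amplitude <- 1  # no tract effect in naive tissue
    cfg_n <- cfg
    cfg_n$seed <- cfg$seed + 1000L * (n_implanted + j)
    ds <- simulate_spot_dataset(cfg_n, pan_n)
    samples[[n_implanted + j]] <- list(dataset = ds, timepoint = "naive",
                                       implanted = FALSE, site = NULL)
    met_rows[[n_implanted + j]] <- tibble::tibble(
      sample = sprintf("naive%02d", j), timepoint = "naive",
      MUA = NA_real_, LFP = NA_real_, SNR = NA_real_,
      GFAP = NA_real_, ND = NA_real_
    )
  }
  x <- do.call(cbind, x_list)
  dimnames(x) <- list(panel$gene, sprintf("implant%02d", seq_len(n_implanted)))
  names(samples) <- c(sprintf("implant%02d", seq_len(n_implanted)),
                      if (n_naive > 0) sprintf("naive%02d", seq_len(n_naive)))
  structure(
    list(samples = samples,
         metrics = dplyr::bind_rows(met_rows),
         truth = list(x = x, spec = truth_spec,
                      amplitudes = do.call(cbind, amp_list))),
    class = "cohort"
  )
}

#' @export
print.cohort <- function(x, ...) {
  n_imp <- sum(vapply(x$samples, function(s) s$implanted, logical(1)))
  cat(sprintf("<cohort> %d implanted + %d naive samples\n",
              n_imp, length(x$samples) - n_imp))
  invisible(x)
}
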