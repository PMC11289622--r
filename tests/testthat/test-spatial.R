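test_that("spot distances: point tract, translation invariance, units", {
  spots <- tibble::tibble(barcode = c("a", "b", "c"),
                          x_um = c(0, 300, 10), y_um = c(0, 400, 0))
  tr <- tract_geometry(c(0, 0))
  d <- spot_distances(spots, tr)$dist_um
  expect_equal(d, c(0, 500, 10))

  # translating spots and tract together leaves distances unchanged
  shift <- c(123.4, -77.9)
  spots2 <- dplyr::mutate(spots, x_um = x_um + shift[1],
                          y_um = y_um + shift[2])
  tr2 <- tract_geometry(shift)
  expect_equal(spot_distances(spots2, tr2)$dist_um, d, tolerance = 1e-9)
})

test_that("polygon tract distance matches dense edge-sampling oracle", {
  # 100 um square tract
  poly <- rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100))
  tr <- tract_geometry(c(50, 50), polygon = poly)
  spots <- tibble::tibble(
    barcode = sprintf("s%d", 1:4),
    x_um = c(150, 50, 50, 180), y_um = c(50, 50, -30, 180)
  )
  d <- spot_distances(spots, tr)$dist_um
  expect_equal(d[1], 50)   # 50 um outside the right edge
  expect_equal(d[2], 0)    # inside
  expect_equal(d[3], 30)
  # brute force: min distance over densely sampled boundary points
  edges <- rbind(poly, poly[1, ])
  samp <- do.call(rbind, lapply(1:4, function(i) {
    t <- seq(0, 1, length.out = 4001)
    cbind(edges[i, 1] + t * (edges[i + 1, 1] - edges[i, 1]),
          edges[i, 2] + t * (edges[i + 1, 2] - edges[i, 2]))
  }))
  brute <- apply(as.matrix(spots[, c("x_um", "y_um")]), 1, function(p) {
    min(sqrt((samp[, 1] - p[1])^2 + (samp[, 2] - p[2])^2))
  })
  brute[2] <- 0
  expect_equal(d, brute, tolerance = 0.1)
})

test_that("bin assignment follows the half-open floor rule and matches a histogram oracle", {
  expect_equal(assign_bins(150, 100)$bin, 1L)
  expect_equal(assign_bins(100, 100)$bin, 1L)  # boundary goes up
  expect_equal(assign_bins(99.999, 100)$bin, 0L)

  withr::with_seed(7, {
    d <- runif(1000, 0, 1000)
  })
  b <- assign_bins(d, 100, max_radius_um = 1000)
  expect_false(anyNA(b$bin))
  counts <- table(factor(b$bin, levels = 0:9))
  oracle <- hist(d, breaks = seq(0, 1000, by = 100), right = FALSE,
                 plot = FALSE)$counts
  expect_equal(as.integer(counts), oracle)
  expect_equal(sum(counts), 1000L)

  # outside marking partitions eligible spots
  b2 <- assign_bins(d, 100, max_radius_um = 500)
  expect_equal(sum(!is.na(b2$bin)) + sum(is.na(b2$bin)), 1000L)
  expect_true(all(b2$dist_um[is.na(b2$bin)] >= 500))
})

test_that("electrode-site cluster selection is strict and matches brute force", {
  spots <- toy_spots(11, 11)
  tr <- tract_geometry(c(500, 500))
  cl <- select_cluster(spots, tr, rmax_um = 300)
  d <- sqrt((spots$x_um - 500)^2 + (spots$y_um - 500)^2)
  expect_setequal(cl$barcodes, spots$barcode[d < 300])
  # boundary: d = 300 excluded, 299.9 included
  spots2 <- tibble::tibble(barcode = c("in", "out"),
                           x_um = c(299.9, 300), y_um = 0)
  cl2 <- select_cluster(spots2, tract_geometry(c(0, 0)))
  expect_equal(cl2$barcodes, "in")
  # artifact spots are never members; all-artifact input errors
  spots3 <- dplyr::mutate(spots, artifact = TRUE)
  expect_error(select_cluster(spots3, tr), "empty")
})

test_that("naive sites are disjoint, seeded, and match a disc filter", {
  spots <- toy_spots(30, 30)
  sites <- select_naive_sites(spots, n_sites = 3, radius_um = 300, seed = 5)
  centers <- do.call(rbind, lapply(sites, function(s) s$center_um))
  dmat <- as.matrix(dist(centers))
  expect_true(all(dmat[upper.tri(dmat)] > 600))
  # membership equals brute-force disc filter
  for (s in sites) {
    d <- sqrt((spots$x_um - s$center_um[1])^2 +
              (spots$y_um - s$center_um[2])^2)
    expect_setequal(s$barcodes, spots$barcode[d < 300])
  }
  # determinism
  sites2 <- select_naive_sites(spots, n_sites = 3, radius_um = 300, seed = 5)
  expect_identical(centers,
                   do.call(rbind, lapply(sites2, function(s) s$center_um)))
  # pairwise disjointness across a seed sweep
  for (seed in 1:25) {
    ss <- select_naive_sites(spots, n_sites = 3, radius_um = 300, seed = seed)
    cc <- do.call(rbind, lapply(ss, function(s) s$center_um))
    dm <- as.matrix(dist(cc))
    expect_true(all(dm[upper.tri(dm)] > 600))
  }
  # tissue too small -> error
  expect_error(select_naive_sites(toy_spots(3, 3), n_sites = 3,
                                  radius_um = 300, seed = 1, max_tries = 50),
               "non-overlapping")
})

test_that("neuronal density profile recovers CSR rate and single points", {
  tr <- tract_geometry(c(0, 0))
  # single point at d = 50
  prof <- neuronal_density_profile(
    tibble::tibble(x_um = 50, y_um = 0), tr, max_radius_um = 300)
  expect_equal(prof$n, c(1L, 0L, 0L))
  # homogeneous Poisson: every bin within 3 SE of the rate
  lambda <- 2000  # mm^-2
  withr::with_seed(9, {
    ext <- 1000
    n0 <- rpois(1, lambda * (2 * ext / 1e3)^2)
    pts <- tibble::tibble(x_um = runif(n0, -ext, ext),
                          y_um = runif(n0, -ext, ext))
  })
  prof2 <- neuronal_density_profile(pts, tr, max_radius_um = 900)
  se <- sqrt(lambda / prof2$area_mm2)
  expect_true(all(abs(prof2$value - lambda) <= 3 * se))
})

test_that("simulated neuronal suppression yields rising density over the first bins", {
  tr <- tract_geometry(c(0, 0))
  rising <- vapply(1:30, function(seed) {
    s <- simulate_ihc_sample(tr, density_far = 3000,
                             suppression_radius_um = 150, seed = seed)
    prof <- neuronal_density_profile(s$points, tr, max_radius_um = 300)
    all(diff(prof$value) >= 0)
  }, logical(1))
  expect_gte(mean(rising), 0.9)
})

test_that("intensity profile: constant field, analytic decay, missing bins", {
  tr <- tract_geometry(c(0, 0))
  g <- expand.grid(x_um = seq(-300, 300, by = 2),
                   y_um = seq(-300, 300, by = 2))
  const <- tibble::tibble(x_um = g$x_um, y_um = g$y_um, intensity = 7)
  prof <- intensity_profile(const, tr, bin_width_um = 10, max_radius_um = 200)
  expect_true(all(prof$value == 7))

  # exact exponential field vs analytic annulus average
  d <- sqrt(g$x_um^2 + g$y_um^2)
  f <- tibble::tibble(x_um = g$x_um, y_um = g$y_um,
                      intensity = exp(-d / 100))
  prof2 <- intensity_profile(f, tr, bin_width_um = 10, max_radius_um = 250)
  analytic <- vapply(prof2$bin, function(k) {
    lo <- k * 10; hi <- (k + 1) * 10
    # area-weighted mean of exp(-r/100) over the annulus
    num <- integrate(function(r) exp(-r / 100) * 2 * pi * r, lo, hi)$value
    num / (pi * (hi^2 - lo^2))
  }, numeric(1))
  expect_equal(prof2$value, analytic, tolerance = 0.02)

  # a bin with no pixel centers is missing, not zero
  sparse <- tibble::tibble(x_um = c(5, 200), y_um = 0, intensity = c(1, 2))
  prof3 <- intensity_profile(sparse, tr, bin_width_um = 10,
                             max_radius_um = 300)
  expect_true(is.na(prof3$value[5]))
})

test_that("GFAP intensity is elevated at the tract across seeded replicates", {
  tr <- tract_geometry(c(0, 0))
  higher <- vapply(1:30, function(seed) {
    s <- simulate_ihc_sample(tr, gfap_peak = 150, gfap_decay_um = 100,
                             seed = seed)
    prof <- intensity_profile(s$field, tr, bin_width_um = 10,
                              max_radius_um = 300)
    prof$value[1] > prof$value[30]
  }, logical(1))
  expect_gte(mean(higher), 0.95)
  # flat when gfap_peak = 0
  s0 <- simulate_ihc_sample(tr, gfap_peak = 0, noise_sd = 1, seed = 2)
  prof0 <- intensity_profile(s0$field, tr, bin_width_um = 10,
                             max_radius_um = 300)
  expect_lt(max(prof0$value) - min(prof0$value), 3)
})

test_that("summarize_within pools by area and matches raw pooling", {
  # two annuli with values 1 and 2: area-weighted mean = 1.75
  tr <- tract_geometry(c(0, 0))
  prof <- structure(
    tibble::tibble(bin = 0:1, bin_start_um = c(0, 100),
                   bin_end_um = c(100, 200), n = c(1L, 1L),
                   area_mm2 = c(pi * 0.01, 3 * pi * 0.01),
                   value = c(1, 2)),
    class = c("radial_profile", "tbl_df", "tbl", "data.frame"),
    profile_type = "intensity", bin_width_um = 100)
  expect_equal(summarize_within(prof, 200), 1.75)

  # density summary equals brute-force pooling of raw points
  withr::with_seed(21, {
    pts <- tibble::tibble(x_um = runif(500, -400, 400),
                          y_um = runif(500, -400, 400))
  })
  dp <- neuronal_density_profile(pts, tr, max_radius_um = 300)
  pooled <- sum(sqrt(pts$x_um^2 + pts$y_um^2) < 300) / (pi * 0.3^2)
  expect_equal(summarize_within(dp, 300), pooled)

  # incomplete coverage errors
  expect_error(summarize_within(dp, 600), "cover")
})
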