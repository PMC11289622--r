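test_that("DE list consolidation takes the union with max-|LFC| representatives", {
  t1 <- tibble::tibble(gene = c("A", "B"), lfc = c(1.0, 0.8))
  t2 <- tibble::tibble(gene = c("B", "C"), lfc = c(-1.5, 0.7))
  out <- consolidate_de_lists(list(`24h` = t1, `1wk` = t2))
  expect_setequal(out$gene, c("A", "B", "C"))
  expect_equal(out$lfc[out$gene == "B"], -1.5)  # sign preserved
  expect_equal(out$n_timepoints[out$gene == "B"], 2L)

  # disjoint lists: union arithmetic
  lists <- list(a = tibble::tibble(gene = c("g1", "g2", "g3"), lfc = 1),
                b = tibble::tibble(gene = c("g4", "g5"), lfc = 1),
                c = tibble::tibble(gene = "g6", lfc = 1))
  expect_equal(nrow(consolidate_de_lists(lists)), 6)

  # random synthetic lists vs set oracle
  withr::with_seed(3, {
    mk <- function() {
      g <- sample(sprintf("gene%02d", 1:40), sample(5:20, 1))
      tibble::tibble(gene = g, lfc = rnorm(length(g)))
    }
    ls <- list(x = mk(), y = mk(), z = mk())
  })
  out2 <- consolidate_de_lists(ls)
  expect_setequal(out2$gene, unique(unlist(lapply(ls, `[[`, "gene"))))
  # representative lfc via independent loop
  for (g in out2$gene) {
    vals <- unlist(lapply(ls, function(tb) tb$lfc[tb$gene == g]))
    expect_equal(out2$lfc[out2$gene == g],
                 unname(vals[which.max(abs(vals))]))
  }

  # duplicate genes within one table are rejected
  dup <- tibble::tibble(gene = c("A", "A"), lfc = c(1, 2))
  expect_error(consolidate_de_lists(list(dup)), "[Dd]uplicate")
})

test_that("electrode-site expression composes MNA and handles absent genes", {
  panel <- gene_panel(n_genes = 30)
  co <- simulate_cohort(3, 1, panel,
                        cfg = sim_config(grid_shape = c(8, 8), seed = 7))
  expr <- electrode_site_expression(co, c("Gfap", "Snap25"))
  expect_equal(dim(expr), c(2L, 3L))  # naive sample excluded
  # single gene equals mna_normalize mean for that cluster
  s1 <- co$samples[[1]]
  norm <- mna_normalize(s1$dataset$counts, s1$site)
  expect_equal(expr["Gfap", 1], unname(rowMeans(norm$normalized)["Gfap"]))
  # absent gene: zero with one warning per affected sample
  w <- testthat::capture_warnings(
    expr2 <- electrode_site_expression(co, c("Gfap", "Nope")))
  expect_true(all(grepl("absent", w)))
  expect_equal(unname(expr2["Nope", ]), rep(0, 3))
})

test_that("single-gene regression matches the correlation identity and perfect fits", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  r <- suppressWarnings(single_gene_regression(x, 2 * x))
  expect_equal(r$r_squared, 1)
  expect_lt(r$p, 1e-10)
  expect_equal(r$slope, 2)
  # R^2 equals squared Pearson correlation
  withr::with_seed(5, {
    for (i in 1:20) {
      xr <- rnorm(8); yr <- rnorm(8)
      rr <- single_gene_regression(xr, yr)
      expect_equal(rr$r_squared, cor(xr, yr)^2, tolerance = 1e-12)
    }
  })
  # affine rescaling of x and y leaves R^2 unchanged
  withr::with_seed(6, { xr <- rnorm(8); yr <- rnorm(8) })
  r1 <- single_gene_regression(xr, yr)$r_squared
  r2 <- single_gene_regression(10 * xr + 3, 0.1 * yr - 7)$r_squared
  expect_equal(r1, r2, tolerance = 1e-12)
  # zero-variance predictor: NA result with warning
  expect_warning(rz <- single_gene_regression(rep(1, 8), yr), "variance")
  expect_true(is.na(rz$r_squared))
})

test_that("F-test is calibrated under the null at n = 8", {
  hits <- vapply(1:2000, function(seed) {
    withr::with_seed(seed + 5000, {
      x <- rnorm(8); y <- rnorm(8)
    })
    single_gene_regression(x, y)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.035)
  expect_lte(mean(hits), 0.065)
})

test_that("PCA inspection matches an independent eigendecomposition", {
  withr::with_seed(8, mat <- matrix(rnorm(20 * 6), nrow = 20,
                                    dimnames = list(sprintf("g%02d", 1:20),
                                                    sprintf("s%d", 1:6))))
  pc <- pca_inspect(mat)
  # eigen oracle on the gene-space covariance of centred data
  xc <- t(scale(t(mat), center = TRUE, scale = FALSE))
  cv <- tcrossprod(xc) / (ncol(mat) - 1)
  eg <- eigen(cv)
  s1 <- as.numeric(t(xc) %*% eg$vectors[, 1])
  # match up to sign
  expect_lt(min(sum((pc$scores$PC1 - s1)^2), sum((pc$scores$PC1 + s1)^2)),
            1e-16 + 1e-8)
  # identical samples share identical scores
  m2 <- cbind(a = mat[, 1], b = mat[, 1], c = mat[, 2])
  pc2 <- pca_inspect(m2)
  expect_equal(pc2$scores$PC1[1], pc2$scores$PC1[2], tolerance = 1e-10)
  # exact rank-1 data: PC1 explains everything
  r1 <- outer(rnorm(10), c(1, 2, 3))
  rownames(r1) <- sprintf("g%d", 1:10); colnames(r1) <- sprintf("s%d", 1:3)
  expect_equal(pca_inspect(r1)$var_explained[1], 1)
  expect_error(pca_inspect(mat[, 1:2]), "3 samples")
})

test_that("gene-set enumeration is lexicographic, capped, and counts correctly", {
  pool <- c("a", "b", "c", "d")
  sets <- enumerate_gene_sets(pool, sizes = 2)
  expect_length(sets, 6)
  expect_equal(sets[[1]], c("a", "b"))
  expect_warning(capped <- enumerate_gene_sets(pool, sizes = 2, cap = 3),
                 "cap")
  expect_length(capped, 3)
  withr::with_seed(9, {
    for (i in 1:5) {
      p <- sprintf("g%d", seq_len(sample(5:9, 1)))
      k <- sample(2:4, 1)
      expect_length(enumerate_gene_sets(p, sizes = k), choose(length(p), k))
    }
  })
  expect_error(enumerate_gene_sets(pool, sizes = 9), "exceeds")
})

test_that("singleton PCR reproduces single-gene regression exactly", {
  withr::with_seed(10, {
    expr <- matrix(rnorm(8), nrow = 1, dimnames = list("gA", NULL))
    y <- rnorm(8)
  })
  pcr <- gene_set_pcr(expr, y)
  reg <- single_gene_regression(expr[1, ], y)
  expect_equal(pcr$r_squared, reg$r_squared, tolerance = 1e-9)
  expect_equal(pcr$p, reg$p, tolerance = 1e-9)

  # two perfectly correlated genes: PC1 explains all variance, same R^2
  expr2 <- rbind(gA = expr[1, ], gB = 3 * expr[1, ] + 2)
  pcr2 <- gene_set_pcr(expr2, y)
  expect_equal(pcr2$pc1_var_explained, 1)
  expect_equal(pcr2$r_squared, reg$r_squared, tolerance = 1e-9)

  # zero-variance gene dropped with warning
  expr3 <- rbind(expr2, gC = rep(5, 8))
  expect_warning(pcr3 <- gene_set_pcr(expr3, y), "zero-variance")
  expect_equal(pcr3$n_genes, 2)
})

test_that("PCR on a common-factor cohort matches or beats single genes", {
  ok <- vapply(1:50, function(seed) {
    withr::with_seed(seed, {
      f <- rnorm(8)                       # latent factor
      expr <- rbind(g1 = f + rnorm(8, 0, 0.3),
                    g2 = f + rnorm(8, 0, 0.3),
                    g3 = f + rnorm(8, 0, 0.3))
      y <- 2 * f + rnorm(8, 0, 0.3)
    })
    pcr <- gene_set_pcr(expr, y)
    singles <- vapply(1:3, function(i)
      single_gene_regression(expr[i, ], y)$r_squared, numeric(1))
    pcr$r_squared >= max(singles) - 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("candidate selection uses the min-of-normalized-axes rule", {
  res <- tibble::tibble(
    gene = c("dom", "r2only", "lfconly", "mid1", "mid2", "mid3", "mid4"),
    lfc = c(3, 0.1, 2.9, 1.5, 1.6, 1.4, 1.7),
    r_squared = c(0.9, 0.95, 0.05, 0.5, 0.55, 0.45, 0.6),
    p = 0.01
  )
  cs <- select_candidates(res, k = 5)
  expect_equal(cs$gene[1], "dom")  # dominates both axes
  # top R^2 with minimal |lfc| scores zero and is never selected
  expect_false("r2only" %in% cs$gene[cs$selected])
  expect_true(cs$pareto[cs$gene == "dom"])
  expect_error(select_candidates(res, k = 3), "between 4 and 7")
  expect_warning(select_candidates(res[1:4, ], k = 5), "Fewer")
})

test_that("selection recovers planted biomarkers among decoys", {
  hits <- vapply(1:100, function(seed) {
    withr::with_seed(seed + 200, {
      n <- 8
      true_genes <- sprintf("true%d", 1:3)
      # 3 true biomarkers: high |lfc| and a real link to the metric via a
      # shared severity factor (correlated markers of the same response)
      f <- rnorm(n)
      x_true <- matrix(rep(f, each = 3) + rnorm(3 * n, 0, 0.25), nrow = 3,
                       dimnames = list(true_genes, NULL))
      y <- 2 * f + rnorm(n, 0, 0.5)
      # 25 decoys with high lfc but no link, 25 with link but low lfc
      x_dec <- matrix(rnorm(50 * n), nrow = 50,
                      dimnames = list(sprintf("dec%d", 1:50), NULL))
      x_dec[26:50, ] <- rep(y, each = 25) + rnorm(25 * n, 0, 0.5)
      lfc <- c(stats::setNames(runif(3, 2, 3), true_genes),
               stats::setNames(c(runif(25, 2, 3), runif(25, 0.2, 0.5)),
                               sprintf("dec%d", 1:50)))
    })
    expr <- rbind(x_true, x_dec)
    res <- dplyr::bind_rows(lapply(rownames(expr), function(g) {
      r <- single_gene_regression(expr[g, ], y, gene = g)
      r$lfc <- lfc[[g]]
      r
    }))
    cs <- select_candidates(res, k = 5)
    all(sprintf("true%d", 1:3) %in% cs$gene[cs$selected])
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("predicted metrics reproduce stored R^2 and degenerate fits", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 8)
  y <- 3 + 0.5 * x
  r <- suppressWarnings(single_gene_regression(x, y))
  fit <- predict_metric(r)
  expect_equal(fit$fitted, fit$actual, tolerance = 1e-12)
  withr::with_seed(12, { xr <- rnorm(8); yr <- rnorm(8) })
  r2 <- single_gene_regression(xr, yr)
  fit2 <- predict_metric(r2)
  expect_equal(attr(fit2, "r_squared"), r2$r_squared, tolerance = 1e-12)
  # mean-only model: x orthogonal to y gives slope 0 and fitted = mean(y)
  x0 <- c(-2, -1, 1, 2, -2, -1, 1, 2)
  y0 <- c(1, 1, 1, 1, -1, -1, -1, -1)
  r3 <- single_gene_regression(x0, y0)
  expect_equal(r3$slope, 0)
  fit3 <- predict_metric(r3)
  expect_equal(fit3$fitted, rep(mean(y0), 8))
  expect_equal(fit3$residual, fit3$actual - fit3$fitted)
})

test_that("the full screen ranks planted cohort biomarkers highly", {
  panel <- gene_panel(n_genes = 40)
  spec <- cohort_truth_spec(
    betas = tibble::tibble(gene = c("Gfap", "Hspb1"),
                           metric = c("GFAP", "MUA"),
                           beta = c(0.08, 0.05)),
    noise_sd = c(MUA = 2, LFP = 15, SNR = 0.2, GFAP = 4, ND = 60))
  co <- simulate_cohort(8, 1, panel, truth_spec = spec,
                        cfg = sim_config(grid_shape = c(10, 10), seed = 31))
  consolidated <- tibble::tibble(
    gene = c("Gfap", "Hspb1", "Lcn2", "C3", "Snap25", "Syp"),
    lfc = c(2.8, 2.4, 2.1, 1.8, -1.2, -0.9))
  expr <- electrode_site_expression(co, consolidated$gene)
  scr <- biomarker_screen(expr, co$metrics, consolidated, k = 4)
  expect_true("Gfap" %in%
    scr$candidates$GFAP$gene[scr$candidates$GFAP$selected])
  expect_s3_class(autoplot(scr$candidates$GFAP), "ggplot")
})
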