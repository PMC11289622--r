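#' Consolidate per-timepoint significant DE gene lists
#'
#' Takes the union of gene symbols across timepoints. For genes significant
#' at more than one timepoint, the representative LFC is the per-timepoint
#' value of largest magnitude with its sign preserved (so strong
#' down-regulation is not discarded); provenance is retained.
#'
#' @param tables Named list of significant DE tables (one per timepoint),
#'   each with `gene` and `lfc` columns.
#' @return A tibble `gene`, `lfc` (representative), `n_timepoints`,
#'   `timepoints` (comma-separated sources), `lfc_by_timepoint` (list
#'   column).
#' @export
consolidate_de_lists <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L) {
    abort("`tables` must be a non-empty list of DE tables.")
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("timepoint", seq_along(tables))
  }
  long <- purrr::imap(tables, function(tb, tp) {
    if (!all(c("gene", "lfc") %in% names(tb))) {
      abort(sprintf("Table '%s' lacks `gene`/`lfc` columns.", tp))
    }
    if (anyDuplicated(tb$gene)) {
      abort(sprintf("Duplicate genes within table '%s'.", tp))
    }
    tibble::tibble(gene = tb$gene, lfc = tb$lfc, timepoint = tp)
  })
  long <- dplyr::bind_rows(long)
  out <- long |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      lfc_by_timepoint = list(stats::setNames(.data$lfc, .data$timepoint)),
      n_timepoints = dplyr::n(),
      timepoints = paste(.data$timepoint, collapse = ","),
      .groups = "drop"
    )
  out$lfc <- vapply(out$lfc_by_timepoint,
                    function(v) v[[which.max(abs(v))]], numeric(1))
  out <- out[, c("gene", "lfc", "n_timepoints", "timepoints",
                 "lfc_by_timepoint")]
  dplyr::arrange(out, dplyr::desc(abs(.data$lfc)))
}

#' Electrode-site gene x sample MNA matrix
#'
#' For each implanted sample, genes' MNA values over the sample's <= 300 um
#' electrode-site cluster. Naive samples (no site) are excluded. Genes
#' absent from a sample's feature list are recorded as 0 with a warning.
#'
#' @param cohort A `cohort` from [simulate_cohort()], or a list of per-sample
#'   lists with elements `dataset` (a `spot_dataset`) and `site`
#'   (a `cluster_selection`; NULL for naive).
#' @param genes Character vector of genes (e.g. the consolidated list).
#' @return Numeric matrix, genes x implanted samples.
#' @export
electrode_site_expression <- function(cohort, genes) {
  samples <- if (inherits(cohort, "cohort")) cohort$samples else cohort
  implanted <- purrr::keep(samples, function(s) !is.null(s$site))
  if (length(implanted) == 0L) abort("No implanted samples with a site.")
  cols <- purrr::map(implanted, function(s) {
    counts <- s$dataset$counts
    norm <- mna_normalize(counts, s$site)
    vals <- rowMeans(norm$normalized)
    missing <- setdiff(genes, names(vals))
    if (length(missing)) {
      warn(sprintf("Gene(s) absent from sample features, set to 0: %s.",
                   paste(head(missing, 3), collapse = ", ")))
    }
    out <- stats::setNames(numeric(length(genes)), genes)
    present <- intersect(genes, names(vals))
    out[present] <- vals[present]
    out
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(implanted)
  mat
}

#' Single-gene linear regression against a recording or histology metric
#'
#' Ordinary least squares of the metric on the gene's electrode-site MNA
#' across samples; reports the slope, intercept, R-squared, and the
#' non-adjusted F-statistic p-value.
#'
#' @param x Per-sample gene MNA values.
#' @param y Per-sample metric values (pairs with missing y are dropped).
#' @param gene Gene label for the result row.
#' @param metric Metric name.
#' @return A `gene_regression`: one-row tibble `gene`, `metric`, `slope`,
#'   `intercept`, `r_squared`, `p`, `n`; NULL-like (NA row) when x has zero
#'   variance. The `lm` fit is attached as attribute `fit`.
#' @export
single_gene_regression <- function(x, y, gene = "gene", metric = "metric") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("Need at least 3 paired observations.")
  if (var(x) == 0) {
    warn(sprintf("Zero variance in '%s'; regression undefined.", gene))
    out <- tibble::tibble(gene = gene, metric = metric, slope = NA_real_,
                          intercept = NA_real_, r_squared = NA_real_,
                          p = NA_real_, n = length(x))
    return(structure(out, class = c("gene_regression", class(out))))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  out <- tibble::tibble(
    gene = gene, metric = metric,
    slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared, p = p, n = length(x)
  )
  structure(out, class = c("gene_regression", class(out)),
            fit = fit, x = x, y = y)
}

#' @export
glance.gene_regression <- function(x, ...) {
  tibble::as_tibble(x)[, c("r_squared", "p", "n")]
}

#' PCA inspection of per-sample expression
#'
#' Centers each gene across samples (no scaling) and computes principal
#' component scores per sample via singular value decomposition, for
#' whole-tissue or electrode-site (<= 300 um) MNA matrices.
#'
#' @param mat Gene x sample numeric matrix.
#' @param scope Label, "whole_tissue" or "site300".
#' @return List with `scores` (tibble: sample, PC1, PC2), `var_explained`
#'   (fractions), `loadings` (genes x PCs), `scope`.
#' @export
pca_inspect <- function(mat, scope = c("site300", "whole_tissue")) {
  scope <- match.arg(scope)
  if (is.null(dim(mat)) || ncol(mat) < 3L) {
    abort("`mat` must be a gene x sample matrix with >= 3 samples.")
  }
  pc <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  scores <- tibble::as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- dplyr::mutate(scores, sample = colnames(mat), .before = 1)
  list(scores = scores, var_explained = ve, loadings = pc$rotation,
       scope = scope)
}

#' Enumerate gene subsets
#'
#' All subsets of the requested sizes in deterministic lexicographic order
#' (sizes ascending, combinations in `combn` order), truncated at `cap` with
#' a warning.
#'
#' @param pool Character vector of genes.
#' @param sizes Subset sizes (default 2:5).
#' @param cap Maximum number of subsets to return (default 10000).
#' @return List of character vectors.
#' @export
enumerate_gene_sets <- function(pool, sizes = 2:5, cap = 10000) {
  if (length(pool) == 0L) abort("`pool` must be non-empty.")
  if (cap <= 0) abort("`cap` must be positive.")
  if (any(sizes > length(pool))) {
    abort("Requested subset size exceeds the pool size.")
  }
  out <- list()
  for (k in sort(unique(sizes))) {
    sets <- combn(pool, k, simplify = FALSE)
    room <- cap - length(out)
    if (length(sets) > room) {
      warn(sprintf("Gene-set enumeration truncated at cap = %d.", cap))
      out <- c(out, sets[seq_len(room)])
      return(out)
    }
    out <- c(out, sets)
  }
  out
}

#' Principal component regression for a gene set
#'
#' Genes are z-scored across samples (zero-variance genes dropped with a
#' warning), PCA is run on the samples x genes matrix, and the metric is
#' regressed on the per-sample PC1 score. For a singleton set this reduces
#' exactly to the single-gene regression R-squared.
#'
#' @param expr Gene x sample MNA matrix restricted to the subset.
#' @param y Per-sample metric values.
#' @param lfc Optional named per-gene representative LFC values; their mean
#'   absolute value is attached to the result.
#' @param metric Metric name.
#' @return A `gene_set_pcr`: one-row tibble `gene_set`, `metric`,
#'   `n_genes`, `pc1_var_explained`, `r_squared`, `p`, `mean_abs_lfc`, `n`,
#'   with attributes `scores` (per-sample PC1) and `fit`.
#' @export
gene_set_pcr <- function(expr, y, lfc = NULL, metric = "metric") {
  if (is.null(dim(expr))) expr <- matrix(expr, nrow = 1)
  keep <- is.finite(y)
  expr <- expr[, keep, drop = FALSE]; y <- y[keep]
  if (ncol(expr) < 3L) abort("Need at least 3 samples.")
  gvar <- apply(expr, 1, var)
  if (any(gvar == 0)) {
    warn(sprintf("Dropping zero-variance gene(s) from subset: %s.",
                 paste(rownames(expr)[gvar == 0], collapse = ", ")))
    expr <- expr[gvar > 0, , drop = FALSE]
  }
  if (nrow(expr) == 0L) abort("No non-degenerate genes left in the subset.")
  z <- t(scale(t(expr)))  # z-score each gene across samples
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  score1 <- pc$x[, 1]
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  fit <- lm(y ~ score1)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  p <- unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  genes <- rownames(expr)
  mean_abs_lfc <- if (is.null(lfc)) NA_real_ else {
    mean(abs(lfc[intersect(genes, names(lfc))]))
  }
  out <- tibble::tibble(
    gene_set = paste(genes, collapse = "+"), metric = metric,
    n_genes = length(genes), pc1_var_explained = ve[1],
    r_squared = sm$r.squared, p = p, mean_abs_lfc = mean_abs_lfc,
    n = length(y)
  )
  structure(out, class = c("gene_set_pcr", class(out)),
            scores = score1, fit = fit, y = y)
}

#' @export
glance.gene_set_pcr <- function(x, ...) {
  tibble::as_tibble(x)[, c("pc1_var_explained", "r_squared", "p", "n")]
}

#' Select top biomarker candidates for one metric
#'
#' Normalizes `|lfc|` and R-squared to [0, 1] across results (min-max),
#' scores each result by the minimum of the two normalized axes (a
#' conservative "both must be high" rule), and ranks descending by score
#' with ties broken by R-squared then name. Pareto-undominated results are
#' flagged.
#'
#' @param results Tibble of regression/PCR results with columns `r_squared`,
#'   a gene label column (`gene` or `gene_set`), and `lfc` or `mean_abs_lfc`.
#' @param k Number of candidates to select, between 4 and 7 (default 5).
#' @return A `candidate_set` tibble: all results with `score`, `rank`,
#'   `pareto`, `selected`, sorted by rank; attribute `k`.
#' @export
select_candidates <- function(results, k = 5) {
  if (k < 4 || k > 7) abort("`k` must be between 4 and 7.")
  results <- tibble::as_tibble(results)
  label <- if ("gene" %in% names(results)) "gene" else "gene_set"
  lfc_col <- if ("lfc" %in% names(results)) "lfc" else "mean_abs_lfc"
  if (!all(c(label, lfc_col, "r_squared") %in% names(results))) {
    abort("`results` must have a gene label, an LFC column, and r_squared.")
  }
  res <- results[is.finite(results$r_squared) &
                 is.finite(results[[lfc_col]]), , drop = FALSE]
  if (nrow(res) < k) {
    warn(sprintf("Fewer than k = %d results; returning all %d.",
                 k, nrow(res)))
    k <- nrow(res)
  }
  minmax <- function(v) {
    r <- range(v)
    if (diff(r) == 0) rep(1, length(v)) else (v - r[1]) / diff(r)
  }
  abs_lfc <- abs(res[[lfc_col]])
  norm_lfc <- minmax(abs_lfc)
  norm_r2 <- minmax(res$r_squared)
  res$score <- pmin(norm_lfc, norm_r2)
  res$pareto <- vapply(seq_len(nrow(res)), function(i) {
    !any(abs_lfc > abs_lfc[i] & res$r_squared > res$r_squared[i])
  }, logical(1))
  ord <- order(-res$score, -res$r_squared, res[[label]])
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  res$selected <- res$rank <= k
  structure(res, class = c("candidate_set", class(res)), k = k)
}

#' Fitted metric values from a regression or PCR result
#'
#' Recomputes fitted values from the stored model and returns a
#' fitted-versus-actual table for plotting; residuals and recomputed
#' R-squared are included.
#'
#' @param result A `gene_regression` or `gene_set_pcr`.
#' @return A tibble `actual`, `fitted`, `residual`, with attribute
#'   `r_squared` recomputed from the fitted values.
#' @export
predict_metric <- function(result) {
  fit <- attr(result, "fit")
  if (is.null(fit)) {
    abort("`result` carries no fitted model (zero-variance predictor?).")
  }
  y <- if (!is.null(attr(result, "y"))) attr(result, "y") else fit$model$y
  fitted <- unname(predict(fit))
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  out <- tibble::tibble(actual = y, fitted = fitted, residual = y - fitted)
  structure(out, class = c("metric_fit", class(out)), r_squared = r2)
}

#' Run the full biomarker screen for every metric
#'
#' Single-gene regressions of every consolidated gene against each metric,
#' optional gene-set PCR over enumerated subsets of the top pool, and
#' candidate selection per metric.
#'
#' @param site_expr Gene x sample MNA matrix ([electrode_site_expression()]).
#' @param metrics Tibble with a `sample` column and one column per metric
#'   (MUA, LFP, SNR, GFAP, ND); samples must match `colnames(site_expr)`.
#' @param consolidated Consolidated DE gene tibble ([consolidate_de_lists()]).
#' @param k Candidates per metric (default 5).
#' @param set_sizes Gene-set sizes for PCR (NULL to skip sets).
#' @param pool_size Top-|LFC| pool size for set enumeration (default 10).
#' @param cap Enumeration cap (default 2000).
#' @return A `biomarker_screen`: list with `single` (tibble of single-gene
#'   results with lfc), `sets` (PCR results or NULL), `candidates` (named
#'   list of `candidate_set` per metric).
#' @export
biomarker_screen <- function(site_expr, metrics, consolidated, k = 5,
                             set_sizes = NULL, pool_size = 10, cap = 2000) {
  metric_names <- intersect(c("MUA", "LFP", "SNR", "GFAP", "ND"),
                            names(metrics))
  if (!length(metric_names)) abort("`metrics` has no known metric columns.")
  if (!"sample" %in% names(metrics)) abort("`metrics` needs a `sample` column.")
  samples <- colnames(site_expr)
  met <- metrics[match(samples, metrics$sample), , drop = FALSE]
  genes <- intersect(consolidated$gene, rownames(site_expr))
  lfc <- stats::setNames(consolidated$lfc, consolidated$gene)[genes]
  single <- purrr::map(metric_names, function(m) {
    y <- met[[m]]
    rows <- purrr::map(genes, function(g) {
      suppressWarnings(
        single_gene_regression(site_expr[g, ], y, gene = g, metric = m)
      )
    })
    dplyr::bind_rows(rows)
  })
  single <- dplyr::bind_rows(single)
  single$lfc <- unname(lfc[single$gene])
  sets <- NULL
  if (!is.null(set_sizes)) {
    pool <- names(sort(abs(lfc), decreasing = TRUE))
    pool <- pool[seq_len(min(pool_size, length(pool)))]
    subsets <- enumerate_gene_sets(pool, sizes = set_sizes, cap = cap)
    sets <- purrr::map(metric_names, function(m) {
      y <- met[[m]]
      rows <- purrr::map(subsets, function(gs) {
        suppressWarnings(
          gene_set_pcr(site_expr[gs, , drop = FALSE], y, lfc = lfc,
                       metric = m)
        )
      })
      dplyr::bind_rows(rows)
    })
    sets <- dplyr::bind_rows(sets)
  }
  candidates <- purrr::map(metric_names, function(m) {
    res <- single[single$metric == m, , drop = FALSE]
    select_candidates(res, k = k)
  })
  names(candidates) <- metric_names
  structure(list(single = single, sets = sets, candidates = candidates),
            class = "biomarker_screen")
}

#' @export
print.biomarker_screen <- function(x, ...) {
  cat(sprintf("<biomarker_screen> %d single-gene results, %s set results\n",
              nrow(x$single),
              if (is.null(x$sets)) "no" else nrow(x$sets)))
  for (m in names(x$candidates)) {
    sel <- x$candidates[[m]]
    lab <- if ("gene" %in% names(sel)) sel$gene else sel$gene_set
    cat(sprintf("  %s: %s\n", m,
                paste(lab[sel$selected], collapse = ", ")))
  }
  invisible(x)
}
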