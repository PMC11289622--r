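#' Pipeline run configuration
#'
#' Collects every stage constant in one place: bin widths, the electrode-site
#' radius, DE thresholds, screen settings, cohort simulation settings, and
#' the seed. The configuration round-trips losslessly through JSON
#' ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param seed Master RNG seed.
#' @param bin_width_um Expression/density bin width (default 100).
#' @param intensity_bin_width_um Intensity bin width (default 10).
#' @param rmax_um Electrode-site radius (default 300).
#' @param alpha DE significance level (default 0.05).
#' @param lfc_min Absolute LFC threshold (default 0.6).
#' @param p_column "raw" or "bh" (default "raw").
#' @param depth_threshold Depth-QC threshold, UMI/spot (default 50000).
#' @param k Candidates per metric, 4-7 (default 5).
#' @param set_sizes Gene-set sizes for PCR (default NULL: single genes only).
#' @param pool_size Pool size for set enumeration (default 10).
#' @param cap Enumeration cap (default 2000).
#' @param n_implanted,n_naive Cohort sizes for simulated runs (defaults 9, 3).
#' @param n_genes Simulated panel size (default 120).
#' @param grid_shape Simulated lattice shape (default c(12, 12)).
#' @param mean_depth Simulated mean UMI/spot (default 60000, emulating
#'   samples that comfortably exceed the recommended 50000 depth).
#' @param cohort_betas Optional tibble (gene, metric, beta) of planted
#'   gene-metric relationships for simulated runs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, bin_width_um = 100,
                            intensity_bin_width_um = 10, rmax_um = 300,
                            alpha = 0.05, lfc_min = 0.6,
                            p_column = c("raw", "bh"),
                            depth_threshold = 5e4, k = 5, set_sizes = NULL,
                            pool_size = 10, cap = 2000,
                            n_implanted = 9, n_naive = 3, n_genes = 120,
                            grid_shape = c(12, 12), mean_depth = 6e4,
                            cohort_betas = NULL) {
  p_column <- match.arg(p_column)
  for (nm in c("bin_width_um", "intensity_bin_width_um", "rmax_um", "alpha",
               "lfc_min", "depth_threshold")) {
    assert_positive_scalar(get(nm), nm)
  }
  structure(
    list(seed = as.integer(seed), bin_width_um = bin_width_um,
         intensity_bin_width_um = intensity_bin_width_um, rmax_um = rmax_um,
         alpha = alpha, lfc_min = lfc_min, p_column = p_column,
         depth_threshold = depth_threshold, k = k, set_sizes = set_sizes,
         pool_size = pool_size, cap = cap, n_implanted = n_implanted,
         n_naive = n_naive, n_genes = n_genes,
         grid_shape = as.integer(grid_shape), mean_depth = mean_depth,
         cohort_betas = cohort_betas),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(pipeline_config, raw[setdiff(names(raw), "cohort_betas")])
  if (!is.null(raw$cohort_betas)) {
    cfg$cohort_betas <- tibble::as_tibble(raw$cohort_betas)
  }
  cfg
}

#' Run the end-to-end analysis on a simulated cohort
#'
#' Simulates a cohort from the configuration (or accepts one), then runs
#' every stage: depth and housekeeping QC per sample, per-timepoint
#' differential expression of the pooled 0-300 um electrode-site spots
#' against seeded naive-matched sites, consolidation of the significant
#' lists, the electrode-site expression matrix, and the LFC-vs-R-squared
#' biomarker screen against the cohort's metrics. All outputs are written as
#' TSV/JSON under `out_dir`; re-running with the same config reproduces them
#' byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @param cohort Optional pre-built `cohort` (skips simulation).
#' @return Invisibly, a list with the in-memory stage results (`cohort`,
#'   `qc`, `de`, `consolidated`, `site_expr`, `screen`, `files`).
#' @export
run_pipeline <- function(config, out_dir, cohort = NULL) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be a pipeline_config.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cohort)) {
    panel <- gene_panel(n_genes = config$n_genes)
    truth <- if (is.null(config$cohort_betas)) default_cohort_truth() else
      cohort_truth_spec(betas = config$cohort_betas)
    cohort <- simulate_cohort(
      n_implanted = config$n_implanted, n_naive = config$n_naive,
      panel = panel, truth_spec = truth,
      cfg = sim_config(grid_shape = config$grid_shape,
                       mean_depth = config$mean_depth, seed = config$seed),
      rmax_um = config$rmax_um
    )
  }
  files <- character(0)
  # ---- per-sample QC ----
  qc <- purrr::imap(cohort$samples, function(s, nm) {
    counts <- s$dataset$counts
    dq <- depth_qc(counts, min_mean_umi = config$depth_threshold)
    hk <- c("Gapdh", "Actb")
    hk <- hk[hk %in% rownames(counts)]
    lin <- dplyr::bind_rows(
      purrr::map(hk, function(g) housekeeping_linearity(counts, g)))
    tibble::tibble(sample = nm, mean_umi = dq$mean_umi,
                   depth_pass = dq$pass,
                   hk_min_r2 = if (nrow(lin)) min(lin$r_squared) else NA_real_,
                   hk_pass = if (nrow(lin)) all(lin$pass) else NA)
  })
  qc <- dplyr::bind_rows(qc)
  f <- file.path(out_dir, "qc.tsv"); readr::write_tsv(qc, f)
  files <- c(files, f)
  # ---- per-timepoint DE vs naive-matched sites ----
  naive <- purrr::keep(cohort$samples, function(s) !s$implanted)
  if (length(naive) == 0L) abort("Pipeline requires naive samples for DE.")
  naive_sites <- purrr::imap(naive, function(s, nm) {
    site <- select_naive_sites(s$dataset$spots, n_sites = 1,
                               radius_um = config$rmax_um,
                               seed = config$seed + 7L)[[1]]
    list(sample = nm, dataset = s$dataset, site = site)
  })
  tps <- unique(purrr::map_chr(
    purrr::keep(cohort$samples, function(s) s$implanted),
    function(s) s$timepoint))
  de <- purrr::map(tps, function(tp) {
    imp <- purrr::keep(cohort$samples,
                       function(s) s$implanted && s$timepoint == tp)
    combined <- combine_counts(
      c(purrr::map(imp, function(s) list(dataset = s$dataset, site = s$site)),
        naive_sites))
    a_bc <- combined$barcodes[seq_len(length(imp))]
    b_bc <- combined$barcodes[-seq_len(length(imp))]
    differential_expression(
      combined$counts,
      new_cluster_selection(paste0(tp, "_site"), unlist(a_bc),
                            config$rmax_um),
      new_cluster_selection("naive_sites", unlist(b_bc), config$rmax_um),
      alpha = config$alpha, lfc_min = config$lfc_min,
      p_column = config$p_column
    )
  })
  names(de) <- tps
  for (tp in tps) {
    f <- file.path(out_dir, sprintf("de_%s.tsv", tp))
    readr::write_tsv(tibble::as_tibble(de[[tp]]), f)
    files <- c(files, f)
  }
  # ---- consolidation & screen ----
  sig <- purrr::map(de, significance_filter, alpha = config$alpha,
                    lfc_min = config$lfc_min, p_column = config$p_column)
  sig <- purrr::keep(sig, function(tb) nrow(tb) > 0)
  if (length(sig) == 0L) {
    warn("No significant genes at any timepoint; screen skipped.")
    consolidated <- NULL; site_expr <- NULL; screen <- NULL
  } else {
    consolidated <- consolidate_de_lists(sig)
    f <- file.path(out_dir, "consolidated_genes.tsv")
    readr::write_tsv(dplyr::select(consolidated, -"lfc_by_timepoint"), f)
    files <- c(files, f)
    site_expr <- suppressWarnings(
      electrode_site_expression(cohort, consolidated$gene))
    f <- file.path(out_dir, "site_expression.tsv")
    readr::write_tsv(tibble::as_tibble(site_expr, rownames = "gene"), f)
    files <- c(files, f)
    f <- file.path(out_dir, "metrics.tsv")
    readr::write_tsv(cohort$metrics, f)
    files <- c(files, f)
    if (ncol(site_expr) >= 3) {
      pca <- pca_inspect(site_expr, scope = "site300")
      f <- file.path(out_dir, "pca_site300.tsv")
      readr::write_tsv(pca$scores, f)
      files <- c(files, f)
    }
    screen <- biomarker_screen(site_expr, cohort$metrics, consolidated,
                               k = config$k, set_sizes = config$set_sizes,
                               pool_size = config$pool_size, cap = config$cap)
    for (m in names(screen$candidates)) {
      f <- file.path(out_dir, sprintf("screen_%s.tsv", m))
      readr::write_tsv(tibble::as_tibble(screen$candidates[[m]]), f)
      files <- c(files, f)
    }
    cand <- purrr::map(screen$candidates, function(cs) {
      lab <- if ("gene" %in% names(cs)) cs$gene else cs$gene_set
      lab[cs$selected]
    })
    f <- file.path(out_dir, "candidates.json")
    jsonlite::write_json(cand, f, auto_unbox = FALSE, digits = NA)
    files <- c(files, f)
  }
  log <- list(
    package = "peritract",
    version = as.character(utils::packageVersion("peritract")),
    seed = config$seed,
    thresholds = list(alpha = config$alpha, lfc_min = config$lfc_min,
                      rmax_um = config$rmax_um,
                      depth_threshold = config$depth_threshold),
    n_samples = length(cohort$samples),
    timepoints = tps,
    n_significant = purrr::map_int(sig, nrow)
  )
  f <- file.path(out_dir, "run_log.json")
  jsonlite::write_json(log, f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)
  invisible(list(cohort = cohort, qc = qc, de = de,
                 consolidated = consolidated, site_expr = site_expr,
                 screen = screen, files = files))
}

# Default planted truth for simulated pipeline runs: the canonical markers
# carry modest relationships to the metrics they are biologically tied to.
default_cohort_truth <- function() {
  cohort_truth_spec(betas = tibble::tibble(
    gene = c("Gfap", "Snap25", "Lcn2"),
    metric = c("GFAP", "MUA", "SNR"),
    beta = c(0.05, 0.1, -0.002)
  ))
}

# Merge several (dataset, site) pairs into one count matrix over the shared
# gene panel, prefixing barcodes by sample to keep columns unique.
combine_counts <- function(items) {
  genes <- Reduce(intersect, purrr::map(items, function(it)
    rownames(it$dataset$counts)))
  mats <- purrr::imap(items, function(it, i) {
    m <- it$dataset$counts[genes, it$site$barcodes, drop = FALSE]
    colnames(m) <- paste0("s", i, "_", colnames(m))
    m
  })
  barcodes <- purrr::map(mats, colnames)
  list(counts = do.call(cbind, mats), barcodes = barcodes)
}
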