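#' Median-normalized average (MNA) depth normalization
#'
#' Within a spot cluster, each spot's counts are scaled by
#' `median(cluster totals) / spot total`, so every normalized spot total
#' equals the cluster median total. The per-gene MNA for the cluster is the
#' mean of the normalized counts over the cluster's spots.
#'
#' Zero-total spots cannot be depth-normalized and are dropped with a
#' warning; an all-zero cluster is an error.
#'
#' @param counts Gene x spot count matrix (sparse or dense) with dimnames.
#' @param cluster A `cluster_selection`, or a character vector of spot
#'   barcodes (column names of `counts`).
#' @return An `mna_matrix`: list with `normalized` (gene x spot matrix),
#'   `scale` (per-spot factors), `median_total`, `cluster` (name),
#'   `barcodes`.
#' @export
mna_normalize <- function(counts, cluster) {
  bc <- cluster_barcodes(cluster)
  counts <- check_counts(counts)
  missing <- setdiff(bc, colnames(counts))
  if (length(missing)) {
    abort(sprintf("Cluster barcodes absent from counts: %s%s.",
                  paste(head(missing, 3), collapse = ", "),
                  if (length(missing) > 3) ", ..." else ""))
  }
  sub <- counts[, bc, drop = FALSE]
  totals <- Matrix::colSums(sub)
  if (all(totals == 0)) abort("Cluster has all-zero spot totals.")
  if (any(totals == 0)) {
    warn(sprintf("Dropping %d zero-total spot(s) from MNA normalization.",
                 sum(totals == 0)))
    sub <- sub[, totals > 0, drop = FALSE]
    totals <- totals[totals > 0]
  }
  med <- median(totals)
  scale <- med / totals
  normalized <- sweep(as.matrix(sub), 2, scale, "*")
  structure(
    list(normalized = normalized, scale = scale, median_total = med,
         cluster = if (inherits(cluster, "cluster_selection")) cluster$name
                   else "cluster",
         barcodes = colnames(normalized)),
    class = "mna_matrix"
  )
}

cluster_barcodes <- function(cluster) {
  if (inherits(cluster, "cluster_selection")) return(cluster$barcodes)
  if (is.character(cluster) && length(cluster) > 0L) return(cluster)
  abort("`cluster` must be a cluster_selection or non-empty barcode vector.")
}

check_counts <- function(counts) {
  if (is.null(dim(counts)) || is.null(rownames(counts)) ||
      is.null(colnames(counts))) {
    abort("`counts` must be a gene x spot matrix with dimnames.")
  }
  counts
}

#' @export
print.mna_matrix <- function(x, ...) {
  cat(sprintf("<mna_matrix> '%s': %d genes x %d spots, median total %g\n",
              x$cluster, nrow(x$normalized), ncol(x$normalized),
              x$median_total))
  invisible(x)
}

#' Per-gene MNA values of a normalized cluster
#'
#' @param x An `mna_matrix` from [mna_normalize()].
#' @return A tibble `gene`, `mna`.
#' @export
mna_means <- function(x) {
  if (!inherits(x, "mna_matrix")) abort("`x` must be an mna_matrix.")
  tibble::tibble(gene = rownames(x$normalized), mna = rowMeans(x$normalized))
}

#' Binned MNA expression profile for one gene
#'
#' For each 100 um annulus out to `max_bin`, the bin's spots form the
#' normalization cluster and the gene's MNA within that bin is reported
#' (the radial expression profile convention). Empty bins are missing.
#'
#' @param counts Gene x spot count matrix.
#' @param bins Bin assignment table from [assign_bins()] run on the spot
#'   table (must carry `barcode` and `bin` columns; width 100 um).
#' @param gene Gene name.
#' @param max_bin Last bin index (default 9: the 900-1000 um annulus).
#' @return A tibble `bin`, `bin_start_um`, `bin_end_um`, `n_spots`, `mna`
#'   with class `mna_profile`.
#' @export
binned_mna_profile <- function(counts, bins, gene, max_bin = 9) {
  counts <- check_counts(counts)
  if (!all(c("barcode", "bin") %in% names(bins))) {
    abort("`bins` must have `barcode` and `bin` columns (see assign_bins()).")
  }
  if (!gene %in% rownames(counts)) {
    abort(sprintf("Gene '%s' not in counts.", gene))
  }
  eligible <- bins
  if ("in_tissue" %in% names(eligible)) {
    eligible <- eligible[eligible$in_tissue, , drop = FALSE]
  }
  if ("artifact" %in% names(eligible)) {
    eligible <- eligible[!eligible$artifact, , drop = FALSE]
  }
  rows <- purrr::map(0:max_bin, function(b) {
    bc <- eligible$barcode[!is.na(eligible$bin) & eligible$bin == b]
    bc <- intersect(bc, colnames(counts))
    if (length(bc) == 0L) {
      return(tibble::tibble(bin = b, n_spots = 0L, mna = NA_real_))
    }
    norm <- mna_normalize(counts, bc)
    tibble::tibble(bin = b, n_spots = length(norm$barcodes),
                   mna = unname(rowMeans(norm$normalized)[gene]))
  })
  out <- dplyr::bind_rows(rows)
  w <- attr(bins, "bin_width_um") %||% 100
  out <- dplyr::mutate(out, bin_start_um = .data$bin * w,
                       bin_end_um = (.data$bin + 1) * w,
                       .after = "bin")
  structure(out, class = c("mna_profile", class(out)), gene = gene)
}

#' Housekeeping-gene linearity QC
#'
#' Ordinary least squares of a housekeeping gene's raw counts on per-spot
#' total UMI counts. Consistently expressed genes should track sequencing
#' depth, so a high R-squared indicates no spot-level capture anomaly.
#'
#' @param counts Gene x spot count matrix.
#' @param gene Housekeeping gene name (e.g. "Gapdh", "Actb").
#' @param spots Optional barcodes restricting the spots used.
#' @param r2_threshold Pass threshold on R-squared (default 0.5).
#' @return A one-row tibble `gene`, `slope`, `intercept`, `r_squared`,
#'   `n_spots`, `pass`.
#' @export
housekeeping_linearity <- function(counts, gene, spots = NULL,
                                   r2_threshold = 0.5) {
  counts <- check_counts(counts)
  if (!gene %in% rownames(counts)) {
    abort(sprintf("Gene '%s' not in counts.", gene))
  }
  if (!is.null(spots)) counts <- counts[, spots, drop = FALSE]
  if (ncol(counts) < 10L) abort("Need at least 10 spots for linearity QC.")
  totals <- Matrix::colSums(counts)
  if (var(totals) == 0) abort("Zero variance in spot totals.")
  y <- as.numeric(counts[gene, ])
  fit <- lm(y ~ totals)
  r2 <- summary(fit)$r.squared
  tibble::tibble(
    gene = gene,
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = r2,
    n_spots = ncol(counts),
    pass = r2 >= r2_threshold
  )
}

#' Sequencing-depth QC
#'
#' Checks that mean UMI per spot reaches the recommended depth for
#' spot-based spatial expression assays.
#'
#' @param counts Gene x spot count matrix.
#' @param min_mean_umi Depth threshold (default 50000).
#' @return A `qc_report`: list with `mean_umi`, `totals`, `threshold`,
#'   `pass`.
#' @export
depth_qc <- function(counts, min_mean_umi = 5e4) {
  counts <- check_counts(counts)
  totals <- Matrix::colSums(counts)
  mean_umi <- mean(totals)
  structure(
    list(mean_umi = mean_umi, totals = totals, threshold = min_mean_umi,
         pass = mean_umi >= min_mean_umi),
    class = "qc_report"
  )
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> mean UMI/spot %.0f (threshold %g): %s\n",
              x$mean_umi, x$threshold, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(mean_umi = x$mean_umi, threshold = x$threshold,
                 n_spots = length(x$totals), pass = x$pass)
}
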