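#' Low-count gene filter for a two-cluster comparison
#'
#' Keeps a gene when its mean raw count reaches 1 in at least one of the two
#' clusters (genes below one count per spot on average in both clusters are
#' removed).
#'
#' @param counts Gene x spot count matrix.
#' @param A,B `cluster_selection`s or barcode vectors (disjoint, non-empty).
#' @return Named logical mask over genes.
#' @export
low_count_filter <- function(counts, A, B) {
  counts <- check_counts(counts)
  bcA <- cluster_barcodes(A); bcB <- cluster_barcodes(B)
  check_disjoint(bcA, bcB)
  mA <- Matrix::rowSums(counts[, bcA, drop = FALSE]) / length(bcA)
  mB <- Matrix::rowSums(counts[, bcB, drop = FALSE]) / length(bcB)
  mask <- mA >= 1 | mB >= 1
  names(mask) <- rownames(counts)
  mask
}

check_disjoint <- function(bcA, bcB) {
  if (length(bcA) == 0L || length(bcB) == 0L) {
    abort("Both clusters must be non-empty.")
  }
  if (length(intersect(bcA, bcB))) {
    abort("Clusters must be disjoint.")
  }
  invisible(TRUE)
}

# Size factors: per-spot total over the median total across both clusters.
de_size_factors <- function(counts, bcA, bcB) {
  totals <- Matrix::colSums(counts[, c(bcA, bcB), drop = FALSE])
  if (any(totals == 0)) {
    abort("Zero-total spot(s) in the DE comparison; drop them first.")
  }
  totals / median(totals)
}

#' Method-of-moments dispersion estimation with shrinkage
#'
#' Per-gene negative-binomial dispersions are estimated from size-corrected
#' counts by the method of moments, `phi_g = max(0, (v_g - m_g) / m_g^2)`
#' with `v_g` the pooled within-cluster variance, then shrunk toward the
#' panel mean dispersion with a James-Stein-type weight. The weight compares
#' the between-gene spread of the raw estimates with their expected sampling
#' variance (delta-method, normal approximation to the sample variance), so
#' noisy per-gene estimates borrow strength from the ensemble.
#'
#' @param counts Gene x spot count matrix (filtered genes only).
#' @param A,B Clusters (disjoint).
#' @return A `dispersion_model`: tibble `gene`, `phi_raw`, `phi_shrunk`, with
#'   attributes `phi_mean` (pooled target) and `delta` (shrinkage weight).
#' @export
estimate_dispersions <- function(counts, A, B) {
  counts <- check_counts(counts)
  bcA <- cluster_barcodes(A); bcB <- cluster_barcodes(B)
  check_disjoint(bcA, bcB)
  s <- de_size_factors(counts, bcA, bcB)
  yA <- sweep(as.matrix(counts[, bcA, drop = FALSE]), 2, s[bcA], "/")
  yB <- sweep(as.matrix(counts[, bcB, drop = FALSE]), 2, s[bcB], "/")
  nA <- length(bcA); nB <- length(bcB)
  if (nA < 2L && nB < 2L) {
    warn("Single-spot clusters: falling back to pooled dispersion 0.")
    out <- tibble::tibble(gene = rownames(counts),
                          phi_raw = 0, phi_shrunk = 0)
    attr(out, "phi_mean") <- 0; attr(out, "delta") <- 1
    class(out) <- c("dispersion_model", class(out))
    return(out)
  }
  mA <- rowMeans(yA); mB <- rowMeans(yB)
  vA <- if (nA > 1) apply(yA, 1, var) else rep(0, nrow(yA))
  vB <- if (nB > 1) apply(yB, 1, var) else rep(0, nrow(yB))
  dfA <- max(nA - 1L, 0L); dfB <- max(nB - 1L, 0L)
  v <- (dfA * vA + dfB * vB) / (dfA + dfB)
  m <- (nA * mA + nB * mB) / (nA + nB)
  phi_raw <- pmax(0, (v - m) / m^2)
  phi_mean <- mean(phi_raw)
  g <- length(phi_raw)
  n_eff <- nA + nB
  # delta-method sampling variance of phi_hat under a common dispersion:
  # Var(v) ~ 2 sigma^4 / (n - 2), sigma^2 = m + phi_mean m^2
  samp_var <- 2 * (1 / m + phi_mean)^2 / max(n_eff - 2L, 1L)
  spread <- sum((phi_raw - phi_mean)^2)
  delta <- if (spread == 0) 1 else {
    min(1, max(0, (g - 3) * mean(samp_var) / spread))
  }
  out <- tibble::tibble(
    gene = rownames(counts),
    phi_raw = phi_raw,
    phi_shrunk = (1 - delta) * phi_raw + delta * phi_mean
  )
  attr(out, "phi_mean") <- phi_mean
  attr(out, "delta") <- delta
  class(out) <- c("dispersion_model", class(out))
  out
}

# Negative-binomial density with graceful Poisson limit at phi = 0.
dnb_phi <- function(x, mu, phi) {
  if (phi <= 0) dpois(x, lambda = mu) else dnbinom(x, mu = mu, size = 1 / phi)
}

#' Conditional exact test for a single gene between two clusters
#'
#' Tests the split of the gene's pooled count between clusters A and B under
#' the null that per-spot means are proportional to the size factors. The
#' cluster sums are modelled as negative binomial with matched first and
#' second moments (`mean q S`, `var q S + phi q^2 sum(s^2)`); the two-sided
#' p-value sums the probabilities of all splits no more likely than the
#' observed one. Above `enum_cutoff` pooled counts, a conditional-normal
#' approximation with continuity correction is used.
#'
#' @param kA,kB Observed cluster count sums for the gene (non-negative
#'   integers).
#' @param sA,sB Per-spot size factors for clusters A and B.
#' @param phi Shrunken dispersion for the gene.
#' @param enum_cutoff Pooled-count threshold for switching to the normal
#'   branch (default 900).
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(kA, kB, sA, sB, phi, enum_cutoff = 900) {
  if (kA != round(kA) || kB != round(kB) || kA < 0 || kB < 0) {
    abort("Counts must be non-negative integers.")
  }
  total <- kA + kB
  if (total == 0) return(1)
  SA <- sum(sA); SB <- sum(sB)
  q <- total / (SA + SB)
  muA <- q * SA; muB <- q * SB
  varA <- muA + phi * q^2 * sum(sA^2)
  varB <- muB + phi * q^2 * sum(sB^2)
  if (total <= enum_cutoff) {
    phiA <- max(0, (varA - muA) / muA^2)
    phiB <- max(0, (varB - muB) / muB^2)
    a <- 0:total
    p_split <- dnb_phi(a, muA, phiA) * dnb_phi(total - a, muB, phiB)
    tot <- sum(p_split)
    if (tot <= 0 || !is.finite(tot)) return(1)
    p_split <- p_split / tot
    p_obs <- p_split[kA + 1L]
    p <- sum(p_split[p_split <= p_obs * (1 + 1e-8)])
  } else {
    sig2 <- varA * varB / (varA + varB)
    z <- (abs(kA - muA) - 0.5) / sqrt(sig2)
    p <- 2 * pnorm(-max(z, 0))
  }
  min(1, max(p, .Machine$double.xmin))
}

#' Log2 fold change between clusters
#'
#' Pseudocount-regularized normalized means:
#' `lfc = log2((kA + 1) / (SA + 1)) - log2((kB + 1) / (SB + 1))` with `S` the
#' summed size factors per cluster, keeping the LFC finite for one-sided
#' zeros.
#'
#' @param kA,kB Cluster count sums for the gene.
#' @param SA,SB Summed size factors per cluster.
#' @return Log2 fold change (A vs B).
#' @export
log_fold_change <- function(kA, kB, SA, SB) {
  log2((kA + 1) / (SA + 1)) - log2((kB + 1) / (SB + 1))
}

#' Two-cluster differential expression
#'
#' Applies the low-count filter, estimates shrunken dispersions, runs the
#' per-gene conditional exact test, computes pseudocount-regularized log2
#' fold changes and BH-adjusted p-values, and flags significant genes
#' (`p_used < alpha` and `|lfc| >= lfc_min`). Rows are sorted by p-value.
#'
#' @param counts Gene x spot count matrix containing both clusters' spots.
#' @param A,B `cluster_selection`s or barcode vectors; must be disjoint.
#' @param alpha Significance level (default 0.05).
#' @param lfc_min Absolute LFC threshold (default 0.6).
#' @param p_column Which p-value the significance flag uses: "raw" (default)
#'   or "bh".
#' @param enum_cutoff Exact-test enumeration cutoff (default 900).
#' @return A `de_result` tibble: `gene`, `mean_norm_A`, `mean_norm_B`,
#'   `lfc`, `p`, `p_adj`, `significant`, `neg_log10_p`.
#' @export
differential_expression <- function(counts, A, B, alpha = 0.05,
                                    lfc_min = 0.6,
                                    p_column = c("raw", "bh"),
                                    enum_cutoff = 900) {
  p_column <- match.arg(p_column)
  counts <- check_counts(counts)
  bcA <- cluster_barcodes(A); bcB <- cluster_barcodes(B)
  check_disjoint(bcA, bcB)
  cmat <- counts[, c(bcA, bcB), drop = FALSE]
  if (any(cmat != round(cmat))) abort("Counts must be integers.")
  mask <- low_count_filter(counts, bcA, bcB)
  kept <- counts[mask, , drop = FALSE]
  if (nrow(kept) == 0L) {
    return(empty_de_result())
  }
  s <- de_size_factors(kept, bcA, bcB)
  disp <- estimate_dispersions(kept, bcA, bcB)
  kA <- Matrix::rowSums(kept[, bcA, drop = FALSE])
  kB <- Matrix::rowSums(kept[, bcB, drop = FALSE])
  SA <- sum(s[bcA]); SB <- sum(s[bcB])
  p <- vapply(seq_len(nrow(kept)), function(i) {
    nb_exact_test(kA[i], kB[i], s[bcA], s[bcB], disp$phi_shrunk[i],
                  enum_cutoff = enum_cutoff)
  }, numeric(1))
  lfc <- log_fold_change(kA, kB, SA, SB)
  out <- tibble::tibble(
    gene = rownames(kept),
    mean_norm_A = kA / SA,
    mean_norm_B = kB / SB,
    lfc = lfc,
    p = p,
    p_adj = p.adjust(p, method = "BH")
  )
  p_used <- if (p_column == "raw") out$p else out$p_adj
  out$significant <- p_used < alpha & abs(out$lfc) >= lfc_min
  out$neg_log10_p <- -log10(out$p)
  out <- dplyr::arrange(out, .data$p)
  structure(out, class = c("de_result", class(out)),
            alpha = alpha, lfc_min = lfc_min, p_column = p_column)
}

empty_de_result <- function() {
  out <- tibble::tibble(
    gene = character(), mean_norm_A = numeric(), mean_norm_B = numeric(),
    lfc = numeric(), p = numeric(), p_adj = numeric(),
    significant = logical(), neg_log10_p = numeric()
  )
  structure(out, class = c("de_result", class(out)))
}

#' Significance filter for a DE table
#'
#' Keeps rows with `p_used < alpha` and `|lfc| >= lfc_min` (strict p
#' inequality, inclusive LFC bound).
#'
#' @param table A `de_result` from [differential_expression()].
#' @param alpha Significance level (default 0.05).
#' @param lfc_min Absolute LFC threshold (default 0.6).
#' @param p_column "raw" or "bh".
#' @return The filtered tibble.
#' @export
significance_filter <- function(table, alpha = 0.05, lfc_min = 0.6,
                                p_column = c("raw", "bh")) {
  p_column <- match.arg(p_column)
  need <- c("gene", "lfc", "p", "p_adj")
  if (!all(need %in% names(table))) {
    abort("`table` must come from differential_expression().")
  }
  p_used <- if (p_column == "raw") table$p else table$p_adj
  table[p_used < alpha & abs(table$lfc) >= lfc_min, , drop = FALSE]
}
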