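#' Write a spot dataset in 10x convention
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate, genes x spots),
#' `features.tsv`, `barcodes.tsv`, `tissue_positions.csv` (barcode,
#' in_tissue, array_row, array_col, x_um, y_um), and a `tract.json` sidecar
#' holding the tract geometry and the artifact-spot mask.
#'
#' @param ds A `spot_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spot_dataset <- function(ds, dir) {
  if (!inherits(ds, "spot_dataset")) abort("`ds` must be a spot_dataset.")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(ds$counts, "dMatrix"),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  readr::write_tsv(
    tibble::tibble(id = rownames(ds$counts), name = rownames(ds$counts),
                   type = "Gene Expression"),
    file.path(dir, "features.tsv"), col_names = FALSE)
  readr::write_tsv(tibble::tibble(barcode = colnames(ds$counts)),
                   file.path(dir, "barcodes.tsv"), col_names = FALSE)
  readr::write_csv(
    dplyr::select(ds$spots, "barcode", "in_tissue",
                  array_row = "row", array_col = "col", "x_um", "y_um"),
    file.path(dir, "tissue_positions.csv"))
  sidecar <- list(
    tract = list(center_um = ds$tract$center_um,
                 polygon = if (is.null(ds$tract$polygon)) NULL else
                   unname(apply(ds$tract$polygon, 1, as.numeric,
                                simplify = FALSE))),
    artifact_barcodes = ds$spots$barcode[ds$spots$artifact]
  )
  jsonlite::write_json(sidecar, file.path(dir, "tract.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load a spot dataset written in 10x convention
#'
#' Reads the MatrixMarket counts, features/barcodes TSVs, the tissue
#' positions table, and the tract/artifact JSON sidecar, checking that the
#' pieces agree.
#'
#' @param dir Directory containing `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`, `tissue_positions.csv`, `tract.json`.
#' @return A `spot_dataset` (without simulation truth).
#' @export
load_spot_dataset <- function(dir) {
  need <- c("matrix.mtx", "features.tsv", "barcodes.tsv",
            "tissue_positions.csv", "tract.json")
  have <- file.exists(file.path(dir, need))
  if (!all(have)) {
    abort(sprintf("Missing file(s) in '%s': %s.", dir,
                  paste(need[!have], collapse = ", ")))
  }
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  if (any(counts@x != round(counts@x))) {
    abort("matrix.mtx contains non-integer counts.")
  }
  features <- readr::read_tsv(file.path(dir, "features.tsv"),
                              col_names = FALSE, show_col_types = FALSE)
  barcodes <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                              col_names = FALSE, show_col_types = FALSE)
  if (nrow(features) != nrow(counts) || nrow(barcodes) != ncol(counts)) {
    abort("features/barcodes dimensions do not match matrix.mtx.")
  }
  dimnames(counts) <- list(features[[1]], barcodes[[1]])
  pos <- readr::read_csv(file.path(dir, "tissue_positions.csv"),
                         show_col_types = FALSE)
  extra <- setdiff(pos$barcode, colnames(counts))
  extra2 <- setdiff(colnames(counts), pos$barcode)
  if (length(extra) || length(extra2)) {
    abort(sprintf("Barcode mismatch between positions and matrix: %s.",
                  paste(head(c(extra, extra2), 3), collapse = ", ")))
  }
  sidecar <- jsonlite::read_json(file.path(dir, "tract.json"))
  poly <- if (is.null(sidecar$tract$polygon)) NULL else
    do.call(rbind, lapply(sidecar$tract$polygon, unlist))
  tract <- tract_geometry(unlist(sidecar$tract$center_um), poly)
  artifact_bc <- unlist(sidecar$artifact_barcodes)
  spots <- pos |>
    dplyr::rename(row = "array_row", col = "array_col") |>
    dplyr::mutate(artifact = .data$barcode %in% artifact_bc) |>
    dplyr::arrange(match(.data$barcode, colnames(counts)))
  structure(
    list(counts = Matrix(as.matrix(counts), sparse = TRUE,
                         dimnames = dimnames(counts)),
         spots = tibble::as_tibble(spots), tract = tract, truth = NULL),
    class = "spot_dataset"
  )
}

#' Write a recording as flat float32 binary plus JSON sidecar
#'
#' Samples are written little-endian float32, channel-major (channel 1's
#' samples first); the sidecar records the sampling rate, shape, dtype, byte
#' order, and units (microvolts).
#'
#' @param rec An `ephys_recording`.
#' @param path Output path for the binary (`.bin`); the sidecar is written
#'   alongside as `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  check_recording(rec)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$signal)), con, size = 4, endian = "little")
  jsonlite::write_json(
    list(fs_hz = rec$fs_hz, n_channels = nrow(rec$signal),
         n_samples = ncol(rec$signal), dtype = "float32",
         byte_order = "little", units = "uV",
         channels = rec$channels),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the `.bin` file (sidecar `<path>.json` must exist).
#' @return An `ephys_recording`.
#' @export
read_recording <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(path) || !file.exists(sidecar_path)) {
    abort(sprintf("Missing recording file or sidecar for '%s'.", path))
  }
  meta <- jsonlite::read_json(sidecar_path)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 4, endian = "little")
  sig <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  ephys_recording(sig, meta$fs_hz, channels = unlist(meta$channels))
}

#' Write a radial profile or bin assignment as TSV
#'
#' @param x A `radial_profile`, `mna_profile`, or bin-assignment tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
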