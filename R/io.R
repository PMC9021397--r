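#' Write spectra as per-sample two-column TSV files plus a manifest
#'
#' Each spectrum becomes `<sample_id>.tsv` with columns `ppm` and
#' `intensity`; `manifest.csv` lists `sample_id` and `file`.
#'
#' @param spectra List of `spectrum` objects.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_spectra <- function(spectra, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    sample_id = vapply(spectra, function(s) s$sample_id, character(1)),
    file = vapply(spectra, function(s) paste0(s$sample_id, ".tsv"),
                  character(1)),
    stringsAsFactors = FALSE)
  for (s in spectra) {
    utils::write.table(data.frame(ppm = s$ppm, intensity = s$intensity),
                       file.path(dir, paste0(s$sample_id, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read spectra written by [write_spectra()]
#'
#' @param dir Directory containing `manifest.csv` and the per-sample TSVs.
#' @return Named list of `spectrum` objects.
#' @export
read_spectra <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stopf("no manifest.csv in %s", dir)
  manifest <- utils::read.csv(mf, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    tb <- utils::read.table(file.path(dir, manifest$file[i]), header = TRUE,
                            sep = "\t")
    new_spectrum(tb$ppm, tb$intensity, manifest$sample_id[i])
  })
  names(out) <- manifest$sample_id
  out
}

#' Write a binned matrix as CSV plus a JSON sidecar
#'
#' The CSV has one row per sample (first column `sample_id`) and one column
#' per retained bin, headed by the bin's starting ppm. The sidecar records
#' bin width, starts, exclusions, normalization state and PQN quotients.
#'
#' @param matrix A `binned_matrix`.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @return Invisibly, `path`.
#' @export
write_binned_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "binned_matrix"))
  df <- data.frame(sample_id = rownames(matrix$values),
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(bin_width = matrix$bin_width,
               bin_starts = matrix$bin_starts,
               excluded_regions = matrix$excluded_regions,
               normalization = matrix$normalization,
               quotients = matrix$quotients)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a binned matrix written by [write_binned_matrix()]
#'
#' @param path CSV path (the `<path>.meta.json` sidecar must sit next to it;
#'   without it the matrix is loaded as raw with bin starts parsed from the
#'   header).
#' @return A `binned_matrix`.
#' @export
read_binned_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    excl <- lapply(meta$excluded_regions, as.numeric)
    q <- meta$quotients
    if (!is.null(q) && !is.null(rownames(values)) && length(q) == nrow(values))
      names(q) <- rownames(values)
    structure(list(values = values, bin_starts = as.numeric(meta$bin_starts),
                   bin_width = meta$bin_width, excluded_regions = excl,
                   normalization = meta$normalization,
                   quotients = q, reference = NULL),
              class = "binned_matrix")
  } else {
    starts <- as.numeric(colnames(values))
    structure(list(values = values, bin_starts = starts,
                   bin_width = if (length(starts) > 1) min(diff(starts)) else NA,
                   excluded_regions = list(), normalization = "raw",
                   quotients = NULL, reference = NULL),
              class = "binned_matrix")
  }
}

#' Write / read a cohort table
#'
#' Plain CSV with the documented cohort columns.
#' @param cohort Cohort data frame.
#' @param path CSV path.
#' @return Invisibly `path` (write) or the data frame (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
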