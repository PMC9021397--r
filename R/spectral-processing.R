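#' Construct a spectrum object
#'
#' @param ppm Strictly monotone chemical-shift axis (ppm).
#' @param intensity Intensities, same length as `ppm`.
#' @param sample_id Label.
#' @return Object of class `spectrum`.
#' @export
new_spectrum <- function(ppm, intensity, sample_id = "S1") {
  if (length(ppm) != length(intensity))
    stopf("ppm and intensity lengths differ (%d vs %d)",
          length(ppm), length(intensity))
  d <- diff(ppm)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stopf("ppm axis must be strictly monotone")
  structure(list(ppm = as.numeric(ppm), intensity = as.numeric(intensity),
                 sample_id = sample_id),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: %d points, %.3f-%.3f ppm\n", x$sample_id,
              length(x$ppm), min(x$ppm), max(x$ppm)))
  invisible(x)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "ppm", ylab = "intensity") {
  graphics::plot(x$ppm, x$intensity, type = "l", xlim = rev(range(x$ppm)),
                 xlab = xlab, ylab = ylab, main = x$sample_id, ...)
  invisible(x)
}

#' Calibrate the chemical-shift axis to a reference peak
#'
#' Shifts the ppm axis so that the tallest point within
#' `reference_ppm +/- search_halfwidth` sits exactly at `reference_ppm`.
#' The conventional serum reference is the anomeric glucose doublet at
#' 5.24 ppm. Intensities are untouched.
#'
#' @param spectrum A `spectrum`.
#' @param reference_ppm Target position (ppm).
#' @param search_halfwidth Half-width of the search window (ppm).
#' @return Calibrated `spectrum`; the applied shift is stored in
#'   `attr(, "shift")`.
#' @export
calibrate_ppm <- function(spectrum, reference_ppm = 5.24,
                          search_halfwidth = 0.05) {
  stopifnot(inherits(spectrum, "spectrum"))
  lo <- reference_ppm - search_halfwidth
  hi <- reference_ppm + search_halfwidth
  in_win <- spectrum$ppm >= lo & spectrum$ppm <= hi
  if (!any(in_win))
    stopf("calibration error: spectrum does not cover window [%.3f, %.3f] ppm",
          lo, hi)
  yw <- spectrum$intensity[in_win]
  if (diff(range(yw)) <= 0)
    stopf("calibration error: no peak found in window [%.3f, %.3f] ppm", lo, hi)
  peak_ppm <- spectrum$ppm[in_win][which.max(yw)]
  shift <- reference_ppm - peak_ppm
  out <- new_spectrum(spectrum$ppm + shift, spectrum$intensity,
                      spectrum$sample_id)
  attr(out, "shift") <- shift
  out
}

#' Default excluded spectral regions
#'
#' Residual water (4.37-5.13 ppm) and ethanol (1.12-1.23 and 3.53-3.73 ppm).
#' @return List of length-2 numeric intervals.
#' @export
default_exclusions <- function() {
  list(water = c(4.37, 5.13), ethanol_triplet = c(1.12, 1.23),
       ethanol_quartet = c(3.53, 3.73))
}

# Exact trapezoidal integrals of the (linearly interpolated) spectrum over
# segments [a_k, b_k], with limits allowed to fall between grid points
# (clamped to the spectrum's support). Vectorized over segments: the
# cumulative trapezoid is computed once.
trapz_segments <- function(ppm, intensity, a, b) {
  np <- length(ppm)
  cum <- c(0, cumsum(diff(ppm) * (intensity[-np] + intensity[-1]) / 2))
  eval_cum <- function(x) {
    x <- pmin(pmax(x, ppm[1]), ppm[np])
    j <- findInterval(x, ppm, rightmost.closed = TRUE)
    j <- pmin(pmax(j, 1L), np - 1L)
    y_x <- intensity[j] + (intensity[j + 1L] - intensity[j]) *
      (x - ppm[j]) / (ppm[j + 1L] - ppm[j])
    cum[j] + (x - ppm[j]) * (intensity[j] + y_x) / 2
  }
  eval_cum(b) - eval_cum(a)
}

#' Bin a spectrum into equal-width chemical-shift bins
#'
#' Segments the axis into `bin_width`-wide bins over `range`, integrates each
#' bin trapezoidally, and drops every bin whose interval has positive-length
#' overlap with an exclusion region. With the defaults (0.02 ppm bins over
#' 0.2-10 ppm, water + ethanol exclusions) 490 bins are formed and 434
#' retained. Bins are labeled by their starting ppm.
#'
#' @param spectrum A `spectrum` covering `range` (either axis direction).
#' @param bin_width Bin width in ppm (> 0).
#' @param range Length-2 interval binned over.
#' @param exclusions List of length-2 ppm intervals to remove (possibly
#'   empty); intervals outside `range` are clipped with a warning.
#' @return Named numeric vector of retained bin integrals (names = starting
#'   ppm), with attributes `bin_starts`, `bin_width`, `excluded_regions`.
#' @export
bin_spectrum <- function(spectrum, bin_width = 0.02, range = c(0.2, 10),
                         exclusions = default_exclusions()) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (bin_width <= 0) stopf("bin_width must be > 0")
  o <- order(spectrum$ppm)
  ppm <- spectrum$ppm[o]; intensity <- spectrum$intensity[o]
  # a freshly calibrated axis may fall short of the range by up to the
  # calibration shift; tolerate that, integrating edge bins over the
  # covered part only
  if (ppm[1] > range[1] + 0.05 || ppm[length(ppm)] < range[2] - 0.05)
    stopf("spectrum (%.3f-%.3f ppm) does not cover the binning range [%g, %g]",
          ppm[1], ppm[length(ppm)], range[1], range[2])
  n_bins <- floor((range[2] - range[1]) / bin_width + 1e-9)
  starts <- range[1] + bin_width * (seq_len(n_bins) - 1)
  ends <- starts + bin_width
  keep <- rep(TRUE, n_bins)
  for (ex in exclusions) {
    ex <- sort(as.numeric(ex))
    if (ex[2] < range[1] || ex[1] > range[2]) {
      warnf("exclusion [%g, %g] lies outside the binning range; ignored",
            ex[1], ex[2])
      next
    }
    clipped <- c(max(ex[1], range[1]), min(ex[2], range[2]))
    if (!isTRUE(all.equal(clipped, ex)))
      warnf("exclusion [%g, %g] clipped to the binning range", ex[1], ex[2])
    keep <- keep & !(starts < clipped[2] - 1e-9 & ends > clipped[1] + 1e-9)
  }
  vals <- trapz_segments(ppm, intensity, starts[keep], ends[keep])
  names(vals) <- formatC(starts[keep], format = "f", digits = 2)
  structure(vals, bin_starts = starts[keep], bin_width = bin_width,
            excluded_regions = exclusions)
}

#' Bin a set of spectra into a samples-by-bins matrix
#'
#' @param spectra List of `spectrum` objects.
#' @inheritParams bin_spectrum
#' @return A `binned_matrix`: list with `values` (samples x bins matrix),
#'   `bin_starts`, `bin_width`, `excluded_regions`, `normalization`
#'   (`"raw"`), and (after PQN) `quotients` and `reference`.
#' @export
bin_spectra <- function(spectra, bin_width = 0.02, range = c(0.2, 10),
                        exclusions = default_exclusions()) {
  rows <- lapply(spectra, bin_spectrum, bin_width = bin_width, range = range,
                 exclusions = exclusions)
  values <- do.call(rbind, rows)
  rownames(values) <- unname(vapply(spectra, function(s) s$sample_id,
                                    character(1)))
  structure(list(values = values,
                 bin_starts = attr(rows[[1]], "bin_starts"),
                 bin_width = bin_width,
                 excluded_regions = exclusions,
                 normalization = "raw",
                 quotients = NULL,
                 reference = NULL),
            class = "binned_matrix")
}

#' @export
print.binned_matrix <- function(x, ...) {
  cat(sprintf("<binned_matrix> %d samples x %d bins (width %g ppm), %s\n",
              nrow(x$values), ncol(x$values), x$bin_width, x$normalization))
  invisible(x)
}

#' @export
dim.binned_matrix <- function(x) dim(x$values)

#' @export
as.matrix.binned_matrix <- function(x, ...) x$values

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution differences: each sample is divided by the
#' median, over bins where the reference is strictly positive, of its
#' bin-wise ratio to a reference spectrum. The reference is the element-wise
#' median spectrum of the matrix. Renormalizing an already-normalized matrix
#' reuses the stored reference, so it is an exact no-op (all quotients 1).
#'
#' @param matrix A `binned_matrix` with at least 2 samples.
#' @return The normalized `binned_matrix` with `quotients` (one per sample)
#'   and `reference` filled in and `normalization = "pqn"`.
#' @export
pqn_normalize <- function(matrix) {
  stopifnot(inherits(matrix, "binned_matrix"))
  v <- matrix$values
  if (nrow(v) < 2) stopf("PQN needs at least 2 samples")
  zero_rows <- rowSums(abs(v)) == 0
  if (any(zero_rows))
    stopf("PQN error: all-zero sample(s): %s",
          paste(rownames(v)[zero_rows], collapse = ", "))
  ref <- if (identical(matrix$normalization, "pqn")) matrix$reference
         else apply(v, 2, stats::median)
  pos <- ref > 0
  if (mean(pos) < 0.5)
    stopf("PQN error: reference spectrum positive on only %.0f%% of bins",
          100 * mean(pos))
  quotients <- apply(v[, pos, drop = FALSE], 1, function(s)
    stats::median(s / ref[pos]))
  if (any(!is.finite(quotients) | quotients == 0))
    stopf("PQN error: degenerate quotient for sample(s): %s",
          paste(rownames(v)[!is.finite(quotients) | quotients == 0],
                collapse = ", "))
  matrix$values <- v / quotients
  matrix$quotients <- quotients
  matrix$reference <- ref
  matrix$normalization <- "pqn"
  matrix
}

#' Principal component scores of a binned matrix
#'
#' Column-mean-centered singular value decomposition, the standard
#' unsupervised first look at a fingerprint matrix.
#'
#' @param matrix A `binned_matrix` or plain numeric matrix.
#' @param n_components Number of components (1 <= k <= min(n-1, p)).
#' @return List with `scores` (n x k), `explained_variance` (fractions,
#'   non-increasing) and `loadings` (p x k).
#' @export
pca_scores <- function(matrix, n_components = 2) {
  v <- if (inherits(matrix, "binned_matrix")) matrix$values else as.matrix(matrix)
  kmax <- min(nrow(v) - 1L, ncol(v))
  if (n_components < 1) stopf("n_components must be >= 1")
  if (n_components > kmax)
    stopf("n_components must be <= min(samples - 1, bins) = %d", kmax)
  vc <- scale(v, scale = FALSE)
  sv <- svd(vc, nu = n_components, nv = n_components)
  scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
  rownames(scores) <- rownames(v)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores,
       explained_variance = (sv$d^2 / sum(sv$d^2))[seq_len(n_components)],
       loadings = sv$v)
}
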