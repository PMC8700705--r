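#' Construct a spectrum set
#'
#' A `spectrum_set` is the common currency of the pipeline: one averaged
#' transmittance spectrum per sample, together with the wavelength grid,
#' the class labels and the measurement orientation.
#'
#' @param intensities numeric matrix, samples in rows, wavelengths in columns;
#'   all values must be strictly positive (band ratios require it).
#' @param wavelengths_nm strictly increasing numeric vector of wavelengths in
#'   nanometres, one per column of `intensities`.
#' @param labels vector of class labels, `1` for healthy and `-1` for
#'   watercore samples.
#' @param sample_ids character vector of unique sample identifiers; generated
#'   as `"s1"`, `"s2"`, ... when omitted.
#' @param orientation measurement orientation, one of `"O1"`, `"O2"`, `"O3"`:
#'   stem-up equatorial, stem-to-lamp axial, and travel-axis equatorial poses
#'   of the fruit on the conveyor.
#'
#' @return An object of class `spectrum_set`: a list with elements
#'   `intensities`, `wavelengths_nm`, `labels`, `sample_ids`, `orientation`.
#' @export
#' @examples
#' s <- spectrum_set(matrix(1:6 + 0, 2, 3), c(700, 800, 900), c(1, -1))
#' dim(s$intensities)
spectrum_set <- function(intensities, wavelengths_nm, labels,
                         sample_ids = NULL, orientation = "O1") {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavelengths_nm <- as.numeric(wavelengths_nm)
  if (ncol(intensities) != length(wavelengths_nm)) {
    stop("number of intensity columns (", ncol(intensities),
         ") does not match number of wavelengths (", length(wavelengths_nm), ")")
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths_nm must be strictly increasing")
  }
  labels <- as.numeric(labels)
  if (nrow(intensities) != length(labels)) {
    stop("number of intensity rows (", nrow(intensities),
         ") does not match number of labels (", length(labels), ")")
  }
  if (!all(labels %in% c(1, -1))) {
    stop("labels must be 1 (healthy) or -1 (watercore)")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(intensities)) {
    stop("sample_ids length does not match number of samples")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  orientation <- match_orientation(orientation)
  structure(
    list(intensities = unname(intensities),
         wavelengths_nm = wavelengths_nm,
         labels = labels,
         sample_ids = sample_ids,
         orientation = orientation),
    class = "spectrum_set"
  )
}

match_orientation <- function(orientation) {
  if (length(orientation) != 1L || !orientation %in% c("O1", "O2", "O3")) {
    stop("orientation must be one of \"O1\", \"O2\", \"O3\"")
  }
  orientation
}

#' @export
print.spectrum_set <- function(x, ...) {
  n <- nrow(x$intensities)
  cat("Spectrum set (", x$orientation, "): ", n, " samples x ",
      length(x$wavelengths_nm), " wavelengths [",
      format(min(x$wavelengths_nm)), "-", format(max(x$wavelengths_nm)),
      " nm]\n", sep = "")
  cat("  healthy (1): ", sum(x$labels == 1),
      "   watercore (-1): ", sum(x$labels == -1), "\n", sep = "")
  invisible(x)
}

#' Subset a spectrum set by sample
#'
#' @param set a [spectrum_set()].
#' @param idx integer, logical, or character (sample id) index of samples to
#'   keep.
#' @return A `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(set, idx) {
  stopifnot(inherits(set, "spectrum_set"))
  if (is.character(idx)) idx <- match(idx, set$sample_ids)
  if (anyNA(idx)) stop("unknown sample ids in subset")
  spectrum_set(set$intensities[idx, , drop = FALSE], set$wavelengths_nm,
               set$labels[idx], set$sample_ids[idx], set$orientation)
}
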