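#' Trim saturated scans and average a raw scan block
#'
#' The first three and last three scans of each block are recorded while the
#' fruit enters or leaves the light path and are saturated; they are
#' discarded unconditionally, and the per-wavelength arithmetic mean of the
#' remaining scans becomes the sample's spectrum.
#'
#' @param block a `scan_block` (see [simulate_scan_blocks()]).
#' @return Numeric vector: the mean spectrum over scans `4..(n_scans - 3)`.
#' @export
#' @examples
#' b <- simulate_scan_blocks(synthetic_config(
#'   n_healthy = 1, n_watercore = 1, n_wavelengths = 20))[[1]]
#' length(trim_and_average(b))
trim_and_average <- function(block) {
  stopifnot(inherits(block, "scan_block"))
  n <- nrow(block$scans)
  if (n <= 6) {
    stop("sample ", block$sample_id, " has only ", n,
         " scans; at least 7 are required to survive the 3 + 3 trim")
  }
  colMeans(block$scans[4:(n - 3), , drop = FALSE])
}

#' Average a list of scan blocks into a spectrum set
#'
#' Applies [trim_and_average()] to every block and assembles the result into
#' a [spectrum_set()]. All blocks must share one wavelength grid and one
#' orientation.
#'
#' @param blocks list of `scan_block` objects.
#' @return A [spectrum_set()] with one row per block.
#' @export
average_scans <- function(blocks) {
  if (length(blocks) == 0) stop("no scan blocks supplied")
  wl <- blocks[[1]]$wavelengths_nm
  orientation <- blocks[[1]]$orientation
  for (b in blocks) {
    if (!identical(b$wavelengths_nm, wl)) {
      stop("scan blocks have inconsistent wavelength grids")
    }
    if (!identical(b$orientation, orientation)) {
      stop("scan blocks mix measurement orientations")
    }
  }
  intensities <- t(vapply(blocks, trim_and_average, numeric(length(wl))))
  spectrum_set(intensities, wl,
               labels = vapply(blocks, function(b) b$label, numeric(1)),
               sample_ids = vapply(blocks, function(b) b$sample_id, character(1)),
               orientation = orientation)
}

#' Crop a spectrum set to a wavelength range
#'
#' Retains exactly the wavelengths inside the closed interval
#' `[lo_nm, hi_nm]`; used to discard the low signal-to-noise ends of the
#' detector range before analysis.
#'
#' @param set a [spectrum_set()].
#' @param lo_nm,hi_nm closed interval bounds in nm.
#' @return The cropped `spectrum_set`; labels and sample ids are untouched.
#' @export
crop_range <- function(set, lo_nm = 680, hi_nm = 1000) {
  stopifnot(inherits(set, "spectrum_set"))
  if (lo_nm >= hi_nm) stop("lo_nm must be below hi_nm")
  keep <- set$wavelengths_nm >= lo_nm & set$wavelengths_nm <= hi_nm
  if (sum(keep) < 2) {
    stop("fewer than 2 wavelengths fall inside [", lo_nm, ", ", hi_nm, "] nm")
  }
  spectrum_set(set$intensities[, keep, drop = FALSE],
               set$wavelengths_nm[keep], set$labels, set$sample_ids,
               set$orientation)
}
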