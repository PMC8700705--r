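#' Two-band transmittance ratio
#'
#' The ratio feature R_i/k = T_i / T_k: per sample, the transmittance at
#' band `i` divided by the transmittance at band `k`. Being a quotient it
#' cancels per-sample multiplicative intensity variation (fruit size,
#' scatter), which is why a single well-chosen ratio can discriminate
#' watercore tissue.
#'
#' @param set a [spectrum_set()].
#' @param i,k column indices of the numerator and denominator bands.
#' @return Numeric vector with one ratio per sample.
#' @export
ratio_values <- function(set, i, k) {
  stopifnot(inherits(set, "spectrum_set"))
  W <- ncol(set$intensities)
  if (i < 1 || i > W || k < 1 || k > W) stop("band index out of range")
  denom <- set$intensities[, k]
  bad <- which(denom <= 0)
  if (length(bad)) {
    stop("nonpositive denominator intensity at band ", k, " for sample ",
         set$sample_ids[bad[1]])
  }
  set$intensities[, i] / denom
}

#' Exhaustive two-band-ratio F-value search
#'
#' Computes the two-group ANOVA F value of every ordered band ratio
#' R_i/k = T_i / T_k (all `W x W` pairs, `i != k`) between the healthy and
#' watercore samples, and selects the pair with the largest F value as the
#' optimal ratio. Run on the calibration samples only.
#'
#' The matrix is filled one denominator band at a time (all numerators of
#' one `k` are vectorised together), so peak memory is one `n x block` ratio
#' block; `block_cols` caps the number of numerator columns held at once.
#' The diagonal is `NA`: a self-ratio is constant 1 and its F value is
#' undefined (0/0). Ties for the maximum are broken by the smaller `i`,
#' then the smaller `k`.
#'
#' @param set a [spectrum_set()] with both classes and strictly positive
#'   intensities.
#' @param block_cols maximum number of numerator columns evaluated per
#'   block; the default handles the full 1185-band grid in one block per
#'   denominator.
#' @return An object of class `ratio_f_matrix`: list with `wavelengths_nm`,
#'   `f_matrix` (entry `[i, k]` is the F value of T_i/T_k, diagonal `NA`),
#'   `best_pair` (indices `i`, `k`), `best_pair_nm` and `best_f`.
#' @export
ratio_f_search <- function(set, block_cols = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  X <- set$intensities
  if (any(X <= 0)) stop("all intensities must be strictly positive for ratios")
  ia <- set$labels == 1
  ib <- set$labels == -1
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("both classes need at least 2 samples for the ratio search")
  }
  W <- ncol(X)
  if (is.null(block_cols)) block_cols <- W
  block_cols <- max(1L, as.integer(block_cols))
  starts <- seq.int(1L, W, by = block_cols)
  Fm <- matrix(NA_real_, W, W)
  for (k in seq_len(W)) {
    inv_k <- 1 / X[, k]
    for (s in starts) {
      cols <- s:min(s + block_cols - 1L, W)
      R <- X[, cols, drop = FALSE] * inv_k
      Fm[cols, k] <- f_columns(R, ia, ib)
    }
    Fm[k, k] <- NA_real_
  }
  best_f <- max(Fm, na.rm = TRUE)
  ties <- which(Fm == best_f, arr.ind = TRUE)
  ties <- ties[order(ties[, 1], ties[, 2]), , drop = FALSE]
  best <- as.integer(ties[1, ])
  structure(list(wavelengths_nm = set$wavelengths_nm,
                 f_matrix = Fm,
                 best_pair = c(i = best[1], k = best[2]),
                 best_pair_nm = c(i = set$wavelengths_nm[best[1]],
                                  k = set$wavelengths_nm[best[2]]),
                 best_f = best_f),
            class = "ratio_f_matrix")
}

#' @export
print.ratio_f_matrix <- function(x, ...) {
  cat("Two-band-ratio F matrix over", length(x$wavelengths_nm),
      "wavelengths\n")
  cat("  optimal ratio: ", format(x$best_pair_nm[["i"]], digits = 6), " nm / ",
      format(x$best_pair_nm[["k"]], digits = 6), " nm (F = ",
      format(x$best_f, digits = 5), ")\n", sep = "")
  invisible(x)
}

#' Export a ratio F matrix as a long-format contour table
#'
#' Writes one row per defined (off-diagonal) entry with columns
#' `wavelength_i`, `wavelength_k`, `F`, the format contour plots are drawn
#' from. [read_ratio_contour()] reconstructs the matrix.
#'
#' @param matrix a [ratio_f_search()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratio_contour <- function(matrix, path) {
  stopifnot(inherits(matrix, "ratio_f_matrix"))
  W <- length(matrix$wavelengths_nm)
  idx <- which(!is.na(matrix$f_matrix), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(wavelength_i = matrix$wavelengths_nm[idx[, 1]],
                   wavelength_k = matrix$wavelengths_nm[idx[, 2]],
                   F = matrix$f_matrix[idx])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format contour table back into a ratio F matrix
#'
#' @param path CSV written by [write_ratio_contour()].
#' @return An object of class `ratio_f_matrix` (see [ratio_f_search()]).
#' @export
read_ratio_contour <- function(path) {
  df <- utils::read.csv(path)
  wl <- sort(unique(c(df$wavelength_i, df$wavelength_k)))
  W <- length(wl)
  Fm <- matrix(NA_real_, W, W)
  Fm[cbind(match(df$wavelength_i, wl), match(df$wavelength_k, wl))] <- df$F
  best_f <- max(Fm, na.rm = TRUE)
  ties <- which(Fm == best_f, arr.ind = TRUE)
  ties <- ties[order(ties[, 1], ties[, 2]), , drop = FALSE]
  best <- as.integer(ties[1, ])
  structure(list(wavelengths_nm = wl, f_matrix = Fm,
                 best_pair = c(i = best[1], k = best[2]),
                 best_pair_nm = c(i = wl[best[1]], k = wl[best[2]]),
                 best_f = best_f),
            class = "ratio_f_matrix")
}
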