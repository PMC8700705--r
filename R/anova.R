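#' One-way ANOVA F statistic for two groups
#'
#' For two groups the one-way ANOVA F value is the ratio of the
#' between-group mean square (1 degree of freedom) to the pooled
#' within-group mean square, and equals the square of the pooled two-sample
#' t statistic. It is used here as a separability score ranking wavelengths
#' and band ratios, not as a significance test.
#'
#' @param a,b numeric vectors, the two groups (each of size at least 2).
#' @return The F value, nonnegative. If the within-group sum of squares is
#'   zero while the group means differ, the separation is perfect and
#'   `Inf` is returned; if the group means are equal the value is 0.
#' @export
#' @examples
#' f_oneway_two_groups(c(1, 2, 3), c(4, 5, 6))  # 13.5
f_oneway_two_groups <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop("both groups need at least 2 observations")
  }
  na <- length(a)
  nb <- length(b)
  ma <- mean(a)
  mb <- mean(b)
  m <- (sum(a) + sum(b)) / (na + nb)
  ssb <- na * (ma - m)^2 + nb * (mb - m)^2
  ssw <- sum((a - ma)^2) + sum((b - mb)^2)
  if (ssb == 0) return(0)
  if (ssw == 0) return(Inf)
  ssb / (ssw / (na + nb - 2))
}

# Vectorized column-wise two-group F values. `X` is samples x variables,
# `ia`/`ib` logical row masks. Same summation structure as the scalar
# function; returns Inf where SSW == 0 with SSB > 0 and 0 where SSB == 0.
f_columns <- function(X, ia, ib) {
  na <- sum(ia)
  nb <- sum(ib)
  sa <- colSums(X[ia, , drop = FALSE])
  sb <- colSums(X[ib, , drop = FALSE])
  qa <- colSums(X[ia, , drop = FALSE]^2)
  qb <- colSums(X[ib, , drop = FALSE]^2)
  ma <- sa / na
  mb <- sb / nb
  m <- (sa + sb) / (na + nb)
  ssb <- na * (ma - m)^2 + nb * (mb - m)^2
  ssw <- pmax((qa - na * ma^2) + (qb - nb * mb^2), 0)
  f <- ssb / (ssw / (na + nb - 2))
  f[ssw == 0] <- Inf
  f[ssb == 0] <- 0
  f
}

#' Per-wavelength ANOVA F scan of a spectrum set
#'
#' Computes the two-group F value at every wavelength, comparing healthy
#' (label 1) against watercore (label -1) samples. Wavelengths where the F
#' value is infinite (zero within-group variance, degenerate with real
#' data) are flagged and excluded from characteristic-wavelength selection.
#'
#' @param set a [spectrum_set()] containing both classes, typically the
#'   calibration subset.
#' @return An object of class `f_scan`: list with `wavelengths_nm`,
#'   `f_values`, `infinite` (logical flags), and empty selection slots to be
#'   filled by [select_characteristic_wavelengths()].
#' @export
f_scan <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  ia <- set$labels == 1
  ib <- set$labels == -1
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("both classes need at least 2 samples for an F scan")
  }
  f <- f_columns(set$intensities, ia, ib)
  structure(list(wavelengths_nm = set$wavelengths_nm,
                 f_values = f,
                 infinite = is.infinite(f),
                 selected_indices = integer(0),
                 selected_wavelengths_nm = numeric(0)),
            class = "f_scan")
}

# Indices of strict interior local maxima of `f`; plateaus
# (f[i-1] < f[i] == ... == f[i+r] > next) contribute their leftmost index.
local_maxima <- function(f) {
  r <- rle(f)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nr <- length(r$values)
  if (nr < 3) return(integer(0))
  mid <- 2:(nr - 1)
  is_max <- r$values[mid] > r$values[mid - 1] & r$values[mid] > r$values[mid + 1]
  starts[mid][is_max]
}

#' Select characteristic wavelengths from an F scan
#'
#' Characteristic wavelengths are the strict interior local maxima of the
#' F-value curve, ranked by F value; the top `k` are kept. If fewer than `k`
#' local maxima exist (e.g. a monotone curve), the selection is padded with
#' the largest remaining finite F values that are not adjacent to an
#' already-selected index, so a monotone curve still yields its global
#' maximum. Infinite F values are excluded.
#'
#' @param result an [f_scan()] result (curve of length at least 3).
#' @param k number of wavelengths to select; the models downstream use 2.
#' @return The `f_scan` object with `selected_indices` and
#'   `selected_wavelengths_nm` filled (ascending wavelength order).
#' @export
select_characteristic_wavelengths <- function(result, k = 2) {
  stopifnot(inherits(result, "f_scan"))
  if (k < 1) stop("k must be at least 1")
  f <- result$f_values
  if (length(f) < 3) stop("F curve must have at least 3 points")
  usable <- is.finite(f)
  peaks <- local_maxima(f)
  peaks <- peaks[usable[peaks]]
  peaks <- peaks[order(-f[peaks], peaks)]
  sel <- utils::head(peaks, k)
  if (length(sel) < k) {
    pool <- setdiff(which(usable), sel)
    pool <- pool[order(-f[pool], pool)]
    for (i in pool) {
      if (length(sel) >= k) break
      if (all(abs(sel - i) > 1)) sel <- c(sel, i)
    }
  }
  sel <- sort(sel)
  result$selected_indices <- sel
  result$selected_wavelengths_nm <- result$wavelengths_nm[sel]
  result
}

#' @export
print.f_scan <- function(x, ...) {
  cat("ANOVA F scan over", length(x$f_values), "wavelengths; max F =",
      format(max(x$f_values[is.finite(x$f_values)]), digits = 5), "\n")
  if (length(x$selected_indices)) {
    cat("  characteristic wavelengths:",
        paste(format(x$selected_wavelengths_nm, digits = 6), collapse = ", "),
        "nm\n")
  }
  invisible(x)
}

#' @export
plot.f_scan <- function(x, ...) {
  graphics::plot(x$wavelengths_nm, x$f_values, type = "l",
                 xlab = "wavelength (nm)", ylab = "F value", ...)
  if (length(x$selected_indices)) {
    graphics::points(x$selected_wavelengths_nm,
                     x$f_values[x$selected_indices], col = 2, pch = 19)
  }
  invisible(x)
}
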