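#' Fit the single-ratio threshold discriminator
#'
#' Given the selected two-band ratio of each calibration sample, scans
#' candidate thresholds from the smallest to the largest observed ratio in
#' fixed steps (both endpoints included) and keeps the candidate with the
#' highest total calibration accuracy under the rule
#' *ratio <= threshold => watercore (-1), ratio > threshold => healthy (1)*.
#' Ties are resolved towards the largest maximising candidate, i.e. the
#' upper edge of the class-overlap region.
#'
#' @param ratios numeric vector of two-band ratio values, one per sample.
#' @param labels class labels, `1` healthy / `-1` watercore; both classes
#'   must be present.
#' @param step threshold grid step; the scan resolution of 1e-4 resolves
#'   ratio values quoted to 4 decimals.
#' @param band_i_nm,band_k_nm optional band metadata stored in the model.
#' @return An object of class `threshold_model` with fields `band_i_nm`,
#'   `band_k_nm`, `threshold`, `step`, `calibration_accuracy` (fraction),
#'   and `accuracy_curve` (data frame of candidate thresholds and their
#'   total/per-class accuracies, for plotting).
#' @export
#' @examples
#' m <- fit_threshold(c(1.0, 1.1, 1.5, 1.6), c(-1, -1, 1, 1))
#' m$threshold
#' predict(m, c(1.2, 1.55))
fit_threshold <- function(ratios, labels, step = 1e-4,
                          band_i_nm = NA_real_, band_k_nm = NA_real_) {
  ratios <- as.numeric(ratios)
  labels <- as.numeric(labels)
  if (length(ratios) != length(labels)) stop("ratios and labels differ in length")
  if (!all(labels %in% c(1, -1))) stop("labels must be 1 or -1")
  if (!any(labels == 1) || !any(labels == -1)) {
    stop("both classes must be present to fit a threshold")
  }
  if (!is.numeric(step) || step <= 0) stop("step must be positive")
  lo <- min(ratios)
  hi <- max(ratios)
  grid <- seq(lo, hi, by = step)
  if (grid[length(grid)] < hi) grid <- c(grid, hi)

  rw <- sort(ratios[labels == -1])
  rh <- sort(ratios[labels == 1])
  n <- length(ratios)
  # watercore correct: ratio <= t; healthy correct: ratio > t
  w_le <- findInterval(grid, rw)
  h_le <- findInterval(grid, rh)
  correct <- w_le + (length(rh) - h_le)
  acc <- correct / n
  best_acc <- max(acc)
  best_idx <- max(which(acc == best_acc))   # largest maximising candidate
  curve <- data.frame(threshold = grid,
                      total = acc,
                      watercore = w_le / length(rw),
                      healthy = (length(rh) - h_le) / length(rh))
  structure(list(band_i_nm = band_i_nm, band_k_nm = band_k_nm,
                 threshold = grid[best_idx],
                 step = step,
                 calibration_accuracy = best_acc,
                 n_calibration = n,
                 ratio_range = c(lo, hi),
                 accuracy_curve = curve,
                 calibration_ratios = ratios,
                 calibration_labels = labels),
            class = "threshold_model")
}

#' Predict classes from a fitted threshold model
#'
#' @param object a [fit_threshold()] model.
#' @param ratios numeric vector of two-band ratio values.
#' @param ... unused.
#' @return Numeric label vector: `-1` (watercore) where
#'   `ratio <= threshold` (the boundary itself counts as watercore), `1`
#'   (healthy) otherwise.
#' @export
predict.threshold_model <- function(object, ratios, ...) {
  ifelse(as.numeric(ratios) <= object$threshold, -1, 1)
}

#' @export
print.threshold_model <- function(x, ...) {
  bands <- if (is.na(x$band_i_nm)) "" else {
    paste0(" [", format(x$band_i_nm, digits = 6), "/",
           format(x$band_k_nm, digits = 6), " nm]")
  }
  cat("Two-band-ratio threshold model", bands, "\n", sep = "")
  cat("  rule: ratio <= ", format(x$threshold, digits = 6),
      " => watercore (-1), otherwise healthy (1)\n", sep = "")
  cat("  calibration accuracy: ",
      format(100 * x$calibration_accuracy, digits = 4), "% of ",
      x$n_calibration, " samples\n", sep = "")
  invisible(x)
}

#' @export
summary.threshold_model <- function(object, ...) {
  cat("Threshold discrimination model\n")
  print(object)
  cat("  ratio range: [", format(object$ratio_range[1], digits = 6), ", ",
      format(object$ratio_range[2], digits = 6), "], scan step ",
      object$step, " (", nrow(object$accuracy_curve), " candidates)\n",
      sep = "")
  invisible(object)
}

#' Plot the calibration ratio distribution and the accuracy scan
#'
#' Left panel: per-class two-band ratio values of the calibration samples
#' with the fitted threshold. Right panel: total and per-class accuracy as
#' the candidate threshold sweeps the observed ratio range.
#'
#' @param x a [fit_threshold()] model.
#' @param ... passed to the underlying plot calls.
#' @export
plot.threshold_model <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  col <- ifelse(x$calibration_labels == 1, "red3", "blue3")
  graphics::plot(seq_along(x$calibration_ratios), x$calibration_ratios,
                 col = col, pch = 19, xlab = "sample",
                 ylab = "two-band ratio", ...)
  graphics::abline(h = x$threshold, lty = 2)
  cv <- x$accuracy_curve
  graphics::plot(cv$threshold, 100 * cv$total, type = "l",
                 xlab = "candidate threshold", ylab = "accuracy (%)", ...)
  graphics::lines(cv$threshold, 100 * cv$healthy, col = "red3")
  graphics::lines(cv$threshold, 100 * cv$watercore, col = "blue3")
  graphics::abline(v = x$threshold, lty = 2)
  invisible(x)
}

#' Serialize a threshold model to JSON
#'
#' @param model a [fit_threshold()] model.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_threshold_model_json <- function(model, path) {
  stopifnot(inherits(model, "threshold_model"))
  obj <- list(band_i_nm = model$band_i_nm, band_k_nm = model$band_k_nm,
              threshold = model$threshold, step = model$step,
              calibration_accuracy = model$calibration_accuracy)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
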