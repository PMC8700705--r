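#' Calibration/prediction sizes for one class
#'
#' Splits a class of `n_class` samples at the given ratio. The prediction
#' count is `n_class * pred_ratio / (cal_ratio + pred_ratio)` rounded half
#' to even; the calibration count is the remainder. At the default 3:1 this
#' reproduces the study's printed partition (138 -> 104/34, 127 -> 95/32).
#'
#' @param n_class class size (at least 2).
#' @param cal_ratio,pred_ratio integer ratio parts, calibration:prediction.
#' @return Named integer vector `c(n_cal, n_pred)`.
#' @export
#' @examples
#' split_sizes(127)  # 95 calibration, 32 prediction
split_sizes <- function(n_class, cal_ratio = 3, pred_ratio = 1) {
  if (n_class < 2) stop("a class needs at least 2 samples to split")
  if (cal_ratio <= 0 || pred_ratio <= 0) stop("ratio parts must be positive")
  n_pred <- as.integer(round(n_class * pred_ratio / (cal_ratio + pred_ratio)))
  c(n_cal = as.integer(n_class) - n_pred, n_pred = n_pred)
}

#' SPXY calibration-sample selection
#'
#' Greedy sample-set partitioning based on joint X--Y distances, a
#' generalisation of the Kennard--Stone algorithm: pairwise distances are
#' Euclidean in `X` and absolute differences in `y`, each normalised by its
#' maximum, and summed. Selection starts with the most distant pair and
#' repeatedly adds the sample whose minimum distance to the selected set is
#' largest (maximin), so the calibration set spans both predictor and
#' response space.
#'
#' When `y` is constant (the within-class case) its distance contribution is
#' defined as zero and the procedure reduces exactly to Kennard--Stone on
#' `X` alone. Ties are broken by the lowest sample index, so the selection
#' is deterministic.
#'
#' @param X numeric matrix (samples x features).
#' @param y numeric response vector, one value per row of `X`.
#' @param k number of samples to select, between 2 and `nrow(X)`.
#' @return Integer vector of the `k` selected row indices, in selection
#'   order.
#' @export
#' @examples
#' spxy_select(matrix(c(0, 1, 10)), c(0, 0, 0), 2)  # the extreme pair
spxy_select <- function(X, y, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) stop("y must have one value per row of X")
  if (k < 2 || k > n) stop("k must be between 2 and the number of samples")
  dX <- as.matrix(stats::dist(X))
  dY <- abs(outer(as.numeric(y), as.numeric(y), "-"))
  mX <- max(dX)
  mY <- max(dY)
  D <- (if (mX > 0) dX / mX else dX * 0) + (if (mY > 0) dY / mY else dY * 0)

  # seed with the globally most distant pair; ties -> lowest (i, j) indices
  best <- which(D == max(D), arr.ind = TRUE)
  best <- best[best[, 1] < best[, 2], , drop = FALSE]
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
  selected <- as.integer(best[1, ])
  remaining <- setdiff(seq_len(n), selected)
  min_d <- pmin(D[, selected[1]], D[, selected[2]])
  while (length(selected) < k) {
    cand <- remaining[min_d[remaining] == max(min_d[remaining])]
    pick <- min(cand)
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    min_d <- pmin(min_d, D[, pick])
  }
  selected
}

#' Split a spectrum set into calibration and prediction sets per class
#'
#' Applies [split_sizes()] and [spxy_select()] within each class (the
#' selected samples form the calibration set; within a class the response is
#' constant, so the selection is Kennard--Stone on the spectra) and merges
#' the two classes.
#'
#' @param set a [spectrum_set()] containing both classes.
#' @param cal_ratio,pred_ratio split ratio, calibration:prediction.
#' @return An object of class `split_result`: list with `calibration_ids`,
#'   `prediction_ids` and `per_class_counts` (matrix with rows `healthy`,
#'   `watercore` and columns `n_cal`, `n_pred`).
#' @export
split_per_class <- function(set, cal_ratio = 3, pred_ratio = 1) {
  stopifnot(inherits(set, "spectrum_set"))
  counts <- matrix(0L, 2, 2,
                   dimnames = list(c("healthy", "watercore"),
                                   c("n_cal", "n_pred")))
  cal_ids <- character(0)
  pred_ids <- character(0)
  for (lab in c(1, -1)) {
    cls <- which(set$labels == lab)
    row <- if (lab == 1) "healthy" else "watercore"
    if (length(cls) < 2) {
      stop("class ", row, " has fewer than 2 samples; cannot partition")
    }
    sizes <- split_sizes(length(cls), cal_ratio, pred_ratio)
    counts[row, ] <- sizes
    sel <- spxy_select(set$intensities[cls, , drop = FALSE],
                       set$labels[cls], sizes[["n_cal"]])
    cal_ids <- c(cal_ids, set$sample_ids[cls[sel]])
    pred_ids <- c(pred_ids, set$sample_ids[cls[-sel]])
  }
  structure(list(calibration_ids = cal_ids, prediction_ids = pred_ids,
                 per_class_counts = counts),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("Calibration/prediction split:", length(x$calibration_ids), "/",
      length(x$prediction_ids), "samples\n")
  print(x$per_class_counts)
  invisible(x)
}
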