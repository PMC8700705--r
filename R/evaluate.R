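#' Percentage accuracy
#'
#' `100 * correct / total`, rounded half-to-even to two decimals (the
#' resolution the classification tables are reported at).
#'
#' @param correct number of correctly classified samples.
#' @param total group size (at least 1).
#' @return Accuracy in percent.
#' @export
#' @examples
#' accuracy_pct(30, 32)  # 93.75
accuracy_pct <- function(correct, total) {
  if (length(total) != 1 || total < 1) stop("total must be a positive count")
  if (correct < 0 || correct > total) stop("correct must lie in [0, total]")
  round(100 * correct / total, 2)
}

#' Per-class classification report
#'
#' Aggregates predictions into the table layout used to compare the
#' classifiers: total, healthy and watercore accuracy (percent) for the
#' calibration and prediction sets, plus the raw confusion counts.
#'
#' @param truth true labels (`1` / `-1`).
#' @param predicted predicted labels (`1` / `-1`), aligned with `truth`.
#' @param split character vector assigning each sample to `"calibration"`
#'   or `"prediction"`.
#' @param orientation measurement orientation tag.
#' @param model_name name of the classifier being scored.
#' @return An object of class `classification_report`: list with
#'   `orientation`, `model_name`, `accuracies` (data frame, one row per
#'   split) and `counts` (correct/total per class and split).
#' @export
classification_report <- function(truth, predicted, split,
                                  orientation = "O1", model_name = "model") {
  truth <- as.numeric(truth)
  predicted <- as.numeric(predicted)
  if (length(truth) != length(predicted) || length(truth) != length(split)) {
    stop("truth, predicted and split must be aligned")
  }
  if (!all(truth %in% c(1, -1)) || !all(predicted %in% c(1, -1))) {
    stop("labels must be 1 or -1")
  }
  if (!all(split %in% c("calibration", "prediction"))) {
    stop("split entries must be \"calibration\" or \"prediction\"")
  }
  splits <- intersect(c("calibration", "prediction"), unique(split))
  acc <- data.frame(set = splits, total = NA_real_, healthy = NA_real_,
                    watercore = NA_real_)
  counts <- list()
  for (s in splits) {
    in_s <- split == s
    h <- in_s & truth == 1
    w <- in_s & truth == -1
    ch <- sum(predicted[h] == 1)
    cw <- sum(predicted[w] == -1)
    counts[[s]] <- c(healthy_correct = ch, healthy_total = sum(h),
                     watercore_correct = cw, watercore_total = sum(w))
    acc[acc$set == s, "total"] <- accuracy_pct(ch + cw, sum(in_s))
    acc[acc$set == s, "healthy"] <- if (sum(h)) accuracy_pct(ch, sum(h)) else NA
    acc[acc$set == s, "watercore"] <- if (sum(w)) accuracy_pct(cw, sum(w)) else NA
  }
  structure(list(orientation = orientation, model_name = model_name,
                 accuracies = acc, counts = counts),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat("Classification report: ", x$model_name, " (", x$orientation, ")\n",
      sep = "")
  print(x$accuracies, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.classification_report <- function(x, ...) {
  df <- x$accuracies
  df$orientation <- x$orientation
  df$model <- x$model_name
  df[, c("orientation", "model", "set", "total", "healthy", "watercore")]
}

#' Write a classification report as CSV and JSON
#'
#' The CSV mirrors the accuracy table (percent, two decimals); the JSON
#' carries the raw confusion counts alongside.
#'
#' @param report a [classification_report()].
#' @param csv_path,json_path output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_report <- function(report, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(report, "classification_report"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(report), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(orientation = report$orientation, model = report$model_name,
           accuracies = report$accuracies,
           counts = lapply(report$counts, as.list)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
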