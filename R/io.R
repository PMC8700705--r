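#' Write scan blocks or a spectrum set as a wide CSV
#'
#' One row per scan (or per sample mean): columns `sample_id`,
#' `orientation`, `label`, `scan_index` (an integer, or `"mean"` for
#' averaged spectra), then one column per wavelength named by its value in
#' nm with two decimals. One file holds one orientation.
#'
#' @param x a list of `scan_block` objects or a [spectrum_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(x, path) {
  if (inherits(x, "spectrum_set")) {
    wl <- x$wavelengths_nm
    df <- data.frame(sample_id = x$sample_ids,
                     orientation = x$orientation,
                     label = x$labels,
                     scan_index = "mean",
                     stringsAsFactors = FALSE)
    mat <- x$intensities
  } else {
    if (!length(x) || !inherits(x[[1]], "scan_block")) {
      stop("x must be a spectrum_set or a list of scan blocks")
    }
    wl <- x[[1]]$wavelengths_nm
    df <- do.call(rbind, lapply(x, function(b) {
      data.frame(sample_id = b$sample_id, orientation = b$orientation,
                 label = b$label, scan_index = seq_len(nrow(b$scans)),
                 stringsAsFactors = FALSE)
    }))
    mat <- do.call(rbind, lapply(x, function(b) b$scans))
  }
  colnames(mat) <- sprintf("%.2f", wl)
  utils::write.csv(cbind(df, mat), path, row.names = FALSE)
  invisible(path)
}

#' Read a wide spectra CSV
#'
#' Reads the format written by [write_spectra_csv()]. Files whose
#' `scan_index` column is entirely `"mean"` come back as a
#' [spectrum_set()]; otherwise the rows are regrouped into `scan_block`
#' objects by `sample_id`.
#'
#' @param path CSV path.
#' @return A `spectrum_set` or a list of `scan_block` objects.
#' @export
read_spectra_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("sample_id", "orientation", "label", "scan_index")
  if (!all(meta_cols %in% names(df))) {
    stop("not a spectra CSV: missing columns ",
         paste(setdiff(meta_cols, names(df)), collapse = ", "))
  }
  wl_cols <- setdiff(names(df), meta_cols)
  wl <- as.numeric(wl_cols)
  mat <- as.matrix(df[, wl_cols, drop = FALSE])
  if (all(df$scan_index == "mean")) {
    return(spectrum_set(mat, wl, df$label, df$sample_id, df$orientation[1]))
  }
  ids <- unique(df$sample_id)
  lapply(ids, function(id) {
    rows <- which(df$sample_id == id)
    rows <- rows[order(as.integer(df$scan_index[rows]))]
    structure(list(sample_id = id,
                   orientation = df$orientation[rows[1]],
                   label = df$label[rows[1]],
                   wavelengths_nm = wl,
                   scans = unname(mat[rows, , drop = FALSE])),
              class = "scan_block")
  })
}

#' Write a calibration/prediction split as a two-column CSV
#'
#' @param split a [split_per_class()] result.
#' @param path output CSV path (columns `sample_id`, `set`).
#' @return `path`, invisibly.
#' @export
write_split_csv <- function(split, path) {
  stopifnot(inherits(split, "split_result"))
  df <- data.frame(
    sample_id = c(split$calibration_ids, split$prediction_ids),
    set = rep(c("calibration", "prediction"),
              c(length(split$calibration_ids), length(split$prediction_ids))),
    stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a split CSV back into a split result
#'
#' @param path CSV written by [write_split_csv()].
#' @return An object of class `split_result` (per-class counts absent).
#' @export
read_split_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "set") %in% names(df))) {
    stop("not a split CSV")
  }
  structure(list(calibration_ids = df$sample_id[df$set == "calibration"],
                 prediction_ids = df$sample_id[df$set == "prediction"],
                 per_class_counts = NULL),
            class = "split_result")
}
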