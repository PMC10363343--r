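#' Labeled multichannel time series
#'
#' The unit of subject-level input: a numeric time-by-channel matrix together
#' with per-time-point paradigm and phase labels, channel identifiers and the
#' sampling rate.  A phase is one of `"stimulus"`, `"fixation"`, `"baseline"`
#' or `"missing"`; downstream analysis keeps stimulus rows only.
#'
#' @param data Numeric matrix, time points in rows, channels in columns.
#' @param channels Character vector of unique channel ids, one per column.
#'   Defaults to the column names of `data`, or `ch001`, `ch002`, ... when
#'   those are absent.
#' @param sampling_rate Sampling rate in Hz (positive scalar).
#' @param paradigm Character scalar or per-row character vector of paradigm
#'   labels.
#' @param phase Character scalar or per-row vector of phase labels; each must
#'   be one of `stimulus`, `fixation`, `baseline`, `missing`.
#' @param subject Character scalar subject id.
#'
#' @return An object of class `labeled_ts`.
#' @examples
#' x <- labeled_ts(matrix(rnorm(20), 10, 2), sampling_rate = 256,
#'                 paradigm = "wm", subject = "s01")
#' x
#' @export
labeled_ts <- function(data, channels = NULL, sampling_rate = 256,
                       paradigm = "unknown", phase = "stimulus",
                       subject = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) {
    abort("`data` must be a numeric matrix (time x channels).")
  }
  nt <- nrow(data)
  if (is.null(channels)) {
    channels <- colnames(data) %||% sprintf("ch%03d", seq_len(ncol(data)))
  }
  channels <- as.character(channels)
  if (length(channels) != ncol(data)) {
    abort("`channels` must name every column of `data`.")
  }
  if (anyDuplicated(channels)) abort("channel ids must be unique.")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a positive number (Hz).")
  }
  paradigm <- recycle_label(paradigm, nt, "paradigm")
  phase <- recycle_label(phase, nt, "phase")
  bad <- setdiff(unique(phase), c("stimulus", "fixation", "baseline", "missing"))
  if (length(bad)) {
    abort(paste0("unknown phase label(s): ", paste(bad, collapse = ", ")))
  }
  colnames(data) <- channels
  structure(
    list(data = data, channels = channels,
         sampling_rate = as.numeric(sampling_rate),
         paradigm = paradigm, phase = phase,
         subject = as.character(subject)[1]),
    class = "labeled_ts"
  )
}

recycle_label <- function(x, nt, what) {
  x <- as.character(x)
  if (length(x) == 1) x <- rep(x, nt)
  if (length(x) != nt) {
    abort(paste0("`", what, "` must have one entry per time row (or length 1)."))
  }
  if (anyNA(x)) abort(paste0("`", what, "` labels must not be NA."))
  x
}

#' @export
print.labeled_ts <- function(x, ...) {
  cat(sprintf(
    "<labeled_ts> subject %s: %d time points x %d channels @ %g Hz\n",
    x$subject, nrow(x$data), ncol(x$data), x$sampling_rate))
  cat("  paradigms: ", paste(unique(x$paradigm), collapse = ", "), "\n", sep = "")
  cat("  phases:    ", paste(names(table(x$phase)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.labeled_ts <- function(x) dim(x$data)

#' Coerce a labeled time series to a tibble
#'
#' One row per time point: a time index, the paradigm and phase labels, then
#' one column per channel.
#'
#' @param x A [labeled_ts()].
#' @param ... Unused.
#' @return A tibble with `nrow(x$data)` rows.
#' @export
as_tibble.labeled_ts <- function(x, ...) {
  out <- as_tibble(x$data)
  dplyr::bind_cols(
    tibble(time = seq_len(nrow(x$data)), subject = x$subject,
           paradigm = x$paradigm, phase = x$phase),
    out
  )
}

#' Analysis matrix: two paradigms concatenated over common channels
#'
#' Internal constructor used by [intersect_and_concatenate()]; exported so
#' synthetic pipelines can assemble one directly.
#'
#' @param data Numeric matrix (time x channels), channels as column names.
#' @param paradigm Per-row paradigm label.
#' @param boundary Row index where the first paradigm block ends.
#' @param subject Subject id.
#' @return An object of class `analysis_matrix`.
#' @export
analysis_matrix <- function(data, paradigm, boundary, subject = "subject") {
  if (!is.matrix(data) || !is.numeric(data)) abort("`data` must be a numeric matrix.")
  if (anyNA(data) || !all(is.finite(data))) {
    abort("analysis matrix must be fully finite after cleaning.")
  }
  paradigm <- recycle_label(paradigm, nrow(data), "paradigm")
  boundary <- as.integer(boundary)
  if (boundary < 0 || boundary > nrow(data)) abort("invalid paradigm boundary index.")
  structure(
    list(data = data, channels = colnames(data), paradigm = paradigm,
         boundary = boundary, subject = as.character(subject)[1]),
    class = "analysis_matrix"
  )
}

#' @export
print.analysis_matrix <- function(x, ...) {
  cat(sprintf("<analysis_matrix> subject %s: %d x %d, boundary at row %d\n",
              x$subject, nrow(x$data), ncol(x$data), x$boundary))
  cat("  paradigms: ", paste(unique(x$paradigm), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.analysis_matrix <- function(x) dim(x$data)
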