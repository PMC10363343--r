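#' Write a labeled time series to a single CSV container
#'
#' One row per time point: `time` index, `paradigm` and `phase` label
#' tracks, then one column per channel.  Subject id and sampling rate are
#' kept in `# key: value` comment lines before the header, so one file
#' round-trips the whole object.
#'
#' @param ts A [labeled_ts()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_labeled_ts <- function(ts, path) {
  stopifnot(inherits(ts, "labeled_ts"))
  writeLines(c(sprintf("# subject: %s", ts$subject),
               sprintf("# sampling_rate: %g", ts$sampling_rate)), path)
  df <- dplyr::bind_cols(
    tibble(time = seq_len(nrow(ts$data)), paradigm = ts$paradigm,
           phase = ts$phase),
    as_tibble(ts$data))
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a labeled time series written by [write_labeled_ts()]
#'
#' @param path File path.
#' @return A [labeled_ts()].
#' @export
read_labeled_ts <- function(path) {
  if (!file.exists(path)) abort("file not found.", class = "data_error")
  hdr <- readLines(path, n = 10)
  hdr <- hdr[startsWith(hdr, "# ")]
  meta <- list(subject = "subject", sampling_rate = 256)
  for (h in hdr) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  need <- c("time", "paradigm", "phase")
  if (!all(need %in% names(df))) {
    abort("container is missing the time/paradigm/phase label track.",
          class = "data_error")
  }
  chans <- setdiff(names(df), need)
  labeled_ts(as.matrix(df[chans]), channels = chans,
             sampling_rate = as.numeric(meta$sampling_rate),
             paradigm = df$paradigm, phase = df$phase,
             subject = meta$subject)
}
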