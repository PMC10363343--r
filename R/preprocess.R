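#' Resample a labeled time series to a lower rate
#'
#' Anti-aliased polyphase resampling of every channel to `target_rate`
#' (upsampling is not supported).  Label tracks are carried over by the
#' nearest-original-point rule: the resampled point at time `t` takes the
#' paradigm and phase labels of the original sample closest to `t`; labels
#' are piecewise constant over trials, so this is exact away from block
#' boundaries.  The new row count is `floor(n * target/current)` within one
#' row (the polyphase filter's edge convention).
#'
#' @param ts A [labeled_ts()].
#' @param target_rate Target sampling rate in Hz; must be positive and no
#'   larger than the current rate.
#' @return A [labeled_ts()] at `target_rate`.
#' @examples
#' x <- labeled_ts(matrix(rnorm(1024 * 2), 1024, 2), sampling_rate = 512)
#' y <- resample_ts(x, 256)
#' nrow(y$data)
#' @export
resample_ts <- function(ts, target_rate) {
  stopifnot(inherits(ts, "labeled_ts"))
  if (!is.numeric(target_rate) || target_rate <= 0) {
    abort("`target_rate` must be positive.")
  }
  if (target_rate > ts$sampling_rate) {
    abort("upsampling is not supported; `target_rate` must not exceed the current rate.",
          class = "unsupported_operation")
  }
  if (target_rate == ts$sampling_rate) return(ts)

  pq <- rational_ratio(target_rate / ts$sampling_rate)
  n_old <- nrow(ts$data)
  resampled <- apply(ts$data, 2, function(col) {
    signal::resample(col, p = pq[1], q = pq[2])
  })
  if (is.null(dim(resampled))) resampled <- matrix(resampled, ncol = ncol(ts$data))
  n_new <- nrow(resampled)
  # nearest original sample for each resampled time instant
  idx <- round((seq_len(n_new) - 1) * ts$sampling_rate / target_rate) + 1
  idx <- pmin(pmax(idx, 1L), n_old)
  labeled_ts(resampled, channels = ts$channels, sampling_rate = target_rate,
             paradigm = ts$paradigm[idx], phase = ts$phase[idx],
             subject = ts$subject)
}

# Continued-fraction rational approximation p/q of a ratio in (0, 1].
rational_ratio <- function(r, max_denom = 10000L) {
  stopifnot(r > 0, r <= 1)
  h0 <- 0; h1 <- 1; k0 <- 1; k1 <- 0; x <- r
  repeat {
    a <- floor(x)
    h2 <- a * h1 + h0; k2 <- a * k1 + k0
    if (k2 > max_denom) break
    h0 <- h1; h1 <- h2; k0 <- k1; k1 <- k2
    if (abs(h1 / k1 - r) < 1e-12) break
    frac <- x - a
    if (frac < 1e-12) break
    x <- 1 / frac
  }
  c(as.integer(h1), as.integer(k1))
}

#' Keep stimulus time points with complete data
#'
#' Retains exactly the rows whose phase label is `"stimulus"` and whose data
#' row is fully finite, preserving temporal order.  Fixation, baseline and
#' missing-phase rows are dropped, as are stimulus rows containing any
#' non-finite value (no imputation).
#'
#' @param ts A [labeled_ts()].
#' @return A [labeled_ts()] containing the surviving rows.
#' @examples
#' x <- labeled_ts(matrix(1:8, 4, 2), paradigm = "wm",
#'                 phase = c("stimulus", "fixation", "baseline", "stimulus"))
#' nrow(select_stimulus_timepoints(x)$data)
#' @export
select_stimulus_timepoints <- function(ts) {
  stopifnot(inherits(ts, "labeled_ts"))
  keep <- ts$phase == "stimulus" &
    apply(ts$data, 1, function(r) all(is.finite(r)))
  if (!any(keep)) {
    abort("no stimulus time points with complete data survive.",
          class = "empty_output")
  }
  labeled_ts(ts$data[keep, , drop = FALSE], channels = ts$channels,
             sampling_rate = ts$sampling_rate,
             paradigm = ts$paradigm[keep], phase = ts$phase[keep],
             subject = ts$subject)
}

#' Concatenate two paradigm blocks over their common channels
#'
#' Restricts both blocks to the intersection of their channel-id sets (in
#' lexicographic order, so the column order is reproducible across runs),
#' stacks the rows of the first-named paradigm above the second, and records
#' the boundary row index.  Inputs are expected to be already resampled and
#' stimulus-filtered.
#'
#' @param a,b [labeled_ts()] blocks for the two paradigms.
#' @param order Optional length-2 character vector of paradigm names giving
#'   the concatenation order; defaults to `a` first.
#' @return An [analysis_matrix()] whose `boundary` equals the number of rows
#'   contributed by the first paradigm.
#' @examples
#' a <- labeled_ts(matrix(rnorm(10), 5, 2), paradigm = "wm")
#' b <- labeled_ts(matrix(rnorm(14), 7, 2), paradigm = "sm")
#' m <- intersect_and_concatenate(a, b)
#' m$boundary
#' @export
intersect_and_concatenate <- function(a, b, order = NULL) {
  stopifnot(inherits(a, "labeled_ts"), inherits(b, "labeled_ts"))
  if (!is.null(order)) {
    stopifnot(length(order) == 2)
    pa <- unique(a$paradigm); pb <- unique(b$paradigm)
    if (length(pa) == 1 && length(pb) == 1 && pa == order[2] && pb == order[1]) {
      tmp <- a; a <- b; b <- tmp
    }
  }
  common <- sort(intersect(a$channels, b$channels))
  if (!length(common)) {
    abort("the two paradigms share no channels.", class = "incompatible_inputs")
  }
  da <- a$data[, common, drop = FALSE]
  db <- b$data[, common, drop = FALSE]
  analysis_matrix(rbind(da, db),
                  paradigm = c(a$paradigm, b$paradigm),
                  boundary = nrow(da),
                  subject = a$subject)
}

#' Standard preprocessing of one subject's pair of paradigm blocks
#'
#' Convenience composition of [resample_ts()] (when a `target_rate` below
#' the current one is requested), [select_stimulus_timepoints()] and
#' [intersect_and_concatenate()].
#'
#' @param sessions A named list of two [labeled_ts()] blocks, first paradigm
#'   first.
#' @param target_rate Optional target sampling rate in Hz; `NULL` keeps the
#'   native rate.
#' @return An [analysis_matrix()].
#' @export
preprocess_subject <- function(sessions, target_rate = NULL) {
  stopifnot(is.list(sessions), length(sessions) == 2)
  prep <- purrr::map(sessions, function(ts) {
    if (!is.null(target_rate) && target_rate < ts$sampling_rate) {
      ts <- resample_ts(ts, target_rate)
    }
    select_stimulus_timepoints(ts)
  })
  intersect_and_concatenate(prep[[1]], prep[[2]])
}
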