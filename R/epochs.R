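#' Trial-segmented epoch container
#'
#' An `epoch_set` holds baseline-referenced, band-limited HbO2 epochs as a
#' `trial x channel x sample` array together with its timing metadata. Epochs
#' span `[-(margin + pre), post + margin)` seconds relative to stimulus onset
#' (default `[-6, 14)` s: 2 s leading margin, 4 s pre-stimulus baseline
#' support, 12 s post-stimulus window, 2 s trailing margin), so each epoch has
#' `round(20 * fs)` samples. The margins exist only to absorb edge effects of
#' the analytic-signal computation and are never averaged.
#'
#' @param data numeric array, `trial x channel x sample`.
#' @param fs sampling rate in Hz.
#' @param window numeric length-4 vector of durations in seconds:
#'   leading margin, pre-stimulus, post-stimulus, trailing margin.
#' @param channel_labels character vector of channel names.
#'
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs, window = c(2, 4, 12, 2),
                      channel_labels = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_invalid("`data` must be a trial x channel x sample array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("`fs` must be a positive scalar")
  window <- as.numeric(window)
  if (length(window) != 4L || any(window < 0))
    stop_invalid("`window` must be four non-negative durations (margin, pre, post, margin)")
  n_expected <- round(sum(window) * fs)
  if (dim(data)[3L] != n_expected)
    stop_invalid("epoch length is ", dim(data)[3L], " samples but the window (",
                 sum(window), " s at ", fs, " Hz) requires ", n_expected)
  if (any(!is.finite(data)))
    stop_invalid("epoch data contain non-finite values")
  channel_labels <- channel_labels %||% default_channel_labels(dim(data)[2L])
  if (length(channel_labels) != dim(data)[2L])
    stop_invalid("channel_labels length does not match the channel dimension")
  if (anyDuplicated(channel_labels))
    stop_invalid("duplicated channel label: ",
                 channel_labels[duplicated(channel_labels)][1L])
  structure(
    list(data = data, fs = fs, t_start = -(window[1L] + window[2L]),
         window = window, channel_labels = channel_labels),
    class = "epoch_set"
  )
}

#' Epoch time axis
#'
#' Time in seconds, relative to stimulus onset, of each sample of an
#' [epoch_set()] (or of any object carrying `fs` and `t_start`).
#'
#' @param x an `epoch_set`, `phase_epochs` or `plv_time_series` object.
#' @return numeric vector of times in seconds.
#' @export
epoch_time <- function(x) {
  n <- if (inherits(x, "plv_time_series")) ncol(x$values) else dim(x$data %||% x$phases)[3L]
  x$t_start + (seq_len(n) - 1L) / x$fs
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat("<epoch_set> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$fs, " Hz, t in [", x$t_start, ", ",
      x$t_start + d[3L] / x$fs, ") s\n", sep = "")
  invisible(x)
}

n_trials <- function(x) dim(x$data %||% x$phases)[1L]
n_channels <- function(x) dim(x$data %||% x$phases)[2L]
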