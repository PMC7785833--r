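#' Continuous multi-channel recording
#'
#' Container for a continuous HbO2 (or optical-density-derived) recording:
#' a `time x channel` matrix, its sampling rate, channel labels, and the
#' target-stimulus onset times used for epoching.
#'
#' @param samples numeric `time x channel` matrix.
#' @param fs sampling rate in Hz.
#' @param onsets strictly increasing stimulus onset times in seconds.
#' @param channel_labels channel names; defaults to `colnames(samples)`.
#'
#' @return An object of class `continuous_recording`.
#' @export
continuous_recording <- function(samples, fs, onsets,
                                 channel_labels = colnames(samples)) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples)) stop_invalid("`samples` must be numeric")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop_invalid("`fs` must be a positive scalar")
  onsets <- as.numeric(onsets)
  if (length(onsets) && any(diff(onsets) <= 0))
    stop_invalid("`onsets` must be strictly increasing")
  channel_labels <- channel_labels %||% default_channel_labels(ncol(samples))
  if (anyDuplicated(channel_labels))
    stop_invalid("duplicated channel label: ",
                 channel_labels[duplicated(channel_labels)][1L])
  structure(
    list(samples = samples, fs = fs, onsets = onsets,
         channel_labels = channel_labels),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat("<continuous_recording> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " channels @ ", x$fs, " Hz, ",
      length(x$onsets), " onsets\n", sep = "")
  invisible(x)
}

# Tabulated extinction coefficients, 1/(mM cm), rows = wavelengths (760 nm,
# 850 nm), columns = chromophores (HbO2, HbR). Gratzer/Cope-derived values
# commonly used in continuous-wave fNIRS.
default_extinction <- function() {
  matrix(c(0.586, 1.548,
           1.058, 0.691),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("760", "850"), c("HbO2", "HbR")))
}

#' Modified Beer-Lambert conversion to HbO2
#'
#' Converts two-wavelength optical-density changes into oxygenated-hemoglobin
#' concentration changes by solving the 2x2 extinction-coefficient system per
#' channel and sample:
#' \deqn{\Delta OD(\lambda) = (\epsilon_{HbO2}(\lambda)\,\Delta HbO2 +
#'   \epsilon_{HbR}(\lambda)\,\Delta HbR)\; d \; DPF(\lambda)}
#' Only the HbO2 component is returned; the phase-synchronization analysis
#' downstream operates on HbO2 exclusively. A pipeline starting from exported
#' HbO2 series skips this step entirely.
#'
#' @param od_changes numeric `time x channel x wavelength` array of
#'   optical-density changes (wavelength order must match `extinction` rows).
#' @param dpf differential pathlength factor per wavelength (length 2).
#'   The acquisition-software value is rarely reported; the conventional
#'   default 6.0 is used for both wavelengths.
#' @param distances source-detector separation(s) in cm, scalar or one per
#'   channel.
#' @param extinction 2x2 matrix of extinction coefficients in 1/(mM cm),
#'   rows = wavelengths, columns = (HbO2, HbR).
#'
#' @return numeric `time x channel` matrix of HbO2 concentration changes in
#'   micromolar.
#' @export
beer_lambert <- function(od_changes, dpf = c(6, 6), distances = 3,
                         extinction = default_extinction()) {
  if (!is.array(od_changes) || length(dim(od_changes)) != 3L ||
      dim(od_changes)[3L] != 2L)
    stop_invalid("`od_changes` must be a time x channel x 2 array")
  if (length(dpf) != 2L || any(dpf <= 0))
    stop_invalid("`dpf` must be two positive scalars")
  n_ch <- dim(od_changes)[2L]
  distances <- rep_len(as.numeric(distances), n_ch)
  if (any(distances <= 0)) stop_invalid("`distances` must be positive")
  extinction <- as.matrix(extinction)
  if (abs(det(extinction)) < 1e-12)
    stop_invalid("extinction matrix is singular; the two wavelengths do not ",
                 "separate HbO2 from HbR")
  einv <- solve(extinction)
  out <- matrix(NA_real_, dim(od_changes)[1L], n_ch)
  for (ch in seq_len(n_ch)) {
    # effective OD per unit pathlength for this channel
    od <- cbind(od_changes[, ch, 1L] / (distances[ch] * dpf[1L]),
                od_changes[, ch, 2L] / (distances[ch] * dpf[2L]))
    conc <- od %*% t(einv)        # columns: HbO2, HbR in mM
    out[, ch] <- conc[, 1L] * 1000 # micromolar
  }
  colnames(out) <- dimnames(od_changes)[[2L]]
  out
}

#' Zero-phase band-pass filter
#'
#' Band-limits a continuous recording to the task-related hemodynamic band
#' (default 0.01-0.15 Hz), suppressing respiratory (~0.2-0.3 Hz), cardiac
#' (~0.8-2 Hz) and broadband high-frequency noise. A Butterworth filter is
#' applied forward and backward (`signal::filtfilt`), so the instantaneous
#' phase extracted later is not biased by filter delay.
#'
#' @param recording a [continuous_recording()].
#' @param low,high band edges in Hz; `0 < low < high < fs/2` required.
#' @param order Butterworth prototype order (default 4).
#'
#' @return A filtered `continuous_recording`.
#' @export
bandpass <- function(recording, low = 0.01, high = 0.15, order = 4) {
  stopifnot(inherits(recording, "continuous_recording"))
  nyq <- recording$fs / 2
  if (!(low > 0 && low < high)) stop_invalid("need 0 < low < high")
  if (high >= nyq)
    stop_invalid("`high` (", high, " Hz) must be below the Nyquist frequency (",
                 nyq, " Hz)")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  filtered <- apply(recording$samples, 2L,
                    function(x) signal::filtfilt(bf, x))
  recording$samples <- matrix(filtered, nrow = nrow(recording$samples),
                              dimnames = dimnames(recording$samples))
  recording
}

#' Segment a recording into stimulus-locked epochs
#'
#' Cuts one epoch per stimulus onset covering
#' `[onset - margin - pre, onset + post + margin)` seconds (default
#' `[-6, 14)`). Sample indexing uses `floor(t * fs)` with sample 0 at the
#' recording start; every epoch has `round(total_window * fs)` samples.
#' Onsets too close to a recording edge to fit the full window are dropped
#' with a warning; fewer than two surviving trials is an error (the
#' phase-locking value is degenerate for a single trial).
#'
#' @param recording a band-limited [continuous_recording()] with onsets.
#' @param window durations in seconds (leading margin, pre, post, trailing
#'   margin); default `c(2, 4, 12, 2)`.
#'
#' @return An [epoch_set()].
#' @export
epoch_recording <- function(recording, window = c(2, 4, 12, 2)) {
  stopifnot(inherits(recording, "continuous_recording"))
  window <- as.numeric(window)
  fs <- recording$fs
  n_total <- nrow(recording$samples)
  n_ep <- round(sum(window) * fs)
  pre_dur <- window[1L] + window[2L]
  starts0 <- floor((recording$onsets - pre_dur) * fs) # 0-based
  ok <- starts0 >= 0 & (starts0 + n_ep) <= n_total
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to a recording edge; trial(s) dropped: ",
            paste(signif(recording$onsets[!ok], 4), collapse = ", "),
            call. = FALSE)
  starts0 <- starts0[ok]
  if (length(starts0) < 2L)
    stop_invalid("fewer than 2 trials fit inside the recording")
  n_ch <- ncol(recording$samples)
  data <- array(NA_real_, c(length(starts0), n_ch, n_ep))
  for (i in seq_along(starts0)) {
    idx <- starts0[i] + seq_len(n_ep) # 1-based rows of the half-open window
    data[i, , ] <- t(recording$samples[idx, , drop = FALSE])
  }
  epoch_set(data, fs = fs, window = window,
            channel_labels = recording$channel_labels)
}
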