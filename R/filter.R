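#' Zero-phase band filtering of a recording
#'
#' Applies a 4th-order Butterworth filter forward and backward
#' ([signal::filtfilt()]) to every channel, independently within each
#' artifact-free segment, so no filter state leaks across artifact
#' boundaries. `low_hz = 0` gives a pure low-pass. Typical uses are the
#' 1-20 Hz band for microstate analysis and the 8-12 Hz alpha band for
#' phase connectivity.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz lower band edge in Hz (0 for low-pass).
#' @param high_hz upper band edge in Hz; must be below Nyquist.
#' @param order Butterworth order per pass.
#' @return the filtered `eeg_recording`; segment boundaries unchanged.
#' @export
bandpass_zero_phase <- function(rec, low_hz, high_hz, order = 4L) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < nyq))
    stop("parameter error: need 0 <= low < high < fs/2 (Nyquist ", nyq, ")")
  flt <- if (low_hz <= 0) {
    signal::butter(order, high_hz / nyq, type = "low")
  } else {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  }
  for (idx in segment_indices(rec)) {
    seg <- rec$data[, idx, drop = FALSE]
    rec$data[, idx] <- t(apply(seg, 1L, function(ch)
      signal::filtfilt(flt, ch)))
  }
  rec
}
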