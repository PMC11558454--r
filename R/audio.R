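#' Calibration-tone record for one recording channel
#'
#' Holds the measured linear RMS and peak-to-peak amplitude of a recorded
#' calibration tone of known sound-pressure level (114 dB reference tone),
#' used by [to_db()] to convert linear call amplitudes to dB and to remove
#' microphone differences between channels.
#'
#' @param channel_id channel identifier.
#' @param tone_rms,tone_p2p linear RMS and peak-to-peak amplitude of the
#'   recorded tone; both > 0 and `tone_p2p >= tone_rms`.
#' @param reference_db sound-pressure level of the tone (dB).
#' @return object of class `calibration_record`.
#' @export
#' @examples
#' cal <- calibration_record("ch1", tone_rms = 0.2, tone_p2p = 0.57)
#' to_db(0.2, cal, "rms")  # 114
calibration_record <- function(channel_id, tone_rms, tone_p2p,
                               reference_db = 114) {
  if (!is.finite(tone_rms) || tone_rms <= 0) {
    stop("tone_rms must be > 0", call. = FALSE)
  }
  if (!is.finite(tone_p2p) || tone_p2p <= 0) {
    stop("tone_p2p must be > 0", call. = FALSE)
  }
  if (tone_p2p < tone_rms) {
    stop("tone_p2p must be >= tone_rms", call. = FALSE)
  }
  structure(
    list(channel_id = channel_id, tone_rms = tone_rms, tone_p2p = tone_p2p,
         reference_db = reference_db),
    class = "calibration_record"
  )
}

#' Band-pass filter a waveform
#'
#' Zero-phase band-pass with an effective 24 dB/octave roll-off, the
#' filtering applied to recordings before amplitude measurement. Realized as
#' a 2nd-order Butterworth band-pass run forward and backward
#' ([signal::filtfilt()]): each pass contributes 12 dB/octave per band edge,
#' giving 24 dB/octave total with no phase distortion.
#'
#' @param wave numeric waveform, samples in [-1, 1].
#' @param sample_rate sampling rate (Hz).
#' @param low,high band edges (Hz); `0 < low < high < sample_rate / 2`.
#' @return filtered waveform, same length.
#' @export
bandpass_filter <- function(wave, sample_rate, low = 300, high = 4500) {
  if (!(is.finite(low) && is.finite(high) && low > 0 && low < high &&
        high < sample_rate / 2)) {
    stop("band edges must satisfy 0 < low < high < sample_rate/2", call. = FALSE)
  }
  if (length(wave) == 0L) return(wave)
  bf <- signal::butter(2, c(low, high) / (sample_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, wave))
}

#' Background-corrected amplitude of one call
#'
#' Measures the raw RMS and peak-to-peak (P2P) amplitude of a call window
#' and subtracts the background level estimated from two flanking windows,
#' 0.1 to 0.02 s before the onset and 0.02 to 0.1 s after the offset. The
#' background RMS (resp. P2P) is the mean of the two flank-window RMS
#' (resp. P2P) values; corrected values are floored at zero and flagged when
#' flooring occurred. Subtraction is on linear amplitudes, not power.
#'
#' @param wave numeric waveform.
#' @param sample_rate sampling rate (Hz).
#' @param onset,offset call window (s from waveform start, 0-based).
#' @param flank_inner,flank_outer flank-window distances from the call
#'   edges (s); defaults 0.02 and 0.1.
#' @return object of class `amplitude_measurement`: list with `raw_rms`,
#'   `raw_p2p`, `background_rms`, `background_p2p`, `corrected_rms`,
#'   `corrected_p2p`, and logical `floored_rms`, `floored_p2p`.
#' @export
measure_call <- function(wave, sample_rate, onset, offset,
                         flank_inner = 0.02, flank_outer = 0.1) {
  if (!(offset > onset)) stop("offset must exceed onset", call. = FALSE)
  dur <- length(wave) / sample_rate
  if (onset - flank_outer < 0 || offset + flank_outer > dur) {
    stop(sprintf(
      "call at [%.3f, %.3f] s too close to the waveform edge (need %.2f s margins)",
      onset, offset, flank_outer), call. = FALSE)
  }
  win <- function(a, b) {
    i1 <- floor(a * sample_rate) + 1L
    i2 <- max(i1, floor(b * sample_rate))
    wave[i1:min(i2, length(wave))]
  }
  rms <- function(x) sqrt(mean(x^2))
  p2p <- function(x) max(x) - min(x)

  call_x <- win(onset, offset)
  pre <- win(onset - flank_outer, onset - flank_inner)
  post <- win(offset + flank_inner, offset + flank_outer)

  raw_rms <- rms(call_x)
  raw_p2p <- p2p(call_x)
  bg_rms <- mean(c(rms(pre), rms(post)))
  bg_p2p <- mean(c(p2p(pre), p2p(post)))

  structure(
    list(
      raw_rms = raw_rms, raw_p2p = raw_p2p,
      background_rms = bg_rms, background_p2p = bg_p2p,
      corrected_rms = max(raw_rms - bg_rms, 0),
      corrected_p2p = max(raw_p2p - bg_p2p, 0),
      floored_rms = raw_rms < bg_rms,
      floored_p2p = raw_p2p < bg_p2p
    ),
    class = "amplitude_measurement"
  )
}

#' Convert a linear amplitude to dB via a calibration tone
#'
#' `dB = reference + 20 * log10(linear / tone)`, where the tone value is the
#' calibration record's RMS or P2P depending on `which`, so a call whose
#' amplitude equals the recorded tone reads exactly the tone's
#' sound-pressure level (114 dB by default).
#'
#' @param linear linear amplitude(s), > 0.
#' @param cal a [calibration_record()] for the call's channel.
#' @param which `"rms"` or `"p2p"`: which tone statistic to reference.
#' @return amplitude(s) in dB.
#' @export
to_db <- function(linear, cal, which = c("rms", "p2p")) {
  which <- match.arg(which)
  if (!inherits(cal, "calibration_record")) {
    stop("a calibration_record is required; missing calibration is an error",
         call. = FALSE)
  }
  if (any(!is.finite(linear)) || any(linear <= 0)) {
    stop("dB level undefined for non-positive linear amplitude", call. = FALSE)
  }
  tone <- if (which == "rms") cal$tone_rms else cal$tone_p2p
  cal$reference_db + 20 * log10(linear / tone)
}
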