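#' Preprocessing configuration
#'
#' Bundles the preprocessing chain applied by [preprocess()]: band-pass
#' filtering, notch (band-stop) filtering for line noise, common average
#' referencing (CAR) and anti-aliased downsampling, applied in that order.
#'
#' Filters are zero-phase (forward-backward) Butterworth designs, so the
#' timing of topographic events is not shifted; `order` is the order of the
#' underlying one-pass design.
#'
#' @param bandpass numeric length-2 `(low, high)` in Hz, or `NULL` to skip.
#'   The default 1-45 Hz covers the delta-to-gamma range conventionally
#'   retained for microstate analysis.
#' @param notch numeric length-2 band to suppress in Hz (default 48-52 Hz,
#'   bracketing 50 Hz mains), or `NULL` to skip.
#' @param car logical; apply common average referencing (default `TRUE`).
#' @param target_fs new sampling rate in Hz after polyphase resampling, or
#'   `NULL` to keep the input rate.
#' @param order Butterworth design order (default 4).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(bandpass = c(1, 45), notch = c(48, 52),
                              car = TRUE, target_fs = NULL, order = 4L) {
  for (band in list(bandpass, notch)) {
    if (!is.null(band)) {
      if (length(band) != 2L || !all(is.finite(band)) ||
          band[1L] <= 0 || band[1L] >= band[2L])
        abort_validation("a frequency band must satisfy 0 < low < high")
    }
  }
  if (!is.null(target_fs) && (!is.finite(target_fs) || target_fs <= 0))
    abort_validation("target_fs must be a positive scalar")
  structure(list(bandpass = bandpass, notch = notch, car = isTRUE(car),
                 target_fs = target_fs, order = as.integer(order)),
            class = "preprocess_config")
}

#' Apply the standard preprocessing chain to a recording
#'
#' Applies, in order: band-pass filter, notch filter, common average
#' reference, and resampling to `cfg$target_fs`. Bands must lie strictly
#' below the Nyquist frequency of the input.
#'
#' @param rec an [recording()] object.
#' @param cfg a [preprocess_config()].
#' @return A new [recording()] with the chain applied; `fs` equals
#'   `cfg$target_fs` when resampling is requested.
#' @examples
#' rec <- recording(matrix(rnorm(8 * 1000), 8, 1000), fs = 1000)
#' out <- preprocess(rec, preprocess_config(target_fs = 200))
#' n_samples(out)  # 200
#' @export
preprocess <- function(rec, cfg = preprocess_config()) {
  stop_if_not_recording(rec)
  stopifnot(inherits(cfg, "preprocess_config"))
  nyq <- rec$fs / 2
  for (band in list(cfg$bandpass, cfg$notch)) {
    if (!is.null(band) && band[2L] >= nyq)
      abort_validation("band edge %g Hz is not below Nyquist (%g Hz)", band[2L], nyq)
  }
  if (!is.null(cfg$target_fs) && cfg$target_fs > rec$fs)
    abort_validation("target_fs (%g) exceeds the input rate (%g)",
                     cfg$target_fs, rec$fs)
  data <- rec$data
  if (!is.null(cfg$bandpass)) {
    flt <- signal::butter(cfg$order, cfg$bandpass / nyq, type = "pass")
    data <- t(apply(data, 1L, function(x) signal::filtfilt(flt, x)))
  }
  if (!is.null(cfg$notch)) {
    flt <- signal::butter(cfg$order, cfg$notch / nyq, type = "stop")
    data <- t(apply(data, 1L, function(x) signal::filtfilt(flt, x)))
  }
  if (cfg$car) data <- common_average_reference(data)
  fs <- rec$fs
  if (!is.null(cfg$target_fs) && cfg$target_fs != rec$fs) {
    frac <- ratio_approx(cfg$target_fs / rec$fs)
    data <- t(apply(data, 1L, function(x) signal::resample(x, frac[1L], frac[2L])))
    fs <- cfg$target_fs
  }
  recording(data, fs = fs, channel_names = rec$channel_names, meta = rec$meta)
}

#' Common average reference
#'
#' Subtracts, at every time point, the mean over channels, so each column of
#' the data matrix has zero mean. Idempotent.
#'
#' @param data channels x samples numeric matrix.
#' @return The re-referenced matrix.
#' @export
common_average_reference <- function(data) {
  sweep(data, 2L, colMeans(data), "-")
}

# small rational approximation p/q of a resampling ratio
ratio_approx <- function(r, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- r * q
    if (abs(p - round(p)) < 1e-9) return(c(as.integer(round(p)), q))
  }
  abort_validation("cannot express resampling ratio %g as a small fraction", r)
}
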