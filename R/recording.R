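#' Multichannel EEG recording
#'
#' Container for a continuous multichannel EEG signal: a channels-by-samples
#' matrix in microvolts together with its sampling rate and channel names.
#' All pipeline stages consume and produce this class.
#'
#' @param data numeric matrix, C channels x N samples, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_names character vector of length C with unique names.
#'   Defaults to `Ch1..ChC`.
#' @param meta named list of free-form annotations (subject, trial,
#'   condition, ...).
#'
#' @return An object of class `eeg_recording`: a list with elements `data`,
#'   `fs`, `channel_names`, `meta`.
#' @examples
#' rec <- recording(matrix(rnorm(4 * 100), 4, 100), fs = 100)
#' dim(rec$data)
#' @export
recording <- function(data, fs, channel_names = NULL, meta = list()) {
  if (!is.matrix(data) || !is.numeric(data))
    abort_validation("`data` must be a numeric matrix (channels x samples)")
  C <- nrow(data); N <- ncol(data)
  if (C < 2L) abort_validation("a recording needs at least 2 channels, got %d", C)
  if (N < 1L) abort_validation("a recording needs at least 1 sample")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    abort_validation("`fs` must be a positive scalar (Hz)")
  if (is.null(channel_names)) channel_names <- paste0("Ch", seq_len(C))
  channel_names <- as.character(channel_names)
  if (length(channel_names) != C)
    abort_validation("channel_names has length %d but data has %d channels",
                     length(channel_names), C)
  if (anyDuplicated(channel_names))
    abort_validation("channel names must be unique")
  if (any(!nzchar(channel_names)))
    abort_validation("channel names must be non-empty")
  if (!is.list(meta)) abort_validation("`meta` must be a list")
  rownames(data) <- channel_names
  structure(list(data = data, fs = as.numeric(fs),
                 channel_names = channel_names, meta = meta),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / channels of a recording
#' @param rec an `eeg_recording`.
#' @return integer count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @export
n_channels <- function(rec) nrow(rec$data)

is_recording <- function(x) inherits(x, "eeg_recording")

stop_if_not_recording <- function(x) {
  if (!is_recording(x)) abort_validation("expected an `eeg_recording` object")
  invisible(x)
}
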