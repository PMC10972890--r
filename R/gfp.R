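#' Global field power curve
#'
#' The global field power (GFP) at a time point is the spatial standard
#' deviation of the average-referenced scalp map: with channel potentials
#' `v[i, n]` and per-time-point mean `vbar[n]`,
#' `GFP[n] = sqrt( sum_i (v[i,n] - vbar[n])^2 / C )`.
#' It is a reference-free measure of instantaneous field strength; its local
#' maxima are the moments of highest topographic signal-to-noise where
#' microstate topographies are sampled.
#'
#' The recording is average-referenced internally, so the result does not
#' depend on the input reference.
#'
#' @param rec an [recording()] object (C >= 2 channels).
#' @return A list of class `gfp_series` with `values` (length N,
#'   non-negative, microvolts) and `fs`.
#' @examples
#' rec <- recording(rbind(c(1, 2), c(-1, 2)), fs = 10)
#' gfp_curve(rec)$values  # 1, 0
#' @export
gfp_curve <- function(rec) {
  stop_if_not_recording(rec)
  v <- common_average_reference(rec$data)
  structure(list(values = sqrt(colMeans(v^2)), fs = rec$fs),
            class = "gfp_series")
}

# GFP of zero-mean topography rows of a matrix (M x C)
gfp_of_maps <- function(maps) sqrt(rowMeans(maps^2))

#' Locate local maxima of a GFP curve
#'
#' Returns interior sample indices `n` with
#' `values[n-1] < values[n] > values[n+1]`. Plateaus are broken by taking
#' the first sample at which the plateau level is reached, i.e. a sample
#' qualifies when it strictly exceeds its predecessor and is not exceeded
#' later within the plateau. With `min_distance_samples > 0`, peaks are kept
#' greedily in order of descending GFP, discarding any peak closer than the
#' minimum distance to an already retained one.
#'
#' @param g a `gfp_series` from [gfp_curve()], or a plain numeric vector.
#' @param min_distance_samples non-negative integer minimum spacing.
#' @return Integer vector of peak indices (possibly empty), increasing.
#' @examples
#' find_gfp_peaks(c(0, 1, 0, 2, 0))  # 2 and 4
#' @export
find_gfp_peaks <- function(g, min_distance_samples = 0L) {
  values <- if (inherits(g, "gfp_series")) g$values else as.numeric(g)
  n <- length(values)
  if (n < 3L) abort_validation("need at least 3 samples to find peaks")
  stopifnot(min_distance_samples >= 0L)
  # strict rise then (possibly after a plateau) strict fall; index the rise
  d <- diff(values)
  rises <- which(d > 0)
  peaks <- integer(0)
  for (i in rises) {
    j <- i + 1L                       # candidate peak sample
    k <- j
    while (k < n && values[k + 1L] == values[j]) k <- k + 1L  # skip plateau
    if (k < n && values[k + 1L] < values[j]) peaks <- c(peaks, j)
  }
  if (min_distance_samples > 0L && length(peaks) > 1L) {
    ord <- peaks[order(values[peaks], peaks, decreasing = c(TRUE, FALSE),
                       method = "radix")]
    kept <- integer(0)
    for (p in ord)
      if (!length(kept) || min(abs(kept - p)) >= min_distance_samples)
        kept <- c(kept, p)
    peaks <- sort(kept)
  }
  peaks
}

#' Extract GFP-peak topographies into a pooled bank
#'
#' Collects the average-referenced scalp maps at the GFP local maxima of one
#' or more recordings into a single bank, the input to group-level
#' microstate clustering. When `cap_per_recording` is set and a recording
#' has more peaks than the cap, a seeded uniform random subsample of size
#' `cap_per_recording` is retained (keeping the pooled bank tractable
#' without biasing the topography distribution).
#'
#' Maps are stored average-referenced but not norm-scaled: the raw GFP at
#' each peak is needed later for GEV weighting.
#'
#' @param recs a single recording or a list of recordings sharing channel
#'   count and order.
#' @param cap_per_recording integer cap on peaks kept per recording, or
#'   `NULL` for no cap. Default 1000.
#' @param min_distance_samples passed to [find_gfp_peaks()].
#' @param seed integer seed for the subsampling draw.
#' @return A `topography_bank`: list with `maps` (M x C, rows zero-mean),
#'   `source` (data.frame: recording, sample), `gfp` (length M).
#' @export
extract_peak_maps <- function(recs, cap_per_recording = 1000L,
                              min_distance_samples = 0L, seed = 1L) {
  if (is_recording(recs)) recs <- list(recs)
  stopifnot(length(recs) >= 1L)
  C <- n_channels(recs[[1L]])
  names1 <- recs[[1L]]$channel_names
  maps <- list(); src_rec <- integer(0); src_smp <- integer(0)
  for (r in seq_along(recs)) {
    rec <- recs[[r]]
    stop_if_not_recording(rec)
    if (n_channels(rec) != C || !identical(rec$channel_names, names1))
      abort_validation("recording %d has a different channel set", r)
    g <- gfp_curve(rec)
    peaks <- find_gfp_peaks(g, min_distance_samples)
    if (!is.null(cap_per_recording) && length(peaks) > cap_per_recording) {
      keep <- with_seed(seed + r, sample.int(length(peaks), cap_per_recording))
      peaks <- sort(peaks[keep])
    }
    if (length(peaks)) {
      v <- common_average_reference(rec$data)
      maps[[length(maps) + 1L]] <- t(v[, peaks, drop = FALSE])
      src_rec <- c(src_rec, rep.int(r, length(peaks)))
      src_smp <- c(src_smp, peaks)
    }
  }
  if (!length(maps))
    abort_validation("no GFP peaks found in any recording")
  maps <- do.call(rbind, maps)
  structure(list(maps = maps,
                 source = data.frame(recording = src_rec, sample = src_smp),
                 gfp = gfp_of_maps(maps)),
            class = "topography_bank")
}

#' @export
print.topography_bank <- function(x, ...) {
  cat(sprintf("<topography_bank> %d maps x %d channels from %d recording(s)\n",
              nrow(x$maps), ncol(x$maps), length(unique(x$source$recording))))
  invisible(x)
}
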