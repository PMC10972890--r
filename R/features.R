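#' Per-class microstate parameters of a labeled window
#'
#' Computes the six per-class parameter families plus the transition matrix
#' for one analysis window:
#' * occurrence: segments of class k per second of window;
#' * duration: mean lifespan of class-k segments, in ms;
#' * coverage: fraction of samples labeled k;
#' * gev: GFP-weighted explained variance contributed by class-k samples,
#'   `sum Corr^2 * GFP^2 / sum GFP^2` (sums over the window);
#' * gfp: mean GFP over class-k samples, in microvolts;
#' * mspatcorr: mean absolute spatial correlation between class-k samples
#'   and their template.
#'
#' A class absent from the window gets 0 in every family and is listed in
#' the `absent` attribute. On fully labeled windows coverage sums to 1 and
#' `coverage = occurrence * duration / 1000` holds per class.
#'
#' @param seq a `label_sequence` for the window.
#' @param segs its [segmentize()] result (computed if missing).
#' @param K number of classes.
#' @return A list of class `parameter_set` with numeric vectors
#'   `occurrence`, `duration`, `coverage`, `gev`, `gfp`, `mspatcorr` (length
#'   K), matrix `transition` (K x K), and attribute `absent`.
#' @export
class_parameters <- function(seq, segs = NULL, K = seq$K) {
  stopifnot(inherits(seq, "label_sequence"))
  if (is.null(segs)) segs <- segmentize(seq)
  N <- length(seq$labels)
  window_s <- N / seq$fs
  assigned <- seq$labels > 0L
  n_assigned <- sum(assigned)
  occurrence <- duration <- coverage <- gev_k <- gfp_k <- msc <- numeric(K)
  denom_gev <- sum(seq$gfp[assigned]^2)
  for (k in seq_len(K)) {
    segs_k <- segs[segs$label == k, , drop = FALSE]
    smp_k <- which(seq$labels == k)
    if (!length(smp_k)) next
    occurrence[k] <- nrow(segs_k) / window_s
    duration[k] <- mean(segs_k$duration_ms)
    coverage[k] <- length(smp_k) / N
    if (denom_gev > 0)
      gev_k[k] <- sum(seq$corr[smp_k]^2 * seq$gfp[smp_k]^2) / denom_gev
    gfp_k[k] <- mean(seq$gfp[smp_k])
    msc[k] <- mean(abs(seq$corr[smp_k]))
  }
  absent <- which(tabulate(seq$labels[assigned], K) == 0L)
  structure(list(occurrence = occurrence, duration = duration,
                 coverage = coverage, gev = gev_k, gfp = gfp_k,
                 mspatcorr = msc,
                 transition = transition_matrix(segs, K)),
            class = "parameter_set", absent = absent)
}

#' Transition probability matrix between microstate classes
#'
#' Counts transitions between consecutive distinct segments and normalizes
#' each row to probabilities. The diagonal is zero by construction (a
#' segment never transitions to itself). Rows with no outgoing transition
#' are all-zero and listed in the `no_outgoing` attribute. A single-segment
#' input yields an all-zero matrix with a warning.
#'
#' @param segs a `segment_list` (only labels 1..K enter the counts).
#' @param K number of classes.
#' @return K x K matrix; rows with outgoing transitions sum to 1.
#' @export
transition_matrix <- function(segs, K) {
  lab <- segs$label[segs$label > 0L]
  P <- matrix(0, K, K)
  if (length(lab) < 2L) {
    warning("fewer than 2 segments; transition matrix is all zero")
  } else {
    from <- lab[-length(lab)]; to <- lab[-1L]
    for (i in seq_along(from)) P[from[i], to[i]] <- P[from[i], to[i]] + 1
    rs <- rowSums(P)
    P[rs > 0, ] <- P[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  attr(P, "no_outgoing") <- which(rowSums(P) == 0)
  P
}

#' Flatten a parameter set into a named feature vector
#'
#' Order: occurrence (K), duration (K), coverage (K), gev (K), transition
#' (K^2, row-major, zero diagonal included), then gfp (K) and mspatcorr (K)
#' when `include_spatial`. The transition block keeps the diagonal so the
#' temporal block has exactly `4K + K^2` entries for any K.
#'
#' @param ps a `parameter_set`.
#' @param include_spatial append the 2K spatial features?
#' @return Named numeric vector.
#' @export
flatten_parameters <- function(ps, include_spatial = TRUE) {
  K <- length(ps$occurrence)
  tr <- as.vector(t(ps$transition))     # row-major
  nm <- c(paste0("occurrence_", seq_len(K)), paste0("duration_", seq_len(K)),
          paste0("coverage_", seq_len(K)), paste0("gev_", seq_len(K)),
          paste0("trans_", rep(seq_len(K), each = K), "_", rep(seq_len(K), K)))
  out <- c(ps$occurrence, ps$duration, ps$coverage, ps$gev, tr)
  if (include_spatial) {
    nm <- c(nm, paste0("gfp_", seq_len(K)), paste0("mspatcorr_", seq_len(K)))
    out <- c(out, ps$gfp, ps$mspatcorr)
  }
  names(out) <- nm
  out
}

#' Windowed microstate feature table for one recording
#'
#' Splits the recording into non-overlapping windows of `window_s` seconds
#' from the start (an incomplete trailing window is dropped), then per
#' window backfits, smooths, segments and extracts the parameter families,
#' producing one feature row per window. With `include_spatial` the row has
#' `4K + K^2 + 2K` columns, otherwise `4K + K^2`.
#'
#' @param rec an [recording()].
#' @param templates a `template_set` (or K x C matrix).
#' @param window_s window length in seconds (default 15, a length at which
#'   the parameter estimates stabilize while several windows fit in a
#'   trial).
#' @param params a [smoothing_params()] applied per window.
#' @param include_spatial append mean-GFP and mean-spatial-correlation
#'   features?
#' @param polarity passed to [backfit()].
#' @return A data.frame (rows = windows) with a `window` column followed by
#'   the named features.
#' @export
windowed_feature_table <- function(rec, templates, window_s = 15,
                                   params = smoothing_params(),
                                   include_spatial = TRUE,
                                   polarity = "absolute") {
  stop_if_not_recording(rec)
  wlen <- floor(window_s * rec$fs)
  if (wlen < 2L) abort_validation("window_s * fs must be at least 2 samples")
  n_win <- floor(n_samples(rec) / wlen)
  if (n_win < 1L)
    abort_validation("recording (%.1f s) shorter than one %g s window",
                     n_samples(rec) / rec$fs, window_s)
  tpl <- if (inherits(templates, "template_set")) templates$templates else templates
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    sub <- recording(rec$data[, idx, drop = FALSE], rec$fs,
                     rec$channel_names, rec$meta)
    seq <- backfit(sub, tpl, polarity = polarity)
    seq <- switch(params$mode,
                  windowed = smooth_window(seq, sub, tpl, params),
                  min_duration = reject_short_segments(seq,
                                                       params$min_duration_ms,
                                                       sub, tpl),
                  none = seq)
    ps <- suppressWarnings(class_parameters(seq, K = nrow(tpl)))
    rows[[w]] <- flatten_parameters(ps, include_spatial)
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(window = seq_len(n_win), out)
}

#' Canonical EEG frequency bands
#'
#' Delta 1-4, theta 4-8, alpha 8-12, beta 12-30, gamma 30-45 Hz.
#' @return Named list of length-2 numeric ranges.
#' @export
eeg_bands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 12),
       beta = c(12, 30), gamma = c(30, 45))
}

# Averaged modified periodogram (Welch) PSD of one signal.
# Hann window, seg_s-second segments, 50% overlap. Returns freq + density
# such that sum(psd) * df approximates the signal's variance (one-sided).
welch_psd <- function(x, fs, seg_s = 2) {
  nseg <- floor(seg_s * fs)
  if (nseg < 4L || length(x) < nseg)
    abort_validation("signal shorter than one %g s spectral segment", seg_s)
  step <- max(1L, floor(nseg / 2))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))   # Hann
  U <- sum(w^2)
  nfreq <- nseg %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[seq_len(nfreq)])^2 / (U * fs)
    # fold two-sided density into one side (DC and Nyquist not doubled)
    sp[2:(nfreq - 1L)] <- 2 * sp[2:(nfreq - 1L)]
    acc <- acc + sp
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / nseg, psd = acc / length(starts))
}

#' Band-power features per channel
#'
#' Mean spectral power of every channel in each named frequency band,
#' estimated with an averaged modified periodogram (Hann window, `seg_s`
#' second segments, 50% overlap). Power is the PSD integrated over the band
#' (uV^2), so over bands that tile a range the values add up to the power
#' in that range. With `window_s` set, features are computed per
#' non-overlapping window (rows), matching [windowed_feature_table()];
#' otherwise one row covers the whole recording.
#'
#' @param rec an [recording()].
#' @param bands named list of `(low, high)` ranges; default [eeg_bands()].
#' @param window_s optional analysis-window length in seconds.
#' @param seg_s spectral segment length in seconds (default 2).
#' @return A data.frame with a `window` column and `length(bands) * C`
#'   feature columns named `<band>_<channel>`.
#' @export
band_power <- function(rec, bands = eeg_bands(), window_s = NULL, seg_s = 2) {
  stop_if_not_recording(rec)
  nyq <- rec$fs / 2
  for (b in bands) if (b[2L] > nyq)
    abort_validation("band edge %g Hz exceeds Nyquist (%g Hz)", b[2L], nyq)
  wlen <- if (is.null(window_s)) n_samples(rec) else floor(window_s * rec$fs)
  n_win <- floor(n_samples(rec) / wlen)
  if (n_win < 1L) abort_validation("recording shorter than one window")
  C <- n_channels(rec)
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    feats <- numeric(0)
    for (i in seq_len(C)) {
      est <- welch_psd(rec$data[i, idx], rec$fs, seg_s)
      df <- est$freq[2L] - est$freq[1L]
      for (bn in names(bands)) {
        rng <- bands[[bn]]
        sel <- est$freq >= rng[1L] & est$freq < rng[2L]
        feats[paste0(bn, "_", rec$channel_names[i])] <- sum(est$psd[sel]) * df
      }
    }
    rows[[w]] <- feats
  }
  out <- as.data.frame(do.call(rbind, rows))
  cbind(window = seq_len(n_win), out)
}
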