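#' Backfit microstate templates onto every EEG sample
#'
#' Labels each time point of a recording with the template of highest
#' spatial correlation, turning the continuous EEG into a microstate label
#' sequence. In `"absolute"` mode (default, consistent with
#' polarity-invariant clustering) the winner is `argmax_k |Corr(x_n, a_k)|`;
#' `"signed"` mode uses the raw correlation. The stored `corr` is always the
#' winning signed value. A zero map (all channels equal) inherits the
#' previous sample's label; at the first sample it is labeled 0 with a
#' warning.
#'
#' @param rec an [recording()] whose channel order matches the templates.
#' @param templates a `template_set` or K x C unit-norm matrix.
#' @param polarity `"absolute"` or `"signed"`.
#' @return A `label_sequence`: list with `labels` (length N, 0 =
#'   unassigned), `corr`, `gfp`, `fs`, `K`.
#' @export
backfit <- function(rec, templates, polarity = c("absolute", "signed")) {
  stop_if_not_recording(rec)
  polarity <- match.arg(polarity)
  tpl <- if (inherits(templates, "template_set")) templates$templates else templates
  if (ncol(tpl) != n_channels(rec))
    abort_validation("templates have %d channels, recording has %d",
                     ncol(tpl), n_channels(rec))
  v <- common_average_reference(rec$data)
  maps <- t(v)
  g <- gfp_of_maps(maps)
  corr <- correlation_matrix(maps, tpl)
  score <- if (polarity == "absolute") abs(corr) else corr
  labels <- max.col(score, ties.method = "first")
  win <- corr[cbind(seq_along(labels), labels)]
  zero <- g == 0
  if (any(zero)) {
    labels[zero] <- NA_integer_
    win[zero] <- 0
    labels <- fill_forward(labels)
    if (is.na(labels[1L])) {
      warning("recording starts with a zero map; leading samples labeled 0")
      labels[is.na(labels)] <- 0L
    }
  }
  structure(list(labels = as.integer(labels), corr = win, gfp = g,
                 fs = rec$fs, K = nrow(tpl)),
            class = "label_sequence")
}

fill_forward <- function(x) {
  na <- is.na(x)
  if (!any(na)) return(x)
  idx <- cummax(ifelse(na, 0L, seq_along(x)))
  out <- x
  out[na & idx > 0L] <- x[idx[na & idx > 0L]]
  out
}

#' Temporal smoothing parameters
#'
#' @param mode `"windowed"` (penalized relabeling), `"min_duration"`
#'   (dissolve short segments) or `"none"`.
#' @param b window half-width in samples for windowed smoothing (default 3).
#' @param lam penalty weight rewarding label agreement inside the window.
#'   The default 1 is calibrated to the objective's scales: dissolving a
#'   segment boundary gains about `2 b (b + 1) lam` agreement units, so at
#'   `lam = 1` a noise-driven label flip with no fit support is absorbed
#'   while a genuine segment of a few samples at full field strength (fit
#'   margin ~10 cost units per sample) survives; much larger values absorb
#'   the short-lifespan tail of real label sequences wholesale and bias the
#'   mean duration upward.
#' @param min_duration_ms threshold for the min-duration smoother
#'   (default 30 ms, roughly a third of a typical microstate lifespan).
#' @param max_smooth_iter iteration cap for the windowed smoother.
#' @return A `smoothing_params` list.
#' @export
smoothing_params <- function(mode = c("windowed", "min_duration", "none"),
                             b = 3L, lam = 1, min_duration_ms = 30,
                             max_smooth_iter = 1000L) {
  stopifnot(b >= 1L, lam >= 0, min_duration_ms >= 0)
  structure(list(mode = match.arg(mode), b = as.integer(b), lam = lam,
                 min_duration_ms = min_duration_ms,
                 max_smooth_iter = as.integer(max_smooth_iter)),
            class = "smoothing_params")
}

# Per-sample, per-template fit cost used by the windowed smoother:
# d2[n,k] / (2 * e * (C - 1)) with d2[n,k] = x'x - (x'a_k)^2 the orthogonal
# squared distance, and e the mean residual variance of the incoming
# labeling, e = sum_n d2[n, l_n] / (N * (C - 1)). This is the scaling of the
# classic windowed segmentation smoother, which keeps the penalty weight
# lambda commensurate with the fit term regardless of signal amplitude.
# Zero-GFP samples cost 0 for every label.
smooth_cost_matrix <- function(maps, templates, labels) {
  C <- ncol(maps)
  proj2 <- (maps %*% t(templates))^2
  d2 <- rowSums(maps^2) - proj2
  assigned <- labels > 0L
  e <- sum(d2[cbind(which(assigned), labels[assigned])]) /
    (sum(assigned) * (C - 1))
  if (e <= 0) e <- .Machine$double.eps
  cost <- d2 / (2 * e * (C - 1))
  cost[gfp_of_maps(maps) == 0, ] <- 0
  cost
}

#' Windowed smoothing of a microstate label sequence
#'
#' Iteratively relabels each sample n to minimize
#' `cost(n, k) - lam * N_k(n)`, where the fit cost is the orthogonal squared
#' distance to template k scaled by the residual variance of the incoming
#' labeling, `cost(n, k) = d2(n, k) / (2 e (C - 1))` with
#' `d2(n, k) = x'x - (x'a_k)^2` and `e = mean_n d2(n, l_n) / (C - 1)`, and
#' `N_k(n)` counts samples with label k inside the window
#' `n-b .. n+b` (excluding n itself; windows truncate at the edges). All
#' samples are relabeled simultaneously per pass, from the previous pass's
#' labels; passes run until none changes a label or `max_smooth_iter` is
#' reached (then the current state is returned with a warning). This is the
#' classic windowed segmentation smoother: the penalty term absorbs brief
#' noise-driven label flips into their temporal context, while the
#' simultaneous update keeps the relabeling symmetric in time (an in-place
#' sweep would drag labels in the sweep direction).
#'
#' @param seq a `label_sequence` from [backfit()].
#' @param rec the recording the sequence was fitted on (source of the maps).
#' @param templates the `template_set` (or matrix) used for backfitting.
#' @param params a [smoothing_params()] with `mode = "windowed"`.
#' @return A relabeled `label_sequence` (corr updated to the new labels).
#' @export
smooth_window <- function(seq, rec, templates, params = smoothing_params()) {
  stopifnot(inherits(seq, "label_sequence"), params$mode == "windowed")
  tpl <- if (inherits(templates, "template_set")) templates$templates else templates
  maps <- t(common_average_reference(rec$data))
  corr <- correlation_matrix(maps, tpl)
  cost <- smooth_cost_matrix(maps, tpl, seq$labels)
  labels <- seq$labels
  N <- length(labels); K <- nrow(tpl); b <- params$b
  unassigned <- labels == 0L
  converged <- FALSE
  idx <- seq_len(N)
  lo <- pmax(0L, idx - b - 1L); hi <- pmin(N, idx + b)
  window_counts <- function(lab) {
    vapply(seq_len(K), function(k) {
      ind <- as.numeric(lab == k)
      cs <- c(0, cumsum(ind))
      cs[hi + 1L] - cs[lo + 1L] - ind
    }, numeric(N))
  }
  total_objective <- function(lab) {
    a <- which(lab > 0L)
    cnt <- window_counts(lab)
    sum(cost[cbind(a, lab[a])]) - params$lam * sum(cnt[cbind(a, lab[a])])
  }
  prev <- NULL
  for (pass in seq_len(params$max_smooth_iter)) {
    obj <- cost - params$lam * window_counts(labels)
    new_labels <- max.col(-obj, ties.method = "first")
    new_labels[unassigned] <- 0L
    if (identical(new_labels, labels)) { converged <- TRUE; break }
    if (!is.null(prev) && identical(new_labels, prev)) {
      # simultaneous updates can settle into a 2-cycle; keep the better state
      if (total_objective(prev) < total_objective(labels)) labels <- prev
      converged <- TRUE
      break
    }
    prev <- labels
    labels <- new_labels
  }
  if (!converged)
    warning("windowed smoothing did not converge within max_smooth_iter")
  out <- seq
  out$labels <- as.integer(labels)
  out$corr[!unassigned] <- corr[cbind(which(!unassigned), labels[!unassigned])]
  out
}

#' Dissolve segments shorter than a duration threshold
#'
#' Alternative smoother: any maximal run shorter than `min_duration_ms` is
#' dissolved sample-by-sample into one of the two neighboring labels. When
#' `templates` and `rec` are supplied, each sample joins the neighbor whose
#' template correlates more strongly (in absolute value) with the sample's
#' map; otherwise each sample joins the nearer neighbor (ties to the left).
#' Repeats until no short segment remains. If the whole sequence is shorter
#' than the threshold it is returned unchanged with a warning.
#'
#' @param seq a `label_sequence`.
#' @param min_duration_ms duration threshold in milliseconds.
#' @param rec,templates optional recording + templates enabling
#'   correlation-guided reassignment.
#' @return A `label_sequence` with no run shorter than the threshold.
#' @export
reject_short_segments <- function(seq, min_duration_ms, rec = NULL,
                                  templates = NULL) {
  stopifnot(inherits(seq, "label_sequence"), min_duration_ms >= 0)
  if (min_duration_ms == 0) return(seq)
  min_len <- ceiling(min_duration_ms * seq$fs / 1000)
  labels <- seq$labels
  if (length(labels) < min_len) {
    warning("sequence shorter than min_duration_ms; returned unchanged")
    return(seq)
  }
  corr_mat <- NULL
  if (!is.null(rec) && !is.null(templates)) {
    tpl <- if (inherits(templates, "template_set")) templates$templates else templates
    corr_mat <- abs(correlation_matrix(t(common_average_reference(rec$data)), tpl))
  }
  repeat {
    r <- rle(labels)
    short <- which(r$lengths < min_len)
    short <- short[!(short == 1L & length(r$lengths) == 1L)]
    if (!length(short)) break
    # dissolve the shortest run first (ties: leftmost)
    i <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    left <- if (i > 1L) r$values[i - 1L] else NA_integer_
    right <- if (i < length(r$values)) r$values[i + 1L] else NA_integer_
    for (n in starts[i]:ends[i]) {
      if (is.na(left)) labels[n] <- right
      else if (is.na(right)) labels[n] <- left
      else if (!is.null(corr_mat)) {
        labels[n] <- if (corr_mat[n, left] >= corr_mat[n, right]) left else right
      } else {
        labels[n] <- if (n - starts[i] <= ends[i] - n) left else right
      }
    }
  }
  out <- seq
  out$labels <- as.integer(labels)
  if (!is.null(corr_mat)) {
    moved <- which(labels != seq$labels & labels > 0L)
    # recompute signed corr for relabeled samples
    if (length(moved)) {
      tpl <- if (inherits(templates, "template_set")) templates$templates else templates
      signed <- correlation_matrix(t(common_average_reference(rec$data)), tpl)
      out$corr[moved] <- signed[cbind(moved, labels[moved])]
    }
  }
  out
}

#' Run-length segmentation of a label sequence
#'
#' @param seq a `label_sequence`.
#' @return A data.frame of class `segment_list` with one row per maximal
#'   run: `label`, `start` (1-based), `end` (half-open, i.e. first sample
#'   after the run), `duration_ms`.
#' @export
segmentize <- function(seq) {
  stopifnot(inherits(seq, "label_sequence"), length(seq$labels) >= 1L)
  r <- rle(seq$labels)
  ends <- cumsum(r$lengths)
  out <- data.frame(label = r$values,
                    start = ends - r$lengths + 1L,
                    end = ends + 1L,
                    duration_ms = r$lengths / seq$fs * 1000)
  class(out) <- c("segment_list", "data.frame")
  out
}

#' Expand a segment list back into per-sample labels
#'
#' Inverse of [segmentize()] (for the labels).
#'
#' @param segs a `segment_list`.
#' @return Integer label vector.
#' @export
expand_segments <- function(segs) {
  rep.int(segs$label, segs$end - segs$start)
}

#' @export
print.label_sequence <- function(x, ...) {
  cat(sprintf("<label_sequence> %d samples @ %g Hz, K = %d, %d segment(s)\n",
              length(x$labels), x$fs, x$K, length(rle(x$labels)$values)))
  invisible(x)
}
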