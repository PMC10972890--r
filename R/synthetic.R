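#' Synthetic microstate templates
#'
#' Builds K zero-mean, unit-norm scalp maps with pairwise absolute
#' correlation below `max_corr`. Maps start as smooth random spatial
#' profiles (Gaussian channel noise smoothed along the channel index,
#' mimicking the spatial coherence of real topographies) and are then
#' blended with their symmetric (Loewdin) orthogonalization just far enough
#' to bring every pairwise correlation under the bound, so the result keeps
#' as much of the smooth random structure as the separation constraint
#' allows. With `orthogonal = TRUE` the fully orthogonalized set is
#' returned (pairwise correlation exactly 0).
#'
#' @param K number of templates (>= 2).
#' @param C number of channels (> K).
#' @param seed integer seed.
#' @param max_corr pairwise absolute-correlation bound (default 0.3).
#' @param orthogonal return the exactly orthogonal set?
#' @return A `template_set` with `templates` (K x C), `K`, and NA-filled
#'   fit fields (no bank has been fitted).
#' @export
make_templates <- function(K, C, seed = 1L, max_corr = 0.3,
                           orthogonal = FALSE) {
  stopifnot(K >= 2L, C > K)
  smooth_width <- max(1L, min(C %/% 4L, 7L))
  kern <- rep(1 / smooth_width, smooth_width)
  tpl <- with_seed(seed, {
    m <- matrix(stats::rnorm(K * C), K, C)
    if (smooth_width > 1L)
      m <- t(apply(m, 1L, function(x)
        as.numeric(stats::filter(x, kern, sides = 2L, circular = TRUE))))
    normalize_rows(m)
  })
  # symmetric orthogonalization: O = (M M')^(-1/2) M has orthonormal rows
  # and is the closest such set to M
  gram <- tcrossprod(tpl)
  eg <- eigen(gram, symmetric = TRUE)
  if (min(eg$values) < 1e-10)
    stop("degenerate random templates; use a different seed", call. = FALSE)
  ortho <- normalize_rows(
    eg$vectors %*% diag(1 / sqrt(eg$values), K) %*% t(eg$vectors) %*% tpl)
  out <- NULL
  for (beta in seq(0, 1, by = 0.05)) {
    cand <- normalize_rows((1 - beta) * tpl + beta * ortho)
    cc <- abs(tcrossprod(cand)); diag(cc) <- 0
    if (max(cc) < max_corr) { out <- cand; break }
  }
  if (orthogonal) out <- ortho
  structure(list(templates = out, K = as.integer(K),
                 labels_of_bank = integer(0), gev_total = NA_real_,
                 gev_per_class = rep(NA_real_, K)),
            class = "template_set")
}

#' Synthetic-recording configuration
#'
#' Parameters of the planted-microstate generator. Defaults emulate the
#' conventional picture of spontaneous EEG microstates: quasi-stable
#' topographies with a mean lifespan of about 100 ms (the middle of the
#' typical 80-120 ms range), switching as a first-order Markov chain, with
#' the template amplitude modulated by a rectified 10 Hz sinusoid (two GFP
#' peaks per cycle, the alpha-band GFP rhythm) plus white sensor noise.
#'
#' @param K_true number of planted microstates (default 4).
#' @param C channels (default 32).
#' @param fs sampling rate, Hz (default 200).
#' @param duration_s recording length in seconds (default 60).
#' @param mean_duration_ms mean segment lifespan (default 100).
#' @param transition K x K row-stochastic matrix with zero diagonal, or
#'   `"uniform"` for equal probability over the other states.
#' @param snr amplitude ratio of template signal RMS to noise RMS
#'   (default 4).
#' @param duration_dist `"geometric"` (memoryless, matching a first-order
#'   Markov chain at the sample level) or `"truncnorm"` (truncated Gaussian
#'   with sd = 0.3 * mean, a more peaked duration histogram).
#' @param envelope_hz frequency of the rectified-sinusoid amplitude
#'   envelope (default 10).
#' @param seed integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(K_true = 4L, C = 32L, fs = 200, duration_s = 60,
                         mean_duration_ms = 100, transition = "uniform",
                         snr = 4, duration_dist = c("geometric", "truncnorm"),
                         envelope_hz = 10, seed = 1L) {
  stopifnot(K_true >= 2L, C > K_true, fs > 0, duration_s > 0, snr > 0)
  if (mean_duration_ms <= 1000 / fs)
    abort_validation("mean_duration_ms must exceed one sample period (%g ms)",
                     1000 / fs)
  if (is.matrix(transition)) {
    stopifnot(nrow(transition) == K_true, ncol(transition) == K_true,
              all(abs(diag(transition)) == 0),
              all(abs(rowSums(transition) - 1) < 1e-9))
  } else stopifnot(identical(transition, "uniform"))
  structure(list(K_true = as.integer(K_true), C = as.integer(C), fs = fs,
                 duration_s = duration_s, mean_duration_ms = mean_duration_ms,
                 transition = transition, snr = snr,
                 duration_dist = match.arg(duration_dist),
                 envelope_hz = envelope_hz, seed = as.integer(seed)),
            class = "synth_config")
}

#' Simulate an EEG recording with planted microstate structure
#'
#' Draws a semi-Markov label sequence (segment durations geometric or
#' truncated-Gaussian around `mean_duration_ms`, next state from the
#' transition matrix), emits `signal = template[l_n] * envelope_n`, adds
#' white Gaussian sensor noise scaled so that signal RMS / noise RMS =
#' `snr`, and common-average-references every sample. The ground-truth
#' labels and segments are returned alongside the recording, so every
#' downstream stage can be scored against the truth.
#'
#' @param cfg a [synth_config()].
#' @param templates optional pre-built `template_set` (otherwise
#'   [make_templates()] with the config's seed).
#' @return List with `recording`, `labels` (a ground-truth
#'   `label_sequence`), `segments` (its `segment_list`), and `templates`.
#' @export
simulate_recording <- function(cfg = synth_config(), templates = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  if (is.null(templates))
    templates <- make_templates(cfg$K_true, cfg$C, seed = cfg$seed)
  tpl <- templates$templates
  N <- floor(cfg$duration_s * cfg$fs)
  mean_len <- cfg$mean_duration_ms * cfg$fs / 1000
  P <- if (is.matrix(cfg$transition)) cfg$transition else {
    m <- matrix(1 / (cfg$K_true - 1), cfg$K_true, cfg$K_true)
    diag(m) <- 0
    m
  }
  sim <- with_seed(cfg$seed + 7919L, {
    labels <- integer(N)
    pos <- 1L
    state <- sample.int(cfg$K_true, 1L)
    while (pos <= N) {
      len <- switch(cfg$duration_dist,
                    geometric = stats::rgeom(1L, 1 / mean_len) + 1L,
                    truncnorm = max(1L, round(stats::rnorm(1L, mean_len,
                                                           0.3 * mean_len))))
      end <- min(N, pos + len - 1L)
      labels[pos:end] <- state
      pos <- end + 1L
      state <- sample.int(cfg$K_true, 1L, prob = P[state, ])
    }
    t_axis <- (seq_len(N) - 1L) / cfg$fs
    env <- abs(sin(2 * pi * cfg$envelope_hz * t_axis))
    sig <- t(tpl[labels, , drop = FALSE] * env)
    sig_rms <- sqrt(mean(sig^2))
    noise <- matrix(stats::rnorm(cfg$C * N, sd = sig_rms / cfg$snr), cfg$C, N)
    list(labels = labels, data = common_average_reference(sig + noise))
  })
  rec <- recording(sim$data, fs = cfg$fs,
                   meta = list(generator = "planted_microstates",
                               K_true = cfg$K_true, seed = cfg$seed))
  truth <- structure(list(labels = sim$labels,
                          corr = rep(1, N), gfp = gfp_of_maps(t(sim$data)),
                          fs = cfg$fs, K = cfg$K_true),
                     class = "label_sequence")
  list(recording = rec, labels = truth, segments = segmentize(truth),
       templates = templates)
}

#' Match recovered templates to planted ones
#'
#' Greedy one-to-one matching by absolute spatial correlation (polarity is a
#' gauge freedom). Returns, per planted template, the matched recovered
#' index and the |correlation|.
#'
#' @param truth,fitted `template_set`s (or matrices) with equal C.
#' @return data.frame with columns `planted`, `recovered`, `abs_corr`.
#' @export
match_templates <- function(truth, fitted) {
  A <- if (inherits(truth, "template_set")) truth$templates else truth
  B <- if (inherits(fitted, "template_set")) fitted$templates else fitted
  cc <- abs(A %*% t(B)) / (sqrt(rowSums(A^2)) %o% sqrt(rowSums(B^2)))
  out <- data.frame(planted = seq_len(nrow(A)), recovered = NA_integer_,
                    abs_corr = NA_real_)
  avail <- rep(TRUE, nrow(B))
  for (step in seq_len(min(nrow(A), nrow(B)))) {
    masked <- cc
    masked[!is.na(out$abs_corr), ] <- -Inf
    masked[, !avail] <- -Inf
    ij <- arrayInd(which.max(masked), dim(masked))
    out$recovered[ij[1L]] <- ij[2L]
    out$abs_corr[ij[1L]] <- cc[ij[1L], ij[2L]]
    avail[ij[2L]] <- FALSE
  }
  out
}
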