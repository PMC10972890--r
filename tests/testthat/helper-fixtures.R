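# Fixtures are built in code at test time; nothing binary ships in the repo.

random_recording <- function(C = 8, N = 512, fs = 200, seed = 1) {
  set.seed(seed)
  recording(matrix(rnorm(C * N), C, N), fs = fs,
            channel_names = paste0("E", seq_len(C)))
}

# bank of noisy copies of planted templates, mixed polarity
planted_bank <- function(templates, per_class = 10, noise = 0.05,
                         amp = 5, seed = 1) {
  set.seed(seed)
  K <- nrow(templates); C <- ncol(templates)
  rows <- do.call(rbind, lapply(seq_len(K), function(k) {
    signs <- sample(c(-1, 1), per_class, replace = TRUE)
    t(sapply(seq_len(per_class), function(i)
      signs[i] * amp * templates[k, ] + noise * rnorm(C)))
  }))
  rows <- rows - rowMeans(rows)
  structure(list(maps = rows,
                 source = data.frame(recording = 1L, sample = seq_len(nrow(rows))),
                 gfp = sqrt(rowMeans(rows^2))),
            class = "topography_bank")
}

# independent (loop-based) uncentered correlation, used by several oracles
oracle_corr <- function(u, v) sum(u * v) / sqrt(sum(u^2) * sum(v^2))

# label sequence built directly from parts, for feature tests
make_label_sequence <- function(labels, fs, corr = NULL, gfp = NULL,
                                K = max(labels)) {
  structure(list(labels = as.integer(labels),
                 corr = corr %||% rep(1, length(labels)),
                 gfp = gfp %||% rep(1, length(labels)),
                 fs = fs, K = as.integer(K)),
            class = "label_sequence")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
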