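test_that("single-segment window gives the textbook parameter values", {
  N <- 2000; fs <- 200                     # 10 s of constant label 1
  seq <- make_label_sequence(rep(1L, N), fs = fs, K = 3)
  ps <- suppressWarnings(class_parameters(seq))
  expect_equal(ps$coverage, c(1, 0, 0))
  expect_equal(ps$duration[1], 10000)
  expect_equal(ps$occurrence[1], 0.1)      # one segment in 10 s
  expect_identical(attr(ps, "absent"), c(2L, 3L))
})

test_that("exact template copies give unit mean correlation and total GEV", {
  tpl <- make_templates(3, 10, seed = 1)$templates
  set.seed(2)
  lab <- sample(1:3, 300, replace = TRUE)
  amp <- runif(300, 0.5, 2)
  maps <- tpl[lab, ] * amp
  rec <- recording(t(maps), fs = 100)
  seq <- backfit(rec, tpl)
  expect_identical(seq$labels, lab)
  ps <- class_parameters(seq)
  expect_equal(ps$mspatcorr, rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(ps$gev), 1, tolerance = 1e-9)
})

test_that("parameters match an independent loop-based oracle", {
  set.seed(3)
  K <- 4; N <- 800; fs <- 200
  lab <- rep(sample(1:K, 60, replace = TRUE), times = sample(5:25, 60, TRUE))[1:N]
  corr <- runif(N, -1, 1); gfp <- runif(N, 0.1, 3)
  seq <- make_label_sequence(lab, fs = fs, corr = corr, gfp = gfp, K = K)
  ps <- class_parameters(seq)
  segs <- segmentize(seq)
  win_s <- N / fs
  denom <- sum(gfp^2)
  for (k in 1:K) {
    idx <- which(lab == k)
    runs <- rle(lab)
    segs_k <- sum(runs$values == k)
    expect_equal(ps$occurrence[k], segs_k / win_s, tolerance = 1e-9)
    expect_equal(ps$duration[k],
                 mean(runs$lengths[runs$values == k]) / fs * 1000,
                 tolerance = 1e-9)
    expect_equal(ps$coverage[k], length(idx) / N, tolerance = 1e-9)
    expect_equal(ps$gev[k], sum(corr[idx]^2 * gfp[idx]^2) / denom,
                 tolerance = 1e-9)
    expect_equal(ps$gfp[k], mean(gfp[idx]), tolerance = 1e-9)
    expect_equal(ps$mspatcorr[k], mean(abs(corr[idx])), tolerance = 1e-9)
  }
})

test_that("coverage conservation and the occurrence-duration identity hold", {
  set.seed(4)
  for (i in 1:5) {
    lab <- rep(sample(1:3, 40, replace = TRUE), times = sample(3:30, 40, TRUE))
    seq <- make_label_sequence(lab, fs = 250, K = 3)
    ps <- suppressWarnings(class_parameters(seq))
    expect_equal(sum(ps$coverage), 1, tolerance = 1e-9)
    present <- ps$occurrence > 0
    expect_equal(ps$coverage[present],
                 ps$occurrence[present] * ps$duration[present] / 1000,
                 tolerance = 1e-6)
  }
})

test_that("transition probabilities are hand-countable", {
  seg <- function(lab) data.frame(label = lab)
  P <- transition_matrix(seg(c(1L, 2L, 1L, 2L)), 2)
  expect_equal(P, matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)
  P2 <- transition_matrix(seg(c(1L, 2L, 3L, 1L, 2L, 3L)), 3)
  expect_equal(P2, rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
               ignore_attr = TRUE)
  expect_warning(P3 <- transition_matrix(seg(1L), 2), "fewer than 2")
  expect_true(all(P3 == 0))
  # counting oracle on a random 50-segment sequence
  set.seed(5)
  lab <- 1L + c(0L, cumsum(sample(1:2, 49, replace = TRUE))) %% 3L
  got <- transition_matrix(seg(lab), 3)
  counts <- matrix(0, 3, 3)
  for (i in seq_len(49)) counts[lab[i], lab[i + 1]] <- counts[lab[i], lab[i + 1]] + 1
  expected <- counts / pmax(rowSums(counts), 1)
  expect_equal(got, expected, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(diag(got) == 0))
  rows_out <- rowSums(got) > 0
  expect_equal(rowSums(got)[rows_out], rep(1, sum(rows_out)), ignore_attr = TRUE)
})

test_that("window segmentation yields the expected window counts", {
  fs <- 100
  rec178 <- random_recording(C = 4, N = 178 * fs, fs = fs, seed = 6)
  tpl4 <- make_templates(3, 4, seed = 7)$templates
  ft <- windowed_feature_table(rec178, tpl4, window_s = 15,
                               params = smoothing_params(mode = "none"))
  expect_identical(nrow(ft), 11L)
  rec60 <- random_recording(C = 4, N = 60 * fs, fs = fs, seed = 8)
  ft60 <- windowed_feature_table(rec60, tpl4, window_s = 15,
                                 params = smoothing_params(mode = "none"))
  expect_identical(nrow(ft60), 4L)
  expect_error(windowed_feature_table(
    random_recording(C = 4, N = 100, fs = fs), tpl4, window_s = 15), "shorter")
})

test_that("feature vector widths follow 4K + K^2 (+2K) for any K and C", {
  fs <- 100
  rec62 <- random_recording(C = 62, N = 30 * fs, fs = fs, seed = 9)
  tpl10 <- make_templates(10, 62, seed = 10)$templates
  ft <- windowed_feature_table(rec62, tpl10, window_s = 15,
                               params = smoothing_params(mode = "none"))
  expect_identical(ncol(ft) - 1L, 160L)      # 140 temporal + 20 spatial
  ft_t <- windowed_feature_table(rec62, tpl10, window_s = 15,
                                 params = smoothing_params(mode = "none"),
                                 include_spatial = FALSE)
  expect_identical(ncol(ft_t) - 1L, 140L)
  rec32 <- random_recording(C = 32, N = 30 * fs, fs = fs, seed = 11)
  tpl9 <- make_templates(9, 32, seed = 12)$templates
  ft9 <- windowed_feature_table(rec32, tpl9, window_s = 15,
                                params = smoothing_params(mode = "none"))
  expect_identical(ncol(ft9) - 1L, 135L)     # 117 temporal + 18 spatial
  bp <- band_power(rec62)
  expect_identical(ncol(bp) - 1L, 310L)      # 62 channels x 5 bands
  bp32 <- band_power(rec32)
  expect_identical(ncol(bp32) - 1L, 160L)
})

test_that("band power concentrates a pure alpha tone in the alpha band", {
  fs <- 200; t_ax <- (0:(20 * fs - 1)) / fs
  rec <- recording(rbind(sin(2 * pi * 10 * t_ax),
                         0.01 * rnorm(length(t_ax))), fs = fs,
                   channel_names = c("tone", "noise"))
  bp <- band_power(rec)
  tone_cols <- grep("_tone$", names(bp))
  powers <- unlist(bp[1, tone_cols])
  expect_gt(powers[["alpha_tone"]] / sum(powers), 0.9)
})

test_that("summed band powers match the filtered time-domain variance", {
  fs <- 200
  set.seed(13)
  rec <- recording(matrix(rnorm(2 * 60 * fs), 2), fs = fs)
  bp <- band_power(rec)
  total_welch <- sum(unlist(bp[1, grep("_Ch1$", names(bp))]))
  filtered <- preprocess(rec, preprocess_config(bandpass = c(1, 45),
                                                notch = NULL, car = FALSE))
  expect_equal(total_welch, stats::var(filtered$data[1, ]), tolerance = 0.1)
})
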