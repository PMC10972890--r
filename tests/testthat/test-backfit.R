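make_rec_from_maps <- function(maps, fs = 200) {
  recording(t(maps), fs = fs)
}

test_that("backfitting labels samples by highest spatial correlation", {
  tpl <- make_templates(3, 10, seed = 1)$templates
  rec <- make_rec_from_maps(rbind(4 * tpl[2, ], -4 * tpl[2, ], 2 * tpl[1, ]))
  seq <- backfit(rec, tpl)
  expect_identical(seq$labels, c(2L, 2L, 1L))
  expect_equal(seq$corr[1], 1, tolerance = 1e-9)
  expect_equal(seq$corr[2], -1, tolerance = 1e-9)  # polarity kept in corr
  # signed mode must not map the flipped sample onto template 2
  expect_false(backfit(rec, tpl, polarity = "signed")$labels[2] == 2L)
})

test_that("backfit equals an exhaustive argmax oracle on random samples", {
  tpl <- make_templates(4, 12, seed = 2)$templates
  set.seed(3)
  maps <- matrix(rnorm(100 * 12), 100, 12)
  rec <- make_rec_from_maps(maps)
  seq <- backfit(rec, tpl)
  v <- sweep(maps, 1, rowMeans(maps))   # CAR happens along channels per sample
  oracle <- vapply(seq_len(100), function(n) {
    scores <- vapply(1:4, function(k) abs(oracle_corr(v[n, ], tpl[k, ])), 0)
    which.max(scores)
  }, 0L)
  expect_identical(seq$labels, oracle)
})

test_that("a global sign flip of the recording leaves labels unchanged", {
  tpl <- make_templates(3, 8, seed = 4)$templates
  rec <- random_recording(C = 8, N = 200, fs = 200, seed = 5)
  flipped <- recording(-rec$data, rec$fs, rec$channel_names)
  expect_identical(backfit(rec, tpl)$labels, backfit(flipped, tpl)$labels)
})

test_that("zero maps inherit the previous label, or 0 with a warning at start", {
  tpl <- make_templates(2, 6, seed = 6)$templates
  maps <- rbind(3 * tpl[1, ], 0, 3 * tpl[2, ])
  seq <- backfit(make_rec_from_maps(maps), tpl)
  expect_identical(seq$labels, c(1L, 1L, 2L))
  maps0 <- rbind(0, 3 * tpl[1, ])
  expect_warning(seq0 <- backfit(make_rec_from_maps(maps0), tpl), "zero map")
  expect_identical(seq0$labels, c(0L, 1L))
})

test_that("windowed smoothing keeps clean segmentations fixed and absorbs blips", {
  tpl <- make_templates(2, 8, seed = 7, orthogonal = TRUE)$templates
  # 3 long segments, strong fit, no segment shorter than 2b + 1
  labels_true <- rep(c(1L, 2L, 1L), times = c(20, 20, 20))
  set.seed(8)
  maps <- tpl[labels_true, ] * 5 + 0.1 * matrix(rnorm(60 * 8), 60, 8)
  rec <- make_rec_from_maps(maps)
  seq <- backfit(rec, tpl)
  smoothed <- smooth_window(seq, rec, tpl, smoothing_params(b = 3, lam = 1))
  expect_identical(smoothed$labels, seq$labels)

  # a single-sample blip inside a homogeneous stretch dies under large
  # lambda (sensor noise keeps the residual scale of the cost realistic)
  set.seed(81)
  maps2 <- tpl[rep(1L, 41), ] * 3 + 0.5 * matrix(rnorm(41 * 8), 41, 8)
  maps2[21, ] <- tpl[2, ] * 3 + 0.5 * rnorm(8)
  rec2 <- make_rec_from_maps(maps2)
  seq2 <- backfit(rec2, tpl)
  expect_identical(seq2$labels[21], 2L)
  sm2 <- smooth_window(seq2, rec2, tpl, smoothing_params(b = 3, lam = 50))
  expect_identical(sm2$labels, rep(1L, 41))
})

test_that("the windowed smoother matches exhaustive minimization on 12 samples", {
  tpl <- make_templates(2, 6, seed = 9, orthogonal = TRUE)$templates
  truth <- rep(c(1L, 2L), times = c(6, 6))
  set.seed(10)
  maps <- tpl[truth, ] * 3 + 0.8 * matrix(rnorm(12 * 6), 12, 6)
  maps[4, ] <- tpl[2, ] * 0.8 + 0.8 * rnorm(6)   # weak contrarian sample
  maps <- maps - rowMeans(maps)
  rec <- make_rec_from_maps(maps)
  b <- 1L; lam <- 0.8
  seq <- backfit(rec, tpl)
  sm <- smooth_window(seq, rec, tpl,
                      smoothing_params(b = b, lam = lam))

  # independent objective: recompute cost from first principles with the
  # documented residual scaling, then enumerate all 2^12 labelings
  v <- sweep(maps, 1, rowMeans(maps))
  proj2 <- (v %*% t(tpl))^2
  d2 <- rowSums(v^2) - proj2
  e <- sum(d2[cbind(1:12, seq$labels)]) / (12 * (ncol(v) - 1))
  cost <- d2 / (2 * e * (ncol(v) - 1))
  objective <- function(lab) {
    agree <- 0
    for (n in 1:12) {
      win <- max(1, n - b):min(12, n + b)
      agree <- agree + sum(lab[setdiff(win, n)] == lab[n])
    }
    sum(cost[cbind(1:12, lab)]) - lam * agree
  }
  all_labs <- as.matrix(expand.grid(rep(list(1:2), 12)))
  objs <- apply(all_labs, 1, function(l) objective(as.integer(l)))
  best <- as.integer(all_labs[which.min(objs), ])
  expect_identical(sm$labels, best)
  expect_lte(objective(sm$labels), objective(seq$labels))
})

test_that("smoothing never increases the segment count", {
  tpl <- make_templates(3, 10, seed = 11)$templates
  for (s in 1:5) {
    sim <- simulate_recording(synth_config(K_true = 3, C = 10, fs = 200,
                                           duration_s = 10, snr = 2, seed = s),
                              templates = make_templates(3, 10, seed = 11))
    seq <- backfit(sim$recording, tpl)
    sm <- smooth_window(seq, sim$recording, tpl, smoothing_params())
    expect_lte(nrow(segmentize(sm)), nrow(segmentize(seq)))
    rj <- reject_short_segments(seq, 30, sim$recording, tpl)
    expect_lte(nrow(segmentize(rj)), nrow(segmentize(seq)))
  }
})

test_that("short-segment rejection dissolves sub-threshold runs", {
  tpl <- make_templates(2, 6, seed = 12)$templates
  lab <- rep(c(1L, 2L, 1L), times = c(10, 1, 10))
  seq <- make_label_sequence(lab, fs = 200)
  expect_identical(reject_short_segments(seq, 0)$labels, lab)  # identity at 0
  out <- reject_short_segments(seq, 30)        # 1 sample = 5 ms < 30 ms
  expect_identical(out$labels, rep(1L, 21))
  # random sequences: postcondition scan
  set.seed(13)
  for (i in 1:5) {
    seq_r <- make_label_sequence(sample(1:3, 200, replace = TRUE), fs = 200)
    out_r <- reject_short_segments(seq_r, 25)
    runs <- rle(out_r$labels)
    expect_true(all(runs$lengths >= ceiling(25 * 200 / 1000)))
  }
  short_seq <- make_label_sequence(c(1L, 2L), fs = 200)
  expect_warning(reject_short_segments(short_seq, 1000), "shorter")
})

test_that("segmentation round-trips and reports durations in ms", {
  seq <- make_label_sequence(rep(1L, 2000), fs = 200)
  segs <- segmentize(seq)
  expect_identical(nrow(segs), 1L)
  expect_equal(segs$duration_ms, 10000)
  alt <- make_label_sequence(rep(c(1L, 2L), 50), fs = 200)
  segs_alt <- segmentize(alt)
  expect_identical(nrow(segs_alt), 100L)
  expect_true(all(segs_alt$duration_ms == 5))
  expect_identical(expand_segments(segs_alt), alt$labels)
  # tiling: half-open segments cover 1..N without overlap
  set.seed(14)
  seq_r <- make_label_sequence(sample(1:4, 300, replace = TRUE), fs = 100)
  segs_r <- segmentize(seq_r)
  expect_identical(segs_r$start[1], 1L)
  expect_identical(segs_r$end[nrow(segs_r)], 301L)
  expect_true(all(segs_r$start[-1] == segs_r$end[-nrow(segs_r)]))
  expect_identical(expand_segments(segs_r), seq_r$labels)
})
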