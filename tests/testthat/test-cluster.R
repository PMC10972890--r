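test_that("spatial correlation covers identity, polarity and orthogonality", {
  u <- c(1, -1, 0, 0); v <- c(0, 0, 1, -1)
  expect_equal(spatial_correlation(u, u), 1)
  expect_equal(spatial_correlation(u, -u), -1)
  expect_equal(spatial_correlation(u, v), 0)
  expect_error(spatial_correlation(u, rep(0, 4)), "zero-norm")
  expect_error(spatial_correlation(u, c(1, 2)), "lengths")
})

test_that("assignment is polarity-invariant and matches a brute-force argmax", {
  tpl <- make_templates(3, 12, seed = 11)$templates
  expect_identical(assign_maps(tpl[3, , drop = FALSE] * 4, tpl), 3L)
  expect_identical(assign_maps(-tpl[3, , drop = FALSE] * 4, tpl), 3L)
  set.seed(12)
  bank <- matrix(rnorm(10 * 12), 10, 12)
  bank <- bank - rowMeans(bank)
  got <- assign_maps(bank, tpl)
  oracle <- vapply(seq_len(10), function(n) {
    scores <- vapply(1:3, function(k)
      oracle_corr(bank[n, ], tpl[k, ])^2, 0)
    which.max(scores)
  }, 0L)
  expect_identical(got, oracle)
})

test_that("GEV is 1 for exact fits, 0 for orthogonal maps, and matches a loop", {
  tpl <- make_templates(2, 8, seed = 3, orthogonal = TRUE)$templates
  exact <- rbind(3 * tpl[1, ], -2 * tpl[2, ], 5 * tpl[1, ])
  expect_equal(gev(exact, tpl, c(1L, 2L, 1L))$gev_total, 1, tolerance = 1e-12)
  # a map orthogonal to its assigned template explains nothing
  expect_equal(gev(tpl[2, , drop = FALSE], tpl, 1L)$gev_total, 0,
               tolerance = 1e-12)

  set.seed(4)
  maps <- matrix(rnorm(20 * 8), 20, 8); maps <- maps - rowMeans(maps)
  labels <- assign_maps(maps, tpl)
  got <- gev(maps, tpl, labels)
  g <- apply(maps, 1, function(m) sqrt(mean((m - mean(m))^2)))
  denom <- sum(g^2)
  gev_n <- vapply(seq_len(20), function(n)
    oracle_corr(maps[n, ], tpl[labels[n], ])^2 * g[n]^2 / denom, 0)
  per_class <- c(sum(gev_n[labels == 1]), sum(gev_n[labels == 2]))
  expect_equal(got$gev_per_class, per_class, tolerance = 1e-12)
  expect_equal(got$gev_total, sum(per_class), tolerance = 1e-12)
})

test_that("template-set invariants hold after clustering", {
  tpl <- make_templates(3, 16, seed = 21)$templates
  bank <- planted_bank(tpl, per_class = 12, noise = 0.3, seed = 22)
  fit <- modified_kmeans(bank, 3, cluster_config(seed = 23, restarts = 5))
  expect_lt(max(abs(rowMeans(fit$templates))), 1e-10)
  expect_equal(sqrt(rowSums(fit$templates^2)), rep(1, 3), tolerance = 1e-9)
  expect_equal(sum(fit$gev_per_class), fit$gev_total, tolerance = 1e-9)
  expect_gte(fit$gev_total, 0)
  expect_lte(fit$gev_total, 1)
})

test_that("modified K-means recovers planted orthogonal templates exactly", {
  tpl <- make_templates(2, 10, seed = 31, orthogonal = TRUE)$templates
  bank <- tpl[rep(1:2, each = 10), ] * 4      # exact copies, no noise
  fit <- modified_kmeans(bank, 2, cluster_config(seed = 32))
  m <- match_templates(tpl, fit)
  expect_true(all(m$abs_corr > 0.999))
  expect_gt(fit$gev_total, 0.999)
  expect_error(modified_kmeans(bank[1:3, ], 4), "exceeds")
})

test_that("flipping the polarity of any bank subset leaves the fit unchanged", {
  tpl <- make_templates(3, 12, seed = 41)$templates
  bank <- planted_bank(tpl, per_class = 8, noise = 0.2, seed = 42)$maps
  set.seed(43)
  flip <- sample(c(-1, 1), nrow(bank), replace = TRUE)
  cfg <- cluster_config(seed = 44, restarts = 5)
  f1 <- modified_kmeans(bank, 3, cfg)
  f2 <- modified_kmeans(bank * flip, 3, cfg)
  expect_equal(f2$gev_total, f1$gev_total, tolerance = 1e-12)
  expect_identical(f2$labels_of_bank, f1$labels_of_bank)
})

test_that("on a tiny bank the clustering attains the exhaustive-optimum GEV", {
  # 6 maps, K = 2: enumerate all 2^6 labelings x all polarity patterns,
  # score each with sign-aligned-mean centers, and take the best GEV
  tpl <- make_templates(2, 6, seed = 51, orthogonal = TRUE)$templates
  set.seed(52)
  maps <- tpl[c(1, 1, 1, 2, 2, 2), ] * c(2, -3, 2.5, 3, -2, 2) +
    0.2 * matrix(rnorm(36), 6, 6)
  maps <- maps - rowMeans(maps)
  best <- 0
  for (mask in 0:(2^6 - 1)) {
    lab <- bitwAnd(mask, 2^(0:5)) > 0
    lab <- as.integer(lab) + 1L
    if (length(unique(lab)) < 2L) next
    centers <- matrix(0, 2, 6)
    ok <- TRUE
    for (k in 1:2) {
      members <- maps[lab == k, , drop = FALSE]
      # best sign pattern for the mean: maximize the norm of the signed sum
      m <- nrow(members)
      best_center <- NULL; best_norm <- -1
      for (smask in 0:(2^m - 1)) {
        s <- ifelse(bitwAnd(smask, 2^(0:(m - 1))) > 0, 1, -1)
        cen <- colSums(members * s) / m
        cen <- cen - mean(cen)
        nn <- sqrt(sum(cen^2))
        if (nn > best_norm) { best_norm <- nn; best_center <- cen / nn }
      }
      if (best_norm <= 0) ok <- FALSE else centers[k, ] <- best_center
    }
    if (!ok) next
    best <- max(best, gev(maps, centers, lab)$gev_total)
  }
  fit <- modified_kmeans(maps, 2, cluster_config(seed = 53, restarts = 30))
  expect_gte(fit$gev_total, best - 1e-9)
})

test_that("GEV is non-decreasing in K on a fixed bank", {
  tpl <- make_templates(4, 16, seed = 61)$templates
  bank <- planted_bank(tpl, per_class = 15, noise = 0.5, seed = 62)
  cfg <- cluster_config(seed = 63, restarts = 10)
  gevs <- vapply(2:6, function(k) modified_kmeans(bank, k, cfg)$gev_total, 0)
  expect_true(all(diff(gevs) >= -1e-6))
})

test_that("degenerate GEV series yield the analytic differences and no peak", {
  K <- 3:15; const <- 0.6
  scan <- klgev_criterion(data.frame(K = K, gev = const), C = 30)
  defined <- !is.na(scan$table$diff)
  expected <- const * (K^(2 / 30) - (K - 2)^(2 / 30))
  expect_equal(scan$table$diff[defined], expected[defined], tolerance = 1e-12)
  # strictly decreasing KL: no interior peak -> explicit failure
  expect_error(select_k_optimal(scan), "no interior local peak")
  expect_error(klgev_criterion(data.frame(K = c(2, 3, 5, 6, 7, 8), gev = 0.5),
                               C = 10), "contiguous")
})

test_that("scan over K is deterministic and polarity-gauge-free", {
  tpl <- make_templates(4, 16, seed = 71)$templates
  bank <- planted_bank(tpl, per_class = 20, noise = 0.4, seed = 72)
  cfg <- cluster_config(seed = 73, restarts = 5)
  r1 <- scan_and_select(bank, 2, 8, cfg)
  r2 <- scan_and_select(bank, 2, 8, cfg)
  expect_identical(r1$scan$table, r2$scan$table)
  expect_identical(r1$scan$k_optimal, r2$scan$k_optimal)
  # flipping a fitted template's sign is a gauge change: assignments and
  # GEV are untouched
  tset <- r1$templates
  flipped <- tset$templates * c(-1, rep(1, tset$K - 1))
  expect_identical(assign_maps(bank, flipped), assign_maps(bank, tset$templates))
  expect_equal(gev(bank, flipped)$gev_total, gev(bank, tset$templates)$gev_total,
               tolerance = 1e-12)
})
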