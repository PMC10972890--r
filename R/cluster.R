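#' Spatial correlation between two topographies
#'
#' Uncentered cosine similarity `sum(u*v) / (||u|| * ||v||)`. On
#' average-referenced maps (zero channel mean) this equals the Pearson
#' correlation across electrodes, the conventional topographic similarity
#' measure.
#'
#' @param u,v numeric vectors of equal length with non-zero norm.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' spatial_correlation(c(1, -1, 0, 0), c(0, 0, 1, -1))  # orthogonal: 0
#' @export
spatial_correlation <- function(u, v) {
  if (length(u) != length(v))
    abort_validation("maps have different lengths (%d vs %d)", length(u), length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort_validation("zero-norm map in spatial_correlation")
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

# M x K matrix of spatial correlations between bank rows and template rows.
# Templates are unit-norm; rows with zero norm get correlation 0.
correlation_matrix <- function(maps, templates) {
  norms <- sqrt(rowSums(maps^2))
  proj <- maps %*% t(templates)
  sweep(proj, 1L, pmax(norms, .Machine$double.xmin), "/")
}

#' Polarity-invariant template assignment
#'
#' Assigns each topography to the template minimizing the orthogonal squared
#' Euclidean distance `d2[k,n] = x'x - (x'a_k)^2` (templates unit-norm),
#' which is equivalent to maximizing the squared spatial correlation -- so a
#' map and its polarity flip receive the same label. Ties break to the
#' smallest template index.
#'
#' @param bank a `topography_bank` from [extract_peak_maps()], or a plain
#'   M x C matrix of maps.
#' @param templates K x C matrix with unit-norm, zero-mean rows.
#' @return Integer label vector of length M with values in `1..K`.
#' @export
assign_maps <- function(bank, templates) {
  maps <- if (inherits(bank, "topography_bank")) bank$maps else bank
  if (ncol(maps) != ncol(templates))
    abort_validation("maps have %d channels, templates %d", ncol(maps),
                     ncol(templates))
  proj2 <- (maps %*% t(templates))^2
  max.col(proj2, ties.method = "first")
}

#' Global explained variance of a labeled topography set
#'
#' The per-sample explained variance is
#' `GEV[n] = Corr(x_n, a_{l_n})^2 * GFP[n]^2 / sum(GFP^2)`; class totals sum
#' it over members and the overall GEV is the sum over classes. GEV is the
#' GFP-weighted fraction of topographic variance captured by the templates;
#' it lies in `[0, 1]` and is the quantity the model-order criterion
#' operates on.
#'
#' @param bank a `topography_bank` or M x C matrix (rows zero-mean).
#' @param templates K x C unit-norm template matrix.
#' @param labels integer labels in `1..K` (length M); defaults to
#'   [assign_maps()].
#' @return List with `gev_total` and `gev_per_class` (length K).
#' @export
gev <- function(bank, templates, labels = NULL) {
  maps <- if (inherits(bank, "topography_bank")) bank$maps else bank
  g <- if (inherits(bank, "topography_bank")) bank$gfp else gfp_of_maps(maps)
  K <- nrow(templates)
  if (is.null(labels)) labels <- assign_maps(maps, templates)
  stopifnot(length(labels) == nrow(maps), all(labels >= 1L), all(labels <= K))
  denom <- sum(g^2)
  if (denom == 0) abort_validation("all maps have zero GFP")
  corr <- correlation_matrix(maps, templates)
  cw <- corr[cbind(seq_len(nrow(maps)), labels)]
  gev_n <- cw^2 * g^2 / denom
  per_class <- vapply(seq_len(K), function(k) sum(gev_n[labels == k]), 0)
  list(gev_total = sum(per_class), gev_per_class = per_class)
}

#' Clustering configuration for the modified K-means
#'
#' @param max_iter maximum alternations of reassignment and center
#'   recalculation per restart (default 100; iteration also stops as soon as
#'   the labels no longer change).
#' @param restarts number of seeded random initializations; the restart with
#'   the highest total GEV is kept (default 20).
#' @param seed integer seed from which every restart's initialization is
#'   derived.
#' @param tol unused slack reserved for center-movement stopping; label
#'   stability is the active criterion.
#' @param align_mode `"sign_aligned_mean"` (default): before averaging, each
#'   member map is multiplied by the sign of its projection on the current
#'   center, so opposite-polarity members reinforce rather than cancel;
#'   `"literal_mean"` averages members as-is.
#' @return A `cluster_config` list.
#' @export
cluster_config <- function(max_iter = 100L, restarts = 20L, seed = 1L,
                           tol = 0,
                           align_mode = c("sign_aligned_mean", "literal_mean")) {
  stopifnot(max_iter >= 1L, restarts >= 1L, tol >= 0)
  structure(list(max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts), seed = as.integer(seed),
                 tol = tol, align_mode = match.arg(align_mode)),
            class = "cluster_config")
}

#' Polarity-invariant modified K-means over a topography bank
#'
#' Alternates polarity-invariant assignment ([assign_maps()]) with center
#' recalculation until the labels stop changing or `max_iter` is reached.
#' Centers are the (by default sign-aligned) mean of their members,
#' re-centered to zero mean and re-normalized to unit norm. The best of
#' `cfg$restarts` seeded random initializations (centers drawn from the bank
#' rows) by total GEV is returned. An emptied cluster is re-seeded from the
#' currently worst-fitted map.
#'
#' @param bank a `topography_bank` or M x C matrix of zero-mean maps.
#' @param K number of clusters, `2 <= K <= M` (K = 1 is served by the
#'   principal-topography special case used in [scan_and_select()]).
#' @param cfg a [cluster_config()].
#' @return A `template_set`: list with `templates` (K x C, zero-mean
#'   unit-norm rows), `K`, `labels_of_bank`, `gev_total`, `gev_per_class`.
#' @examples
#' tpl <- make_templates(2, 8, seed = 1)$templates
#' bank <- tpl[rep(1:2, each = 10), ] * 5
#' fit <- modified_kmeans(bank, 2, cluster_config(seed = 2))
#' fit$gev_total  # ~1: exactly separable
#' @export
modified_kmeans <- function(bank, K, cfg = cluster_config()) {
  maps <- if (inherits(bank, "topography_bank")) bank$maps else bank
  g <- if (inherits(bank, "topography_bank")) bank$gfp else gfp_of_maps(maps)
  M <- nrow(maps)
  if (K > M) abort_validation("K = %d exceeds the number of maps (%d)", K, M)
  if (K < 2L) abort_validation("modified_kmeans needs K >= 2")
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    init <- with_seed(cfg$seed * 1000L + r, sample.int(M, K))
    fit <- kmeans_once(maps, K, init, cfg)
    sc <- gev(bank, fit$templates, fit$labels)
    if (is.null(best) || sc$gev_total > best$gev_total + 1e-15)
      best <- list(templates = fit$templates, K = K, labels_of_bank = fit$labels,
                   gev_total = sc$gev_total, gev_per_class = sc$gev_per_class)
  }
  structure(best, class = "template_set")
}

normalize_rows <- function(x) {
  x <- x - rowMeans(x)
  n <- sqrt(rowSums(x^2))
  n[n == 0] <- 1
  x / n
}

kmeans_once <- function(maps, K, init, cfg) {
  templates <- normalize_rows(maps[init, , drop = FALSE])
  labels <- rep.int(0L, nrow(maps))
  for (it in seq_len(cfg$max_iter)) {
    proj <- maps %*% t(templates)
    new_labels <- max.col(proj^2, ties.method = "first")
    # re-seed empty clusters from the worst-fitted map
    fit2 <- proj[cbind(seq_len(nrow(maps)), new_labels)]^2 / rowSums(maps^2)
    for (k in which(tabulate(new_labels, K) == 0L)) {
      worst <- which.min(fit2)
      templates[k, ] <- normalize_rows(maps[worst, , drop = FALSE])
      new_labels[worst] <- k
      fit2[worst] <- 1
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    for (k in seq_len(K)) {
      members <- which(labels == k)
      mk <- maps[members, , drop = FALSE]
      if (cfg$align_mode == "sign_aligned_mean") {
        s <- sign(proj[members, k])
        s[s == 0] <- 1
        mk <- mk * s
      }
      templates[k, ] <- colMeans(mk)
    }
    templates <- normalize_rows(templates)
  }
  list(templates = templates, labels = labels)
}

# K = 1 analogue of the sign-aligned K-means: the dominant eigenvector of the
# map scatter matrix (the single template maximizing summed squared
# projections, polarity-invariant). Used to anchor the low end of the GEV
# scan.
principal_topography <- function(maps) {
  sc <- crossprod(maps)                    # C x C
  v <- eigen(sc, symmetric = TRUE)$vectors[, 1L]
  normalize_rows(matrix(v, nrow = 1L))
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("<template_set> K = %d over %d channels, GEV = %.4f\n",
              x$K, ncol(x$templates), x$gev_total))
  invisible(x)
}
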