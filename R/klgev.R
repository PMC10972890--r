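#' Model-order criterion on the GEV curve
#'
#' Turns a per-K GEV series into the derived series used to locate the
#' "elbow" of the GEV curve. With C channels, the normalized curve is
#' `K^(2/C) * GEV_K`; `DIFF_K` is its first-order discrete difference with
#' interval 2 (`DIFF_K = K^(2/C) GEV_K - (K-2)^(2/C) GEV_{K-2}`), which
#' smooths out single-step jitter; and the criterion value is the ratio
#' `KL_K = DIFF_K / DIFF_{K+2}`. Before the optimal K both differences are
#' large; after it both are small; exactly at it the numerator is large and
#' the denominator small, so the criterion peaks.
#'
#' `DIFF_K` is defined only where `K - 2` is in the grid, and `KL_K` only
#' where both `DIFF_K` and `DIFF_{K+2}` are defined. A zero `DIFF_{K+2}`
#' leaves that KL entry undefined (with a warning).
#'
#' @param gev_by_k named numeric vector or data.frame with columns `K` and
#'   `gev`: the total GEV at each K of a contiguous integer grid (step 1,
#'   span >= 5).
#' @param C electrode count used in the normalization exponent `2/C`.
#' @return A `model_order_scan`: list with `table` (data.frame: `K`, `gev`,
#'   `norm_gev`, `diff`, `kl`), `C`, and `k_optimal` (filled by
#'   [select_k_optimal()]; `NA` until then).
#' @examples
#' g <- c(0.40, 0.52, 0.60, 0.64, 0.655, 0.665, 0.672, 0.678)
#' scan <- klgev_criterion(data.frame(K = 2:9, gev = g), C = 32)
#' select_k_optimal(scan)
#' @export
klgev_criterion <- function(gev_by_k, C) {
  if (is.data.frame(gev_by_k)) {
    K <- as.integer(gev_by_k$K); g <- as.numeric(gev_by_k$gev)
  } else {
    K <- as.integer(names(gev_by_k)); g <- as.numeric(gev_by_k)
  }
  if (anyNA(K)) abort_validation("gev_by_k needs integer K identifiers")
  ord <- order(K); K <- K[ord]; g <- g[ord]
  if (any(diff(K) != 1L))
    abort_validation("the K grid must be contiguous with step 1")
  if (length(K) < 6L)
    abort_validation("the K grid must span at least 5 (got %d..%d)",
                     min(K), max(K))
  stopifnot(C >= 2L)
  norm_gev <- K^(2 / C) * g
  n <- length(K)
  dif <- rep(NA_real_, n)
  idx2 <- match(K - 2L, K)
  has2 <- !is.na(idx2)
  dif[has2] <- norm_gev[has2] - norm_gev[idx2[has2]]
  kl <- rep(NA_real_, n)
  idxp2 <- match(K + 2L, K)
  for (i in which(!is.na(dif) & !is.na(idxp2))) {
    d2 <- dif[idxp2[i]]
    if (is.na(d2)) next
    if (d2 == 0) {
      warning(sprintf("DIFF at K = %d is zero; KL at K = %d left undefined",
                      K[i] + 2L, K[i]))
      next
    }
    kl[i] <- dif[i] / d2
  }
  structure(list(table = data.frame(K = K, gev = g, norm_gev = norm_gev,
                                    diff = dif, kl = kl),
                 C = as.integer(C), k_optimal = NA_integer_),
            class = "model_order_scan")
}

#' Select the optimal number of microstates from a criterion scan
#'
#' Among interior points of the defined KL series (both K-1 and K+1 have
#' defined KL values) that are strict local maxima, returns the K with the
#' largest KL value (ties break to the smallest K). Endpoints of the defined
#' series are never eligible: a series that starts or ends at its maximum
#' carries no evidence of an elbow. If no interior local peak exists, an
#' error asks for a wider K grid.
#'
#' @param scan a `model_order_scan` from [klgev_criterion()].
#' @return The selected integer K.
#' @export
select_k_optimal <- function(scan) {
  stopifnot(inherits(scan, "model_order_scan"))
  tab <- scan$table[!is.na(scan$table$kl), ]
  if (nrow(tab) < 3L)
    abort_validation("need at least 3 defined KL entries, have %d", nrow(tab))
  kl <- tab$kl; K <- tab$K
  interior <- which(seq_along(K) > 1L & seq_along(K) < length(K))
  peaks <- interior[kl[interior] > kl[interior - 1L] &
                    kl[interior] > kl[interior + 1L]]
  if (!length(peaks))
    stop("no interior local peak in the KL series; widen the K grid",
         call. = FALSE)
  K[peaks[which.max(kl[peaks])]]
}

#' @export
print.model_order_scan <- function(x, ...) {
  cat(sprintf("<model_order_scan> K = %d..%d (C = %d)\n",
              min(x$table$K), max(x$table$K), x$C))
  print(format(x$table, digits = 4), row.names = FALSE)
  if (!is.na(x$k_optimal)) cat("k_optimal:", x$k_optimal, "\n")
  invisible(x)
}

#' Cluster over a grid of K and select the optimal microstate count
#'
#' Runs [modified_kmeans()] for every K in `k_min..k_max`, applies
#' [klgev_criterion()] and [select_k_optimal()], and returns both the scan
#' and the already-fitted template set at the selected K (no refit). When
#' `k_min <= 2` the GEV series is additionally anchored at K = 1 (the
#' principal topography, the K = 1 analogue of sign-aligned K-means), which
#' extends the interval-2 difference series one step lower so that small K
#' values sit in the interior of the KL series and remain selectable.
#'
#' Because the criterion needs `K - 2`, `K + 2` and both KL neighbors, the
#' selectable range is `k_min + 2 .. k_max - 3` (with the K = 1 anchor when
#' `k_min = 2`); choose the scan bounds so the plausible optimum lies well
#' inside it.
#'
#' @param bank a `topography_bank` or M x C matrix.
#' @param k_min,k_max inclusive scan bounds, `k_min >= 2`,
#'   `k_max - k_min >= 4`.
#' @param cfg a [cluster_config()]; the same seed drives every K.
#' @return List with `scan` (a `model_order_scan` with `k_optimal` set) and
#'   `templates` (the `template_set` at the optimum).
#' @export
scan_and_select <- function(bank, k_min = 2L, k_max = 12L,
                            cfg = cluster_config()) {
  if (k_min < 2L) abort_validation("k_min must be >= 2")
  if (k_max - k_min < 4L) abort_validation("the scan must span at least 5 K values")
  maps <- if (inherits(bank, "topography_bank")) bank$maps else bank
  kgrid <- k_min:k_max
  fits <- vector("list", length(kgrid))
  gevs <- numeric(length(kgrid))
  for (i in seq_along(kgrid)) {
    fits[[i]] <- modified_kmeans(bank, kgrid[i], cfg)
    gevs[i] <- fits[[i]]$gev_total
  }
  K <- kgrid; g <- gevs
  if (k_min <= 2L) {
    tpl1 <- principal_topography(maps)
    g1 <- gev(bank, tpl1, rep.int(1L, nrow(maps)))$gev_total
    K <- c(1L, K); g <- c(g1, g)
  }
  scan <- klgev_criterion(data.frame(K = K, gev = g), C = ncol(maps))
  scan$k_optimal <- select_k_optimal(scan)
  list(scan = scan, templates = fits[[match(scan$k_optimal, kgrid)]])
}

#' Write / read a model-order scan as a delimited table
#'
#' Columns `K`, `GEV`, `normGEV`, `DIFF`, `KL_GEV` mirror the conventional
#' presentation of the criterion.
#'
#' @param scan a `model_order_scan`.
#' @param path destination TSV file.
#' @return `path` invisibly (`write_scan_table`); for `read_gev_table`, a
#'   data.frame with columns `K` and `gev` suitable for
#'   [klgev_criterion()].
#' @export
write_scan_table <- function(scan, path) {
  tab <- scan$table
  out <- data.frame(K = tab$K, GEV = tab$gev, normGEV = tab$norm_gev,
                    DIFF = tab$diff, KL_GEV = tab$kl)
  utils::write.table(format(out, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  invisible(path)
}

#' @rdname write_scan_table
#' @param k_col,gev_col column names holding K and GEV in the file at `path`.
#' @export
read_gev_table <- function(path, k_col = "K", gev_col = "GEV") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c(k_col, gev_col) %in% names(tab)))
    abort_validation("'%s' lacks columns %s / %s", path, k_col, gev_col)
  data.frame(K = as.integer(tab[[k_col]]), gev = as.numeric(tab[[gev_col]]))
}
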