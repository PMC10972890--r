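#' Grouping configuration for emotion conditions
#'
#' Controls how continuous valence/arousal ratings (1-9 scale) are split
#' into high/low groups. `"fixed"` compares every rating to `fixed_value`;
#' `"per_subject_mean"` / `"per_subject_median"` derive a threshold from
#' each subject's own ratings, absorbing individual differences in how the
#' rating scale is used. Ratings exactly at the threshold go to the low
#' group. A subject whose ratings are all identical cannot define a
#' per-subject threshold; the fixed value is used for them with a warning.
#'
#' @param mode `"explicit_labels"` (labels given directly, e.g. positive /
#'   negative / neutral) or `"rating_threshold"`.
#' @param threshold_rule `"per_subject_mean"` (default), `"per_subject_median"`
#'   or `"fixed"`.
#' @param fixed_value threshold for `"fixed"` and the fallback (default 5).
#' @return A `grouping_config` list.
#' @export
grouping_config <- function(mode = c("rating_threshold", "explicit_labels"),
                            threshold_rule = c("per_subject_mean",
                                               "per_subject_median", "fixed"),
                            fixed_value = 5.0) {
  structure(list(mode = match.arg(mode),
                 threshold_rule = match.arg(threshold_rule),
                 fixed_value = fixed_value),
            class = "grouping_config")
}

#' Assign valence/arousal quadrant labels to trials
#'
#' Splits each trial into high/low arousal and high/low valence against the
#' configured threshold and returns the quadrant label: HAHV, HALV, LAHV or
#' LALV (e.g. HALV = high arousal, low valence).
#'
#' @param ratings data.frame with columns `subject`, `arousal`, `valence`
#'   (ratings in `[1, 9]`), one row per trial.
#' @param cfg a [grouping_config()] with `mode = "rating_threshold"`.
#' @return Character vector of quadrant labels, one per trial, plus
#'   attribute `thresholds` (per-subject data.frame).
#' @export
assign_groups <- function(ratings, cfg = grouping_config()) {
  stopifnot(is.data.frame(ratings),
            all(c("subject", "arousal", "valence") %in% names(ratings)))
  if (cfg$mode != "rating_threshold")
    abort_validation("assign_groups requires mode = 'rating_threshold'")
  vals <- c(ratings$arousal, ratings$valence)
  if (any(vals < 1 | vals > 9))
    abort_validation("ratings must lie in [1, 9]")
  thr_for <- function(x, subj) {
    if (cfg$threshold_rule == "fixed") return(cfg$fixed_value)
    if (length(unique(x)) == 1L) {
      warning(sprintf("subject %s has constant ratings; using fixed threshold %g",
                      subj, cfg$fixed_value))
      return(cfg$fixed_value)
    }
    if (cfg$threshold_rule == "per_subject_mean") mean(x) else stats::median(x)
  }
  subjects <- unique(ratings$subject)
  thr <- data.frame(subject = subjects,
                    arousal = NA_real_, valence = NA_real_)
  lab <- character(nrow(ratings))
  for (s in subjects) {
    sel <- ratings$subject == s
    ta <- thr_for(ratings$arousal[sel], s)
    tv <- thr_for(ratings$valence[sel], s)
    thr[thr$subject == s, c("arousal", "valence")] <- c(ta, tv)
    # at-threshold ratings fall in the low group
    a <- ifelse(ratings$arousal[sel] > ta, "HA", "LA")
    v <- ifelse(ratings$valence[sel] > tv, "HV", "LV")
    lab[sel] <- paste0(a, v)
  }
  structure(lab, thresholds = thr)
}

#' Rank-sum comparison of features between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test per feature column
#' between two groups, as used to screen microstate parameters for
#' condition differences. The exact null distribution is used for small
#' untied samples and the tie-corrected normal approximation otherwise
#' (the behavior of [stats::wilcox.test()]). No multiple-testing
#' correction is applied by default, matching the conventional raw-alpha
#' screen; set `adjust = "fdr"` (or any [stats::p.adjust()] method) to
#' correct.
#'
#' @param features data.frame or matrix of numeric feature columns.
#' @param groups vector of group labels, length `nrow(features)`, with
#'   exactly two distinct values among the rows compared.
#' @param alpha significance level for the flag column (default 0.05).
#' @param adjust p-adjustment method, default `"none"`.
#' @return A data.frame of class `stat_table`: one row per feature with
#'   group medians, the rank-sum statistic `W`, the two-sided `p`, and
#'   `significant = p < alpha`. Features with an empty group are skipped
#'   (with a message).
#' @export
ranksum_compare <- function(features, groups, alpha = 0.05, adjust = "none") {
  features <- as.data.frame(features)
  stopifnot(length(groups) == nrow(features))
  lev <- unique(groups[!is.na(groups)])
  if (length(lev) != 2L)
    abort_validation("ranksum_compare needs exactly 2 groups, got %d", length(lev))
  ga <- groups == lev[1L]; gb <- groups == lev[2L]
  rows <- list()
  for (nm in names(features)) {
    x <- features[[nm]][ga]; y <- features[[nm]][gb]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (!length(x) || !length(y)) {
      message(sprintf("feature '%s' skipped: empty group", nm))
      next
    }
    ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    rows[[nm]] <- data.frame(feature = nm,
                             median_a = stats::median(x),
                             median_b = stats::median(y),
                             W = unname(ht$statistic), p = ht$p.value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out$significant <- out$p_adj < alpha
  names(out)[names(out) == "median_a"] <- paste0("median_", lev[1L])
  names(out)[names(out) == "median_b"] <- paste0("median_", lev[2L])
  class(out) <- c("stat_table", "data.frame")
  out
}
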