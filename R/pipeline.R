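#' Pipeline configuration
#'
#' A nested list describing every stage of the full analysis, readable from
#' and writable to YAML. Unknown keys are rejected so a typo cannot
#' silently disable a stage.
#'
#' Sections and defaults:
#' * `preprocess`: `bandpass`, `notch`, `car`, `target_fs` (see
#'   [preprocess_config()]);
#' * `peaks`: `cap_per_recording`, `min_distance_samples`;
#' * `scan`: `k_min`, `k_max`, `restarts`, `max_iter`;
#' * `smoothing`: `mode`, `b`, `lam`, `min_duration_ms`;
#' * `features`: `window_s`, `include_spatial`, `band_power`;
#' * `seed`: one integer driving all randomness.
#'
#' @param ... named sections overriding the defaults (each a named list, or
#'   `seed = <int>`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    preprocess = list(bandpass = c(1, 45), notch = c(48, 52), car = TRUE,
                      target_fs = NULL),
    peaks = list(cap_per_recording = 1000L, min_distance_samples = 0L),
    scan = list(k_min = 2L, k_max = 12L, restarts = 20L, max_iter = 100L),
    smoothing = list(mode = "windowed", b = 3L, lam = 1,
                     min_duration_ms = 30),
    features = list(window_s = 15, include_spatial = TRUE, band_power = FALSE),
    seed = 1L
  )
  override <- list(...)
  if (length(override) == 1L && is.null(names(override)) &&
      is.list(override[[1L]]))
    override <- override[[1L]]
  bad <- setdiff(names(override), names(defaults))
  if (length(bad))
    abort_validation("unknown config section(s): %s", paste(bad, collapse = ", "))
  for (nm in names(override)) {
    if (nm == "seed") { defaults$seed <- as.integer(override$seed); next }
    sec <- override[[nm]]
    badk <- setdiff(names(sec), names(defaults[[nm]]))
    if (length(badk))
      abort_validation("unknown key(s) in [%s]: %s", nm,
                       paste(badk, collapse = ", "))
    defaults[[nm]][names(sec)] <- sec
  }
  if (defaults$scan$k_max - defaults$scan$k_min < 4L)
    abort_validation("scan range must span at least 5 K values")
  structure(defaults, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return `read_pipeline_config`: a `pipeline_config`;
#'   `write_pipeline_config`: `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full microstate pipeline
#'
#' Preprocess every input recording, pool GFP-peak topographies, scan the
#' cluster number and select the optimum, backfit and smooth every
#' recording, extract windowed feature tables, and write all artifacts plus
#' a manifest to `out_dir`. Identical config + seed + inputs produce
#' identical outputs.
#'
#' Artifacts written: `scan.tsv` (the model-order table), `templates.tsv`
#' (K x C template matrix with channel-name header), per-recording
#' `labels_<i>.tsv` (sample, label) and `features_<i>.tsv`, optional
#' `bandpower_<i>.tsv`, and `manifest.json` (config echo, config hash,
#' seed, selected K, artifact list).
#'
#' @param cfg a [pipeline_config()].
#' @param inputs list of [recording()] objects, or character paths readable
#'   by [load_recording()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly (a list).
#' @export
run_pipeline <- function(cfg, inputs, out_dir) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is_recording(inputs)) inputs <- list(inputs)
  if (!length(inputs)) abort_validation("no input recordings")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  recs <- lapply(seq_along(inputs), function(i) {
    x <- inputs[[i]]
    rec <- if (is.character(x)) load_recording(x) else x
    stage("preprocess", i, preprocess(rec, do.call(preprocess_config,
                                                   cfg$preprocess)))
  })
  bank <- stage("peaks", NA, do.call(extract_peak_maps,
                                     c(list(recs), cfg$peaks,
                                       list(seed = cfg$seed))))
  ccfg <- cluster_config(max_iter = cfg$scan$max_iter,
                         restarts = cfg$scan$restarts, seed = cfg$seed)
  sel <- stage("scan", NA, scan_and_select(bank, cfg$scan$k_min,
                                           cfg$scan$k_max, ccfg))
  write_scan_table(sel$scan, file.path(out_dir, "scan.tsv"))
  tpl_out <- as.data.frame(sel$templates$templates)
  names(tpl_out) <- recs[[1L]]$channel_names
  utils::write.table(format(tpl_out, digits = 10, trim = TRUE),
                     file.path(out_dir, "templates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  artifacts <- c("scan.tsv", "templates.tsv")

  sp <- smoothing_params(mode = cfg$smoothing$mode, b = cfg$smoothing$b,
                         lam = cfg$smoothing$lam,
                         min_duration_ms = cfg$smoothing$min_duration_ms)
  for (i in seq_along(recs)) {
    rec <- recs[[i]]
    seq <- stage("backfit", i, backfit(rec, sel$templates))
    seq <- switch(sp$mode,
                  windowed = smooth_window(seq, rec, sel$templates, sp),
                  min_duration = reject_short_segments(seq, sp$min_duration_ms,
                                                       rec, sel$templates),
                  none = seq)
    lab_file <- sprintf("labels_%d.tsv", i)
    utils::write.table(data.frame(sample = seq_along(seq$labels),
                                  label = seq$labels),
                       file.path(out_dir, lab_file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    feat <- stage("features", i,
                  windowed_feature_table(rec, sel$templates,
                                         window_s = cfg$features$window_s,
                                         params = sp,
                                         include_spatial =
                                           cfg$features$include_spatial))
    feat_file <- sprintf("features_%d.tsv", i)
    utils::write.table(format(feat, digits = 10, trim = TRUE),
                       file.path(out_dir, feat_file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, lab_file, feat_file)
    if (isTRUE(cfg$features$band_power)) {
      bp <- stage("bandpower", i,
                  band_power(rec, window_s = cfg$features$window_s))
      bp_file <- sprintf("bandpower_%d.tsv", i)
      utils::write.table(format(bp, digits = 10, trim = TRUE),
                         file.path(out_dir, bp_file), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      artifacts <- c(artifacts, bp_file)
    }
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  write_pipeline_config(cfg, cfg_file)
  manifest <- list(config = unclass(cfg),
                   config_hash = unname(tools::md5sum(cfg_file)),
                   seed = cfg$seed,
                   k_optimal = sel$scan$k_optimal,
                   gev_total = sel$templates$gev_total,
                   n_recordings = length(recs),
                   artifacts = c(artifacts, "config.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# wrap a stage so failures name the stage and input
stage <- function(name, input, value) {
  tryCatch(value, error = function(e) {
    where <- if (is.na(input)) name else sprintf("%s (input %s)", name, input)
    stop(sprintf("pipeline stage '%s' failed: %s", where, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Criterion-only mode: derive the model-order table from a GEV table
#'
#' Computes the normalized-GEV, interval-2 difference and KL columns and the
#' selected K from a per-K GEV table alone, without touching any EEG. This
#' is the `klgev` entry point of the command-line tool.
#'
#' @param gev_table data.frame with columns `K` and `gev` (or `GEV`), or a
#'   path to a TSV readable by [read_gev_table()].
#' @param C electrode count for the `K^(2/C)` normalization.
#' @return A `model_order_scan` with `k_optimal` set (or `NA` with a
#'   warning if the series has no interior peak).
#' @export
klgev_table <- function(gev_table, C) {
  if (is.character(gev_table)) gev_table <- read_gev_table(gev_table)
  if (!"gev" %in% names(gev_table) && "GEV" %in% names(gev_table))
    names(gev_table)[names(gev_table) == "GEV"] <- "gev"
  scan <- klgev_criterion(gev_table[, c("K", "gev")], C = C)
  scan$k_optimal <- tryCatch(select_k_optimal(scan), error = function(e) {
    warning(conditionMessage(e))
    NA_integer_
  })
  scan
}
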