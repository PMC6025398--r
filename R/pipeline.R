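## One-shot study pipeline and the stage-command dispatcher.
##
## run_study(): simulate (or ingest) -> [detect] -> filter -> segment ->
## HRV features -> CRTT scoring -> group statistics -> results bundle.
## Every constant of the analysis (filter thresholds, pNNx threshold, band
## edges, block length, detector parameters) lives in the config and is
## validated against the stage contracts before any stage runs.

#' Default pipeline configuration
#'
#' @return Nested named list: `detector` ([qrs_params()]), `filter`
#'   ([rr_filter_params()]), `hrv` (`pnnx_threshold` 20 ms, `bands`
#'   [hrv_bands()], `method` "lomb"), `block_len` 300 s, `stats`
#'   (`posthoc` "paired_t", exact-test size caps), `cohort`
#'   ([default_cohort_spec()]), `seed`.
#' @export
default_config <- function() {
  list(detector = qrs_params(),
       filter = rr_filter_params(),
       hrv = list(pnnx_threshold = 20, bands = hrv_bands(), method = "lomb"),
       block_len = 300,
       stats = list(posthoc = "paired_t", friedman_exact_n_max = 8L,
                    wilcoxon_exact_n_max = 25L, spearman_exact_n_max = 8L),
       cohort = default_cohort_spec(),
       seed = 1L)
}

validate_config <- function(config) {
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)
  if (cfg$block_len <= 0) stop_config("block_len must be positive")
  if (cfg$hrv$pnnx_threshold <= 0) stop_config("pnnx_threshold must be positive")
  with(cfg$filter, if (abs_low <= 0 || abs_high <= abs_low)
    stop_config("invalid filter thresholds"))
  if (!cfg$hrv$method %in% c("lomb", "welch"))
    stop_config("hrv method must be 'lomb' or 'welch'")
  cfg
}

#' Analyse one subject's recording
#'
#' RR-level entry point: filter -> segment -> per-block features.
#'
#' @param rr An [rr_series()] with beat times (from [beats_to_rr()] after
#'   [detect_r_peaks()], or read directly).
#' @param events [event_annotations()].
#' @param config Pipeline configuration.
#' @param subject Subject id used in the output.
#' @return data.frame of per-block features (`subject`, `condition`,
#'   `block`, feature columns).
#' @export
analyze_subject <- function(rr, events, config = default_config(),
                            subject = "S01") {
  cfg <- validate_config(config)
  filt <- filter_rr(rr, cfg$filter)
  blocks <- segment_blocks(filt, events, block_len = cfg$block_len)
  rows <- list()
  for (cond in names(blocks)) {
    for (j in seq_along(blocks[[cond]])) {
      b <- blocks[[cond]][[j]]
      if (length(b$intervals) < 2L) next
      f <- extract_block_features(b$intervals, b$beat_times,
                                  x = cfg$hrv$pnnx_threshold,
                                  bands = cfg$hrv$bands,
                                  method = cfg$hrv$method,
                                  block_id = sprintf("%s/%s/%d", subject, cond, j))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(subject = subject, condition = cond, block = j),
              as.data.frame(f))
    }
  }
  do.call(rbind, rows)
}

#' Run the full study pipeline
#'
#' With no `input_dir`, simulates a cohort from `config$cohort` under
#' `config$seed`; otherwise ingests the per-subject CSV files that
#' [write_cohort()] emits. Produces the study frame, the omnibus and
#' post-hoc statistics for every HRV measure plus VAS, the pre/post
#' cognitive comparisons, and a manifest that suffices to reproduce the
#' bundle (config hash + seed + package version). Identical config and
#' inputs yield an identical bundle.
#'
#' @param config Pipeline configuration ([default_config()]).
#' @param input_dir Optional directory of recordings (layout of
#'   [write_cohort()]).
#' @param out_dir Optional output directory; when given, writes
#'   `study_frame.csv`, `block_features.csv`, `stats.json`, `manifest.json`.
#' @return list of class `study_results`: `study_frame`, `block_features`,
#'   `stats`, `manifest`.
#' @export
run_study <- function(config = default_config(), input_dir = NULL,
                      out_dir = NULL) {
  cfg <- validate_config(config)
  if (is.null(input_dir)) {
    cohort <- generate_cohort(cfg$cohort, seed = cfg$seed)
    subjects <- cohort$subjects
  } else {
    subjects <- read_cohort_dir(input_dir)
  }

  feats <- list(); scores <- list(); crtt_rows <- list()
  for (subj in subjects) {
    feats[[subj$subject]] <- analyze_subject(subj$rr, subj$events, cfg,
                                             subject = subj$subject)
    if (!is.null(subj$scores)) scores[[subj$subject]] <- subj$scores
    if (!is.null(subj$crtt)) {
      for (cond in names(subj$crtt)) {
        sm <- score_crtt(subj$crtt[[cond]])
        crtt_rows[[paste(subj$subject, cond)]] <-
          data.frame(subject = subj$subject, condition = cond,
                     median_rt_ms = sm$median_rt_ms, accuracy = sm$accuracy)
      }
    }
  }
  block_features <- do.call(rbind, feats)
  rownames(block_features) <- NULL
  score_df <- if (length(scores)) do.call(rbind, scores) else NULL
  if (!is.null(score_df)) rownames(score_df) <- NULL
  crtt_df <- if (length(crtt_rows)) do.call(rbind, crtt_rows) else NULL
  if (!is.null(crtt_df)) rownames(crtt_df) <- NULL
  frame <- build_study_frame(block_features, scores = score_df,
                             crtt_summaries = crtt_df)

  measures <- intersect(c("avnn", "sdnn", "rmssd", "pnnx", "lf_hf", "vas"),
                        names(frame))
  stats_out <- list()
  for (m in measures) {
    mm <- measure_matrix(frame, m)
    fr <- friedman_test(mm, exact_n_max = cfg$stats$friedman_exact_n_max)
    ph <- posthoc_pairwise(mm, method = cfg$stats$posthoc)
    stats_out[[m]] <- list(friedman = unclass(fr), posthoc = ph)
  }
  if (!is.null(crtt_df)) {
    rt <- measure_matrix(frame, "median_rt_ms", complete_only = FALSE)
    rt <- rt[, c("CRTT1", "CRTT2"), drop = FALSE]
    rt <- rt[stats::complete.cases(rt), , drop = FALSE]
    acc <- measure_matrix(frame, "accuracy", complete_only = FALSE)
    acc <- acc[rownames(rt), c("CRTT1", "CRTT2"), drop = FALSE]
    rt_z <- matrix(zscore(as.vector(rt)), ncol = 2, dimnames = dimnames(rt))
    stats_out$cognitive <- list(
      zscore_reference = "pooled CRTT1+CRTT2",
      rt_wilcoxon = unclass(wilcoxon_signed_rank(
        rt_z[, 1], rt_z[, 2], exact_n_max = cfg$stats$wilcoxon_exact_n_max)),
      accuracy_wilcoxon = unclass(wilcoxon_signed_rank(
        acc[, 1], acc[, 2], exact_n_max = cfg$stats$wilcoxon_exact_n_max)),
      rt_spearman = unclass(spearman_test(
        rt[, 1], rt[, 2], exact_n_max = cfg$stats$spearman_exact_n_max)),
      rt_median_z = apply(rt_z, 2, stats::median),
      accuracy_median = apply(acc, 2, stats::median))
  }

  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  manifest <- list(package = "stresshrv",
                   version = as.character(utils::packageVersion("stresshrv")),
                   seed = cfg$seed,
                   config_hash = fnv1a(as.character(cfg_json)),
                   n_subjects = length(subjects),
                   input = if (is.null(input_dir)) "simulated" else input_dir)

  res <- structure(list(study_frame = frame, block_features = block_features,
                        stats = stats_out, manifest = manifest,
                        config = cfg),
                   class = "study_results")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(frame, file.path(out_dir, "study_frame.csv"),
                     row.names = FALSE)
    utils::write.csv(block_features, file.path(out_dir, "block_features.csv"),
                     row.names = FALSE)
    jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  res
}

## Ingest a directory in the write_cohort() layout.
read_cohort_dir <- function(dir) {
  rr_files <- sort(list.files(dir, "_rr\\.csv$", full.names = TRUE))
  if (!length(rr_files)) stop_format(paste("no *_rr.csv recordings in", dir))
  lapply(rr_files, function(f) {
    id <- sub("_rr\\.csv$", "", basename(f))
    pre <- file.path(dir, id)
    crtt <- list()
    for (cond in c("CRTT1", "CRTT2")) {
      p <- paste0(pre, "_", tolower(cond), ".csv")
      if (file.exists(p)) crtt[[cond]] <- read_crtt_log(p)
    }
    sc <- paste0(pre, "_scores.csv")
    list(subject = id,
         rr = read_rr(f),
         events = read_events(paste0(pre, "_events.csv")),
         crtt = if (length(crtt)) crtt else NULL,
         scores = if (file.exists(sc))
           utils::read.csv(sc, stringsAsFactors = FALSE) else NULL)
  })
}

#' @export
print.study_results <- function(x, ...) {
  cat(sprintf("<study_results> %d subjects, %d frame rows, measures: %s\n",
              x$manifest$n_subjects, nrow(x$study_frame),
              paste(setdiff(names(x$stats), "cognitive"), collapse = ", ")))
  invisible(x)
}
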