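#' Read a recording from a delimited-text file
#'
#' Expects a header row with a time column `t_s` (seconds from recording
#' start, strictly increasing) plus one column per channel, named by channel
#' kind (MABP, HbO2, HHb, HbD, HbT, oxCCO, BFI, HR, SpO2, Temp). Non-numeric
#' cells (e.g. "NA") become masked samples; column lengths are preserved.
#' Unknown channel names are rejected rather than silently carried, because
#' downstream pair selection is by name.
#'
#' @param path CSV/TSV file path (delimiter auto-detected from extension;
#'   `.tsv` means tab).
#' @param subject_id Subject identifier.
#' @param group `"control"`, `"moderate"` or `"severe"`.
#' @param insult_onset_s Insult onset, seconds from recording start.
#' @param baseline_window_s Optional `(start, end)` baseline window.
#' @return An [sw_recording()].
#' @examples
#' f <- system.file("extdata", "example_recording.csv", package = "slowwave")
#' rec <- read_recording(f, subject_id = "EX1", group = "control")
#' rec
#' @export
read_recording <- function(path, subject_id, group = "control",
                           insult_onset_s = NA_real_,
                           baseline_window_s = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        colClasses = "character", strip.white = TRUE)
  if (!"t_s" %in% names(df))
    sw_data_error(sprintf("'%s': no time column 't_s' in header", path))
  times <- suppressWarnings(as.numeric(df[["t_s"]]))
  if (anyNA(times))
    sw_data_error(sprintf("'%s': non-numeric timestamps", path))
  if (length(times) >= 2L && any(diff(times) <= 0))
    sw_data_error(sprintf("'%s': timestamps not strictly increasing", path))
  cols <- setdiff(names(df), "t_s")
  if (!length(cols)) sw_data_error(sprintf("'%s': no channel columns", path))
  bad <- setdiff(cols, names(CHANNEL_KINDS))
  if (length(bad))
    sw_data_error(sprintf("'%s': unknown channel kind(s): %s", path,
                          paste(bad, collapse = ", ")))
  channels <- lapply(cols, function(nm) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    sw_channel(nm, times, v)
  })
  sw_recording(subject_id, group, channels,
               insult_onset_s = insult_onset_s,
               baseline_window_s = baseline_window_s)
}

#' Write a recording to CSV
#'
#' Inverse of [read_recording()]. Synchronized recordings write one row per
#' shared time point; mixed-rate recordings are written on the union of the
#' channel time grids, with `NA` marking time points a channel does not
#' sample (these read back as masked samples). Values round-trip through
#' the text format to better than 1e-9 relative error.
#'
#' @param rec An [sw_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "sw_recording"))
  times <- rec$channels[[1L]]$times
  shared <- all(vapply(rec$channels, function(ch)
    length(ch$times) == length(times) &&
      max(abs(ch$times - times)) <= 1e-9, TRUE))
  if (!shared)
    times <- sort(unique(unlist(lapply(rec$channels, `[[`, "times"))))
  df <- data.frame(t_s = format(times, digits = 15, trim = TRUE),
                   check.names = FALSE)
  for (ch in rec$channels) {
    col <- rep("NA", length(times))
    at <- if (shared) seq_along(times) else match(round(ch$times, 9),
                                                  round(times, 9))
    col[at] <- ifelse(ch$mask, format(ch$values, digits = 15, trim = TRUE),
                      "NA")
    df[[ch$name]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-subject outcome table
#'
#' Expects columns `subject_id, group, bgt_lac_naa, wm_lac_naa, tunel_log10,
#' aeeg_score`. Lac/NAA ratios must be non-negative; the aEEG background
#' score is an integer 0--4.
#'
#' @param path CSV path.
#' @return A validated `data.frame` of outcomes.
#' @export
read_outcomes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_outcomes(df)
}

validate_outcomes <- function(df) {
  need <- c("subject_id", "bgt_lac_naa", "wm_lac_naa", "tunel_log10",
            "aeeg_score")
  miss <- setdiff(need, names(df))
  if (length(miss))
    sw_data_error(sprintf("outcome table missing column(s): %s",
                          paste(miss, collapse = ", ")))
  if (any(df$bgt_lac_naa < 0, na.rm = TRUE) ||
      any(df$wm_lac_naa < 0, na.rm = TRUE))
    sw_data_error("Lac/NAA ratios must be >= 0")
  if (any(df$aeeg_score < 0 | df$aeeg_score > 4, na.rm = TRUE))
    sw_data_error("aeeg_score must lie in 0..4")
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Write the cohort statistics report as a set of delimited tables
#'
#' Emits one CSV per analysis family -- the per-subject index table, the
#' regression table, the group-test table and the normality log -- plus a
#' machine-readable JSON run manifest (config snapshot, seed, package
#' version, file digests). Re-running with the same inputs reproduces the
#' tables byte for byte.
#'
#' @param report A `sw_stats_report` from [run_outcome_analysis()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
write_tables <- function(report, dir) {
  stopifnot(inherits(report, "sw_stats_report"))
  if (is.null(report$indices) || nrow(report$indices) == 0L)
    sw_data_error("refusing to write tables for an empty cohort")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(indices = "subject_indices.csv", regressions = "regressions.csv",
             group_tests = "group_tests.csv", normality = "normality.csv")
  tables <- list(indices = widen_index_table(report$indices),
                 regressions = report$regressions,
                 group_tests = report$group_tests,
                 normality = report$normality)
  for (k in names(files)) {
    df <- tables[[k]]
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) format(x, digits = 15, trim = TRUE))
    utils::write.csv(df, file.path(dir, files[[k]]), row.names = FALSE,
                     quote = FALSE)
  }
  paths <- file.path(dir, files)
  # machine-readable report (no timestamps: byte-identical on re-run)
  report_path <- file.path(dir, "report.json")
  jsonlite::write_json(
    list(indices = tables$indices, regressions = report$regressions,
         group_tests = report$group_tests, normality = report$normality,
         config = unclass_config(report$config)),
    report_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, report_path)
  manifest <- list(
    package = "slowwave",
    version = as.character(utils::packageVersion("slowwave")),
    seed = report$config$seed,
    config = unclass_config(report$config),
    files = as.list(setNames(vapply(paths, function(p)
      unname(tools::md5sum(p)), ""), files)))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(paths, manifest_path))
}

# long (subject x pair) index rows -> one row per subject with
# <pair>_semblance / <pair>_coherence / <pair>_valid columns
widen_index_table <- function(idx) {
  idx <- as.data.frame(idx)
  subs <- unique(idx$subject_id)
  prs <- unique(idx$pair)
  out <- data.frame(subject_id = subs,
                    group = idx$group[match(subs, idx$subject_id)])
  for (p in prs) {
    sel <- idx[idx$pair == p, ]
    m <- match(subs, sel$subject_id)
    key <- gsub("[^A-Za-z0-9]", "_", p)
    out[[paste0(key, "_semblance")]] <- sel$semblance[m]
    out[[paste0(key, "_coherence")]] <- sel$coherence[m]
    out[[paste0(key, "_valid")]] <- sel$valid_fraction[m]
  }
  out
}

# config -> plain list for JSON serialization
unclass_config <- function(cfg) {
  x <- unclass(cfg)
  x$epoch <- unclass(x$epoch)
  x$pairs <- lapply(x$pairs, as.list)
  x
}
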