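#' Per-subject reactivity indices for the configured channel pairs
#'
#' For each configured pair the analysis epoch is selected (insult onset as
#' origin for insult groups, recording start for controls), both channels
#' are wavelet-transformed, and the band/epoch means of the semblance and
#' coherence maps are pooled over all valid time-scale cells inside the
#' cone of influence. Decompositions are cached per channel, so a channel
#' appearing in several pairs is transformed once. Pairs with a missing
#' channel are skipped with a warning, never silently returned as NaN. A
#' `valid_fraction` below 0.5 marks the index as low-confidence.
#'
#' @param rec A preprocessed, synchronized [sw_recording()].
#' @param cfg An [analysis_config()].
#' @param keep_maps Keep the full time-scale maps for each pair (for map
#'   rendering); off by default to bound memory.
#' @param compute Which indices to compute (`"semblance"`, `"coherence"`);
#'   restricting to semblance skips the smoothing stage in large
#'   simulation studies.
#' @return A `data.frame` (class `sw_index_table`) with one row per pair:
#'   `subject_id, group, pair, semblance, coherence, valid_fraction,
#'   low_confidence`, with the `sw_pair_index` objects in
#'   `attr(, "pair_results")` when `keep_maps = TRUE`.
#' @export
compute_subject_indices <- function(rec, cfg = analysis_config(),
                                    keep_maps = FALSE,
                                    compute = c("semblance", "coherence")) {
  stopifnot(inherits(rec, "sw_recording"), inherits(cfg, "sw_config"))
  needed <- unique(unlist(cfg$pairs))
  have <- intersect(needed, names(rec$channels))
  usable <- Filter(function(p) all(p %in% have), cfg$pairs)
  dropped <- Filter(function(p) !all(p %in% have), cfg$pairs)
  for (p in dropped)
    warning(sprintf("subject %s: pair %s skipped (channel missing)",
                    rec$subject_id, pair_label(p)))
  if (!length(usable))
    sw_data_error(sprintf("subject %s: no computable pairs", rec$subject_id))

  ep <- select_epoch(rec, cfg$epoch, channels = unique(unlist(usable)))
  # coherence smoothing wants margin octaves around the band; the
  # semblance-only path needs none
  f_range <- if ("coherence" %in% compute) {
    c(0.5 * cfg$band_hz[1L], min(2 * cfg$band_hz[2L],
                                 0.5 * cfg$target_rate_hz))
  } else cfg$band_hz
  decomp <- list()
  get_dec <- function(nm) {
    if (is.null(decomp[[nm]])) {
      ch <- ep$channels[[nm]]
      if (any(!ch$mask))
        ch <- repair_by_interpolation(ch, !ch$mask, "linear")
      decomp[[nm]] <<- cwt_morlet(ch$values, dt = 1 / ch$native_rate,
                                  f_range = f_range, omega0 = cfg$omega0,
                                  voices_per_octave = cfg$voices_per_octave)
    }
    decomp[[nm]]
  }
  results <- lapply(usable, function(p)
    pair_indices(get_dec(p[1L]), get_dec(p[2L]), pair = p,
                 band_hz = cfg$band_hz, compute = compute))
  tab <- data.frame(
    subject_id = rec$subject_id,
    group = rec$group,
    pair = vapply(results, function(r) pair_label(r$pair), ""),
    semblance = vapply(results, `[[`, 0, "band_mean_semblance"),
    coherence = vapply(results, `[[`, 0, "band_mean_coherence"),
    valid_fraction = vapply(results, `[[`, 0, "valid_fraction"))
  tab$low_confidence <- tab$valid_fraction < 0.5
  class(tab) <- c("sw_index_table", "data.frame")
  if (keep_maps) attr(tab, "pair_results") <- setNames(results, tab$pair)
  tab
}

#' Reactivity indices for a whole cohort
#'
#' Applies [compute_subject_indices()] to each recording. Failures are
#' isolated: a subject that errors is dropped with a warning and the rest
#' of the cohort is still returned; only an all-fail cohort is an error.
#' Row order follows input order.
#'
#' @param recs List of preprocessed [sw_recording()]s.
#' @param cfg An [analysis_config()].
#' @param compute Which indices to compute (see
#'   [compute_subject_indices()]).
#' @return A combined `sw_index_table` data.frame.
#' @export
compute_cohort_indices <- function(recs, cfg = analysis_config(),
                                   compute = c("semblance", "coherence")) {
  if (!length(recs)) sw_data_error("empty cohort")
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rows[[i]] <- tryCatch(compute_subject_indices(recs[[i]], cfg,
                                                  compute = compute),
                          error = function(e) {
                            warning(sprintf("subject %s failed: %s",
                                            recs[[i]]$subject_id,
                                            conditionMessage(e)))
                            NULL
                          })
  }
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) sw_data_error("all subjects failed index computation")
  out <- do.call(rbind, rows)
  class(out) <- c("sw_index_table", "data.frame")
  out
}
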