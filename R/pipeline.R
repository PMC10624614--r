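#' Read and validate a JSON run configuration
#'
#' Schema: optional `cohort` (named counts `control/moderate/severe`),
#' optional `subject` overrides (duration_s, rates, artifact settings,
#' outcome_link), and any [analysis_config()] field under `analysis`
#' (band_hz, target_rate_hz, epoch = list(start_s, duration_s), pairs,
#' ...). Violations are reported with the offending field path before any
#' computation starts.
#'
#' @param path JSON file path.
#' @return List with `cohort`, `spec` (a [subject_gen_spec()]) and `cfg`
#'   (an [analysis_config()]).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) sw_config_error(sprintf("config '%s' not found", path))
  raw <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    sw_config_error(sprintf("config '%s': invalid JSON (%s)",
                                            path, conditionMessage(e))))
  cohort <- c(control = 5, moderate = 7, severe = 7)
  if (!is.null(raw$cohort)) {
    bad <- setdiff(names(raw$cohort), names(cohort))
    if (length(bad)) sw_config_error(sprintf("cohort.%s: unknown group", bad[1L]))
    cohort[names(raw$cohort)] <- unlist(raw$cohort)
  }
  sargs <- as.list(raw$subject)
  # JSON objects arrive as named lists; the spec wants named numeric vectors
  for (f in c("rates", "baselines", "osc_sd", "noise_sd", "drift_sd"))
    if (!is.null(sargs[[f]])) sargs[[f]] <- unlist(sargs[[f]])
  if (!is.null(sargs$outcome_link)) sargs$outcome_link <- as.list(sargs$outcome_link)
  spec <- tryCatch(do.call(subject_gen_spec, as.list(sargs)),
                   error = function(e)
                     sw_config_error(sprintf("subject: %s", conditionMessage(e))))
  aargs <- if (is.null(raw$analysis)) list() else as.list(raw$analysis)
  if (!is.null(aargs$epoch))
    aargs$epoch <- do.call(epoch_spec, as.list(aargs$epoch))
  if (!is.null(aargs$pairs))
    aargs$pairs <- lapply(seq_len(nrow(aargs$pairs)),
                          function(i) unlist(aargs$pairs[i, ]))
  cfg <- tryCatch(do.call(analysis_config, aargs),
                  error = function(e)
                    sw_config_error(sprintf("analysis: %s", conditionMessage(e))))
  list(cohort = cohort, spec = spec, cfg = cfg)
}

#' Run the full study pipeline
#'
#' simulate -> preprocess -> indices -> stats as one reproducible run:
#' generates (or loads) the cohort, cleans and synchronizes every
#' recording, computes the per-subject reactivity indices, runs the
#' outcome statistics, and writes all tables plus a JSON run manifest to
#' `out_dir`. Identical config + seed reproduces identical outputs.
#'
#' @param config Path to a JSON run config, or the list from
#'   [read_run_config()].
#' @param out_dir Output directory.
#' @param recordings Optional pre-built list of [sw_recording()]s with an
#'   `outcomes` data.frame attribute; skips the simulate stage.
#' @return The `sw_stats_report`, invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_study <- function(config, out_dir, recordings = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  cohort <- config$cohort
  spec <- config$spec
  cfg <- config$cfg
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(recordings)) {
    sim <- generate_cohort(n_per_group = cohort, base_spec = spec,
                           seed = cfg$seed)
    recs <- sim$recordings
    outcomes <- sim$outcomes
    utils::write.csv(sim$truth, file.path(out_dir, "truth.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes, file.path(out_dir, "outcomes.csv"),
                     row.names = FALSE)
    rec_dir <- file.path(out_dir, "recordings")
    dir.create(rec_dir, showWarnings = FALSE)
  } else {
    recs <- recordings
    outcomes <- attr(recordings, "outcomes")
    if (is.null(outcomes)) sw_data_error("recordings need an outcomes attribute")
  }

  recs_pp <- lapply(recs, preprocess_recording, cfg = cfg)
  if (is.null(recordings)) {
    for (r in recs_pp)
      write_recording(r, file.path(out_dir, "recordings",
                                   paste0(r$subject_id, ".csv")))
  }
  idx <- compute_cohort_indices(recs_pp, cfg)
  report <- run_outcome_analysis(idx, outcomes, cfg)
  write_tables(report, out_dir)
  jsonlite::write_json(
    list(stage = "complete", subjects = length(recs_pp),
         preprocess_log = lapply(recs_pp, attr, "preprocess_log")),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE)
  invisible(report)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `preprocess`, `indices`, `stats`,
#' `run` and `render-maps` (see `inst/cli/slowwave.R`). Exit codes: 0 on
#' success, 2 for configuration errors, 3 for data errors, 4 for compute
#' errors.
#'
#' @param args Character vector of CLI arguments.
#' @return Integer exit code.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: slowwave <command> [options]",
    "commands:",
    "  simulate   --config cfg.json --out DIR",
    "  preprocess --config cfg.json --in rec.csv --meta group[,onset] --out rec_pp.csv",
    "  indices    --config cfg.json --in rec_pp.csv --meta group[,onset] --out idx.csv",
    "  stats      --config cfg.json --indices idx.csv --outcomes outcomes.csv --out DIR",
    "  run        --config cfg.json --out DIR",
    "  render-maps --config cfg.json --in rec_pp.csv --meta group[,onset] --out DIR",
    sep = "\n")
  if (!length(args)) { message(usage); return(2L) }
  cmd <- args[1L]
  opt <- parse_cli_opts(args[-1L])
  code <- tryCatch({
    switch(cmd,
      simulate = {
        conf <- read_run_config(req_opt(opt, "config"))
        sim <- generate_cohort(conf$cohort, conf$spec, seed = conf$cfg$seed)
        dir.create(req_opt(opt, "out"), showWarnings = FALSE, recursive = TRUE)
        for (r in sim$recordings)
          write_recording(r, file.path(opt$out, paste0(r$subject_id, ".csv")))
        utils::write.csv(sim$outcomes, file.path(opt$out, "outcomes.csv"),
                         row.names = FALSE)
        utils::write.csv(sim$truth, file.path(opt$out, "truth.csv"),
                         row.names = FALSE)
        0L
      },
      preprocess = {
        conf <- read_run_config(req_opt(opt, "config"))
        rec <- read_cli_recording(opt)
        pp <- preprocess_recording(rec, conf$cfg)
        write_recording(pp, req_opt(opt, "out"))
        write_artifact_masks(pp, sub("(\\.[A-Za-z]+)?$", "_masks.csv",
                                     opt$out))
        0L
      },
      indices = {
        conf <- read_run_config(req_opt(opt, "config"))
        rec <- read_cli_recording(opt)
        idx <- compute_subject_indices(rec, conf$cfg)
        utils::write.csv(as.data.frame(idx), req_opt(opt, "out"),
                         row.names = FALSE)
        0L
      },
      stats = {
        conf <- read_run_config(req_opt(opt, "config"))
        idx <- utils::read.csv(req_opt(opt, "indices"))
        class(idx) <- c("sw_index_table", "data.frame")
        outcomes <- read_outcomes(req_opt(opt, "outcomes"))
        rep <- run_outcome_analysis(idx, outcomes, conf$cfg)
        write_tables(rep, req_opt(opt, "out"))
        0L
      },
      run = {
        run_study(req_opt(opt, "config"), req_opt(opt, "out"))
        0L
      },
      `render-maps` = {
        conf <- read_run_config(req_opt(opt, "config"))
        rec <- read_cli_recording(opt)
        idx <- compute_subject_indices(rec, conf$cfg, keep_maps = TRUE)
        dir.create(req_opt(opt, "out"), showWarnings = FALSE, recursive = TRUE)
        for (pr in attr(idx, "pair_results"))
          render_pair_maps(pr, file.path(
            opt$out, paste0(gsub("[^A-Za-z0-9]", "_", pair_label(pr$pair)),
                            ".png")))
        0L
      },
      { message(usage); 2L })
  },
  slowwave_config_error = function(e) { message("config error: ",
                                                conditionMessage(e)); 2L },
  slowwave_data_error = function(e) { message("data error: ",
                                              conditionMessage(e)); 3L },
  error = function(e) { message("compute error: ", conditionMessage(e)); 4L })
  code
}

parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    if (startsWith(args[i], "--") && i < length(args)) {
      opt[[substring(args[i], 3L)]] <- args[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  opt
}

req_opt <- function(opt, name) {
  if (is.null(opt[[name]]))
    sw_config_error(sprintf("missing required option --%s", name))
  opt[[name]]
}

read_cli_recording <- function(opt) {
  meta <- strsplit(req_opt(opt, "meta"), ",")[[1L]]
  group <- meta[1L]
  onset <- if (length(meta) > 1L) as.numeric(meta[2L]) else NA_real_
  read_recording(req_opt(opt, "in"), subject_id = basename(opt[["in"]]),
                 group = group, insult_onset_s = onset)
}

#' Render semblance and coherence maps for one pair to PNG
#'
#' Colour maps over the time-frequency plane (semblance -1..+1 diverging,
#' coherence 0..1 sequential) with the cone of influence drawn as a white
#' line.
#'
#' @param pr An `sw_pair_index` from [pair_indices()] (maps retained).
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
render_pair_maps <- function(pr, path) {
  stopifnot(inherits(pr, "sw_pair_index"))
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  lf <- log10(pr$freqs)
  draw <- function(map, zlim, pal, label) {
    graphics::image(x = pr$times, y = rev(lf), z = t(map[rev(seq_len(nrow(map))), ]),
                    zlim = zlim, col = pal, xlab = "time (s)",
                    ylab = "log10 frequency (Hz)", main = label,
                    useRaster = TRUE)
    coi <- log10(pmin(pmax(pr$coi_min_freq, min(pr$freqs)), max(pr$freqs)))
    graphics::lines(pr$times, coi, col = "white", lwd = 2)
  }
  smap <- pr$semblance_map
  smap[!is.finite(smap)] <- 0
  draw(smap, c(-1, 1), grDevices::hcl.colors(64, "RdBu", rev = TRUE),
       sprintf("%s semblance (band mean %.2f)", pair_label(pr$pair),
               pr$band_mean_semblance))
  draw(pr$coherence_map, c(0, 1), grDevices::hcl.colors(64, "viridis"),
       sprintf("%s coherence (band mean %.2f)", pair_label(pr$pair),
               pr$band_mean_coherence))
  invisible(path)
}
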