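#' Analysis configuration
#'
#' Collects every tunable the pipeline uses, with the defaults the analysis
#' is designed around: the slow-wave band 0.003--0.05 Hz, a shared 1 Hz time
#' base (Nyquist 0.5 Hz, far above the band top), the 15% from-baseline
#' artifact threshold, a 60-min analysis epoch starting 1 h after the
#' epoch origin, the seven standard reactivity pairs, and the 0.39 basal
#' ganglia-thalamic Lac/NAA outcome cutoff.
#'
#' @param band_hz Length-2 numeric, analysis band `(f_low, f_high)` in Hz.
#' @param target_rate_hz Shared sampling rate after synchronization, Hz.
#' @param artifact_threshold_frac Fractional deviation from baseline that
#'   flags a transient artifact (0.15 = 15%).
#' @param max_artifact_s Longest excursion still considered transient;
#'   longer deviations count as consistent signal change, not artifact.
#' @param despike_window Moving-statistics window for optical despiking,
#'   in samples.
#' @param despike_k_sd Number of local SDs that flags a spike.
#' @param epoch An [epoch_spec()].
#' @param pairs List of length-2 character vectors naming channel pairs.
#' @param lacnaa_threshold Good/poor outcome cutoff on BGT Lac/NAA.
#' @param alpha Significance level.
#' @param omega0 Morlet central frequency (nondimensional).
#' @param voices_per_octave Scale-grid density of the CWT.
#' @param seed Master seed for all stochastic stages.
#' @return An object of class `sw_config`.
#' @export
analysis_config <- function(band_hz = c(0.003, 0.05),
                            target_rate_hz = 1,
                            artifact_threshold_frac = 0.15,
                            max_artifact_s = 30,
                            despike_window = 20L,
                            despike_k_sd = 3,
                            epoch = epoch_spec(),
                            pairs = DEFAULT_PAIRS,
                            lacnaa_threshold = 0.39,
                            alpha = 0.05,
                            omega0 = 6,
                            voices_per_octave = 12L,
                            seed = 1L) {
  band_hz <- as.numeric(band_hz)
  if (length(band_hz) != 2L || !all(is.finite(band_hz)) ||
      band_hz[1L] <= 0 || band_hz[1L] >= band_hz[2L])
    sw_config_error("band_hz must satisfy 0 < f_low < f_high")
  if (band_hz[2L] >= target_rate_hz / 2)
    sw_config_error("band top must lie below the target Nyquist frequency")
  if (!is.finite(artifact_threshold_frac) ||
      artifact_threshold_frac <= 0 || artifact_threshold_frac >= 1)
    sw_config_error("artifact_threshold_frac must be in (0, 1)")
  if (!inherits(epoch, "sw_epoch_spec")) sw_config_error("epoch must be an epoch_spec")
  pairs <- lapply(pairs, as.character)
  for (p in pairs) {
    if (length(p) != 2L) sw_config_error("each pair must name two channels")
    bad <- setdiff(p, names(CHANNEL_KINDS))
    if (length(bad)) sw_config_error(sprintf("unknown channel in pair: %s", bad[1L]))
  }
  structure(
    list(band_hz = band_hz, target_rate_hz = target_rate_hz,
         artifact_threshold_frac = artifact_threshold_frac,
         max_artifact_s = max_artifact_s,
         despike_window = as.integer(despike_window),
         despike_k_sd = despike_k_sd, epoch = epoch, pairs = pairs,
         lacnaa_threshold = lacnaa_threshold, alpha = alpha,
         omega0 = omega0, voices_per_octave = as.integer(voices_per_octave),
         seed = as.integer(seed)),
    class = "sw_config")
}

#' @export
print.sw_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sw_config> band %.3g-%.3g Hz @ %g Hz | artifact >%.0f%% (<%g s) | ",
    "epoch %g+%g s | %d pairs | Lac/NAA cutoff %.2f | seed %d\n"),
    x$band_hz[1L], x$band_hz[2L], x$target_rate_hz,
    100 * x$artifact_threshold_frac, x$max_artifact_s,
    x$epoch$start_s, x$epoch$duration_s, length(x$pairs),
    x$lacnaa_threshold, x$seed))
  invisible(x)
}

pair_label <- function(p) paste(p, collapse = "-")
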