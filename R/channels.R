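#' Construct a time-series channel
#'
#' A channel is one physiological signal: a strictly increasing time axis in
#' seconds from recording start, sample values in the channel's native units
#' (mmHg for MABP, micromolar for haemoglobin species and oxCCO, cm^2/s for
#' BFI), a validity mask and a nominal native sampling rate. Masked samples
#' are carried explicitly (never dropped) so that repair operations can see
#' where the gaps are.
#'
#' @param name Channel kind; one of `r paste(names(CHANNEL_KINDS), collapse = ", ")`.
#' @param times Numeric vector, seconds from recording start, strictly
#'   increasing.
#' @param values Numeric vector, same length as `times`. Non-finite entries
#'   are converted to masked samples.
#' @param native_rate Nominal sampling rate in Hz. Estimated from the median
#'   time step when omitted.
#' @param mask Logical vector, `TRUE` where the sample is valid.
#' @return An object of class `sw_channel`.
#' @export
#' @examples
#' ch <- sw_channel("MABP", times = 0:9, values = rnorm(10, 45, 2),
#'                  native_rate = 1)
#' ch
sw_channel <- function(name, times, values, native_rate = NULL, mask = NULL) {
  name <- as.character(name)
  if (!name %in% names(CHANNEL_KINDS))
    sw_data_error(sprintf(
      "unknown channel kind '%s' (known: %s)", name,
      paste(names(CHANNEL_KINDS), collapse = ", ")))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    sw_data_error(sprintf("channel '%s': times and values differ in length", name))
  if (length(times) >= 2L && any(diff(times) <= 0))
    sw_data_error(sprintf("channel '%s': timestamps not strictly increasing", name))
  if (is.null(mask)) mask <- rep(TRUE, length(values))
  mask <- as.logical(mask) & is.finite(values)
  values[!mask] <- NA_real_
  if (is.null(native_rate)) {
    native_rate <- if (length(times) >= 2L) 1 / median(diff(times)) else NA_real_
  }
  structure(
    list(name = name, times = times, values = values,
         mask = mask, native_rate = as.numeric(native_rate)),
    class = "sw_channel")
}

#' @export
print.sw_channel <- function(x, ...) {
  cat(sprintf("<sw_channel %s> %d samples @ %.3g Hz [%s], %d masked\n",
              x$name, length(x$values), x$native_rate,
              CHANNEL_KINDS[[x$name]], sum(!x$mask)))
  invisible(x)
}

#' @export
length.sw_channel <- function(x) length(x$values)

#' Construct a recording
#'
#' A recording bundles one subject's synchronized or raw channels with the
#' metadata the analysis needs: insult group, insult-onset time (absent for
#' controls) and the baseline window used as reference for artifact
#' detection.
#'
#' @param subject_id Subject identifier.
#' @param group One of `"control"`, `"moderate"`, `"severe"`.
#' @param channels List of [sw_channel()] objects; names are taken from the
#'   channels themselves and must be unique.
#' @param insult_onset_s Insult onset in seconds from recording start;
#'   `NA` for controls, mandatory otherwise.
#' @param baseline_window_s Length-2 numeric `(start, end)` in seconds; must
#'   precede the insult onset when one is present.
#' @return An object of class `sw_recording`.
#' @export
sw_recording <- function(subject_id, group = c("control", "moderate", "severe"),
                         channels, insult_onset_s = NA_real_,
                         baseline_window_s = NULL) {
  group <- match.arg(group)
  stopifnot(is.list(channels), length(channels) >= 1L)
  for (ch in channels)
    if (!inherits(ch, "sw_channel"))
      sw_data_error("all channels must be sw_channel objects")
  nms <- vapply(channels, `[[`, "", "name")
  if (anyDuplicated(nms))
    sw_data_error("duplicate channel names in recording")
  names(channels) <- nms
  if (group != "control" && !is.finite(insult_onset_s))
    sw_data_error(sprintf("subject '%s': insult group '%s' requires insult_onset_s",
                          subject_id, group))
  if (is.null(baseline_window_s)) {
    t0 <- min(vapply(channels, function(c) c$times[1L], 0))
    end <- if (is.finite(insult_onset_s)) insult_onset_s else t0 + 900
    baseline_window_s <- c(t0, end)
  }
  if (is.finite(insult_onset_s) && baseline_window_s[2L] > insult_onset_s)
    sw_data_error("baseline window must precede insult onset")
  structure(
    list(subject_id = as.character(subject_id), group = group,
         channels = channels, insult_onset_s = as.numeric(insult_onset_s),
         baseline_window_s = as.numeric(baseline_window_s),
         # frozen at construction so epoch selection stays idempotent
         t_start_s = min(vapply(channels, function(c) c$times[1L], 0))),
    class = "sw_recording")
}

#' @export
print.sw_recording <- function(x, ...) {
  cat(sprintf("<sw_recording %s> group=%s, %d channels: %s\n",
              x$subject_id, x$group, length(x$channels),
              paste(names(x$channels), collapse = ", ")))
  if (is.finite(x$insult_onset_s))
    cat(sprintf("  insult onset at %.0f s\n", x$insult_onset_s))
  invisible(x)
}

#' Epoch specification
#'
#' `start_s` is the offset of the analysis window from the epoch *origin*:
#' the insult onset for insult-group subjects, the recording start for
#' controls ("at the same time" rule). The default selects a 60-min epoch
#' starting 1 h after the origin.
#'
#' @param start_s Offset from origin in seconds.
#' @param duration_s Epoch length in seconds (> 0).
#' @export
epoch_spec <- function(start_s = 3600, duration_s = 3600) {
  if (!is.finite(duration_s) || duration_s <= 0)
    sw_config_error("epoch duration_s must be > 0")
  structure(list(start_s = as.numeric(start_s),
                 duration_s = as.numeric(duration_s)),
            class = "sw_epoch_spec")
}

#' Crop a recording to an analysis epoch
#'
#' The epoch window is `[origin + start_s, origin + start_s + duration_s)`
#' where the origin is the insult onset for moderate/severe subjects and the
#' recording start for controls. Selecting the same window twice is a no-op.
#'
#' @param rec An [sw_recording()].
#' @param spec An [epoch_spec()].
#' @param channels Optional character vector restricting which channels must
#'   cover the window (all channels by default).
#' @return The cropped `sw_recording`; `insult_onset_s` and the baseline
#'   window are kept in original time coordinates.
#' @export
select_epoch <- function(rec, spec = epoch_spec(), channels = NULL) {
  stopifnot(inherits(rec, "sw_recording"), inherits(spec, "sw_epoch_spec"))
  origin <- if (rec$group == "control" || !is.finite(rec$insult_onset_s)) {
    if (!is.null(rec$t_start_s)) rec$t_start_s
    else min(vapply(rec$channels, function(c) c$times[1L], 0))
  } else rec$insult_onset_s
  t0 <- origin + spec$start_s
  t1 <- t0 + spec$duration_s
  keep <- if (is.null(channels)) names(rec$channels) else channels
  out <- rec$channels
  for (nm in keep) {
    ch <- rec$channels[[nm]]
    if (is.null(ch)) sw_data_error(sprintf("channel '%s' absent", nm))
    dt <- if (is.finite(ch$native_rate) && ch$native_rate > 0)
      1 / ch$native_rate else 0
    if (ch$times[1L] > t0 + 1e-9 || ch$times[length(ch$times)] < t1 - dt - 1e-9)
      sw_data_error(sprintf(
        "epoch [%.0f, %.0f) s exceeds extent of channel '%s' ([%.0f, %.0f] s)",
        t0, t1, nm, ch$times[1L], ch$times[length(ch$times)]))
    idx <- ch$times >= t0 - 1e-9 & ch$times < t1 - 1e-9
    out[[nm]] <- sw_channel(nm, ch$times[idx], ch$values[idx],
                            native_rate = ch$native_rate, mask = ch$mask[idx])
  }
  rec$channels <- out[keep]
  rec
}
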