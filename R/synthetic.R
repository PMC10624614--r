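#' Coupling specification for one channel pair
#'
#' Describes the latent slow-wave coupling the generator builds in: the
#' driven channel shares `coupling_weight` of its in-band oscillation
#' variance with the driver, at a constant per-frequency phase offset
#' `phase_lag_rad`. Because the lag is a constant phase (not a constant
#' time delay), the target semblance of the pair is exactly
#' `cos(phase_lag_rad)` across the shared band.
#'
#' @param pair Character vector `(driver, driven)`.
#' @param phase_lag_rad Phase lag in radians, in `[-pi, pi]`.
#' @param coupling_weight Shared-variance fraction in `[0, 1]`.
#' @param shared_band_hz Band of the shared oscillation; defaults to the
#'   slow-wave analysis band.
#' @export
coupling_spec <- function(pair, phase_lag_rad = 0, coupling_weight = 0.8,
                          shared_band_hz = c(0.003, 0.05)) {
  pair <- as.character(pair)
  if (length(pair) != 2L || anyNA(match(pair, names(CHANNEL_KINDS))))
    sw_config_error("coupling pair must name two known channels")
  if (!is.finite(coupling_weight) || coupling_weight < 0 || coupling_weight > 1)
    sw_config_error("coupling_weight must lie in [0, 1]")
  if (!is.finite(phase_lag_rad) || abs(phase_lag_rad) > pi + 1e-9)
    sw_config_error("phase_lag_rad must lie in [-pi, pi]")
  structure(list(pair = pair, phase_lag_rad = phase_lag_rad,
                 coupling_weight = coupling_weight,
                 shared_band_hz = as.numeric(shared_band_hz)),
            class = "sw_coupling_spec")
}

#' Subject generation specification
#'
#' The stated world a synthetic subject is drawn from. Each channel is
#' baseline level + slow drift (band-limited below the analysis band) +
#' band-limited stochastic slow-wave oscillation + white measurement noise,
#' with couplings imposing shared in-band structure between pairs.
#' Outcomes are linked linearly (with noise) to the latent target semblance
#' of the outcome pair on the log10 Lac/NAA scale.
#'
#' @param subject_id Identifier.
#' @param group `"control"`, `"moderate"` or `"severe"`.
#' @param duration_s Recording length in seconds.
#' @param rates Named numeric vector of per-channel sampling rates (Hz);
#'   each must exceed twice the oscillation band top.
#' @param baselines Named numeric vector of channel baseline levels.
#' @param osc_sd Named numeric vector of slow-wave oscillation SDs
#'   (channel units).
#' @param noise_sd Named numeric vector of white-noise SDs.
#' @param drift_sd Named numeric vector of drift SDs.
#' @param drift_tau_s Drift timescale; drift occupies frequencies below
#'   `1 / drift_tau_s`.
#' @param couplings List of [coupling_spec()]s.
#' @param artifact_rate_per_hour Poisson rate of injected transients.
#' @param artifact_magnitude_frac Transient amplitude as a fraction of the
#'   channel baseline.
#' @param artifact_duration_s Length-2 range of transient durations.
#' @param artifact_channels Channels receiving injected transients
#'   (default MABP, the channel the threshold-and-interpolate rule
#'   targets).
#' @param insult_onset_s Onset time for insult groups.
#' @param outcome_link List with `alpha`, `beta`, `sigma` mapping latent
#'   target semblance to log10 Lac/NAA, plus `tunel_alpha`, `tunel_beta`,
#'   `tunel_sigma` for the TUNEL scale.
#' @export
subject_gen_spec <- function(subject_id = "sim",
                             group = "control",
                             duration_s = 21600,
                             rates = c(MABP = 5, HbD = 1, HbT = 1,
                                       oxCCO = 1, BFI = 1),
                             baselines = c(MABP = 45, HbD = 10, HbT = 40,
                                           oxCCO = 0, BFI = 1.5e-8),
                             osc_sd = NULL,
                             noise_sd = NULL,
                             drift_sd = NULL,
                             drift_tau_s = 3000,
                             couplings = list(),
                             artifact_rate_per_hour = 0,
                             artifact_magnitude_frac = 0.3,
                             artifact_duration_s = c(2, 15),
                             artifact_channels = "MABP",
                             insult_onset_s = 900,
                             outcome_link = list(alpha = -1.05, beta = 1.25,
                                                 sigma = 0.12,
                                                 tunel_alpha = 0.0,
                                                 tunel_beta = 1.6,
                                                 tunel_sigma = 0.25)) {
  group <- match.arg(group, c("control", "moderate", "severe"))
  chans <- names(rates)
  bad <- setdiff(chans, names(CHANNEL_KINDS))
  if (length(bad)) sw_config_error(sprintf("unknown channel '%s'", bad[1L]))
  # plausible default amplitudes relative to baseline
  if (is.null(osc_sd))
    osc_sd <- setNames(pmax(abs(baselines[chans]) * 0.02, 0.02), chans)
  if (is.null(noise_sd))
    noise_sd <- setNames(osc_sd[chans] * 0.15, chans)
  if (is.null(drift_sd))
    drift_sd <- setNames(osc_sd[chans] * 1.0, chans)
  for (cs in couplings) {
    if (!inherits(cs, "sw_coupling_spec"))
      sw_config_error("couplings must be coupling_spec objects")
    miss <- setdiff(cs$pair, chans)
    if (length(miss))
      sw_config_error(sprintf("coupling names channel '%s' with no rate", miss[1L]))
    for (nm in cs$pair)
      if (rates[[nm]] <= 2 * cs$shared_band_hz[2L])
        sw_config_error(sprintf(
          "channel '%s' rate %.3g Hz below Nyquist for shared band top %.3g Hz",
          nm, rates[[nm]], cs$shared_band_hz[2L]))
  }
  structure(
    list(subject_id = subject_id, group = group, duration_s = duration_s,
         rates = rates, baselines = baselines[chans], osc_sd = osc_sd[chans],
         noise_sd = noise_sd[chans], drift_sd = drift_sd[chans],
         drift_tau_s = drift_tau_s, couplings = couplings,
         artifact_rate_per_hour = artifact_rate_per_hour,
         artifact_magnitude_frac = artifact_magnitude_frac,
         artifact_duration_s = artifact_duration_s,
         artifact_channels = artifact_channels,
         insult_onset_s = insult_onset_s, outcome_link = outcome_link),
    class = "sw_subject_gen_spec")
}

# Unit-variance Gaussian process band-limited to [f1, f2] Hz, synthesized in
# the frequency domain on a uniform grid of n samples at rate fs.
# mode = "narrowband" keeps the stated band; mode = "tone" returns a pure
# sinusoid at the band centre with random phase (analytic test mode).
band_limited_noise <- function(n, fs, band, mode = c("narrowband", "tone")) {
  mode <- match.arg(mode)
  if (mode == "tone") {
    f0 <- sqrt(band[1L] * band[2L])
    ph <- runif(1L, 0, 2 * pi)
    return(sqrt(2) * cos(2 * pi * f0 * (seq_len(n) - 1L) / fs + ph))
  }
  z <- stats::rnorm(n)
  zf <- stats::fft(z)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
  keep <- abs(f) >= band[1L] & abs(f) <= band[2L]
  zf[!keep] <- 0
  x <- Re(stats::fft(zf, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# Apply a constant phase offset to every Fourier component of a real
# signal: positive frequencies rotated by -phi, negative by +phi, keeping
# the output real. A zero-lag signal in cos(wt) becomes cos(wt - phi).
phase_shift <- function(x, phi) {
  n <- length(x)
  xf <- stats::fft(x)
  k <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  rot <- complex(argument = -phi * sign(k))
  Re(stats::fft(xf * rot, inverse = TRUE)) / n
}

#' Generate one synthetic subject
#'
#' Builds a multichannel recording per the [subject_gen_spec()]: each
#' channel is drift + band-limited slow-wave oscillation + white noise on
#' its own native time grid, and each [coupling_spec()] replaces the driven
#' channel's in-band oscillation by
#' `sqrt(w) * phase_shift(driver, lag) + sqrt(1 - w) * independent`.
#' Shared processes are synthesized once on a master grid (the fastest
#' channel rate) and interpolated onto each channel's grid, so couplings
#' hold across differing native rates. Latent truth (per-pair target
#' semblance `cos(lag)` and coupling weight) is returned alongside.
#'
#' @param spec A [subject_gen_spec()].
#' @param seed Integer seed; the same `(spec, seed)` reproduces the subject
#'   bit for bit.
#' @param oscillation_mode `"narrowband"` (default, band-limited Gaussian
#'   slow waves) or `"tone"` (pure sinusoid at the band centre, for
#'   analytic tests).
#' @return List with `recording` (an [sw_recording()]), `truth`
#'   (data.frame: pair, phase_lag_rad, coupling_weight, target_semblance)
#'   and `artifacts` (list of injected-truth masks, if any).
#' @export
generate_subject <- function(spec, seed = 1L,
                             oscillation_mode = c("narrowband", "tone")) {
  stopifnot(inherits(spec, "sw_subject_gen_spec"))
  oscillation_mode <- match.arg(oscillation_mode)
  for (cs in spec$couplings) {
    miss <- setdiff(cs$pair, names(spec$rates))
    if (length(miss))
      sw_config_error(sprintf(
        "coupling pair %s names channel '%s' the generator does not produce",
        pair_label(cs$pair), miss[1L]))
  }
  with_seed(seed, {
    chans <- names(spec$rates)
    fs_master <- max(spec$rates)
    n_master <- ceiling(spec$duration_s * fs_master)
    t_master <- (seq_len(n_master) - 1L) / fs_master

    band_of <- function(nm) {
      for (cs in spec$couplings)
        if (nm %in% cs$pair) return(cs$shared_band_hz)
      c(0.003, 0.05)
    }
    # per-channel latent oscillations on the master grid
    osc <- setNames(vector("list", length(chans)), chans)
    for (nm in chans)
      osc[[nm]] <- band_limited_noise(n_master, fs_master, band_of(nm),
                                      oscillation_mode)
    # impose couplings (driver's process phase-shifted into the driven)
    for (cs in spec$couplings) {
      drv <- cs$pair[1L]; dvn <- cs$pair[2L]
      w <- cs$coupling_weight
      shifted <- phase_shift(osc[[drv]], cs$phase_lag_rad)
      osc[[dvn]] <- sqrt(w) * shifted + sqrt(1 - w) * osc[[dvn]]
      s <- stats::sd(osc[[dvn]])
      if (s > 0) osc[[dvn]] <- osc[[dvn]] / s
    }

    drift_band <- c(1 / (20 * spec$drift_tau_s), 1 / spec$drift_tau_s)
    channels <- vector("list", length(chans))
    names(channels) <- chans
    art_masks <- list()
    for (nm in chans) {
      fs <- spec$rates[[nm]]
      n <- ceiling(spec$duration_s * fs)
      tt <- (seq_len(n) - 1L) / fs
      o <- if (abs(fs - fs_master) < 1e-12) osc[[nm]]
           else stats::approx(t_master, osc[[nm]], xout = tt, rule = 2)$y
      drift <- band_limited_noise(n, fs, drift_band)
      v <- spec$baselines[[nm]] + spec$osc_sd[[nm]] * o +
        spec$drift_sd[[nm]] * drift +
        stats::rnorm(n, sd = spec$noise_sd[[nm]])
      ch <- sw_channel(nm, tt, v, native_rate = fs)
      if (spec$artifact_rate_per_hour > 0 && nm %in% spec$artifact_channels) {
        inj <- inject_artifacts(ch, spec$artifact_rate_per_hour,
                                spec$artifact_magnitude_frac,
                                spec$artifact_duration_s, seed = NULL)
        ch <- inj$channel
        art_masks[[nm]] <- inj
      }
      channels[[nm]] <- ch
    }

    onset <- if (spec$group == "control") NA_real_ else spec$insult_onset_s
    rec <- sw_recording(spec$subject_id, spec$group, channels,
                        insult_onset_s = onset,
                        baseline_window_s = c(0, min(900, spec$duration_s,
                                                     onset, na.rm = TRUE)))
    truth <- if (length(spec$couplings)) {
      data.frame(
        pair = vapply(spec$couplings, function(cs) pair_label(cs$pair), ""),
        phase_lag_rad = vapply(spec$couplings, `[[`, 0, "phase_lag_rad"),
        coupling_weight = vapply(spec$couplings, `[[`, 0, "coupling_weight"),
        target_semblance = vapply(spec$couplings,
                                  function(cs) cos(cs$phase_lag_rad), 0))
    } else {
      data.frame(pair = character(), phase_lag_rad = numeric(),
                 coupling_weight = numeric(), target_semblance = numeric())
    }
    list(recording = rec, truth = truth, artifacts = art_masks)
  })
}

#' Inject transient artifacts into a channel
#'
#' Adds Poisson-placed rectangular offsets of
#' `+/- magnitude_frac * channel median` with random durations, returning
#' both the corrupted channel and the ground-truth positions for
#' detector-recall tests.
#'
#' @param chan An [sw_channel()].
#' @param rate_per_hour Expected artifact count per hour (Poisson).
#' @param magnitude_frac Offset magnitude as a fraction of the channel
#'   median (the local baseline).
#' @param duration_s_range Length-2 range of artifact durations, seconds.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return List with `channel`, `positions` (data.frame `start_s`, `end_s`,
#'   `sign`) and `mask` (an [artifact_mask()], provenance
#'   `"injected-truth"`).
#' @export
inject_artifacts <- function(chan, rate_per_hour, magnitude_frac = 0.3,
                             duration_s_range = c(2, 15), seed = NULL) {
  stopifnot(inherits(chan, "sw_channel"))
  if (magnitude_frac <= 0) sw_config_error("magnitude_frac must be > 0")
  run <- function() {
    dur_h <- (chan$times[length(chan$times)] - chan$times[1L]) / 3600
    n_art <- stats::rpois(1L, rate_per_hour * dur_h)
    flags <- logical(length(chan$values))
    v <- chan$values
    base <- median(v, na.rm = TRUE)
    pos <- data.frame(start_s = numeric(), end_s = numeric(), sign = numeric())
    if (n_art > 0L) {
      starts <- sort(stats::runif(n_art, chan$times[1L],
                                  chan$times[length(chan$times)]))
      durs <- stats::runif(n_art, duration_s_range[1L], duration_s_range[2L])
      signs <- ifelse(stats::runif(n_art) < 0.5, -1, 1)
      for (i in seq_len(n_art)) {
        idx <- chan$times >= starts[i] & chan$times <= starts[i] + durs[i]
        if (!any(idx)) next
        v[idx] <- v[idx] + signs[i] * magnitude_frac * abs(base)
        flags[idx] <- TRUE
        pos <- rbind(pos, data.frame(start_s = starts[i],
                                     end_s = starts[i] + durs[i],
                                     sign = signs[i]))
      }
    }
    out <- chan
    out$values <- v
    list(channel = out, positions = pos,
         mask = artifact_mask(flags, "injected-truth", chan$name))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Severity presets for the default cohort
#'
#' Latent BFI--HbD and oxCCO--HbD coupling rises monotonically with insult
#' severity: near-orthogonal weak coupling in controls (band-mean semblance
#' near 0, as in an intact autoregulating brain), intermediate in moderate
#' insult, strong in-phase coupling in severe insult (pressure-passive,
#' metabolically coupled). Values are the package's stated world, not
#' claims about piglet physiology.
#'
#' @param group `"control"`, `"moderate"` or `"severe"`.
#' @return Named list with `target_semblance` and `coupling_weight`.
#' @export
severity_preset <- function(group = c("control", "moderate", "severe")) {
  group <- match.arg(group)
  switch(group,
         control = list(target_semblance = 0.05, coupling_weight = 0.45),
         moderate = list(target_semblance = 0.35, coupling_weight = 0.65),
         severe = list(target_semblance = 0.65, coupling_weight = 0.85))
}

#' Generate a full synthetic cohort with linked outcomes
#'
#' Draws `n_per_group` subjects per insult group from the severity presets
#' (couplings on BFI--HbD and oxCCO--HbD by default), then draws outcomes
#' from the linear latent link:
#' `log10(Lac/NAA) = alpha + beta * target_semblance + N(0, sigma)`,
#' truncated to plausible ranges, with the TUNEL log10 count linked the
#' same way on its own scale and the aEEG background score tied to group.
#' The returned truth table retains all latent parameters for recovery
#' tests. One master seed drives everything through the documented
#' splitting scheme.
#'
#' @param n_per_group Named integer vector, e.g.
#'   `c(control = 5, moderate = 7, severe = 7)`.
#' @param base_spec Template [subject_gen_spec()]; group, subject id,
#'   couplings and insult onset are overridden per subject.
#' @param seed Master seed.
#' @param outcome_pair Pair whose latent semblance drives outcomes.
#' @param presets Function `group -> list(target_semblance,
#'   coupling_weight)`; defaults to [severity_preset()]. Supplying a flat
#'   function makes null cohorts for calibration studies.
#' @return List with `recordings` (list of [sw_recording()]), `outcomes`
#'   (data.frame) and `truth` (data.frame of latent parameters).
#' @export
generate_cohort <- function(n_per_group = c(control = 5, moderate = 7,
                                            severe = 7),
                            base_spec = subject_gen_spec(),
                            seed = 1L,
                            outcome_pair = c("BFI", "HbD"),
                            presets = severity_preset) {
  if (any(n_per_group < 0) || sum(n_per_group) == 0L)
    sw_config_error("cohort must contain at least one subject")
  groups <- rep(names(n_per_group), n_per_group)
  n_tot <- length(groups)
  seeds <- split_seeds(seed, n_tot + 1L)
  out_seed <- seeds[n_tot + 1L]
  link <- base_spec$outcome_link
  chans <- names(base_spec$rates)

  recs <- vector("list", n_tot)
  truth_rows <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    g <- groups[i]
    preset <- presets(g)
    lag <- acos(pmin(pmax(preset$target_semblance, -1), 1))
    couplings <- list(
      coupling_spec(outcome_pair, phase_lag_rad = lag,
                    coupling_weight = preset$coupling_weight))
    # metabolic coupling driven *from* HbD so it does not dilute the
    # already-imposed outcome-pair coupling on HbD
    if (all(c("oxCCO", "HbD") %in% chans) &&
        !"oxCCO" %in% outcome_pair)
      couplings <- c(couplings, list(
        coupling_spec(c("HbD", "oxCCO"), phase_lag_rad = lag,
                      coupling_weight = preset$coupling_weight)))
    spec_i <- base_spec
    spec_i$subject_id <- sprintf("S%02d", i)
    spec_i$group <- g
    spec_i$couplings <- couplings
    sub <- generate_subject(spec_i, seed = seeds[i])
    recs[[i]] <- sub$recording
    truth_rows[[i]] <- data.frame(
      subject_id = spec_i$subject_id, group = g,
      target_semblance = preset$target_semblance,
      coupling_weight = preset$coupling_weight,
      phase_lag_rad = lag)
  }
  truth <- do.call(rbind, truth_rows)

  outcomes <- with_seed(out_seed, {
    s <- truth$target_semblance
    bgt <- 10 ^ (link$alpha + link$beta * s + rnorm(n_tot, sd = link$sigma))
    wm <- 10 ^ (link$alpha + link$beta * s + rnorm(n_tot, sd = link$sigma))
    tunel <- link$tunel_alpha + link$tunel_beta * s +
      rnorm(n_tot, sd = link$tunel_sigma)
    aeeg_centre <- c(control = 0.5, moderate = 2.5, severe = 3.5)[truth$group]
    aeeg <- pmin(4L, pmax(0L, as.integer(round(
      aeeg_centre + rnorm(n_tot, sd = 0.5)))))
    data.frame(
      subject_id = truth$subject_id, group = truth$group,
      bgt_lac_naa = pmin(pmax(bgt, 0.02), 2),
      wm_lac_naa = pmin(pmax(wm, 0.02), 2),
      tunel_log10 = pmin(pmax(tunel, -0.5), 2),
      aeeg_score = aeeg)
  })
  list(recordings = recs, outcomes = validate_outcomes(outcomes),
       truth = truth)
}
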