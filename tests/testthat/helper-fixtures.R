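# Fixture builders shared across test files. All fixtures are generated in
# code; nothing is read from disk except what a test writes itself.

# uniform channel from a function of time
make_channel <- function(name, fs, dur, f = function(t) rep(0, length(t)),
                         noise_sd = 0, seed = NULL) {
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  v <- f(tt)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v + rnorm(length(tt), sd = noise_sd)
  }
  sw_channel(name, tt, v, native_rate = fs)
}

# minimal two-channel recording for plumbing tests
make_recording <- function(dur = 7200, fs = 1, group = "control",
                           onset = NA_real_, seed = 1) {
  set.seed(seed)
  tt <- seq(0, dur - 1 / fs, by = 1 / fs)
  sw_recording(
    "T01", group,
    list(sw_channel("MABP", tt, 45 + rnorm(length(tt)), native_rate = fs),
         sw_channel("BFI", tt, 1.5e-8 * (1 + 0.05 * rnorm(length(tt))),
                    native_rate = fs)),
    insult_onset_s = onset)
}

# spec for a fast two-channel coupled subject on a single 1 Hz grid;
# the analysis epoch [3600, 7200) fits for both control and insult origins
fast_pair_spec <- function(lag = 0, weight = 1, noise_frac = 0,
                           shared_band = c(0.003, 0.05),
                           group = "control", duration_s = 8200) {
  subject_gen_spec(
    group = group, duration_s = duration_s,
    rates = c(BFI = 1, HbD = 1),
    baselines = c(BFI = 1.5e-8, HbD = 10),
    osc_sd = c(BFI = 3e-9, HbD = 2),
    noise_sd = c(BFI = 3e-9 * noise_frac, HbD = 2 * noise_frac),
    drift_sd = c(BFI = 0, HbD = 0),
    couplings = list(coupling_spec(c("BFI", "HbD"), phase_lag_rad = lag,
                                   coupling_weight = weight,
                                   shared_band_hz = shared_band)))
}

# analysis config matched to the fast pair spec
fast_pair_cfg <- function(band = c(0.003, 0.05)) {
  analysis_config(band_hz = band, pairs = list(c("BFI", "HbD")))
}
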