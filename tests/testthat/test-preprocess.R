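test_that("threshold rule flags transient but not sustained deviations", {
  fs <- 1
  tt <- 0:1799
  v <- rep(50, 1800)
  v[1000:1004] <- 60                      # 5-s excursion, 20% > 15%
  ch <- sw_channel("MABP", tt, v, native_rate = fs)
  m <- detect_threshold_artifacts(ch, c(0, 900), 0.15, max_artifact_s = 30)
  expect_true(all(m$flags[1000:1004]))
  expect_equal(sum(m$flags), 5)

  # sustained step for the rest of the epoch: consistent change, NOT flagged
  v2 <- rep(50, 1800)
  v2[1000:1799] <- 60
  m2 <- detect_threshold_artifacts(
    sw_channel("MABP", tt, v2, native_rate = fs), c(0, 900), 0.15, 30)
  expect_equal(sum(m2$flags), 0)

  # non-positive baseline reference is an error
  ch0 <- sw_channel("oxCCO", tt, c(rep(0, 900), rep(1, 900)), native_rate = fs)
  expect_error(detect_threshold_artifacts(ch0, c(0, 899), 0.15), "positive")
})

test_that("repair restores interior samples and is identity on clean channels", {
  tt <- 0:99
  line <- sw_channel("MABP", tt, 2 * tt + 7, native_rate = 1)
  flags <- rep(FALSE, 100); flags[50] <- TRUE
  rep1 <- repair_by_interpolation(line, flags, "linear")
  expect_equal(rep1$values[50], 2 * tt[50] + 7)  # exact linear restoration
  expect_equal(rep1$values, line$values)

  rep_id <- repair_by_interpolation(line, rep(FALSE, 100))
  expect_identical(rep_id$values, line$values)

  expect_error(repair_by_interpolation(line, rep(TRUE, 100)), "entire")

  # spline repair of a sinusoid beats / matches a local cubic-fit oracle
  tt2 <- 0:499
  sig <- sin(2 * pi * 0.01 * tt2)
  bad <- c(120, 240, 360)
  ch <- sw_channel("HbD", tt2, sig, native_rate = 1)
  fl <- rep(FALSE, 500); fl[bad] <- TRUE
  rp <- repair_by_interpolation(ch, fl, "spline")
  err <- max(abs(rp$values[bad] - sig[bad]))
  oracle_err <- oracle_polyfit_error(tt2, sig, bad)
  expect_lte(err, oracle_err + 1e-9)
})

test_that("moving-SD despiking recovers spikes and leaves smooth signals alone", {
  # constant signal + one spike: exactly the spike flagged and removed
  v <- rep(5, 200); v[77] <- 15
  ch <- sw_channel("HbD", 0:199, v, native_rate = 1)
  out <- despike_moving_sd(ch, window = 20, k_sd = 3)
  expect_equal(which(out$mask$flags), 77)
  expect_equal(out$channel$values[77], 5, tolerance = 1e-6)

  # pure slow sinusoid: < 1% flagged. Gaussian-tail oracle: for detrended
  # residuals a 3-SD rule flags ~0.3% at most
  tt <- 0:1999
  ch2 <- sw_channel("HbD", tt, 10 * sin(2 * pi * 0.01 * tt), native_rate = 1)
  out2 <- despike_moving_sd(ch2, 20, 3)
  expect_lt(mean(out2$mask$flags), 0.01)

  # spike train at known positions: all recovered within +/- 1 sample
  # slow trend small enough that a spike dominates the local variability
  # (the moving-SD rule makes no attempt to detrend steep slopes)
  set.seed(31)
  base <- 2 * sin(2 * pi * 0.005 * tt) + rnorm(2000, sd = 0.3)
  pos <- c(150, 500, 900, 1300, 1700)
  spiked <- base
  spiked[pos] <- spiked[pos] + sample(c(-8, 8), 5, replace = TRUE)
  ch3 <- sw_channel("oxCCO", tt, spiked, native_rate = 1)
  out3 <- despike_moving_sd(ch3, 20, 3)
  found <- which(out3$mask$flags)
  for (p in pos)
    expect_true(any(abs(found - p) <= 1),
                label = sprintf("spike at %d recovered", p))

  # constant channel: zero SD handled, nothing flagged
  out4 <- despike_moving_sd(sw_channel("HbD", 0:199, rep(3, 200),
                                       native_rate = 1), 20, 3)
  expect_equal(sum(out4$mask$flags), 0)
  expect_error(despike_moving_sd(ch, window = 3), ">= 5")
})

test_that("wavelet denoising keeps trend, removes noise, preserves band power", {
  tt <- 0:4095
  s <- sin(2 * pi * 0.01 * tt)

  # noiseless slow sinusoid passes through (trend preservation)
  expect_gt(cor(s, wavelet_denoise(s, fs = 1)), 0.999)

  # SNR 0 dB: RMSE to clean strictly lower after denoising, 100/100 seeds
  fails <- 0L
  for (i in 1:100) {
    set.seed(i)
    z <- s + rnorm(4096, sd = 1 / sqrt(2))
    y <- wavelet_denoise(z, fs = 1)
    if (sqrt(mean((y - s) ^ 2)) >= sqrt(mean((z - s) ^ 2))) fails <- fails + 1L
  }
  expect_equal(fails, 0L)

  # band power of a band-limited signal changes <= 5% (periodogram oracle)
  set.seed(32)
  n <- 4096
  f <- fft(rnorm(n))
  fr <- (0:(n - 1)) / n
  keep <- (fr >= 0.003 & fr <= 0.05) | (fr >= 1 - 0.05 & fr <= 1 - 0.003)
  bl <- Re(fft(f * keep, inverse = TRUE)) / n
  bl <- bl / sd(bl)
  ratio <- oracle_band_power(wavelet_denoise(bl, fs = 1), 1, c(0.003, 0.05)) /
    oracle_band_power(bl, 1, c(0.003, 0.05))
  expect_lt(abs(ratio - 1), 0.05)

  # output length always equals input length, incl. non-dyadic lengths
  for (n2 in c(1000, 3600, 5000))
    expect_length(wavelet_denoise(rnorm(n2), fs = 1), n2)
  expect_error(wavelet_denoise(rnorm(4), fs = 1), "short")
})

test_that("synchronize aligns mixed-rate channels and is identity when aligned", {
  t10 <- seq(0, 3599.9, by = 0.1)
  t1 <- 0:3599
  rec <- sw_recording("sync", "control", list(
    sw_channel("MABP", t10, 50 + sin(2 * pi * 0.01 * t10), native_rate = 10),
    sw_channel("BFI", t1, 1 + 0.1 * sin(2 * pi * 0.01 * t1), native_rate = 1)))
  sy <- synchronize(rec, 1)
  expect_equal(sy$channels$MABP$times, sy$channels$BFI$times)
  expect_length(sy$channels$MABP, 3600)

  # 0.01 Hz sinusoid downsampled 10 -> 1 Hz: amplitude loss <= 1%
  # (analytic filter response is unity well below the cutoff)
  mid <- 300:3300
  amp <- sd(sy$channels$MABP$values[mid]) / sd(50 + sin(2 * pi * 0.01 * t10))
  expect_gt(amp, 0.99)
  expect_lt(amp, 1.01)

  # already-synchronized recording -> identity to 1e-9
  sy2 <- synchronize(sy, 1)
  expect_lt(max(abs(sy2$channels$MABP$values - sy$channels$MABP$values)), 1e-9)

  # disjoint channels -> error
  rec_dis <- sw_recording("d", "control", list(
    sw_channel("MABP", 0:99, rep(50, 100), native_rate = 1),
    sw_channel("BFI", 200:299, rep(1, 100), native_rate = 1)))
  expect_error(synchronize(rec_dis, 1), "overlap")

  # upsampling warns
  rec_up <- sw_recording("u", "control", list(
    sw_channel("Temp", seq(0, 995, by = 5), rnorm(200) + 38,
               native_rate = 0.2)))
  expect_warning(synchronize(rec_up, 1), "upsampled")
})

test_that("derive_channels computes HbD/HbT and passes through existing ones", {
  tt <- 0:99
  rec <- sw_recording("d", "control", list(
    sw_channel("HbO2", tt, rep(2, 100), native_rate = 1),
    sw_channel("HHb", tt, rep(1, 100), native_rate = 1)))
  der <- derive_channels(rec)
  expect_equal(der$channels$HbD$values, rep(1, 100))
  expect_equal(der$channels$HbT$values, rep(3, 100))

  # HbO2 = HHb -> HbD = 0 everywhere
  rec2 <- sw_recording("d2", "control", list(
    sw_channel("HbO2", tt, 5 + sin(tt / 5), native_rate = 1),
    sw_channel("HHb", tt, 5 + sin(tt / 5), native_rate = 1)))
  expect_true(all(derive_channels(rec2)$channels$HbD$values == 0))

  # pass-through when already present
  pre <- derive_channels(der)
  expect_identical(pre$channels$HbD$values, der$channels$HbD$values)

  rec3 <- sw_recording("d3", "control",
                       list(sw_channel("HbO2", tt, rep(2, 100),
                                       native_rate = 1)))
  expect_error(derive_channels(rec3), "HHb")
})

test_that("preprocessing chain is idempotent and length preserving", {
  spec <- subject_gen_spec(duration_s = 5400,
                           rates = c(MABP = 5, HbD = 1, BFI = 1),
                           baselines = c(MABP = 45, HbD = 10, BFI = 1.5e-8),
                           artifact_rate_per_hour = 4)
  rec <- generate_subject(spec, seed = 33)$recording
  cfg <- analysis_config()
  once <- preprocess_recording(rec, cfg)
  twice <- preprocess_recording(once, cfg)
  n1 <- length(once$channels$MABP)
  expect_equal(length(twice$channels$MABP), n1)
  for (nm in names(once$channels)) {
    scale <- max(abs(once$channels[[nm]]$values))
    expect_lt(max(abs(twice$channels[[nm]]$values -
                        once$channels[[nm]]$values)) / scale, 1e-6)
  }
  expect_false(is.null(attr(once, "preprocess_log")))

  # artifact masks are retained and exportable for audit
  masks <- attr(once, "artifact_masks")
  expect_true("MABP" %in% names(masks))
  f <- file.path(withr::local_tempdir(), "masks.csv")
  write_artifact_masks(once, f)
  audit <- read.csv(f)
  expect_equal(sum(audit$channel == "MABP"), sum(masks$MABP$flags))

  # alternative order: denoise after synchronization
  alt <- preprocess_recording(rec, cfg, denoise_first = FALSE)
  expect_true(any(grepl("post-sync", attr(alt, "preprocess_log"))))
  expect_equal(length(alt$channels$HbD), length(once$channels$HbD))
})
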