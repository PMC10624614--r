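test_that("cwt_morlet: zero signal, linearity, peak localization", {
  # zero signal -> all coefficients zero
  W0 <- cwt_morlet(rep(0, 512), dt = 1)
  expect_true(all(abs(W0$coefficients) == 0))

  # linearity (normalization disabled): cwt(3x) = 3 cwt(x)
  set.seed(21)
  x <- rnorm(1024)
  Wa <- cwt_morlet(x, 1, normalize = FALSE)
  Wb <- cwt_morlet(3 * x, 1, normalize = FALSE)
  expect_lt(max(abs(Wb$coefficients - 3 * Wa$coefficients)), 1e-9)

  # 0.01 Hz tone, 2 h at 1 Hz: power-peak scale within one sub-octave of
  # the periodogram peak
  tt <- 0:7199
  W <- cwt_morlet(sin(2 * pi * 0.01 * tt), 1)
  f_peak <- W$freqs[which.max(rowMeans(abs(W$coefficients) ^ 2))]
  P <- abs(fft(sin(2 * pi * 0.01 * tt))) ^ 2
  f_axis <- (0:7199) / 7200
  f_oracle <- f_axis[which.max(P[1:3600])]
  expect_lt(abs(log2(f_peak / f_oracle)), 1 / 12 + 1e-9)

  # grid invariants
  expect_true(all(diff(W$freqs) < 0))
  expect_length(W$coi_min_freq, W$n)
  expect_error(cwt_morlet(rnorm(512), 1, f_range = c(0.01, 0.7)), "Nyquist")
})

test_that("cross_spectrum identities", {
  set.seed(22)
  x <- rnorm(600)
  y <- rnorm(600)
  Wx <- cwt_morlet(x, 1)
  Wy <- cwt_morlet(y, 1)
  self <- cross_spectrum(Wx, Wx)
  expect_lt(max(abs(Im(self))), 1e-12 * max(abs(self)))

  Wneg <- Wx
  Wneg$coefficients <- -Wx$coefficients
  anti <- cross_spectrum(Wx, Wneg)
  ph <- abs(Arg(anti[abs(anti) > 1e-10 * max(abs(anti))]))
  expect_lt(max(abs(ph - pi)), 1e-9)

  cr <- cross_spectrum(Wx, Wy)
  expect_equal(abs(cr), abs(Wx$coefficients) * abs(Wy$coefficients),
               tolerance = 1e-12)
  Wshort <- cwt_morlet(rnorm(500), 1)
  expect_error(cross_spectrum(Wx, Wshort), "grids")
})

test_that("smooth_map preserves constants, is linear, conserves impulse mass", {
  sc <- 4 * 2 ^ (seq(0, 3, by = 1 / 12))
  n <- 400
  C <- matrix(2.5, length(sc), n)
  expect_lt(max(abs(smooth_map(C, sc, 1) - 2.5)), 1e-12)

  set.seed(23)
  M1 <- matrix(rnorm(length(sc) * n), length(sc), n)
  M2 <- matrix(rnorm(length(sc) * n), length(sc), n)
  lhs <- smooth_map(2 * M1 + M2, sc, 1)
  rhs <- 2 * smooth_map(M1, sc, 1) + smooth_map(M2, sc, 1)
  expect_lt(max(abs(lhs - rhs)), 1e-10)

  # delta impulse away from edges: smoothed mass conserved within 1%.
  # kernel-sum oracle: an interior kernel sums to 1 by construction, so the
  # map total must be preserved.
  D <- matrix(0, length(sc), n)
  D[20, n %/% 2] <- 1
  S <- smooth_map(D, sc, 1)
  expect_equal(sum(S), 1, tolerance = 0.01)
})

test_that("coherence is 1 for identical signals and degenerate without smoothing", {
  set.seed(24)
  x <- rnorm(2048)
  W <- cwt_morlet(x, 1)
  coh <- wavelet_coherence(W, W)
  inb <- W$freqs >= 0.003 & W$freqs <= 0.05
  coi_ok <- outer(W$freqs[inb], W$coi_min_freq, `>=`)
  expect_gt(min(coh[inb, ][coi_ok]), 1 - 1e-6)

  # guard: without smoothing, coherence degenerates to 1 everywhere on
  # arbitrary independent inputs -- documents why smoothing is mandatory
  y <- rnorm(2048)
  Wy <- cwt_morlet(y, 1)
  coh_raw <- wavelet_coherence(W, Wy, smooth = FALSE)
  expect_gt(min(coh_raw[is.finite(coh_raw) & coh_raw > 0]), 1 - 1e-6)
  expect_lt(max(coh_raw), 1 + 1e-9)

  # two equal-frequency noiseless sinusoids, any phase: band coherence
  # over powered cells >= 0.99
  tt <- 0:7199
  for (ph in c(0.4, 2.0)) {
    Wa <- cwt_morlet(sin(2 * pi * 0.01 * tt), 1)
    Wb <- cwt_morlet(sin(2 * pi * 0.01 * tt + ph), 1)
    pr <- suppressWarnings(pair_indices(Wa, Wb))
    expect_gt(pr$band_mean_coherence, 0.99)
  }
})

test_that("semblance encodes phase alignment", {
  set.seed(25)
  x <- rnorm(2048)
  W <- cwt_morlet(x, 1)
  s_self <- wavelet_semblance(W, W)
  expect_true(all(abs(s_self[is.finite(s_self)] - 1) < 1e-9))

  Wneg <- cwt_morlet(-x, 1)
  s_anti <- wavelet_semblance(W, Wneg)
  expect_true(all(abs(s_anti[is.finite(s_anti)] + 1) < 1e-9))

  # quarter-period lag at 0.01 Hz -> semblance ~ 0 at the 0.01 Hz scale
  tt <- 0:7199
  Wa <- cwt_morlet(sin(2 * pi * 0.01 * tt), 1)
  Wb <- cwt_morlet(sin(2 * pi * 0.01 * (tt - 25)), 1)
  s <- wavelet_semblance(Wa, Wb)
  row <- which.min(abs(Wa$freqs - 0.01))
  mid <- s[row, 1000:6200]
  expect_lt(max(abs(mid[is.finite(mid)])), 0.05)
})

test_that("band_epoch_mean pools valid in-band cells inside the COI", {
  set.seed(26)
  W <- cwt_morlet(rnorm(2048), 1)
  ones <- matrix(1, length(W$scales), W$n)
  m <- band_epoch_mean(ones, W, c(0.003, 0.05))
  expect_equal(as.numeric(m), 1)
  expect_gt(attr(m, "valid_fraction"), 0)
  expect_lte(attr(m, "valid_fraction"), 1)

  # half +1 / half -1 -> 0
  half <- ones
  half[, seq(2, W$n, by = 2)] <- -1
  m2 <- band_epoch_mean(half, W, c(0.003, 0.05))
  expect_lt(abs(as.numeric(m2)), 0.02)

  expect_error(band_epoch_mean(ones, W, c(0.4, 0.45)), "band")

  # alternative averaging order agrees on a constant map and stays close
  # on random maps (they differ only through per-scale COI cell counts)
  expect_equal(as.numeric(band_epoch_mean(ones, W, average = "scale_then_time")), 1)
  set.seed(28)
  M <- matrix(rnorm(length(W$scales) * W$n, 0.3, 0.2), length(W$scales), W$n)
  a <- as.numeric(band_epoch_mean(M, W))
  b <- as.numeric(band_epoch_mean(M, W, average = "scale_then_time"))
  expect_lt(abs(a - b), 0.05)
})

test_that("semblance exponent sharpens the index but keeps the sign", {
  set.seed(29)
  Wx <- cwt_morlet(rnorm(1024), 1)
  Wy <- cwt_morlet(rnorm(1024), 1)
  s1 <- wavelet_semblance(Wx, Wy)
  s3 <- wavelet_semblance(Wx, Wy, exponent = 3)
  expect_equal(s3, s1 ^ 3, tolerance = 1e-12)
  expect_error(wavelet_semblance(Wx, Wy, exponent = 2), "odd")
})

test_that("pair index maps stay inside their ranges", {
  set.seed(27)
  for (i in 1:5) {
    Wa <- cwt_morlet(rnorm(1200) + 0.5 * sin(2 * pi * 0.01 * (1:1200)), 1)
    Wb <- cwt_morlet(rnorm(1200), 1)
    pr <- pair_indices(Wa, Wb)
    expect_true(all(pr$semblance_map[is.finite(pr$semblance_map)] >= -1))
    expect_true(all(pr$semblance_map[is.finite(pr$semblance_map)] <= 1))
    expect_true(all(pr$coherence_map >= 0 & pr$coherence_map <= 1))
    expect_gte(pr$band_mean_semblance, -1)
    expect_lte(pr$band_mean_semblance, 1)
    expect_gte(pr$band_mean_coherence, 0)
    expect_lte(pr$band_mean_coherence, 1)
  }
})
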