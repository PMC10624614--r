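# Independent oracles. Each reimplements the quantity under test from its
# textbook definition with a different code path from the package, so
# implementation and check never share code.

# --- analytic-signal phase oracle -------------------------------------------
# Instantaneous phase via the discrete Hilbert transform (analytic signal),
# after brickwall band-filtering. Used to verify the generator's imposed
# phase lag without any wavelet machinery.
oracle_mean_phase_diff <- function(x, y, fs, band) {
  bandpass <- function(v) {
    n <- length(v)
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * fs / n
    vf <- stats::fft(v)
    vf[!(abs(f) >= band[1] & abs(f) <= band[2])] <- 0
    Re(stats::fft(vf, inverse = TRUE)) / n
  }
  analytic <- function(v) {
    n <- length(v)
    vf <- stats::fft(v)
    h <- numeric(n)
    h[1] <- 1
    if (n %% 2 == 0) {
      h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
    } else h[2:((n + 1) / 2)] <- 2
    stats::fft(vf * h, inverse = TRUE) / n
  }
  ax <- analytic(bandpass(x))
  ay <- analytic(bandpass(y))
  # circular mean of the phase difference, amplitude weighted
  Arg(sum(ax * Conj(ay)))
}

# --- brute-force wavelet coherence oracle -----------------------------------
# Textbook implementation written independently of the package: explicit
# daughter-wavelet construction per scale, smoothing by stats::convolve
# with explicitly computed edge weights, plain per-row loops. Returns a
# function of (x, y) so the scale-grid constants are computed once for a
# Monte-Carlo study.
oracle_coherence_factory <- function(n, fs, band = c(0.003, 0.05),
                                     omega0 = 6, voices = 12) {
  dt <- 1 / fs
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  # band rows plus margin rows feeding the cross-scale boxcar
  margin <- 2 ^ (4 / voices)
  f_hi <- band[2] * margin
  nsc <- ceiling(log2(f_hi / (band[1] / margin)) * voices) + 1
  freqs <- f_hi / 2 ^ ((seq_len(nsc) - 1) / voices)
  scales <- 1 / (ff * freqs)

  np <- 2 ^ ceiling(log2(n))
  w <- 2 * pi * seq(0, np - 1) / (np * dt)
  w[w > pi / dt] <- w[w > pi / dt] - 2 * pi / dt
  daughters <- lapply(scales, function(s)
    ifelse(w > 0, pi^(-0.25) * sqrt(2 * pi * s / dt) *
             exp(-0.5 * (s * w - omega0)^2), 0))
  kernels <- lapply(scales, function(s) {
    half <- max(1, ceiling(3 * s / dt))
    g <- exp(-((-half:half) * dt)^2 / (2 * s^2))
    g / sum(g)
  })
  # linear convolution via explicit zero-padding to a power of two
  # (stats::convolve picks pathological FFT lengths for these sizes);
  # scales sharing a padded length are batched through one mvfft pair
  kfft <- lapply(kernels, function(g) {
    np2 <- 2 ^ ceiling(log2(n + length(g)))
    list(np2 = np2, gf = stats::fft(c(g, rep(0, np2 - length(g)))),
         idx = ((length(g) - 1) / 2 + 1):((length(g) - 1) / 2 + n))
  })
  conv_c <- function(v, j) {
    kf <- kfft[[j]]
    vf <- stats::fft(c(v, rep(0 + 0i, kf$np2 - n)))
    (stats::fft(vf * kf$gf, inverse = TRUE) / kf$np2)[kf$idx]
  }
  # edge weights: how much kernel mass falls inside the record
  wts <- lapply(seq_along(kernels), function(j)
    Re(conv_c(rep(1 + 0i, n), j)))
  d <- pmin(seq_len(n) - 1, n - seq_len(n)) * dt
  coi_min <- ifelse(d > 0, sqrt(2) / (ff * d), Inf)
  rows <- which(freqs >= band[1] & freqs <= band[2])
  coi_ok <- outer(freqs[rows], coi_min, `>=`)
  m <- max(1, round(0.6 * voices))
  bhalf <- m %/% 2

  dmat <- do.call(cbind, daughters)   # np x nsc, batched inverse transform

  function(x, y) {
    x <- (x - mean(x)) / sd(x)
    y <- (y - mean(y)) / sd(y)
    xf <- stats::fft(c(x, rep(0, np - n)))
    yf <- stats::fft(c(y, rep(0, np - n)))
    Wxm <- stats::mvfft(dmat * xf, inverse = TRUE)[seq_len(n), , drop = FALSE] / np
    Wym <- stats::mvfft(dmat * yf, inverse = TRUE)[seq_len(n), , drop = FALSE] / np
    Sc <- matrix(0 + 0i, nsc, n)
    Sx <- matrix(0, nsc, n)
    Sy <- matrix(0, nsc, n)
    for (j in seq_len(nsc)) {
      Wx <- Wxm[, j]
      Wy <- Wym[, j]
      Sc[j, ] <- conv_c(Wx * Conj(Wy) / scales[j], j) / wts[[j]]
      # the two real auto-power rows share one complex transform: their
      # linear convolutions with a real kernel are themselves real
      pp <- conv_c(complex(real = abs(Wx)^2, imaginary = abs(Wy)^2) /
                     scales[j], j)
      Sx[j, ] <- Re(pp)
      Sy[j, ] <- Im(pp)
    }
    for (j in seq_len(nsc)) {
      Sx[j, ] <- Sx[j, ] / wts[[j]]
      Sy[j, ] <- Sy[j, ] / wts[[j]]
    }
    boxcar <- function(M) {
      out <- M
      for (j in seq_len(nsc)) {
        lo <- max(1, j - bhalf); hi <- min(nsc, j + bhalf)
        out[j, ] <- colMeans(M[lo:hi, , drop = FALSE])
      }
      out
    }
    coh <- abs(boxcar(Sc))^2 / (boxcar(Sx) * boxcar(Sy))
    mean(coh[rows, ][coi_ok])
  }
}

# --- local polynomial repair oracle -----------------------------------------
# Reconstruction error bound for spline gap repair: fit a cubic through the
# nearest clean neighbours of each gap and measure its own error.
oracle_polyfit_error <- function(times, values, bad_idx) {
  errs <- vapply(bad_idx, function(i) {
    good <- setdiff(order(abs(times - times[i]))[1:12], bad_idx)
    good <- good[1:8]
    fit <- lm(v ~ poly(t, 3), data.frame(t = times[good], v = values[good]))
    abs(predict(fit, data.frame(t = times[i])) - values[i])
  }, 0)
  max(errs)
}

# --- periodogram band power -------------------------------------------------
oracle_band_power <- function(x, fs, band) {
  n <- length(x)
  P <- abs(stats::fft(x - mean(x)))^2
  f <- (0:(n - 1)) * fs / n
  sum(P[f >= band[1] & f <= band[2]])
}
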