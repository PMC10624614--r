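#' Continuous Morlet wavelet transform
#'
#' Transforms a uniformly sampled signal with the analytic Morlet wavelet
#' (central frequency `omega0`, default 6), on a logarithmic scale grid with
#' `voices_per_octave` voices spanning `f_range`. The signal is mean-removed
#' and variance-normalized (switchable), zero-padded to the next power of
#' two to contain wraparound, and transformed in the frequency domain; the
#' cone of influence (COI) is derived from the e-folding time `sqrt(2)*scale`
#' of the wavelet envelope and stored as the minimum trustworthy frequency at
#' each time point.
#'
#' @param x Numeric signal, uniformly sampled, finite.
#' @param dt Sampling interval in seconds.
#' @param f_range Length-2 numeric `(f_min, f_max)` Hz the scale grid must
#'   cover. The default spans half the slow-wave band floor to twice its
#'   ceiling, giving the band-mean machinery a one-octave smoothing margin.
#' @param omega0 Morlet nondimensional central frequency.
#' @param voices_per_octave Scales per octave.
#' @param normalize Remove mean and scale to unit variance first. Disable
#'   only for linearity checks; the reactivity indices are amplitude
#'   invariant either way.
#' @return An object of class `sw_cwt`: complex `coefficients`
#'   (scales x time), `scales` (s), `freqs` (Hz, decreasing with scale),
#'   `coi_min_freq` (Hz per time point), `dt`, `n`, `omega0`.
#' @export
cwt_morlet <- function(x, dt, f_range = c(0.5 * 0.003, 2 * 0.05),
                       omega0 = 6, voices_per_octave = 12L,
                       normalize = TRUE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L) sw_data_error("signal too short for CWT")
  if (!all(is.finite(x))) sw_data_error("CWT input must be finite (repair masks first)")
  if (!is.finite(dt) || dt <= 0) sw_config_error("dt must be positive")
  f_nyq <- 1 / (2 * dt)
  if (f_range[2L] > f_nyq + 1e-12)
    sw_config_error("requested frequency range exceeds Nyquist")

  if (normalize) {
    x <- x - mean(x)
    s <- stats::sd(x)
    if (s > 0) x <- x / s
  }

  ff <- fourier_factor(omega0)            # period = ff * scale
  s_min <- 1 / (ff * f_range[2L])
  s_max <- 1 / (ff * f_range[1L])
  dj <- 1 / voices_per_octave
  n_sc <- max(1L, ceiling(log2(s_max / s_min) / dj)) + 1L
  scales <- s_min * 2 ^ ((seq_len(n_sc) - 1L) * dj)
  freqs <- 1 / (ff * scales)

  npad <- 2 ^ ceiling(log2(n))            # zero-pad to next power of two
  xp <- c(x, rep(0, npad - n))
  xf <- stats::fft(xp)
  k <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1)) # FFT bin ordering
  w <- 2 * pi * k / (npad * dt)

  norm_base <- pi ^ (-0.25)
  pos <- which(w > 0)
  # build all daughters, batch the inverse transforms with mvfft
  prod <- matrix(0 + 0i, nrow = npad, ncol = n_sc)
  for (j in seq_len(n_sc)) {
    s <- scales[j]
    psi <- norm_base * sqrt(2 * pi * s / dt) *
      exp(-0.5 * (s * w[pos] - omega0) ^ 2)
    prod[pos, j] <- xf[pos] * psi
  }
  W <- t(stats::mvfft(prod, inverse = TRUE)[seq_len(n), , drop = FALSE]) / npad

  # distance to nearest edge in seconds; trustworthy scales satisfy
  # sqrt(2) * scale <= distance, i.e. freq >= sqrt(2) / (ff * distance)
  d <- pmin(seq_len(n) - 1L, n - seq_len(n)) * dt
  coi_min_freq <- ifelse(d > 0, sqrt(2) / (ff * d), Inf)

  structure(
    list(coefficients = W, scales = scales, freqs = freqs,
         coi_min_freq = coi_min_freq, dt = dt, n = n, omega0 = omega0,
         voices_per_octave = as.integer(voices_per_octave)),
    class = "sw_cwt")
}

# Morlet scale <-> Fourier period conversion factor.
fourier_factor <- function(omega0) 4 * pi / (omega0 + sqrt(2 + omega0 ^ 2))

#' @export
print.sw_cwt <- function(x, ...) {
  cat(sprintf("<sw_cwt> %d scales (%.4g-%.4g Hz) x %d samples, dt=%.3g s, omega0=%g\n",
              length(x$scales), min(x$freqs), max(x$freqs), x$n, x$dt, x$omega0))
  invisible(x)
}

check_same_grid <- function(Wx, Wy) {
  if (!inherits(Wx, "sw_cwt") || !inherits(Wy, "sw_cwt"))
    sw_data_error("expected sw_cwt objects")
  if (Wx$n != Wy$n || length(Wx$scales) != length(Wy$scales) ||
      abs(Wx$dt - Wy$dt) > 1e-12 ||
      max(abs(Wx$scales - Wy$scales)) > 1e-9)
    sw_data_error("wavelet decompositions are on different grids")
}

#' Cross-wavelet spectrum
#'
#' Elementwise `Wx * Conj(Wy)`. Its modulus is the cross power and its
#' argument the instantaneous phase difference between the two signals.
#'
#' @param Wx,Wy [cwt_morlet()] decompositions on the same grid.
#' @return Complex matrix (scales x time).
#' @export
cross_spectrum <- function(Wx, Wy) {
  check_same_grid(Wx, Wy)
  Wx$coefficients * Conj(Wy$coefficients)
}

#' Smooth a time-scale map
#'
#' The smoothing operator that makes wavelet coherence non-degenerate:
#' scale-dependent Gaussian smoothing in time (SD equal to the scale)
#' followed by a boxcar across scales spanning the Morlet decorrelation
#' scale of 0.6 octaves. The operator is linear and preserves constants
#' (kernels are renormalized at the edges).
#'
#' @param map Numeric or complex matrix (scales x time).
#' @param scales Scale vector in seconds, one per row.
#' @param dt Sampling interval, seconds.
#' @param voices_per_octave Scale-grid density (sets the boxcar width in
#'   rows).
#' @return Smoothed matrix of the same shape.
#' @export
smooth_map <- function(map, scales, dt, voices_per_octave = 12L) {
  smooth_maps(list(map), scales, dt, voices_per_octave)[[1L]]
}

# Smooth several maps that share one grid, amortizing kernel transforms
# across maps (hot path of coherence). Real map pairs are packed into one
# complex FFT; the edge renormalizer is computed in closed form.
smooth_maps <- function(maps, scales, dt, voices_per_octave = 12L) {
  n <- ncol(maps[[1L]])
  for (m in maps)
    if (nrow(m) != length(scales) || ncol(m) != n)
      sw_data_error("map dimensions must match scales/time grid")
  out <- maps
  is_cplx <- vapply(maps, is.complex, TRUE)
  re_idx <- which(!is_cplx)
  for (j in seq_along(scales)) {
    s <- scales[j]
    half <- max(1L, ceiling(3 * s / dt))
    g <- exp(-((0:half) * dt) ^ 2 / (2 * s ^ 2))   # right half incl. centre
    g <- g / (2 * sum(g) - g[1L])
    npad <- stats::nextn(n + 2L * half + 1L, 2)
    # kernel laid out circularly, centre at index 1 -> real symmetric FFT
    gv <- numeric(npad)
    gv[1L:(half + 1L)] <- g
    gv[npad - (1L:half) + 1L] <- g[2L:(half + 1L)]
    gf <- Re(stats::fft(gv))
    # closed-form edge renormalizer: mass of the kernel inside [1, n]
    cg <- cumsum(c(rev(g[-1L]), g))                # cdf over offsets -half..half
    i <- seq_len(n)
    den <- cg[pmin(half, n - i) + half + 1L] -
      c(0, cg)[pmax(-half, 1L - i) + half + 1L]
    conv1 <- function(v) {
      vf <- stats::fft(c(v, rep(0 + 0i, npad - n)))
      stats::fft(vf * gf, inverse = TRUE)[seq_len(n)] / npad
    }
    # complex maps individually; real maps two at a time, packed
    for (q in which(is_cplx))
      out[[q]][j, ] <- conv1(out[[q]][j, ]) / den
    q <- 1L
    while (q <= length(re_idx)) {
      a <- re_idx[q]
      b <- if (q + 1L <= length(re_idx)) re_idx[q + 1L] else NA_integer_
      v <- if (is.na(b)) complex(real = out[[a]][j, ], imaginary = 0)
           else complex(real = out[[a]][j, ], imaginary = out[[b]][j, ])
      r <- conv1(v)
      out[[a]][j, ] <- Re(r) / den
      if (!is.na(b)) out[[b]][j, ] <- Im(r) / den
      q <- q + 2L
    }
  }
  # scale direction: boxcar over ~0.6 octave of rows, edge-renormalized
  m <- max(1L, round(0.6 * voices_per_octave))
  if (m > 1L && length(scales) > 1L) {
    half <- m %/% 2L
    for (q in seq_along(out)) {
      sm <- out[[q]]
      for (j in seq_along(scales)) {
        lo <- max(1L, j - half)
        hi <- min(length(scales), j + half)
        sm[j, ] <- colMeans(out[[q]][lo:hi, , drop = FALSE])
      }
      out[[q]] <- sm
    }
  }
  out
}

#' Wavelet coherence
#'
#' Squared modulus of the smoothed, scale-normalized cross-spectrum over the
#' product of the smoothed auto-spectra; values in [0, 1]. Without the
#' smoothing step the quantity is identically 1 (the classic degeneracy),
#' which the `smooth` argument exposes for documentation tests.
#'
#' @param Wx,Wy Decompositions on a common grid.
#' @param smooth Apply the [smooth_map()] operator (default). `FALSE`
#'   reproduces the degenerate unsmoothed estimator.
#' @return Numeric matrix in [0, 1].
#' @export
wavelet_coherence <- function(Wx, Wy, smooth = TRUE) {
  check_same_grid(Wx, Wy)
  inv_s <- 1 / Wx$scales
  cross <- sweep(cross_spectrum(Wx, Wy), 1L, inv_s, `*`)
  px <- sweep(abs(Wx$coefficients) ^ 2, 1L, inv_s, `*`)
  py <- sweep(abs(Wy$coefficients) ^ 2, 1L, inv_s, `*`)
  if (smooth) {
    sm <- smooth_maps(list(cross, px, py), Wx$scales, Wx$dt,
                      Wx$voices_per_octave)
    cross <- sm[[1L]]; px <- sm[[2L]]; py <- sm[[3L]]
  }
  den <- px * py
  # absolute guard: only genuinely zero-power cells are undefined
  zero <- !is.finite(den) | den < .Machine$double.xmin * 1e10
  coh <- abs(cross) ^ 2 / pmax(den, .Machine$double.xmin)
  if (any(zero)) {
    warning("zero-power region in coherence; defined as 0 there")
    coh[zero] <- 0
  }
  pmin(pmax(coh, 0), 1)
}

#' Wavelet semblance
#'
#' Cosine of the instantaneous cross-wavelet phase difference: +1 where the
#' signals oscillate in phase, -1 in anti-phase, 0 in quadrature. Computed
#' from the unsmoothed cross-spectrum. Cells where either signal has
#' (numerically) zero amplitude have no defined phase; they are returned as
#' `NaN` and excluded from band means.
#'
#' @param Wx,Wy Decompositions on a common grid.
#' @param exponent Odd exponent on the cosine (semblance = cos^n of the
#'   phase difference); higher odd powers sharpen the index around exact
#'   phase alignment. Default 1.
#' @return Numeric matrix in [-1, 1] with `NaN` at zero-amplitude cells.
#' @export
wavelet_semblance <- function(Wx, Wy, exponent = 1) {
  check_same_grid(Wx, Wy)
  if (exponent < 1 || exponent %% 2 != 1)
    sw_config_error("semblance exponent must be a positive odd integer")
  cross <- cross_spectrum(Wx, Wy)
  amp <- abs(cross)
  semb <- Re(cross) / amp          # cos(Arg(z)) = Re(z) / |z|
  semb[amp <= max(amp) * 1e-12] <- NaN
  if (exponent != 1) semb <- semb ^ exponent
  pmin(pmax(semb, -1), 1)
}

#' Band- and epoch-mean of a time-scale map
#'
#' Unweighted mean over all grid cells whose equivalent Fourier frequency
#' lies in `band_hz`, that sit inside the cone of influence, and that are
#' valid (finite and not vetoed by `validity`). The attached
#' `valid_fraction` is the share of band-grid cells that entered the mean.
#'
#' @param map Numeric matrix (scales x time).
#' @param dec The [cwt_morlet()] decomposition supplying frequencies and COI.
#' @param band_hz Length-2 numeric band `(f_low, f_high)`.
#' @param validity Optional logical matrix vetoing cells.
#' @param average `"pooled"` (default): one mean over all valid cells;
#'   `"scale_then_time"`: average each scale row over time first, then
#'   average the row means. The two differ only when the COI leaves
#'   different numbers of valid cells per scale.
#' @return Scalar mean with attribute `valid_fraction`.
#' @export
band_epoch_mean <- function(map, dec, band_hz = c(0.003, 0.05),
                            validity = NULL,
                            average = c("pooled", "scale_then_time")) {
  average <- match.arg(average)
  rows <- which(dec$freqs >= band_hz[1L] & dec$freqs <= band_hz[2L])
  if (!length(rows))
    sw_data_error("analysis band does not intersect the scale grid")
  sub <- map[rows, , drop = FALSE]
  ok <- is.finite(sub)
  # inside COI: cell frequency at or above the per-time minimum valid freq
  coi_ok <- outer(dec$freqs[rows], dec$coi_min_freq, `>=`)
  ok <- ok & coi_ok
  if (!is.null(validity)) ok <- ok & validity[rows, , drop = FALSE]
  if (!any(ok)) sw_data_error("no valid cells in band/COI for mean")
  out <- if (average == "pooled") {
    mean(sub[ok])
  } else {
    rm <- vapply(seq_len(nrow(sub)), function(j) {
      o <- ok[j, ]
      if (any(o)) mean(sub[j, o]) else NA_real_
    }, 0)
    mean(rm, na.rm = TRUE)
  }
  attr(out, "valid_fraction") <- mean(ok)
  out
}

#' Semblance and coherence maps plus band means for one channel pair
#'
#' Bundles the full pairwise computation: cross-wavelet semblance and
#' smoothed coherence maps over the time-scale plane, and their pooled
#' band/epoch means inside the cone of influence.
#'
#' @param Wx,Wy Decompositions of the two channels on a common grid.
#' @param pair Character vector of the two channel names (labels only).
#' @param band_hz Analysis band.
#' @param compute Which indices to compute; dropping `"coherence"` skips
#'   the smoothing stage (substantially cheaper in simulation studies).
#' @return An object of class `sw_pair_index` with elements
#'   `semblance_map`, `coherence_map`, `band_mean_semblance`,
#'   `band_mean_coherence`, `valid_fraction`, `pair`, `band_hz`.
#' @export
pair_indices <- function(Wx, Wy, pair = c("x", "y"),
                         band_hz = c(0.003, 0.05),
                         compute = c("semblance", "coherence")) {
  semb <- wavelet_semblance(Wx, Wy)
  ms <- band_epoch_mean(semb, Wx, band_hz)
  if ("coherence" %in% compute) {
    coh <- wavelet_coherence(Wx, Wy)
    mc <- band_epoch_mean(coh, Wx, band_hz, validity = is.finite(semb))
  } else {
    coh <- NULL
    mc <- NA_real_
  }
  structure(
    list(pair = as.character(pair), band_hz = band_hz,
         semblance_map = semb, coherence_map = coh,
         band_mean_semblance = as.numeric(ms),
         band_mean_coherence = as.numeric(mc),
         valid_fraction = attr(ms, "valid_fraction"),
         freqs = Wx$freqs, times = (seq_len(Wx$n) - 1L) * Wx$dt,
         coi_min_freq = Wx$coi_min_freq),
    class = "sw_pair_index")
}

#' @export
print.sw_pair_index <- function(x, ...) {
  cat(sprintf(
    pair_label(x$pair), x$band_hz[1L], x$band_hz[2L],
    x$band_mean_semblance, x$band_mean_coherence, 100 * x$valid_fraction))
  invisible(x)
}
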