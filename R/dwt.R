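# Periodic discrete wavelet transform with the 4-tap Daubechies filter
# (two vanishing moments), used only by the denoiser. Hand-rolled because
# no DWT package is available in the dependency budget; perfect
# reconstruction is property-tested.

D4_H <- c(1 + sqrt(3), 3 + sqrt(3), 3 - sqrt(3), 1 - sqrt(3)) / (4 * sqrt(2))
D4_G <- c(D4_H[4L], -D4_H[3L], D4_H[2L], -D4_H[1L])

dwt_step <- function(x) {
  n <- length(x)
  stopifnot(n %% 2L == 0L)
  idx0 <- 2L * (seq_len(n %/% 2L) - 1L)          # 0-based start of each pair
  a <- numeric(n %/% 2L); d <- numeric(n %/% 2L)
  for (m in 0:3) {
    xi <- x[(idx0 + m) %% n + 1L]
    a <- a + D4_H[m + 1L] * xi
    d <- d + D4_G[m + 1L] * xi
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  n <- 2L * length(a)
  x <- numeric(n)
  idx0 <- 2L * (seq_along(a) - 1L)
  # for fixed m the positions (2k + m) mod n are all distinct, so a plain
  # indexed add per tap is a collision-free scatter
  for (m in 0:3) {
    pos <- (idx0 + m) %% n + 1L
    x[pos] <- x[pos] + D4_H[m + 1L] * a + D4_G[m + 1L] * d
  }
  x
}

# Full analysis to depth J: returns list(details = list(d1..dJ), approx = aJ)
dwt_periodic <- function(x, J) {
  details <- vector("list", J)
  a <- x
  for (j in seq_len(J)) {
    st <- dwt_step(a)
    details[[j]] <- st$d
    a <- st$a
  }
  list(details = details, approx = a)
}

idwt_periodic <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_along(dec$details)))
    a <- idwt_step(a, dec$details[[j]])
  a
}

#' Automatic wavelet denoising
#'
#' Discrete wavelet shrinkage tuned to remove high-frequency noise while
#' leaving slow-wave trend information untouched: a periodic 4-tap
#' Daubechies decomposition deep enough that the approximation band lies
#' below `f_low` (so the analysis band sits entirely in detail levels), a
#' noise estimate from the finest detail level
#' (`sigma = median(|d1|) / 0.6745`), and hard universal thresholding
#' (`sigma * sqrt(2 log n)`) of the detail coefficients only. Hard rather
#' than soft shrinkage is used because soft shrinkage biases every
#' supra-threshold in-band coefficient by the threshold and measurably
#' dents slow-wave band power; hard thresholding leaves surviving structure
#' untouched. The approximation is never modified and output length equals
#' input length.
#'
#' @param x Numeric signal or [sw_channel()] (masked samples must be
#'   repaired first).
#' @param fs Sampling rate in Hz (taken from the channel when `x` is one).
#' @param f_low Lower edge of the band that must be preserved, Hz.
#' @return Denoised object of the same type as `x`.
#' @export
wavelet_denoise <- function(x, fs = NULL, f_low = 0.003) {
  if (inherits(x, "sw_channel")) {
    if (any(!x$mask)) sw_data_error("repair masked samples before denoising")
    out <- x
    out$values <- wavelet_denoise(x$values, fs = x$native_rate, f_low = f_low)
    return(out)
  }
  x <- as.numeric(x)
  n <- length(x)
  if (is.null(fs) || !is.finite(fs) || fs <= 0)
    sw_config_error("wavelet_denoise needs a sampling rate")
  J <- max(1L, as.integer(ceiling(log2(fs / f_low))) - 1L)
  Jmax <- as.integer(floor(log2(n))) - 2L
  if (Jmax < 1L) sw_data_error("signal too short to denoise")
  J <- min(J, Jmax)
  block <- 2L ^ J
  npad <- as.integer(ceiling(n / block)) * block
  xp <- if (npad > n) c(x, rev(x)[seq_len(npad - n)]) else x  # reflect pad
  dec <- dwt_periodic(xp, J)
  sigma <- median(abs(dec$details[[1L]])) / 0.6745
  lambda <- sigma * sqrt(2 * log(npad))
  dec$details <- lapply(dec$details, function(d)
    ifelse(abs(d) > lambda, d, 0))
  y <- idwt_periodic(dec)
  y[seq_len(n)]
}
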