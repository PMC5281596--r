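#' 1/f background noise
#'
#' Generates coloured noise with power spectral density proportional to
#' `1/f^exponent`, by shaping a random-phase spectrum and inverse FFT. The
#' spectrum is flattened below `floor_hz` so the infra-slow end does not
#' dominate the variance, and the series is rescaled to the requested RMS.
#'
#' @param n number of samples.
#' @param rate sampling rate, Hz.
#' @param amplitude target RMS, microvolts.
#' @param exponent spectral exponent (1 = pink noise).
#' @param floor_hz frequency below which the spectrum is flat.
#' @return numeric vector of length `n`.
#' @export
oneoverf_noise <- function(n, rate, amplitude = 10, exponent = 1,
                           floor_hz = 0.1) {
  if (amplitude == 0) return(numeric(n))
  # synthesize at a 2-3-5-smooth length >= n (fast mixed-radix FFT), then
  # truncate: a stationary series stays stationary under truncation
  n_out <- n
  n <- stats::nextn(n, c(2L, 3L, 5L))
  nf <- n %/% 2L
  f <- (1:nf) * rate / n
  mag <- pmax(f, floor_hz)^(-exponent / 2)
  phase <- stats::runif(nf, 0, 2 * pi)
  pos <- mag * exp(1i * phase)
  spec <- complex(length.out = n)
  spec[2:(nf + 1L)] <- pos
  if (n %% 2L == 0L) {
    spec[nf + 1L] <- complex(real = mag[nf] * sign(cos(phase[nf])), imaginary = 0)
    if (nf > 1L) spec[n:(nf + 2L)] <- Conj(pos[1:(nf - 1L)])
  } else {
    spec[n:(nf + 2L)] <- Conj(pos)
  }
  x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n_out)] / n
  x <- x - mean(x)
  x / stats::sd(x) * amplitude
}

# Multichannel variant used by the forward model: synthesizes two
# independent channels per complex FFT (real and imaginary parts of a
# circularly-symmetric complex-Gaussian spectrum are independent
# realizations with the same 1/f power spectrum).
noise_channels <- function(n, nch, rate, amplitude, exponent, floor_hz = 0.1) {
  out <- matrix(0, n, nch)
  if (amplitude == 0 || nch == 0L) return(out)
  m <- stats::nextn(n, c(2L, 3L, 5L))
  k <- 0:(m - 1L)
  f <- pmin(k, m - k) * rate / m
  mag <- c(0, pmax(f[-1], floor_hz)^(-exponent / 2))
  for (j in seq(1L, nch, by = 2L)) {
    spec <- mag * complex(real = stats::rnorm(m), imaginary = stats::rnorm(m))
    x <- stats::fft(spec, inverse = TRUE)[seq_len(n)]
    re <- Re(x); im <- Im(x)
    out[, j] <- (re - mean(re)) / stats::sd(re) * amplitude
    if (j + 1L <= nch) out[, j + 1L] <- (im - mean(im)) / stats::sd(im) * amplitude
  }
  out
}
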