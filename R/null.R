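#' Simulate a noise-only subject difference wave
#'
#' Draws one subject-level, ROI-pooled difference potential containing no
#' change-related signal, with the noise statistics implied by the default
#' generator and preprocessing chain. A continuous 1/f noise stretch is
#' simulated per ROI channel, band-pass filtered, epoched and
#' baseline-corrected exactly as in the pipeline, pooled over the ROI's
#' channels, and scaled by `sqrt(1/n_deviant + 1/n_standard)` — the standard
#' error factor of a deviant-average minus opposite-standard-average
#' contrast built from that many independent epochs. This gives the exact
#' Gaussian-process distribution of a pipeline null difference wave under
#' the approximation that baseline-corrected epochs separated by at least
#' one inter-trial interval are independent, at a tiny fraction of the
#' simulation cost; it is the workhorse for empirical type-I-error studies
#' of the run criterion.
#'
#' @param profile a [group_profile()] (only its noise model is used).
#' @param n_deviant,n_standard epoch counts entering the two averages
#'   (defaults: 2 sequences x 50 deviants and 2 sequences x 200 standards).
#' @param n_roi_channels channels pooled into the ROI.
#' @param window an [epoch_window()].
#' @param spec a [filter_spec()].
#' @param rate sampling rate, Hz.
#' @param soa SOA assigned to the epoch (shifts the analysis axis).
#' @param seed RNG seed.
#' @return a `vmmn_series` on the analysis time axis.
#' @export
simulate_noise_difference_wave <- function(profile = group_profile("older"),
                                           n_deviant = 100, n_standard = 400,
                                           n_roi_channels = 2,
                                           window = epoch_window(),
                                           spec = filter_spec(),
                                           rate = 1000, soa = 0, seed = NULL) {
  step <- 1000 / rate
  n_samp <- as.integer(round((window$end - window$start) * rate / 1000)) + 1L
  times_acq <- window$start + (seq_len(n_samp) - 1L) * step
  pad <- as.integer(round(2000 * rate / 1000)) # settle margin on both sides
  n_total <- n_samp + 2L * pad
  bl_sel <- times_acq >= window$baseline[1] & times_acq <= window$baseline[2]
  scale <- sqrt(1 / n_deviant + 1 / n_standard)

  with_seed(seed, {
    flt <- design_filters(spec, rate)
    pooled <- numeric(n_samp)
    for (ch in seq_len(n_roi_channels)) {
      x <- oneoverf_noise(n_total, rate, profile$noise_amplitude,
                          profile$noise_exponent)
      x <- apply_bandpass(x, flt)
      ep <- x[(pad + 1L):(pad + n_samp)]
      pooled <- pooled + (ep - mean(ep[bl_sel]))
    }
    pooled <- pooled / n_roi_channels * scale
    structure(
      list(time = times_acq - soa, value = pooled, roi = "null"),
      class = "vmmn_series"
    )
  })
}
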