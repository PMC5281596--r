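#' Simulate a raw multichannel recording for one oddball sequence
#'
#' Forward model: every stimulus event contributes, for each component of the
#' group profile whose `applies` predicate holds, a Gaussian-windowed pulse
#' centred `peak_latency` ms after the locking fragment onset, scaled by the
#' component's per-channel topography gain; independent 1/f noise is then
#' added per channel. The vMMN component is inserted only for deviant events
#' whose SOA does not exceed the group's persistence limit for the deviant
#' category, which is what makes detection group- and SOA-dependent
#' downstream.
#'
#' The output is deterministic for a fixed `(schedule, profile, seed)`.
#'
#' @param schedule a [generate_schedule()] result.
#' @param profile a [group_profile()].
#' @param seed integer RNG seed for the noise.
#' @param channels channel labels to simulate; defaults to the full
#'   [default_montage()]. Restricting to the ROI channels makes large
#'   simulation studies considerably cheaper without changing the ROI-level
#'   analysis.
#' @return object of class `vmmn_recording`: `data` is a samples x channels
#'   matrix in microvolts with named columns, plus `sampling_rate`,
#'   `channel_labels` and the originating `schedule`.
#' @export
#' @examples
#' sch <- generate_schedule(session_config(), 0, "pseudo-letter", seed = 1)
#' rec <- generate_recording(sch, group_profile("young"), seed = 1,
#'                           channels = c("PO7", "PO8"))
#' dim(rec$data)
generate_recording <- function(schedule, profile, seed = NULL, channels = NULL) {
  stopifnot(inherits(schedule, "vmmn_schedule"), inherits(profile, "vmmn_profile"))
  channels <- channels %||% default_montage()
  rate <- schedule$config$sampling_rate

  for (comp in profile$components) {
    unknown <- setdiff(channels, names(comp$topography))
    if (length(unknown)) {
      stopf("component '%s' has no topography gain for channel(s): %s",
            comp$name, paste(unknown, collapse = ", "))
    }
  }

  events <- schedule$events
  total_ms <- max(events$onset_fragment2) + schedule$config$fragment_duration + 1000
  n <- ms_to_sample(total_ms, rate)
  t_ms <- (seq_len(n) - 1) * 1000 / rate

  clean <- matrix(0, nrow = n, ncol = length(channels),
                  dimnames = list(NULL, channels))
  for (comp in profile$components) {
    gains <- comp$topography[channels]
    if (all(gains == 0)) next
    centers <- component_centers(events, comp)
    if (!length(centers)) next
    shape <- numeric(n)
    half_support <- 4 * comp$width
    for (mu in centers) {
      i0 <- max(1L, ms_to_sample(mu - half_support, rate))
      i1 <- min(n, ms_to_sample(mu + half_support, rate))
      idx <- i0:i1
      shape[idx] <- shape[idx] +
        exp(-((t_ms[idx] - mu)^2) / (2 * comp$width^2))
    }
    clean <- clean + (comp$amplitude * shape) %o% gains
  }

  data <- with_seed(seed, {
    if (profile$noise_amplitude > 0) {
      clean + noise_channels(n, length(channels), rate,
                             profile$noise_amplitude, profile$noise_exponent)
    } else {
      clean
    }
  })
  colnames(data) <- channels

  out <- list(
    channel_labels = channels,
    sampling_rate = rate,
    data = data,
    schedule = schedule,
    group = profile$group
  )
  class(out) <- "vmmn_recording"
  out
}

# ms centers of a component's pulses over all events it applies to
component_centers <- function(events, comp) {
  keep <- vapply(
    seq_len(nrow(events)),
    function(i) isTRUE(comp$applies(events$role[i], events$category[i],
                                    events$soa[i])),
    logical(1)
  )
  if (!any(keep)) return(numeric(0))
  onset <- if (comp$lock == "fragment1") {
    events$onset_fragment1[keep]
  } else {
    events$onset_fragment2[keep]
  }
  onset + comp$peak_latency
}

#' @export
print.vmmn_recording <- function(x, ...) {
  cat(sprintf(
    "<vmmn_recording> %d channels x %d samples at %g Hz (%.1f s), group %s\n",
    ncol(x$data), nrow(x$data), x$sampling_rate,
    nrow(x$data) / x$sampling_rate, x$group
  ))
  invisible(x)
}
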