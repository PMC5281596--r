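#' Oddball session configuration
#'
#' Bundles the stimulus-sequence design parameters of the passive oddball
#' session. The defaults reproduce the study design this package emulates:
#' 250 stimulus pairs per sequence, deviant probability 0.2 split over two
#' variants per role (so each deviant variant has probability 0.1), fragment
#' pairs at stimulus onset asynchronies (SOA) of 0/30/50/70 ms with 30 ms
#' fragment duration, 600 +/- 50 ms inter-trial interval (onset-to-onset,
#' uniform jitter), 16 sequences per session (4 SOAs x 2 deviant categories
#' x 2 repetitions), and frame-thickening task events of 300 ms occurring
#' every 5-15 s.
#'
#' @param n_trials_per_sequence stimulus pairs per oddball sequence.
#' @param deviant_prob probability of a deviant; must lie in (0, 0.5) and
#'   `n_trials_per_sequence * deviant_prob` must be an integer (exact-count
#'   design).
#' @param n_variants_per_role number of physically different exemplars per
#'   role (standard/deviant).
#' @param soa_levels onset-to-onset interval between the two character
#'   fragments, ms, ascending; 0 means the whole character is shown at once.
#' @param fragment_duration duration of each fragment, ms.
#' @param iti_mean,iti_jitter inter-trial interval: onset-to-onset gap drawn
#'   uniformly from `iti_mean +/- iti_jitter` (ms).
#' @param n_sequences sequences per session; must equal
#'   `length(soa_levels) * 2 * repetitions` for an integer repetition count.
#' @param task_event_interval_range min/max gap between successive
#'   frame-thickening onsets, ms (uniform).
#' @param task_event_duration duration of the frame thickening, ms.
#' @param sampling_rate acquisition rate, Hz.
#' @return an object of class `vmmn_config` (a validated list).
#' @export
#' @examples
#' cfg <- session_config()
#' cfg$n_trials_per_sequence * cfg$deviant_prob  # 50 deviants per sequence
session_config <- function(n_trials_per_sequence = 250,
                           deviant_prob = 0.2,
                           n_variants_per_role = 2,
                           soa_levels = c(0, 30, 50, 70),
                           fragment_duration = 30,
                           iti_mean = 600,
                           iti_jitter = 50,
                           n_sequences = 16,
                           task_event_interval_range = c(5000, 15000),
                           task_event_duration = 300,
                           sampling_rate = 1000) {
  cfg <- list(
    n_trials_per_sequence = as.integer(n_trials_per_sequence),
    deviant_prob = deviant_prob,
    n_variants_per_role = as.integer(n_variants_per_role),
    soa_levels = as.numeric(soa_levels),
    fragment_duration = fragment_duration,
    iti_mean = iti_mean,
    iti_jitter = iti_jitter,
    n_sequences = as.integer(n_sequences),
    task_event_interval_range = as.numeric(task_event_interval_range),
    task_event_duration = task_event_duration,
    sampling_rate = sampling_rate
  )
  if (cfg$deviant_prob <= 0 || cfg$deviant_prob >= 0.5) {
    stopf("deviant_prob must lie in (0, 0.5), got %g", cfg$deviant_prob)
  }
  n_dev <- cfg$n_trials_per_sequence * cfg$deviant_prob
  if (abs(n_dev - round(n_dev)) > 1e-9) {
    stopf(
      "exact-count design requires an integral deviant count; %d x %g = %g",
      cfg$n_trials_per_sequence, cfg$deviant_prob, n_dev
    )
  }
  if (cfg$iti_jitter >= cfg$iti_mean) stopf("iti_jitter must be < iti_mean")
  if (is.unsorted(cfg$soa_levels, strictly = TRUE)) {
    stopf("soa_levels must be sorted ascending")
  }
  if (length(cfg$task_event_interval_range) != 2 ||
      diff(cfg$task_event_interval_range) < 0) {
    stopf("task_event_interval_range must be an increasing (min, max) pair")
  }
  class(cfg) <- "vmmn_config"
  cfg
}

#' @export
print.vmmn_config <- function(x, ...) {
  cat("<vmmn_config>\n")
  cat(sprintf(
    "  %d trials/sequence, deviant p = %g (%d variants/role)\n",
    x$n_trials_per_sequence, x$deviant_prob, x$n_variants_per_role
  ))
  cat(sprintf(
    "  SOA levels: %s ms; fragments %g ms; ITI %g +/- %g ms\n",
    paste(x$soa_levels, collapse = "/"), x$fragment_duration,
    x$iti_mean, x$iti_jitter
  ))
  cat(sprintf(
    "  %d sequences/session; sampling %g Hz\n",
    x$n_sequences, x$sampling_rate
  ))
  invisible(x)
}
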