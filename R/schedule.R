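#' Generate a constrained oddball trial schedule
#'
#' Produces one oddball sequence: an ordered list of stimulus events
#' (standard/deviant characters presented as fragment pairs) plus the
#' task-related frame-thickening events, under the design constraints of the
#' paradigm:
#'
#' * exactly `n_trials * deviant_prob` deviants, split equally (+/-1) over
#'   the variants of each role;
#' * at least two standards between successive deviants (and before the
#'   first deviant), so every deviant has a well-defined "last standard";
#' * inter-trial interval (onset-to-onset) uniform in `iti_mean +/- iti_jitter`;
#' * task events never overlap the presentation of a deviant nor of the last
#'   standard preceding it, and their sides are balanced (+/-1) across the
#'   sequence.
#'
#' All times are in ms from sequence start. For `soa > 0` the second fragment
#' starts `soa` ms after the first; at `soa = 0` the whole character is shown
#' at once and both onsets coincide.
#'
#' @param config a [session_config()].
#' @param soa stimulus onset asynchrony for this sequence; must be one of
#'   `config$soa_levels`.
#' @param deviant_category `"letter"` or `"pseudo-letter"`; the other
#'   category serves as standard.
#' @param sequence_id identifier stored with the schedule.
#' @param seed integer; fixed seed gives a byte-identical schedule.
#' @return object of class `vmmn_schedule`: list with `events` and
#'   `task_events` data frames plus design metadata.
#' @export
#' @examples
#' sch <- generate_schedule(session_config(), soa = 50,
#'                          deviant_category = "pseudo-letter", seed = 1)
#' table(sch$events$role)
generate_schedule <- function(config, soa, deviant_category = c("pseudo-letter", "letter"),
                              sequence_id = 1L, seed = NULL) {
  stopifnot(inherits(config, "vmmn_config"))
  deviant_category <- match.arg(deviant_category)
  if (!soa %in% config$soa_levels) {
    stopf("soa %g is not one of the configured levels (%s)",
          soa, paste(config$soa_levels, collapse = ", "))
  }
  n <- config$n_trials_per_sequence
  n_dev <- as.integer(round(n * config$deviant_prob))
  min_gap <- 3L # >= 2 standards between deviants, and before the first

  with_seed(seed, {
    events <- build_events(config, n, n_dev, min_gap, soa, deviant_category)
    task_events <- place_task_events(config, events)
    out <- list(
      sequence_id = sequence_id,
      soa = soa,
      deviant_category = deviant_category,
      standard_category = setdiff(c("letter", "pseudo-letter"), deviant_category),
      config = config,
      events = events,
      task_events = task_events
    )
    class(out) <- "vmmn_schedule"
    out
  })
}

build_events <- function(config, n, n_dev, min_gap, soa, deviant_category) {
  # Uniformly sample deviant positions with first position >= min_gap and
  # successive gaps >= min_gap, via the standard bijection onto unconstrained
  # combinations.
  slack <- n - (min_gap - 1L) * (n_dev - 1L) - (min_gap - 1L)
  if (slack < n_dev) {
    stopf("cannot place %d deviants with %d-trial spacing in %d trials",
          n_dev, min_gap, n)
  }
  base <- sort(sample.int(slack, n_dev))
  dev_pos <- base + (min_gap - 1L) * (seq_len(n_dev) - 1L) + (min_gap - 1L)

  role <- rep("standard", n)
  role[dev_pos] <- "deviant"
  category <- ifelse(role == "deviant", deviant_category,
                     setdiff(c("letter", "pseudo-letter"), deviant_category))

  variant <- integer(n)
  nv <- config$n_variants_per_role
  variant[dev_pos] <- sample(rep_len(seq_len(nv), n_dev))
  variant[-dev_pos] <- sample(rep_len(seq_len(nv), n - n_dev))

  iti <- stats::runif(n, config$iti_mean - config$iti_jitter,
                      config$iti_mean + config$iti_jitter)
  onset1 <- cumsum(iti)
  onset2 <- onset1 + soa

  data.frame(
    index = seq_len(n),
    onset_fragment1 = onset1,
    onset_fragment2 = onset2,
    role = role,
    category = category,
    variant = variant,
    fragmentation = sample.int(5L, n, replace = TRUE),
    soa = soa,
    stringsAsFactors = FALSE
  )
}

# Presentation spans (fragment on-screen intervals) of every deviant and of
# the last standard preceding it; task events must avoid all of them.
protected_spans <- function(events, fragment_duration) {
  dev_idx <- which(events$role == "deviant")
  idx <- c(dev_idx, dev_idx - 1L)
  idx <- idx[idx >= 1L]
  starts <- c(events$onset_fragment1[idx], events$onset_fragment2[idx])
  cbind(start = starts, end = starts + fragment_duration)
}

place_task_events <- function(config, events) {
  spans <- protected_spans(events, config$fragment_duration)
  dur <- config$task_event_duration
  lo <- config$task_event_interval_range[1]
  hi <- config$task_event_interval_range[2]
  seq_end <- max(events$onset_fragment2) + config$fragment_duration

  onsets <- numeric(0)
  t_prev <- 0
  repeat {
    placed <- FALSE
    for (try in seq_len(200L)) {
      cand <- t_prev + stats::runif(1, lo, hi)
      if (cand + dur > seq_end) {
        placed <- NA
        break
      }
      overlaps <- any(cand < spans[, "end"] & cand + dur > spans[, "start"])
      if (!overlaps) {
        onsets <- c(onsets, cand)
        t_prev <- cand
        placed <- TRUE
        break
      }
    }
    if (is.na(placed)) break
    if (!placed) {
      stopf("task-event placement infeasible: exclusion zones cover the sequence")
    }
  }

  n_task <- length(onsets)
  sides <- sample(rep_len(c("top", "bottom", "left", "right"), n_task))
  data.frame(
    onset = onsets,
    side = sides,
    duration = rep(dur, n_task),
    stringsAsFactors = FALSE
  )
}

#' @export
print.vmmn_schedule <- function(x, ...) {
  cat(sprintf(
    "<vmmn_schedule #%s> %d trials (%d deviant %s), SOA %g ms, %d task events\n",
    x$sequence_id, nrow(x$events), sum(x$events$role == "deviant"),
    x$deviant_category, x$soa, nrow(x$task_events)
  ))
  invisible(x)
}
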