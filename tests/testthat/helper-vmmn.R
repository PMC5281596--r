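# Shared fixtures and independent oracles, built in code at test time.

# minimal vmmn_series constructor
make_series <- function(value, time = seq(-100, 600), roi = "test") {
  structure(list(time = time, value = value, roi = roi),
            class = "vmmn_series")
}

# minimal vmmn_epochs constructor: arr is samples x channels x epochs
make_epochs <- function(arr, role = "deviant", category = "pseudo-letter",
                        variant = 1L, soa = 0, rate = 1000,
                        times = NULL) {
  n_ep <- dim(arr)[3]
  times <- times %||% seq(-100, by = 1000 / rate,
                          length.out = dim(arr)[1])
  rec_role <- rep_len(role, n_ep)
  rec_cat <- rep_len(category, n_ep)
  structure(list(
    data = arr,
    info = data.frame(
      epoch = seq_len(n_ep), role = rec_role, category = rec_cat,
      variant = rep_len(variant, n_ep), soa = soa,
      rejected = FALSE, reason = "", stringsAsFactors = FALSE
    ),
    times_acq = times,
    times_ana = times - soa,
    channels = dimnames(arr)[[2]] %||% paste0("ch", seq_len(dim(arr)[2])),
    sampling_rate = rate,
    window = list(start = min(times), end = max(times),
                  baseline = c(min(times), min(0, max(times)))),
    soa = soa
  ), class = "vmmn_epochs")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force run scanner: enumerates every candidate interval [i, j] and
# keeps those that are entirely significant, maximal, and long enough after
# clipping to the search window. Independent of the rle-based implementation.
oracle_find_runs <- function(p, tval, time, criterion) {
  n <- length(p)
  rate <- 1000 / stats::median(diff(time))
  min_samples <- as.integer(ceiling(criterion$min_run * rate / 1000))
  sig <- !is.na(p) & p < criterion$alpha
  if (!is.null(criterion$polarity) && criterion$polarity != "any") {
    sig <- sig & if (criterion$polarity == "negative") tval < 0 else tval > 0
  }
  w <- criterion$search_window
  found <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!all(sig[i:j])) break # no superset interval can be all-significant
      maximal <- (i == 1 || !sig[i - 1]) && (j == n || !sig[j + 1])
      if (!maximal) next
      keep <- (i:j)[time[i:j] >= w[1] & time[i:j] <= w[2]]
      if (length(keep) >= min_samples) {
        found[[length(found) + 1L]] <- data.frame(
          start = time[keep[1]], end = time[keep[length(keep)]],
          n_samples = length(keep),
          duration = length(keep) * 1000 / rate
        )
      }
    }
  }
  if (!length(found)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_samples = integer(0), duration = numeric(0)))
  }
  unique(do.call(rbind, found))
}

# small session for fast simulation-based tests (invariants preserved:
# integral deviant count, jitter < mean)
tiny_session <- function(n_trials = 20) {
  session_config(n_trials_per_sequence = n_trials)
}

# Simulate one cohort condition through the real pipeline (schedules ->
# recordings -> preprocessing -> opposite-condition difference waves) and
# run group detection per category. Mirrors run_experiment's per-condition
# path with the ROI-only channel set for speed.
cohort_detect <- function(group, soa, seed, n_subjects = 15,
                          config = run_config(channels = roi_channels())) {
  profile <- config$profiles[[group]]
  roi_names <- names(config$rois)
  series <- lapply(seq_len(n_subjects), function(s) {
    vmmn:::simulate_subject_soa(config, profile, soa,
                                vmmn:::derive_seed(seed, s))$diff_series
  })
  out <- list()
  for (cat in c("letter", "pseudo-letter")) {
    ts <- lapply(roi_names, function(rn) {
      pointwise_t(lapply(series, function(x) x[[cat]][[rn]]),
                  tails = config$criterion$tails)
    })
    names(ts) <- roi_names
    out[[cat]] <- detect_vmmn(ts, config$criterion)
  }
  out
}
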