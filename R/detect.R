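#' vMMN detection criterion
#'
#' Presence criterion for the vMMN: a run of at least `min_run` ms of
#' consecutively significant pointwise t-tests (difference potential against
#' zero) inside the a-priori search window, in at least one ROI. Defaults:
#' alpha 0.05, 20 ms minimum run, 150-300 ms window (analysis axis,
#' i.e. relative to second-fragment onset), two-tailed tests, any-ROI rule,
#' negative-going runs only.
#'
#' The two-tailed reading of "against zero, p < 0.05" is the conservative
#' default; a one-tailed (negative-going) variant is available since the
#' vMMN's sign is predicted. Independently of the tails, only runs over
#' which the difference potential is *negative* qualify by default: a
#' significantly positive difference is not a mismatch negativity.
#'
#' @param alpha pointwise significance level.
#' @param min_run minimum run duration, ms. Run duration is count-based:
#'   `n_samples * 1000 / rate` ms, so 20 consecutive significant samples at
#'   1000 Hz constitute a 20 ms run. Conversion to samples uses
#'   `ceiling(min_run * rate / 1000)` for non-1000 Hz rates.
#' @param search_window c(start, end) ms on the analysis axis.
#' @param tails `"two"` or `"one"` (one-tailed = negative direction).
#' @param require `"any-roi"` (default) or `"all-roi"`.
#' @param polarity direction a qualifying run must have: `"negative"`
#'   (default; the vMMN is by definition a negativity, so only runs with
#'   negative t-values count as vMMN windows), `"positive"`, or `"any"`.
#' @return object of class `vmmn_criterion`.
#' @export
detection_criterion <- function(alpha = 0.05, min_run = 20,
                                search_window = c(150, 300),
                                tails = c("two", "one"),
                                require = c("any-roi", "all-roi"),
                                polarity = c("negative", "any", "positive")) {
  tails <- match.arg(tails)
  require <- match.arg(require)
  polarity <- match.arg(polarity)
  stopifnot(alpha > 0, alpha < 1, min_run > 0, diff(search_window) > 0)
  structure(
    list(alpha = alpha, min_run = min_run, search_window = search_window,
         tails = tails, require = require, polarity = polarity),
    class = "vmmn_criterion"
  )
}

#' Pointwise one-sample t-test across subjects
#'
#' At every sample, tests the across-subject mean of the (ROI-pooled)
#' difference potentials against zero. Samples with zero across-subject
#' variance are degenerate for the t statistic; they are flagged and
#' assigned `p = 0` when the mean is nonzero (an exact, noiseless effect)
#' and `p = 1` when the mean is zero.
#'
#' @param subject_series list of `vmmn_series`, one per subject, identical
#'   time axes; at least 3 subjects.
#' @param tails `"two"` (default) or `"one"` (negative direction).
#' @return object of class `vmmn_tseries`: `t`, `p`, `df`, `time`,
#'   `degenerate` (logical per sample), `n`.
#' @export
pointwise_t <- function(subject_series, tails = c("two", "one")) {
  tails <- match.arg(tails)
  if (length(subject_series) < 3) {
    stopf("pointwise t requires at least 3 subjects, got %d", length(subject_series))
  }
  times <- subject_series[[1]]$time
  for (s in subject_series[-1]) {
    if (!isTRUE(all.equal(s$time, times))) stopf("subject time axes differ")
  }
  mat <- do.call(rbind, lapply(subject_series, function(s) s$value))
  n <- nrow(mat)
  m <- colMeans(mat)
  sdv <- apply(mat, 2L, stats::sd)
  degenerate <- sdv == 0
  tval <- rep(NA_real_, length(m))
  tval[!degenerate] <- m[!degenerate] / (sdv[!degenerate] / sqrt(n))
  # degenerate samples keep the sign of the (noiseless) mean for run polarity
  tval[degenerate & m != 0] <- sign(m[degenerate & m != 0]) * Inf
  p <- rep(NA_real_, length(m))
  if (tails == "two") {
    p[!degenerate] <- 2 * stats::pt(-abs(tval[!degenerate]), df = n - 1)
  } else {
    p[!degenerate] <- stats::pt(tval[!degenerate], df = n - 1)
  }
  p[degenerate] <- ifelse(m[degenerate] != 0, 0, 1)
  structure(
    list(t = tval, p = p, df = n - 1L, time = times,
         degenerate = degenerate, n = n),
    class = "vmmn_tseries"
  )
}

#' Find runs of consecutive significant samples
#'
#' Maximal runs of consecutive samples with `p < alpha` (and, under the
#' default `polarity = "negative"`, with negative t-values, since only a
#' negativity qualifies as a vMMN) are computed on the full series and then
#' intersected with the search window; a run straddling the window edge
#' counts only its inside portion. Runs whose inside duration (count-based,
#' `n_samples * 1000 / rate` ms) reaches `min_run` are reported.
#'
#' @param ts a `vmmn_tseries` (see [pointwise_t()]), or any list with `p`
#'   and `time` fields.
#' @param criterion a [detection_criterion()].
#' @return data frame with one row per detected window: `start`, `end` (ms,
#'   first/last significant sample inside the search window), `n_samples`,
#'   `duration` (ms).
#' @export
find_runs <- function(ts, criterion = detection_criterion()) {
  time <- ts$time
  step <- stats::median(diff(time))
  rate <- 1000 / step
  min_samples <- as.integer(ceiling(criterion$min_run * rate / 1000))
  w <- criterion$search_window
  if (w[1] < min(time) || w[2] > max(time)) {
    stopf("search window [%g, %g] ms outside the series span [%g, %g] ms",
          w[1], w[2], min(time), max(time))
  }

  sig <- !is.na(ts$p) & ts$p < criterion$alpha
  pol <- criterion$polarity %||% "any"
  if (pol != "any") {
    if (is.null(ts$t)) {
      stopf("polarity-restricted run detection needs t-values in the series")
    }
    sig <- sig & !is.na(ts$t) &
      (if (pol == "negative") ts$t < 0 else ts$t > 0)
  }
  inside <- time >= w[1] & time <= w[2]
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L

  out <- list()
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    idx <- idx[inside[idx]]
    if (length(idx) >= min_samples) {
      out[[length(out) + 1L]] <- data.frame(
        start = time[idx[1]],
        end = time[idx[length(idx)]],
        n_samples = length(idx),
        duration = length(idx) * 1000 / rate
      )
    }
  }
  if (!length(out)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_samples = integer(0), duration = numeric(0)))
  }
  do.call(rbind, out)
}

#' Decide vMMN presence from per-ROI t-series
#'
#' Applies [find_runs()] per ROI and combines: with the default `"any-roi"`
#' rule the vMMN counts as present when at least one ROI shows a qualifying
#' window; `"all-roi"` requires every ROI to.
#'
#' @param tseries_by_roi named list of `vmmn_tseries`, one per ROI (both
#'   ROIs must be supplied).
#' @param criterion a [detection_criterion()].
#' @return object of class `vmmn_detection`: `windows` data frame (with a
#'   `roi` column), `vmmn_present` flag and the criterion.
#' @export
detect_vmmn <- function(tseries_by_roi, criterion = detection_criterion()) {
  if (is.null(names(tseries_by_roi)) || any(names(tseries_by_roi) == "")) {
    stopf("tseries_by_roi must be a named list (one element per ROI)")
  }
  per_roi <- lapply(tseries_by_roi, find_runs, criterion = criterion)
  windows <- do.call(rbind, lapply(names(per_roi), function(nm) {
    w <- per_roi[[nm]]
    if (nrow(w)) cbind(roi = nm, w, stringsAsFactors = FALSE) else NULL
  }))
  if (is.null(windows)) {
    windows <- data.frame(roi = character(0), start = numeric(0),
                          end = numeric(0), n_samples = integer(0),
                          duration = numeric(0))
  }
  present <- if (criterion$require == "any-roi") {
    nrow(windows) > 0
  } else {
    all(vapply(per_roi, nrow, integer(1)) > 0)
  }
  structure(
    list(windows = windows, vmmn_present = present, criterion = criterion),
    class = "vmmn_detection"
  )
}

#' @export
print.vmmn_detection <- function(x, ...) {
  cat(sprintf("<vmmn_detection> vMMN %s\n",
              if (x$vmmn_present) "PRESENT" else "absent"))
  if (nrow(x$windows)) {
    for (i in seq_len(nrow(x$windows))) {
      cat(sprintf("  %s ROI: %g-%g ms (%d samples)\n",
                  x$windows$roi[i], x$windows$start[i], x$windows$end[i],
                  x$windows$n_samples[i]))
    }
  }
  invisible(x)
}
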