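#' Average epochs into a condition ERP
#'
#' Pointwise mean over the retained epochs that match the requested
#' condition. The two physical variants of a role are pooled by default
#' (pass `variant` to restrict), matching the convention of analysing
#' letter vs. pseudo-letter conditions rather than individual exemplars.
#'
#' @param epochs a `vmmn_epochs` set (after [reject_artifacts()]).
#' @param role `"standard"` or `"deviant"`.
#' @param category `"letter"` or `"pseudo-letter"`; `NULL` pools both.
#' @param variant restrict to one exemplar; `NULL` (default) pools.
#' @return object of class `vmmn_erp`: samples x channels matrix `data`,
#'   epoch count, condition labels and both time axes.
#' @export
average_epochs <- function(epochs, role, category = NULL, variant = NULL) {
  stopifnot(inherits(epochs, "vmmn_epochs"))
  info <- epochs$info
  sel <- !info$rejected & info$role == role
  if (!is.null(category)) sel <- sel & info$category == category
  if (!is.null(variant)) sel <- sel & info$variant == variant
  if (!any(sel)) {
    stopf("no retained epochs match condition (role=%s, category=%s, variant=%s)",
          role, category %||% "*", variant %||% "*")
  }
  d <- dim(epochs$data)
  flat <- matrix(epochs$data[, , sel, drop = FALSE], nrow = d[1] * d[2])
  avg <- matrix(rowMeans(flat), nrow = d[1], ncol = d[2],
                dimnames = list(NULL, epochs$channels))
  out <- list(
    data = avg,
    n_epochs = sum(sel),
    condition = list(role = role,
                     category = category %||% unique(info$category[sel]),
                     soa = epochs$soa),
    times_acq = epochs$times_acq,
    times_ana = epochs$times_ana,
    channels = epochs$channels,
    sampling_rate = epochs$sampling_rate
  )
  class(out) <- "vmmn_erp"
  out
}

#' Opposite-condition difference wave
#'
#' Subtracts the ERP to a stimulus presented as *standard* (taken from the
#' sequence in which the roles were swapped) from the ERP to the physically
#' identical stimulus presented as *deviant*. Because minuend and subtrahend
#' share category and SOA, exogenous stimulus-specific activity cancels and
#' the remainder indexes change-related processing.
#'
#' @param deviant_erp ERP with `role == "deviant"`.
#' @param opposite_standard_erp ERP with `role == "standard"`, same category
#'   and SOA, from the opposite sequence.
#' @return object of class `vmmn_diffwave` (same layout as `vmmn_erp`, with
#'   `minuend`/`subtrahend` metadata).
#' @export
difference_wave <- function(deviant_erp, opposite_standard_erp) {
  stopifnot(inherits(deviant_erp, "vmmn_erp"),
            inherits(opposite_standard_erp, "vmmn_erp"))
  a <- deviant_erp$condition
  b <- opposite_standard_erp$condition
  if (identical(a$role, b$role)) {
    stopf("minuend and subtrahend must have different roles (both are '%s')", a$role)
  }
  if (!identical(a$category, b$category) || !identical(a$soa, b$soa)) {
    stopf(
      "pairing error: opposite-condition subtraction requires matching category and SOA (deviant: %s/SOA %g, standard: %s/SOA %g)",
      a$category, a$soa, b$category, b$soa
    )
  }
  if (!isTRUE(all.equal(deviant_erp$times_ana, opposite_standard_erp$times_ana))) {
    stopf("time axes of the two ERPs differ")
  }
  out <- list(
    data = deviant_erp$data - opposite_standard_erp$data,
    minuend = a,
    subtrahend = b,
    times_acq = deviant_erp$times_acq,
    times_ana = deviant_erp$times_ana,
    channels = deviant_erp$channels,
    sampling_rate = deviant_erp$sampling_rate
  )
  class(out) <- "vmmn_diffwave"
  out
}

#' Region-of-interest definitions
#'
#' The vMMN regions of interest: an unweighted pool of PO8 + PO10 on the
#' right and PO7 + PO9 on the left, reflecting the usual posterior scalp
#' distribution of the component.
#'
#' @param name ROI label.
#' @param channels electrode labels pooled into the ROI.
#' @return `roi_def()` returns a single ROI; `default_rois()` the standard
#'   left/right pair as a named list.
#' @export
roi_def <- function(name, channels) {
  stopifnot(is.character(channels), length(channels) >= 1)
  structure(list(name = name, channels = channels), class = "vmmn_roi")
}

#' @rdname roi_def
#' @export
default_rois <- function() {
  list(
    left = roi_def("left", c("PO7", "PO9")),
    right = roi_def("right", c("PO8", "PO10"))
  )
}

#' Pool channels into a single ROI time series
#'
#' @param wave a `vmmn_erp` or `vmmn_diffwave`.
#' @param roi a [roi_def()].
#' @return object of class `vmmn_series`: list with `time` (analysis axis,
#'   ms) and `value` (microvolts).
#' @export
roi_pool <- function(wave, roi) {
  stopifnot(inherits(roi, "vmmn_roi"))
  missing <- setdiff(roi$channels, wave$channels)
  if (length(missing)) {
    stopf("ROI '%s' channel(s) not present in the waveform: %s",
          roi$name, paste(missing, collapse = ", "))
  }
  value <- rowMeans(wave$data[, roi$channels, drop = FALSE])
  structure(
    list(time = wave$times_ana, value = as.numeric(value), roi = roi$name),
    class = "vmmn_series"
  )
}

#' Peak latency and amplitude measurement
#'
#' Finds the largest polarity-signed excursion inside a latency window on the
#' analysis time axis. Ties are broken towards the earliest sample. Two
#' amplitude conventions are supported: the value at the subject peak itself
#' (`"subject-peak"`), or the mean over a 20 ms span centred on a supplied
#' group-average peak latency (`"group-peak-centered-mean"`, the convention
#' used for reporting vMMN amplitudes). The 20 ms span is
#' inclusive-symmetric, `[peak - 10, peak + 10]` ms; if it protrudes past the
#' measurement window it is clipped to it and `clipped = TRUE` is reported.
#'
#' @param series a `vmmn_series` (see [roi_pool()]).
#' @param window c(start, end) ms on the analysis axis; default the vMMN
#'   search range 150-300 ms.
#' @param polarity `"negative"` (default; vMMN) or `"positive"`.
#' @param method amplitude convention, see above.
#' @param group_peak_latency ms; required for `"group-peak-centered-mean"`.
#' @return list with `latency`, `amplitude`, `window`, `polarity`, `method`,
#'   `clipped`.
#' @export
measure_peak <- function(series, window = c(150, 300),
                         polarity = c("negative", "positive"),
                         method = c("subject-peak", "group-peak-centered-mean"),
                         group_peak_latency = NULL) {
  polarity <- match.arg(polarity)
  method <- match.arg(method)
  stopifnot(inherits(series, "vmmn_series"))
  if (window[1] < min(series$time) || window[2] > max(series$time)) {
    stopf("measurement window [%g, %g] ms lies outside the series span [%g, %g] ms",
          window[1], window[2], min(series$time), max(series$time))
  }
  sel <- which(series$time >= window[1] & series$time <= window[2])
  sign <- if (polarity == "negative") -1 else 1
  peak_i <- sel[which.max(sign * series$value[sel])] # which.max: earliest tie
  latency <- series$time[peak_i]

  clipped <- FALSE
  if (method == "subject-peak") {
    amplitude <- series$value[peak_i]
  } else {
    if (is.null(group_peak_latency)) {
      stopf("group_peak_latency is required for method 'group-peak-centered-mean'")
    }
    span <- c(group_peak_latency - 10, group_peak_latency + 10)
    clip <- c(max(span[1], window[1]), min(span[2], window[2]))
    clipped <- !isTRUE(all.equal(span, clip))
    in_span <- series$time >= clip[1] & series$time <= clip[2]
    amplitude <- mean(series$value[in_span])
  }
  list(latency = latency, amplitude = amplitude, window = window,
       polarity = polarity, method = method, clipped = clipped)
}
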