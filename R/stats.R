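#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Mixed-design ANOVA on a long-format table: one or more within-subject
#' factors (e.g. ROI, SOA) with an optional between-subject factor (e.g.
#' Age). Fits the multivariate linear model on the subject x cell matrix and
#' decomposes it with type-III univariate repeated-measures tests
#' ([car::Anova()]); within-subject effects involving a factor with more
#' than two levels get the Greenhouse-Geisser epsilon and corrected p-value.
#' Effect sizes are partial eta squared,
#' `SS_effect / (SS_effect + SS_error)` within each error stratum.
#'
#' The design must be balanced: exactly one value per subject per
#' within-cell, and each subject in exactly one between group. Unbalanced
#' data raise an error rather than being imputed.
#'
#' @param data long-format data frame.
#' @param dv name of the response column.
#' @param subject name of the subject identifier column.
#' @param within character vector of within-subject factor columns.
#' @param between optional name of a between-subject factor column.
#' @return data frame of class `vmmn_anova` with one row per effect:
#'   `effect`, `ss`, `error_ss`, `df_num`, `df_den`, `F`, `p_uncorrected`,
#'   `gg_epsilon`, `p_gg`, `partial_eta_sq`. For effects where sphericity is
#'   not at issue
#'   (between-only effects, or within factors with two levels) the epsilon
#'   is 1 and `p_gg` equals `p_uncorrected`.
#' @export
#' @examples
#' d <- expand.grid(subject = 1:6, roi = c("left", "right"))
#' d$age <- ifelse(d$subject <= 3, "young", "older")
#' d$amp <- rnorm(nrow(d))
#' rm_anova(d, dv = "amp", subject = "subject", within = "roi", between = "age")
rm_anova <- function(data, dv, subject, within, between = NULL) {
  stopifnot(is.data.frame(data), length(within) >= 1)
  for (col in c(dv, subject, within, between)) {
    if (!col %in% names(data)) stopf("column '%s' not found in data", col)
  }
  for (col in c(within, between)) data[[col]] <- factor(data[[col]])
  subj <- factor(data[[subject]])

  # balance check: one observation per subject per within-cell
  tab <- table(data[c(subject, within)])
  if (any(tab != 1L)) {
    stopf("unbalanced design: need exactly one value per subject per within-subject cell")
  }

  cells <- do.call(tapply, list(data[[dv]], data[c(subject, within)], mean))
  mat <- matrix(cells, nrow = dim(cells)[1])
  idata <- expand.grid(lapply(data[within], levels), KEEP.OUT.ATTRS = FALSE)
  names(idata) <- within
  idata[] <- lapply(idata, factor)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))

  subj_levels <- dimnames(cells)[[1]]
  if (!is.null(between)) {
    btw_map <- unique(data[c(subject, between)])
    if (nrow(btw_map) != length(subj_levels)) {
      stopf("each subject must belong to exactly one '%s' group", between)
    }
    btw <- btw_map[[between]][match(subj_levels, as.character(btw_map[[subject]]))]
    mdata <- data.frame(.g = factor(btw))
    names(mdata) <- between
    rhs <- between
  } else {
    mdata <- data.frame(row.names = seq_along(subj_levels))
    rhs <- "1"
  }

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  mlm <- stats::lm(stats::as.formula(paste("mat ~", rhs)), data = mdata)
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  # car warns whenever the (unused) Huynh-Feldt epsilon exceeds 1
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  uni <- s$univariate.tests
  keep <- rownames(uni) != "(Intercept)"
  eff <- rownames(uni)[keep]
  ss <- uni[keep, "Sum Sq"]
  err_ss <- uni[keep, "Error SS"]
  df1 <- uni[keep, "num Df"]
  df2 <- uni[keep, "den Df"]
  Fv <- ifelse(ss == 0, 0, uni[keep, "F value"])
  p <- stats::pf(Fv, df1, df2, lower.tail = FALSE)

  eps <- rep(1, length(eff))
  adj <- s$pval.adjustments
  if (!is.null(adj) && length(adj) && !is.null(rownames(adj))) {
    i <- match(eff, rownames(adj))
    ok <- which(!is.na(i))
    vals <- adj[i[ok], "GG eps"]
    eps[ok[!is.na(vals)]] <- vals[!is.na(vals)]
  }
  p_gg <- stats::pf(Fv, df1 * eps, df2 * eps, lower.tail = FALSE)
  pes <- ifelse(ss + err_ss == 0, 0, ss / (ss + err_ss))

  out <- data.frame(
    effect = eff, ss = ss, error_ss = err_ss, df_num = df1, df_den = df2,
    F = Fv, p_uncorrected = p, gg_epsilon = eps, p_gg = p_gg,
    partial_eta_sq = pes,
    row.names = NULL, stringsAsFactors = FALSE
  )
  class(out) <- c("vmmn_anova", "data.frame")
  out
}

#' @export
print.vmmn_anova <- function(x, digits = 3, ...) {
  cat("Repeated-measures ANOVA (Greenhouse-Geisser corrected)\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf(
      "  %-20s F(%g, %g) = %.*f, p = %.4g (GG eps = %.3f, p_GG = %.4g), eta_p^2 = %.*f\n",
      x$effect[i], x$df_num[i], x$df_den[i], digits, x$F[i],
      x$p_uncorrected[i], x$gg_epsilon[i], x$p_gg[i], digits,
      x$partial_eta_sq[i]
    ))
  }
  invisible(x)
}

#' Tukey HSD pairwise comparisons
#'
#' Studentized-range post hoc tests from cell means and the ANOVA error
#' term, for balanced designs: `q = |m_i - m_j| / sqrt(ms_error / n)` with
#' p-values from [stats::ptukey()].
#'
#' @param cell_means named numeric vector of cell means.
#' @param ms_error mean-square error from the corresponding ANOVA stratum.
#' @param df_error its degrees of freedom.
#' @param n_per_cell observations per cell (scalar; the design is balanced,
#'   supplying unequal n is an error).
#' @return data frame of pairwise contrasts with `diff`, `q` and adjusted
#'   `p`.
#' @export
tukey_hsd <- function(cell_means, ms_error, df_error, n_per_cell) {
  stopifnot(is.numeric(cell_means), length(cell_means) >= 2,
            ms_error >= 0, df_error >= 1)
  if (length(n_per_cell) != 1L) {
    stopf("tukey_hsd assumes a balanced design: n_per_cell must be a single count")
  }
  if (is.null(names(cell_means))) {
    names(cell_means) <- paste0("cell", seq_along(cell_means))
  }
  k <- length(cell_means)
  pairs <- utils::combn(k, 2)
  se <- sqrt(ms_error / n_per_cell)
  out <- data.frame(
    contrast = apply(pairs, 2, function(ij) {
      paste(names(cell_means)[ij], collapse = " - ")
    }),
    diff = apply(pairs, 2, function(ij) cell_means[ij[1]] - cell_means[ij[2]]),
    stringsAsFactors = FALSE
  )
  out$q <- abs(out$diff) / se
  out$p <- stats::ptukey(out$q, nmeans = k, df = df_error, lower.tail = FALSE)
  out
}

#' Score hits to the frame-thickening task
#'
#' A task event is a hit when at least one response falls inside the
#' response window after its onset; each response can be consumed by at most
#' one event, and repeated responses to the same event count once. The
#' default window of 200-1000 ms after thickening onset is the conventional
#' simple-RT acceptance range and is configurable.
#'
#' @param response_times numeric vector of button-press times, ms.
#' @param task_events data frame with an `onset` column (as in a
#'   `vmmn_schedule`).
#' @param response_window c(min, max) ms after event onset.
#' @return list with `n_events`, `n_hits`, `hit_rate` (percent).
#' @export
score_hits <- function(response_times, task_events,
                       response_window = c(200, 1000)) {
  onsets <- sort(task_events$onset)
  responses <- sort(response_times)
  used <- logical(length(responses))
  hits <- 0L
  for (on in onsets) {
    ok <- which(!used & responses >= on + response_window[1] &
                  responses <= on + response_window[2])
    if (length(ok)) {
      used[ok[1]] <- TRUE
      hits <- hits + 1L
    }
  }
  n <- length(onsets)
  list(n_events = n, n_hits = hits,
       hit_rate = if (n == 0) NA_real_ else 100 * hits / n)
}

#' Simulate button presses to the frame-thickening task
#'
#' Bernoulli responder: each task event is answered with probability
#' `hit_prob`, at a normally distributed reaction time truncated to the
#' scoring window.
#'
#' @param schedule a `vmmn_schedule` (its `task_events` are used).
#' @param hit_prob per-event response probability.
#' @param rt_mean,rt_sd reaction-time distribution, ms.
#' @param seed RNG seed.
#' @return numeric vector of response times (ms from sequence start).
#' @export
generate_task_responses <- function(schedule, hit_prob = 0.8,
                                    rt_mean = 450, rt_sd = 100, seed = NULL) {
  onsets <- schedule$task_events$onset
  with_seed(seed, {
    answered <- stats::runif(length(onsets)) < hit_prob
    rt <- pmin(pmax(stats::rnorm(sum(answered), rt_mean, rt_sd), 210), 990)
    sort(onsets[answered] + rt)
  })
}
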