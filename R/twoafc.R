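#' Two-alternative forced-choice observer model
#'
#' Psychometric model for the fragment-integration 2AFC task: the observer
#' reports which member of a character pair was the legal letter. Accuracy
#' starts at `p_correct_at_min_soa` for the shortest SOA (fragments abut:
#' 30 ms SOA = 0 ms inter-stimulus interval) and decays exponentially toward
#' chance (0.5) with increasing SOA:
#' `p(soa) = 0.5 + (p0 - 0.5) * exp(-(soa - min_soa) / decay_constant)`,
#' mixed with a lapse rate (random guesses). The defaults emulate successful
#' integration at 30 ms falling to near-chance at 50 ms, in both age groups.
#'
#' @param n_trials trials per session; split as evenly as possible (cell
#'   counts differ by at most one) over SOA x letter-position cells.
#' @param soa_levels SOAs tested, ms.
#' @param p_correct_at_min_soa accuracy at the shortest SOA, in (0.5, 1].
#' @param decay_constant ms; accuracy e-folds toward chance over this SOA
#'   increment.
#' @param lapse_rate fraction of trials answered by a random guess.
#' @return object of class `vmmn_2afc_model`.
#' @export
psychometric_2afc <- function(n_trials = 164, soa_levels = c(30, 50, 70),
                              p_correct_at_min_soa = 0.9,
                              decay_constant = 8, lapse_rate = 0.02) {
  stopifnot(p_correct_at_min_soa >= 0.5, p_correct_at_min_soa <= 1,
            decay_constant > 0, lapse_rate >= 0, lapse_rate < 1)
  structure(
    list(n_trials = as.integer(n_trials), soa_levels = sort(soa_levels),
         p_correct_at_min_soa = p_correct_at_min_soa,
         decay_constant = decay_constant, lapse_rate = lapse_rate),
    class = "vmmn_2afc_model"
  )
}

#' @rdname psychometric_2afc
#' @param model a `vmmn_2afc_model`.
#' @param soa SOA value(s), ms.
#' @return `p_correct_2afc()` returns the modeled probability of a correct
#'   choice (in `[0.5, 1]`, non-increasing in SOA).
#' @export
p_correct_2afc <- function(model, soa) {
  p <- 0.5 + (model$p_correct_at_min_soa - 0.5) *
    exp(-(soa - min(model$soa_levels)) / model$decay_constant)
  (1 - model$lapse_rate) * p + model$lapse_rate * 0.5
}

#' Simulate a 2AFC session
#'
#' Generates one session's response table. Trials are balanced as evenly as
#' possible over the SOA x letter-position design cells (the default 164
#' trials over 3 SOAs and 2 positions give cells of 27-28 trials; per-SOA
#' totals differ by at most one) and presented in random order. Each trial
#' is answered correctly with probability [p_correct_2afc()] at its SOA.
#'
#' @param model a [psychometric_2afc()].
#' @param seed RNG seed.
#' @return data frame with columns `trial`, `soa_ms`, `letter_position`
#'   (`"first"`/`"second"`), `response`, `correct` (logical).
#' @export
#' @examples
#' tbl <- generate_2afc_responses(psychometric_2afc(), seed = 1)
#' table(tbl$soa_ms)
generate_2afc_responses <- function(model, seed = NULL) {
  stopifnot(inherits(model, "vmmn_2afc_model"))
  cells <- expand.grid(
    soa_ms = model$soa_levels,
    letter_position = c("first", "second"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  k <- nrow(cells)
  n <- model$n_trials
  counts <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) {
    # round-robin over SOAs first so per-SOA totals stay within one trial
    counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  }
  trials <- cells[rep(seq_len(k), counts), , drop = FALSE]

  with_seed(seed, {
    trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
    trials$trial <- seq_len(nrow(trials))
    p <- p_correct_2afc(model, trials$soa_ms)
    trials$correct <- stats::runif(nrow(trials)) < p
    trials$response <- ifelse(
      trials$correct, trials$letter_position,
      ifelse(trials$letter_position == "first", "second", "first")
    )
    rownames(trials) <- NULL
    trials[c("trial", "soa_ms", "letter_position", "response", "correct")]
  })
}

#' Score a 2AFC response table
#'
#' Proportion of correct choices per SOA.
#'
#' @param responses a data frame as produced by [generate_2afc_responses()]
#'   (columns `soa_ms` and `correct`).
#' @return data frame with `soa_ms`, `n_trials`, `n_correct`, `proportion`.
#' @export
score_2afc <- function(responses) {
  for (col in c("soa_ms", "correct")) {
    if (!col %in% names(responses)) stopf("response table lacks column '%s'", col)
  }
  if (!is.numeric(responses$soa_ms)) stopf("soa_ms must be numeric")
  agg <- stats::aggregate(
    cbind(n_trials = rep(1L, nrow(responses)), n_correct = responses$correct),
    by = list(soa_ms = responses$soa_ms), FUN = sum
  )
  agg$proportion <- agg$n_correct / agg$n_trials
  agg
}
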