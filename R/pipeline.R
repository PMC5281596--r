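#' End-to-end experiment configuration
#'
#' Bundles every parameter of a simulated cohort study. The defaults
#' reproduce the emulated design: 15 subjects per age group, 16 sequences
#' per subject (4 SOAs x 2 deviant categories x 2 repetitions), the default
#' young/older simulation profiles, 0.1-30 Hz preprocessing, -100..+600 ms
#' epochs and the 20-ms-run detection criterion.
#'
#' @param session a [session_config()].
#' @param profiles named list with `young` and `older` [group_profile()]s.
#' @param n_subjects_per_group subjects per age group.
#' @param criterion a [detection_criterion()].
#' @param rois ROI list as from [default_rois()].
#' @param window an [epoch_window()].
#' @param filter a [filter_spec()].
#' @param rejection_threshold artifact screen, microvolts.
#' @param channels channels to simulate; `NULL` = full montage. Restricting
#'   to the ROI channels (`roi_channels(rois)`) leaves all ROI-level results
#'   unchanged and is much faster.
#' @param seed base seed; every stream of randomness in the run is derived
#'   from it deterministically.
#' @return object of class `vmmn_run_config`.
#' @export
run_config <- function(session = session_config(),
                       profiles = default_profiles(),
                       n_subjects_per_group = 15,
                       criterion = detection_criterion(),
                       rois = default_rois(),
                       window = epoch_window(),
                       filter = filter_spec(),
                       rejection_threshold = 100,
                       channels = NULL,
                       seed = 1) {
  stopifnot(inherits(session, "vmmn_config"),
            all(c("young", "older") %in% names(profiles)))
  reps <- session$n_sequences / (length(session$soa_levels) * 2)
  if (reps != round(reps) || reps < 1) {
    stopf("n_sequences (%d) must be a multiple of soa levels x 2 categories",
          session$n_sequences)
  }
  structure(
    list(session = session, profiles = profiles,
         n_subjects_per_group = as.integer(n_subjects_per_group),
         criterion = criterion, rois = rois, window = window,
         filter = filter, rejection_threshold = rejection_threshold,
         channels = channels, seed = seed, repetitions = as.integer(reps)),
    class = "vmmn_run_config"
  )
}

#' @rdname run_config
#' @export
roi_channels <- function(rois = default_rois()) {
  unique(unlist(lapply(rois, `[[`, "channels")))
}

# One subject x one SOA: simulate all sequences (repetitions x both deviant
# categories), preprocess, and return per-category ROI difference series
# plus task hit counts.
simulate_subject_soa <- function(config, profile, soa, subject_seed) {
  ses <- config$session
  channels <- config$channels %||% default_montage()
  categories <- c("letter", "pseudo-letter")
  epoch_sets <- list(letter = list(), `pseudo-letter` = list())
  hits <- 0L
  n_events <- 0L

  k <- 0L
  for (rep_i in seq_len(config$repetitions)) {
    for (cat in categories) {
      k <- k + 1L
      sch <- generate_schedule(ses, soa, cat,
                               sequence_id = sprintf("%s-%d", cat, rep_i),
                               seed = derive_seed(subject_seed, 2L * k))
      rec <- generate_recording(sch, profile,
                                seed = derive_seed(subject_seed, 2L * k + 1L),
                                channels = channels)
      rec <- bandpass_filter(rec, config$filter)
      eps <- segment_epochs(rec, config$window)
      eps <- reject_artifacts(eps, config$rejection_threshold)
      epoch_sets[[cat]][[rep_i]] <- eps

      resp <- generate_task_responses(sch, hit_prob = profile$hit_prob,
                                      seed = derive_seed(subject_seed, 1000L + k))
      sc <- score_hits(resp, sch$task_events)
      hits <- hits + sc$n_hits
      n_events <- n_events + sc$n_events
    }
  }

  diff_series <- list()
  for (cat in categories) {
    other <- setdiff(categories, cat)
    dev <- combine_erps(lapply(epoch_sets[[cat]], average_epochs,
                               role = "deviant", category = cat))
    std <- combine_erps(lapply(epoch_sets[[other]], average_epochs,
                               role = "standard", category = cat))
    dw <- difference_wave(dev, std)
    diff_series[[cat]] <- lapply(config$rois, function(roi) roi_pool(dw, roi))
  }

  list(diff_series = diff_series,
       hit_rate = if (n_events > 0) 100 * hits / n_events else NA_real_)
}

# epoch-count-weighted combination of condition ERPs (equivalent to pooling
# the underlying epochs)
combine_erps <- function(erps) {
  w <- vapply(erps, `[[`, numeric(1), "n_epochs")
  out <- erps[[1]]
  acc <- Reduce(`+`, Map(function(e, wi) e$data * wi, erps, w))
  out$data <- acc / sum(w)
  out$n_epochs <- sum(w)
  out
}

# grand-average of subject vmmn_series
grand_average_series <- function(series_list) {
  out <- series_list[[1]]
  out$value <- rowMeans(vapply(series_list, `[[`, numeric(length(out$value)),
                               "value"))
  out
}

#' Run a full simulated vMMN experiment
#'
#' Simulates both age-group cohorts through the complete chain — schedule
#' generation, EEG forward model, filtering, epoching, artifact rejection,
#' condition averaging, opposite-condition subtraction, ROI pooling — then
#' performs group-level detection (pointwise t + run criterion), peak
#' measurement, task hit-rate scoring with an Age x SOA ANOVA, and a
#' simulated 2AFC session per subject with its Age x SOA ANOVA. vMMN
#' amplitude/latency ANOVAs (Age x ROI at SOA 0; ROI x SOA within the older
#' group) are run only for conditions in which the run criterion flagged a
#' vMMN.
#'
#' The run is fully reproducible: every random stream derives from
#' `config$seed`. With `out_dir` set, result tables are written as CSV/JSON
#' together with a manifest listing each file's MD5 checksum.
#'
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @param twoafc_model a [psychometric_2afc()] observer shared by both
#'   groups (the behavioural task showed no group difference).
#' @return list with `detection` (Table-2-style data frame: one row per
#'   significant window), `presence` (per condition flag), `peaks`
#'   (Table-3-style measures for detected conditions), `hit_rates` and
#'   `hit_anova`, `twoafc` and `twoafc_anova`, `vmmn_anovas`, `errors`, and
#'   the `config`.
#' @export
run_experiment <- function(config, out_dir = NULL,
                           twoafc_model = psychometric_2afc()) {
  stopifnot(inherits(config, "vmmn_run_config"))
  ses <- config$session
  groups <- c("young", "older")
  categories <- c("letter", "pseudo-letter")
  roi_names <- names(config$rois)

  subject_data <- list() # [[group]][[subject]][[soa]]
  hit_rows <- list()
  errors <- list()

  for (gi in seq_along(groups)) {
    g <- groups[gi]
    profile <- config$profiles[[g]]
    subject_data[[g]] <- vector("list", config$n_subjects_per_group)
    for (s in seq_len(config$n_subjects_per_group)) {
      for (soa_i in seq_along(ses$soa_levels)) {
        soa <- ses$soa_levels[soa_i]
        sseed <- derive_seed(config$seed, ((gi * 100L + s) * 10L + soa_i))
        res <- tryCatch(
          simulate_subject_soa(config, profile, soa, sseed),
          error = function(e) e
        )
        if (inherits(res, "error")) {
          errors[[length(errors) + 1L]] <- list(
            group = g, subject = s, soa = soa, message = conditionMessage(res)
          )
          next
        }
        subject_data[[g]][[s]][[as.character(soa)]] <- res$diff_series
        hit_rows[[length(hit_rows) + 1L]] <- data.frame(
          group = g, subject = sprintf("%s-%02d", g, s), soa = soa,
          hit_rate = res$hit_rate, stringsAsFactors = FALSE
        )
      }
    }
  }

  # ---- group-level detection and peaks --------------------------------
  detection_rows <- list()
  presence <- list()
  peak_rows <- list()
  peak_measures <- list() # subject-level, for the vMMN ANOVAs

  for (g in groups) {
    for (soa in ses$soa_levels) {
      for (cat in categories) {
        key <- paste(g, cat, soa, sep = "|")
        series_by_subj <- lapply(subject_data[[g]], function(subj) {
          subj[[as.character(soa)]][[cat]]
        })
        series_by_subj <- Filter(Negate(is.null), series_by_subj)
        if (length(series_by_subj) < 3) next
        ts_by_roi <- lapply(roi_names, function(rn) {
          pointwise_t(lapply(series_by_subj, `[[`, rn),
                      tails = config$criterion$tails)
        })
        names(ts_by_roi) <- roi_names
        det <- detect_vmmn(ts_by_roi, config$criterion)
        presence[[key]] <- det$vmmn_present
        if (nrow(det$windows)) {
          detection_rows[[length(detection_rows) + 1L]] <- data.frame(
            soa = soa, group = g, stimulus = cat, roi = det$windows$roi,
            window_start_ms = det$windows$start,
            window_end_ms = det$windows$end,
            stringsAsFactors = FALSE
          )
        }
        if (det$vmmn_present) {
          for (rn in roi_names) {
            subj_series <- lapply(series_by_subj, `[[`, rn)
            grand <- grand_average_series(subj_series)
            gp <- measure_peak(grand, config$criterion$search_window,
                               "negative", "subject-peak")
            amp <- measure_peak(grand, config$criterion$search_window,
                                "negative", "group-peak-centered-mean",
                                group_peak_latency = gp$latency)
            peak_rows[[length(peak_rows) + 1L]] <- data.frame(
              group = g, stimulus = cat, soa = soa, roi = rn,
              amplitude = amp$amplitude, latency = gp$latency,
              n_subjects = length(subj_series), stringsAsFactors = FALSE
            )
            peak_measures[[key]][[rn]] <- lapply(subj_series, function(ss) {
              pk <- measure_peak(ss, config$criterion$search_window,
                                 "negative", "group-peak-centered-mean",
                                 group_peak_latency = gp$latency)
              lat <- measure_peak(ss, config$criterion$search_window,
                                  "negative", "subject-peak")
              list(amplitude = pk$amplitude, latency = lat$latency)
            })
          }
        }
      }
    }
  }

  detection <- if (length(detection_rows)) {
    do.call(rbind, detection_rows)
  } else {
    data.frame(soa = numeric(0), group = character(0), stimulus = character(0),
               roi = character(0), window_start_ms = numeric(0),
               window_end_ms = numeric(0))
  }

  # ---- vMMN ANOVAs (only where detection flagged a vMMN) --------------
  vmmn_anovas <- list()
  key0 <- function(g) paste(g, "pseudo-letter", 0, sep = "|")
  if (isTRUE(presence[[key0("young")]]) && isTRUE(presence[[key0("older")]])) {
    long <- do.call(rbind, lapply(groups, function(g) {
      pm <- peak_measures[[key0(g)]]
      do.call(rbind, lapply(roi_names, function(rn) {
        data.frame(
          subject = sprintf("%s-%02d", g, seq_along(pm[[rn]])),
          age = g, roi = rn,
          amplitude = vapply(pm[[rn]], `[[`, numeric(1), "amplitude"),
          latency = vapply(pm[[rn]], `[[`, numeric(1), "latency"),
          stringsAsFactors = FALSE
        )
      }))
    }))
    vmmn_anovas$amplitude_soa0 <- rm_anova(long, "amplitude", "subject",
                                           within = "roi", between = "age")
    vmmn_anovas$latency_soa0 <- rm_anova(long, "latency", "subject",
                                         within = "roi", between = "age")
  }

  # ---- behaviour: hit rates -------------------------------------------
  hit_rates <- do.call(rbind, hit_rows)
  hit_summary <- stats::aggregate(hit_rate ~ group + soa, hit_rates,
                                  function(x) c(mean = mean(x), sd = stats::sd(x)))
  hit_summary <- cbind(hit_summary[c("group", "soa")],
                       as.data.frame(hit_summary$hit_rate))
  hit_anova <- rm_anova(hit_rates, "hit_rate", "subject",
                        within = "soa", between = "group")

  # ---- behaviour: 2AFC ------------------------------------------------
  two_rows <- list()
  for (gi in seq_along(groups)) {
    for (s in seq_len(config$n_subjects_per_group)) {
      tbl <- generate_2afc_responses(
        twoafc_model, seed = derive_seed(config$seed, 900000L + gi * 1000L + s)
      )
      sc <- score_2afc(tbl)
      sc$group <- groups[gi]
      sc$subject <- sprintf("%s-%02d", groups[gi], s)
      two_rows[[length(two_rows) + 1L]] <- sc
    }
  }
  twoafc <- do.call(rbind, two_rows)
  twoafc_anova <- rm_anova(twoafc, "proportion", "subject",
                           within = "soa_ms", between = "group")

  out <- list(
    detection = detection,
    presence = presence,
    peaks = if (length(peak_rows)) do.call(rbind, peak_rows) else NULL,
    hit_rates = hit_rates, hit_summary = hit_summary, hit_anova = hit_anova,
    twoafc = twoafc, twoafc_anova = twoafc_anova,
    vmmn_anovas = vmmn_anovas,
    errors = errors,
    config = config
  )
  class(out) <- "vmmn_run"

  if (!is.null(out_dir)) write_run_bundle(out, out_dir)
  if (length(errors)) {
    warning(sprintf("%d subject x SOA cell(s) failed; see $errors", length(errors)))
  }
  out
}

# write result tables + manifest (file -> md5) to out_dir
write_run_bundle <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wr <- function(obj, name) {
    p <- file.path(out_dir, name)
    if (is.data.frame(obj)) {
      utils::write.csv(obj, p, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, p, auto_unbox = TRUE, digits = NA, force = TRUE)
    }
    paths <<- c(paths, p)
  }
  wr(run$detection, "detection_windows.csv")
  if (!is.null(run$peaks)) wr(run$peaks, "vmmn_peaks.csv")
  wr(run$hit_rates, "hit_rates.csv")
  wr(run$twoafc, "twoafc_scores.csv")
  wr(run$presence, "vmmn_presence.json")
  manifest <- list(
    seed = run$config$seed,
    n_subjects_per_group = run$config$n_subjects_per_group,
    r_version = as.character(getRversion()),
    files = lapply(stats::setNames(paths, basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.vmmn_run <- function(x, ...) {
  cat(sprintf(
    "<vmmn_run> %d subjects/group, %d SOA levels; %d significant window(s)\n",
    x$config$n_subjects_per_group, length(x$config$session$soa_levels),
    nrow(x$detection)
  ))
  present <- names(Filter(isTRUE, x$presence))
  if (length(present)) {
    cat("  vMMN present in:", paste(present, collapse = ", "), "\n")
  }
  invisible(x)
}
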