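#' Evoked-component specification
#'
#' Describes one simulated event-related component as a Gaussian-windowed
#' pulse: a peak latency (ms, relative to the onset of the first or second
#' fragment), a signed peak amplitude (microvolts), a temporal width
#' (Gaussian SD, ms) and a scalp topography (per-channel gain in 0-1).
#' An `applies` predicate decides, per stimulus event, whether the component
#' is inserted; it receives `(role, category, soa)` and returns a logical.
#'
#' @param name component label, e.g. `"P1"`, `"N1"`, `"vMMN"`.
#' @param peak_latency ms relative to the locking fragment onset.
#' @param amplitude signed peak amplitude, microvolts (negative for vMMN).
#' @param width Gaussian SD, ms.
#' @param topography named numeric vector of per-channel gains in 0-1;
#'   names must be channel labels of the montage used at simulation time.
#' @param lock `"fragment1"` (exogenous components) or `"fragment2"`
#'   (change-related activity: the vMMN clock starts at deviance onset).
#' @param applies `function(role, category, soa)` returning `TRUE` when the
#'   component should be added to that event.
#' @return object of class `vmmn_component`.
#' @export
component_spec <- function(name, peak_latency, amplitude, width, topography,
                           lock = c("fragment1", "fragment2"),
                           applies = function(role, category, soa) TRUE) {
  lock <- match.arg(lock)
  stopifnot(is.numeric(topography), !is.null(names(topography)),
            all(topography >= 0), all(topography <= 1), width > 0)
  out <- list(
    name = name, peak_latency = peak_latency, amplitude = amplitude,
    width = width, topography = topography, lock = lock, applies = applies
  )
  class(out) <- "vmmn_component"
  out
}

#' Group simulation profile
#'
#' Collects everything the forward model needs for one age group: the evoked
#' components common to all stimuli (P1, N1), the change-related vMMN, the
#' group's temporal-integration behaviour, and the background-noise model.
#'
#' Temporal integration is encoded by per-category *persistence limits*: the
#' largest SOA (ms) at which a deviant of that category still elicits a vMMN
#' (the two fragments are still fused into one percept). A limit of `-1`
#' means the category never elicits a vMMN in that group. The defaults
#' emulate the qualitative result pattern this package is built around:
#'
#' * young adults: vMMN to pseudo-letter deviants only in the whole-character
#'   condition (`persistence_limit_pseudo = 0`), never to letter deviants;
#' * older adults: vMMN to letter deviants at SOA 0 and to pseudo-letter
#'   deviants up to SOA 50 (`persistence_limit_pseudo = 50`), i.e. longer
#'   stimulus persistence.
#'
#' @param group `"young"` or `"older"`.
#' @param persistence_limit_letter,persistence_limit_pseudo max SOA (ms) at
#'   which deviants of the category evoke a vMMN; `-1` = never.
#' @param vmmn_latency,vmmn_amplitude,vmmn_width vMMN Gaussian parameters
#'   (latency relative to second-fragment onset; amplitude must be negative
#'   with peak latency inside 150-300 ms).
#' @param p1_latency,p1_amplitude,n1_latency,n1_amplitude exogenous component
#'   parameters (fragment-1 locked).
#' @param noise_amplitude RMS of the 1/f background noise per channel,
#'   microvolts.
#' @param noise_exponent spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param hit_prob probability that the simulated observer responds to a
#'   frame-thickening task event (used by [generate_task_responses()]).
#' @return object of class `vmmn_profile`.
#' @export
#' @examples
#' older <- group_profile("older")
#' older$persistence_limit_pseudo  # 50: integration survives a 50 ms SOA
group_profile <- function(group = c("young", "older"),
                          persistence_limit_letter = NULL,
                          persistence_limit_pseudo = NULL,
                          vmmn_latency = NULL,
                          vmmn_amplitude = -1.0,
                          vmmn_width = 20,
                          p1_latency = NULL, p1_amplitude = 2.5,
                          n1_latency = NULL, n1_amplitude = -4,
                          noise_amplitude = 10,
                          noise_exponent = 1,
                          hit_prob = 0.8) {
  group <- match.arg(group)
  defaults <- if (group == "young") {
    list(pl_letter = -1, pl_pseudo = 0, vmmn_lat = 234, p1_lat = 106, n1_lat = 185)
  } else {
    list(pl_letter = 0, pl_pseudo = 50, vmmn_lat = 248, p1_lat = 110, n1_lat = 178)
  }
  pl_letter <- persistence_limit_letter %||% defaults$pl_letter
  pl_pseudo <- persistence_limit_pseudo %||% defaults$pl_pseudo
  vmmn_lat <- vmmn_latency %||% defaults$vmmn_lat
  if (vmmn_amplitude >= 0) stopf("vmmn_amplitude must be negative")
  if (vmmn_lat < 150 || vmmn_lat > 300) {
    stopf("vMMN peak latency must lie within 150-300 ms")
  }

  limits <- c(letter = pl_letter, `pseudo-letter` = pl_pseudo)
  vmmn_applies <- function(role, category, soa) {
    role == "deviant" && limits[[category]] >= 0 && soa <= limits[[category]]
  }

  components <- list(
    component_spec("P1", p1_latency %||% defaults$p1_lat, p1_amplitude, width = 15,
                   topography = posterior_topography(left_gain = 0.7),
                   lock = "fragment1"),
    component_spec("N1", n1_latency %||% defaults$n1_lat, n1_amplitude, width = 25,
                   topography = posterior_topography(),
                   lock = "fragment1"),
    component_spec("vMMN", vmmn_lat, vmmn_amplitude, width = vmmn_width,
                   topography = posterior_topography(),
                   lock = "fragment2", applies = vmmn_applies)
  )

  out <- list(
    group = group,
    persistence_limit_letter = pl_letter,
    persistence_limit_pseudo = pl_pseudo,
    components = components,
    noise_amplitude = noise_amplitude,
    noise_exponent = noise_exponent,
    hit_prob = hit_prob
  )
  class(out) <- "vmmn_profile"
  out
}

#' @rdname group_profile
#' @export
default_profiles <- function() {
  list(young = group_profile("young"), older = group_profile("older"))
}

#' @export
print.vmmn_profile <- function(x, ...) {
  cat(sprintf(
    "<vmmn_profile %s> persistence limits: letter %g ms, pseudo-letter %g ms; noise %g uV (1/f^%g)\n",
    x$group, x$persistence_limit_letter, x$persistence_limit_pseudo,
    x$noise_amplitude, x$noise_exponent
  ))
  invisible(x)
}

# convenience accessor used by the forward model
persistence_limit <- function(profile, category) {
  switch(category,
    "letter" = profile$persistence_limit_letter,
    "pseudo-letter" = profile$persistence_limit_pseudo,
    stopf("unknown category '%s'", category)
  )
}
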