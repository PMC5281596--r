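#' Default electrode montage
#'
#' Channel labels for the simulated recordings: 37 scalp electrodes laid out
#' according to the extended 10-20 system plus two bipolar ocular channels
#' (HEOG, VEOG). The posterior parieto-occipital sites PO7/PO9 (left) and
#' PO8/PO10 (right) carry the vMMN regions of interest.
#'
#' @param include_eog include the two bipolar EOG channels (default `TRUE`).
#' @return character vector of channel labels.
#' @export
#' @examples
#' length(default_montage())              # 39
#' length(default_montage(include_eog = FALSE))  # 37
default_montage <- function(include_eog = TRUE) {
  scalp <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP1", "CP2", "CP6", "TP9", "TP10",
    "P7", "P3", "Pz", "P4", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8", "PO9", "PO10",
    "O1", "Oz", "O2"
  )
  stopifnot(length(scalp) == 37L)
  if (include_eog) c(scalp, "HEOG", "VEOG") else scalp
}

#' Posterior scalp topography
#'
#' Gain map (0-1 per channel) peaking over the parieto-occipital electrodes,
#' used as the default spatial distribution of the simulated visual evoked
#' components and of the vMMN. Gains fall off towards anterior sites; the
#' ocular channels receive none of the cortical signal.
#'
#' @param right_gain,left_gain multipliers applied to right- respectively
#'   left-hemisphere channels (odd labels are left, even right), allowing
#'   lateralised components such as the right-dominant P1.
#' @return named numeric vector over [default_montage()].
#' @export
posterior_topography <- function(right_gain = 1, left_gain = 1) {
  base <- c(
    Fp1 = 0.05, Fp2 = 0.05, F7 = 0.05, F3 = 0.05, Fz = 0.05, F4 = 0.05,
    F8 = 0.05, FC5 = 0.1, FC1 = 0.1, FC2 = 0.1, FC6 = 0.1,
    T7 = 0.15, C3 = 0.15, Cz = 0.15, C4 = 0.15, T8 = 0.15,
    CP5 = 0.3, CP1 = 0.3, CP2 = 0.3, CP6 = 0.3, TP9 = 0.3, TP10 = 0.3,
    P7 = 0.6, P3 = 0.55, Pz = 0.55, P4 = 0.55, P8 = 0.6,
    PO7 = 1, PO3 = 0.8, POz = 0.8, PO4 = 0.8, PO8 = 1, PO9 = 1, PO10 = 1,
    O1 = 0.9, Oz = 0.9, O2 = 0.9,
    HEOG = 0, VEOG = 0
  )
  side <- channel_side(names(base))
  base[side == "left"] <- base[side == "left"] * left_gain
  base[side == "right"] <- base[side == "right"] * right_gain
  base
}

# left/right/midline classification from 10-20 labels (odd digit = left)
channel_side <- function(labels) {
  digit <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", labels)))
  out <- rep("midline", length(labels))
  out[!is.na(digit) & digit %% 2L == 1L] <- "left"
  out[!is.na(digit) & digit %% 2L == 0L] <- "right"
  out[labels %in% c("HEOG", "VEOG")] <- "midline"
  out
}
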