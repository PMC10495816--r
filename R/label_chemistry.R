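# Monoisotopic masses (Da). The user-facing tag masses are derived from these,
# never hard-coded, so the printed 4-decimal values are a genuine cross-check.
ISOTOPE_MASS <- c(
  H1  = 1.0078250319,
  H2  = 2.0141017780,
  C12 = 12.0,
  C13 = 13.0033548
)

# Per-label isotopic substitutions relative to the light (+C2H4) dimethyl:
# channel k substitutes k/2 pairs of H -> D, and channel 8 additionally swaps
# both carbons for 13C (2x(13C-12C) + 6x(2H-1H) = 8.0444 per label).
.channel_composition <- function(channel) {
  switch(as.character(channel),
    "0" = c(nD = 0L, n13C = 0L),
    "2" = c(nD = 2L, n13C = 0L),
    "4" = c(nD = 4L, n13C = 0L),
    "6" = c(nD = 6L, n13C = 0L),
    "8" = c(nD = 6L, n13C = 2L),
    abort(paste0("Unknown dimethyl channel: ", channel,
                 " (valid channels: 0, 2, 4, 6, 8)"))
  )
}

#' Dimethyl label schemes
#'
#' A `label_scheme` describes a multiplex design: the protease, the channel
#' set, and the per-label monoisotopic mass additions. Two schemes are in
#' routine use: a tryptic 3-plex (channels \eqn{\Delta}0/\eqn{\Delta}4/\eqn{\Delta}8)
#' and a Lys-N 5-plex (\eqn{\Delta}0/\eqn{\Delta}2/\eqn{\Delta}4/\eqn{\Delta}6/\eqn{\Delta}8),
#' where Lys-N digestion clusters both labelable amines at the peptide
#' N-terminus.
#'
#' @param kind `"3plex-trypsin"` or `"5plex-lysn"`.
#' @return A tibble of class `label_scheme` with one row per channel:
#'   `channel` (integer nominal delta), `label_mass` (monoisotopic mass added
#'   per label, Da), `label_delta` (mass difference to the \eqn{\Delta}0 label,
#'   Da), plus attributes `protease` and `kind`.
#' @examples
#' label_scheme("3plex-trypsin")
#' label_scheme("5plex-lysn")
#' @export
label_scheme <- function(kind = c("3plex-trypsin", "5plex-lysn")) {
  kind <- match.arg(kind)
  channels <- if (kind == "3plex-trypsin") c(0L, 4L, 8L) else c(0L, 2L, 4L, 6L, 8L)
  protease <- if (kind == "3plex-trypsin") "trypsin" else "lysn"
  out <- tibble(
    channel = channels,
    label_mass = vapply(channels, label_mass, numeric(1)),
    label_delta = vapply(channels, channel_delta, numeric(1))
  )
  structure(out, class = c("label_scheme", class(out)),
            protease = protease, kind = kind)
}

#' Monoisotopic mass of one dimethyl label
#'
#' Mass added to a single primary amine (peptide N-terminus or lysine
#' \eqn{\epsilon}-amine) by one dimethyl label of the given channel, computed
#' from isotope composition: the light label adds C2H4 (28.0313 Da), heavier
#' channels substitute deuterium for hydrogen and/or 13C for 12C.
#'
#' @param channel Integer nominal mass delta: 0, 2, 4, 6 or 8.
#' @return Mass addition in Da (full precision; the field prints 4 decimals).
#' @examples
#' round(label_mass(0), 4) # 28.0313
#' round(label_mass(4), 4) # 32.0564
#' @export
label_mass <- function(channel) {
  comp <- .channel_composition(channel)
  light <- 2 * ISOTOPE_MASS[["C12"]] + 4 * ISOTOPE_MASS[["H1"]]
  light +
    comp[["nD"]] * (ISOTOPE_MASS[["H2"]] - ISOTOPE_MASS[["H1"]]) +
    comp[["n13C"]] * (ISOTOPE_MASS[["C13"]] - ISOTOPE_MASS[["C12"]])
}

#' Per-label mass delta of a channel relative to the light channel
#'
#' @inheritParams label_mass
#' @return Mass delta in Da per label (e.g. 4.0251 for channel 4, the value
#'   passed to the search engine's channel declaration).
#' @examples
#' round(channel_delta(4), 4) # 4.0251
#' round(channel_delta(8), 4) # 8.0444
#' @export
channel_delta <- function(channel) {
  label_mass(channel) - label_mass(0L)
}

#' Number of dimethyl labels on a peptide
#'
#' Every peptide carries one label on its N-terminal amine plus one per lysine
#' residue. Tryptic peptides ending in arginine therefore carry 1 label, those
#' ending in lysine 2; Lys-N peptides (lysine at the N-terminus) carry 2 with
#' both clustered at the N-terminus. The count rule is protease-independent
#' and safe under missed cleavages (each internal K adds one).
#'
#' @param peptide Stripped peptide sequence, one-letter amino-acid codes.
#' @param protease `"trypsin"`, `"lysc"` or `"lysn"` (informational; the count
#'   is 1 + #K for all of them).
#' @return Integer label count.
#' @examples
#' label_count("PEPTIDER") # 1
#' label_count("PEPTIDEK") # 2
#' @export
label_count <- function(peptide, protease = c("trypsin", "lysc", "lysn")) {
  match.arg(protease)
  if (!is.character(peptide) || length(peptide) != 1L || is.na(peptide) ||
      nchar(peptide) == 0L) {
    abort("`peptide` must be a single non-empty sequence string.")
  }
  if (grepl("[^A-Z]", peptide)) {
    abort("`peptide` must use one-letter amino-acid codes (A-Z).")
  }
  1L + stringr::str_count(peptide, stringr::fixed("K"))
}

#' Total precursor mass shift from dimethyl labeling
#'
#' @inheritParams label_count
#' @inheritParams label_mass
#' @return `label_count(peptide) * label_mass(channel)`, in Da.
#' @examples
#' round(precursor_mass_shift("PEPTIDEK", 0), 4) # 56.0626
#' @export
precursor_mass_shift <- function(peptide, channel,
                                 protease = c("trypsin", "lysc", "lysn")) {
  protease <- match.arg(protease)
  label_count(peptide, protease) * label_mass(channel)
}

#' Labeling efficiency from a DDA evidence table
#'
#' Intensity-weighted fraction of the detected peptide signal that is fully
#' labeled: `sum(intensity[fully labeled]) / sum(intensity)`. A peptide is
#' fully labeled iff every labelable site (see [label_count()]) carries a
#' dimethyl label; partially labeled peptides count against efficiency.
#'
#' @param evidence Data frame with an `intensity` column and either a logical
#'   `fully_labeled` column, or `peptide` + `n_labels` columns from which full
#'   labeling is derived as `n_labels == label_count(peptide)`.
#' @param protease Passed to [label_count()] when deriving `fully_labeled`.
#' @return Fraction in `[0, 1]`.
#' @examples
#' labeling_efficiency(data.frame(
#'   fully_labeled = c(TRUE, FALSE), intensity = c(995, 5)
#' )) # 0.995
#' @export
labeling_efficiency <- function(evidence,
                                protease = c("trypsin", "lysc", "lysn")) {
  protease <- match.arg(protease)
  evidence <- as_tibble(evidence)
  if (nrow(evidence) == 0L) abort("`evidence` must contain at least one row.")
  if (!"intensity" %in% names(evidence)) {
    abort("`evidence` must have an `intensity` column.")
  }
  if (any(evidence$intensity < 0, na.rm = TRUE)) {
    abort("Intensities must be non-negative.")
  }
  if (!"fully_labeled" %in% names(evidence)) {
    if (!all(c("peptide", "n_labels") %in% names(evidence))) {
      abort(paste0("`evidence` needs either a logical `fully_labeled` column ",
                   "or `peptide` + `n_labels` columns."))
    }
    evidence$fully_labeled <- purrr::map2_lgl(
      evidence$peptide, evidence$n_labels,
      function(p, n) n == label_count(p, protease)
    )
  }
  total <- sum(evidence$intensity, na.rm = TRUE)
  if (!is.finite(total) || total <= 0) {
    abort("Total intensity is zero; labeling efficiency is undefined.")
  }
  sum(evidence$intensity[evidence$fully_labeled], na.rm = TRUE) / total
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme: %s, protease %s>\n",
              attr(x, "kind"), attr(x, "protease")))
  NextMethod()
}
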