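#' Monoisotopic mass constants
#'
#' Fixed physical constants used throughout the package: the proton mass, the
#' mass of water, and the monoisotopic masses of the 20 standard amino-acid
#' residues. Isoleucine and leucine share one mass; no attempt is made to
#' distinguish them.
#'
#' @return A named list with elements `proton` (Da), `water` (Da) and
#'   `residues` (named numeric vector of 20 residue masses, Da).
#' @export
#' @examples
#' mass_constants()$proton
mass_constants <- function() {
  list(proton = 1.007276, water = 18.010565, residues = .residue_masses)
}

.residue_masses <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.proton <- 1.007276
.water <- 18.010565

#' Monoisotopic residue masses
#'
#' @return Named numeric vector of the 20 standard residue masses in Da.
#' @export
residue_masses <- function() .residue_masses

.check_peptide <- function(peptide) {
  if (length(peptide) != 1L || is.na(peptide) || !nzchar(peptide)) {
    stop("`peptide` must be a single non-empty string", call. = FALSE)
  }
  aa <- strsplit(peptide, "")[[1]]
  bad <- which(!aa %in% names(.residue_masses))
  if (length(bad)) {
    stop(sprintf(
      "unknown residue '%s' at position %d in peptide '%s'",
      aa[bad[1]], bad[1], peptide
    ), call. = FALSE)
  }
  aa
}

#' Theoretical b-ion prefix series of a peptide
#'
#' Builds the b-ion model of a candidate peptide: singly charged prefix masses
#' `b_i = proton + sum(residues 1..i)`. The peptide is represented by this
#' series alone during alignment; y-ion evidence enters through spectrum
#' completion (see [complete_spectrum()]).
#'
#' @param peptide Uppercase amino-acid string (20 standard residues).
#' @return A tibble with one row per residue: `position`, `residue`,
#'   `residue_mass` and `b_mz` (the b-ion m/z in Da). The peptide neutral
#'   mass (sum of residues + water) is attached as attribute `neutral_mass`,
#'   and the peptide as attribute `peptide`.
#' @export
#' @examples
#' b_ion_series("HINATESVR")
b_ion_series <- function(peptide) {
  aa <- .check_peptide(peptide)
  rm <- unname(.residue_masses[aa])
  out <- tibble::tibble(
    position = seq_along(aa),
    residue = aa,
    residue_mass = rm,
    b_mz = .proton + cumsum(rm)
  )
  attr(out, "neutral_mass") <- sum(rm) + .water
  attr(out, "peptide") <- peptide
  class(out) <- c("specshift_model", class(out))
  out
}

#' Peptide monoisotopic neutral mass
#'
#' @param peptide Amino-acid string.
#' @return Neutral monoisotopic mass in Da (residues + water).
#' @export
peptide_neutral_mass <- function(peptide) {
  aa <- .check_peptide(peptide)
  sum(.residue_masses[aa]) + .water
}

#' Neutral mass from a precursor m/z and charge
#'
#' @param mz Precursor m/z in Da.
#' @param charge Positive integer charge state.
#' @return Neutral mass `(mz - proton) * charge` in Da.
#' @export
#' @examples
#' precursor_neutral_mass(528.26, 2)
precursor_neutral_mass <- function(mz, charge) {
  if (any(charge <= 0) || any(charge != as.integer(charge))) {
    stop("`charge` must be a positive integer", call. = FALSE)
  }
  (mz - .proton) * charge
}

#' Precursor mass difference between a spectrum and a candidate peptide
#'
#' The quantity the alignment splits into localized shifts plus a residual:
#' observed precursor neutral mass minus the candidate peptide neutral mass.
#'
#' @param precursor_mz Observed precursor m/z (Da).
#' @param charge Precursor charge state.
#' @param peptide Candidate peptide string.
#' @return Mass difference in Da.
#' @export
#' @examples
#' delta_mass(514.27, 2, "HINATESVR")
delta_mass <- function(precursor_mz, charge, peptide) {
  precursor_neutral_mass(precursor_mz, charge) - peptide_neutral_mass(peptide)
}
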