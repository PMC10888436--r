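# Residue masses (Da): mass of the amino-acid residue as incorporated in a
# peptide chain, i.e. the free amino acid minus one water. Monoisotopic
# values to 5 decimals, average to 4; cross-checked against a published
# residue-mass table before freezing. I and L are isobaric by construction.
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

AVG_RESIDUE_MASS <- c(
  G = 57.0514, A = 71.0780, S = 87.0774, P = 97.1154, V = 99.1313,
  T = 101.1040, C = 103.1428, L = 113.1579, I = 113.1579,
  N = 114.1028, D = 115.0876, Q = 128.1294, K = 128.1725,
  E = 129.1142, M = 131.1960, H = 137.1395, F = 147.1742,
  R = 156.1859, Y = 163.1736, W = 186.2103)

#' Physical mass constants used throughout the package
#'
#' Monoisotopic and average water, the proton mass used for charge-state
#' arithmetic, and the methionine-oxidation shift. The proton is
#' 1.007276 Da (the mass of H+), not the atomic weight of hydrogen;
#' four-decimal agreement with high-resolution MH+ values requires it.
#'
#' @format Named list with elements `water_mono`, `water_avg`, `proton`,
#'   `met_oxidation`.
#' @export
mass_constants <- function() {
  list(water_mono = 18.010565,
       water_avg  = 18.01528,
       proton     = 1.007276,
       met_oxidation = 15.994915)
}

#' Describe a residue modification
#'
#' @param name Modification name, e.g. `"oxidation"`.
#' @param target_residue One-letter code the modification applies to.
#' @param position 1-based residue index on the parent sequence.
#' @param mass_shift Mass shift in Da (monoisotopic; also used on the
#'   average scale, where the sub-0.01 Da difference is immaterial).
#' @return A `modification` object.
#' @export
modification <- function(name, target_residue, position, mass_shift) {
  stopifnot(is.character(name), length(position) == 1L, position >= 1,
            is.numeric(mass_shift))
  structure(list(name = name, target_residue = toupper(target_residue),
                 position = as.integer(position), mass_shift = mass_shift),
            class = "modification")
}

#' Methionine oxidation at a given position
#'
#' Convenience constructor for the +15.994915 Da variable modification.
#'
#' @param position 1-based residue index of the methionine.
#' @export
met_oxidation <- function(position) {
  modification("oxidation", "M", position, mass_constants()$met_oxidation)
}

check_mods <- function(seq, mods) {
  if (is.null(mods)) return(invisible(NULL))
  if (inherits(mods, "modification")) mods <- list(mods)
  chars <- seq_chars(seq)
  for (m in mods) {
    if (!inherits(m, "modification"))
      stop("`mods` must be modification objects", call. = FALSE)
    if (m$position > length(chars))
      stop(sprintf("modification position %d beyond sequence length %d",
                   m$position, length(chars)), call. = FALSE)
    if (chars[m$position] != m$target_residue)
      stop(sprintf(
        "modification '%s' targets %s but residue at position %d is %s",
        m$name, m$target_residue, m$position, chars[m$position]),
        call. = FALSE)
  }
  invisible(NULL)
}

mod_list <- function(mods) {
  if (is.null(mods)) list()
  else if (inherits(mods, "modification")) list(mods)
  else mods
}

#' Neutral mass of a linear or head-to-tail circular peptide
#'
#' Linear peptides are the residue-mass sum plus one water (the chain's
#' terminal H and OH); circular peptides omit the water, reflecting the
#' dehydration that forms the head-to-tail amide bond. Modifications add
#' their shifts.
#'
#' @param seq A [residue_seq] or a plain string (treated as linear).
#' @param mods `NULL`, a single [modification], or a list of them.
#' @param scale `"monoisotopic"` (default) or `"average"`.
#' @return Neutral mass in Da at full double precision.
#' @examples
#' peptide_mass("GG")                               # 132.05359
#' peptide_mass(residue_seq("GG", "circular"))      # minus one water
#' @export
peptide_mass <- function(seq, mods = NULL,
                         scale = c("monoisotopic", "average")) {
  scale <- match.arg(scale)
  seq <- as_residue_seq(seq)
  check_mods(seq, mods)
  tab <- if (scale == "monoisotopic") MONO_RESIDUE_MASS else AVG_RESIDUE_MASS
  water <- if (scale == "monoisotopic") mass_constants()$water_mono
           else mass_constants()$water_avg
  m <- sum(tab[seq_chars(seq)])
  if (!is_circular(seq)) m <- m + water
  m + sum(vapply(mod_list(mods), function(x) x$mass_shift, numeric(1)))
}

#' Singly-protonated monoisotopic mass (MH+)
#'
#' The theoretical MH+ of a linear peptide: monoisotopic neutral mass
#' plus one proton. Tryptic fragments are linear by construction, so
#' circular input is an error.
#'
#' @inheritParams peptide_mass
#' @return MH+ in Da.
#' @examples
#' mh_plus("GLSLIAAAGK")  # 900.5512 to 4 decimals
#' @export
mh_plus <- function(seq, mods = NULL) {
  seq <- as_residue_seq(seq)
  if (is_circular(seq))
    stop("mh_plus is defined for linear peptides; got circular topology",
         call. = FALSE)
  peptide_mass(seq, mods, "monoisotopic") + mass_constants()$proton
}

#' m/z of a neutral mass at a given positive charge
#'
#' `(M + z * proton) / z` for a neutral mass `M`.
#'
#' @param neutral_mass Neutral mass in Da.
#' @param charge Positive integer charge state.
#' @return m/z in Da per elementary charge.
#' @export
mz_for_charge <- function(neutral_mass, charge) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge))
    stop("`charge` must be a positive integer", call. = FALSE)
  (neutral_mass + charge * mass_constants()$proton) / charge
}

#' Signed relative mass error in parts per million
#'
#' @param observed Observed m/z (or mass).
#' @param theoretical Theoretical m/z (or mass); must be positive.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0))
    stop("`theoretical` must be positive", call. = FALSE)
  1e6 * (observed - theoretical) / theoretical
}
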