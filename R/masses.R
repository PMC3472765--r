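# Atomic masses (Da).  Monoisotopic values: CODATA/IUPAC atomic mass
# evaluation, principal isotope, >= 5 d.p.  Average values: IUPAC 2021
# standard atomic weights.
.atomic_mono <- c(
  C = 12.00000000,
  H = 1.00782503,
  N = 14.00307401,
  O = 15.99491462,
  S = 31.97207117
)

.atomic_avg <- c(
  C = 12.011,
  H = 1.008,
  N = 14.007,
  O = 15.999,
  S = 32.06
)

# Proton (CODATA) and residue elemental compositions of the 20 standard
# amino-acid residues (i.e. amino acid minus one water).
.proton_mono <- 1.00727646

.residue_formula <- rbind(
  G = c(C = 2,  H = 3,  N = 1, O = 1, S = 0),
  A = c(C = 3,  H = 5,  N = 1, O = 1, S = 0),
  S = c(C = 3,  H = 5,  N = 1, O = 2, S = 0),
  P = c(C = 5,  H = 7,  N = 1, O = 1, S = 0),
  V = c(C = 5,  H = 9,  N = 1, O = 1, S = 0),
  T = c(C = 4,  H = 7,  N = 1, O = 2, S = 0),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6,  H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4,  H = 6,  N = 2, O = 2, S = 0),
  D = c(C = 4,  H = 5,  N = 1, O = 3, S = 0),
  Q = c(C = 5,  H = 8,  N = 2, O = 2, S = 0),
  K = c(C = 6,  H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5,  H = 7,  N = 1, O = 3, S = 0),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1, S = 0),
  F = c(C = 9,  H = 9,  N = 1, O = 1, S = 0),
  R = c(C = 6,  H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9,  H = 9,  N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.formula_mass <- function(counts, kind) {
  tab <- if (kind == "monoisotopic") .atomic_mono else .atomic_avg
  sum(counts * tab[colnames(.residue_formula)])
}

.residue_mono <- apply(.residue_formula, 1, .formula_mass, kind = "monoisotopic")
.residue_avg  <- apply(.residue_formula, 1, .formula_mass, kind = "average")

.water_mono <- .formula_mass(c(C = 0, H = 2, N = 0, O = 1, S = 0), "monoisotopic")
.water_avg  <- .formula_mass(c(C = 0, H = 2, N = 0, O = 1, S = 0), "average")

.check_kind <- function(kind) match.arg(kind, c("monoisotopic", "average"))

#' Residue masses for the 20 standard amino acids
#'
#' Masses are derived from a single embedded table of atomic masses and
#' residue elemental compositions, so monoisotopic residue masses, the GG
#' remnant mass and peptide masses are mutually consistent to the last digit.
#'
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Named numeric vector of residue masses in Da, one per one-letter
#'   amino-acid code.
#' @export
#' @examples
#' residue_masses()[["G"]]
residue_masses <- function(kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  if (kind == "monoisotopic") .residue_mono else .residue_avg
}

#' Mass of water
#'
#' @inheritParams residue_masses
#' @return Mass of H2O in Da.
#' @export
water_mass <- function(kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  if (kind == "monoisotopic") .water_mono else .water_avg
}

#' Mass of the proton
#'
#' @return Proton mass in Da, used for m/z conversion.
#' @export
proton_mass <- function() .proton_mono

#' Mass delta of the GG (diglycine) ubiquitination remnant
#'
#' Tryptic digestion of a ubiquitinated protein leaves a Gly-Gly dipeptide
#' isopeptide-linked to the modified lysine's epsilon-amine.  Both glycines
#' are in amide linkage, so the added mass is exactly two glycine residue
#' masses (elemental composition C4H6N2O2, no water): 114.04 Da
#' monoisotopic, 114.1 Da average.
#'
#' @inheritParams residue_masses
#' @return The GG remnant mass delta in Da.
#' @export
#' @examples
#' round(gg_delta_mass("monoisotopic"), 2)  # 114.04
#' round(gg_delta_mass("average"), 1)       # 114.1
gg_delta_mass <- function(kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  .formula_mass(c(C = 4, H = 6, N = 2, O = 2, S = 0), kind)
}

#' Mass delta of cysteine carbamidomethylation
#'
#' Fixed modification from iodoacetamide alkylation of cysteine SH groups
#' during sample preparation (+C2H3NO).
#'
#' @inheritParams residue_masses
#' @return Modification delta in Da (+57.02146 monoisotopic).
#' @export
carbamidomethyl_delta <- function(kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  .formula_mass(c(C = 2, H = 3, N = 1, O = 1, S = 0), kind)
}

#' Mass delta of methionine oxidation
#'
#' Variable modification (+O, +15.99491 monoisotopic).
#'
#' @inheritParams residue_masses
#' @return Modification delta in Da.
#' @export
oxidation_delta <- function(kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  .formula_mass(c(C = 0, H = 0, N = 0, O = 1, S = 0), kind)
}

.check_sequence <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), rownames(.residue_formula))
  if (length(bad)) {
    stop("unknown residue code(s) in sequence: ", paste(bad, collapse = ", "))
  }
  chars
}

#' Build a peptide modification table
#'
#' Modifications are represented as a data frame with columns `pos`
#' (1-based position within the peptide), `delta` (Da) and `label`.
#' GG remnants must sit on lysine.
#'
#' @param sequence Peptide sequence.
#' @param gg_sites Integer positions (1-based, within the peptide) of
#'   GG-modified lysines.
#' @param carbamidomethyl If `TRUE`, add the fixed carbamidomethyl delta at
#'   every cysteine.
#' @param oxidized_met Integer positions of oxidised methionines.
#' @param kind Mass scale for the deltas.
#' @return data.frame with columns `pos`, `delta`, `label`.
#' @export
#' @examples
#' build_mods("GKCR", gg_sites = 2, carbamidomethyl = TRUE)
build_mods <- function(sequence, gg_sites = integer(), carbamidomethyl = FALSE,
                       oxidized_met = integer(),
                       kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  chars <- .check_sequence(sequence)
  gg_sites <- as.integer(gg_sites)
  if (length(gg_sites) && any(chars[gg_sites] != "K")) {
    stop("GG modification positions must index 'K' residues")
  }
  oxidized_met <- as.integer(oxidized_met)
  if (length(oxidized_met) && any(chars[oxidized_met] != "M")) {
    stop("oxidation positions must index 'M' residues")
  }
  cys <- if (carbamidomethyl) which(chars == "C") else integer()
  data.frame(
    pos = c(gg_sites, cys, oxidized_met),
    delta = c(rep(gg_delta_mass(kind), length(gg_sites)),
              rep(carbamidomethyl_delta(kind), length(cys)),
              rep(oxidation_delta(kind), length(oxidized_met))),
    label = c(rep("GG", length(gg_sites)),
              rep("Carbamidomethyl", length(cys)),
              rep("Oxidation", length(oxidized_met))),
    stringsAsFactors = FALSE
  )
}

#' Neutral monoisotopic or average mass of a (modified) peptide
#'
#' Sum of residue masses plus one water plus all modification deltas.
#'
#' @param sequence Peptide sequence (one-letter codes).
#' @param mods Optional modification table as built by [build_mods()];
#'   only the `delta` column enters the mass.
#' @param kind `"monoisotopic"` or `"average"`.
#' @return Neutral peptide mass in Da.
#' @export
#' @examples
#' peptide_mass("GK")
#' peptide_mass("GK", mods = build_mods("GK", gg_sites = 2))
peptide_mass <- function(sequence, mods = NULL,
                         kind = c("monoisotopic", "average")) {
  kind <- .check_kind(kind)
  chars <- .check_sequence(sequence)
  res <- if (kind == "monoisotopic") .residue_mono else .residue_avg
  m <- sum(res[chars]) + water_mass(kind)
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > length(chars))) {
      stop("modification position outside peptide")
    }
    m <- m + sum(mods$delta)
  }
  m
}

#' Mass-to-charge ratio of an ion
#'
#' @param mass Neutral mass in Da.
#' @param charge Positive integer charge state.
#' @return `(mass + charge * proton) / charge`.
#' @export
#' @examples
#' mz(1000, 2)
mz <- function(mass, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  (mass + charge * .proton_mono) / charge
}

#' Neutral mass from an observed m/z and charge
#'
#' Inverse of [mz()]: charge deconvolution of a precursor.
#'
#' @param x Observed m/z.
#' @param charge Positive integer charge state.
#' @return Neutral mass in Da.
#' @export
neutral_mass <- function(x, charge) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer")
  }
  x * charge - charge * .proton_mono
}
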