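#' @keywords internal
"_PACKAGE"

## Monoisotopic elemental masses (IUPAC/CODATA). These constants are the
## foundation of every m/z in the package; do not round.
.ELEMENTS <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163,
  S = 31.97207100
)

.PROTON_MASS  <- 1.007276466
.WATER_MASS   <- 2 * .ELEMENTS[["H"]] + .ELEMENTS[["O"]]  # 18.0105646
.ISOTOPE_SPACING <- 1.0033548  # 13C - 12C

#' Monoisotopic mass of an elemental formula
#'
#' Parses a Hill-style formula such as `"C8H13NO5"`, `"H2O"`, `"CO"` or
#' `"HPO3"` and returns its monoisotopic mass. Supported elements are
#' C, H, N, O, P and S.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' formula_mass("H2O")        # 18.010565
#' formula_mass("C8H13NO5")   # the HexNAc residue, 203.079373
#' @export
formula_mass <- function(formula) {
  vapply(formula, function(f) {
    if (!is.character(f) || is.na(f) || !nzchar(f))
      stop("formula must be a non-empty string", call. = FALSE)
    matches <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    tokens <- regmatches(f, list(matches))[[1]]
    if (length(tokens) == 0L || sum(attr(matches, "match.length")) != nchar(f))
      stop("unparsable formula: '", f, "'", call. = FALSE)
    total <- 0
    for (tok in tokens) {
      elem <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!elem %in% names(.ELEMENTS))
        stop("unknown element '", elem, "' in formula '", f, "'", call. = FALSE)
      total <- total + n * .ELEMENTS[[elem]]
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

## Residue (i.e., dehydrated monosaccharide) formulas. A residue mass plus
## one water is the free monosaccharide; oxonium ions are residue + proton.
.RESIDUE_FORMULAS <- c(
  Hex     = "C6H10O5",
  HexNAc  = "C8H13NO5",
  dHex    = "C6H10O4",
  Pent    = "C5H8O4",
  NeuAc   = "C11H17NO8",
  NeuGc   = "C11H17NO9",
  Phospho = "HPO3",
  Acetyl  = "C2H2O",
  Sulfo   = "SO3"
)

#' Monosaccharide residue mass table
#'
#' Returns the immutable table of monoisotopic residue masses used to build
#' diagnostic-ion m/z values, together with the elemental constants
#' `proton`, `water` and `isotope` (the 13C-12C spacing). Residue masses
#' are dehydrated: Hex is 162.0528, HexNAc 203.0794, NeuAc 291.0954.
#'
#' @return Named numeric vector of masses in Da.
#' @export
monosaccharide_table <- function() {
  out <- c(
    formula_mass(unname(.RESIDUE_FORMULAS)),
    .PROTON_MASS, .WATER_MASS, .ISOTOPE_SPACING
  )
  names(out) <- c(names(.RESIDUE_FORMULAS), "proton", "water", "isotope")
  out
}

.residue_mass <- function(residue) {
  unknown <- setdiff(residue, names(.RESIDUE_FORMULAS))
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         ". Known residues: ", paste(names(.RESIDUE_FORMULAS), collapse = ", "),
         call. = FALSE)
  formula_mass(.RESIDUE_FORMULAS[residue])
}

#' Singly protonated oxonium ion m/z from a residue composition
#'
#' Computes the m/z of a glycan oxonium (B-type) ion as the sum of residue
#' masses, minus any neutral losses, plus any adducts, plus one proton.
#'
#' @param composition Named integer vector of residue counts, e.g.
#'   `c(HexNAc = 1)` or `c(Hex = 2, HexNAc = 1)`. May be empty only when
#'   at least one adduct is supplied.
#' @param losses Character vector of elemental formulas lost (e.g. `"H2O"`,
#'   `"CH6O3"`), or `NULL`.
#' @param adducts Character vector of elemental formulas gained (e.g.
#'   `"CO"` for formylation's net +28 Da), or `NULL`.
#' @return m/z in Da of the singly protonated ion.
#' @examples
#' oxonium_mz(c(HexNAc = 1))                     # 204.0866
#' oxonium_mz(c(Hex = 1, HexNAc = 1))            # 366.1395
#' oxonium_mz(c(NeuAc = 1), losses = "H2O")      # 274.0921
#' oxonium_mz(c(HexNAc = 1), adducts = "CO")     # formylated, 232.0816
#' @export
oxonium_mz <- function(composition, losses = NULL, adducts = NULL) {
  if (length(composition) == 0L && length(adducts) == 0L)
    stop("empty composition with no adduct does not define an ion",
         call. = FALSE)
  mass <- .PROTON_MASS
  if (length(composition)) {
    if (is.null(names(composition)) || any(!nzchar(names(composition))))
      stop("composition must be a named vector of residue counts",
           call. = FALSE)
    if (any(composition < 0) || any(composition != round(composition)))
      stop("residue counts must be non-negative integers", call. = FALSE)
    mass <- mass + sum(.residue_mass(names(composition)) * composition)
  }
  if (length(losses))  mass <- mass - sum(formula_mass(losses))
  if (length(adducts)) mass <- mass + sum(formula_mass(adducts))
  if (mass <= .PROTON_MASS)
    stop("resolved m/z (", format(mass), ") not above the proton mass",
         call. = FALSE)
  mass
}

## Amino-acid residue formulas (monoisotopic, dehydrated).
.AA_FORMULAS <- c(
  G = "C2H3NO",  A = "C3H5NO",   S = "C3H5NO2",  P = "C5H7NO",
  V = "C5H9NO",  T = "C4H7NO2",  C = "C3H5NOS",  L = "C6H11NO",
  I = "C6H11NO", N = "C4H6N2O2", D = "C4H5NO3",  Q = "C5H8N2O2",
  K = "C6H12N2O", E = "C5H7NO3", M = "C5H9NOS",  H = "C6H7N3O",
  F = "C9H9NO",  R = "C6H12N4O", Y = "C9H9NO2",  W = "C11H10N2O"
)

#' Monoisotopic amino-acid residue masses
#'
#' @return Named numeric vector over the 20 canonical residues (Da,
#'   dehydrated residue masses; add one water for the free peptide).
#' @examples
#' aa <- amino_acid_masses()
#' aa[["D"]] - aa[["N"]]  # the Asn -> Asp deamidation shift, 0.984 Da
#' @export
amino_acid_masses <- function() {
  out <- formula_mass(unname(.AA_FORMULAS))
  names(out) <- names(.AA_FORMULAS)
  out
}
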