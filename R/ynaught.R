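## Y-ion enumeration and extraction for identified glycopeptides.
##
## Y-type ions are the peptide backbone retaining a truncated glycan.
## Targets are defined either by the monosaccharide composition REMAINING
## on the peptide (remainder mode, built on the unmodified backbone mass)
## or by a NEUTRAL LOSS of monosaccharides from the intact precursor.

#' Neutral monoisotopic mass of a peptide backbone
#'
#' Sum of residue masses plus one water plus any non-glycan modification
#' deltas. The glycan mass is deliberately excluded: Y-ion arithmetic
#' starts from the unmodified backbone.
#'
#' @param sequence Amino-acid string over the 20 canonical residues.
#' @param modifications Numeric vector of modification delta masses in Da
#'   (positions are irrelevant to the total mass), or `NULL`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_backbone_mass("G")        # 75.03203
#' peptide_backbone_mass("PEPTIDE")  # 799.35997
#' @export
peptide_backbone_mass <- function(sequence, modifications = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a non-empty amino-acid string", call. = FALSE)
  aa <- strsplit(sequence, "")[[1]]
  masses <- amino_acid_masses()
  unknown <- setdiff(aa, names(masses))
  if (length(unknown))
    stop("unknown residue letter(s): ", paste(unique(unknown), collapse = ", "),
         call. = FALSE)
  sum(masses[aa]) + .WATER_MASS + sum(modifications %||% 0)
}

#' Y-ion m/z, remainder mode
#'
#' m/z of the peptide backbone carrying `remainder_mass` of glycan, at
#' charge `z` and isotopologue `k` (0 = monoisotopic, 1 = M+1, 2 = M+2).
#'
#' @param peptide_mass Neutral backbone mass (Da), glycan excluded.
#' @param remainder_mass Glycan mass remaining on the peptide (Da, >= 0;
#'   0 gives the bare-peptide Y0 ion).
#' @param z Charge (>= 1).
#' @param k Isotope index in 0..2.
#' @return m/z in Da.
#' @export
y_ion_mz_remainder <- function(peptide_mass, remainder_mass, z = 1L, k = 0L) {
  .check_zk(z, k)
  if (remainder_mass < 0) stop("remainder mass must be >= 0", call. = FALSE)
  (peptide_mass + remainder_mass + z * .PROTON_MASS) / z +
    k * .ISOTOPE_SPACING / z
}

#' Y-ion m/z, neutral-loss mode
#'
#' m/z of the intact precursor glycopeptide after a neutral loss of
#' `loss_mass`, at charge `z` and isotopologue `k`.
#'
#' @param precursor_neutral_mass Neutral mass of the intact glycopeptide
#'   (backbone + glycan), Da.
#' @param loss_mass Neutral loss (Da, in `[0, precursor_neutral_mass)`).
#' @param z Charge (>= 1).
#' @param k Isotope index in 0..2.
#' @return m/z in Da.
#' @export
y_ion_mz_neutral_loss <- function(precursor_neutral_mass, loss_mass,
                                  z = 1L, k = 0L) {
  .check_zk(z, k)
  if (loss_mass < 0 || loss_mass >= precursor_neutral_mass)
    stop("loss mass must lie in [0, precursor neutral mass)", call. = FALSE)
  (precursor_neutral_mass - loss_mass + z * .PROTON_MASS) / z +
    k * .ISOTOPE_SPACING / z
}

.check_zk <- function(z, k) {
  if (length(z) != 1L || z < 1L || z != round(z))
    stop("charge z must be a positive integer", call. = FALSE)
  if (length(k) != 1L || !k %in% 0:2)
    stop("isotope index k must be 0, 1 or 2", call. = FALSE)
}

#' Resolve a charge-range specification against a precursor charge
#'
#' Bounds may be integers or symbolic expressions in the precursor
#' charge `P`, e.g. `"1"` to `"P-1"`.
#'
#' @param lower,upper Bound specifications (integer or string in `P`).
#' @param P Precursor charge.
#' @return Integer vector of charges.
#' @examples
#' resolve_charge_range("1", "P-1", P = 3)  # 1 2
#' @export
resolve_charge_range <- function(lower, upper, P) {
  stopifnot(length(P) == 1L, P >= 1L)
  resolve_one <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    x <- gsub("[[:space:]]", "", x)
    if (!grepl("^[0-9P+*/()-]+$", x))
      stop("invalid charge bound: '", x, "'", call. = FALSE)
    as.integer(eval(parse(text = x), envir = list(P = as.integer(P))))
  }
  lo <- resolve_one(lower); hi <- resolve_one(upper)
  if (lo < 1L) stop("resolved lower charge bound ", lo, " < 1", call. = FALSE)
  if (hi > P) stop("resolved upper charge bound ", hi, " > precursor charge ",
                   P, call. = FALSE)
  if (hi < lo) stop("resolved charge range empty: ", lo, "..", hi,
                    call. = FALSE)
  lo:hi
}

#' Default Y-ion remainder compositions
#'
#' The bare peptide (Y0) plus the N-glycan core build-up series, as
#' residue-composition remainder masses.
#'
#' @return Named numeric vector of remainder masses (Da).
#' @export
default_y_remainders <- function() {
  tab <- monosaccharide_table()
  c(Y0 = 0,
    "Y-HexNAc" = tab[["HexNAc"]],
    "Y-HexNAc-dHex" = tab[["HexNAc"]] + tab[["dHex"]],
    "Y-HexNAc2" = 2 * tab[["HexNAc"]],
    "Y-HexNAc2-Hex" = 2 * tab[["HexNAc"]] + tab[["Hex"]],
    "Y-HexNAc2-Hex2" = 2 * tab[["HexNAc"]] + 2 * tab[["Hex"]],
    "Y-HexNAc2-Hex3" = 2 * tab[["HexNAc"]] + 3 * tab[["Hex"]])
}

#' Read a glycan mass database
#'
#' Tab-delimited file with columns `glycan` (name/composition) and
#' `mass` (neutral monoisotopic mass, Da).
#'
#' @param path TSV path.
#' @return Data frame with columns `glycan`, `mass`.
#' @export
read_glycan_db <- function(path) {
  if (!file.exists(path)) stop("glycan database not found: ", path,
                               call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if (!all(c("glycan", "mass") %in% names(tab)))
    stop("glycan database needs columns 'glycan' and 'mass': ", path,
         call. = FALSE)
  tab$mass <- as.numeric(tab$mass)
  if (any(is.na(tab$mass)) || any(tab$mass <= 0))
    stop("glycan database contains non-positive or unparsable masses",
         call. = FALSE)
  if (anyDuplicated(tab$glycan))
    stop("duplicate glycan names in database", call. = FALSE)
  tab[c("glycan", "mass")]
}

#' Read a glycopeptide PSM table
#'
#' Parses a FragPipe-psm.tsv-like tab-delimited table. Required columns
#' (case-insensitive): `Spectrum` (ending `.<scan>.<scan>.<charge>`) or
#' an explicit `Scan` column, `Peptide`, `Charge`, and a glycan column
#' (`Total Glycan Composition`, `Glycan`, or `Observed Modifications`).
#' `Assigned Modifications` entries like `"4C(57.0215)"` contribute
#' non-glycan delta masses.
#'
#' @param path TSV path.
#' @return Data frame of GlycoPSM records: `scan_number`, `peptide`,
#'   `charge`, `glycan`, `mod_deltas` (list-column of numeric deltas).
#' @export
read_psm_table <- function(path) {
  if (!file.exists(path)) stop("PSM table not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  lower <- tolower(names(tab))
  col <- function(...) {
    for (cand in c(...)) {
      i <- match(cand, lower)
      if (!is.na(i)) return(tab[[i]])
    }
    NULL
  }
  peptide <- col("peptide")
  charge <- col("charge")
  glycan <- col("total glycan composition", "glycan",
                "observed modifications")
  spectrum <- col("spectrum")
  scan <- col("scan")
  if (is.null(peptide) || is.null(glycan) || (is.null(spectrum) && is.null(scan)))
    stop("PSM table needs Peptide, a glycan column, and Spectrum or Scan: ",
         path, call. = FALSE)
  if (is.null(scan)) {
    m <- regmatches(spectrum, regexec("\\.([0-9]+)\\.[0-9]+\\.([0-9]+)$",
                                      spectrum))
    bad <- vapply(m, length, integer(1)) != 3L
    if (any(bad))
      stop("unparsable Spectrum identifier(s), expected '...<scan>.<scan>.<charge>': ",
           spectrum[bad][1], call. = FALSE)
    scan <- as.integer(vapply(m, `[[`, character(1), 2L))
    if (is.null(charge)) charge <- as.integer(vapply(m, `[[`, character(1), 3L))
  }
  mods_raw <- col("assigned modifications")
  mod_deltas <- lapply(seq_along(peptide), function(i) {
    s <- if (is.null(mods_raw)) "" else mods_raw[i]
    if (is.na(s) || !nzchar(trimws(s))) return(numeric(0))
    as.numeric(unlist(regmatches(s, gregexpr("(?<=\\()[0-9.+-]+(?=\\))",
                                             s, perl = TRUE))))
  })
  out <- data.frame(scan_number = as.integer(scan),
                    peptide = as.character(peptide),
                    charge = as.integer(charge),
                    glycan = as.character(glycan),
                    stringsAsFactors = FALSE)
  out$mod_deltas <- mod_deltas
  out
}

#' Enumerate and extract Y-ions for one glycopeptide PSM
#'
#' Builds every Y-ion target from the remainder/loss choices, the charge
#' range and the isotope selection, then matches each against the
#' spectrum with the same tolerance and threshold semantics as oxonium
#' extraction.
#'
#' @param spectrum The `spectrum` record for the PSM's scan.
#' @param psm One row of [read_psm_table()] output (data frame or list
#'   with `scan_number`, `peptide`, `charge`, `glycan`, `mod_deltas`).
#' @param glycans Glycan database from [read_glycan_db()].
#' @param settings An [extraction_settings()] object.
#' @param remainders Named numeric vector of remainder masses
#'   (default [default_y_remainders()]).
#' @param losses Named numeric vector of neutral-loss masses, or `NULL`.
#' @param charge_range `c(lower, upper)` specification resolved against
#'   the precursor charge (default `c("1", "P")`).
#' @param isotopes Integer subset of 0..2 (default 0).
#' @param custom_additions Named numeric vector of extra masses combined
#'   with every remainder (default none).
#' @param custom_subtractions Named numeric vector of extra masses
#'   combined with every loss (default none).
#' @return Data frame of Y-ion targets and matches: `label`, `mode`,
#'   `charge`, `isotope`, `theoretical_mz`, `observed_mz`, `intensity`,
#'   `peak_depth`, `mass_error_ppm`, `matched`.
#' @export
extract_y_ions <- function(spectrum, psm, glycans,
                           settings = extraction_settings(),
                           remainders = default_y_remainders(),
                           losses = NULL,
                           charge_range = c("1", "P"),
                           isotopes = 0L,
                           custom_additions = NULL,
                           custom_subtractions = NULL) {
  psm <- as.list(psm)
  if (!is.null(spectrum) && spectrum$scan_number != psm$scan_number)
    stop("spectrum scan ", spectrum$scan_number,
         " does not match PSM scan ", psm$scan_number, call. = FALSE)
  gi <- match(psm$glycan, glycans$glycan)
  if (is.na(gi))
    stop("glycan '", psm$glycan, "' not in database; known: ",
         paste(utils::head(glycans$glycan, 10), collapse = ", "),
         call. = FALSE)
  glycan_mass <- glycans$mass[gi]
  pep_mass <- peptide_backbone_mass(psm$peptide, unlist(psm$mod_deltas))
  prec_neutral <- pep_mass + glycan_mass
  charges <- resolve_charge_range(charge_range[[1]], charge_range[[2]],
                                  P = psm$charge)
  isotopes <- as.integer(isotopes)

  if (length(custom_additions)) {
    extra <- stats::setNames(
      rep(remainders, each = length(custom_additions)) +
        rep(custom_additions, times = length(remainders)),
      paste(rep(names(remainders), each = length(custom_additions)),
            rep(names(custom_additions), times = length(remainders)),
            sep = "+"))
    remainders <- c(remainders, extra)
  }
  if (length(custom_subtractions) && length(losses)) {
    extra <- stats::setNames(
      rep(losses, each = length(custom_subtractions)) +
        rep(custom_subtractions, times = length(losses)),
      paste(rep(names(losses), each = length(custom_subtractions)),
            rep(names(custom_subtractions), times = length(losses)),
            sep = "+"))
    losses <- c(losses, extra)
  } else if (length(custom_subtractions)) {
    losses <- custom_subtractions
  }

  targets <- list()
  add_target <- function(label, mode, mz, z, k)
    targets[[length(targets) + 1L]] <<- list(label = label, mode = mode,
                                             mz = mz, z = z, k = k)
  for (z in charges) for (k in isotopes) {
    for (i in seq_along(remainders))
      add_target(names(remainders)[i], "REMAINDER",
                 y_ion_mz_remainder(pep_mass, remainders[[i]], z, k), z, k)
    for (i in seq_along(losses))
      add_target(names(losses)[i], "NEUTRAL_LOSS",
                 y_ion_mz_neutral_loss(prec_neutral, losses[[i]], z, k), z, k)
  }

  ranks <- if (is.null(spectrum)) NULL else rank_peaks(spectrum)
  rows <- lapply(targets, function(t) {
    hit <- if (is.null(spectrum)) NULL
           else match_ion(spectrum, t$mz, settings, ranks)
    data.frame(label = t$label, mode = t$mode, charge = t$z, isotope = t$k,
               theoretical_mz = t$mz,
               observed_mz = if (is.null(hit)) NA_real_ else hit$observed_mz,
               intensity = if (is.null(hit)) NA_real_ else hit$intensity,
               peak_depth = if (is.null(hit)) NA_integer_ else hit$peak_depth,
               mass_error_ppm = if (is.null(hit)) NA_real_ else hit$mass_error_ppm,
               matched = !is.null(hit),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
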