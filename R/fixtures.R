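## Synthetic spectra with planted, fully known diagnostic-ion structure.
##
## Planted ions sit at their theoretical m/z (± a drawn mass error of at
## most 5 ppm) and occupy the top intensity ranks; decoy peaks are kept
## at least 30 ppm away from every catalog ion so recall and false-match
## assertions are exact, not probabilistic. Decoy intensities are scaled
## so the planted ions contribute exactly the requested fraction of TIC.

.DECOY_EXCLUSION_PPM <- 30
.PLANT_ERROR_PPM <- 5

#' Specification of a synthetic-spectrum fixture
#'
#' @param n_scans Number of scans to generate.
#' @param activation Activation type for all scans, or a vector recycled
#'   across scans.
#' @param planted_ions Character vector of catalog ion names to plant
#'   (they receive intensity ranks 1..k), or a named numeric vector of
#'   explicit m/z values. Empty = null (decoy-only) fixture.
#' @param target_fraction Planted share of the TIC (default 0.30).
#' @param n_decoys Number of decoy peaks (default 100).
#' @param mz_range Decoy m/z range (default 120-2000).
#' @param with_noise Attach a flat noise array (value 1) so S/N filtering
#'   is exercised (default `FALSE`).
#' @param seed Integer seed; generation is bit-reproducible.
#' @return A `fixture_spec` list (validated for feasibility).
#' @export
fixture_spec <- function(n_scans = 10L, activation = "HCD",
                         planted_ions = c("HexNAc", "Hex-HexNAc", "NeuAc",
                                          "NeuAc-H2O", "Hex", "HexNAc-H2O",
                                          "NeuAc-Hex-HexNAc", "Hex2-HexNAc"),
                         target_fraction = 0.30, n_decoys = 100L,
                         mz_range = c(120, 2000), with_noise = FALSE,
                         seed = 1L) {
  stopifnot(n_scans >= 1L, target_fraction >= 0, target_fraction < 1,
            n_decoys >= 1L, mz_range[1] > 0, mz_range[2] > mz_range[1])
  if (is.character(planted_ions) && length(planted_ions)) {
    cat_all <- builtin_catalog("all")
    idx <- match(planted_ions, cat_all$name)
    if (anyNA(idx))
      stop("unknown catalog ion(s): ",
           paste(planted_ions[is.na(idx)], collapse = ", "), call. = FALSE)
    planted_mz <- stats::setNames(cat_all$mz[idx], planted_ions)
  } else if (length(planted_ions)) {
    planted_mz <- planted_ions
  } else {
    planted_mz <- numeric(0)
  }
  k <- length(planted_mz)
  if (k > 0 && target_fraction > 0) {
    ## Feasibility: decoys must absorb P*(1-f)/f total while each stays
    ## below the weakest planted peak (preserving planted ranks 1..k).
    planted_int <- 1000 * seq(k, 1)
    decoy_total <- sum(planted_int) * (1 - target_fraction) / target_fraction
    if (decoy_total / n_decoys > 0.95 * min(planted_int))
      stop("infeasible fixture: ", n_decoys, " decoys cannot carry ",
           format(decoy_total), " intensity while staying below the ",
           "weakest planted peak; lower target_fraction or add decoys",
           call. = FALSE)
  }
  structure(list(n_scans = as.integer(n_scans),
                 activation = activation,
                 planted_mz = planted_mz,
                 target_fraction = target_fraction,
                 n_decoys = as.integer(n_decoys),
                 mz_range = mz_range,
                 with_noise = isTRUE(with_noise),
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

.far_from_catalog <- function(mz, forbidden_mz, min_ppm = .DECOY_EXCLUSION_PPM) {
  if (length(forbidden_mz) == 0L) return(rep(TRUE, length(mz)))
  ok <- rep(TRUE, length(mz))
  for (f in forbidden_mz)
    ok <- ok & abs(mz - f) / f * 1e6 >= min_ppm
  ok
}

#' Generate one synthetic spectrum from a fixture specification
#'
#' Planted ions occupy intensity ranks 1..k with descending intensities;
#' decoys are drawn uniformly in the m/z range, rejected within 30 ppm
#' of any catalog ion (full catalog plus the planted list), and scaled
#' so the planted TIC share equals `target_fraction` exactly.
#'
#' @param spec A [fixture_spec()].
#' @param scan_index Scan number (also offsets the seed, so each scan is
#'   distinct but reproducible).
#' @return A `spectrum` record.
#' @export
generate_spectrum <- function(spec, scan_index = 1L) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed * 10000L + as.integer(scan_index))
  k <- length(spec$planted_mz)
  activation <- rep(spec$activation, length.out = spec$n_scans)[
    ((scan_index - 1L) %% spec$n_scans) + 1L]

  forbidden <- unique(c(builtin_catalog("all")$mz, spec$planted_mz))
  decoy_mz <- numeric(0)
  while (length(decoy_mz) < spec$n_decoys) {
    cand <- stats::runif(2L * spec$n_decoys, spec$mz_range[1], spec$mz_range[2])
    cand <- cand[.far_from_catalog(cand, forbidden)]
    decoy_mz <- c(decoy_mz, cand)
  }
  decoy_mz <- decoy_mz[seq_len(spec$n_decoys)]

  if (k > 0 && spec$target_fraction > 0) {
    planted_int <- 1000 * seq(k, 1)
    err_ppm <- stats::runif(k, -.PLANT_ERROR_PPM, .PLANT_ERROR_PPM)
    planted_obs <- spec$planted_mz * (1 + err_ppm / 1e6)
    decoy_total <- sum(planted_int) *
      (1 - spec$target_fraction) / spec$target_fraction
  } else {
    planted_int <- numeric(0); planted_obs <- numeric(0)
    decoy_total <- 1000 * spec$n_decoys
  }
  decoy_int <- stats::runif(spec$n_decoys, 0.2, 1)
  decoy_int <- decoy_int / sum(decoy_int) * decoy_total
  if (k > 0 && spec$target_fraction > 0) {
    cap <- 0.95 * min(planted_int)
    over <- decoy_int > cap
    if (any(over)) {  # clip and redistribute to keep ranks exact
      excess <- sum(decoy_int[over] - cap)
      decoy_int[over] <- cap
      room <- cap - decoy_int
      decoy_int <- decoy_int + excess * room / sum(room)
    }
  }

  mz <- c(planted_obs, decoy_mz)
  intensity <- c(planted_int, decoy_int)
  spectrum_record(
    scan_number = scan_index,
    mz = mz, intensity = intensity,
    ms_level = 2L, activation = activation,
    noise = if (spec$with_noise) rep(1, length(mz)) else NULL,
    precursor_mz = 1000 + scan_index, precursor_charge = 2L,
    retention_time = scan_index / 10
  )
}

#' Generate every scan of a fixture
#'
#' @param spec A [fixture_spec()].
#' @return List of `spectrum` records of length `spec$n_scans`.
#' @export
generate_fixture_spectra <- function(spec) {
  lapply(seq_len(spec$n_scans), function(i) generate_spectrum(spec, i))
}

#' Write a fixture to an mzML file
#'
#' @param spec A [fixture_spec()] (or a list of `spectrum` records).
#' @param path Output mzML path.
#' @param zlib Compress binary arrays (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_fixture_mzml <- function(spec, path, zlib = FALSE) {
  spectra <- if (inherits(spec, "fixture_spec"))
    generate_fixture_spectra(spec) else spec
  write_mzml(spectra, path, zlib = zlib)
}

#' Generate a glycopeptide fixture bundle (mzML + PSM + glycan database)
#'
#' Builds one MS/MS scan per PSM with the requested Y-ions planted at
#' their closed-form m/z, plus decoys, and writes the matching
#' FragPipe-style PSM table and glycan mass database. Running
#' [extract_y_ions()] on the bundle recovers the planted set exactly.
#'
#' @param out_dir Output directory.
#' @param peptide Peptide sequence (default `"PEPTIDEK"`).
#' @param glycan_name Glycan name (default `"HexNAc2-Hex5"`).
#' @param glycan_composition Named residue counts defining the glycan
#'   mass (default `c(HexNAc = 2, Hex = 5)`).
#' @param precursor_charge Precursor charge P (default 3).
#' @param plant Named numeric vector of remainder masses to plant
#'   (default `default_y_remainders()[1:3]`), at `plant_charge`/`plant_k`.
#' @param plant_charge Charge of the planted Y-ions (default 1).
#' @param plant_k Isotope index of the planted Y-ions (default 0).
#' @param n_decoys Decoy peaks per scan (default 60).
#' @param seed Integer seed.
#' @return Named list of paths: `mzml`, `psm`, `glycans`.
#' @export
generate_glycopeptide_fixture <- function(out_dir,
                                          peptide = "PEPTIDEK",
                                          glycan_name = "HexNAc2-Hex5",
                                          glycan_composition = c(HexNAc = 2, Hex = 5),
                                          precursor_charge = 3L,
                                          plant = default_y_remainders()[1:3],
                                          plant_charge = 1L,
                                          plant_k = 0L,
                                          n_decoys = 60L,
                                          seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  set.seed(seed)
  tab <- monosaccharide_table()
  glycan_mass <- sum(tab[names(glycan_composition)] * glycan_composition)
  pep_mass <- peptide_backbone_mass(peptide)
  prec_neutral <- pep_mass + glycan_mass
  prec_mz <- (prec_neutral + precursor_charge * tab[["proton"]]) /
    precursor_charge

  planted_mz <- vapply(plant, function(r)
    y_ion_mz_remainder(pep_mass, r, plant_charge, plant_k), numeric(1))
  k <- length(planted_mz)
  planted_int <- 1000 * seq(k, 1)
  decoy_mz <- numeric(0)
  while (length(decoy_mz) < n_decoys) {
    cand <- stats::runif(2L * n_decoys, 150, prec_mz * precursor_charge)
    cand <- cand[.far_from_catalog(cand, planted_mz)]
    decoy_mz <- c(decoy_mz, cand)
  }
  decoy_mz <- decoy_mz[seq_len(n_decoys)]
  decoy_int <- stats::runif(n_decoys, 50, 0.9 * min(planted_int))

  scan_number <- 7L
  sp <- spectrum_record(scan_number,
                        mz = c(planted_mz, decoy_mz),
                        intensity = c(planted_int, decoy_int),
                        ms_level = 2L, activation = "HCD",
                        precursor_mz = unname(prec_mz),
                        precursor_charge = precursor_charge)
  mzml_path <- file.path(out_dir, "glycopeptide_fixture.mzML")
  write_mzml(list(sp), mzml_path)

  psm_path <- file.path(out_dir, "glycopeptide_fixture_psm.tsv")
  psm <- data.frame(
    Spectrum = sprintf("glycopeptide_fixture.%d.%d.%d", scan_number,
                       scan_number, precursor_charge),
    Peptide = peptide,
    Charge = precursor_charge,
    `Assigned Modifications` = "",
    `Total Glycan Composition` = glycan_name,
    check.names = FALSE
  )
  .write_tsv(psm, psm_path)

  glycan_path <- file.path(out_dir, "glycopeptide_fixture_glycans.tsv")
  .write_tsv(data.frame(glycan = glycan_name, mass = unname(glycan_mass)),
             glycan_path)

  list(mzml = mzml_path, psm = psm_path, glycans = glycan_path)
}

#' Generate the full fixture set used by tests and demos
#'
#' Writes a planted-positive mzML, a decoy-only null mzML, a custom-ion
#' TSV example, and a glycopeptide Y-ion bundle into a directory.
#'
#' @param out_dir Target directory.
#' @param seed Integer seed.
#' @return Named list of paths.
#' @export
generate_fixture_set <- function(out_dir, seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  pos <- fixture_spec(n_scans = 10L, seed = seed)
  null <- fixture_spec(n_scans = 10L, planted_ions = character(0),
                       target_fraction = 0, seed = seed + 1L)
  pos_path <- file.path(out_dir, "planted_positive.mzML")
  null_path <- file.path(out_dir, "null_decoys.mzML")
  write_fixture_mzml(pos, pos_path)
  write_fixture_mzml(null, null_path)
  custom_path <- file.path(out_dir, "custom_ions_example.tsv")
  .write_tsv(data.frame(
    name = c("HexNAzoSi", "HexNAc+formyl"),
    mz = c(345.14, NA),
    composition = c("", "HexNAc:1"),
    adducts = c("", "CO")
  ), custom_path)
  gp <- generate_glycopeptide_fixture(out_dir, seed = seed + 2L)
  c(list(positive = pos_path, null = null_path, custom_ions = custom_path), gp)
}
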