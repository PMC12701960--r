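## Per-scan diagnostic-ion extraction: tolerance matching, noise/intensity
## filtering, peak-depth ranking, and TIC accounting.

#' Extraction settings
#'
#' @param tolerance_value Matching tolerance (default 15).
#' @param tolerance_unit `"ppm"` (default) or `"Da"`.
#' @param sn_threshold Signal-to-noise cutoff, applied when the spectrum
#'   carries noise estimates (default 3).
#' @param intensity_threshold Absolute intensity cutoff, applied when no
#'   noise data are present (default 0 = accept all positive peaks).
#' @param ms_levels MS levels to process (default 2).
#' @return An `extraction_settings` list.
#' @export
extraction_settings <- function(tolerance_value = 15,
                                tolerance_unit = c("ppm", "Da"),
                                sn_threshold = 3,
                                intensity_threshold = 0,
                                ms_levels = 2L) {
  tolerance_unit <- match.arg(tolerance_unit)
  stopifnot(tolerance_value > 0, sn_threshold >= 0, intensity_threshold >= 0)
  structure(list(tolerance_value = tolerance_value,
                 tolerance_unit = tolerance_unit,
                 sn_threshold = sn_threshold,
                 intensity_threshold = intensity_threshold,
                 ms_levels = as.integer(ms_levels)),
            class = "extraction_settings")
}

#' Peak depth: intensity rank within one scan
#'
#' Rank 1 is the most intense peak; ties are broken by ascending m/z
#' (the lower-m/z peak gets the better rank).
#'
#' @param spectrum A `spectrum` record.
#' @return Integer vector of ranks parallel to the peak arrays (a
#'   permutation of `1..n_peaks`); empty for an empty spectrum.
#' @export
rank_peaks <- function(spectrum) {
  n <- length(spectrum$intensity)
  if (n == 0L) return(integer(0))
  o <- order(-spectrum$intensity, spectrum$mz)
  ranks <- integer(n)
  ranks[o] <- seq_len(n)
  ranks
}

.tolerance_da <- function(target_mz, settings) {
  if (settings$tolerance_unit == "ppm")
    settings$tolerance_value * target_mz / 1e6
  else settings$tolerance_value
}

## Indices of peaks that pass the S/N-or-intensity filter. S/N governs
## whenever noise data accompany the spectrum; the absolute intensity
## threshold governs otherwise. Zero-intensity peaks never qualify.
.qualifying_peaks <- function(spectrum, settings) {
  int <- spectrum$intensity
  if (!is.null(spectrum$noise)) {
    nz <- pmax(spectrum$noise, .Machine$double.eps)
    which(int > 0 & int / nz >= settings$sn_threshold)
  } else {
    which(int > 0 & int >= settings$intensity_threshold)
  }
}

#' Match one diagnostic ion in a spectrum
#'
#' Searches the peak list for the target m/z within the tolerance window
#' (ppm windows are computed on the theoretical m/z, symmetric). Among
#' in-window peaks passing the threshold filter, the most intense one is
#' returned; an intensity tie goes to the smallest absolute mass error.
#'
#' @param spectrum A `spectrum` record (peaks sorted by m/z).
#' @param target_mz Theoretical ion m/z in Da.
#' @param settings An [extraction_settings()] object.
#' @param ranks Optional precomputed [rank_peaks()] result.
#' @return A list with `observed_mz`, `intensity`, `peak_depth`,
#'   `mass_error_ppm`, or `NULL` when no peak qualifies.
#' @export
match_ion <- function(spectrum, target_mz, settings = extraction_settings(),
                      ranks = NULL) {
  tol <- .tolerance_da(target_mz, settings)
  # left.open keeps the window closed on both sides: [target-tol, target+tol]
  lo <- findInterval(target_mz - tol, spectrum$mz, left.open = TRUE) + 1L
  hi <- findInterval(target_mz + tol, spectrum$mz)
  if (hi < lo) return(NULL)
  idx <- lo:hi
  idx <- idx[idx %in% .qualifying_peaks(spectrum, settings)]
  if (length(idx) == 0L) return(NULL)
  err <- abs(spectrum$mz[idx] - target_mz)
  best <- idx[order(-spectrum$intensity[idx], err)][1L]
  if (is.null(ranks)) ranks <- rank_peaks(spectrum)
  list(observed_mz = spectrum$mz[best],
       intensity = spectrum$intensity[best],
       peak_depth = ranks[best],
       mass_error_ppm = (spectrum$mz[best] - target_mz) / target_mz * 1e6)
}

#' Extract all selected diagnostic ions from one scan
#'
#' Runs [match_ion()] for every ion in the selection, computes the
#' oxonium fraction of the TIC over all matches, and counts matches
#' falling inside the activation-specific peak-depth window (25 for HCD,
#' 50 for the ETD family, 25 for UVPD by default). One peak may satisfy
#' several isobaric ions; each ion consumes at most one peak.
#'
#' @param spectrum A `spectrum` record.
#' @param ions An `ion_selection`.
#' @param settings An [extraction_settings()] object.
#' @param cls A [classifier_settings()] object (supplies depth windows).
#' @return A `spectrum_summary` list: `scan_number`, `activation`, `tic`,
#'   `matches` (data frame: ion_name, theoretical_mz, observed_mz,
#'   intensity, peak_depth, mass_error_ppm), `oxonium_tic_fraction`,
#'   `n_matched`, `n_matched_in_window`, `likely_glyco` (`NA` until
#'   classified), `eligible` (`FALSE` for activation `OTHER`).
#' @export
extract_spectrum <- function(spectrum, ions,
                             settings = extraction_settings(),
                             cls = classifier_settings()) {
  ranks <- rank_peaks(spectrum)
  hits <- lapply(ions$mz, match_ion, spectrum = spectrum,
                 settings = settings, ranks = ranks)
  found <- !vapply(hits, is.null, logical(1))
  matches <- data.frame(
    ion_name = ions$name[found],
    theoretical_mz = ions$mz[found],
    observed_mz = vapply(hits[found], `[[`, numeric(1), "observed_mz"),
    intensity = vapply(hits[found], `[[`, numeric(1), "intensity"),
    peak_depth = vapply(hits[found], `[[`, integer(1), "peak_depth"),
    mass_error_ppm = vapply(hits[found], `[[`, numeric(1), "mass_error_ppm"),
    stringsAsFactors = FALSE
  )
  window <- .depth_window(spectrum$activation, cls)
  frac <- if (spectrum$tic > 0) sum(matches$intensity) / spectrum$tic else 0
  structure(list(
    scan_number = spectrum$scan_number,
    ms_level = spectrum$ms_level,
    activation = spectrum$activation,
    retention_time = spectrum$retention_time,
    tic = spectrum$tic,
    matches = matches,
    oxonium_tic_fraction = min(max(frac, 0), 1),
    n_matched = nrow(matches),
    n_matched_in_window = sum(matches$peak_depth <= window),
    likely_glyco = NA,
    eligible = spectrum$activation != "OTHER"
  ), class = "spectrum_summary")
}

#' Extract and classify every scan of a file
#'
#' Convenience pipeline: [read_mzml()], [extract_spectrum()] per scan,
#' then [classify_spectrum()].
#'
#' @param path mzML file path.
#' @param ions An `ion_selection`.
#' @param settings An [extraction_settings()] object.
#' @param cls A [classifier_settings()] object.
#' @return List of classified `spectrum_summary` objects.
#' @export
extract_file <- function(path, ions, settings = extraction_settings(),
                         cls = classifier_settings()) {
  spectra <- read_mzml(path, ms_levels = settings$ms_levels)
  lapply(spectra, function(sp) {
    s <- extract_spectrum(sp, ions, settings, cls)
    s$likely_glyco <- classify_spectrum(s, nrow(ions), cls)
    s
  })
}
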