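## LikelyGlycoSpectrum classification.
##
## A scan is called a likely glycopeptide spectrum when (1) enough of the
## selected diagnostic ions are matched within the activation's peak-depth
## window and (2) the summed oxonium intensity is a large enough fraction
## of the TIC. Both thresholds are activation-specific.

#' Classifier settings
#'
#' Defaults follow the shipped screening rules: depth windows of 25 (HCD),
#' 50 (ETD family) and 25 (UVPD) most-abundant peaks; minimum oxonium TIC
#' fractions of 0.20, 0.05 and 0.20; a required-count rule that scales
#' with the number of selected ions (4 below 6 selected, half the
#' selection for 6 through 15, 8 above 15), halved for ETD-family scans,
#' with an absolute floor of 4 matched ions. Selecting fewer than 4 ions
#' disables the classifier entirely.
#'
#' @param depth_window Named integer vector of peak-depth windows.
#' @param tic_fraction_min Named numeric vector of minimum TIC fractions.
#' @param small_set_count Required count when fewer than `small_set_limit`
#'   ions are selected (default 4).
#' @param small_set_limit Lower regime boundary (default 6; "fewer than
#'   six" uses `small_set_count`).
#' @param mid_set_limit Upper boundary of the half-the-selection regime
#'   (default 15, inclusive).
#' @param large_set_count Required count above `mid_set_limit` (default 8).
#' @param etd_halving Halve the requirement for ETD-family scans
#'   (default `TRUE`).
#' @param absolute_min Floor on the matched-ion requirement and on the
#'   usable selection size (default 4).
#' @return A `classifier_settings` list.
#' @export
classifier_settings <- function(
    depth_window = c(HCD = 25L, ETD_FAMILY = 50L, UVPD = 25L),
    tic_fraction_min = c(HCD = 0.20, ETD_FAMILY = 0.05, UVPD = 0.20),
    small_set_count = 4L, small_set_limit = 6L, mid_set_limit = 15L,
    large_set_count = 8L, etd_halving = TRUE, absolute_min = 4L) {
  stopifnot(all(depth_window >= 1L),
            all(tic_fraction_min >= 0), all(tic_fraction_min <= 1),
            all(c("HCD", "ETD_FAMILY", "UVPD") %in% names(depth_window)),
            all(c("HCD", "ETD_FAMILY", "UVPD") %in% names(tic_fraction_min)))
  structure(list(depth_window = depth_window,
                 tic_fraction_min = tic_fraction_min,
                 small_set_count = as.integer(small_set_count),
                 small_set_limit = as.integer(small_set_limit),
                 mid_set_limit = as.integer(mid_set_limit),
                 large_set_count = as.integer(large_set_count),
                 etd_halving = isTRUE(etd_halving),
                 absolute_min = as.integer(absolute_min)),
            class = "classifier_settings")
}

.depth_window <- function(activation, cls) {
  if (activation %in% names(cls$depth_window))
    cls$depth_window[[activation]]
  else cls$depth_window[["HCD"]]
}

.round_half_up <- function(x) floor(x + 0.5)

#' Required matched-ion count for the LikelyGlyco call
#'
#' Scales with the size of the ion selection: `small_set_count` (4) when
#' fewer than 6 ions are checked, half the selection (rounded half up)
#' for 6 through 15, and `large_set_count` (8) above 15. ETD-family scans
#' halve the result (rounded half up). The requirement never drops below
#' `absolute_min` (4), and a selection smaller than 4 ions can never
#' produce a LikelyGlyco call (`Inf` is returned).
#'
#' @param n_selected Number of ions in the selection.
#' @param activation Activation class of the scan.
#' @param settings A [classifier_settings()] object.
#' @return Integer requirement, or `Inf` when classification is disabled.
#' @examples
#' required_ion_count(17, "HCD")         # 8
#' required_ion_count(17, "ETD_FAMILY")  # 4
#' required_ion_count(10, "HCD")         # 5
#' required_ion_count(3, "HCD")          # Inf (never LikelyGlyco)
#' @export
required_ion_count <- function(n_selected, activation = "HCD",
                               settings = classifier_settings()) {
  stopifnot(n_selected >= 0)
  if (n_selected < settings$absolute_min) return(Inf)
  base <- if (n_selected < settings$small_set_limit) settings$small_set_count
          else if (n_selected <= settings$mid_set_limit)
            .round_half_up(n_selected / 2)
          else settings$large_set_count
  if (identical(activation, "ETD_FAMILY") && settings$etd_halving)
    base <- .round_half_up(base / 2)
  max(settings$absolute_min, base)
}

#' Classify one scan as a likely glycopeptide spectrum
#'
#' `TRUE` iff the number of matched ions inside the activation's
#' peak-depth window reaches [required_ion_count()] and the oxonium TIC
#' fraction reaches the activation's minimum. Scans with activation
#' `OTHER` are never classified (`FALSE`).
#'
#' @param summary A `spectrum_summary` from [extract_spectrum()].
#' @param n_selected Number of ions that were searched.
#' @param settings A [classifier_settings()] object.
#' @return Logical.
#' @export
classify_spectrum <- function(summary, n_selected,
                              settings = classifier_settings()) {
  if (!isTRUE(summary$eligible)) return(FALSE)
  need <- required_ion_count(n_selected, summary$activation, settings)
  frac_min <- settings$tic_fraction_min[[summary$activation]]
  summary$n_matched_in_window >= need &&
    summary$oxonium_tic_fraction >= frac_min
}
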