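# Shared helpers: independent brute-force matcher and small builders.

# O(n_peaks x n_ions) reference matcher, independent of match_ion()'s
# binary-search path. Same documented semantics: closed symmetric window
# on the theoretical m/z, S/N filter when noise is present else absolute
# intensity, most intense qualifying peak, intensity tie -> smallest
# absolute mass error.
brute_force_match <- function(spectrum, target_mz, tol_value = 15,
                              tol_unit = "ppm", sn = 3, int_thr = 0) {
  tol <- if (tol_unit == "ppm") tol_value * target_mz / 1e6 else tol_value
  ok <- abs(spectrum$mz - target_mz) <= tol & spectrum$intensity > 0
  if (!is.null(spectrum$noise)) {
    ok <- ok & spectrum$intensity / pmax(spectrum$noise,
                                         .Machine$double.eps) >= sn
  } else {
    ok <- ok & spectrum$intensity >= int_thr
  }
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  best <- idx[order(-spectrum$intensity[idx],
                    abs(spectrum$mz[idx] - target_mz))][1]
  list(observed_mz = spectrum$mz[best], intensity = spectrum$intensity[best])
}

# A spectrum with fully-controlled peaks (unsorted input on purpose).
make_spectrum <- function(mz, intensity, activation = "HCD", ...) {
  spectrum_record(1L, mz = mz, intensity = intensity,
                  activation = activation, ...)
}

# A random spectrum for property tests.
random_spectrum <- function(n_peaks, with_noise = FALSE,
                            mz_range = c(100, 1200)) {
  mz <- runif(n_peaks, mz_range[1], mz_range[2])
  intensity <- rexp(n_peaks, rate = 1 / 1000)
  spectrum_record(1L, mz, intensity,
                  noise = if (with_noise) runif(n_peaks, 0.5, 500) else NULL)
}

# A bare spectrum_summary for direct classifier tests.
make_summary <- function(activation, n_in_window, fraction,
                         eligible = activation != "OTHER") {
  structure(list(activation = activation,
                 n_matched_in_window = n_in_window,
                 oxonium_tic_fraction = fraction,
                 eligible = eligible),
            class = "spectrum_summary")
}
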