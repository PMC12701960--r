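test_that("rank_peaks ranks by intensity with m/z tie-break", {
  expect_equal(rank_peaks(make_spectrum(c(100, 200, 300), c(10, 50, 30))),
               c(3L, 1L, 2L))
  expect_equal(rank_peaks(make_spectrum(c(100, 200), c(5, 5))), c(1L, 2L))
  expect_equal(rank_peaks(make_spectrum(150, 7)), 1L)
  expect_equal(rank_peaks(make_spectrum(numeric(0), numeric(0))), integer(0))
  # always a permutation
  set.seed(7)
  for (i in 1:20) {
    sp <- random_spectrum(sample(1:50, 1))
    expect_setequal(rank_peaks(sp), seq_along(sp$mz))
  }
})

test_that("match_ion matches within tolerance and reports ppm error", {
  sp <- make_spectrum(c(204.0871, 350, 500), c(100, 50, 10))
  hit <- match_ion(sp, 204.0866)
  expect_equal(hit$observed_mz, 204.0871)
  expect_equal(hit$mass_error_ppm, (204.0871 - 204.0866) / 204.0866 * 1e6,
               tolerance = 1e-9)
  expect_equal(hit$peak_depth, 1L)
  # 0.063 Da away at 15 ppm -> absent
  expect_null(match_ion(make_spectrum(c(204.15, 300), c(100, 10)), 204.0866))
  # two in-window peaks: the more intense wins regardless of closeness
  sp2 <- make_spectrum(c(204.0864, 204.0871), c(100, 900))
  expect_equal(match_ion(sp2, 204.0866)$intensity, 900)
  # intensity tie -> smaller |mass error|
  sp3 <- make_spectrum(c(204.0860, 204.0868), c(500, 500))
  expect_equal(match_ion(sp3, 204.0866)$observed_mz, 204.0868)
  # Dalton tolerance unit
  da <- extraction_settings(tolerance_value = 0.5, tolerance_unit = "Da")
  expect_equal(match_ion(make_spectrum(c(204.4, 300), c(10, 5)),
                         204.0866, da)$observed_mz, 204.4)
})

test_that("threshold semantics: S/N governs with noise, intensity without", {
  mz <- c(204.0866, 300)
  noisy <- make_spectrum(mz, c(100, 10), noise = c(50, 1))
  # S/N = 2 < default 3 -> no match despite high intensity
  expect_null(match_ion(noisy, 204.0866))
  lax <- extraction_settings(sn_threshold = 2)
  expect_equal(match_ion(noisy, 204.0866, lax)$intensity, 100)
  # without noise the intensity threshold governs
  plain <- make_spectrum(mz, c(100, 10))
  strict <- extraction_settings(intensity_threshold = 200)
  expect_null(match_ion(plain, 204.0866, strict))
  expect_equal(match_ion(plain, 204.0866)$intensity, 100)
})

test_that("extract_spectrum accounts matches, TIC fraction and depth window", {
  spec <- fixture_spec(n_scans = 1L, target_fraction = 0.30, seed = 21L)
  sp <- generate_spectrum(spec, 1L)
  s <- extract_spectrum(sp, builtin_catalog("common"))
  expect_equal(s$n_matched, 8L)
  expect_equal(s$n_matched_in_window, 8L)
  expect_equal(s$oxonium_tic_fraction, 0.30, tolerance = 1e-6)
  expect_equal(nrow(s$matches), s$n_matched)
  # no catalog ions present
  bare <- make_spectrum(c(1000, 1100), c(5, 5))
  s0 <- extract_spectrum(bare, builtin_catalog("common"))
  expect_equal(s0$n_matched, 0L)
  expect_equal(s0$oxonium_tic_fraction, 0)
  # OTHER activation -> summary produced but ineligible
  oth <- make_spectrum(c(204.0866, 900), c(100, 10), activation = "OTHER")
  expect_false(extract_spectrum(oth, builtin_catalog("common"))$eligible)
})

test_that("tolerance monotonicity: 5 ppm matches are a subset of 15 ppm", {
  ions <- builtin_catalog("common")
  set.seed(33)
  for (i in 1:25) {
    sp <- random_spectrum(150, mz_range = c(120, 700))
    m5 <- extract_spectrum(sp, ions, extraction_settings(tolerance_value = 5))
    m15 <- extract_spectrum(sp, ions, extraction_settings(tolerance_value = 15))
    expect_true(all(m5$matches$ion_name %in% m15$matches$ion_name))
  }
})

test_that("extraction equals brute force on random spectra", {
  ions <- builtin_catalog("common")
  set.seed(99)
  for (i in 1:60) {
    with_noise <- i %% 2 == 0
    sp <- random_spectrum(sample(5:200, 1), with_noise = with_noise,
                          mz_range = c(120, 700))
    s <- extract_spectrum(sp, ions)
    for (j in seq_len(nrow(ions))) {
      ref <- brute_force_match(sp, ions$mz[j])
      row <- s$matches[s$matches$ion_name == ions$name[j], ]
      if (is.null(ref)) {
        expect_equal(nrow(row), 0L)
      } else {
        expect_equal(row$observed_mz, ref$observed_mz)
        expect_equal(row$intensity, ref$intensity)
      }
    }
    expect_gte(s$oxonium_tic_fraction, 0)
    expect_lte(s$oxonium_tic_fraction, 1)
  }
})

test_that("TIC fraction stays in [0,1] even when metadata TIC is too small", {
  # adversarial: matched intensity exceeds the recorded TIC
  sp <- spectrum_record(1L, c(204.0866, 800), c(1000, 10), tic = 500)
  s <- extract_spectrum(sp, builtin_catalog("common"))
  expect_lte(s$oxonium_tic_fraction, 1)
  expect_gte(s$oxonium_tic_fraction, 0)
})
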