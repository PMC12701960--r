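test_that("mzML write/read round-trips spectra to float precision", {
  spec <- fixture_spec(n_scans = 3L, seed = 11L)
  spectra <- generate_fixture_spectra(spec)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(spectra, path)
  back <- read_mzml(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$mz, spectra[[i]]$mz, tolerance = 1e-12)
    expect_equal(back[[i]]$intensity, spectra[[i]]$intensity,
                 tolerance = 1e-12)
    expect_equal(back[[i]]$scan_number, spectra[[i]]$scan_number)
    expect_equal(back[[i]]$activation, spectra[[i]]$activation)
    expect_equal(back[[i]]$tic, spectra[[i]]$tic, tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_mz, spectra[[i]]$precursor_mz,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$precursor_charge, spectra[[i]]$precursor_charge)
    expect_equal(back[[i]]$retention_time, spectra[[i]]$retention_time,
                 tolerance = 1e-6)
  }
  # zlib-compressed arrays are accepted and identical
  zpath <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(spectra, zpath, zlib = TRUE)
  zback <- read_mzml(zpath)
  expect_equal(zback[[1]]$mz, spectra[[1]]$mz, tolerance = 1e-12)
})

test_that("ms_level filtering and degenerate scans behave as documented", {
  ms1 <- spectrum_record(1L, c(400, 500), c(10, 20), ms_level = 1L)
  ms2a <- spectrum_record(2L, c(204.0866, 300), c(100, 50), ms_level = 2L)
  ms2b <- spectrum_record(3L, c(366.1395, 310), c(80, 40), ms_level = 2L)
  empty <- spectrum_record(4L, numeric(0), numeric(0), ms_level = 2L, tic = 1)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(list(ms1, ms2a, ms2b, empty), path)
  expect_warning(back <- read_mzml(path, ms_levels = 2L), "skipped")
  expect_equal(vapply(back, `[[`, integer(1), "scan_number"), c(2L, 3L))
  both <- suppressWarnings(read_mzml(path, ms_levels = c(1L, 2L)))
  expect_length(both, 3L)
})

test_that("activation metadata maps to activation families", {
  expect_equal(detect_activation(names = "beam-type collision-induced dissociation"),
               "HCD")
  # EThcD: ETD term plus supplemental beam-type CID still maps to ETD family
  expect_equal(detect_activation(
    names = c("electron transfer dissociation",
              "beam-type collision-induced dissociation")), "ETD_FAMILY")
  expect_equal(detect_activation(accessions = "MS:1000598"), "ETD_FAMILY")
  expect_equal(detect_activation(names = "ultraviolet photodissociation"),
               "UVPD")
  expect_equal(detect_activation(names = "in-source dissociation"), "OTHER")
  # round-trip through a file
  sp <- spectrum_record(1L, c(204.0866, 300), c(10, 5),
                        activation = "ETD_FAMILY")
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(list(sp), path)
  expect_equal(read_mzml(path)[[1]]$activation, "ETD_FAMILY")
})

test_that("gzip-packaged and profile-mode inputs are rejected with guidance", {
  spec <- fixture_spec(n_scans = 1L, seed = 3L)
  plain <- withr::local_tempfile(fileext = ".mzML")
  write_fixture_mzml(spec, plain)
  gz <- withr::local_tempfile(fileext = ".mzML.gz")
  con <- gzfile(gz, "wb")
  writeBin(readBin(plain, "raw", file.size(plain)), con)
  close(con)
  expect_error(read_mzml(gz), "gzip")
  expect_error(read_mzml(withr::local_tempfile()), "not found")

  profile <- sub("MS:1000127\" name=\"centroid spectrum",
                 "MS:1000128\" name=\"profile spectrum",
                 readLines(plain))
  ppath <- withr::local_tempfile(fileext = ".mzML")
  writeLines(profile, ppath)
  expect_error(read_mzml(ppath), "centroided")
})

test_that("file TIC metadata is overridden when it disagrees with peak sums", {
  sp <- spectrum_record(1L, c(204.0866, 300), c(100, 100), tic = 1e6)
  path <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(list(sp), path)
  expect_message(back <- read_mzml(path), "using peak sum")
  expect_equal(back[[1]]$tic, 200)
  # agreement within 20%: metadata TIC is kept
  sp2 <- spectrum_record(1L, c(204.0866, 300), c(100, 100), tic = 210)
  write_mzml(list(sp2), path)
  expect_equal(read_mzml(path)[[1]]$tic, 210)
})
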