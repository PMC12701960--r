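test_that("peptide_backbone_mass sums residues, water, and mod deltas", {
  expect_equal(peptide_backbone_mass("G"), 75.03203, tolerance = 1e-4)
  expect_equal(peptide_backbone_mass("PEPTIDE"), 799.35997, tolerance = 5e-4)
  # independent oracle: whole-molecule elemental formula of PEPTIDE
  # (C34H53N7O15) must equal the residue-sum route
  expect_equal(peptide_backbone_mass("PEPTIDE"), formula_mass("C34H53N7O15"),
               tolerance = 1e-9)
  expect_equal(peptide_backbone_mass("PEPTIDE", c(57.02146, 15.99491)),
               peptide_backbone_mass("PEPTIDE") + 57.02146 + 15.99491)
  expect_error(peptide_backbone_mass(""), "non-empty")
  expect_error(peptide_backbone_mass("PEPTIDEZ"), "Z")
})

test_that("Y-ion closed forms match their frozen examples", {
  expect_equal(y_ion_mz_remainder(1000.0, 203.07937, 1L, 0L), 1204.08665,
               tolerance = 1e-5)
  expect_equal(y_ion_mz_remainder(1000.0, 0, 1L, 0L), 1001.00728,
               tolerance = 1e-5)
  # closed form: (1000 + 203.07937 + 2*1.007276)/2 + 1.0033548/2
  expect_equal(y_ion_mz_remainder(1000.0, 203.07937, 2L, 1L), 603.04864,
               tolerance = 1e-5)
  # neutral-loss identity: loss 0 at z = P gives the precursor's own m/z
  proton <- monosaccharide_table()[["proton"]]
  expect_equal(y_ion_mz_neutral_loss(3000, 0, 3L, 0L),
               (3000 + 3 * proton) / 3, tolerance = 1e-9)
  expect_error(y_ion_mz_neutral_loss(1000, 1500, 1L, 0L), "loss mass")
  expect_error(y_ion_mz_remainder(1000, -5, 1L, 0L), "remainder")
  expect_error(y_ion_mz_remainder(1000, 0, 0L, 0L), "charge")
  expect_error(y_ion_mz_remainder(1000, 0, 1L, 3L), "isotope")
})

test_that("remainder and neutral-loss modes agree algebraically", {
  set.seed(17)
  tab <- monosaccharide_table()
  for (i in 1:50) {
    pep <- runif(1, 500, 3000)
    glycan <- runif(1, 300, 2500)
    remainder <- runif(1, 0, glycan)
    loss <- glycan - remainder
    z <- sample(1:5, 1)
    k <- sample(0:2, 1)
    expect_equal(
      y_ion_mz_remainder(pep, remainder, z, k),
      y_ion_mz_neutral_loss(pep + glycan, loss, z, k),
      tolerance = 1e-6
    )
    # isotope spacing property is exact
    if (k < 2)
      expect_equal(
        y_ion_mz_remainder(pep, remainder, z, k + 1L) -
          y_ion_mz_remainder(pep, remainder, z, k),
        tab[["isotope"]] / z, tolerance = 1e-12)
    # m/z strictly decreases with charge
    if (z > 1)
      expect_lt(y_ion_mz_remainder(pep, remainder, z, k),
                y_ion_mz_remainder(pep, remainder, z - 1L, k))
  }
})

test_that("charge-range specs resolve against the precursor charge", {
  expect_equal(resolve_charge_range("1", "P-1", P = 3), c(1L, 2L))
  expect_equal(resolve_charge_range(2, 2, P = 4), 2L)
  expect_equal(resolve_charge_range("1", "P", P = 1), 1L)
  expect_error(resolve_charge_range("3", "2", P = 4), "empty")
  expect_error(resolve_charge_range("0", "P", P = 2), "< 1")
  expect_error(resolve_charge_range("1", "P+1", P = 2), "> precursor")
  expect_error(resolve_charge_range("P; q()", "P", P = 2), "invalid")
})

test_that("PSM table and glycan database parse the documented dialect", {
  psm_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Spectrum\tPeptide\tCharge\tAssigned Modifications\tTotal Glycan Composition",
    "run1.7.7.3\tPEPTIDEK\t3\t\tHexNAc2-Hex5",
    "run1.9.9.2\tGASK\t2\t2A(15.9949), 4K(57.0215)\tHexNAc1"), psm_path)
  psms <- read_psm_table(psm_path)
  expect_equal(psms$scan_number, c(7L, 9L))
  expect_equal(psms$charge, c(3L, 2L))
  expect_equal(psms$mod_deltas[[1]], numeric(0))
  expect_equal(psms$mod_deltas[[2]], c(15.9949, 57.0215))

  gdb_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("glycan\tmass", "HexNAc2-Hex5\t1216.4229", "HexNAc1\t203.0794"),
             gdb_path)
  gdb <- read_glycan_db(gdb_path)
  expect_equal(nrow(gdb), 2L)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("glycan\tmass", "X\t-3"), bad)
  expect_error(read_glycan_db(bad), "non-positive")
})

test_that("extract_y_ions recovers planted Y-ions and gates isotopes", {
  dir <- withr::local_tempdir()
  fx <- generate_glycopeptide_fixture(dir, seed = 101L)
  sp <- read_mzml(fx$mzml)[[1]]
  psm <- read_psm_table(fx$psm)[1, ]
  gdb <- read_glycan_db(fx$glycans)
  yt <- extract_y_ions(sp, psm, gdb)
  planted <- names(default_y_remainders())[1:3]
  hit <- yt[yt$matched, ]
  expect_setequal(hit$label, planted)
  expect_true(all(hit$charge == 1L))
  expect_true(all(abs(hit$mass_error_ppm) < 15))

  # isotope gating: plant only M+1, then k=0 misses and k=1 finds it
  fx1 <- generate_glycopeptide_fixture(file.path(dir, "m1"),
                                       plant = default_y_remainders()[1],
                                       plant_k = 1L, seed = 102L)
  sp1 <- read_mzml(fx1$mzml)[[1]]
  psm1 <- read_psm_table(fx1$psm)[1, ]
  y_k0 <- extract_y_ions(sp1, psm1, gdb, isotopes = 0L)
  y_k1 <- extract_y_ions(sp1, psm1, gdb, isotopes = 1L)
  expect_false(any(y_k0$matched[y_k0$label == "Y0"]))
  expect_true(any(y_k1$matched[y_k1$label == "Y0"]))

  # decoy-only spectrum: nothing matched
  decoy <- make_spectrum(c(500.123, 777.456), c(10, 10))
  decoy$scan_number <- psm$scan_number
  y0 <- extract_y_ions(decoy, psm, gdb)
  expect_false(any(y0$matched))

  expect_error(extract_y_ions(sp, psm,
                              data.frame(glycan = "Other", mass = 1)),
               "not in database")
  wrong <- generate_spectrum(fixture_spec(n_scans = 1L, seed = 1L), 1L)
  expect_error(extract_y_ions(wrong, psm, gdb), "does not match")
})

test_that("custom additions and subtractions expand the target grid", {
  dir <- withr::local_tempdir()
  fx <- generate_glycopeptide_fixture(dir, seed = 44L)
  sp <- read_mzml(fx$mzml)[[1]]
  psm <- read_psm_table(fx$psm)[1, ]
  gdb <- read_glycan_db(fx$glycans)
  base <- extract_y_ions(sp, psm, gdb, charge_range = c("1", "1"))
  plus <- extract_y_ions(sp, psm, gdb, charge_range = c("1", "1"),
                         custom_additions = c(Deamidated = 0.984),
                         custom_subtractions = c(Water = 18.0106))
  expect_gt(nrow(plus), nrow(base))
  expect_true(any(grepl("\\+Deamidated$", plus$label)))
  expect_true(any(plus$mode == "NEUTRAL_LOSS"))
})
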