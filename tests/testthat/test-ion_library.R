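test_that("oxonium_mz reproduces anchor ion m/z values", {
  cases <- list(
    list(comp = c(HexNAc = 1), losses = NULL, expect = 204.0866),
    list(comp = c(Hex = 1, HexNAc = 1), losses = NULL, expect = 366.1395),
    list(comp = c(NeuAc = 1), losses = NULL, expect = 292.1027),
    list(comp = c(NeuAc = 1), losses = "H2O", expect = 274.0921),
    list(comp = c(HexNAc = 1), losses = "CH6O3", expect = 138.0550),
    list(comp = c(HexNAc = 1), losses = "C2H4O2", expect = 144.0655)
  )
  for (cs in cases)
    expect_equal(oxonium_mz(cs$comp, cs$losses), cs$expect, tolerance = 1e-4)
  # formylation as an adduct: HexNAc + CO = +27.9949
  expect_equal(oxonium_mz(c(HexNAc = 1), adducts = "CO"), 232.0816,
               tolerance = 1e-4)
})

test_that("oxonium_mz rejects degenerate input with named tokens", {
  expect_error(oxonium_mz(c()), "empty composition")
  expect_error(oxonium_mz(c(Foo = 1)), "Foo")
  expect_error(oxonium_mz(c(HexNAc = 1), losses = "Xx9"), "Xx")
  expect_error(formula_mass("notaformula!"), "unparsable")
})

test_that("additivity: mz(A+B) = mz(A) + mz(B) - proton", {
  proton <- monosaccharide_table()[["proton"]]
  residues <- c("Hex", "HexNAc", "dHex", "NeuAc", "NeuGc", "Pent")
  for (a in residues) for (b in residues) {
    comp_ab <- setNames(c(1, 1), c(a, b))
    if (a == b) comp_ab <- setNames(2, a)
    expect_equal(oxonium_mz(comp_ab),
                 oxonium_mz(setNames(1, a)) + oxonium_mz(setNames(1, b)) -
                   proton,
                 tolerance = 1e-9)
  }
})

test_that("built-in catalog has the documented shape and self-consistency", {
  common <- builtin_catalog("common")
  all_ions <- builtin_catalog("all")
  expect_equal(nrow(common), 17L)
  expect_gte(nrow(all_ions), 50L)
  expect_true(all(common$name %in% all_ions$name))
  expect_false(anyDuplicated(all_ions$name) > 0)
  expect_false(is.unsorted(all_ions$mz))
  expect_error(builtin_catalog("neither"))
  # round-trip: every stored composition re-derives its registered m/z
  rederived <- vapply(seq_len(nrow(all_ions)), function(i)
    oxonium_mz(all_ions$composition[[i]], all_ions$losses[[i]],
               all_ions$adducts[[i]]), numeric(1))
  expect_true(all(abs(rederived - all_ions$mz) < 0.005))
})

test_that("custom-ion TSV parsing handles m/z, composition, and errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmz\tcomposition\tadducts",
               "HexNAzoSi\t345.14\t\t",
               "HexNAc+formyl\t\tHexNAc:1\tCO"), path)
  sel <- parse_custom_ions(path)
  expect_equal(nrow(sel), 2L)
  expect_equal(sel$mz[sel$name == "HexNAzoSi"], 345.14)
  expect_equal(sel$mz[sel$name == "HexNAc+formyl"], 232.0816,
               tolerance = 1e-4)
  expect_equal(attr(sel, "label"), "custom")

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmz", "ok\t345.14", "broken\t"), bad)
  expect_error(parse_custom_ions(bad), "line 3")

  low <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmz", "subproton\t0.5"), low)
  expect_error(parse_custom_ions(low), "proton")

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("name\tmz", empty)
  expect_warning(sel0 <- parse_custom_ions(empty), "no data rows")
  expect_equal(nrow(sel0), 0L)
})

test_that("combining selections keeps order and rejects duplicate names", {
  common <- builtin_catalog("common")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("name\tmz", "ClickTag\t345.14"), path)
  custom <- parse_custom_ions(path)
  mixed <- combine_ions(common, custom)
  expect_equal(nrow(mixed), 18L)
  expect_equal(mixed$name, c(common$name, "ClickTag"))
  expect_error(combine_ions(common, common), "duplicate")
})
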