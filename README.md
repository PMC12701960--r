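# glycoscreen

Glycopeptide MS/MS spectra are full of glycan-specific fragments —
oxonium (B-type) ions from the non-reducing end of the glycan and
Y-type ions (peptide backbone plus a truncated glycan) — but most
pipelines only look at them in the small fraction of spectra a search
engine identifies. `glycoscreen` extracts these diagnostic ions from
**every** centroided MS/MS scan in an mzML file, independent of any
search engine, and classifies each scan as a likely glycopeptide
spectrum.

For each scan the package records, per selected ion found within a mass
tolerance (default 15 ppm, configurable in ppm or Da):

* **peak depth** — the ion's intensity rank within the scan (1 = most
  intense peak);
* **intensity**, filtered by signal-to-noise (when the file carries
  noise estimates) or by an absolute intensity threshold;
* the **oxonium TIC fraction** — summed matched intensity / total ion
  current.

A scan is called **LikelyGlycoSpectrum** when both hold:

1. at least *r(n)* selected ions are matched within the activation's
   peak-depth window (25 most-abundant peaks for HCD, 50 for the ETD
   family, 25 for UVPD), where for *n* selected ions
   *r(n)* = 4 for *n* < 6, ⌈*n*/2⌋ for 6 ≤ *n* ≤ 15, and 8 for *n* > 15,
   halved for ETD-family scans and never below 4 (fewer than 4 selected
   ions disables the call entirely); and
2. the oxonium TIC fraction reaches 0.20 (HCD), 0.05 (ETD family) or
   0.20 (UVPD).

The package ships a 56-ion catalog (17-ion "common" subset) whose m/z
values are derived at run time from monoisotopic residue masses, a
custom-ion TSV loader, a Y-ion calculator driven by a FragPipe-style
PSM table plus a glycan mass database, a synthetic-spectrum generator
with planted ions for testing, tab-delimited report writers, and a CLI.

## Worked example

```r
library(glycoscreen)

# ion masses are computed, not tabulated
oxonium_mz(c(HexNAc = 1))            # 204.0866
oxonium_mz(c(NeuAc = 1))             # 292.1027
required_ion_count(17, "HCD")        # 8
required_ion_count(17, "ETD_FAMILY") # 4

# a synthetic file with 8 planted common ions at 30% of TIC per scan
dir <- tempfile(); dir.create(dir)
write_fixture_mzml(fixture_spec(n_scans = 3, seed = 42),
                   file.path(dir, "fix.mzML"))
res <- run_extract(file.path(dir, "fix.mzML"), file.path(dir, "out"),
                   ions = "common")
#> fix.mzML: 3 scans, 3 LikelyGlyco (100.0%)
read.delim(file.path(dir, "out", "fix_OxoSummary.txt"))[, c(1, 6:9)]
#>   Scan IonsMatched IonsInDepthWindow OxoniumTICFraction LikelyGlycoSpectrum
#> 1    1           8                 8               0.3                TRUE
#> 2    2           8                 8               0.3                TRUE
#> 3    3           8                 8               0.3                TRUE
```

Each processed file yields three tab-delimited outputs:
`<stem>_OxoPeakDepth.txt` (rows = scans, columns = ions, cells = peak
depth), `<stem>_OxoSignal.txt` (same shape, intensities) and
`<stem>_OxoSummary.txt` (per-scan totals and the LikelyGlyco flag).
Y-ion runs (`run_ynaught()`) produce `Y`-prefixed analogs.

## Command line

```sh
exec/glycoscreen extract  --input data/ --out results --ions common --tolerance 15
exec/glycoscreen ynaught  --input run.mzML --psm psm.tsv --glycans glycans.tsv --out results
exec/glycoscreen fixtures --out fixtures --seed 1
```

`--ions` accepts `common`, `all`, a custom TSV (columns `name` and
`mz`, or `composition`/`losses`/`adducts`), or a union such as
`common+extra.tsv`. Folders are processed in batch; per-file failures
are logged without aborting the run (exit code 2).

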