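---
title: "Screening glycopeptide MS/MS spectra for glycan diagnostic ions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening glycopeptide MS/MS spectra for glycan diagnostic ions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoscreen)
```

# The problem

Glycosidic bonds are labile, so glycopeptide MS/MS spectra are rich in
glycan-specific fragments: low-m/z oxonium (B-type) ions such as HexNAc
at m/z 204.0866 or NeuAc at 292.1027, and Y-type ions that retain the
peptide backbone with a truncated glycan. These ions indicate glycan
presence and composition without requiring a peptide identification —
yet most workflows only inspect them in the minority of spectra a
search engine assigns. `glycoscreen` screens *every* MS/MS scan for a
user-selected ion set and flags likely glycopeptide spectra, decoupling
spectral evaluation from identification. Typical uses: checking
glyco-enzyme efficiency (PNGaseF leaves a 0.984 Da deamidation;
sialidase removes NeuAc/NeuGc ions), comparing enrichment methods,
screening for modified glycans (formylation, click-chemistry tags) via
custom ions, and validating database-search conclusions.

# The mass model

All m/z values are derived at run time from monoisotopic elemental
masses (H 1.00782503207, C 12, N 14.0030740048, O 15.9949146196,
P 30.97376163, S 31.972071; proton 1.007276466; 13C–12C spacing
1.0033548 Da). A residue mass is the dehydrated monosaccharide
(Hex 162.0528, HexNAc 203.0794, dHex 146.0579, NeuAc 291.0954,
NeuGc 307.0903, HPO3 79.9663); an oxonium ion is

$$ m/z = \sum_i n_i \, m_{\text{residue},i} - \sum m_{\text{loss}} +
         \sum m_{\text{adduct}} + m_{\text{proton}} $$

This choice of constants reproduces the four-decimal literature value
292.1027 for NeuAc and every two/three-decimal figure value the catalog
covers. Two literature printings (366.140, 138.06) are double-rounded
from shorter printings of the same quantities; the tests compare those
at printed precision with a 0.55-ULP band rather than pretending the
double rounding is exact.

The shipped catalog holds 56 ions; the 17-ion "common" subset is the
package's default screening set. The exact membership of a "common" set
is a community convention, not a derivable quantity, so the membership
here is a documented, configurable default (the count of 17 is fixed by
convention). One catalog note: the literature labels m/z 964.33 as
NeuGc2-Hex-HexNAc, but that composition computes to 980.32; 964.33
corresponds to NeuAc-NeuGc-Hex-HexNAc, and the catalog registers both
ions under the compositions that actually produce their m/z.

# Extraction semantics

* **Tolerance.** Default 15 ppm (suits ~30k-resolution Orbitrap
  fragment spectra); a Dalton tolerance supports ion-trap data. The ppm
  window is computed on the theoretical m/z and is symmetric and closed.
* **Peak filtering.** When the file carries per-peak noise estimates,
  a signal-to-noise threshold governs (default S/N ≥ 3); otherwise an
  absolute intensity threshold (default 0 = accept all positive peaks).
* **Within-window choice.** Among qualifying in-window peaks the *most
  intense* wins (diagnostic ions are high-abundance); an intensity tie
  goes to the smallest absolute mass error. This is deliberately not
  "closest m/z" — both policies were considered, the choice is
  documented here and enforced by an independent brute-force oracle in
  the tests.
* **Peak sharing.** Isobaric catalog entries may match the same peak;
  each ion consumes at most one peak. The hash-set-style lookup is
  per-ion and independent.
* **Peak depth.** Rank by descending intensity, ties broken by
  ascending m/z so ranks are a deterministic permutation.
* **TIC fraction.** Sum of *all* matched intensities over the scan TIC,
  clamped to [0, 1]; the depth window gates only the classifier count,
  not the fraction.

# Classification

Per activation type (ETD here covers EThcD, AI-ETD and ETcaD; any ETD
term in the activation metadata wins even when supplemental collisional
activation is present):

| parameter | HCD | ETD family | UVPD |
|---|---|---|---|
| depth window (peaks) | 25 | 50 | 25 |
| min oxonium TIC fraction | 0.20 | 0.05 | 0.20 |

The required matched-ion count scales with the selection size *n*:
4 when *n* < 6, half of *n* (rounded half up) for 6–15, 8 when *n* > 15;
halved (again half up) for ETD-family scans; floored at 4. With fewer
than 4 selected ions no scan is ever flagged. UVPD uses the HCD counts:
only ETD's halving is stated by the rule, and HCD/UVPD spectra show
similar oxonium behaviour. Regime boundaries are inclusive ("6 through
15"). Half-up rounding for odd *n* is the conservative documented
choice; the printed anchors (17 → 8 → 4) are invariant to it. All
thresholds are user-overridable.

# mzML handling

No mzML reader exists in the supported dependency set, so the package
implements the required subset of mzML 1.1 directly over `xml2`:
spectrum/activation cvParams, selected-ion blocks, and base64 binary
arrays (64- or 32-bit little-endian floats, optionally
zlib-compressed). Deliberate behaviours:

* zlib-compressed arrays are **accepted** (compression is lossless);
  gzip-packaged `.mzML.gz` files are rejected with guidance.
* Profile-mode MS/MS raises an error instructing centroiding, detected
  from the file's own declaration or a heuristic (median peak spacing
  < 0.005 Da over > 500 peaks).
* The scan TIC from file metadata is trusted unless it disagrees with
  the summed peak intensities by more than 20%, in which case the sum
  is used (the TIC fraction must be self-consistent with the matched
  peaks).
* The document is parsed with `xml2` and peak arrays are decoded one
  spectrum at a time; this is not constant-memory SAX streaming, which
  is acceptable at the file sizes the package targets.

# Y-ion arithmetic

For an identified glycopeptide (peptide backbone mass *M*&#8209;*p* =
Σ residue + water + non-glycan modification deltas, glycan mass *G*
from the database):

* remainder mode: $(M_p + R + z\,m_H)/z + k\,\Delta_{13C}/z$
* neutral-loss mode: $(M_p + G - L + z\,m_H)/z + k\,\Delta_{13C}/z$

with charge *z* resolved from a range spec in the precursor charge *P*
(e.g. `"1"`–`"P-1"`) and isotope index *k* ∈ {0, 1, 2}. The two modes
are algebraically identical when *L* = *G* − *R*; this mode equivalence
is the module's central property test (1e-6 Da over randomized grids).
The precursor neutral mass is computed from the backbone plus the
database glycan mass, not back-calculated from the observed precursor
m/z, so results are calibration-independent. Custom additions combine
with every remainder and custom subtractions with every loss
(cartesian).

# The synthetic-data generator

Fixtures state a known world: *k* planted ions at their theoretical m/z
± at most 5 ppm occupying intensity ranks 1..*k*, decoy peaks drawn
uniformly over m/z 120–2000 but at least 30 ppm away from **every**
catalog ion, and decoy intensities scaled so the planted TIC share is
exactly the requested fraction (default 0.30, comfortably above the
0.20 HCD threshold; 100 decoys per scan). The 30-ppm exclusion zone
makes recall and false-positive assertions exact rather than
probabilistic; infeasible requests (decoys unable to absorb the
required intensity while staying below the weakest planted peak) fail
at specification time. Generation is bit-reproducible from a single
seed.

What the generator does **not** emulate: real isotope envelopes,
peptide backbone fragment ladders, correlated noise, chromatographic
structure, or the scan-range truncation of real instruments. A green
planted-recovery test therefore establishes the correctness of the
matching/classification machinery, not biological performance on real
data; the desk-scale null check (decoy-only scans flagged < 1% of the
time) is the analog of a no-glycopeptide control sample, not a
replacement for one.

# Numerical and degenerate-input choices

* Tolerance windows are closed on both sides; boundary peaks match.
* Empty scans are skipped with a warning; an empty spectrum ranks to an
  empty vector; a scan whose metadata TIC is too small still yields a
  TIC fraction clamped to [0, 1].
* Report files freeze formatting (fractions 4 decimals, m/z 5 decimals,
  intensities 4-significant-digit scientific) so identical inputs give
  byte-identical outputs; existing outputs are never clobbered
  (timestamp suffix).
* Duplicate ion names are rejected; duplicate m/z values are allowed
  and logged (isobaric compositions are legitimate).

# Known limitations

Single-threaded, whole-document XML parsing; no deisotoping or charge
deconvolution of fragments; no DIA-specific logic; no probabilistic
scoring or FDR for the LikelyGlyco flag — it is a deterministic rule
whose thresholds the user should adapt when the acquisition (e.g. a
raised low-m/z scan bound) makes defaults inappropriate.
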