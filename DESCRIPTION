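Package: glycoscreen
Title: Glycan Diagnostic-Ion Screening of Glycopeptide MS/MS Spectra
Version: 0.1.0
Authors@R: person("Glycoscreen", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Extracts glycan-specific diagnostic (oxonium) ions and Y-type
    ions from centroided tandem mass spectra stored in mzML, scores the
    glycan content of every MS/MS scan (matched-ion count, peak depth,
    oxonium fraction of the total ion current), and classifies likely
    glycopeptide spectra with activation-specific rules -- fully decoupled
    from any glycopeptide search engine. Includes a Y-ion calculator driven
    by a PSM table and glycan mass database, a synthetic-spectrum fixture
    generator with planted ions, tab-delimited report writers, and a
    command-line front end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
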