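Package: ggsite
Title: Ubiquitination-Site Identification from GG-Remnant Signature
    Peptides in Tandem Mass Spectrometry Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying protein ubiquitination sites from the
    glycyl-glycine (GG) remnant left on modified lysines after tryptic
    digestion.  Provides exact mass arithmetic for peptides and the
    +114.04 Da GG remnant, in-silico trypsin digestion with missed
    cleavages and cleavage blocking at GG-modified lysines, theoretical
    branched b/y fragment-ion generation, narrow-window extracted ion
    chromatography screening of candidate precursors, spectrum-to-peptide
    matching with a minimum-branched-ion acceptance rule, and two-peptide
    protein-level filtering.  A synthetic-data module simulates proteomes,
    planted GG sites and MS1/MS2 data so the whole pipeline can be
    exercised end to end.  Reporting utilities tally packaged protein
    tables from a rat brain mitochondrial ubiquitination study, and a
    small network module thresholds and clusters confidence-weighted
    protein interaction edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
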