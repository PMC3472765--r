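# ggsite

Identification of protein ubiquitination sites from the glycyl-glycine
(GG) remnant signature in tandem mass spectrometry data.

## The problem

Ubiquitin is conjugated through its C-terminal Gly76 to the ε-amine of a
lysine residue in a substrate protein.  Tryptic digestion of a
ubiquitinated protein cannot cleave after the modified lysine, and it
leaves a Gly-Gly dipeptide isopeptide-linked to it.  The resulting
*signature peptide* is therefore recognisable by two marks:

* a precursor mass shift of **Δm = 114.04293 Da** (monoisotopic; the
  elemental composition C₄H₆N₂O₂ of two glycine residues in amide
  linkage — no water, since neither glycine has a free terminus), and
* *branched* b/y fragment ions — those whose residue span contains the
  modified lysine — shifted by Δm/z relative to their unmodified
  homologs.

`ggsite` implements this search as a reusable pipeline for proteomics
workflows built on ion-trap data:

1. **In-silico tryptic digestion** (cleave after K/R, not before P) with
   missed cleavages and *cleavage blocking* at GG-modified lysines.
2. **Candidate enumeration**: for each lysine, every covering peptide
   with the GG delta applied, at precursor charges 2+–4+.
3. **Narrow-window (±0.3 m/z) extracted ion chromatography** screening
   of candidate precursors against an MS1 trace.
4. **Branched fragment matching**: theoretical b/y ladders are assigned
   to observed peaks greedily by mass error (0.5 Da tolerance; one peak
   per ion), and a site is accepted only when **at least four matched
   fragments are branched**.
5. **Protein-level filtering**: at least two distinct peptides with
   score ≥ 7 and a summed protein score ≥ 14.

A synthetic-data module simulates proteomes, planted GG sites and
MS1/MS2 data with the statistical structure the search assumes, so the
whole pipeline can be validated end to end without any external data.
Reporting utilities reproduce the tallies of a rat brain mitochondrial
ubiquitination study from packaged table transcriptions, and a small
network module thresholds and clusters confidence-weighted interaction
edge lists (k-means over a spectral embedding, k = 5 and confidence
≥ 0.7 by convention).

## Worked example

```r
library(ggsite)

round(gg_delta_mass("monoisotopic"), 2)
#> [1] 114.04

cfg <- sim_config(n_proteins = 6, n_planted_sites = 4, n_distractors = 3,
                  seed = 3)
sim <- simulate_proteome(cfg)                       # proteome + ground truth
dat <- simulate_spectra(sim$proteins, sim$truth, cfg)
res <- ggsite_search(sim$proteins, dat$spectra, dat$trace)
res
#> <gg_search_result: 72 site calls (72 accepted at 4 sites), 3 proteins (3 accepted)>

acc <- res$sites[res$sites$accepted, ]
head(unique(acc[, c("accession", "site", "peptide",
                    "n_branched_matched", "peptide_score")]), 5)
#>   accession site            peptide n_branched_matched peptide_score
#> 1    SYN001    5             RDKIKK                 10            30
#> 2    SYN001    5              DKIKK                  8            26
#> 3    SYN001    5 DKIKKFQATFVGLALGNR                 34            78
#> 4    SYN001    5                IKK                  4            18
#> 5    SYN001    5   IKKFQATFVGLALGNR                 30            70

unlist(score_recovery(res$sites, sim$truth)[c("recall", "precision")])
#>    recall precision
#>         1         1
```

Each accepted row is one spectrum-to-peptide match: the GG site (protein
coordinate), the covering peptide (several missed-cleavage variants of
the same site are typical, because the blocked lysine forces longer
peptides), how many matched fragment ions were branched, and the
surrogate peptide score.  All four planted sites are recovered with no
false calls in this noiseless simulation.

The packaged study tables are summarised with:

```r
fx <- load_fixtures()
tally_groups(fx$table1)                              # 13, 24, ... (sum 50)
classify_signature_localization(fx$table3, fx$table1)  # 2 intra, 10 extra
```

A thin command-line wrapper with `simulate`, `search`, `report` and
`cluster` subcommands is installed at
`system.file("scripts", "ggsite.R", package = "ggsite")`.

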