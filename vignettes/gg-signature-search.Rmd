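---
title: "Identifying ubiquitination sites from GG-remnant signature peptides"
author: "ggsite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying ubiquitination sites from GG-remnant signature peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggsite)
```

## The measurement model

Ubiquitin conjugation attaches the C-terminus of ubiquitin (…LRGG) to a
substrate lysine's ε-amine via an isopeptide bond.  Trypsin cleaves
ubiquitin itself after the arginine of LRGG, so digestion of a
ubiquitinated protein leaves a Gly-Gly dipeptide on the modified lysine.
Two consequences drive everything in this package:

* **Mass shift.**  The remnant adds exactly two glycine *residue*
  masses — elemental composition C₄H₆N₂O₂ — because both glycines are in
  amide linkage and contribute no water.  From the embedded atomic-mass
  table this is 114.04293 Da monoisotopic (114.04 at display precision)
  and 114.104 Da average (114.1).  All residue, water and modification
  masses are derived from the one atomic-mass table, so the identity
  `gg_delta_mass() == 2 * residue_masses()["G"]` holds to the last bit.
* **Blocked cleavage.**  The branch sterically blocks trypsin, so the
  modified lysine is always internal to its peptide (unless it is the
  protein's C-terminus).  Digestion therefore yields longer,
  missed-cleavage-like signature peptides.

A *branched* fragment ion is any b- or y-ion whose residue span contains
the GG-modified lysine; it carries the remnant and is shifted by
114.04293/z against its unmodified homolog.  The literature does not pin
down the term further; this span-membership definition is the standard
GG-remnant reading and makes the acceptance rule computable.  Ions from
fragmentation *within* the branch are not modelled — no masses are
published for them — and the remnant is treated as an inert mass on the
lysine.  Neutral losses, a-ions, ETD ion types and immonium ions are out
of scope; they are extension points, not part of the acceptance rule,
which counts branched b/y evidence only.

## The search procedure

`ggsite_search()` composes five stages:

1. **Candidate enumeration** (`enumerate_signature_candidates`).  For
   every lysine (discovery mode) or a supplied site list (targeted
   mode), every tryptic peptide covering that lysine — with cleavage at
   it blocked — is crossed with precursor charges 2+–4+.  Blocked
   junctions do not consume the missed-cleavage budget: the engine the
   original ion-trap workflow used does not document its counting, and
   exempting the blocked junction is what keeps long printed signature
   peptides reachable under a two-missed-cleavage limit.  This is our
   choice, recorded here rather than attributed to any external
   convention.
2. **XIC screening** (`extract_xic`, `screen_candidates`).  Per MS1
   scan, intensities within ±0.3 m/z of the candidate precursor are
   summed; candidates with no signal are dropped and the apex retention
   time is recorded.  Whether screening preceded or merely validated the
   MS2 evidence in the original workflow is unknowable; we run
   screen-then-match and allow `trace = NULL` to bypass screening.
3. **Spectrum pairing.**  A spectrum is tried against a screened
   candidate iff the charges agree, the precursor m/z lies within the
   XIC half-width, and the candidate shows detectable XIC signal within
   ±30 s of the spectrum.  We deliberately pair on nearby signal rather
   than on the XIC's global apex: a stronger co-eluting peptide inside
   the same ±0.3 m/z window can displace the global apex far from the
   candidate's own elution, which would silently unpair a genuine match
   while leaving chance cross-candidates paired.
4. **Fragment matching** (`match_spectrum`).  After charge
   deconvolution, precursors beyond 1.6 Da of the theoretical mass skip
   the candidate.  Theoretical b/y ladders (fragment charges 1–2 by
   default; informative 3+ fragments are rare in ion-trap data) are
   assigned to peaks greedily by ascending |Δm/z| within 0.5 Da, one
   peak per ion and one ion per peak, ties toward the lower-index
   fragment.  Greedy assignment is deterministic and, on small spectra,
   verified in the test suite against an exhaustive optimal assignment.
   A site call is **accepted** when ≥ 4 matched ions are branched.
5. **Competition and protein filtering.**  A spectrum arises from one
   precursor, so its matches compete.  First, a GG call must explain at
   least as many peaks as the best *unmodified* tryptic peptide
   compatible with the precursor — a spectrum of a plain peptide can
   otherwise chance-match four branched ions of some GG candidate at the
   0.5 Da tolerance.  Second, each spectrum keeps only its top match,
   ranked by peaks explained with the surrogate score as tie-break;
   without this rank-1 selection, dense ladders of unrelated candidates
   accumulate branched coincidences and the noiseless simulation no
   longer attains perfect precision.  When one spectrum supports the
   same peptide with the GG
   on different lysines (equal precursor mass), the placement with more
   matched branched ions wins; exact ties are both reported and flagged
   `ambiguous`.  Finally `filter_proteins` applies the two-peptide rule:
   ≥ 2 distinct peptides with score ≥ 7 and a summed score ≥ 14.

### The surrogate peptide score

The original workflow's commercial scoring function is proprietary and
not reproducible.  We use a transparent surrogate,

\[ s = 10 \cdot \frac{\text{matched ions}}{\text{theoretical ions}}
      + 2 \cdot n_\text{branched}, \]

which is monotone in both kinds of evidence and calibrated so that the
conventional thresholds (7 per peptide, 14 per protein) remain
meaningful on clean ladders: a complete match alone contributes 10, and
each branched ion adds 2, so an accepted site (≥ 4 branched) passes the
peptide threshold comfortably while sparse chance matches do not.

### Key parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `precursor_tol` | 1.6 | Da | neutral-mass window after deconvolution |
| `fragment_tol` | 0.5 | Da | fragment assignment window |
| `xic_halfwidth` | 0.3 | m/z | XIC window half-width; also the pairing window |
| `min_branched_ions` | 4 | ions | site acceptance threshold |
| `precursor_charges` | 2–4 | — | charge states searched |
| `fragment_charges` | 1–2 | — | ladder charges generated |
| `max_missed` | 2 | — | missed-cleavage limit (blocked junctions exempt) |
| `min_peptide_score` / `min_protein_score` | 7 / 14 | — | protein filter |
| `rt_window` | 30 | s | MS2-to-apex pairing window |

Tolerances are in daltons, not ppm, matching ion-trap practice.  Fixed
cysteine carbamidomethylation (+57.02146 Da) is on by default;
methionine oxidation (+15.99491 Da) is available as a variable
modification through `build_mods()`.

## The synthetic-data generator

`simulate_proteome()` draws i.i.d. residues from an embedded
vertebrate-like amino-acid frequency table (≈ 5.8 % lysine), giving 20
proteins of 200–400 residues by default, and plants 10 GG sites drawn
without replacement from all lysine positions.  `simulate_spectra()`
then emits, for every covering candidate peptide × charge: a Gaussian
elution profile (σ = 6 s, apex uniform over the 100–1100 s run, scans
every 2 s) at the precursor m/z in MS1, and one MS2 spectrum at the apex
containing the b/y ladders with per-ion dropout, N(0, σ_jitter) m/z
jitter and log-normal intensities, plus uniform noise peaks and
unmodified distractor peptides.  Defaults are the noiseless case
(dropout 0, jitter 0, no noise peaks); the noise knobs exist to exercise
the specificity of the acceptance rule, not to imitate any instrument.

What the generator does *not* emulate — isotope envelopes, chimeric
co-isolation, chromatographic drift, chemical noise structure,
homologous sequences — bounds what a passing test means: perfect
recovery on this generator shows the pipeline's logic is sound, not that
real-data sensitivity or specificity would be perfect.

All randomness flows from `sim_config(seed = )`; the proteome and
spectrum stages use `seed` and `seed + 1`, so a single integer
reproduces a whole experiment bit for bit.

## Packaged study tables

Three TSV transcriptions of a rat brain mitochondrial ubiquitination
study's printed protein tables ship under `inst/extdata/tables`: 50
specifically bound proteins in seven functional groups (13 in energy /
carbohydrate metabolism, 24 in cytoskeleton / exocytosis), 59
control-incubation proteins, and 12 signature-bearing proteins whose
localizations split 2 intramitochondrial / 10 extramitochondrial.
Transcription quirks are preserved deliberately: the Tubulin alpha-1B
chain (Q6P9V9) is listed twice and tallies count printed rows, not
unique accessions, to match the source's own arithmetic; two scores are
printed with comma decimals and are normalised on read.  Note that
12/50 = 24 %, although the source text describes the ubiquitinated
fraction as "about 20 %"; `report` prints the exact ratio.  Accession is
the join key throughout — names vary between tables.

## Network module

`cluster_nodes()` implements the conventional interactome
post-processing: inclusive confidence thresholding at 0.7 (the STRING
convention) and k-means with k = 5 over a symmetric normalised-Laplacian
spectral embedding (smallest `min(k, n-1)` eigenvectors, rows unit
normalised), with a fixed seed and first-appearance relabelling so
results are deterministic.  The per-node "confidence 0.9" filter used in
such workflows is ambiguous; we expose it as an optional
mean-incident-confidence filter applied before clustering and make no
fidelity claim.  Degenerate cases short-circuit: k = 1 assigns all nodes
to one cluster, k = n assigns each node its own.

## Numerical choices and degenerate inputs

* Internal arithmetic is full double precision; display rounding (2 d.p.
  monoisotopic, 1 d.p. average) happens only at reporting.
* Coordinates are 1-based and inclusive everywhere ("K442"-style).
  Protein N-terminal methionine is never stripped — signature positions
  in initiator-containing peptides depend on it.
* Complementarity (`b_i + y_{n−i} = M + 2·proton` for singly charged
  ladders, within 1e-4 Da) is enforced as an internal oracle.
* An MGF block without a CHARGE line defaults to 2+ with a warning; an
  empty MS1 trace yields an empty XIC, not an error; unsorted MS1
  retention times are rejected naming the row.
* No-call recovery reports precision 1.0 by convention, flagged via the
  `no_calls` attribute.

## Problem sizes in the test suite

The suite validates the analytic examples exactly, property-style
invariants over randomised inputs at fixed seeds (mass additivity,
ladder complementarity, digestion reassembly, GG-blocking, greedy-vs-
exhaustive matching on ≤ 12-peak spectra, monotonicity of acceptance in
the branched-ion threshold), and one full noiseless round trip at the
default scale — 20 proteins, 10 planted sites — chosen as a realistic
small discovery experiment: about 350 lysines yield a few thousand
candidates, of which only the planted ones carry MS1/MS2 evidence.
`scripts/acceptance.R` re-runs that round trip from scratch at a
user-supplied seed.

## Known limitations

* No decoy search or FDR estimation — the acceptance rule is a hard
  evidence count, as in the original targeted workflow.
* Quantification, retention-time prediction and mzML input are out of
  scope; MS2 interchange is MGF and MS1 is a tidy CSV.
* Only trypsin is modelled, fully tryptic termini only, and only lysine
  GG sites (no N-terminal ubiquitination).
* The surrogate score is comparable within a run of this package, not
  across engines.
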