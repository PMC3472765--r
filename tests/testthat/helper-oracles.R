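# Shared test utilities: independent oracles and spectrum builders.

# Exhaustive maximum one-to-one fragment-to-peak assignment (cardinality).
# Independent oracle for the greedy matcher; exponential, for small inputs.
bf_max_matching <- function(frag_mz, peak_mz, tol) {
  ok <- abs(outer(frag_mz, peak_mz, "-")) <= tol
  nf <- length(frag_mz)
  rec <- function(fi, used) {
    if (fi > nf) return(0L)
    best <- rec(fi + 1L, used)
    for (pj in which(ok[fi, ] & !used)) {
      used[pj] <- TRUE
      best <- max(best, 1L + rec(fi + 1L, used))
      used[pj] <- FALSE
    }
    best
  }
  rec(1L, logical(length(peak_mz)))
}

# Sample n elements of x even when length(x) == 1 (avoids sample()'s
# integer-expansion behaviour).
pick <- function(x, n = 1) x[sample.int(length(x), n)]

# Random peptide sequence (uniform residues, no compositional realism).
random_peptide <- function(n, residues = names(residue_masses())) {
  paste(sample(residues, n, replace = TRUE), collapse = "")
}

# Random protein guaranteed to contain at least one lysine.
random_protein_with_k <- function(n) {
  repeat {
    s <- random_peptide(n)
    if (grepl("K", s, fixed = TRUE)) return(s)
  }
}

# Noiseless MS2 spectrum holding exactly the theoretical fragment peaks of
# a GG-modified peptide (optionally a subset), at unit intensity.
noiseless_spectrum <- function(sequence, gg_local, charge,
                               fragment_charges = c(1, 2),
                               keep = NULL, id = "t1", rt = 300,
                               carbamidomethyl = FALSE) {
  mods <- build_mods(sequence, gg_sites = gg_local,
                     carbamidomethyl = carbamidomethyl)
  frags <- generate_fragments(sequence, mods = mods,
                              fragment_charges = fragment_charges)
  if (!is.null(keep)) frags <- frags[keep, , drop = FALSE]
  ms2_spectrum(id, mz(peptide_mass(sequence, mods = mods), charge), charge,
               rt, data.frame(mz = frags$mz, intensity = 1))
}

# Candidate row in the shape enumerate_signature_candidates() emits.
candidate_row <- function(sequence, site, accession = "P1", start = 1L) {
  data.frame(accession = accession, site = site, sequence = sequence,
             start = start, stringsAsFactors = FALSE)
}
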