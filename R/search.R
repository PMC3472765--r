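#' Search configuration
#'
#' Defaults mirror the ion-trap search settings the pipeline was designed
#' around: 1.6 Da precursor tolerance (monoisotopic, after charge
#' deconvolution), 0.5 Da fragment tolerance, +/-0.3 m/z extracted-ion-
#' chromatography window, precursor charges 2+..4+, two missed cleavages,
#' at least four matched branched fragment ions per site, and the
#' two-peptide protein rule with peptide score >= 7 and protein score
#' >= 14.
#'
#' @param precursor_tol Precursor mass tolerance in Da.
#' @param fragment_tol Fragment m/z tolerance in Da.
#' @param xic_halfwidth XIC window half-width in m/z.
#' @param min_branched_ions Minimum matched branched fragment ions for site
#'   acceptance.
#' @param precursor_charges Precursor charge states searched.
#' @param fragment_charges Fragment ion charges generated.
#' @param max_missed Maximum missed cleavages in digestion.
#' @param min_peptides_per_protein Distinct contributing peptides required
#'   per protein.
#' @param min_peptide_score Minimum surrogate peptide score to contribute.
#' @param min_protein_score Minimum summed protein score.
#' @param rt_window Half-width in seconds of the retention-time window
#'   pairing MS2 spectra to an XIC apex.
#' @param xic_min_signal Minimum XIC maximum for a candidate to survive
#'   screening.
#' @param carbamidomethyl Apply fixed Cys carbamidomethylation.
#' @return Object of class `gg_search_config` (a named list).
#' @export
search_config <- function(precursor_tol = 1.6,
                          fragment_tol = 0.5,
                          xic_halfwidth = 0.3,
                          min_branched_ions = 4L,
                          precursor_charges = 2:4,
                          fragment_charges = c(1L, 2L),
                          max_missed = 2L,
                          min_peptides_per_protein = 2L,
                          min_peptide_score = 7,
                          min_protein_score = 14,
                          rt_window = 30,
                          xic_min_signal = 0,
                          carbamidomethyl = TRUE) {
  cfg <- list(
    precursor_tol = precursor_tol, fragment_tol = fragment_tol,
    xic_halfwidth = xic_halfwidth,
    min_branched_ions = as.integer(min_branched_ions),
    precursor_charges = as.integer(precursor_charges),
    fragment_charges = as.integer(fragment_charges),
    max_missed = as.integer(max_missed),
    min_peptides_per_protein = as.integer(min_peptides_per_protein),
    min_peptide_score = min_peptide_score,
    min_protein_score = min_protein_score,
    rt_window = rt_window, xic_min_signal = xic_min_signal,
    carbamidomethyl = isTRUE(carbamidomethyl)
  )
  if (cfg$precursor_tol <= 0 || cfg$fragment_tol <= 0 || cfg$xic_halfwidth <= 0) {
    stop("tolerances must be > 0")
  }
  if (cfg$min_branched_ions < 1L) stop("min_branched_ions must be >= 1")
  structure(cfg, class = "gg_search_config")
}

#' Extracted ion chromatogram over a narrow m/z window
#'
#' For each MS1 scan, sums the intensities of peaks within
#' `abs(mz - target_mz) <= halfwidth`.  One output point per scan; an
#' empty trace yields an empty chromatogram.
#'
#' @param trace An [ms1_trace()].
#' @param target_mz Target m/z.
#' @param halfwidth Window half-width in m/z (default 0.3).
#' @return data.frame with columns `rt_seconds`, `intensity`.
#' @export
extract_xic <- function(trace, target_mz, halfwidth = 0.3) {
  stopifnot(halfwidth > 0)
  if (!nrow(trace)) {
    return(data.frame(rt_seconds = numeric(), intensity = numeric()))
  }
  rts <- unique(trace$rt_seconds)
  hit <- abs(trace$mz - target_mz) <= halfwidth
  sums <- rep(0, length(rts))
  if (any(hit)) {
    agg <- tapply(trace$intensity[hit], match(trace$rt_seconds[hit], rts), sum)
    sums[as.integer(names(agg))] <- as.numeric(agg)
  }
  data.frame(rt_seconds = rts, intensity = sums)
}

#' Screen precursor candidates by extracted ion chromatography
#'
#' Retains candidates whose XIC maximum exceeds `config$xic_min_signal`
#' and records the apex retention time for MS2 pairing.  Co-eluting
#' candidates within one window are all retained (no mutual exclusion).
#'
#' @param trace An [ms1_trace()].
#' @param candidates Candidate table from
#'   [enumerate_signature_candidates()].
#' @param config A [search_config()].
#' @return The retained candidate rows with `apex_rt` and `xic_max` added.
#' @export
screen_candidates <- function(trace, candidates, config = search_config()) {
  if (!nrow(candidates)) {
    out <- candidates
    out$apex_rt <- numeric(0)
    out$xic_max <- numeric(0)
    return(out)
  }
  apex <- numeric(nrow(candidates))
  xmax <- numeric(nrow(candidates))
  rts <- unique(trace$rt_seconds)
  for (i in seq_len(nrow(candidates))) {
    hit <- abs(trace$mz - candidates$precursor_mz[i]) <= config$xic_halfwidth
    if (!any(hit)) { apex[i] <- NA_real_; next }
    agg <- tapply(trace$intensity[hit], trace$rt_seconds[hit], sum)
    j <- which.max(agg)
    xmax[i] <- as.numeric(agg[j])
    apex[i] <- as.numeric(names(agg)[j])
  }
  keep <- !is.na(apex) & xmax > config$xic_min_signal
  out <- candidates[keep, , drop = FALSE]
  out$apex_rt <- apex[keep]
  out$xic_max <- xmax[keep]
  rownames(out) <- NULL
  out
}

# Greedy one-to-one assignment of theoretical fragments to peaks within
# fragment_tol, by ascending |delta m/z|; ties broken toward the
# lower-index fragment (then b before y).  Returns logical vector over
# fragments: matched or not.
.greedy_match <- function(frag_mz, frag_order, peak_mz, tol) {
  nf <- length(frag_mz)
  np <- length(peak_mz)
  if (!nf || !np) return(logical(nf))
  d <- abs(outer(frag_mz, peak_mz, "-"))
  pairs <- which(d <= tol, arr.ind = TRUE)
  if (!nrow(pairs)) return(logical(nf))
  delta <- d[pairs]
  ord <- order(delta, frag_order[pairs[, 1]], pairs[, 2])
  pairs <- pairs[ord, , drop = FALSE]
  frag_used <- logical(nf)
  peak_used <- logical(np)
  for (r in seq_len(nrow(pairs))) {
    fi <- pairs[r, 1]; pj <- pairs[r, 2]
    if (!frag_used[fi] && !peak_used[pj]) {
      frag_used[fi] <- TRUE
      peak_used[pj] <- TRUE
    }
  }
  frag_used
}

#' Match one MS2 spectrum against one GG-candidate peptide
#'
#' The observed precursor is deconvoluted to a neutral mass and compared
#' with the candidate's theoretical mass; a deviation beyond
#' `config$precursor_tol` skips the candidate (returns `NULL`, not an
#' error).  Theoretical b/y fragments are assigned to observed peaks
#' greedily by ascending m/z error, one peak per ion and one ion per peak.
#' The site call is accepted when at least `config$min_branched_ions`
#' matched fragments are branched (span the GG-modified lysine).  The
#' surrogate peptide score is
#' `10 * n_total_matched / n_theoretical + 2 * n_branched_matched`.
#'
#' @param spectrum An [ms2_spectrum()].
#' @param candidate One-row data.frame (or list) with fields `accession`,
#'   `site`, `sequence`, `start` as produced by
#'   [enumerate_signature_candidates()].
#' @param config A [search_config()].
#' @return One-row data.frame site call (`accession`, `site`, `peptide`,
#'   `start`, `charge`, `spectrum_id`, `n_branched_matched`,
#'   `n_total_matched`, `n_theoretical`, `peptide_score`, `accepted`), or
#'   `NULL` when the precursor is outside tolerance.
#' @export
match_spectrum <- function(spectrum, candidate, config = search_config()) {
  site_local <- candidate$site - candidate$start + 1L
  mods <- build_mods(candidate$sequence, gg_sites = site_local,
                     carbamidomethyl = config$carbamidomethyl)
  theo_mass <- peptide_mass(candidate$sequence, mods = mods)
  obs_mass <- neutral_mass(spectrum$precursor_mz, spectrum$precursor_charge)
  if (abs(obs_mass - theo_mass) > config$precursor_tol) return(NULL)

  frags <- generate_fragments(candidate$sequence, mods = mods,
                              fragment_charges = config$fragment_charges)
  frag_order <- frags$index * 2L + (frags$series == "y")
  matched <- .greedy_match(frags$mz, frag_order, spectrum$peaks$mz,
                           config$fragment_tol)
  n_total <- sum(matched)
  n_branched <- sum(matched & frags$branched)
  score <- 10 * n_total / nrow(frags) + 2 * n_branched
  data.frame(
    accession = candidate$accession,
    site = as.integer(candidate$site),
    peptide = candidate$sequence,
    start = as.integer(candidate$start),
    charge = spectrum$precursor_charge,
    spectrum_id = spectrum$spectrum_id,
    n_branched_matched = n_branched,
    n_total_matched = n_total,
    n_theoretical = nrow(frags),
    peptide_score = score,
    accepted = n_branched >= config$min_branched_ions,
    stringsAsFactors = FALSE
  )
}

#' Protein-level filtering of site calls
#'
#' Groups site calls by accession and applies the two-peptide rule: a
#' protein is accepted when it has at least
#' `config$min_peptides_per_protein` distinct peptides whose score reaches
#' `config$min_peptide_score`, and the sum of those contributing scores
#' (best score per distinct peptide) reaches `config$min_protein_score`.
#' Peptides below the peptide-score threshold do not contribute.
#'
#' @param site_calls data.frame of site calls from [match_spectrum()].
#' @param config A [search_config()].
#' @return data.frame with one row per accession: `accession`,
#'   `distinct_peptides`, `protein_score`, `accepted`.
#' @export
filter_proteins <- function(site_calls, config = search_config()) {
  if (!nrow(site_calls)) {
    return(data.frame(accession = character(), distinct_peptides = integer(),
                      protein_score = numeric(), accepted = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(site_calls, site_calls$accession), function(g) {
    contrib <- g[g$peptide_score >= config$min_peptide_score, , drop = FALSE]
    best <- if (nrow(contrib)) {
      tapply(contrib$peptide_score, contrib$peptide, max)
    } else numeric(0)
    data.frame(
      accession = g$accession[1],
      distinct_peptides = length(best),
      protein_score = sum(best),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out$accepted <- out$distinct_peptides >= config$min_peptides_per_protein &
    out$protein_score >= config$min_protein_score
  out <- out[order(out$accession), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Per-spectrum competition: each MS2 spectrum keeps only its best peptide
# match(es), ranked by peaks explained (n_total_matched) with the surrogate
# score as tie-break.  A spectrum arises from one precursor, so lower-ranked
# cross-peptide matches are chance overlaps.
.best_hit_per_spectrum <- function(calls) {
  if (!nrow(calls)) return(calls)
  out <- lapply(split(calls, calls$spectrum_id), function(g) {
    g <- g[g$n_total_matched == max(g$n_total_matched), , drop = FALSE]
    g[g$peptide_score == max(g$peptide_score), , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Unmodified tryptic peptides as competing explanations for a spectrum: a
# GG call that explains fewer peaks than some plain peptide at the same
# precursor is a chance overlap, not a signature.
.unmodified_competitors <- function(proteins, config) {
  peps <- unique(unlist(lapply(proteins$sequence, function(s) {
    d <- digest(s, max_missed = config$max_missed)
    d$sequence[nchar(d$sequence) >= 2]
  })))
  if (!length(peps)) {
    return(data.frame(sequence = character(), charge = integer(),
                      precursor_mz = numeric(), stringsAsFactors = FALSE))
  }
  mass <- vapply(peps, function(p) {
    peptide_mass(p, mods = build_mods(p, carbamidomethyl = config$carbamidomethyl))
  }, numeric(1))
  grid <- expand.grid(i = seq_along(peps), charge = config$precursor_charges)
  data.frame(sequence = peps[grid$i], charge = grid$charge,
             precursor_mz = mz(mass[grid$i], grid$charge),
             stringsAsFactors = FALSE)
}

# Best peak-explanation count over unmodified peptides compatible with the
# spectrum's precursor.
.best_unmodified_total <- function(spectrum, unmod, config) {
  sel <- which(unmod$charge == spectrum$precursor_charge &
                 abs(unmod$precursor_mz - spectrum$precursor_mz) <=
                   config$xic_halfwidth)
  best <- 0L
  for (j in sel) {
    sq <- unmod$sequence[j]
    if (nchar(sq) < 2) next
    frags <- generate_fragments(
      sq, mods = build_mods(sq, carbamidomethyl = config$carbamidomethyl),
      fragment_charges = config$fragment_charges
    )
    matched <- .greedy_match(frags$mz, frags$index * 2L + (frags$series == "y"),
                             spectrum$peaks$mz, config$fragment_tol)
    best <- max(best, sum(matched))
  }
  best
}

# Resolve site-localization isoforms: when one spectrum matches the same
# peptide sequence (same charge) with the GG placed on different lysines,
# keep the placement(s) with the most matched branched ions; exact ties are
# kept and flagged ambiguous.
.resolve_isoforms <- function(calls) {
  if (!nrow(calls)) {
    calls$ambiguous <- logical(0)
    return(calls)
  }
  key <- paste(calls$spectrum_id, calls$peptide, calls$charge, sep = "\r")
  kept <- lapply(split(calls, key), function(g) {
    best <- max(g$n_branched_matched)
    g <- g[g$n_branched_matched == best, , drop = FALSE]
    g$ambiguous <- nrow(g) > 1L
    g
  })
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  out
}

#' Run the full GG signature-peptide search
#'
#' Pipeline: enumerate GG precursor candidates for every protein (all
#' lysines, or only `sites` when given), screen them by narrow-window
#' extracted ion chromatography against the MS1 trace, pair each MS2
#' spectrum with screened candidates of the same charge whose precursor
#' m/z lies within the XIC window and which show detectable XIC signal
#' within `config$rt_window` seconds of the spectrum, match fragments,
#' apply per-spectrum competition (a GG call must explain at least as many
#' peaks as any unmodified tryptic peptide compatible with the precursor,
#' and each spectrum keeps only its best match by peaks explained, then
#' score; exact ties are all kept), resolve site-localization isoforms,
#' and apply protein-level filtering.  Set
#' `trace = NULL` to bypass XIC screening and pair on precursor m/z alone.
#'
#' @param proteins data.frame with columns `accession`, `sequence`.
#' @param spectra List of [ms2_spectrum()] objects.
#' @param trace An [ms1_trace()], or `NULL` to skip XIC screening.
#' @param config A [search_config()].
#' @param sites Optional data.frame (`accession`, `site`) restricting the
#'   search to known lysines (targeted mode).
#' @return List of class `gg_search_result`: `sites` (site-call
#'   data.frame, stably sorted by accession, site, charge) and `proteins`
#'   (from [filter_proteins()], computed over accepted site calls).
#' @export
ggsite_search <- function(proteins, spectra, trace = NULL,
                          config = search_config(), sites = NULL) {
  cand <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    acc <- proteins$accession[i]
    tgt <- if (is.null(sites)) NULL else sites$site[sites$accession == acc]
    if (!is.null(tgt) && !length(tgt)) return(NULL)
    enumerate_signature_candidates(
      proteins$sequence[i], accession = acc, sites = tgt,
      max_missed = config$max_missed, charges = config$precursor_charges,
      carbamidomethyl = config$carbamidomethyl
    )
  }))
  empty_calls <- data.frame(
    accession = character(), site = integer(), peptide = character(),
    start = integer(), charge = integer(), spectrum_id = character(),
    n_branched_matched = integer(), n_total_matched = integer(),
    n_theoretical = integer(), peptide_score = numeric(),
    accepted = logical(), ambiguous = logical(), stringsAsFactors = FALSE
  )
  if (is.null(cand) || !nrow(cand)) {
    return(structure(list(sites = empty_calls,
                          proteins = filter_proteins(empty_calls, config)),
                     class = "gg_search_result"))
  }

  use_xic <- !is.null(trace)
  if (use_xic) {
    cand <- screen_candidates(trace, cand, config)
  } else {
    cand$apex_rt <- NA_real_
  }
  unmod <- .unmodified_competitors(proteins, config)

  calls <- list()
  for (s in spectra) {
    sel <- which(cand$charge == s$precursor_charge &
                   abs(cand$precursor_mz - s$precursor_mz) <= config$xic_halfwidth)
    if (use_xic && !is.na(s$retention_time) && length(sel)) {
      # require detectable XIC signal near the spectrum itself; the global
      # apex can be displaced by a co-eluting interferer in the same window
      near <- trace[abs(trace$rt_seconds - s$retention_time) <= config$rt_window &
                      trace$intensity > config$xic_min_signal, , drop = FALSE]
      sel <- sel[vapply(sel, function(j) {
        any(abs(near$mz - cand$precursor_mz[j]) <= config$xic_halfwidth)
      }, logical(1))]
    }
    if (!length(sel)) next
    best_plain <- .best_unmodified_total(s, unmod, config)
    for (j in sel) {
      call <- match_spectrum(s, cand[j, ], config)
      if (!is.null(call) && call$n_total_matched >= best_plain) {
        calls[[length(calls) + 1L]] <- call
      }
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    empty_calls[, setdiff(names(empty_calls), "ambiguous")]
  calls <- .best_hit_per_spectrum(calls)
  calls <- .resolve_isoforms(calls)
  calls <- calls[order(calls$accession, calls$site, calls$charge,
                       calls$spectrum_id), , drop = FALSE]
  rownames(calls) <- NULL
  structure(
    list(sites = calls,
         proteins = filter_proteins(calls[calls$accepted, , drop = FALSE], config)),
    class = "gg_search_result"
  )
}

#' @export
print.gg_search_result <- function(x, ...) {
  acc <- x$sites[x$sites$accepted, , drop = FALSE]
  cat(sprintf("<gg_search_result: %d site calls (%d accepted at %d sites), %d proteins (%d accepted)>\n",
              nrow(x$sites), nrow(acc),
              nrow(unique(acc[, c("accession", "site")])),
              nrow(x$proteins), sum(x$proteins$accepted)))
  invisible(x)
}
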