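#' In-silico trypsin digestion with GG-blocked lysines
#'
#' Cleaves after K or R except when the next residue is proline, and never
#' after a GG-modified lysine: the isopeptide-linked remnant sterically
#' blocks trypsin, which is what makes the signature peptide observable in
#' the first place.  Peptides are enumerated for 0..`max_missed` missed
#' cleavages; blocked junctions are not cleavage sites at all and therefore
#' do not consume the missed-cleavage budget.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param gg_sites Integer vector of 1-based lysine positions carrying a GG
#'   remnant; cleavage after these positions is suppressed.
#' @param max_missed Maximum number of missed cleavages (default 2).
#' @return data.frame with one row per peptide: `sequence`, `start`, `end`
#'   (1-based, inclusive, protein coordinates) and `missed_cleavages`.
#' @export
#' @examples
#' digest("AKGR", max_missed = 0)$sequence   # "AK", "GR"
#' digest("AKGR", gg_sites = 2, max_missed = 0)$sequence  # "AKGR"
digest <- function(sequence, gg_sites = integer(), max_missed = 2) {
  stopifnot(max_missed >= 0)
  chars <- .check_sequence(sequence)
  n <- length(chars)
  gg_sites <- as.integer(gg_sites)
  if (length(gg_sites) && any(chars[gg_sites] != "K")) {
    stop("gg_sites must index 'K' residues")
  }
  sites <- which(chars %in% c("K", "R"))
  sites <- sites[sites < n & chars[sites + 1L] != "P"]
  sites <- setdiff(sites, gg_sites)
  bounds <- c(0L, sites, n)
  out <- vector("list", length(bounds) - 1L)
  for (a in seq_len(length(bounds) - 1L)) {
    bmax <- min(a + 1L + max_missed, length(bounds))
    b <- seq.int(a + 1L, bmax)
    out[[a]] <- data.frame(
      start = bounds[a] + 1L,
      end = bounds[b],
      missed_cleavages = b - a - 1L
    )
  }
  out <- do.call(rbind, out)
  out$sequence <- substring(sequence, out$start, out$end)
  out[, c("sequence", "start", "end", "missed_cleavages")]
}

#' Enumerate GG signature-peptide precursor candidates
#'
#' For each lysine of interest, enumerates every tryptic peptide (with up
#' to `max_missed` missed cleavages) that covers it when cleavage at that
#' lysine is blocked by the GG remnant, applies the GG mass delta, and
#' crosses the result with the requested precursor charge states.  When
#' `sites` is `NULL` every lysine in the protein is considered (discovery
#' mode); otherwise only the given positions (targeted mode).
#'
#' @param sequence Protein sequence.
#' @param accession Accession carried through to the output.
#' @param sites Optional integer vector of 1-based lysine positions.
#' @param max_missed Maximum missed cleavages (default 2).
#' @param charges Precursor charge states (default 2:4).
#' @param carbamidomethyl Apply the fixed carbamidomethyl delta on Cys when
#'   computing precursor masses (default `FALSE`).
#' @return data.frame with columns `accession`, `site` (protein coordinate
#'   of the modified K), `sequence`, `start`, `missed_cleavages`, `charge`,
#'   `precursor_mz`.
#' @export
enumerate_signature_candidates <- function(sequence, accession = "protein",
                                           sites = NULL, max_missed = 2,
                                           charges = 2:4,
                                           carbamidomethyl = FALSE) {
  chars <- .check_sequence(sequence)
  if (is.null(sites)) {
    sites <- which(chars == "K")
  } else {
    sites <- as.integer(sites)
    if (length(sites) && any(chars[sites] != "K")) {
      stop("sites must index 'K' residues in ", accession)
    }
  }
  charges <- as.integer(charges)
  out <- vector("list", length(sites))
  for (i in seq_along(sites)) {
    s <- sites[i]
    peps <- digest(sequence, gg_sites = s, max_missed = max_missed)
    peps <- peps[peps$start <= s & peps$end >= s, , drop = FALSE]
    if (!nrow(peps)) next
    mass <- vapply(seq_len(nrow(peps)), function(j) {
      mods <- build_mods(peps$sequence[j], gg_sites = s - peps$start[j] + 1L,
                         carbamidomethyl = carbamidomethyl)
      peptide_mass(peps$sequence[j], mods = mods)
    }, numeric(1))
    grid <- expand.grid(j = seq_len(nrow(peps)), charge = charges)
    out[[i]] <- data.frame(
      accession = accession,
      site = s,
      sequence = peps$sequence[grid$j],
      start = peps$start[grid$j],
      missed_cleavages = peps$missed_cleavages[grid$j],
      charge = grid$charge,
      precursor_mz = mz(mass[grid$j], grid$charge),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(accession = character(), site = integer(),
                      sequence = character(), start = integer(),
                      missed_cleavages = integer(), charge = integer(),
                      precursor_mz = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Read protein sequences from a FASTA file
#'
#' Accession is the first whitespace-delimited token of each header.
#' Plain and gzip-compressed files are supported.
#'
#' @param path Path to a FASTA file.
#' @return data.frame with columns `accession` and `sequence`.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  data.frame(
    accession = vapply(strsplit(names(aa), "\\s+"), `[`, character(1), 1L),
    sequence = as.character(aa),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with columns `accession`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$accession
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
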