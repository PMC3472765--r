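.loc_levels <- c("M", "EM", "PM", "unknown")
.group_levels <- c("energy_carbohydrate", "cytoskeleton_exocytosis",
                   "protective", "signal_regulation", "fatty_acid",
                   "transporters", "ubiquitin_related")

#' Load the packaged study tables
#'
#' Reads the three tab-separated transcriptions of the study's printed
#' protein tables shipped under `inst/extdata/tables`: the 50 proteins
#' specifically bound after incubation with biotinylated ubiquitin
#' (table 1), the 59 control-incubation proteins (table 2), and the 12
#' proteins carrying GG ubiquitination signatures with their peptides and
#' sites (table 3).  Localization codes are mapped to the closed
#' vocabulary M / EM / PM / unknown; comma decimals in printed scores are
#' normalised to '.'.
#'
#' @param path Directory holding `table1.tsv`, `table2.tsv`, `table3.tsv`.
#' @return List with elements `table1`, `table2`, `table3` (data.frames;
#'   `table3$peptides` and `table3$sites` are list columns).
#' @export
load_fixtures <- function(path = system.file("extdata", "tables",
                                             package = "ggsite")) {
  read1 <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("fixture not found: ", f)
    df <- utils::read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
    if (!nrow(df)) stop("fixture is empty: ", f)
    df
  }
  num <- function(x) as.numeric(sub(",", ".", x, fixed = TRUE))

  t1 <- read1("table1.tsv")
  t1$search_score <- num(t1$search_score)
  t1$localization <- ifelse(t1$localization %in% c("M", "EM", "PM"),
                            t1$localization, "unknown")
  bad <- !t1$functional_group %in% .group_levels
  if (any(bad)) {
    stop("unknown functional group in table1 row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (any(!nzchar(t1$accession))) stop("empty accession in table1")

  t2 <- read1("table2.tsv")
  t2$search_score <- num(t2$search_score)

  t3 <- read1("table3.tsv")
  t3$search_score <- num(t3$search_score)
  t3$peptides <- strsplit(t3$peptides, ";", fixed = TRUE)
  t3$sites <- strsplit(t3$sites, ";", fixed = TRUE)
  ok <- vapply(t3$sites, function(s) all(grepl("^K[0-9]+$", s)), logical(1))
  if (any(!ok)) {
    stop("malformed site label in table3 row(s): ",
         paste(which(!ok), collapse = ", "))
  }
  list(table1 = t1, table2 = t2, table3 = t3)
}

#' Background subtraction of control identifications
#'
#' Splits the ubiquitin-incubation identifications into those specific to
#' the incubation and those shared with the control pull-down, keyed on
#' accession.
#'
#' @param specific data.frame of proteins from the ubiquitin incubation
#'   (must have an `accession` column).
#' @param control data.frame of control-incubation proteins.
#' @return List with `specific_only` and `shared` (row subsets of
#'   `specific`).  `nrow(specific_only) + nrow(shared) == nrow(specific)`.
#' @export
subtract_background <- function(specific, control) {
  shared <- specific$accession %in% control$accession
  list(specific_only = specific[!shared, , drop = FALSE],
       shared = specific[shared, , drop = FALSE])
}

#' Tally proteins by functional group
#'
#' @param table1 The table-1 data.frame from [load_fixtures()].
#' @return Named integer vector of row counts per functional group (counts
#'   printed rows, not unique accessions, matching the source table's own
#'   arithmetic).
#' @export
tally_groups <- function(table1) {
  counts <- table(factor(table1$functional_group, levels = .group_levels))
  out <- as.integer(counts)
  names(out) <- names(counts)
  out
}

#' Split signature-bearing proteins by localization
#'
#' Resolves each signature-bearing protein's localization against table 1
#' (M is intramitochondrial; EM and PM are extramitochondrial).
#'
#' @param table3 Signature table from [load_fixtures()].
#' @param table1 Protein table from [load_fixtures()].
#' @return Named integer vector `c(n_intramitochondrial, n_extramitochondrial)`.
#' @export
classify_signature_localization <- function(table3, table1) {
  idx <- match(table3$accession, table1$accession)
  if (anyNA(idx)) {
    stop("accession(s) not resolvable against table1: ",
         paste(table3$accession[is.na(idx)], collapse = ", "))
  }
  loc <- table1$localization[idx]
  if (any(loc == "unknown")) {
    stop("localization unknown for: ",
         paste(table3$accession[loc == "unknown"], collapse = ", "))
  }
  c(n_intramitochondrial = sum(loc == "M"),
    n_extramitochondrial = sum(loc %in% c("EM", "PM")))
}
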