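#' Theoretical b/y fragment ions of a (GG-branched) peptide
#'
#' Generates the full b1..b(n-1) and y1..y(n-1) ladders at each requested
#' fragment charge.  A fragment is *branched* when its residue span contains
#' a GG-modified lysine: such ions are shifted by +114.04293/z relative to
#' the unmodified homolog and are the evidence the site-acceptance rule
#' counts.  The GG remnant is treated as an inert mass on the lysine;
#' fragmentation within the branch itself is not modelled.
#'
#' @param sequence Peptide sequence, length >= 2.
#' @param mods Optional modification table from [build_mods()]; rows with
#'   label `"GG"` define the branch points.
#' @param fragment_charges Fragment ion charges (default `c(1, 2)`).
#' @return data.frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`, `branched`.
#' @export
#' @examples
#' generate_fragments("GK", mods = build_mods("GK", gg_sites = 2),
#'                    fragment_charges = 1)
generate_fragments <- function(sequence, mods = NULL,
                               fragment_charges = c(1, 2)) {
  chars <- .check_sequence(sequence)
  n <- length(chars)
  if (n < 2) stop("peptide must have length >= 2 to fragment")
  fragment_charges <- as.integer(fragment_charges)
  if (any(fragment_charges < 1)) stop("fragment charges must be >= 1")

  delta_at <- numeric(n)
  gg_pos <- integer()
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > n)) stop("modification position outside peptide")
    for (j in seq_len(nrow(mods))) {
      delta_at[mods$pos[j]] <- delta_at[mods$pos[j]] + mods$delta[j]
    }
    gg_pos <- mods$pos[mods$label == "GG"]
  }

  res <- .residue_mono[chars] + delta_at
  prefix <- cumsum(res)
  idx <- seq_len(n - 1L)
  b_neutral <- prefix[idx]
  y_neutral <- prefix[n] - prefix[n - idx] + .water_mono
  b_branched <- vapply(idx, function(i) any(gg_pos <= i), logical(1))
  y_branched <- vapply(idx, function(i) any(gg_pos > n - i), logical(1))

  out <- do.call(rbind, lapply(fragment_charges, function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = c(idx, idx),
      charge = z,
      mz = c((b_neutral + z * .proton_mono) / z,
             (y_neutral + z * .proton_mono) / z),
      branched = c(b_branched, y_branched),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Check b/y ladder complementarity
#'
#' For singly charged full ladders, `mz(b_i, 1) + mz(y_{n-i}, 1)` must equal
#' the neutral peptide mass plus two protons for every index i.  Used as an
#' internal consistency oracle on generated ladders.
#'
#' @param fragments Output of [generate_fragments()] containing complete
#'   singly charged b and y ladders.
#' @param peptide_mass_da Neutral peptide mass in Da (modifications
#'   included).
#' @param tol Tolerance in Da (default 1e-4).
#' @return `TRUE` if the identity holds at every index, else `FALSE`.
#' @export
complementary_check <- function(fragments, peptide_mass_da, tol = 1e-4) {
  f1 <- fragments[fragments$charge == 1L, , drop = FALSE]
  b <- f1[f1$series == "b", , drop = FALSE]
  y <- f1[f1$series == "y", , drop = FALSE]
  n1 <- max(c(b$index, y$index, 0L))
  if (!n1 || nrow(b) != n1 || nrow(y) != n1 ||
      !setequal(b$index, seq_len(n1)) || !setequal(y$index, seq_len(n1))) {
    stop("complementary_check requires complete singly charged b and y ladders")
  }
  b <- b[order(b$index), ]
  y <- y[order(y$index), ]
  target <- peptide_mass_da + 2 * .proton_mono
  all(abs(b$mz + y$mz[n1 - b$index + 1L] - target) <= tol)
}
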