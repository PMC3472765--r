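# Amino-acid background frequencies (%), Swiss-Prot vertebrate-like
# composition; gives a realistic ~5-6% lysine density.
.aa_freq <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
)

#' Simulation configuration
#'
#' Defines the data-generating process the search assumes: tryptic
#' GG-modified peptides at precursor charges 2+..4+, Gaussian elution
#' profiles in MS1, b/y fragment ladders with the +114.04 Da shift on ions
#' spanning the modified lysine, per-ion dropout, Gaussian m/z jitter,
#' log-normal intensities, and uniform noise peaks.
#'
#' @param n_proteins Number of synthetic proteins.
#' @param protein_length_range Min/max protein length (residues).
#' @param n_planted_sites Number of GG sites planted (without replacement)
#'   across all lysines.
#' @param elution_sigma Gaussian elution peak width (s).
#' @param fragment_dropout_prob Probability each theoretical fragment ion is
#'   absent from its MS2 spectrum.
#' @param noise_peaks_per_spectrum Uniform noise peaks added per spectrum.
#' @param noise_mz_range m/z range of noise peaks.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model.
#' @param mass_jitter_sd Gaussian m/z jitter SD (Da) applied to every peak.
#' @param rt_range Retention-time range (s) for elution apexes.
#' @param scan_interval MS1 scan spacing (s).
#' @param precursor_charges Precursor charges simulated per candidate.
#' @param fragment_charges Fragment charges present in MS2 spectra.
#' @param max_missed Missed cleavages allowed when enumerating candidate
#'   peptides.
#' @param n_distractors Number of unmodified distractor peptides given MS1
#'   elution and MS2 spectra.
#' @param carbamidomethyl Simulate fixed Cys carbamidomethylation.
#' @param seed Integer seed; every stochastic step derives from it.
#' @return Object of class `gg_sim_config`.
#' @export
sim_config <- function(n_proteins = 20L,
                       protein_length_range = c(200L, 400L),
                       n_planted_sites = 10L,
                       elution_sigma = 6,
                       fragment_dropout_prob = 0,
                       noise_peaks_per_spectrum = 0L,
                       noise_mz_range = c(200, 1500),
                       intensity_meanlog = log(1e4),
                       intensity_sdlog = 0.4,
                       mass_jitter_sd = 0,
                       rt_range = c(100, 1100),
                       scan_interval = 2,
                       precursor_charges = 2:4,
                       fragment_charges = c(1L, 2L),
                       max_missed = 2L,
                       n_distractors = 10L,
                       carbamidomethyl = TRUE,
                       seed = 1L) {
  stopifnot(fragment_dropout_prob >= 0, fragment_dropout_prob <= 1,
            protein_length_range[1] <= protein_length_range[2],
            noise_mz_range[1] <= noise_mz_range[2],
            rt_range[1] < rt_range[2])
  structure(
    list(n_proteins = as.integer(n_proteins),
         protein_length_range = as.integer(protein_length_range),
         n_planted_sites = as.integer(n_planted_sites),
         elution_sigma = elution_sigma,
         fragment_dropout_prob = fragment_dropout_prob,
         noise_peaks_per_spectrum = as.integer(noise_peaks_per_spectrum),
         noise_mz_range = noise_mz_range,
         intensity_meanlog = intensity_meanlog,
         intensity_sdlog = intensity_sdlog,
         mass_jitter_sd = mass_jitter_sd,
         rt_range = rt_range,
         scan_interval = scan_interval,
         precursor_charges = as.integer(precursor_charges),
         fragment_charges = as.integer(fragment_charges),
         max_missed = as.integer(max_missed),
         n_distractors = as.integer(n_distractors),
         carbamidomethyl = isTRUE(carbamidomethyl),
         seed = as.integer(seed)),
    class = "gg_sim_config"
  )
}

#' Simulate a proteome with planted GG sites
#'
#' Residues are drawn i.i.d. from an embedded vertebrate-like amino-acid
#' frequency table; planted ubiquitination sites are drawn without
#' replacement from all lysine positions.  Fully reproducible from
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `proteins` (data.frame `accession`, `sequence`) and
#'   `truth` (data.frame `accession`, `site`).
#' @export
simulate_proteome <- function(config = sim_config()) {
  set.seed(config$seed)
  lens <- sample(seq(config$protein_length_range[1],
                     config$protein_length_range[2]),
                 config$n_proteins, replace = TRUE)
  proteins <- data.frame(
    accession = sprintf("SYN%03d", seq_len(config$n_proteins)),
    sequence = vapply(lens, function(L) {
      paste(sample(names(.aa_freq), L, replace = TRUE, prob = .aa_freq),
            collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  lys <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
    pos <- which(strsplit(proteins$sequence[i], "")[[1]] == "K")
    if (!length(pos)) return(NULL)
    data.frame(accession = proteins$accession[i], site = pos,
               stringsAsFactors = FALSE)
  }))
  n_lys <- if (is.null(lys)) 0L else nrow(lys)
  if (config$n_planted_sites > n_lys) {
    stop("cannot plant ", config$n_planted_sites, " sites: only ",
         n_lys, " lysines in the simulated proteome")
  }
  truth <- if (config$n_planted_sites) {
    lys[sort(sample(n_lys, config$n_planted_sites)), , drop = FALSE]
  } else {
    data.frame(accession = character(), site = integer(),
               stringsAsFactors = FALSE)
  }
  rownames(truth) <- NULL
  list(proteins = proteins, truth = truth)
}

.sim_ms1_points <- function(mzs, apex, amplitude, config) {
  grid <- seq(config$rt_range[1] - 4 * config$elution_sigma,
              config$rt_range[2] + 4 * config$elution_sigma,
              by = config$scan_interval)
  sel <- abs(grid - apex) <= 4 * config$elution_sigma
  rts <- grid[sel]
  data.frame(
    rt_seconds = rts,
    mz = mzs + stats::rnorm(length(rts), 0, config$mass_jitter_sd),
    intensity = amplitude * exp(-(rts - apex)^2 / (2 * config$elution_sigma^2))
  )
}

.sim_ms2 <- function(id, sequence, gg_local, charge, rt, config) {
  mods <- build_mods(sequence, gg_sites = gg_local,
                     carbamidomethyl = config$carbamidomethyl)
  pmz <- mz(peptide_mass(sequence, mods = mods), charge) +
    stats::rnorm(1, 0, config$mass_jitter_sd)
  frags <- generate_fragments(sequence, mods = mods,
                              fragment_charges = config$fragment_charges)
  keep <- stats::runif(nrow(frags)) >= config$fragment_dropout_prob
  fmz <- frags$mz[keep] + stats::rnorm(sum(keep), 0, config$mass_jitter_sd)
  fint <- stats::rlnorm(sum(keep), config$intensity_meanlog,
                        config$intensity_sdlog)
  if (config$noise_peaks_per_spectrum > 0L) {
    fmz <- c(fmz, stats::runif(config$noise_peaks_per_spectrum,
                               config$noise_mz_range[1],
                               config$noise_mz_range[2]))
    fint <- c(fint, stats::rlnorm(config$noise_peaks_per_spectrum,
                                  config$intensity_meanlog,
                                  config$intensity_sdlog))
  }
  ms2_spectrum(id, pmz, charge, rt,
               data.frame(mz = fmz, intensity = fint))
}

#' Simulate MS1 and MS2 data for a proteome with planted GG sites
#'
#' For every candidate peptide covering a planted site (each missed-
#' cleavage variant crossed with each precursor charge): a Gaussian elution
#' profile at the precursor m/z in MS1 and one MS2 spectrum at the elution
#' apex containing the (dropout- and jitter-corrupted) b/y ladders plus
#' uniform noise peaks.  Unmodified distractor peptides sampled from the
#' tryptic digests receive the same treatment.
#'
#' @param proteins data.frame (`accession`, `sequence`).
#' @param truth data.frame (`accession`, `site`) of planted GG sites.
#' @param config A [sim_config()].
#' @return List with `trace` (an [ms1_trace()]), `spectra` (list of
#'   [ms2_spectrum()]) and `provenance` (data.frame `spectrum_id`, `kind`,
#'   `accession`, `site`, `peptide`).
#' @export
simulate_spectra <- function(proteins, truth, config = sim_config()) {
  set.seed(config$seed + 1L)
  ms1 <- list()
  spectra <- list()
  prov <- list()
  counter <- 0L

  for (i in seq_len(nrow(truth))) {
    acc <- truth$accession[i]
    seq_i <- proteins$sequence[proteins$accession == acc]
    cands <- enumerate_signature_candidates(
      seq_i, accession = acc, sites = truth$site[i],
      max_missed = config$max_missed, charges = config$precursor_charges,
      carbamidomethyl = config$carbamidomethyl
    )
    for (j in seq_len(nrow(cands))) {
      counter <- counter + 1L
      id <- sprintf("sim%05d", counter)
      apex <- stats::runif(1, config$rt_range[1], config$rt_range[2])
      amp <- stats::rlnorm(1, config$intensity_meanlog, config$intensity_sdlog)
      ms1[[length(ms1) + 1L]] <-
        .sim_ms1_points(cands$precursor_mz[j], apex, amp, config)
      spectra[[length(spectra) + 1L]] <- .sim_ms2(
        id, cands$sequence[j], cands$site[j] - cands$start[j] + 1L,
        cands$charge[j], apex, config
      )
      prov[[length(prov) + 1L]] <- data.frame(
        spectrum_id = id, kind = "site", accession = acc,
        site = cands$site[j], peptide = cands$sequence[j],
        stringsAsFactors = FALSE
      )
    }
  }

  if (config$n_distractors > 0L && nrow(proteins)) {
    pool <- do.call(rbind, lapply(seq_len(nrow(proteins)), function(i) {
      d <- digest(proteins$sequence[i], max_missed = config$max_missed)
      d <- d[nchar(d$sequence) >= 6 & nchar(d$sequence) <= 30, , drop = FALSE]
      if (!nrow(d)) return(NULL)
      d$accession <- proteins$accession[i]
      d
    }))
    if (!is.null(pool) && nrow(pool)) {
      take <- sample(nrow(pool), min(config$n_distractors, nrow(pool)))
      for (j in take) {
        counter <- counter + 1L
        id <- sprintf("sim%05d", counter)
        charge <- sample(config$precursor_charges, 1)
        apex <- stats::runif(1, config$rt_range[1], config$rt_range[2])
        amp <- stats::rlnorm(1, config$intensity_meanlog, config$intensity_sdlog)
        mods <- build_mods(pool$sequence[j],
                           carbamidomethyl = config$carbamidomethyl)
        pmz <- mz(peptide_mass(pool$sequence[j], mods = mods), charge)
        ms1[[length(ms1) + 1L]] <- .sim_ms1_points(pmz, apex, amp, config)
        spectra[[length(spectra) + 1L]] <- .sim_ms2(
          id, pool$sequence[j], integer(), charge, apex, config
        )
        prov[[length(prov) + 1L]] <- data.frame(
          spectrum_id = id, kind = "distractor",
          accession = pool$accession[j], site = NA_integer_,
          peptide = pool$sequence[j], stringsAsFactors = FALSE
        )
      }
    }
  }

  points <- if (length(ms1)) do.call(rbind, ms1) else
    data.frame(rt_seconds = numeric(), mz = numeric(), intensity = numeric())
  points <- points[order(points$rt_seconds, points$mz), , drop = FALSE]
  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(spectrum_id = character(), kind = character(),
               accession = character(), site = integer(),
               peptide = character(), stringsAsFactors = FALSE)
  list(trace = ms1_trace(points), spectra = spectra, provenance = prov)
}

#' Score site recovery against the planted ground truth
#'
#' Site-level exact match on (accession, position) over *accepted* site
#' calls.  With no accepted calls, precision is undefined and reported as
#' 1.0 by convention, flagged via the `"no_calls"` attribute.
#'
#' @param site_calls Site-call data.frame (e.g. `result$sites`).
#' @param truth data.frame (`accession`, `site`).
#' @return List with `recall`, `precision`, `n_called`, `n_true`,
#'   `n_correct`.
#' @export
score_recovery <- function(site_calls, truth) {
  acc <- site_calls[site_calls$accepted, c("accession", "site"), drop = FALSE]
  called <- unique(paste(acc$accession, acc$site))
  true <- unique(paste(truth$accession, truth$site))
  n_correct <- length(intersect(called, true))
  recall <- if (length(true)) n_correct / length(true) else 1
  no_calls <- length(called) == 0L
  precision <- if (no_calls) 1 else n_correct / length(called)
  out <- list(recall = recall, precision = precision,
              n_called = length(called), n_true = length(true),
              n_correct = n_correct)
  attr(out, "no_calls") <- no_calls
  out
}
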