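test_that("XIC sums intensities within the window, one point per scan", {
  trace <- ms1_trace(data.frame(
    rt_seconds = c(10, 10, 20, 30),
    mz = c(500.0, 500.2, 500.31, 700.0),
    intensity = c(5, 7, 3, 100)
  ))
  x <- extract_xic(trace, 500.0, halfwidth = 0.3)
  expect_equal(x$rt_seconds, c(10, 20, 30))
  expect_equal(x$intensity, c(12, 0, 0))  # 500.31 is just outside +/-0.3
  expect_equal(nrow(extract_xic(ms1_trace(), 500.0)), 0L)
})

test_that("XIC apex of a planted Gaussian elution is at the planted time", {
  rts <- seq(200, 400, by = 2)
  trace <- ms1_trace(data.frame(
    rt_seconds = rts, mz = 650.3,
    intensity = 1000 * exp(-(rts - 300)^2 / (2 * 6^2))
  ))
  x <- extract_xic(trace, 650.3, halfwidth = 0.3)
  expect_lte(abs(x$rt_seconds[which.max(x$intensity)] - 300), 2)
})

test_that("screening keeps detectable candidates and records their apex", {
  rts <- seq(100, 500, by = 2)
  sig <- function(target, apex) {
    data.frame(rt_seconds = rts, mz = target,
               intensity = 500 * exp(-(rts - apex)^2 / 72) +
                 stats::runif(length(rts), 0, 50))
  }
  set.seed(1)
  pts <- rbind(sig(600.0, 250), sig(600.2, 250))
  pts <- pts[order(pts$rt_seconds, pts$mz), ]
  trace <- ms1_trace(pts)
  cand <- data.frame(accession = "P1", site = c(5L, 9L, 9L),
                     sequence = "X", start = 1L, missed_cleavages = 0L,
                     charge = 2L,
                     precursor_mz = c(600.0, 600.2, 980.0),
                     stringsAsFactors = FALSE)
  kept <- screen_candidates(trace, cand, search_config())
  # the zero-signal candidate is dropped; co-eluting candidates both kept
  expect_equal(kept$precursor_mz, c(600.0, 600.2))
  expect_true(all(abs(kept$apex_rt - 250) <= 4))
})

test_that("site acceptance needs at least four matched branched ions", {
  pep <- "GASPKVLR"
  cand <- candidate_row(pep, site = 5L)
  cfg <- search_config(fragment_charges = 1, carbamidomethyl = FALSE)
  mods <- build_mods(pep, gg_sites = 5)
  frags <- generate_fragments(pep, mods = mods, fragment_charges = 1)

  # full noiseless ladder: accepted, with all branched ions matched
  full <- noiseless_spectrum(pep, 5, charge = 2, fragment_charges = 1)
  call <- match_spectrum(full, cand, cfg)
  expect_true(call$accepted)
  expect_equal(call$n_branched_matched, sum(frags$branched))
  expect_equal(call$n_total_matched, nrow(frags))
  expect_gte(call$n_branched_matched, 4)

  # deleting all branched peaks removes the evidence entirely
  none <- noiseless_spectrum(pep, 5, charge = 2, fragment_charges = 1,
                             keep = which(!frags$branched))
  call0 <- match_spectrum(none, cand, cfg)
  expect_false(call0$accepted)
  expect_equal(call0$n_branched_matched, 0L)

  # exactly three surviving branched ions: rejected (3 < 4); four: accepted
  br <- which(frags$branched)
  s3 <- noiseless_spectrum(pep, 5, charge = 2, fragment_charges = 1,
                           keep = c(which(!frags$branched), br[1:3]))
  call3 <- match_spectrum(s3, cand, cfg)
  expect_equal(call3$n_branched_matched, 3L)
  expect_false(call3$accepted)
  s4 <- noiseless_spectrum(pep, 5, charge = 2, fragment_charges = 1,
                           keep = c(which(!frags$branched), br[1:4]))
  call4 <- match_spectrum(s4, cand, cfg)
  expect_equal(call4$n_branched_matched, 4L)
  expect_true(call4$accepted)
})

test_that("precursors outside tolerance skip the candidate", {
  pep <- "GASPKVLR"
  cand <- candidate_row(pep, site = 5L)
  cfg <- search_config(fragment_charges = 1, carbamidomethyl = FALSE)
  sp <- noiseless_spectrum(pep, 5, charge = 2, fragment_charges = 1)
  off <- ms2_spectrum("t2", sp$precursor_mz + 1.0, 2, 300, sp$peaks)
  expect_null(match_spectrum(off, cand, cfg))  # 2 Da neutral error > 1.6
})

test_that("greedy matching equals exhaustive assignment on small spectra", {
  cfg <- search_config(fragment_charges = 1, carbamidomethyl = FALSE)
  set.seed(29)
  for (i in 1:25) {
    pep <- random_protein_with_k(sample(5:10, 1))
    p <- pick(which(strsplit(pep, "")[[1]] == "K"))
    mods <- build_mods(pep, gg_sites = p)
    frags <- generate_fragments(pep, mods = mods, fragment_charges = 1)
    take <- sample(nrow(frags), min(nrow(frags), sample(4:9, 1)))
    peaks_mz <- c(frags$mz[take] + stats::runif(length(take), -0.3, 0.3),
                  stats::runif(2, 100, 1200))
    peaks_mz <- peaks_mz[seq_len(min(12, length(peaks_mz)))]
    sp <- ms2_spectrum("o1", mz(peptide_mass(pep, mods = mods), 2), 2, 0,
                       data.frame(mz = peaks_mz, intensity = 1))
    call <- match_spectrum(sp, candidate_row(pep, site = p), cfg)
    expect_equal(call$n_total_matched,
                 bf_max_matching(frags$mz, sp$peaks$mz, cfg$fragment_tol))
  }
})

test_that("acceptance is monotone in the branched-ion threshold", {
  pep <- "GAKSPKVLTWR"
  site <- 6L
  cand <- candidate_row(pep, site = site)
  mods <- build_mods(pep, gg_sites = site)
  frags <- generate_fragments(pep, mods = mods, fragment_charges = 1)
  br <- which(frags$branched)
  spectra <- lapply(2:7, function(nb) {
    noiseless_spectrum(pep, site, charge = 2, fragment_charges = 1,
                       keep = c(which(!frags$branched), br[seq_len(nb)]))
  })
  accepted_at <- vapply(1:8, function(thr) {
    cfg <- search_config(fragment_charges = 1, carbamidomethyl = FALSE,
                         min_branched_ions = thr)
    sum(vapply(spectra, function(s) match_spectrum(s, cand, cfg)$accepted,
               logical(1)))
  }, numeric(1))
  expect_true(all(diff(accepted_at) <= 0))
})

test_that("widening the fragment tolerance never loses matches", {
  set.seed(31)
  pep <- "GAKSPKVLTWRAK"
  site <- 6L
  cand <- candidate_row(pep, site = site)
  mods <- build_mods(pep, gg_sites = site)
  frags <- generate_fragments(pep, mods = mods, fragment_charges = c(1, 2))
  pmz <- mz(peptide_mass(pep, mods = mods), 2)
  for (i in 1:10) {
    sp <- ms2_spectrum("m1", pmz, 2, 0, data.frame(
      mz = frags$mz + stats::rnorm(nrow(frags), 0, 0.25),
      intensity = 1
    ))
    n_tot <- vapply(c(0.1, 0.3, 0.5, 0.8), function(tol) {
      cfg <- search_config(fragment_tol = tol, carbamidomethyl = FALSE)
      match_spectrum(sp, cand, cfg)$n_total_matched
    }, numeric(1))
    expect_true(all(diff(n_tot) >= 0))
  }
})

test_that("protein filter applies the two-peptide and score rules", {
  cfg <- search_config()
  call <- function(acc, pep, score) {
    data.frame(accession = acc, site = 1L, peptide = pep, start = 1L,
               charge = 2L, spectrum_id = paste0(acc, pep, score),
               n_branched_matched = 4L, n_total_matched = 8L,
               n_theoretical = 20L, peptide_score = score, accepted = TRUE,
               stringsAsFactors = FALSE)
  }
  # one passing peptide: rejected by the two-peptide rule
  one <- filter_proteins(call("P1", "AAK", 10), cfg)
  expect_false(one$accepted)
  # two peptides scoring 7 each: boundary acceptance (14 >= 14)
  two <- filter_proteins(rbind(call("P1", "AAK", 7), call("P1", "CCK", 7)), cfg)
  expect_true(two$accepted)
  expect_equal(two$protein_score, 14)
  # the score-2 peptide does not contribute
  three <- filter_proteins(rbind(call("P1", "AAK", 7), call("P1", "CCK", 7),
                                 call("P1", "DDK", 2)), cfg)
  expect_equal(three$distinct_peptides, 2L)
  expect_true(three$accepted)
})

test_that("the search is deterministic for identical inputs", {
  cfg <- sim_config(n_proteins = 4, n_planted_sites = 2, n_distractors = 3,
                    seed = 5)
  sim <- simulate_proteome(cfg)
  dat <- simulate_spectra(sim$proteins, sim$truth, cfg)
  r1 <- ggsite_search(sim$proteins, dat$spectra, dat$trace, search_config())
  r2 <- ggsite_search(sim$proteins, dat$spectra, dat$trace, search_config())
  expect_identical(r1$sites, r2$sites)
  expect_identical(r1$proteins, r2$proteins)
})
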