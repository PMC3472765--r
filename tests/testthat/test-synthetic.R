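test_that("proteome simulation is reproducible and plants sites on lysines", {
  cfg <- sim_config(seed = 2)
  a <- simulate_proteome(cfg)
  b <- simulate_proteome(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$proteins), 20L)
  expect_equal(nrow(a$truth), 10L)
  for (i in seq_len(nrow(a$truth))) {
    seq_i <- a$proteins$sequence[a$proteins$accession == a$truth$accession[i]]
    expect_identical(substr(seq_i, a$truth$site[i], a$truth$site[i]), "K")
  }
  lens <- nchar(a$proteins$sequence)
  expect_true(all(lens >= 200 & lens <= 400))

  none <- simulate_proteome(sim_config(n_planted_sites = 0, seed = 2))
  expect_equal(nrow(none$truth), 0L)
  expect_error(
    simulate_proteome(sim_config(n_proteins = 1,
                                 protein_length_range = c(20, 20),
                                 n_planted_sites = 50)),
    "lysines")
})

test_that("spectrum simulation is reproducible end to end", {
  cfg <- sim_config(n_proteins = 4, n_planted_sites = 2, n_distractors = 2,
                    noise_peaks_per_spectrum = 5, mass_jitter_sd = 0.05,
                    seed = 3)
  sim <- simulate_proteome(cfg)
  d1 <- simulate_spectra(sim$proteins, sim$truth, cfg)
  d2 <- simulate_spectra(sim$proteins, sim$truth, cfg)
  expect_identical(d1$trace, d2$trace)
  expect_identical(d1$spectra, d2$spectra)
  expect_identical(d1$provenance, d2$provenance)
  expect_true(all(c("site", "distractor") %in% d1$provenance$kind))
})

test_that("total fragment dropout leaves no acceptable evidence", {
  cfg <- sim_config(n_proteins = 4, n_planted_sites = 3, n_distractors = 0,
                    fragment_dropout_prob = 1, seed = 4)
  sim <- simulate_proteome(cfg)
  dat <- simulate_spectra(sim$proteins, sim$truth, cfg)
  res <- ggsite_search(sim$proteins, dat$spectra, dat$trace, search_config())
  expect_equal(sum(res$sites$accepted), 0L)
  sc <- score_recovery(res$sites, sim$truth)
  expect_equal(sc$recall, 0)
})

test_that("m/z jitter well inside the tolerances does not change recall", {
  base <- sim_config(n_proteins = 6, n_planted_sites = 4, n_distractors = 3,
                     seed = 1)
  jit <- sim_config(n_proteins = 6, n_planted_sites = 4, n_distractors = 3,
                    mass_jitter_sd = 0.1, seed = 1)
  sim <- simulate_proteome(base)
  d0 <- simulate_spectra(sim$proteins, sim$truth, base)
  r0 <- ggsite_search(sim$proteins, d0$spectra, d0$trace, search_config())
  d1 <- simulate_spectra(sim$proteins, sim$truth, jit)
  r1 <- ggsite_search(sim$proteins, d1$spectra, d1$trace, search_config())
  expect_equal(score_recovery(r1$sites, sim$truth)$recall,
               score_recovery(r0$sites, sim$truth)$recall)
})

test_that("acceptance degrades monotonically with fragment dropout", {
  pep <- "GAVLKSPTWRMK"
  site <- 5L
  cand <- candidate_row(pep, site = site)
  cfg <- search_config(carbamidomethyl = FALSE)
  mods <- build_mods(pep, gg_sites = site)
  frags <- generate_fragments(pep, mods = mods)
  pmz <- mz(peptide_mass(pep, mods = mods), 2)
  mean_accept <- vapply(c(0, 0.4, 0.7, 0.95), function(p) {
    acc <- vapply(1:20, function(s) {
      set.seed(s)
      keep <- stats::runif(nrow(frags)) >= p
      if (!any(keep)) return(FALSE)
      sp <- ms2_spectrum("d1", pmz, 2, 0,
                         data.frame(mz = frags$mz[keep], intensity = 1))
      match_spectrum(sp, cand, cfg)$accepted
    }, logical(1))
    mean(acc)
  }, numeric(1))
  expect_true(all(diff(mean_accept) <= 0))
})

test_that("recovery scoring follows the stated conventions", {
  calls <- data.frame(accession = c("A", "A", "B"), site = c(5L, 9L, 2L),
                      accepted = c(TRUE, TRUE, FALSE))
  truth <- data.frame(accession = c("A", "A"), site = c(5L, 9L))
  sc <- score_recovery(calls, truth)
  expect_equal(sc$recall, 1)
  expect_equal(sc$precision, 1)

  half <- score_recovery(calls[1, ], truth)
  expect_equal(half$recall, 0.5)
  expect_equal(half$precision, 1)

  none <- score_recovery(calls[calls$accepted == FALSE, , drop = FALSE], truth)
  expect_equal(none$recall, 0)
  expect_equal(none$precision, 1)  # undefined, reported as 1 by convention
  expect_true(attr(none, "no_calls"))
})
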