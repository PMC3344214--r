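test_that("the slippage walk honors its boundary and null cases", {
  set.seed(31)
  expect_equal(evolve_repeat(7, 500, 0), rep(7L, 501))
  traj <- evolve_repeat(1, 2000, 0.4)
  expect_true(all(traj >= 1L))
  expect_equal(traj[1], 1L)
  expect_true(all(abs(diff(traj)) <= 1L))
})

test_that("slippage moments match random-walk theory", {
  set.seed(32)
  steps <- 100L
  rate <- 0.01
  reps <- 10000L
  finals <- vapply(seq_len(reps), function(i) {
    tail(evolve_repeat(50L, steps, rate), 1L)
  }, integer(1))
  change <- finals - 50L
  theory_var <- 2 * rate * steps # each step is +/-1 w.p. `rate` each
  expect_lt(abs(mean(change)),
            2.58 * sqrt(theory_var / reps)) # 99% CI around zero drift
  expect_lt(abs(var(change) - theory_var), 0.15 * theory_var)
})

test_that("flank evolution is the identity at zero rates", {
  s <- random_dna(200)
  expect_equal(evolve_flank(s, 0, kappa = 2, indel_rate = 0), s)
})

test_that("realized Ts:Tv matches kappa:2 and K2P recovers the branch", {
  set.seed(33)
  L <- 10000L
  a <- random_dna(L)
  b <- evolve_flank(a, 0.05, kappa = 2, indel_rate = 0)
  s <- count_site_differences(a, b)
  ratio <- s$ts / s$tv
  expect_lt(abs(ratio - 1), 0.2) # kappa = 2 means Ts:Tv = 2:2
  k <- k2p_distance(s)
  expect_lt(abs(k$d - 0.05), 3 * k$se)

  b4 <- evolve_flank(a, 0.05, kappa = 4, indel_rate = 0)
  s4 <- count_site_differences(a, b4)
  expect_lt(abs(s4$ts / s4$tv - 2), 0.35) # kappa = 4 -> Ts:Tv = 2:1
})

test_that("indels change length by 1-2 nt per event, substitutions never do", {
  set.seed(34)
  s <- random_dna(500)
  no_indel <- evolve_flank(s, 0.1, kappa = 1.4, indel_rate = 0)
  expect_equal(nchar(no_indel), 500L)
  lens <- vapply(1:50, function(i) {
    nchar(evolve_flank(s, 0.02, kappa = 1.4, indel_rate = 1))
  }, integer(1))
  expect_true(any(lens != 500L))
})

test_that("a rate-free dataset is identical to its ancestors end to end", {
  cfg <- simulation_config(seed = 35, slip_rate = 0, allele_branch = 0,
                           flank_indel_rate = 0, interruption_rate = 0,
                           external = c(J = 0, A = 0, M = 0, B = 0),
                           internal = 0, allele_generations = 0)
  sim <- simulate_msat_dataset(cfg)
  expect_equal(nrow(sim$alleles), 274L)
  one <- sim$alleles[sim$alleles$locus == "AJ-1", ]
  expect_equal(length(unique(one$sequence)), 1L)
  rep <- run_msat_pipeline(sim$alleles, anguilla_locus_config())
  expect_true(rep$census$no_variation)
  expect_true(all(rep$distmat$d == 0))
})

test_that("simulation is deterministic given the seed", {
  s1 <- simulate_msat_dataset(simulation_config(seed = 36))
  s2 <- simulate_msat_dataset(simulation_config(seed = 36))
  expect_identical(s1$alleles, s2$alleles)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_sim_fasta(s1, d1)
  write_sim_fasta(s2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  s3 <- simulate_msat_dataset(simulation_config(seed = 37))
  expect_false(identical(s1$alleles$sequence, s3$alleles$sequence))
})

test_that("simulated major regions never contain partial-unit indels", {
  sim <- simulate_msat_dataset(simulation_config(seed = 38))
  expect_silent(validate_simulation(sim))
  lit_lens <- unlist(lapply(sim$truth$alleles$major, function(d) {
    nchar(d$value[d$type == "literal"])
  }))
  if (length(lit_lens) > 0) expect_true(all(lit_lens == 2L))
})

test_that("decomposition recovers the true repeat count of clean alleles", {
  sim <- simulate_msat_dataset(simulation_config(seed = 39))
  dec <- decompose_alleles(sim$alleles, anguilla_locus_config(),
                           on_error = "drop")
  tr <- sim$truth$alleles
  m <- dplyr::inner_join(
    dec, tr, by = c("id", "species", "locus"), suffix = c(".est", ".true"))
  loci <- anguilla_locus_config()
  m <- dplyr::left_join(m, loci[, c("locus", "motif")], by = "locus")
  # condition on: no interruption in truth, and flank bases next to the
  # tract free of motif duplets (otherwise the tract boundary is genuinely
  # ambiguous in the raw sequence)
  clean_boundary <- function(flank, motif, side) {
    rot <- paste0(substr(motif, 2, 2), substr(motif, 1, 1))
    win <- if (side == 5) substring(flank, nchar(flank) - 3L) else
      substring(flank, 1L, 4L)
    !grepl(motif, win, fixed = TRUE) && !grepl(rot, win, fixed = TRUE)
  }
  keep <- !m$interrupted &
    mapply(clean_boundary, m$flank5.true, m$motif, 5) &
    mapply(clean_boundary, m$flank3.true, m$motif, 3)
  expect_gt(sum(keep), 150)
  expect_equal(m$total_units.est[keep], m$total_units.true[keep])
})

test_that("default calibration lands in the expected divergence band", {
  # calibration is about expected values, so average the pairwise distances
  # over a few independent datasets before checking the band
  dsum <- NULL
  for (s in 40:42) {
    sim <- simulate_msat_dataset(simulation_config(seed = s))
    rep <- suppressWarnings(run_msat_pipeline(sim$alleles,
                                              anguilla_locus_config()))
    expect_true(all(rep$consensus$length >= 440 &
                      rep$consensus$length <= 490))
    sp <- sort(rep$distmat$taxa)
    d <- rep$distmat$d[sp, sp]
    dsum <- if (is.null(dsum)) d else dsum + d
  }
  ut <- (dsum / 3)[upper.tri(dsum)]
  expect_true(all(ut > 0.03 & ut < 0.07))
})
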