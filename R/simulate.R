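#' Simulation configuration
#'
#' Defaults describe a 4-species study: a known species tree whose unrooted
#' split pairs M with B (internal edge 0.006 substitutions/site, external
#' edges 0.020-0.028 so that pairwise flank divergences fall in the 0.04-0.06
#' band typical of congeneric fish), six dinucleotide loci with flanks
#' totalling 463 bp, allele sampling depths matching the bundled survey
#' table, stepwise (+/-1 unit) slippage in the repeat tract, transition-
#' biased point substitutions and rare 1-2 nt indels in the flanks, and
#' occasional single-unit interruptions inside the repeat.
#'
#' @param seed integer RNG seed.
#' @param species four species codes; the first two and last two form the
#'   cherries of the generating tree.
#' @param external named branch lengths (substitutions/site) per species.
#' @param internal internal branch length.
#' @param loci tibble with `locus`, `motif`, `ancestral_units`, `flank5_len`,
#'   `flank3_len`.
#' @param depths tibble with `locus`, `species`, `n_alleles`; defaults to
#'   the bundled survey counts.
#' @param slip_rate per-generation probability of a +1 (and of a -1) unit
#'   slippage event.
#' @param generations_per_branch generations corresponding to one unit of
#'   branch length (scales slippage on species branches).
#' @param allele_generations extra slippage generations per sampled allele
#'   (within-species star).
#' @param allele_branch within-species flank branch length per allele.
#' @param kappa transition/transversion rate ratio of the substitution
#'   process (expected realized Ts:Tv count ratio is `kappa:2`).
#' @param flank_indel_rate expected 1-2 nt indel events per site per unit
#'   branch length.
#' @param interruption_rate expected interrupting substitutions per repeat
#'   nucleotide per unit branch length.
#' @return a `msat_sim_config` list.
#' @export
simulation_config <- function(
    seed = 1L,
    species = c("J", "A", "M", "B"),
    external = c(J = 0.025, A = 0.028, M = 0.020, B = 0.024),
    internal = 0.006,
    loci = NULL,
    depths = NULL,
    slip_rate = 0.005,
    generations_per_branch = 20000,
    allele_generations = 400,
    allele_branch = 0.002,
    kappa = 1.4,
    flank_indel_rate = 0.3,
    interruption_rate = 0.05) {
  if (is.null(loci)) {
    loci <- tibble(
      locus = c("AJ-1", "AJ-8", "AJ-9", "AJMS-3", "AJMS-6", "AJMS-10"),
      motif = c("TG", "TG", "TG", "TG", "TG", "GA"),
      ancestral_units = c(9L, 16L, 14L, 9L, 14L, 15L),
      flank5_len = c(39L, 38L, 40L, 38L, 39L, 38L),
      flank3_len = c(39L, 37L, 40L, 38L, 39L, 38L)
    )
  }
  if (is.null(depths)) {
    tb <- anguilla_repeat_table()
    depths <- tibble(locus = tb$locus, species = tb$species_code,
                     n_alleles = tb$n_sequences)
  }
  if (slip_rate < 0 || slip_rate > 1) abort("slip_rate must be in [0, 1]")
  if (any(loci$ancestral_units < 1)) abort("ancestral_units must be >= 1")
  if (any(depths$n_alleles < 1)) abort("allele depths must be >= 1")
  structure(list(
    seed = as.integer(seed), species = species, external = external,
    internal = internal, loci = loci, depths = depths,
    slip_rate = slip_rate, generations_per_branch = generations_per_branch,
    allele_generations = allele_generations, allele_branch = allele_branch,
    kappa = kappa, flank_indel_rate = flank_indel_rate,
    interruption_rate = interruption_rate
  ), class = "msat_sim_config")
}

#' Stepwise-mutation random walk of a repeat count
#'
#' Symmetric single-unit slippage: each generation the count increases by 1
#' with probability `slip_rate`, decreases by 1 with probability `slip_rate`,
#' and is unchanged otherwise. The walk reflects at 1 (a downward step at
#' count 1 is rejected); whole units are the only change -- no partial-unit
#' indels exist in this model.
#'
#' @param count starting repeat number (>= 1).
#' @param steps number of generations.
#' @param slip_rate per-direction per-generation slippage probability.
#' @return integer trajectory of length `steps + 1` (including the start).
#' @export
evolve_repeat <- function(count, steps, slip_rate) {
  if (count < 1) abort("count must be >= 1")
  if (steps == 0) return(as.integer(count))
  delta <- sample(c(-1L, 0L, 1L), steps, replace = TRUE,
                  prob = c(slip_rate, 1 - 2 * slip_rate, slip_rate))
  traj <- count + cumsum(delta)
  if (min(traj) >= 1L) return(c(as.integer(count), traj))
  # rare: replay sequentially, rejecting steps below 1
  cur <- as.integer(count)
  out <- integer(steps + 1L)
  out[1] <- cur
  for (t in seq_len(steps)) {
    d <- delta[t]
    if (cur + d >= 1L) cur <- cur + d
    out[t + 1L] <- cur
  }
  out
}

# substitution partners under the K2P process
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")
TRANSVERSIONS_OF <- list(A = c("C", "T"), G = c("C", "T"),
                         C = c("A", "G"), T = c("A", "G"))

#' Evolve a flanking sequence along a branch
#'
#' Point substitutions follow a K2P process: per site the number of events
#' is Poisson with mean `branch_length`; each event is a transition with
#' probability `kappa / (kappa + 2)` and otherwise one of the two
#' transversions. Short indels (1-2 nt, insertion or deletion with equal
#' probability) occur as a Poisson number of events with mean
#' `length * branch_length * indel_rate`. Indels only ever touch the flank:
#' the repeat tract is evolved separately by [evolve_repeat()].
#'
#' @param seq A/C/G/T string.
#' @param branch_length expected substitutions per site.
#' @param kappa transition/transversion rate ratio.
#' @param indel_rate indel events per site per unit branch length.
#' @return the evolved DNA string.
#' @export
evolve_flank <- function(seq, branch_length, kappa = 1.4, indel_rate = 0) {
  if (nchar(seq) == 0) abort("empty sequence")
  if (branch_length == 0 && indel_rate == 0) return(seq)
  s <- chars(seq)
  n_events <- rpois(length(s), branch_length)
  p_ts <- kappa / (kappa + 2)
  for (i in which(n_events > 0)) {
    for (e in seq_len(n_events[i])) {
      if (runif(1) < p_ts) {
        s[i] <- TRANSITION_OF[[s[i]]]
      } else {
        s[i] <- sample(TRANSVERSIONS_OF[[s[i]]], 1L)
      }
    }
  }
  n_indel <- rpois(1, length(s) * branch_length * indel_rate)
  for (e in seq_len(n_indel)) {
    len <- sample(1:2, 1L)
    if (runif(1) < 0.5 && length(s) > len + 1) { # deletion
      pos <- sample.int(length(s) - len + 1L, 1L)
      s <- s[-(pos:(pos + len - 1L))]
    } else { # insertion
      pos <- sample.int(length(s) + 1L, 1L)
      ins <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      s <- append(s, ins, after = pos - 1L)
    }
  }
  str_from(s)
}

# interrupting substitution inside a decomposition: convert one interior
# unit of a >=3-unit run into a 2-nt literal with one substituted base
interrupt_decomp <- function(d, motif) {
  runs <- which(d$type == "run" & d$count >= 3L)
  if (length(runs) == 0) return(d)
  ri <- if (length(runs) == 1) runs else sample(runs, 1L, prob = d$count[runs])
  cnt <- d$count[ri]
  # interior unit, so the outer units of the run are preserved
  k <- if (cnt == 3L) 2L else sample(2:(cnt - 1L), 1L)
  unit <- chars(d$value[ri])
  pos <- sample(1:2, 1L)
  unit[pos] <- sample(setdiff(c("A", "C", "G", "T"), unit[pos]), 1L)
  lit <- str_from(unit)
  el <- tibble(
    type = c("run", "literal", "run"),
    value = c(d$value[ri], lit, d$value[ri]),
    count = c(k - 1L, NA_integer_, cnt - k)
  )
  parts <- list(d[seq_len(ri - 1L), c("type", "value", "count")],
                el,
                d[seq_len(nrow(d))[-seq_len(ri)], c("type", "value", "count")])
  new_decomposition(bind_rows(parts), attr(d, "locus_motif"))
}

# slippage applied to the longest run of a decomposition
slip_decomp <- function(d, generations, slip_rate) {
  if (generations == 0 || slip_rate == 0) return(d)
  runs <- which(d$type == "run")
  ri <- runs[which.max(d$count[runs])]
  traj <- evolve_repeat(d$count[ri], generations, slip_rate)
  d$count[ri] <- tail(traj, 1L)
  new_decomposition(d[, c("type", "value", "count")], attr(d, "locus_motif"))
}

# evolve one lineage state (flanks + decomposition) along a branch
evolve_lineage <- function(state, branch, cfg) {
  gens <- round(branch * cfg$generations_per_branch)
  d <- slip_decomp(state$major, gens, cfg$slip_rate)
  n_int <- rpois(1, branch * cfg$interruption_rate *
                   nchar(expand_decomposition(d)))
  for (k in seq_len(n_int)) d <- interrupt_decomp(d, attr(d, "locus_motif"))
  list(
    flank5 = evolve_flank(state$flank5, branch, cfg$kappa,
                          cfg$flank_indel_rate),
    major = d,
    flank3 = evolve_flank(state$flank3, branch, cfg$kappa,
                          cfg$flank_indel_rate)
  )
}

# random ancestral flank whose 4 bases nearest the repeat tract avoid the
# motif duplets, so the ancestral tract boundary is unambiguous
ancestral_flank <- function(len, side) {
  guard <- if (side == 5) "ACCC" else "CCCA"
  core <- str_from(sample(c("A", "C", "G", "T"), len - 4L, replace = TRUE))
  if (side == 5) paste0(core, guard) else paste0(guard, core)
}

#' Simulate a full multi-locus allele dataset
#'
#' Forward simulation of cloned microsatellite alleles for four species
#' related by a known tree: the ancestral allele of each locus is evolved
#' down the species tree (substitutions and short indels in the flanks,
#' stepwise slippage and occasional interrupting substitutions in the repeat
#' tract), then each species' allele pool is drawn as a star of short
#' within-species branches. Deterministic given `cfg$seed`.
#'
#' @param cfg a [simulation_config()].
#' @return an `msat_sim` list: `alleles` (tibble `id`, `species`, `locus`,
#'   `sequence`), `truth` (generating split, ancestral states, and the true
#'   per-allele decomposition/flanks), `config`.
#' @export
simulate_msat_dataset <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  sp <- cfg$species
  cherries <- list(sp[1:2], sp[3:4])

  alleles <- list()
  truth_rows <- list()
  anc <- list()

  for (li in seq_len(nrow(cfg$loci))) {
    lc <- cfg$loci[li, ]
    root <- list(
      flank5 = ancestral_flank(lc$flank5_len, 5),
      major = new_decomposition(
        tibble(type = "run", value = lc$motif, count = lc$ancestral_units),
        lc$motif),
      flank3 = ancestral_flank(lc$flank3_len, 3)
    )
    anc[[lc$locus]] <- root
    # two cherry ancestors, half the internal edge each
    mid <- lapply(cherries, function(ch) {
      evolve_lineage(root, cfg$internal / 2, cfg)
    })
    for (ci in 1:2) {
      for (s in cherries[[ci]]) {
        tip <- evolve_lineage(mid[[ci]], cfg$external[[s]], cfg)
        nall <- cfg$depths$n_alleles[cfg$depths$locus == lc$locus &
                                       cfg$depths$species == s]
        if (length(nall) != 1) {
          abort(paste0("no allele depth configured for ", s, " at ",
                       lc$locus))
        }
        for (ai in seq_len(nall)) {
          al <- list(
            flank5 = evolve_flank(tip$flank5, cfg$allele_branch, cfg$kappa,
                                  cfg$flank_indel_rate),
            major = slip_decomp(tip$major, cfg$allele_generations,
                                cfg$slip_rate),
            flank3 = evolve_flank(tip$flank3, cfg$allele_branch, cfg$kappa,
                                  cfg$flank_indel_rate)
          )
          n_int <- rpois(1, cfg$allele_branch * cfg$interruption_rate *
                           nchar(expand_decomposition(al$major)))
          for (k in seq_len(n_int)) {
            al$major <- interrupt_decomp(al$major, lc$motif)
          }
          id <- paste0(s, sprintf("%02d", ai))
          alleles[[length(alleles) + 1L]] <- tibble(
            id = id, species = s, locus = lc$locus,
            sequence = paste0(al$flank5, expand_decomposition(al$major),
                              al$flank3)
          )
          truth_rows[[length(truth_rows) + 1L]] <- tibble(
            id = id, species = s, locus = lc$locus,
            flank5 = al$flank5, flank3 = al$flank3,
            notation = serialize_decomposition(al$major),
            major = list(al$major),
            total_units = sum(al$major$count[al$major$type == "run"]),
            interrupted = any(al$major$type == "literal") ||
              sum(al$major$type == "run") > 1L
          )
        }
      }
    }
  }

  tips <- sort(sp)
  side <- sort(cherries[[2]])
  if (tips[1] %in% side) side <- sort(cherries[[1]])
  sim <- list(
    alleles = bind_rows(alleles),
    truth = list(
      split = paste(side, collapse = ","),
      cherries = cherries,
      ancestors = anc,
      alleles = bind_rows(truth_rows)
    ),
    config = cfg
  )
  class(sim) <- "msat_sim"
  validate_simulation(sim)
  sim
}

#' Validate structural invariants of a simulated dataset
#'
#' Checks that every emitted allele equals `flank5 + expanded major + flank3`
#' of its truth record and that no interruption inside a repeat tract is a
#' single-nucleotide indel: every truth-record literal has length 2 and every
#' run contributes whole units, so the major-region length parity is fixed by
#' its literals.
#'
#' @param sim an `msat_sim`.
#' @return `sim`, invisibly; errors on violation.
#' @export
validate_simulation <- function(sim) {
  tr <- sim$truth$alleles
  rebuilt <- paste0(tr$flank5, map_chr(tr$major, expand_decomposition),
                    tr$flank3)
  if (!identical(rebuilt, sim$alleles$sequence)) {
    abort("simulated allele does not match its truth decomposition")
  }
  bad <- map_lgl(tr$major, function(d) {
    any(d$type == "literal" & nchar(d$value) %% 2L != 0L)
  })
  if (any(bad)) {
    abort("single-nucleotide indel found inside a simulated major region")
  }
  invisible(sim)
}

#' Write a simulated dataset to disk
#'
#' One FASTA per locus, a truth TSV, and a seed log -- the on-disk form of
#' an `msat_sim`.
#'
#' @param sim an `msat_sim`.
#' @param dir output directory (created if needed).
#' @param delim FASTA header delimiter.
#' @return `dir`, invisibly.
#' @export
write_sim_fasta <- function(sim, dir, delim = "|") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lc in unique(sim$alleles$locus)) {
    write_fasta(sim$alleles[sim$alleles$locus == lc, , drop = FALSE],
                file.path(dir, paste0(lc, ".fasta")), delim = delim)
  }
  tr <- sim$truth$alleles
  utils::write.table(
    tr[, c("id", "species", "locus", "notation", "total_units",
           "interrupted")],
    file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(paste0("seed\t", sim$config$seed),
               paste0("split\t", sim$truth$split)),
             file.path(dir, "seed_log.tsv"))
  invisible(dir)
}
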