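# shared fixtures, built in code

# flanks free of TG/GT (and GA/AG) duplets so tract boundaries are exact
GUARD5 <- "CACCATCCTACCTCCACC"
GUARD3 <- "CCACCTTCCATCCTCACC"

# one synthetic raw allele around a decomposition
raw_allele <- function(d, flank5 = GUARD5, flank3 = GUARD3) {
  paste0(flank5, expand_decomposition(d), flank3)
}

# survey table expanded to one row per denoted allele
table1_alleles <- function(list_mode = "auto") {
  parse_repeat_table(anguilla_repeat_table(), anguilla_locus_config(),
                     list_mode = list_mode)
}

# a per-locus FASTA-style allele tibble matching the survey's per-species
# sequence counts: denoted alleles recycled up to each row's n_sequences
survey_locus_fixture <- function(locus) {
  tb <- anguilla_repeat_table()
  tb <- tb[tb$locus == locus, , drop = FALSE]
  loci <- anguilla_locus_config()
  parsed <- parse_repeat_table(tb, loci)
  out <- list()
  for (r in seq_len(nrow(tb))) {
    ds <- parsed$decomp[parsed$species == tb$species[r]]
    idx <- rep_len(seq_along(ds), tb$n_sequences[r])
    for (k in seq_along(idx)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        id = paste0(tb$species_code[r], k),
        species = tb$species_code[r],
        locus = locus,
        sequence = raw_allele(ds[[idx[k]]])
      )
    }
  }
  dplyr::bind_rows(out)
}

# published pairwise K2P distances as a symmetric matrix over species codes
table2_distmat <- function() {
  dt <- anguilla_distance_table()
  sp <- sort(unique(c(dt$code_a, dt$code_b)))
  D <- matrix(0, length(sp), length(sp), dimnames = list(sp, sp))
  for (r in seq_len(nrow(dt))) {
    D[dt$code_a[r], dt$code_b[r]] <- dt$k2p[r]
    D[dt$code_b[r], dt$code_a[r]] <- dt$k2p[r]
  }
  D
}

# exhaustive global-alignment score by enumeration (oracle for short pairs)
brute_force_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      s <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + s)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(nchar(a), nchar(b))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# additive distance matrix from a random unrooted tree with known topology
random_additive <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, rooted = FALSE, br = function(n) runif(n, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}
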