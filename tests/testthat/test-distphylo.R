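test_that("site differences classify all twelve mismatch types", {
  expect_equal(count_site_differences("ACGT", "ACGT"),
               tibble::tibble(ts = 0L, tv = 0L, gap_excluded = 0L,
                              compared = 4L))
  s <- count_site_differences("AG", "GC")
  expect_equal(s$ts, 1L) # A<->G
  expect_equal(s$tv, 1L) # G<->C
  # hand classification: transitions are A/G and C/T, everything else is Tv
  pairs <- expand.grid(a = c("A", "C", "G", "T"), b = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$a != pairs$b, ]
  is_ts <- with(pairs, paste0(pmin(a, b), pmax(a, b)) %in% c("AG", "CT"))
  for (k in seq_len(nrow(pairs))) {
    s1 <- count_site_differences(pairs$a[k], pairs$b[k])
    expect_equal(c(s1$ts, s1$tv),
                 if (is_ts[k]) c(1L, 0L) else c(0L, 1L),
                 label = paste(pairs$a[k], pairs$b[k]))
  }
})

test_that("gaps and ambiguity codes are excluded pairwise", {
  s <- count_site_differences("A-CT", "AGCT")
  expect_equal(s$compared, 3L)
  expect_equal(s$ts + s$tv, 0L)
  s2 <- count_site_differences("AKCT", "ATCT")
  expect_equal(s2$compared, 3L)
  expect_equal(s2$gap_excluded, 1L)
  expect_error(count_site_differences("ACG", "AC"), "length")
})

test_that("K2P evaluates its closed form and flags saturation", {
  expect_equal(k2p_distance(0, 0, 100)$d, 0)
  k <- k2p_distance(8, 12, 469)
  expect_equal(round(k$d, 3), 0.044)
  expect_equal(round(k$se, 3), 0.010)
  expect_error(k2p_distance(200, 200, 400), "saturation")
  expect_error(k2p_distance(0, 0, 0), "no compared sites")
})

test_that("K2P dominates the p-distance and is monotone on a grid", {
  L <- 1000L
  for (ts in c(0L, 5L, 20L, 60L)) {
    for (tv in c(0L, 5L, 20L, 60L)) {
      d <- k2p_distance(ts, tv, L)$d
      expect_gte(d, (ts + tv) / L - 1e-12)
      if (ts + tv > 0) expect_gt(d, 0) else expect_equal(d, 0)
      expect_gte(k2p_distance(ts + 1L, tv, L)$d, d)
      expect_gte(k2p_distance(ts, tv + 1L, L)$d, d)
    }
  }
})

test_that("K2P reduces to Jukes-Cantor under equal-rate proportions", {
  for (p in c(0.01, 0.05, 0.1, 0.2)) {
    d <- k2p_distance(round(1e6 * p / 3), round(1e6 * 2 * p / 3), 1e6)$d
    jc <- -0.75 * log(1 - 4 * p / 3)
    expect_equal(d, jc, tolerance = 1e-4)
  }
})

test_that("K2P agrees with an established implementation", {
  set.seed(21)
  for (k in 1:5) {
    a <- random_dna(500)
    b <- strsplit(a, "")[[1]]
    pos <- sample(500, 30)
    b[pos] <- vapply(b[pos], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1)
    }, character(1))
    b <- paste(b, collapse = "")
    bin <- ape::as.DNAbin(rbind(x = strsplit(tolower(a), "")[[1]],
                                y = strsplit(tolower(b), "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "K80"))
    mine <- k2p_distance(count_site_differences(a, b))$d
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("the distance matrix is symmetric and internally consistent", {
  aln <- tibble::tibble(
    species = c("J", "M", "A", "B"),
    aligned = c("ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC", "ACGTACGTAC"))
  dm0 <- build_distance_matrix(aln)
  expect_true(all(dm0$d == 0))

  set.seed(22)
  sim <- simulate_msat_dataset(simulation_config(seed = 22))
  rep <- suppressWarnings(run_msat_pipeline(sim$alleles,
                                            anguilla_locus_config()))
  dm <- rep$distmat
  expect_equal(dm$d, t(dm$d))
  expect_true(all(diag(dm$d) == 0))
  for (i in 1:3) {
    for (j in (i + 1):4) {
      s <- count_site_differences(rep$alignment$aligned[i],
                                  rep$alignment$aligned[j])
      expect_equal(dm$differences[i, j], s$ts + s$tv)
      expect_equal(dm$ts[i, j], s$ts)
    }
  }
  expect_error(build_distance_matrix(aln[1:2, ]), "three taxa")
})

test_that("three-taxon NJ matches the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
})

test_that("NJ recovers random additive matrices exactly", {
  set.seed(23)
  for (ntaxa in c(4, 5, 6, 8)) {
    for (k in 1:5) {
      ad <- random_additive(ntaxa)
      est <- neighbor_joining(ad$D)
      expect_equal(compare_splits(est, ad$tree)$rf, 0L)
      # path lengths of the estimated tree reproduce the input matrix
      pl <- ape::cophenetic.phylo(est)
      expect_equal(pl[rownames(ad$D), colnames(ad$D)], ad$D,
                   tolerance = 1e-9)
      # cross-check against the reference NJ implementation
      ref <- ape::nj(as.dist(ad$D))
      expect_equal(compare_splits(est, ref)$rf, 0L)
    }
  }
})

test_that("four-taxon NJ always has exactly one internal edge", {
  set.seed(24)
  for (k in 1:10) {
    D <- as.matrix(dist(matrix(runif(8), 4)))
    dimnames(D) <- list(letters[1:4], letters[1:4])
    tr <- neighbor_joining(D)
    expect_equal(tr$Nnode, 2L)
    expect_length(tree_splits(tr), 1L)
  }
})

test_that("split comparison matches exhaustive split sets", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(compare_splits(t1, t1)$rf, 0L)
  expect_equal(compare_splits(t1, t2)$rf, 2L)
  set.seed(25)
  for (k in 1:10) {
    a <- ape::rtree(6, rooted = FALSE)
    b <- ape::rtree(6, rooted = FALSE)
    expect_equal(compare_splits(a, b)$rf,
                 as.integer(phangorn::RF.dist(a, b)))
  }
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(compare_splits(t1, t3), "leaf sets")
})

test_that("unanimous signal bootstraps to 100 and seeds reproduce", {
  # every variable column supports the same split {J,M} | {A,B}
  rows <- c(J = paste0(strrep("A", 30), strrep("C", 10)),
            M = paste0(strrep("A", 30), strrep("C", 10)),
            A = strrep("A", 40),
            B = strrep("A", 40))
  aln <- tibble::tibble(species = names(rows), aligned = unname(rows))
  tr <- bootstrap_support(aln, n_reps = 100, seed = 5)
  sup <- attr(tr, "support")
  expect_equal(unname(sup), 100)
  tr2 <- bootstrap_support(aln, n_reps = 100, seed = 5)
  expect_equal(attr(tr2, "support"), sup)
  expect_error(bootstrap_support(aln, n_reps = 100), "seed")
})

test_that("bootstrap supports match an independent oracle on mixed signal", {
  # gap- and ambiguity-free alignment with conflicting signal so both
  # implementations see exactly the same columns
  set.seed(26)
  L <- 200L
  base <- random_dna(L)
  ch <- matrix(rep(strsplit(base, "")[[1]], 4), nrow = 4, byrow = TRUE,
               dimnames = list(c("J", "M", "A", "B"), NULL))
  put <- function(cols, pattern) {
    for (j in cols) ch[, j] <<- pattern
  }
  put(1:6, c("G", "G", "T", "T"))     # supports {J,M}
  put(7:8, c("G", "T", "G", "T"))     # supports {J,A}
  put(9:10, c("G", "T", "T", "G"))    # supports {J,B}
  put(11:14, c("C", "A", "A", "A"))   # singletons
  aln <- tibble::tibble(species = rownames(ch),
                        aligned = apply(ch, 1, paste, collapse = ""))
  tr <- bootstrap_support(aln, n_reps = 2000, seed = 99)
  sup <- attr(tr, "support")
  split <- tree_splits(tr)[1]

  # independent resampling oracle built on ape's K80 distances and NJ
  chl <- matrix(tolower(ch), nrow = 4,
                dimnames = list(rownames(ch), NULL))
  hits <- 0L
  reps <- 2000L
  for (r in seq_len(reps)) {
    idx <- sample.int(ncol(chl), ncol(chl), replace = TRUE)
    bin <- ape::as.DNAbin(chl[, idx])
    d <- ape::dist.dna(bin, model = "K80")
    bt <- ape::nj(d)
    if (split %in% tree_splits(bt)) hits <- hits + 1L
  }
  oracle <- 100 * hits / reps
  expect_lt(abs(sup[[split]] - oracle), 3)
})

test_that("bootstrap supports are invariant to taxon input order", {
  set.seed(27)
  sim <- simulate_msat_dataset(simulation_config(seed = 27))
  rep <- suppressWarnings(run_msat_pipeline(sim$alleles,
                                            anguilla_locus_config()))
  aln <- rep$alignment
  tr1 <- bootstrap_support(aln, n_reps = 150, seed = 3)
  aln2 <- aln[c(3, 1, 4, 2), ]
  tr2 <- bootstrap_support(aln2, n_reps = 150, seed = 3)
  s1 <- attr(tr1, "support")
  s2 <- attr(tr2, "support")
  expect_equal(s2[names(s1)], s1)
})
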