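test_that("notation parsing matches the printed dialect", {
  d <- parse_repeat_notation("(TG)_8AG(TG)_10", "TG")
  expect_length(d, 1)
  expect_equal(serialize_decomposition(d[[1]]), "(TG)_8AG(TG)_10")
  expect_equal(nchar(expand_decomposition(d[[1]])), 38L)

  expect_length(parse_repeat_notation("(TG)_7~9", "TG"), 3)
  expect_length(parse_repeat_notation("(TG)_1", "TG"), 1)

  d06 <- parse_repeat_notation("(TG)_12~18TA(TG)_0, 2", "TG")
  expect_length(d06, 14)
  zero_variants <- Filter(function(x) nrow(x) == 2, d06)
  expect_true(all(vapply(zero_variants, function(x) {
    x$type[2] == "literal" && x$value[2] == "TA"
  }, logical(1))))
})

test_that("paired vs cartesian list semantics", {
  paired <- parse_repeat_notation("(TG)_3, 8CG(TG)_1, 4", "TG")
  expect_equal(sort(vapply(paired, serialize_decomposition, character(1))),
               c("(TG)_3CG(TG)_1", "(TG)_8CG(TG)_4"))
  crossed <- parse_repeat_notation("(TG)_3, 8CG(TG)_1, 4", "TG",
                                   list_mode = "cartesian")
  expect_length(crossed, 4)
  # unequal list lengths always cross (with scalars broadcast)
  expect_length(parse_repeat_notation("(TG)_10, 19, 21AG(TG)_4", "TG"), 3)
  expect_length(
    parse_repeat_notation("(TG)_9, 10, 13, 14(AG)_1, 2(TG)_9~12", "TG"), 32)
})

test_that("parse errors carry a position", {
  expect_error(parse_repeat_notation("(TG_8", "TG"), "position")
  expect_error(parse_repeat_notation("(TG)_x", "TG"), "position")
  expect_error(parse_repeat_notation("(TGA)_2", "TG"), "dinucleotide")
  expect_error(parse_repeat_notation("", "TG"), "empty")
})

test_that("expansion concatenates runs and literals", {
  expect_equal(expand_decomposition(parse_repeat_notation("(TG)_2", "TG")[[1]]),
               "TGTG")
  tc <- parse_repeat_notation("TC(TG)_6", "TG")[[1]]
  expect_equal(expand_decomposition(tc), "TCTGTGTGTGTGTG")
  expect_equal(nchar(expand_decomposition(
    parse_repeat_notation("(GA)_9AT(GA)_9", "GA")[[1]])), 38L)
})

test_that("serialize/parse is idempotent over the whole survey table", {
  alleles <- table1_alleles()
  expect_gt(nrow(alleles), 24)
  loci <- anguilla_locus_config()
  for (i in seq_len(nrow(alleles))) {
    motif <- loci$motif[loci$locus == alleles$locus[i]]
    re <- parse_repeat_notation(alleles$notation[i], motif)
    expect_length(re, 1)
    expect_equal(serialize_decomposition(re[[1]]), alleles$notation[i])
  }
})

test_that("nucleotide length parity follows total literal length", {
  for (d in table1_alleles()$decomp) {
    lit <- sum(nchar(d$value[d$type == "literal"]))
    expect_equal(nchar(expand_decomposition(d)) %% 2L, lit %% 2L)
  }
})

test_that("major-region detection recovers embedded decompositions", {
  x <- decompose_major_region(paste0("AAAC", strrep("TG", 8), "GGAT"), "TG")
  expect_equal(x$flank5, "AAAC")
  expect_equal(x$flank3, "GGAT")
  expect_equal(serialize_decomposition(x$major), "(TG)_8")
  expect_equal(c(x$start, x$end), c(5L, 20L))

  d <- parse_repeat_notation("(TG)_8AG(TG)_10", "TG")[[1]]
  y <- decompose_major_region(paste0("CC", expand_decomposition(d), "AA"), "TG")
  expect_equal(serialize_decomposition(y$major), "(TG)_8AG(TG)_10")

  expect_error(decompose_major_region("ACACACAAAA", "TG"), "no major region")
})

test_that("expand/decompose round-trips every eligible survey decomposition", {
  loci <- anguilla_locus_config()
  alleles <- table1_alleles()
  eligible <- 0L
  for (i in seq_len(nrow(alleles))) {
    d <- alleles$decomp[[i]]
    first <- d[1, ]
    last <- d[nrow(d), ]
    if (first$type != "run" || first$count < 3L) next
    if (last$type != "run" || last$count < 3L) next
    eligible <- eligible + 1L
    motif <- loci$motif[loci$locus == alleles$locus[i]]
    got <- decompose_major_region(raw_allele(d), motif)
    expect_equal(serialize_decomposition(got$major),
                 serialize_decomposition(d),
                 label = paste("round trip of", alleles$notation[i]))
    expect_equal(got$flank5, GUARD5)
    expect_equal(got$flank3, GUARD3)
  }
  expect_gt(eligible, 100) # the survey denotes many such alleles
})

test_that("classification distinguishes perfect/interrupted/compound", {
  p <- parse_repeat_notation("(TG)_14", "TG")[[1]]
  expect_equal(classify_decomposition(p), "perfect")
  i <- parse_repeat_notation("(TG)_6(TA)(TG)_11", "TG")[[1]]
  expect_equal(classify_decomposition(i), "interrupted")
  cmp <- new_decomposition(
    tibble::tibble(type = c("run", "run"), value = c("CA", "TG"),
                   count = c(5L, 7L)), "TG")
  expect_equal(classify_decomposition(cmp), "compound")
})

test_that("classification is invariant under element reversal", {
  for (d in table1_alleles()$decomp) {
    rev_d <- new_decomposition(d[rev(seq_len(nrow(d))), c("type", "value", "count")],
                               attr(d, "locus_motif"))
    expect_equal(classify_decomposition(rev_d), classify_decomposition(d))
  }
})

test_that("locus tabulation reports counts, ranges and histograms", {
  df <- survey_locus_fixture("AJ-1")
  dec <- decompose_alleles(df, anguilla_locus_config())
  expect_equal(nrow(dec), 49L)
  tab <- tabulate_locus(dec)
  expect_equal(sum(tab$n_alleles), 49L)
  japonica <- tab[tab$species == "J", ]
  expect_equal(max(japonica$perfect_counts[[1]]), 13L)
  expect_equal(range(unlist(tab$perfect_counts)), c(5L, 13L))
  expect_error(tabulate_locus(dec[0, ]), "empty")
  dec2 <- dec
  dec2$locus[1] <- "other"
  expect_error(tabulate_locus(dec2), "single locus")
})

test_that("decompose_alleles can account for undetectable alleles", {
  df <- survey_locus_fixture("AJ-1")[1:3, ]
  df$sequence[2] <- "ACACACACAAAAACCCGG"
  expect_error(decompose_alleles(df, anguilla_locus_config()),
               "no major region")
  dropped <- decompose_alleles(df, anguilla_locus_config(), on_error = "drop")
  expect_equal(nrow(dropped), 2L)
  failed <- attr(dropped, "failed")
  expect_equal(failed$id, df$id[2])
  expect_match(failed$reason, "no major region")
})
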