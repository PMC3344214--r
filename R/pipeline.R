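#' Read every per-locus FASTA in a directory
#'
#' @param dir directory containing `<locus>.fasta` files.
#' @param delim header delimiter (see [read_fasta()]).
#' @return tibble with `id`, `species`, `locus`, `sequence`.
#' @export
read_allele_dir <- function(dir, delim = "|") {
  files <- list.files(dir, pattern = "\\.fa(sta)?$", full.names = TRUE)
  if (length(files) == 0) abort(paste0("no FASTA files in ", dir))
  bind_rows(lapply(files, read_fasta, delim = delim))
}

#' Run the full flanking-region phylogenetics pipeline
#'
#' Stages, in order: major-region decomposition and classification of every
#' allele; per-locus survey tables; per-species, per-locus flank alignment
#' and IUPAC consensus; cross-locus concatenation; cross-species alignment
#' of the concatenated consensus; variable-site census; pairwise Ts/Tv
#' counts and K2P distances; Neighbor-joining tree, with bootstrap supports
#' when `n_boot > 0`. All randomness lives in the bootstrap and is governed
#' by `seed`.
#'
#' @param alleles tibble with `id`, `species`, `locus`, `sequence` (from
#'   [read_allele_dir()] or [simulate_msat_dataset()]`$alleles`).
#' @param loci locus configuration (see [read_locus_config()]); its row
#'   order fixes the concatenation order.
#' @param match,mismatch,gap alignment scores.
#' @param ambiguity_threshold consensus threshold (see [build_consensus()]).
#' @param n_boot bootstrap replicates (0 = no bootstrap).
#' @param seed RNG seed; required when `n_boot > 0`.
#' @return an `msat_report` list: `alleles` (decomposed), `locus_summary`,
#'   `consensus`, `alignment`, `census`, `distmat`, `tree`, `log`.
#' @export
run_msat_pipeline <- function(alleles, loci,
                              match = 1, mismatch = -1, gap = -2,
                              ambiguity_threshold = NULL,
                              n_boot = 0L, seed = NULL) {
  if (length(unique(alleles$species)) < 3) {
    abort("pipeline needs at least three species")
  }
  if (n_boot > 0 && is.null(seed)) {
    abort("a seed is required when bootstrapping")
  }
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1L]] <<- tibble(stage = stage, records_in = n_in,
                                       records_out = n_out)
  }

  dec <- decompose_alleles(alleles, loci, on_error = "drop")
  failed <- attr(dec, "failed")
  note("decompose", nrow(alleles), nrow(dec))
  if (nrow(failed) > 0) {
    warn(paste0(nrow(failed), " allele(s) without a detectable major ",
                "region dropped (listed in the report's `failed` table)"))
  }

  locus_summary <- dec |>
    dplyr::group_split(.data$locus) |>
    map(tabulate_locus) |>
    bind_rows()
  note("tabulate", nrow(dec), nrow(locus_summary))

  groups <- dec |>
    dplyr::group_split(.data$species, .data$locus)
  per_locus <- map(groups, function(g) {
    cons <- build_consensus(
      align_flanks(g, match, mismatch, gap),
      ambiguity_threshold = ambiguity_threshold)
    tibble(species = g$species[1], locus = g$locus[1],
           sequence = cons$sequence, length = cons$length,
           dropped_columns = cons$dropped_columns)
  }) |> bind_rows()
  note("consensus", nrow(dec), nrow(per_locus))

  concat <- per_locus |>
    dplyr::group_split(.data$species) |>
    map(function(g) {
      cc <- concatenate_consensus(g, locus_order = loci$locus)
      tibble(species = cc$species, sequence = cc$sequence,
             length = cc$length, junctions = list(cc$junctions))
    }) |> bind_rows() |>
    arrange(.data$species)
  note("concatenate", nrow(per_locus), nrow(concat))

  aln <- align_species_consensus(concat, match, mismatch, gap)
  census <- census_variation(aln)
  note("census", nrow(concat), 1L)

  distmat <- build_distance_matrix(aln)
  tree <- if (n_boot > 0) {
    bootstrap_support(aln, n_reps = n_boot, seed = seed)
  } else {
    neighbor_joining(distmat)
  }
  note("tree", length(distmat$taxa), length(tree$tip.label))

  structure(list(
    alleles = dec,
    failed = failed,
    locus_summary = locus_summary,
    consensus_per_locus = per_locus,
    consensus = concat,
    alignment = aln,
    census = census,
    distmat = distmat,
    tree = tree,
    log = bind_rows(log),
    params = list(match = match, mismatch = mismatch, gap = gap,
                  ambiguity_threshold = ambiguity_threshold,
                  n_boot = n_boot, seed = seed)
  ), class = "msat_report")
}

#' @export
print.msat_report <- function(x, ...) {
  cat("msat_report:", nrow(x$alleles), "alleles,",
      length(unique(x$alleles$locus)), "loci,",
      length(unique(x$alleles$species)), "species\n")
  cat("consensus lengths:",
      paste0(x$consensus$species, "=", x$consensus$length, collapse = ", "),
      "\n")
  cat("variable sites:", x$census$variable_sites,
      sprintf("(%.2f%% substitutions / %.2f%% indels)\n",
              x$census$pct_substitution, x$census$pct_indel))
  cat("K2P range:", sprintf("%.3f-%.3f",
                            min(x$distmat$d[upper.tri(x$distmat$d)]),
                            max(x$distmat$d[upper.tri(x$distmat$d)])), "\n")
  cat("NJ tree:", ape::write.tree(x$tree), "\n")
  invisible(x)
}

#' Distance/difference table in survey style
#'
#' K2P distances (rounded to `digits`) above the diagonal, integer
#' site-difference counts below.
#'
#' @param dm an `msat_distmat`.
#' @param digits decimals for distances (default 3).
#' @return a data.frame with taxa as row and column names.
#' @export
format_distance_table <- function(dm, digits = 3L) {
  n <- length(dm$taxa)
  out <- matrix("", n, n, dimnames = list(dm$taxa, dm$taxa))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) out[i, j] <- formatC(dm$d[i, j], digits = digits,
                                      format = "f")
      if (i > j) out[i, j] <- as.character(dm$differences[i, j])
      if (i == j) out[i, j] <- "-"
    }
  }
  as.data.frame(out)
}

# atomic write: to a temp file in the same directory, then rename
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path))
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Write pipeline report files
#'
#' Emits the per-locus summary, the distance/difference table, the census,
#' the cross-species alignment (aligned FASTA), the Newick tree and the
#' stage log into `dir`. Files are written atomically.
#'
#' @param report an `msat_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write_atomic(function(p) {
      utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, file.path(dir, name))
  }
  ls <- report$locus_summary
  ls$perfect_counts <- map_chr(ls$perfect_counts, paste, collapse = ",")
  ls$length_histogram <- map_chr(ls$length_histogram, function(h) {
    paste(names(h), unname(h), sep = ":", collapse = ",")
  })
  tsv(ls, "locus_summary.tsv")
  dt <- format_distance_table(report$distmat)
  write_atomic(function(p) {
    utils::write.table(cbind(taxon = rownames(dt), dt), p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }, file.path(dir, "distance_table.tsv"))
  tsv(report$census, "census.tsv")
  tsv(report$log, "stage_log.tsv")
  write_atomic(function(p) {
    df <- tibble(id = report$alignment$species,
                 species = report$alignment$species,
                 locus = "concat", sequence = report$alignment$aligned)
    write_fasta(df, p)
  }, file.path(dir, "consensus_alignment.fasta"))
  write_atomic(function(p) write_newick(report$tree, p),
               file.path(dir, "nj_tree.nwk"))
  invisible(dir)
}
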