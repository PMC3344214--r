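#' Read a per-locus FASTA of allele sequences
#'
#' Headers carry `species<delim>locus<delim>alleleID` (e.g. `>J|AJ-1|a1`).
#' Sequences are uppercased; wrapped lines and CRLF endings are accepted
#' (Biostrings does the actual parsing).
#'
#' @param path FASTA file.
#' @param delim header field delimiter, default `"|"`.
#' @param aligned if `TRUE`, `-` gap characters are allowed.
#' @return tibble with columns `id`, `species`, `locus`, `sequence`, in file
#'   order.
#' @export
read_fasta <- function(path, delim = "|", aligned = FALSE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  xs <- Biostrings::readBStringSet(path)
  headers <- names(xs)
  seqs <- toupper(as.character(xs))
  parts <- strsplit(headers, delim, fixed = TRUE)
  bad <- which(map_int(parts, length) != 3L)
  if (length(bad) > 0) {
    abort(paste0("malformed header (expected species", delim, "locus", delim,
                 "alleleID): '", headers[bad[1]], "' (record ", bad[1], ")"))
  }
  out <- tibble(
    id = map_chr(parts, 3),
    species = map_chr(parts, 1),
    locus = map_chr(parts, 2),
    sequence = unname(seqs)
  )
  if (any(out$sequence == "")) {
    abort(paste0("empty sequence for record: ",
                 out$id[which(out$sequence == "")[1]]))
  }
  if (anyDuplicated(out$id)) {
    abort(paste0("duplicate id in ", path, ": ",
                 out$id[anyDuplicated(out$id)]))
  }
  pat <- if (aligned) "^[ACGTRYSWKMBDHVN-]+$" else "^[ACGTRYSWKMBDHVN]+$"
  ok <- grepl(pat, out$sequence)
  if (!all(ok)) {
    abort(paste0("record ", out$id[which(!ok)[1]],
                 " contains characters outside the DNA/IUPAC alphabet",
                 if (!aligned) " (gaps are only allowed with aligned = TRUE)"))
  }
  out
}

#' Write allele sequences to FASTA
#'
#' The inverse of [read_fasta()]: headers are
#' `species<delim>locus<delim>alleleID`, sequences wrapped at `width`
#' columns.
#'
#' @param df tibble with `id`, `species`, `locus`, `sequence`.
#' @param path output file.
#' @param delim header delimiter.
#' @param width wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(df, path, delim = "|", width = 70L) {
  xs <- Biostrings::BStringSet(df$sequence)
  names(xs) <- paste(df$species, df$locus, df$id, sep = delim)
  Biostrings::writeXStringSet(xs, path, width = width)
  invisible(path)
}

#' Read a locus configuration table
#'
#' A TSV with columns `locus`, `motif` and optionally `min_seed_units`
#' (default 3). Motifs must be non-homopolymer dinucleotides.
#'
#' @param path TSV file.
#' @return tibble with `locus`, `motif`, `min_seed_units`.
#' @export
read_locus_config <- function(path) {
  cfg <- as_tibble(read.delim(path, stringsAsFactors = FALSE))
  if (!all(c("locus", "motif") %in% names(cfg))) {
    abort("locus config needs columns 'locus' and 'motif'")
  }
  if (!"min_seed_units" %in% names(cfg)) cfg$min_seed_units <- 3L
  bad <- nchar(cfg$motif) != 2L |
    substr(cfg$motif, 1, 1) == substr(cfg$motif, 2, 2)
  if (any(bad)) {
    abort(paste0("bad motif for locus ", cfg$locus[which(bad)[1]],
                 ": must be a non-homopolymer dinucleotide"))
  }
  cfg
}

#' Write a phylogenetic tree to Newick
#'
#' Bootstrap supports stored in `tree$node.label` are written as internal
#' node labels; branch lengths are rounded to `decimals` places.
#'
#' @param tree an `ape::phylo`.
#' @param path output file.
#' @param decimals digits for branch lengths (default 3).
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, decimals = 3L) {
  if (!inherits(tree, "phylo")) abort("tree must be an ape 'phylo'")
  if (is.null(tree$edge.length) || any(!is.finite(tree$edge.length))) {
    abort("tree has missing or non-finite branch lengths")
  }
  tree$edge.length <- round(tree$edge.length, decimals)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Bundled repeat-region survey table
#'
#' The published per-locus, per-species survey of six conserved dinucleotide
#' microsatellite loci (AJ-1, AJ-8, AJ-9, AJMS-3, AJMS-6, AJMS-10) cloned
#' across four *Anguilla* eel species: PCR annealing temperature, number of
#' cloned sequences, and the compact repeat-region notation of the observed
#' alleles (groups separated by `;`).
#'
#' @return tibble with columns `locus`, `species`, `species_code`, `ta`,
#'   `n_sequences`, `notation`.
#' @export
anguilla_repeat_table <- function() {
  as_tibble(read.delim(
    system.file("extdata", "anguilla_repeat_table.tsv", package = "msatphylo"),
    stringsAsFactors = FALSE))
}

#' Bundled interspecific K2P distance table
#'
#' Published pairwise Kimura two-parameter distances (with standard errors)
#' and total site-difference counts among the concatenated consensus
#' flanking sequences of the four *Anguilla* species.
#'
#' @return tibble with columns `species_a`, `species_b`, `code_a`, `code_b`,
#'   `k2p`, `se`, `differences`.
#' @export
anguilla_distance_table <- function() {
  as_tibble(read.delim(
    system.file("extdata", "anguilla_distance_table.tsv", package = "msatphylo"),
    stringsAsFactors = FALSE))
}

#' Bundled locus configuration for the six *Anguilla* loci
#'
#' @return tibble with `locus`, `motif`, `min_seed_units`.
#' @export
anguilla_locus_config <- function() {
  read_locus_config(
    system.file("extdata", "anguilla_loci.tsv", package = "msatphylo"))
}
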