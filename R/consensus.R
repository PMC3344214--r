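# alignment rows (equal-length strings) -> character matrix, columns = sites
aln_matrix <- function(rows) {
  if (length(unique(nchar(rows))) != 1L) {
    abort("alignment rows differ in length")
  }
  do.call(rbind, lapply(rows, chars))
}

#' Build an IUPAC consensus from a flank alignment
#'
#' Per column of the intraspecific alignment: columns where gaps are the
#' majority are dropped (minority gaps are ignored and the base call kept).
#' With the default `ambiguity_threshold = NULL`, the plurality residue is
#' emitted when one residue has frequency above 1/2, and the IUPAC code of
#' all observed residues otherwise (ties such as G/T become `K`). A numeric
#' threshold switches to frequency filtering: the IUPAC code of every
#' residue with frequency at or above the threshold (frequencies among
#' non-gap residues).
#'
#' @param aln a `msat_flank_alignment` from [align_flanks()], or any tibble
#'   with an `aligned` column of equal-length gapped strings.
#' @param ambiguity_threshold `NULL` (plurality + ambiguity for ties) or a
#'   fraction in (0, 1].
#' @return list with `sequence` (IUPAC consensus, no gaps), `length`,
#'   `dropped_columns` (count of gap-majority columns), `locus`, `species`.
#' @export
build_consensus <- function(aln, ambiguity_threshold = NULL) {
  m <- aln_matrix(aln$aligned)
  nr <- nrow(m)
  cons <- character(0)
  dropped <- 0L
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    gaps <- sum(col == "-")
    if (gaps > nr / 2) {
      dropped <- dropped + 1L
      if (gaps == nr) warn(paste0("all-gap column ", j, " dropped"))
      next
    }
    res <- col[col != "-"]
    freq <- table(res) / length(res)
    if (is.null(ambiguity_threshold)) {
      if (max(freq) > 0.5) {
        cons <- c(cons, names(freq)[which.max(freq)])
      } else {
        cons <- c(cons, iupac_code(names(freq)))
      }
    } else {
      keep <- names(freq)[freq >= ambiguity_threshold]
      if (length(keep) == 0) keep <- names(freq)[which.max(freq)]
      cons <- c(cons, iupac_code(keep))
    }
  }
  list(
    sequence = str_from(cons),
    length = length(cons),
    dropped_columns = dropped,
    locus = attr(aln, "locus") %||% NA_character_,
    species = attr(aln, "species") %||% NA_character_
  )
}

#' Concatenate per-locus consensus sequences for one species
#'
#' @param per_locus tibble with columns `locus`, `species`, `sequence`
#'   (one consensus per locus).
#' @param locus_order character vector giving the concatenation order; every
#'   locus must be present.
#' @return list with `species`, `sequence`, `length`, `loci`, and
#'   `junctions` -- the 1-based start position of each locus in the
#'   concatenation.
#' @export
concatenate_consensus <- function(per_locus, locus_order) {
  missing <- setdiff(locus_order, per_locus$locus)
  if (length(missing) > 0) {
    abort(paste0("species ", per_locus$species[1],
                 " is missing consensus for: ",
                 paste(missing, collapse = ", ")))
  }
  per_locus <- per_locus[match(locus_order, per_locus$locus), , drop = FALSE]
  lens <- nchar(per_locus$sequence)
  list(
    species = per_locus$species[1],
    sequence = paste(per_locus$sequence, collapse = ""),
    length = sum(lens),
    loci = locus_order,
    junctions = cumsum(c(1L, head(lens, -1L)))
  )
}

#' Align concatenated consensus sequences across species
#'
#' Center-star alignment of the (IUPAC) consensus sequences, one per
#' species.
#'
#' @param consensus tibble with columns `species`, `sequence`.
#' @inheritParams pairwise_align
#' @return tibble with `species`, `aligned`; attribute `columns`.
#' @export
align_species_consensus <- function(consensus, match = 1, mismatch = -1,
                                    gap = -2) {
  al <- progressive_align(consensus$sequence, match, mismatch, gap)
  structure(tibble(species = consensus$species, aligned = al$aligned),
            columns = al$columns,
            class = c("msat_species_alignment", class(tibble())))
}

#' Census variable sites in a cross-species alignment
#'
#' A column is an indel site when any row has `-` there; otherwise it is a
#' substitution site when it holds more than one incompatible residue (IUPAC
#' letters are compared as base sets; overlapping sets are compatible).
#' Indel sites are split into monomorphic (non-gap residues all compatible)
#' and polymorphic (segregating a substitution as well). Percentages are over
#' variable sites; base composition is over unambiguous non-gap residues.
#'
#' @param aln tibble with `species` and `aligned` columns (equal lengths),
#'   e.g. from [align_species_consensus()].
#' @return one-row tibble: `n_sites`, `substitution_sites`, `indel_sites`,
#'   `indel_monomorphic`, `indel_polymorphic`, `variable_sites`,
#'   `pct_substitution`, `pct_indel`, `at_content`, `gc_content`,
#'   `no_variation` (flag set when there are no variable sites).
#' @export
census_variation <- function(aln) {
  if (nrow(aln) < 2) abort("census needs at least two rows")
  m <- aln_matrix(aln$aligned)
  masks <- apply(m, c(1, 2), function(ch) {
    v <- IUPAC_MASK[ch]
    if (is.na(v)) 0L else v
  })
  nsub <- 0L
  nind_mono <- 0L
  nind_poly <- 0L
  for (j in seq_len(ncol(m))) {
    col <- masks[, j]
    has_gap <- any(col == 0L)
    res <- col[col != 0L]
    # residues are incompatible when some pair of base sets is disjoint;
    # for sets, that is equivalent to no common base OR >1 distinct set with
    # pairwise-disjoint members -- test all pairs
    poly <- FALSE
    if (length(res) > 1) {
      for (a in seq_len(length(res) - 1)) {
        if (any(bitwAnd(res[a], res[(a + 1):length(res)]) == 0L)) {
          poly <- TRUE
          break
        }
      }
    }
    if (has_gap) {
      if (poly) nind_poly <- nind_poly + 1L else nind_mono <- nind_mono + 1L
    } else if (poly) {
      nsub <- nsub + 1L
    }
  }
  nind <- nind_mono + nind_poly
  nvar <- nsub + nind
  base_chars <- m[m %in% c("A", "C", "G", "T")]
  at <- sum(base_chars %in% c("A", "T"))
  gc <- sum(base_chars %in% c("G", "C"))
  tibble(
    n_sites = ncol(m),
    substitution_sites = nsub,
    indel_sites = nind,
    indel_monomorphic = nind_mono,
    indel_polymorphic = nind_poly,
    variable_sites = nvar,
    pct_substitution = if (nvar > 0) 100 * nsub / nvar else 0,
    pct_indel = if (nvar > 0) 100 * nind / nvar else 0,
    at_content = if (at + gc > 0) 100 * at / (at + gc) else NA_real_,
    gc_content = if (at + gc > 0) 100 * gc / (at + gc) else NA_real_,
    no_variation = nvar == 0L
  )
}
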