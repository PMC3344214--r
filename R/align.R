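#' Global pairwise alignment
#'
#' Needleman-Wunsch with linear gap penalties and a deterministic traceback
#' (on ties: diagonal, then a gap in `b`, then a gap in `a`). IUPAC letters
#' score as a match when their base sets intersect.
#'
#' @param a,b DNA strings (IUPAC letters allowed).
#' @param match,mismatch,gap scores (defaults +1/-1/-2).
#' @return list with gapped strings `a`, `b` and the optimal `score`.
#' @export
pairwise_align <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(a) == 0 || nchar(b) == 0) abort("sequences must be nonempty")
  r <- .nw_align_cpp(a, b, match, mismatch, gap)
  list(a = unname(r[["a"]]), b = unname(r[["b"]]),
       score = as.numeric(r[["score"]]))
}

#' Global alignment score only
#'
#' @inheritParams pairwise_align
#' @return the optimal alignment score.
#' @export
alignment_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  .nw_score_cpp(a, b, match, mismatch, gap)
}

# merge one center/other pairwise alignment into the running center-star
# master alignment; rows is a list of gapped strings whose first element is
# the (gapped) center. Gaps already in the master are never removed.
merge_into_master <- function(rows, pc, pb) {
  mc <- chars(rows[[1]])
  pc <- chars(pc)
  pb <- chars(pb)
  nrow_m <- length(rows)
  mat <- do.call(rbind, lapply(rows, chars))
  ni <- length(mc)
  nj <- length(pc)
  out <- matrix("-", nrow = nrow_m + 1L, ncol = ni + nj)
  i <- 1L
  j <- 1L
  col <- 0L
  while (i <= ni || j <= nj) {
    col <- col + 1L
    if (i <= ni && mc[i] == "-") {
      out[seq_len(nrow_m), col] <- mat[, i]
      i <- i + 1L
    } else if (j <= nj && pc[j] == "-") {
      # new gap column in the master rows; only the new row has a residue
      out[nrow_m + 1L, col] <- pb[j]
      j <- j + 1L
    } else {
      # both are the same center residue
      out[seq_len(nrow_m), col] <- mat[, i]
      out[nrow_m + 1L, col] <- pb[j]
      i <- i + 1L
      j <- j + 1L
    }
  }
  out <- out[, seq_len(col), drop = FALSE]
  apply(out, 1L, paste, collapse = "")
}

#' Center-star progressive multiple alignment
#'
#' The center is the sequence with maximal summed pairwise alignment score
#' against all others (ties: first in input order). Every other sequence is
#' aligned to the center with [pairwise_align()] and merged; gaps introduced
#' earlier are never removed ("once a gap, always a gap").
#'
#' @param seqs character vector of sequences (optionally named).
#' @inheritParams pairwise_align
#' @return list with `aligned` (gapped strings, input order, equal length),
#'   `center` (index of the center sequence) and `columns`.
#' @export
progressive_align <- function(seqs, match = 1, mismatch = -1, gap = -2) {
  n <- length(seqs)
  if (n == 0) abort("no sequences to align")
  if (n == 1) {
    return(list(aligned = unname(seqs), center = 1L,
                columns = nchar(seqs[[1]])))
  }
  sm <- .nw_score_matrix_cpp(as.character(seqs), match, mismatch, gap)
  center <- which.max(rowSums(sm))
  others <- setdiff(seq_len(n), center)
  rows <- list(seqs[[center]])
  order_added <- integer(0)
  for (k in others) {
    pa <- pairwise_align(seqs[[center]], seqs[[k]], match, mismatch, gap)
    rows <- merge_into_master(rows, pa$a, pa$b)
    order_added <- c(order_added, k)
  }
  aligned <- character(n)
  aligned[center] <- rows[[1]]
  aligned[order_added] <- unlist(rows[-1])
  list(aligned = aligned, center = as.integer(center),
       columns = nchar(rows[[1]]))
}

#' Align the flanking regions of one species at one locus
#'
#' Joins each allele's 5' and 3' flanks (the major region removed), aligns
#' them with [progressive_align()], and records the junction.
#'
#' @param alleles tibble from [decompose_alleles()], one locus and one
#'   species.
#' @inheritParams pairwise_align
#' @return a `msat_flank_alignment`: tibble with `id`, `aligned`, `junction`
#'   (ungapped 5'-flank length per row); attributes `locus`, `species`,
#'   `columns`, `center`.
#' @export
align_flanks <- function(alleles, match = 1, mismatch = -1, gap = -2) {
  if (nrow(alleles) == 0) abort("no alleles to align")
  if (length(unique(alleles$locus)) != 1L ||
      length(unique(alleles$species)) != 1L) {
    abort("align_flanks() expects one locus and one species")
  }
  joined <- paste0(alleles$flank5, alleles$flank3)
  if (any(nchar(joined) == 0)) abort("allele with empty flanks")
  al <- progressive_align(joined, match, mismatch, gap)
  out <- tibble(
    id = alleles$id,
    aligned = al$aligned,
    junction = nchar(alleles$flank5)
  )
  structure(out, locus = alleles$locus[1], species = alleles$species[1],
            columns = al$columns, center = al$center,
            class = c("msat_flank_alignment", class(tibble())))
}
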