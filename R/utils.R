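# IUPAC nucleotide codes as base-set bit masks (A=1, C=2, G=4, T=8).
IUPAC_MASK <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, S = 6L, W = 9L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

# Inverse lookup: bit mask -> IUPAC letter.
MASK_IUPAC <- setNames(names(IUPAC_MASK), IUPAC_MASK)

#' IUPAC code for a set of bases
#'
#' @param bases character vector of A/C/G/T (or IUPAC) letters observed at a
#'   site; their base sets are unioned.
#' @return single IUPAC letter covering the union.
#' @examples
#' iupac_code(c("G", "T")) # "K"
#' @export
iupac_code <- function(bases) {
  bases <- toupper(bases)
  bad <- setdiff(unique(bases), names(IUPAC_MASK))
  if (length(bad) > 0) {
    abort(paste0("not a nucleotide/IUPAC letter: ", paste(bad, collapse = ", ")))
  }
  mask <- Reduce(bitwOr, IUPAC_MASK[bases])
  unname(MASK_IUPAC[as.character(mask)])
}

# base-set masks for each character of a string; '-' and unknowns get 0
seq_masks <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  m <- IUPAC_MASK[ch]
  m[is.na(m)] <- 0L
  unname(m)
}

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

str_from <- function(ch) paste(ch, collapse = "")

is_dna <- function(s) grepl("^[ACGT]+$", s)

# deterministic seed derivation that stays inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
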