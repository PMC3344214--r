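#' Count pairwise transitions and transversions
#'
#' Columns where either sequence has a gap or an ambiguity letter are
#' excluded for that pair (pairwise complete deletion). A<->G and C<->T
#' mismatches are transitions; all other mismatches are transversions.
#'
#' @param a,b equal-length aligned strings (IUPAC letters and `-` allowed).
#' @return one-row tibble: `ts`, `tv`, `gap_excluded` (excluded columns),
#'   `compared` (effective length).
#' @export
count_site_differences <- function(a, b) {
  if (nchar(a) != nchar(b)) abort("sequences differ in length")
  ca <- chars(a)
  cb <- chars(b)
  plain <- c("A", "C", "G", "T")
  use <- ca %in% plain & cb %in% plain
  ca <- ca[use]
  cb <- cb[use]
  diff <- ca != cb
  pur <- c("A", "G")
  ts <- sum(diff & ((ca %in% pur) == (cb %in% pur)))
  tv <- sum(diff) - ts
  tibble(ts = as.integer(ts), tv = as.integer(tv),
         gap_excluded = as.integer(nchar(a) - sum(use)),
         compared = as.integer(sum(use)))
}

#' Kimura two-parameter distance
#'
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with transition proportion
#' `P = ts/compared` and transversion proportion `Q = tv/compared`. The
#' standard error is the analytic delta-method estimate.
#'
#' @param ts,tv,compared counts as returned by [count_site_differences()]
#'   (or a one-row tibble passed as `ts`).
#' @return one-row tibble: `p`, `q`, `d`, `se`.
#' @export
k2p_distance <- function(ts, tv = NULL, compared = NULL) {
  if (is.data.frame(ts)) {
    tv <- ts$tv
    compared <- ts$compared
    ts <- ts$ts
  }
  if (compared <= 0) abort("no compared sites")
  p <- ts / compared
  q <- tv / compared
  w1 <- 1 - 2 * p - q
  w2 <- 1 - 2 * q
  if (w1 <= 0 || w2 <= 0) {
    abort("distance undefined: substitution saturation (1-2P-Q or 1-2Q <= 0)")
  }
  d <- -0.5 * log(w1) - 0.25 * log(w2)
  c1 <- 1 / w1
  c2 <- 1 / w2
  c3 <- (c1 + c2) / 2
  v <- (c1^2 * p + c3^2 * q - (c1 * p + c3 * q)^2) / compared
  tibble(p = p, q = q, d = d, se = sqrt(v))
}

#' Pairwise K2P distance matrix from a species alignment
#'
#' @param aln tibble with `species` and `aligned` columns (equal-length
#'   strings), e.g. from [align_species_consensus()].
#' @return an `msat_distmat`: list with `taxa`, `d` (K2P distances), `se`,
#'   `differences` (integer ts+tv), `ts`, `tv`, `compared` -- all symmetric
#'   matrices with zero diagonals.
#' @export
build_distance_matrix <- function(aln) {
  if (nrow(aln) < 3) abort("need at least three taxa")
  taxa <- aln$species
  n <- length(taxa)
  mk <- function(x = 0) matrix(x, n, n, dimnames = list(taxa, taxa))
  d <- mk()
  se <- mk()
  dif <- mk(0L)
  tsM <- mk(0L)
  tvM <- mk(0L)
  cmp <- mk(0L)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- count_site_differences(aln$aligned[i], aln$aligned[j])
      k <- tryCatch(k2p_distance(s), error = function(e) {
        abort(paste0("pair ", taxa[i], " vs ", taxa[j], ": ",
                     conditionMessage(e)))
      })
      d[i, j] <- d[j, i] <- k$d
      se[i, j] <- se[j, i] <- k$se
      dif[i, j] <- dif[j, i] <- s$ts + s$tv
      tsM[i, j] <- tsM[j, i] <- s$ts
      tvM[i, j] <- tvM[j, i] <- s$tv
      cmp[i, j] <- cmp[j, i] <- s$compared
    }
  }
  structure(list(taxa = taxa, d = d, se = se, differences = dif,
                 ts = tsM, tv = tvM, compared = cmp),
            class = "msat_distmat")
}

#' Build an `msat_distmat` from a plain distance matrix
#'
#' @param d symmetric numeric matrix with dimnames.
#' @return an `msat_distmat` (difference/count slots empty).
#' @export
as_msat_distmat <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), !is.null(rownames(d)))
  structure(list(taxa = rownames(d), d = d, se = NULL, differences = NULL,
                 ts = NULL, tv = NULL, compared = NULL),
            class = "msat_distmat")
}

#' @export
print.msat_distmat <- function(x, ...) {
  cat("K2P distance matrix over", length(x$taxa), "taxa\n")
  print(round(x$d, 3))
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Canonical NJ: at each step the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j` is joined (ties broken on the
#' lexicographically smallest sorted taxon-label pair), branch lengths come
#' from the standard split formula, and negative branch lengths are clamped
#' to zero (the clamped deficit is recorded in the `clamped` attribute).
#'
#' @param dm an `msat_distmat`, or a symmetric numeric matrix with dimnames.
#' @return an unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "msat_distmat")) dm <- dm$d
  if (!all(is.finite(dm))) abort("distance matrix has non-finite entries")
  n <- nrow(dm)
  if (n < 3) abort("neighbor joining needs at least three taxa")
  labels <- rownames(dm)

  # node bookkeeping for the ape edge matrix: tips are 1..n, internal nodes
  # are numbered n+1 (root slot, assigned last) then n+2, ...
  active <- seq_len(n)            # indices into dm rows
  node_of <- seq_len(n)           # ape node id of each active cluster
  next_internal <- n + 2L
  edges <- matrix(integer(0), ncol = 2)
  lens <- numeric(0)
  clamped <- 0

  D <- dm
  while (length(active) > 3) {
    m <- length(active)
    sub <- D[active, active, drop = FALSE]
    r <- rowSums(sub)
    Qm <- (m - 2) * sub - outer(r, r, "+")
    diag(Qm) <- Inf
    qmin <- min(Qm)
    cand <- which(Qm <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      paste(sort(c(labels[active[ij[1]]], labels[active[ij[2]]])),
            collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]
    j <- pick[2]
    dij <- sub[i, j]
    bi <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- dij - bi
    if (bi < 0) { clamped <- clamped - bi; bi <- 0 }
    if (bj < 0) { clamped <- clamped - bj; bj <- 0 }
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_of[active[i]]), c(u, node_of[active[j]]))
    lens <- c(lens, bi, bj)
    # distances to the new node
    newd <- (sub[i, ] + sub[j, ] - dij) / 2
    newd <- newd[-c(i, j)]
    ai <- active[i]
    D[ai, active[-c(i, j)]] <- newd
    D[active[-c(i, j)], ai] <- newd
    labels[ai] <- paste0("__u", u)
    node_of[ai] <- u
    active <- active[-j]
  }

  # final three clusters joined at the root node n+1
  a3 <- active
  d12 <- D[a3[1], a3[2]]
  d13 <- D[a3[1], a3[3]]
  d23 <- D[a3[2], a3[3]]
  b1 <- (d12 + d13 - d23) / 2
  b2 <- (d12 + d23 - d13) / 2
  b3 <- (d13 + d23 - d12) / 2
  for (b in c(b1, b2, b3)) if (b < 0) clamped <- clamped - b
  root <- n + 1L
  edges <- rbind(edges,
                 c(root, node_of[a3[1]]),
                 c(root, node_of[a3[2]]),
                 c(root, node_of[a3[3]]))
  lens <- c(lens, max(b1, 0), max(b2, 0), max(b3, 0))

  tree <- list(edge = edges, edge.length = lens,
               tip.label = rownames(dm), Nnode = next_internal - n - 1L)
  class(tree) <- "phylo"
  tree <- ape::reorder.phylo(tree, "cladewise")
  attr(tree, "clamped") <- clamped
  tree
}

# --- splits ----------------------------------------------------------------

#' Nontrivial splits of an unrooted tree
#'
#' @param tree an `ape::phylo`.
#' @return character vector; each split is the sorted smaller side's tips
#'   joined with `,` (canonicalized so the side not containing the
#'   alphabetically first tip is used).
#' @export
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  bp <- ape::prop.part(tree)
  out <- character(0)
  for (p in bp) {
    side <- sort(tree$tip.label[p])
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    out <- c(out, paste(side, collapse = ","))
  }
  unique(out)
}

#' Compare the split sets of two trees (Robinson-Foulds style)
#'
#' @param t1,t2 `ape::phylo` trees over the same leaf set.
#' @return one-row tibble: `shared`, `unique_t1`, `unique_t2`, `rf`
#'   (symmetric difference count).
#' @export
compare_splits <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    abort("trees have different leaf sets")
  }
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  shared <- length(intersect(s1, s2))
  tibble(shared = shared,
         unique_t1 = length(s1) - shared,
         unique_t2 = length(s2) - shared,
         rf = length(s1) + length(s2) - 2L * shared)
}

# --- bootstrap -------------------------------------------------------------

# per-pair, per-column difference codes for fast resampling:
# 0 = excluded, 1 = identical, 2 = transition, 3 = transversion
pair_column_codes <- function(aln) {
  m <- aln_matrix(aln$aligned)
  n <- nrow(m)
  plain <- c("A", "C", "G", "T")
  pur <- c("A", "G")
  codes <- list()
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% plain & m[j, ] %in% plain
      diff <- ok & m[i, ] != m[j, ]
      is_ts <- diff & ((m[i, ] %in% pur) == (m[j, ] %in% pur))
      code <- integer(ncol(m))
      code[ok] <- 1L
      code[diff] <- 3L
      code[is_ts] <- 2L
      codes[[length(codes) + 1L]] <- code
      pairs[[length(pairs) + 1L]] <- c(i, j)
    }
  }
  list(codes = codes, pairs = pairs, n = n, L = ncol(m),
       taxa = aln$species)
}

#' Bootstrap support for the NJ tree of a species alignment
#'
#' Columns are resampled with replacement `n_reps` times; K2P distances and
#' the NJ tree are recomputed per replicate, and each split's support is the
#' percentage of replicates containing it. Replicates with an undefined
#' distance (saturation or an empty pair) are dropped and counted; a warning
#' is raised when more than 10% are dropped.
#'
#' @param aln tibble with `species`, `aligned` (equal-length rows).
#' @param n_reps number of replicates (default 1000).
#' @param seed RNG seed (required, for reproducibility).
#' @return the NJ tree of the full alignment (`ape::phylo`) with bootstrap
#'   percentages in `node.label` and attributes `support` (named vector per
#'   split) and `dropped_replicates`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000L, seed) {
  if (missing(seed)) abort("bootstrap_support() requires an explicit seed")
  if (n_reps < 1) abort("n_reps must be >= 1")
  pc <- pair_column_codes(aln)
  full <- build_distance_matrix(aln)
  tree <- neighbor_joining(full)
  splits <- tree_splits(tree)
  hit <- setNames(numeric(length(splits)), splits)
  dropped <- 0L

  nj_from_codes <- function(idx) {
    n <- pc$n
    d <- matrix(0, n, n, dimnames = list(pc$taxa, pc$taxa))
    for (k in seq_along(pc$codes)) {
      cd <- pc$codes[[k]][idx]
      compared <- sum(cd >= 1L)
      if (compared == 0) return(NULL)
      ts <- sum(cd == 2L)
      tv <- sum(cd == 3L)
      kd <- tryCatch(k2p_distance(ts, tv, compared)$d,
                     error = function(e) NULL)
      if (is.null(kd)) return(NULL)
      ij <- pc$pairs[[k]]
      d[ij[1], ij[2]] <- d[ij[2], ij[1]] <- kd
    }
    neighbor_joining(d)
  }

  set.seed(seed)
  used <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(pc$L, pc$L, replace = TRUE)
    bt <- nj_from_codes(idx)
    if (is.null(bt)) {
      dropped <- dropped + 1L
      next
    }
    used <- used + 1L
    bs <- tree_splits(bt)
    inb <- splits %in% bs
    hit[inb] <- hit[inb] + 1
  }
  if (dropped > 0.1 * n_reps) {
    warn(paste0(dropped, " of ", n_reps,
                " bootstrap replicates dropped (undefined distances)"))
  }
  support <- if (used > 0) 100 * hit / used else hit * NA_real_
  tree <- annotate_supports(tree, support)
  attr(tree, "support") <- support
  attr(tree, "dropped_replicates") <- dropped
  tree
}

# write per-split supports into node.label (rounded to integer percent)
annotate_supports <- function(tree, support) {
  ntip <- length(tree$tip.label)
  labs <- rep("", tree$Nnode)
  bp <- ape::prop.part(tree)
  tips <- sort(tree$tip.label)
  for (k in seq_along(bp)) {
    side <- sort(tree$tip.label[bp[[k]]])
    if (length(side) <= 1 || length(side) >= ntip - 1) next
    if (tips[1] %in% side) side <- setdiff(tips, side)
    key <- paste(side, collapse = ",")
    if (key %in% names(support)) {
      labs[k] <- as.character(round(support[[key]]))
    }
  }
  tree$node.label <- labs
  tree
}
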