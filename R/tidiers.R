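#' Tidy a distance matrix into pairwise rows
#'
#' @param x an `msat_distmat`.
#' @param ... unused.
#' @return tibble with one row per unordered species pair: `species_a`,
#'   `species_b`, `ts`, `tv`, `differences`, `compared`, `d`, `se`.
#' @export
tidy.msat_distmat <- function(x, ...) {
  n <- length(x$taxa)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rows[[length(rows) + 1L]] <- tibble(
        species_a = x$taxa[i], species_b = x$taxa[j],
        ts = if (is.null(x$ts)) NA_integer_ else x$ts[i, j],
        tv = if (is.null(x$tv)) NA_integer_ else x$tv[i, j],
        differences = if (is.null(x$differences)) NA_integer_
                      else x$differences[i, j],
        compared = if (is.null(x$compared)) NA_integer_ else x$compared[i, j],
        d = x$d[i, j],
        se = if (is.null(x$se)) NA_real_ else x$se[i, j]
      )
    }
  }
  bind_rows(rows)
}

#' @rdname tidy.msat_distmat
#' @export
glance.msat_distmat <- function(x, ...) {
  ut <- x$d[upper.tri(x$d)]
  tibble(n_taxa = length(x$taxa), min_d = min(ut), max_d = max(ut),
         mean_d = mean(ut))
}

#' Tidy pipeline results
#'
#' `tidy()` returns the pairwise distance rows; `glance()` a one-row
#' overview of the run.
#'
#' @param x an `msat_report`.
#' @param ... unused.
#' @export
tidy.msat_report <- function(x, ...) {
  tidy(x$distmat)
}

#' @rdname tidy.msat_report
#' @export
glance.msat_report <- function(x, ...) {
  ut <- x$distmat$d[upper.tri(x$distmat$d)]
  tibble(
    n_alleles = nrow(x$alleles),
    n_loci = length(unique(x$alleles$locus)),
    n_species = length(unique(x$alleles$species)),
    min_consensus_length = min(x$consensus$length),
    max_consensus_length = max(x$consensus$length),
    variable_sites = x$census$variable_sites,
    pct_substitution = x$census$pct_substitution,
    pct_indel = x$census$pct_indel,
    min_d = min(ut),
    max_d = max(ut),
    split = paste(sort(tree_splits(x$tree)), collapse = ";")
  )
}

#' Allele size distributions per locus
#'
#' Histogram of total allele lengths per locus, filled by species -- the
#' usual per-locus allele-size figure for a multi-species survey.
#'
#' @param object an `msat_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msat_report <- function(object, ...) {
  df <- mutate(object$alleles, size = nchar(.data$sequence))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, fill = .data$species)) +
    ggplot2::geom_histogram(binwidth = 2, position = "stack") +
    ggplot2::facet_wrap(ggplot2::vars(.data$locus), scales = "free_x") +
    ggplot2::labs(x = "allele size (bp)", y = "count", fill = "species")
}

#' Heatmap of pairwise K2P distances
#'
#' @param object an `msat_distmat`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.msat_distmat <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$species_a, y = .data$species_b,
                                   fill = .data$d)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = formatC(.data$d, digits = 3, format = "f"))) +
    ggplot2::labs(x = NULL, y = NULL, fill = "K2P")
}

#' Plot the NJ tree with bootstrap supports
#'
#' Thin wrapper around [ape::plot.phylo()] that shows node supports when
#' present.
#'
#' @param tree an `ape::phylo`, e.g. `report$tree`.
#' @param ... passed to [ape::plot.phylo()].
#' @return the tree, invisibly.
#' @export
plot_msat_tree <- function(tree, ...) {
  ape::plot.phylo(tree, type = "unrooted", ...)
  if (!is.null(tree$node.label)) {
    ape::nodelabels(tree$node.label, frame = "none", adj = c(1.1, -0.4))
  }
  invisible(tree)
}
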