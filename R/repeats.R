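#' Repeat-region decompositions
#'
#' A decomposition describes a microsatellite major region as an ordered list
#' of elements: tandem runs of a dinucleotide motif (`type = "run"`, with a
#' `count`) and short interruption literals (`type = "literal"`). It is stored
#' as a tibble with attribute `locus_motif` and class `msat_decomp`.
#'
#' Canonical form: zero-count runs are dropped, adjacent runs of the same
#' motif are merged, adjacent literals are concatenated, and a single-unit
#' run of a motif other than the locus motif is demoted to a 2-nt literal
#' (so `(AG)_1` and the bare literal `AG` are the same interruption).
#'
#' @param elements tibble with columns `type` ("run"/"literal"), `value`
#'   (motif or literal text) and `count` (units; `NA` for literals).
#' @param locus_motif the declared 2-nt motif of the locus.
#' @return an `msat_decomp` tibble.
#' @export
new_decomposition <- function(elements, locus_motif) {
  stopifnot(nchar(locus_motif) == 2L)
  if (substr(locus_motif, 1, 1) == substr(locus_motif, 2, 2)) {
    abort("locus motif must not be a homopolymer")
  }
  el <- as_tibble(elements)
  el$count <- as.integer(el$count)
  # drop zero-count runs
  el <- el[!(el$type == "run" & el$count == 0L), , drop = FALSE]
  # demote single-unit non-locus-motif runs to literals
  dem <- el$type == "run" & el$count == 1L & el$value != locus_motif
  el$type[dem] <- "literal"
  el$count[dem] <- NA_integer_
  # merge adjacent same-motif runs and adjacent literals
  if (nrow(el) > 1) {
    keep <- rep(TRUE, nrow(el))
    for (i in seq_len(nrow(el))[-1]) {
      j <- max(which(keep[seq_len(i - 1)]))
      if (el$type[i] == "run" && el$type[j] == "run" && el$value[i] == el$value[j]) {
        el$count[j] <- el$count[j] + el$count[i]
        keep[i] <- FALSE
      } else if (el$type[i] == "literal" && el$type[j] == "literal") {
        el$value[j] <- paste0(el$value[j], el$value[i])
        keep[i] <- FALSE
      }
    }
    el <- el[keep, , drop = FALSE]
  }
  if (!any(el$type == "run" & el$count >= 1L)) {
    abort("decomposition has no repeat run with count >= 1")
  }
  structure(el, locus_motif = locus_motif,
            class = c("msat_decomp", class(tibble())))
}

#' @export
print.msat_decomp <- function(x, ...) {
  cat("<decomposition ", serialize_decomposition(x),
      " | locus motif ", attr(x, "locus_motif"), ">\n", sep = "")
  invisible(x)
}

#' Serialize a decomposition back to notation
#'
#' Runs are written `(TG)_8`, literals are written bare, e.g.
#' `"(TG)_8AG(TG)_10"`.
#'
#' @param d an `msat_decomp`.
#' @return a notation string.
#' @export
serialize_decomposition <- function(d) {
  paste(ifelse(d$type == "run",
               paste0("(", d$value, ")_", d$count),
               d$value),
        collapse = "")
}

#' Expand a decomposition to its nucleotide sequence
#'
#' @param d an `msat_decomp`.
#' @return DNA string; its length equals `sum(2 * counts) + sum(literal
#'   lengths)`.
#' @examples
#' d <- parse_repeat_notation("(TG)_8AG(TG)_10", "TG")[[1]]
#' nchar(expand_decomposition(d)) # 38
#' @export
expand_decomposition <- function(d) {
  paste(ifelse(d$type == "run", strrep(d$value, d$count), d$value),
        collapse = "")
}

# --- notation grammar ------------------------------------------------------

# parse one subscript spec ("8", "7~13", "6, 7, 8, 10", "14~18, 20") into an
# integer vector of alternative counts, in reading order
parse_spec <- function(spec, pos) {
  items <- strsplit(spec, ",")[[1]]
  out <- integer(0)
  for (it in items) {
    it <- gsub("\\s+", "", it)
    if (grepl("^\\d+$", it)) {
      out <- c(out, as.integer(it))
    } else if (grepl("^\\d+~\\d+$", it)) {
      ab <- as.integer(strsplit(it, "~")[[1]])
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      abort(paste0("bad repeat-count spec '", it, "' at position ", pos))
    }
  }
  out
}

tokenize_notation <- function(text) {
  s <- gsub("\\s+$", "", text)
  tokens <- list()
  i <- 1L
  n <- nchar(s)
  while (i <= n) {
    rest <- substr(s, i, n)
    if (grepl("^\\s", rest)) {
      i <- i + 1L
      next
    }
    if (startsWith(rest, "(")) {
      m <- regmatches(rest, regexec("^\\(([ACGT]+)\\)", rest))[[1]]
      if (length(m) == 0) {
        abort(paste0("unbalanced or empty parentheses at position ", i))
      }
      motif <- m[2]
      if (nchar(motif) != 2L) {
        abort(paste0("motif '", motif, "' at position ", i,
                     " is not a dinucleotide"))
      }
      adv <- nchar(m[1])
      rest2 <- substr(s, i + adv, n)
      if (startsWith(rest2, "_")) {
        sm <- regmatches(rest2,
          regexec("^_(\\s*\\d+(\\s*~\\s*\\d+)?(\\s*,\\s*\\d+(\\s*~\\s*\\d+)?)*)",
                  rest2))[[1]]
        if (length(sm) == 0) {
          abort(paste0("non-integer subscript at position ", i + adv))
        }
        counts <- parse_spec(sm[2], i + adv)
        adv <- adv + nchar(sm[1])
      } else {
        counts <- 1L # bare "(TA)" means one unit
      }
      tokens[[length(tokens) + 1L]] <-
        list(type = "run", motif = motif, counts = counts)
      i <- i + adv
    } else {
      m <- regmatches(rest, regexec("^[ACGT]+", rest))[[1]]
      if (length(m) == 0) {
        abort(paste0("unexpected character '", substr(s, i, i),
                     "' at position ", i))
      }
      tokens[[length(tokens) + 1L]] <- list(type = "literal", value = m[1])
      i <- i + nchar(m[1])
    }
  }
  if (length(tokens) == 0) abort("empty notation")
  tokens
}

#' Parse compact repeat-region notation
#'
#' Parses strings like `"(TG)_8AG(TG)_10"`, `"(TG)_7~13"` or
#' `"(TG)_12~18TA(TG)_0, 2"` into the set of concrete decompositions the
#' notation denotes. A subscript may be a single count, a `~`-range, or a
#' comma list; ranges/lists denote alternative alleles.
#'
#' When several terms carry multi-count subscripts, two expansion semantics
#' exist: `"paired"` matches them position by position (so
#' `"(TG)_3, 8CG(TG)_1, 4"` gives the two alleles 3+1 and 8+4), `"cartesian"`
#' crosses them. The default `"auto"` pairs when all multi-count subscripts
#' have the same length and crosses otherwise.
#'
#' @param text notation string.
#' @param locus_motif declared motif of the locus (2 nt).
#' @param list_mode `"auto"`, `"paired"` or `"cartesian"`.
#' @return list of `msat_decomp` objects (duplicates after canonicalization
#'   removed, order preserved).
#' @examples
#' length(parse_repeat_notation("(TG)_7~9", "TG")) # 3
#' @export
parse_repeat_notation <- function(text, locus_motif,
                                  list_mode = c("auto", "paired", "cartesian")) {
  list_mode <- match.arg(list_mode)
  tokens <- tokenize_notation(text)
  spec_lens <- map_int(tokens, function(t) {
    if (t$type == "run") length(t$counts) else 1L
  })
  multi <- spec_lens[spec_lens > 1L]
  mode <- list_mode
  if (mode == "auto") {
    mode <- if (length(multi) > 1L && length(unique(multi)) == 1L) {
      "paired"
    } else {
      "cartesian"
    }
  }
  if (mode == "paired" && length(multi) > 0 && length(unique(multi)) > 1L) {
    abort("paired expansion requires equal-length count lists")
  }
  combos <- if (mode == "paired") {
    k <- if (length(multi) > 0) max(multi) else 1L
    lapply(seq_len(k), function(i) {
      map_int(tokens, function(t) {
        if (t$type != "run") return(NA_integer_)
        if (length(t$counts) == 1L) t$counts else t$counts[i]
      })
    })
  } else {
    grids <- lapply(tokens, function(t) {
      if (t$type == "run") t$counts else NA_integer_
    })
    # first subscript varies slowest, matching reading order
    g <- expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE)
    g <- g[, rev(seq_along(grids)), drop = FALSE]
    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
  }
  out <- list()
  seen <- character(0)
  for (cb in combos) {
    el <- tibble(
      type = map_chr(tokens, "type"),
      value = map_chr(tokens, function(t) {
        if (t$type == "run") t$motif else t$value
      }),
      count = cb
    )
    d <- new_decomposition(el, locus_motif)
    key <- serialize_decomposition(d)
    if (!key %in% seen) {
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- d
    }
  }
  out
}

#' Parse a repeat-region survey table
#'
#' Expands every notation group (groups separated by `;`) of a per-locus,
#' per-species survey table -- such as [anguilla_repeat_table()] -- into one
#' row per concrete allele decomposition.
#'
#' @param tbl tibble with columns `locus`, `species` (or `species_code`) and
#'   `notation`.
#' @param loci locus configuration tibble (`locus`, `motif`).
#' @param list_mode see [parse_repeat_notation()].
#' @return tibble with one row per denoted allele: `locus`, `species`,
#'   `group` (index of the notation group within the row), `notation`
#'   (canonical serialization), `decomp` (list of `msat_decomp`), `class`,
#'   `max_run` (largest locus-motif run count), `total_units`,
#'   `expanded_length`.
#' @export
parse_repeat_table <- function(tbl, loci, list_mode = "auto") {
  if (!"species" %in% names(tbl) && "species_code" %in% names(tbl)) {
    tbl$species <- tbl$species_code
  }
  rows <- list()
  for (r in seq_len(nrow(tbl))) {
    motif <- loci$motif[loci$locus == tbl$locus[r]]
    if (length(motif) != 1) {
      abort(paste0("no motif configured for locus ", tbl$locus[r]))
    }
    groups <- strsplit(tbl$notation[r], ";", fixed = TRUE)[[1]]
    groups <- trimws(groups)
    for (g in seq_along(groups)) {
      ds <- parse_repeat_notation(groups[g], motif, list_mode = list_mode)
      for (d in ds) {
        runs <- d[d$type == "run", , drop = FALSE]
        rows[[length(rows) + 1L]] <- tibble(
          locus = tbl$locus[r], species = tbl$species[r], group = g,
          notation = serialize_decomposition(d), decomp = list(d),
          class = classify_decomposition(d),
          max_run = max(c(0L, runs$count[runs$value == motif])),
          total_units = sum(runs$count),
          expanded_length = nchar(expand_decomposition(d))
        )
      }
    }
  }
  bind_rows(rows)
}

#' Classify a decomposition as perfect, interrupted or compound
#'
#' Perfect: a single uninterrupted run. Interrupted: runs of the locus motif
#' separated by short literals or by a run of another motif of at most two
#' units. Compound: adjacent runs (three or more units each) of two different
#' motifs with no interrupting literal.
#'
#' @param d an `msat_decomp` in canonical form.
#' @return one of `"perfect"`, `"interrupted"`, `"compound"`.
#' @export
classify_decomposition <- function(d) {
  runs <- d[d$type == "run", , drop = FALSE]
  if (any(d$type == "literal")) return("interrupted")
  if (nrow(runs) == 1L) return("perfect")
  if (any(runs$count <= 2L)) return("interrupted")
  "compound"
}

# --- major-region detection ------------------------------------------------

# maximal exact tandem arrays of `motif` in `seq`: start, end, units
find_arrays <- function(seq, motif) {
  m <- gregexpr(paste0("(?:", motif, ")+"), seq)[[1]]
  if (m[1] == -1L) {
    return(tibble(start = integer(0), end = integer(0),
                  motif = character(0), units = integer(0)))
  }
  len <- attr(m, "match.length")
  units <- len %/% 2L
  tibble(start = as.integer(m), end = as.integer(m) + units * 2L - 1L,
         motif = motif, units = units)
}

#' Locate and decompose the major repeat region of a raw allele
#'
#' Finds every exact tandem array of the locus motif (in both phases, e.g. TG
#' and GT), merges arrays separated by a single short interruption -- a 1-2 nt
#' literal or one extra dinucleotide unit (a 4-nt tandem such as `AGAG`) --
#' and keeps the merged region of greatest expanded length (leftmost on
#' ties). A region qualifies only if it contains an array of at least
#' `min_seed_units` units. The remainder of the sequence becomes the 5' and
#' 3' flanks.
#'
#' @param seq unaligned A/C/G/T string.
#' @param motif locus motif (2 nt).
#' @param min_seed_units minimum units for a seeding array (default 3).
#' @return list with `flank5`, `major` (an `msat_decomp`), `flank3`,
#'   `start`, `end` (1-based closed span of the major region).
#' @export
decompose_major_region <- function(seq, motif, min_seed_units = 3L) {
  if (!is_dna(seq)) abort("sequence must be unaligned A/C/G/T")
  rot <- paste0(substr(motif, 2, 2), substr(motif, 1, 1))
  arr <- bind_rows(find_arrays(seq, motif), find_arrays(seq, rot))
  if (nrow(arr) == 0 || max(arr$units) < min_seed_units) {
    abort(paste0("no major region: no (", motif, ")_", min_seed_units,
                 "+ array found"))
  }
  # overlapping phase-shifted duplicates: keep longer, prefer declared phase
  arr <- arr[order(-arr$units, arr$motif != motif, arr$start), , drop = FALSE]
  keep <- logical(nrow(arr))
  for (i in seq_len(nrow(arr))) {
    ok <- TRUE
    for (j in which(keep)) {
      if (arr$start[i] <= arr$end[j] && arr$end[i] >= arr$start[j]) {
        ok <- FALSE
        break
      }
    }
    keep[i] <- ok
  }
  arr <- arr[keep, , drop = FALSE]
  arr <- arr[order(arr$start), , drop = FALSE]

  # admissible junction between consecutive arrays: a 1-2 nt literal, or one
  # extra dinucleotide unit (4-nt tandem) when it separates two real arrays
  gap_ok <- function(g, gtext, units_left, units_right) {
    if (g == 0L || g == 1L || g == 2L) return(TRUE)
    g == 4L && substr(gtext, 1, 2) == substr(gtext, 3, 4) &&
      units_left >= 3L && units_right >= 3L
  }
  n <- nrow(arr)
  chain_id <- integer(n)
  cid <- 1L
  chain_id[1] <- cid
  if (n > 1) {
    for (i in 2:n) {
      g <- arr$start[i] - arr$end[i - 1] - 1L
      gtext <- if (g > 0) substr(seq, arr$end[i - 1] + 1L, arr$start[i] - 1L) else ""
      if (!gap_ok(g, gtext, arr$units[i - 1], arr$units[i])) cid <- cid + 1L
      chain_id[i] <- cid
    }
  }
  cand <- lapply(split(seq_len(n), chain_id), function(idx) {
    a <- arr[idx, , drop = FALSE]
    list(rows = a,
         start = a$start[1], end = a$end[nrow(a)],
         len = a$end[nrow(a)] - a$start[1] + 1L,
         seeded = any(a$units >= min_seed_units))
  })
  cand <- cand[map_lgl(cand, "seeded")]
  if (length(cand) == 0) {
    abort(paste0("no major region: no (", motif, ")_", min_seed_units,
                 "+ array found"))
  }
  lens <- map_int(cand, "len")
  starts <- map_int(cand, "start")
  best <- cand[[order(-lens, starts)[1]]]

  a <- best$rows
  el <- list()
  for (i in seq_len(nrow(a))) {
    if (i > 1) {
      g <- a$start[i] - a$end[i - 1] - 1L
      if (g > 0) {
        gtext <- substr(seq, a$end[i - 1] + 1L, a$start[i] - 1L)
        if (g == 4L) {
          el[[length(el) + 1L]] <- list(type = "run",
                                        value = substr(gtext, 1, 2), count = 2L)
        } else {
          el[[length(el) + 1L]] <- list(type = "literal", value = gtext,
                                        count = NA_integer_)
        }
      }
    }
    el[[length(el) + 1L]] <- list(type = "run", value = a$motif[i],
                                  count = a$units[i])
  }
  major <- new_decomposition(
    tibble(type = map_chr(el, "type"),
           value = map_chr(el, "value"),
           count = map_int(el, function(e) e$count %||% NA_integer_)),
    locus_motif = motif
  )
  list(
    flank5 = substr(seq, 1L, best$start - 1L),
    major = major,
    flank3 = substr(seq, best$end + 1L, nchar(seq)),
    start = best$start,
    end = best$end
  )
}

#' Decompose a table of alleles
#'
#' Applies [decompose_major_region()] to every row of a sequence tibble (as
#' returned by [read_fasta()] or [simulate_msat_dataset()]) and appends the
#' decomposition columns.
#'
#' @param df tibble with columns `id`, `species`, `locus`, `sequence`.
#' @param loci locus configuration tibble with columns `locus`, `motif` and
#'   optionally `min_seed_units` (see [read_locus_config()]).
#' @param on_error `"abort"` (default) stops on the first allele without a
#'   detectable major region; `"drop"` removes such alleles and records them
#'   in the `failed` attribute of the result (tibble `id`, `species`,
#'   `locus`, `reason`), so every input allele is accounted for.
#' @return the input tibble plus `flank5`, `flank3`, `major` (list column of
#'   `msat_decomp`), `major_start`, `major_end`, `notation`, `class`,
#'   `total_units` (summed run counts) and `expanded_length`.
#' @export
decompose_alleles <- function(df, loci, on_error = c("abort", "drop")) {
  on_error <- match.arg(on_error)
  if (!"min_seed_units" %in% names(loci)) loci$min_seed_units <- 3L
  df <- left_join(df, loci[, c("locus", "motif", "min_seed_units")],
                  by = "locus")
  if (anyNA(df$motif)) {
    abort(paste0("no motif configured for locus: ",
                 paste(unique(df$locus[is.na(df$motif)]), collapse = ", ")))
  }
  recs <- pmap(list(df$sequence, df$motif, df$min_seed_units, df$id, df$locus),
    function(s, m, msu, id, locus) {
      tryCatch(decompose_major_region(s, m, msu),
               error = function(e) {
                 if (on_error == "abort") {
                   abort(paste0("allele ", id, " (", locus, "): ",
                                conditionMessage(e)))
                 }
                 conditionMessage(e)
               })
    })
  bad <- map_lgl(recs, is.character)
  failed <- tibble(id = df$id[bad], species = df$species[bad],
                   locus = df$locus[bad],
                   reason = unlist(recs[bad]) %||% character(0))
  df <- df[!bad, , drop = FALSE]
  recs <- recs[!bad]
  df$flank5 <- map_chr(recs, "flank5")
  df$flank3 <- map_chr(recs, "flank3")
  df$major <- map(recs, "major")
  df$major_start <- map_int(recs, "start")
  df$major_end <- map_int(recs, "end")
  df$notation <- map_chr(df$major, serialize_decomposition)
  df$class <- map_chr(df$major, classify_decomposition)
  df$total_units <- map_int(df$major, function(d) {
    sum(d$count[d$type == "run"])
  })
  df$expanded_length <- map_int(df$major, function(d) {
    nchar(expand_decomposition(d))
  })
  df$motif <- NULL
  df$min_seed_units <- NULL
  attr(df, "failed") <- failed
  df
}

#' Per-locus, per-species summary of decomposed alleles
#'
#' @param alleles tibble from [decompose_alleles()]; all rows must share one
#'   locus.
#' @return per-species tibble: allele count, canonical notation strings,
#'   sorted unique perfect-run counts, min/max total repeat units, and an
#'   allele-length histogram (list column of tables over `expanded_length`).
#' @export
tabulate_locus <- function(alleles) {
  if (nrow(alleles) == 0) abort("empty allele table")
  if (length(unique(alleles$locus)) != 1L) {
    abort("tabulate_locus() expects a single locus")
  }
  alleles |>
    group_by(.data$species) |>
    summarise(
      locus = .data$locus[1],
      n_alleles = dplyr::n(),
      notations = paste(sort(unique(.data$notation)), collapse = "; "),
      perfect_counts = list(sort(unique(
        .data$total_units[.data$class == "perfect"]))),
      min_units = min(.data$total_units),
      max_units = max(.data$total_units),
      length_histogram = list(table(.data$expanded_length)),
      .groups = "drop"
    ) |>
    select("locus", dplyr::everything())
}
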