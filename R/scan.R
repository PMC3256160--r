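# Column classification: the core conservation scan.  Each scannable
# column yields per-group observed symbol sets; the set-algebra rules
# below assign one of UNIVERSAL / PAIR / SHARED / ONLY / UNCLASSIFIED.
#
# The operational rule for "shared by X and Y but not Z" is the weakest
# one consistent with published signature tables that mix degenerate
# group consensus codes: the excluded groups' symbols must be disjoint
# from everything X and Y carry, while X and Y themselves need only a
# non-empty common symbol — not an identical fixed base.  (E.g. a
# eukaryote consensus D = {A,G,T} can share G with an archaeal G while
# a bacterial C is excluded.)

#' Scanner configuration
#'
#' @param min_group_fraction Minimum fraction of a group's taxa that
#'   must contribute a non-missing symbol for the column to be
#'   classifiable; below it the column is `UNCLASSIFIED` with reason
#'   `"insufficient data"`.  Default 0.9.
#' @param tolerance Fraction of observed taxa per group whose symbols
#'   may be discarded (rarest symbols first) before re-classifying a
#'   column that strict scanning leaves unclassified.  0 (default) is
#'   strict conservation: a single deviant taxon vetoes a signature.
#' @param include_universal Emit universally conserved columns as sites
#'   (default `TRUE`; they are the "all cellular organisms" class of a
#'   signature report).
#' @return A list of class `sig_scan_config`.
#' @export
scan_config <- function(min_group_fraction = 0.9, tolerance = 0,
                        include_universal = TRUE) {
  stopifnot(min_group_fraction > 0, min_group_fraction <= 1,
            tolerance >= 0, tolerance < 0.5)
  structure(list(min_group_fraction = min_group_fraction,
                 tolerance = tolerance,
                 include_universal = include_universal),
            class = "sig_scan_config")
}

#' Per-group symbol profile of one alignment column
#'
#' @param a A [sig_alignment()].
#' @param g A group map covering the alignment.
#' @param col Column index (1-based).
#' @return List of class `sig_column_profile`: `column` and `groups`, a
#'   per-group list with `counts` (named symbol counts), `set` (observed
#'   symbol set), `n_observed`, `n_missing`, `n`.
#' @export
column_profile <- function(a, g, col) {
  residues <- unclass(a)[, col]
  labels <- unclass(g)[names(residues)]
  out <- lapply(split(residues, labels), function(r) {
    obs <- r[!is.na(r)]
    counts <- table(factor(obs, levels = SIG_ALPHABET))
    counts <- counts[counts > 0L]
    list(counts = stats::setNames(as.integer(counts), names(counts)),
         set = names(counts),
         n_observed = length(obs),
         n_missing = sum(is.na(r)),
         n = length(r))
  })
  structure(list(column = as.integer(col), groups = out),
            class = "sig_column_profile")
}

#' Classify per-group symbol sets
#'
#' The pure set-algebra core, usable directly on named symbol sets.
#' With groups X, Y, Z (generalized to k groups):
#' \itemize{
#'   \item `UNIVERSAL`: every group's set is the same single non-gap
#'     symbol.
#'   \item `PAIR(X,Y)` (k > 2; for k > 3 any proper subset of >= 2
#'     groups, category `SHARED`): the excluded groups' union is
#'     disjoint from everything X and Y carry, and X and Y have a
#'     non-empty common symbol.  Larger sharing subsets take precedence
#'     over smaller ones.
#'   \item `ONLY(X)`: X has a single symbol absent from all other
#'     groups, and no PAIR applies.  If several groups qualify the
#'     first in the input order is reported (for 3 groups pairs cannot
#'     collide, but distinct single-group fixations can co-occur).
#'   \item `UNCLASSIFIED` otherwise.
#' }
#' Precedence: UNIVERSAL > PAIR/SHARED > ONLY > UNCLASSIFIED.  Subtype
#' is `INDEL` when the diagnostic shared symbol set contains the gap
#' (PAIR) or the group-specific symbol is the gap (ONLY), else
#' `SUBSTITUTION`.
#'
#' @param sets Named list of non-empty symbol sets (subsets of
#'   [SIG_ALPHABET]), one per group.
#' @return List: `category` (`"UNIVERSAL"`, `"PAIR"`, `"SHARED"`,
#'   `"ONLY"`, `"UNCLASSIFIED"`), `groups` (character vector of group
#'   labels involved, sorted; empty for UNIVERSAL/UNCLASSIFIED),
#'   `subtype` (`"SUBSTITUTION"`, `"INDEL"`, or `NA`), `reason`.
#' @export
classify_sets <- function(sets) {
  k <- length(sets)
  labels <- names(sets)
  stopifnot(k >= 2L, !is.null(labels))
  if (any(lengths(sets) == 0L)) {
    return(list(category = "UNCLASSIFIED", groups = character(0),
                subtype = NA_character_, reason = "empty group set"))
  }
  syms <- unique(unlist(sets))
  if (length(syms) == 1L && syms != "-") {
    return(list(category = "UNIVERSAL", groups = character(0),
                subtype = NA_character_, reason = NA_character_))
  }
  # sharing subsets, largest first (for k = 3 this is just the 3 pairs)
  for (m in seq.int(k - 1L, 2L)) {
    if (m < 2L) break
    combos <- utils::combn(k, m, simplify = FALSE)
    for (s in combos) {
      inside <- sets[s]
      outside <- unique(unlist(sets[-s]))
      shared <- Reduce(intersect, inside)
      if (length(shared) > 0L &&
          length(intersect(outside, unique(unlist(inside)))) == 0L) {
        return(list(
          category = if (m == 2L) "PAIR" else "SHARED",
          groups = sort(labels[s]),
          subtype = if ("-" %in% shared) "INDEL" else "SUBSTITUTION",
          reason = NA_character_
        ))
      }
    }
  }
  for (i in seq_len(k)) {
    x <- sets[[i]]
    others <- unique(unlist(sets[-i]))
    if (length(x) == 1L && !(x %in% others)) {
      return(list(category = "ONLY", groups = labels[i],
                  subtype = if (x == "-") "INDEL" else "SUBSTITUTION",
                  reason = NA_character_))
    }
  }
  list(category = "UNCLASSIFIED", groups = character(0),
       subtype = NA_character_, reason = "no exclusive sharing pattern")
}

# Discard up to floor(tolerance * n_observed) minority observations per
# group, whole rarest symbols first, keeping at least one symbol.
.tolerant_set <- function(counts, tolerance) {
  budget <- floor(tolerance * sum(counts))
  ord <- order(counts, match(names(counts), SIG_ALPHABET))
  counts <- counts[ord]
  while (length(counts) > 1L && counts[1] <= budget) {
    budget <- budget - counts[1]
    counts <- counts[-1]
  }
  names(counts)[order(match(names(counts), SIG_ALPHABET))]
}

#' Classify one column profile under a scan configuration
#'
#' Strict classification first; when strict leaves the column
#' unclassified and `tolerance > 0`, minority symbols (up to the
#' tolerance fraction of each group's observed taxa) are discarded and
#' the column is re-classified.  Tolerance can therefore only add
#' sites, never remove or re-label a strict call.
#'
#' @param p A [column_profile()].
#' @param cfg A [scan_config()].
#' @return As [classify_sets()], plus `sets`: the per-group symbol sets
#'   the decision was based on.
#' @export
classify_profile <- function(p, cfg = scan_config()) {
  gs <- p$groups
  frac <- vapply(gs, function(x) x$n_observed / x$n, 0)
  if (any(frac < cfg$min_group_fraction) ||
      any(vapply(gs, function(x) x$n_observed, 0L) == 0L)) {
    return(list(category = "UNCLASSIFIED", groups = character(0),
                subtype = NA_character_, reason = "insufficient data",
                sets = lapply(gs, `[[`, "set")))
  }
  strict <- lapply(gs, `[[`, "set")
  res <- classify_sets(strict)
  res$sets <- strict
  if (res$category == "UNCLASSIFIED" && cfg$tolerance > 0) {
    relaxed <- lapply(gs, function(x) .tolerant_set(x$counts, cfg$tolerance))
    res2 <- classify_sets(relaxed)
    if (res2$category != "UNCLASSIFIED") {
      res2$sets <- relaxed
      return(res2)
    }
  }
  res
}

#' Human-readable category label
#'
#' `"UNIVERSAL"`, `"PAIR(Archaea+Eukaryota)"`, `"ONLY(Eukaryota)"`, ...
#'
#' @param category Category string.
#' @param groups Character vector of involved group labels.
#' @return Character scalar.
#' @export
category_label <- function(category, groups) {
  if (category %in% c("UNIVERSAL", "UNCLASSIFIED") || length(groups) == 0L) {
    return(category)
  }
  paste0(category, "(", paste(sort(groups), collapse = "+"), ")")
}

#' Scan an alignment for signature columns
#'
#' Builds a per-group profile for every scannable column, classifies it,
#' and returns one site row per classified column.  Output is ordered by
#' column and is invariant under permutation of the alignment records.
#'
#' @param a A [sig_alignment()].
#' @param g A group map (validated against `a`).
#' @param mask Optional `sig_mask` of columns excluded from scanning.
#' @param cfg A [scan_config()].
#' @param refs Optional named list of [build_coord_index()] objects; one
#'   coordinate column per reference is added (`coord_<name>`).
#' @return Data frame of class `sig_sites`: `column`, `category`,
#'   `groups` (comma-joined sorted labels), `label`, `subtype`, one
#'   `code_<group>` column per group (IUPAC consensus of the set used in
#'   classification), and `coord_<ref>` columns.
#' @export
scan_alignment <- function(a, g, mask = NULL, cfg = scan_config(),
                           refs = NULL) {
  g <- validate_group_map(g, a)
  group_labels <- sort(unique(unclass(g)))
  cols <- apply_mask(a, mask)
  rows <- vector("list", length(cols))
  n_out <- 0L
  for (col in cols) {
    p <- column_profile(a, g, col)
    res <- classify_profile(p, cfg)
    if (res$category == "UNCLASSIFIED") next
    if (res$category == "UNIVERSAL" && !cfg$include_universal) next
    codes <- vapply(group_labels, function(lb) {
      s <- res$sets[[lb]]
      if (length(s) == 0L) NA_character_ else encode_iupac(s)
    }, "")
    row <- c(
      list(column = col,
           category = res$category,
           groups = paste(res$groups, collapse = ","),
           label = category_label(res$category, res$groups),
           subtype = res$subtype),
      stats::setNames(as.list(codes), paste0("code_", group_labels))
    )
    if (!is.null(refs)) {
      coords <- vapply(refs, function(idx) {
        format_ref_coord(column_to_ref(idx, col))
      }, "")
      row <- c(row, stats::setNames(as.list(coords),
                                    paste0("coord_", names(refs))))
    }
    n_out <- n_out + 1L
    rows[[n_out]] <- row
  }
  rows <- rows[seq_len(n_out)]
  if (n_out == 0L) {
    df <- data.frame(column = integer(0), category = character(0),
                     groups = character(0), label = character(0),
                     subtype = character(0))
  } else {
    df <- do.call(rbind, lapply(rows, function(r) {
      as.data.frame(r, stringsAsFactors = FALSE)
    }))
  }
  rownames(df) <- NULL
  attr(df, "group_labels") <- group_labels
  class(df) <- c("sig_sites", class(df))
  df
}

#' Merge runs of adjacent sites with identical category
#'
#' Composite signatures spanning adjacent columns (e.g. a gap column
#' followed by a diagnostic base column) are reported as one locus:
#' runs of consecutive columns with the same category/groups are
#' collapsed, concatenating the per-group codes in column order.  Used
#' for report output; site-level results keep one row per column.
#'
#' @param sites A `sig_sites` data frame.
#' @return Data frame with `column_start`, `column_end`, `n_columns`,
#'   `category`, `groups`, `label`, `subtype` (`INDEL` if any merged
#'   column is an indel), concatenated `code_*` columns, and
#'   first/last `coord_*` columns when present.
#' @export
merge_sites <- function(sites) {
  if (nrow(sites) == 0L) {
    return(data.frame(column_start = integer(0), column_end = integer(0),
                      n_columns = integer(0), category = character(0),
                      groups = character(0), label = character(0),
                      subtype = character(0)))
  }
  key <- paste(sites$category, sites$groups)
  new_run <- c(TRUE, diff(sites$column) != 1L | key[-1] != key[-nrow(sites)])
  run_id <- cumsum(new_run)
  code_cols <- grep("^code_", names(sites), value = TRUE)
  coord_cols <- grep("^coord_", names(sites), value = TRUE)
  out <- lapply(split(seq_len(nrow(sites)), run_id), function(i) {
    block <- sites[i, , drop = FALSE]
    row <- data.frame(
      column_start = min(block$column),
      column_end = max(block$column),
      n_columns = nrow(block),
      category = block$category[1],
      groups = block$groups[1],
      label = block$label[1],
      subtype = if (any(block$subtype == "INDEL", na.rm = TRUE)) "INDEL"
                else block$subtype[1],
      stringsAsFactors = FALSE
    )
    for (cc in code_cols) row[[cc]] <- paste(block[[cc]], collapse = "")
    for (cc in coord_cols) {
      row[[cc]] <- if (nrow(block) == 1L) block[[cc]][1] else
        paste0(block[[cc]][1], "..", block[[cc]][nrow(block)])
    }
    row
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-category site counts
#'
#' @param sites A `sig_sites` data frame.
#' @return Named integer vector of counts by category label, sorted by
#'   label for deterministic output.
#' @export
count_sites <- function(sites) {
  if (nrow(sites) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(sites$label)
  stats::setNames(as.integer(tab), names(tab))
}

#' Write a site table as TSV
#' @param sites Data frame (site-level or merged).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
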