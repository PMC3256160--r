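# Functional ribosome annotations (PTC, tRNA A/P/E sites, intersubunit
# bridges, antibiotic-resistance positions) are user-supplied BED-like
# files in a reference's published numbering; sites are joined to them
# through the coordinate index.

#' Read a functional annotation file
#'
#' BED-like records `ref <TAB> start <TAB> end <TAB> tags` where
#' start/end are 0-based half-open over the reference's *published*
#' numbering and tags are comma-separated labels (e.g.
#' `PTC,ANTIBIOTIC_RESISTANCE`).  Intervals are expanded to positions;
#' overlapping intervals union their tags.  All records must name the
#' same reference.
#'
#' @param path Path to the annotation file.
#' @return Data frame (`pos`, `tag`), one row per (position, tag) pair,
#'   with attribute `reference` (the reference id, `NA` when empty).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(structure(data.frame(pos = integer(0), tag = character(0)),
                     reference = NA_character_))
  }
  rows <- list()
  refs <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t")[[1]]
    if (length(f) < 4L || !nzchar(trimws(f[4]))) {
      stop("malformed annotation record (need ref, start, end, tags) ",
           "at line ", lineno[i], call. = FALSE)
    }
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s >= e) {
      stop("bad annotation interval at line ", lineno[i], call. = FALSE)
    }
    tags <- trimws(strsplit(f[4], ",")[[1]])
    refs <- c(refs, f[1])
    rows[[i]] <- expand.grid(pos = seq.int(s + 1L, e), tag = tags,
                             stringsAsFactors = FALSE)
  }
  if (length(unique(refs)) > 1L) {
    stop("annotation file mixes references: ",
         paste(unique(refs), collapse = ", "), call. = FALSE)
  }
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$pos, df$tag), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, reference = refs[1])
}

#' Attach functional tags to signature sites
#'
#' Each site's reference coordinate (recomputed from its alignment
#' column through `idx`) is looked up in the annotation: a point
#' coordinate takes the tags at its position; a flanked-gap locus takes
#' the tags of either flank when `match_flanks = TRUE`, otherwise none.
#' Unannotated sites get `"NONE"`.  Idempotent: annotating an already
#' annotated table recomputes the same column.
#'
#' @param sites A `sig_sites` data frame.
#' @param ann A [read_annotations()] result.
#' @param idx A [build_coord_index()] whose `ref` matches the
#'   annotation's reference.
#' @param match_flanks Also match the flanking bases of gap loci
#'   (default `FALSE`).
#' @return `sites` with a `functions` column (comma-joined sorted tags
#'   or `"NONE"`); every input row appears exactly once.
#' @export
overlap_sites <- function(sites, ann, idx, match_flanks = FALSE) {
  ref <- attr(ann, "reference")
  if (!is.na(ref) && ref != idx$ref) {
    stop("annotation reference '", ref, "' does not match index '",
         idx$ref, "'", call. = FALSE)
  }
  tags_at <- function(pos) {
    if (is.na(pos)) character(0) else ann$tag[ann$pos == pos]
  }
  fns <- vapply(sites$column, function(col) {
    rc <- column_to_ref(idx, col)
    tags <- if (rc$type == "POINT") {
      tags_at(rc$pos)
    } else if (match_flanks) {
      c(tags_at(rc$left_pos), tags_at(rc$right_pos))
    } else {
      character(0)
    }
    tags <- sort(unique(tags))
    if (length(tags) == 0L) "NONE" else paste(tags, collapse = ",")
  }, "")
  sites$functions <- fns
  sites
}

#' Contingency of site category by function tag
#'
#' Counts (category label, tag) pairs — a site with several tags counts
#' once per tag — with row/column margins, in sorted order.
#'
#' @param sites An [overlap_sites()] result (must have `functions`).
#' @return Integer matrix with `Total` margins; rows are category
#'   labels, columns function tags (including `NONE` when present).
#' @export
summarize_by_function <- function(sites) {
  if (is.null(sites$functions)) {
    stop("sites are not annotated; run overlap_sites() first", call. = FALSE)
  }
  if (nrow(sites) == 0L) {
    m <- matrix(0L, 1L, 1L, dimnames = list("Total", "Total"))
    return(m)
  }
  tag_list <- strsplit(sites$functions, ",", fixed = TRUE)
  long <- data.frame(
    label = rep(sites$label, lengths(tag_list)),
    tag = unlist(tag_list)
  )
  tab <- table(long$label, long$tag)
  tab <- tab[order(rownames(tab)), order(colnames(tab)), drop = FALSE]
  m <- stats::addmargins(tab, FUN = list(Total = sum), quiet = TRUE)
  out <- matrix(as.integer(m), nrow(m), ncol(m), dimnames = dimnames(m))
  names(dimnames(out)) <- c("category", "function")
  out
}
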