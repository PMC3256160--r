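# Alignment, group-map and mask I/O.  Alignments are stored as a
# character matrix (taxa x columns) over the five-symbol alphabet, with
# NA for residues treated as missing data.  File intervals (BED-like
# masks and annotations) are 0-based half-open; everything reported to
# the user is 1-based.  Conversion happens only at the I/O boundary.

#' Construct an alignment object from residue strings
#'
#' @param seqs Named character vector of aligned residue strings (equal
#'   lengths; unique names).
#' @return A `sig_alignment`: character matrix with taxa as rows,
#'   residues normalized via [normalize_residue()] (`NA` = missing).
#' @export
sig_alignment <- function(seqs) {
  if (length(seqs) == 0L) stop("alignment has no records", call. = FALSE)
  taxa <- names(seqs)
  if (is.null(taxa) || any(!nzchar(taxa))) {
    stop("every alignment record needs a taxon identifier", call. = FALSE)
  }
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup) > 0L) {
    stop("duplicate taxon identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- taxa[widths != widths[1]]  # first record sets the width
    stop("ragged alignment; offending taxa: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  m <- do.call(rbind, lapply(seqs, function(s) {
    normalize_residue(strsplit(s, "", fixed = TRUE)[[1]])
  }))
  rownames(m) <- taxa
  class(m) <- c("sig_alignment", class(m))
  m
}

#' @export
print.sig_alignment <- function(x, ...) {
  cat("Alignment:", nrow(x), "taxa x", ncol(x), "columns;",
      sum(is.na(x)), "missing residues\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param a A `sig_alignment`.
#' @return Integer column count.
#' @export
alignment_width <- function(a) ncol(a)

#' Read an aligned FASTA file
#'
#' Residues are normalized to `{A,C,G,T,-}` (U = T, `.` = `-`); IUPAC
#' ambiguity characters become missing data.  Ragged rows and duplicate
#' identifiers are rejected.
#'
#' @param path Path to an aligned FASTA file.
#' @return A [sig_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) {
    stop("alignment file not found: ", path, call. = FALSE)
  }
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))  # id = first token of header
  sig_alignment(seqs)
}

#' Write an alignment to aligned FASTA
#'
#' Missing residues are written as `N` (they read back as missing).
#'
#' @param a A `sig_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(a, path) {
  m <- unclass(a)
  m[is.na(m)] <- "N"
  seqs <- apply(m, 1L, paste, collapse = "")
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Read a taxon-to-group map
#'
#' Two-column TSV (taxon, group label); `#` comment lines and CRLF line
#' endings are tolerated.
#'
#' @param path Path to the TSV.
#' @return Named character vector mapping taxon id to group label.
#' @export
read_group_map <- function(path) {
  if (!file.exists(path)) {
    stop("group map file not found: ", path, call. = FALSE)
  }
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          comment.char = "#", quote = "",
                          col.names = c("taxon", "group"),
                          colClasses = "character")
  if (nrow(df) == 0L) stop("group map is empty: ", path, call. = FALSE)
  group_map(stats::setNames(df$group, df$taxon))
}

#' Construct/validate a group map from a named vector
#'
#' A taxon listed twice with conflicting labels is an error; consistent
#' repeats collapse to one entry.
#'
#' @param assignments Named character vector, taxon id -> group label.
#' @return Named character vector of class `sig_group_map`.
#' @export
group_map <- function(assignments) {
  taxa <- names(assignments)
  if (is.null(taxa)) stop("group map needs taxon names", call. = FALSE)
  for (t in unique(taxa[duplicated(taxa)])) {
    if (length(unique(assignments[taxa == t])) > 1L) {
      stop("taxon '", t, "' assigned to more than one group", call. = FALSE)
    }
  }
  g <- assignments[!duplicated(taxa)]
  class(g) <- "sig_group_map"
  g
}

#' Check that a group map covers an alignment
#'
#' @param g A group map.
#' @param a A `sig_alignment`.
#' @param min_group_size Minimum members per group (default 1).
#' @return `g` restricted to the alignment's taxa, invisibly usable.
#' @export
validate_group_map <- function(g, a, min_group_size = 1L) {
  missing <- setdiff(rownames(a), names(g))
  if (length(missing) > 0L) {
    stop("alignment taxa absent from group map: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g2 <- g[rownames(a)]
  class(g2) <- "sig_group_map"
  sizes <- table(unclass(g2))
  if (length(sizes) < 2L) {
    stop("group map must contain at least 2 distinct groups", call. = FALSE)
  }
  small <- names(sizes)[sizes < min_group_size]
  if (length(small) > 0L) {
    stop("groups below minimum size ", min_group_size, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  g2
}

#' Write a group map as TSV
#' @param g Group map.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_group_map <- function(g, path) {
  utils::write.table(data.frame(taxon = names(g), group = unclass(g)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a region mask from intervals
#'
#' Intervals are 0-based half-open (BED convention) over alignment
#' columns; overlapping/adjacent intervals are merged into one sorted
#' column set, stored 1-based internally.
#'
#' @param starts,ends Integer vectors, 0-based half-open.
#' @param width Optional alignment width for bounds checking.
#' @return Sorted integer vector of masked columns (1-based), class
#'   `sig_mask`.
#' @export
region_mask <- function(starts, ends, width = NULL) {
  stopifnot(length(starts) == length(ends))
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (any(is.na(starts) | is.na(ends))) {
    stop("mask intervals contain non-integer coordinates", call. = FALSE)
  }
  bad <- which(starts >= ends)
  if (length(bad) > 0L) {
    stop("mask interval with start >= end at record ", bad[1], call. = FALSE)
  }
  if (any(starts < 0L)) stop("negative mask coordinates", call. = FALSE)
  cols <- sort(unique(unlist(mapply(function(s, e) seq.int(s + 1L, e),
                                    starts, ends, SIMPLIFY = FALSE))))
  if (length(cols) == 0L) cols <- integer(0)
  if (!is.null(width) && length(cols) > 0L && max(cols) > width) {
    stop("mask extends beyond alignment width ", width, call. = FALSE)
  }
  structure(as.integer(cols), class = "sig_mask")
}

#' Read a BED-like region mask
#'
#' Three columns (name, start, end), 0-based half-open; `#` comments and
#' CRLF tolerated.  An empty file yields an empty mask.  When `index`
#' (a [build_coord_index()] result) is supplied, start/end are taken as
#' *reference positions* in that index's published numbering and lifted
#' to alignment columns; an interval spanning a reference gap masks all
#' alignment columns between the mapped flanks.
#'
#' @param path Path to the BED-like file.
#' @param index Optional coordinate index for reference-space masks.
#' @param width Optional alignment width for bounds checking.
#' @return A `sig_mask` (possibly empty).
#' @export
read_mask <- function(path, index = NULL, width = NULL) {
  if (!file.exists(path)) stop("mask file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines, which = "right")  # strip CR
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(region_mask(integer(0), integer(0)))
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 3L)) {
    stop("mask records need 3 columns (name, start, end)", call. = FALSE)
  }
  starts <- as.integer(vapply(parts, `[[`, "", 2L))
  ends <- as.integer(vapply(parts, `[[`, "", 3L))
  if (is.null(index)) {
    return(region_mask(starts, ends, width = width))
  }
  # reference-space interval [s, e) = published positions s+1 .. e
  cols <- unlist(mapply(function(s, e) {
    if (s >= e) stop("mask interval with start >= end", call. = FALSE)
    c1 <- ref_to_column(index, s + 1L)
    c2 <- ref_to_column(index, e)
    seq.int(c1, c2)
  }, starts, ends, SIMPLIFY = FALSE))
  structure(sort(unique(as.integer(cols))), class = "sig_mask")
}

#' Write a mask as a BED-like file (0-based half-open, merged runs)
#' @param m A `sig_mask`.
#' @param path Output path.
#' @param name Interval name column value.
#' @return `path`, invisibly.
#' @export
write_mask <- function(m, path, name = "mask") {
  cols <- as.integer(m)
  if (length(cols) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  runs <- split(cols, cumsum(c(1L, diff(cols) != 1L)))
  df <- data.frame(
    name = name,
    start = vapply(runs, min, 1L) - 1L,
    end = vapply(runs, max, 1L)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Scannable columns of an alignment under a mask
#'
#' The alignment is never mutated; masked and scannable columns
#' partition the full column range.
#'
#' @param a A `sig_alignment`.
#' @param m A `sig_mask` or `NULL` (no masking).
#' @return Sorted integer vector of scannable columns (1-based).
#' @export
apply_mask <- function(a, m = NULL) {
  cols <- seq_len(ncol(a))
  if (is.null(m) || length(m) == 0L) return(cols)
  setdiff(cols, as.integer(m))
}
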