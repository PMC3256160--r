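# Mapping between alignment columns and ungapped reference numbering.
# Published rRNA numbering (E. coli 16S/23S, yeast 18S/25S) is a
# convention that cannot be derived from sequence alone, so the index
# carries a user-set offset added to every reported position.

#' Build a column/reference-position index from a reference row
#'
#' Positions count non-gap reference residues, 1-based; a column before
#' the first reference base has cumulative position 0.  `offset` is
#' added to all *reported* positions, reconciling the local ungapped
#' index with published numbering.
#'
#' @param a A [sig_alignment()].
#' @param ref_taxon Taxon identifier of the reference row.
#' @param offset Integer added to reported positions (default 0).
#' @return A `sig_coord_index` list: `ref`, `offset`, `col_to_pos`
#'   (cumulative position per column), `pos_to_col`, `bases` (reference
#'   base per position; missing residues count as a base, shown as `N`),
#'   `width`, `ref_length`.
#' @export
build_coord_index <- function(a, ref_taxon, offset = 0L) {
  if (!ref_taxon %in% rownames(a)) {
    stop("reference taxon not in alignment: ", ref_taxon, call. = FALSE)
  }
  row <- unclass(a)[ref_taxon, ]
  base_chr <- ifelse(is.na(row), "N", row)  # ambiguous residue still occupies a position
  is_base <- base_chr != "-"
  if (!any(is_base)) {
    stop("reference contains no bases: ", ref_taxon, call. = FALSE)
  }
  col_to_pos <- cumsum(is_base)
  pos_to_col <- which(is_base)
  structure(list(
    ref = ref_taxon,
    offset = as.integer(offset),
    col_to_pos = as.integer(col_to_pos),
    pos_to_col = as.integer(pos_to_col),
    bases = base_chr[is_base],
    width = length(row),
    ref_length = length(pos_to_col)
  ), class = "sig_coord_index")
}

#' Map an alignment column to a reference coordinate
#'
#' A column where the reference has a base maps to a point coordinate
#' (base, published position).  A column where the reference has a gap
#' maps to a flanked-gap locus: the nearest reference bases to the left
#' and right.  A leading/trailing reference gap yields an open flank
#' with the absent side marked.
#'
#' @param idx A `sig_coord_index`.
#' @param col Alignment column (1-based).
#' @return A `sig_ref_coord` list: `type` (`"POINT"` or `"FLANK"`) plus
#'   `base`/`pos`, or `left_base`/`left_pos`/`right_base`/`right_pos`
#'   (`NA` for an absent side).  Positions include the offset.
#' @export
column_to_ref <- function(idx, col) {
  col <- as.integer(col)
  if (col < 1L || col > idx$width) {
    stop("column out of range: ", col, call. = FALSE)
  }
  p <- idx$col_to_pos[col]
  if (p > 0L && idx$pos_to_col[p] == col) {
    return(structure(list(type = "POINT", base = idx$bases[p],
                          pos = p + idx$offset), class = "sig_ref_coord"))
  }
  left <- if (p >= 1L) list(base = idx$bases[p], pos = p + idx$offset)
          else list(base = NA_character_, pos = NA_integer_)
  rp <- p + 1L
  right <- if (rp <= idx$ref_length) list(base = idx$bases[rp],
                                          pos = rp + idx$offset)
           else list(base = NA_character_, pos = NA_integer_)
  structure(list(type = "FLANK",
                 left_base = left$base, left_pos = left$pos,
                 right_base = right$base, right_pos = right$pos),
            class = "sig_ref_coord")
}

#' Map a published reference position back to its alignment column
#'
#' @param idx A `sig_coord_index`.
#' @param pos Published (offset-inclusive) 1-based reference position.
#' @return The unique alignment column carrying that base.
#' @export
ref_to_column <- function(idx, pos) {
  local <- as.integer(pos) - idx$offset
  if (is.na(local) || local < 1L || local > idx$ref_length) {
    stop("reference position out of range: ", pos,
         " (reference '", idx$ref, "' spans ",
         1L + idx$offset, "..", idx$ref_length + idx$offset, ")",
         call. = FALSE)
  }
  idx$pos_to_col[local]
}

#' Render a reference coordinate in report style
#'
#' Point coordinates render as base+position (`"T358"`); flanked-gap
#' loci as `"(A412)-(T413)"`.  An absent flank renders as `(5')` or
#' `(3')`.
#'
#' @param rc A `sig_ref_coord`.
#' @return Character scalar.
#' @export
format_ref_coord <- function(rc) {
  if (rc$type == "POINT") {
    return(paste0(rc$base, rc$pos))
  }
  left <- if (is.na(rc$left_pos)) "(5')" else
    paste0("(", rc$left_base, rc$left_pos, ")")
  right <- if (is.na(rc$right_pos)) "(3')" else
    paste0("(", rc$right_base, rc$right_pos, ")")
  paste0(left, "-", right)
}

#' @export
print.sig_coord_index <- function(x, ...) {
  cat("Coordinate index on '", x$ref, "': ", x$ref_length,
      " bases over ", x$width, " columns, offset ", x$offset, "\n", sep = "")
  invisible(x)
}
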