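# Bridge from a published signature table (rows of per-group IUPAC
# consensus codes) to the column classifier.  Each table cell is a
# short string of single-character codes — one per alignment column of
# a possibly composite locus — or a flanked-gap locus like "(Y)-(A)",
# which denotes the absence of a base.

#' Tokenize one consensus-code cell into per-column codes
#'
#' A flanked-gap locus (`"(Y)-(A)"`, `"(C1203) - (A1204)"`) is one gap
#' column.  Any other cell is split into single characters, each a
#' one-column IUPAC code; a leading `-` before a code letter is its own
#' gap-state column of a composite locus (`"-Y"` = gap column then Y
#' column).
#'
#' @param cell Character scalar.
#' @return Character vector of single-column codes.
#' @export
tokenize_code_cell <- function(cell) {
  cell <- trimws(cell)
  if (!nzchar(cell)) stop("empty consensus-code cell", call. = FALSE)
  if (grepl("^\\(.+\\)\\s*-\\s*\\(.+\\)$", cell)) return("-")
  strsplit(cell, "", fixed = TRUE)[[1]]
}

#' Classify rows of a published-style signature table
#'
#' Each row carries one consensus code cell per group; cells are
#' tokenized into per-column codes, every column is classified with
#' [classify_sets()], and adjacent columns of a composite locus are
#' merged into the row's single call (they must agree on category).
#'
#' @param x Data frame, or path to a TSV with `#` comments.
#' @param code_cols Named character vector mapping group label ->
#'   column name in `x` holding that group's codes.  Default: columns
#'   `Bacteria`, `Archaea`, `Eukaryota` named after themselves.
#' @return `x` with appended `category`, `groups`, `label`, `subtype`
#'   columns; attribute `counts` holds per-label row counts.  An empty
#'   table yields an empty result with zero counts.
#' @export
classify_signature_table <- function(x, code_cols = NULL) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, sep = "\t", header = TRUE, comment.char = "#",
                           quote = "", colClasses = "character")
  }
  if (is.null(code_cols)) {
    code_cols <- stats::setNames(c("Bacteria", "Archaea", "Eukaryota"),
                                 c("Bacteria", "Archaea", "Eukaryota"))
  }
  missing_cols <- setdiff(unname(code_cols), names(x))
  if (length(missing_cols) > 0L) {
    stop("table lacks code columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(x)
  category <- groups <- label <- subtype <- character(n)
  for (i in seq_len(n)) {
    tokens <- lapply(code_cols, function(cc) {
      tryCatch(tokenize_code_cell(x[[cc]][i]),
               error = function(e) stop("row ", i, ": ", conditionMessage(e),
                                        call. = FALSE))
    })
    lens <- lengths(tokens)
    if (length(unique(lens)) != 1L) {
      stop("row ", i, ": groups disagree on locus width (",
           paste(lens, collapse = ", "), ")", call. = FALSE)
    }
    calls <- lapply(seq_len(lens[1]), function(j) {
      sets <- lapply(tokens, function(tk) {
        tryCatch(decode_iupac(tk[j]),
                 error = function(e) stop("row ", i, ": ",
                                          conditionMessage(e), call. = FALSE))
      })
      names(sets) <- names(code_cols)
      classify_sets(sets)
    })
    cats <- vapply(calls, function(cl) category_label(cl$category, cl$groups), "")
    if (length(unique(cats)) != 1L) {
      stop("row ", i, ": composite locus columns disagree on category (",
           paste(cats, collapse = " vs "), ")", call. = FALSE)
    }
    category[i] <- calls[[1]]$category
    groups[i] <- paste(calls[[1]]$groups, collapse = ",")
    label[i] <- cats[1]
    subs <- vapply(calls, `[[`, "", "subtype")
    subtype[i] <- if (any(subs == "INDEL", na.rm = TRUE)) "INDEL"
                  else subs[1]
  }
  x$category <- category
  x$groups <- groups
  x$label <- label
  x$subtype <- subtype
  counts <- if (n > 0L) table(label) else table(character(0))
  attr(x, "counts") <- stats::setNames(as.integer(counts), names(counts))
  x
}
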