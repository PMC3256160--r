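# IUPAC degenerate-base set algebra over the five-symbol alphabet
# {A, C, G, T, -}.  The gap is a first-class symbol so that indel
# signatures are handled by the same machinery as substitutions.

#' The five-symbol nucleotide alphabet used throughout the package
#'
#' `"A"`, `"C"`, `"G"`, `"T"` plus the alignment gap `"-"`.  All residue
#' handling is done on this alphabet: U is identified with T and every
#' IUPAC ambiguity character in *input sequences* is treated as missing
#' data (see [normalize_residue()]).
#'
#' @format Character vector of length 5.
#' @export
SIG_ALPHABET <- c("A", "C", "G", "T", "-")

# IUPAC code -> base set (DNA alphabet, no gap).  Single source of truth
# for decode/encode.
.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# canonical ordering of a symbol set: A, C, G, T then gap
.canon_set <- function(x) {
  x <- unique(x)
  x[order(match(x, SIG_ALPHABET))]
}

#' Normalize a raw sequence character to the five-symbol alphabet
#'
#' Maps upper/lower case `a/c/g/t` to themselves, `u/U` to `T`, and the
#' gap glyphs `-` and `.` to `-`.  Every other character — including all
#' IUPAC ambiguity codes such as `N`, `Y`, `R` — is mapped to `NA`
#' (missing).  An ambiguous residue in raw data is treated as *no
#' observation* for its taxon at that column, never as evidence for
#' several bases: counting a sequencing `N` as all four bases would veto
#' genuine signature columns.  Ambiguity codes are used only on the
#' *output* side, to summarize group symbol sets (see [encode_iupac()]).
#'
#' @param raw Character vector of single characters (vectorized).
#' @return Character vector of the same length over
#'   `c("A","C","G","T","-")`, with `NA` for missing.
#' @examples
#' normalize_residue(c("u", ".", "N", "g"))
#' @export
normalize_residue <- function(raw) {
  key <- c(
    a = "A", A = "A", c = "C", C = "C", g = "G", G = "G",
    t = "T", T = "T", u = "T", U = "T", "-" = "-", "." = "-"
  )
  out <- unname(key[as.character(raw)])
  as.character(out)
}

#' Decode an IUPAC code (optionally gap-extended) into a symbol set
#'
#' Accepts the 15 standard IUPAC nucleotide codes, the bare gap `"-"`,
#' and the gap-extended form `"-X"` where a leading `-` adds the gap
#' symbol to the expansion of code `X` (e.g. `"-Y"` is \{-, C, T\}:
#' some taxa in the group carry a gap, the rest carry C or T).
#'
#' @param code A 1- or 2-character string.
#' @return Character vector: a subset of [SIG_ALPHABET] in canonical
#'   order.
#' @examples
#' decode_iupac("Y")   # C T
#' decode_iupac("-Y")  # C T -
#' decode_iupac("-")   # -
#' @export
decode_iupac <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, !is.na(code))
  code <- toupper(trimws(code))
  if (code == "-") {
    return("-")
  }
  gap <- startsWith(code, "-")
  base <- if (gap) substring(code, 2L) else code
  if (nchar(base) != 1L || is.null(.IUPAC_SETS[[base]])) {
    stop("unknown IUPAC code: '", code, "'", call. = FALSE)
  }
  .canon_set(c(.IUPAC_SETS[[base]], if (gap) "-"))
}

#' Encode a symbol set as an IUPAC code
#'
#' Inverse of [decode_iupac()].  A set containing the gap prints as
#' `"-"` alone (pure gap) or as `"-"` prefixed to the IUPAC code of its
#' base content, matching the printed-table convention for groups that
#' mix gaps and bases.
#'
#' @param s Character vector: a non-empty subset of [SIG_ALPHABET].
#' @return A 1- or 2-character string.
#' @examples
#' encode_iupac(c("A", "G"))       # "R"
#' encode_iupac("-")               # "-"
#' encode_iupac(c("-", "C", "T"))  # "-Y"
#' @export
encode_iupac <- function(s) {
  s <- .canon_set(s)
  if (length(s) == 0L) stop("cannot encode an empty symbol set", call. = FALSE)
  if (!all(s %in% SIG_ALPHABET)) {
    stop("symbols outside the {A,C,G,T,-} alphabet: ",
         paste(setdiff(s, SIG_ALPHABET), collapse = ", "), call. = FALSE)
  }
  gap <- "-" %in% s
  bases <- setdiff(s, "-")
  if (length(bases) == 0L) {
    return("-")
  }
  code <- NULL
  for (k in names(.IUPAC_SETS)) {
    if (setequal(.IUPAC_SETS[[k]], bases)) {
      code <- k
      break
    }
  }
  if (gap) paste0("-", code) else code
}

#' All decodable IUPAC codes, including gap extensions
#'
#' The 15 base codes, `"-"`, and the 15 `"-X"` gap extensions; mainly
#' useful for exhaustive round-trip checks.
#'
#' @return Character vector of 31 codes.
#' @export
iupac_codes <- function() {
  base <- names(.IUPAC_SETS)
  c(base, "-", paste0("-", base))
}
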