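# End-to-end drivers tying the stages together: scan a real alignment,
# generate-and-self-test synthetic data, classify a published-style
# table.  Data goes to files, diagnostics to standard error, so TSV
# outputs stay pipeable.

.log <- function(...) message("[rrnasig] ", ...)

#' Run the full signature scan pipeline
#'
#' Reads the alignment, group map and optional mask/annotations,
#' scans, and (when `out_dir` is given) writes `sites.tsv` (one row
#' per column), `sites_merged.tsv` (adjacent same-category runs
#' collapsed), and `summary.json` with per-category counts.  Identical
#' inputs and configuration produce byte-identical outputs.
#'
#' @param alignment Path to an aligned FASTA, or a [sig_alignment()].
#' @param groups Path to a taxon/group TSV, or a [group_map()].
#' @param mask Optional path to a BED-like mask, or a `sig_mask`.
#'   File masks are interpreted in alignment columns unless
#'   `mask_reference` names one of `refs`.
#' @param refs Named list describing reference numberings, each element
#'   `list(taxon =, offset =)`; e.g.
#'   `list(Ecoli = list(taxon = "E_coli", offset = 0))`.
#' @param annotations Optional path to a functional annotation file
#'   (BED-like with a tags column) in the numbering of
#'   `annotation_reference`.
#' @param annotation_reference Name (in `refs`) of the reference the
#'   annotation file uses; defaults to the first.
#' @param mask_reference Optional name in `refs`: interpret the mask
#'   file in that reference's published coordinates.
#' @param config A [scan_config()].
#' @param match_flanks Passed to [overlap_sites()].
#' @param out_dir Optional output directory.
#' @return List: `sites`, `merged`, `summary` (per-category counts),
#'   `indexes` (coordinate indexes), invisibly.
#' @export
run_scan <- function(alignment, groups, mask = NULL, refs = NULL,
                     annotations = NULL, annotation_reference = NULL,
                     mask_reference = NULL, config = scan_config(),
                     match_flanks = FALSE, out_dir = NULL) {
  a <- if (inherits(alignment, "sig_alignment")) alignment
       else read_alignment(alignment)
  g <- if (inherits(groups, "sig_group_map")) groups
       else read_group_map(groups)
  g <- validate_group_map(g, a)
  indexes <- NULL
  if (!is.null(refs)) {
    indexes <- lapply(refs, function(r) {
      build_coord_index(a, r$taxon, offset = if (is.null(r$offset)) 0L
                                             else r$offset)
    })
  }
  m <- NULL
  if (!is.null(mask)) {
    if (inherits(mask, "sig_mask")) {
      m <- mask
    } else {
      idx <- if (!is.null(mask_reference)) indexes[[mask_reference]] else NULL
      m <- read_mask(mask, index = idx, width = ncol(a))
    }
    .log("masked columns: ", length(m))
  }
  sites <- scan_alignment(a, g, mask = m, cfg = config, refs = indexes)
  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    ref_name <- if (is.null(annotation_reference)) names(indexes)[1]
                else annotation_reference
    if (is.null(indexes) || is.null(indexes[[ref_name]])) {
      stop("annotations need a coordinate reference; supply refs=",
           call. = FALSE)
    }
    sites <- overlap_sites(sites, ann, indexes[[ref_name]],
                           match_flanks = match_flanks)
  }
  merged <- merge_sites(sites)
  summary <- count_sites(sites)
  .log("scanned ", length(apply_mask(a, m)), " columns; ",
       nrow(sites), " sites (", nrow(merged), " merged loci)")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_sites(sites, file.path(out_dir, "sites.tsv"))
    write_sites(merged, file.path(out_dir, "sites_merged.tsv"))
    jsonlite::write_json(
      list(n_sites = nrow(sites), n_merged_loci = nrow(merged),
           counts = as.list(summary)),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(list(sites = sites, merged = merged, summary = summary,
                 indexes = indexes))
}

#' Generate a synthetic dataset, optionally self-testing recovery
#'
#' Writes the dataset via [write_synthetic()] when `out_dir` is given;
#' with `self_test = TRUE` immediately scans the generated alignment
#' (masked junk columns excluded) and scores it against the truth
#' table, writing `recovery.tsv`.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Optional output directory.
#' @param self_test Scan-and-score after generating (default `FALSE`).
#' @param scan_cfg Scanner settings for the self test.
#' @return List: the generated dataset plus, under `recovery`, the
#'   [evaluate_recovery()] report when requested; invisibly.
#' @export
run_synth <- function(cfg, out_dir = NULL, self_test = FALSE,
                      scan_cfg = scan_config()) {
  dataset <- generate_alignment(cfg)
  .log("generated ", nrow(dataset$alignment), " taxa x ",
       ncol(dataset$alignment), " columns (seed ", cfg$seed, ")")
  if (!is.null(out_dir)) write_synthetic(dataset, out_dir)
  recovery <- NULL
  if (self_test) {
    sites <- scan_alignment(dataset$alignment, dataset$groups,
                            mask = dataset$mask, cfg = scan_cfg)
    recovery <- evaluate_recovery(sites, dataset$truth)
    .log("self-test: min sensitivity ",
         format(min(recovery$summary$sensitivity), digits = 4),
         ", min precision ",
         format(min(recovery$summary$precision, na.rm = TRUE), digits = 4))
    if (!is.null(out_dir)) {
      utils::write.table(recovery$summary,
                         file.path(out_dir, "recovery.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(c(dataset, list(recovery = recovery)))
}
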