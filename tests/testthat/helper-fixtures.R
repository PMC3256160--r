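# Small in-code fixtures shared across test files.

demo_path <- function(name) {
  system.file("extdata", name, package = "rrnasig")
}

demo_refs <- function() {
  list(Ecoli = list(taxon = "Ecoli", offset = 353L),
       Scer = list(taxon = "Scer", offset = 411L))
}

# three-group toy alignment built column-wise from a list of
# per-column residue vectors (B1,B2,A1,A2,E1,E2 by default)
toy_alignment <- function(cols,
                          taxa = c("B1", "B2", "A1", "A2", "E1", "E2"),
                          groups = c("Bacteria", "Bacteria", "Archaea",
                                     "Archaea", "Eukaryota", "Eukaryota")) {
  m <- do.call(cbind, cols)
  seqs <- stats::setNames(apply(m, 1L, paste, collapse = ""), taxa)
  list(alignment = sig_alignment(seqs),
       groups = group_map(stats::setNames(groups, taxa)))
}

# tiny synthetic config for fast tests
tiny_synth <- function(...) {
  synth_config(group_sizes = c(Bacteria = 8L, Archaea = 5L, Eukaryota = 7L),
               n_universal = 3L,
               n_pair = c("Archaea+Eukaryota" = 4L),
               n_pair_indel = c("Archaea+Eukaryota" = 2L),
               n_only = c(Eukaryota = 3L),
               n_only_indel = c(Archaea = 2L),
               n_background = 0L, n_masked = 2L, ...)
}
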