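Package: rrnasig
Title: Kingdom-Signature Nucleotide Detection in Ribosomal RNA Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans masked multiple sequence alignments of ribosomal DNA,
    partitioned into taxonomic groups (e.g. Bacteria, Archaea, Eukaryota),
    for columns whose residues are exclusively shared between a pair of
    groups or specific to a single group.  Columns are classified with an
    IUPAC degenerate-base set algebra in which the alignment gap is a
    first-class symbol, so indel signatures and substitution signatures
    fall out of one scheme.  Detected sites are mapped to ungapped
    reference numbering (e.g. E. coli 16S/23S, S. cerevisiae 18S/25S),
    joined to functional ribosome annotations (peptidyl transferase
    centre, tRNA A/P/E sites, intersubunit bridges, antibiotic-resistance
    positions), and reported in a publication-style table.  A planted
    signature alignment simulator with a truth table makes every stage
    testable without sequence downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
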