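make_ann <- function(lines) {
  f <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("annotation records expand intervals and union overlapping tags", {
  ann <- read_annotations(make_ann(c(
    "# demo", "Ecoli\t2057\t2058\tPTC,ANTIBIOTIC_RESISTANCE",
    "Ecoli\t2050\t2060\tPTC")))
  expect_identical(attr(ann, "reference"), "Ecoli")
  at2058 <- sort(ann$tag[ann$pos == 2058L])
  expect_identical(at2058, c("ANTIBIOTIC_RESISTANCE", "PTC"))
  expect_identical(sort(unique(ann$pos)), 2051:2060)

  empty <- read_annotations(make_ann(character(0)))
  expect_identical(nrow(empty), 0L)

  expect_error(read_annotations(make_ann("Ecoli\t10\t12")), "line 1")
  expect_error(read_annotations(make_ann(c("Ecoli\t1\t2\tPTC",
                                           "Ecoli\t9\t3\tPTC"))), "line 2")
  expect_error(read_annotations(make_ann(c("r1\t1\t2\tPTC",
                                           "r2\t1\t2\tPTC"))),
               "mixes references")
})

test_that("sites pick up tags at their reference position", {
  # 6-column toy: reference gap at column 3
  toy <- toy_alignment(list(
    c("A", "A", "A", "A", "A", "A"),
    c("C", "T", "G", "G", "G", "G"),   # PAIR(A,E) at ref pos 2
    c("-", "-", "-", "-", "A", "A"),   # euk-only insertion, ref gap
    c("G", "G", "G", "G", "G", "G"),
    c("T", "T", "-", "-", "-", "-"),   # PAIR(A,E) indel at ref pos 4
    c("C", "C", "C", "C", "C", "C")),
    taxa = c("Ecoli", "B2", "A1", "A2", "E1", "E2"),
    groups = c("Bacteria", "Bacteria", "Archaea", "Archaea",
               "Eukaryota", "Eukaryota"))
  idx <- build_coord_index(toy$alignment, "Ecoli")
  sites <- scan_alignment(toy$alignment, toy$groups)
  ann <- read_annotations(make_ann(c("Ecoli\t1\t2\tA_SITE",
                                     "Ecoli\t3\t4\tPTC,BRIDGE")))
  got <- overlap_sites(sites, ann, idx)
  expect_identical(nrow(got), nrow(sites))          # conservation of sites
  expect_identical(got$functions[got$column == 2L], "A_SITE")
  expect_identical(got$functions[got$column == 5L], "BRIDGE,PTC")
  expect_identical(got$functions[got$column == 1L], "NONE")

  # flanked-gap locus: tags only attach when flank matching is on
  ann2 <- read_annotations(make_ann("Ecoli\t1\t2\tE_SITE"))
  off <- overlap_sites(sites, ann2, idx, match_flanks = FALSE)
  on <- overlap_sites(sites, ann2, idx, match_flanks = TRUE)
  expect_identical(off$functions[off$column == 3L], "NONE")
  expect_identical(on$functions[on$column == 3L], "E_SITE")

  # idempotence
  expect_identical(overlap_sites(got, ann, idx), got)

  # reference mismatch
  idx2 <- build_coord_index(toy$alignment, "B2")
  expect_error(overlap_sites(sites, ann, idx2), "does not match")
})

test_that("function summaries cross-tabulate categories with margins", {
  sites <- data.frame(
    column = 1:3,
    category = c("PAIR", "PAIR", "UNIVERSAL"),
    groups = c("Archaea,Eukaryota", "Archaea,Eukaryota", ""),
    label = c("PAIR(Archaea+Eukaryota)", "PAIR(Archaea+Eukaryota)",
              "UNIVERSAL"),
    subtype = c("SUBSTITUTION", "SUBSTITUTION", NA),
    functions = c("PTC", "PTC", "BRIDGE"))
  tab <- summarize_by_function(sites)
  expect_identical(tab["PAIR(Archaea+Eukaryota)", "PTC"], 2L)
  expect_identical(tab["UNIVERSAL", "BRIDGE"], 1L)
  expect_equal(unname(tab[, "Total"]),
               unname(rowSums(tab[, colnames(tab) != "Total"])))
  expect_equal(unname(tab["Total", ]),
               unname(colSums(tab[rownames(tab) != "Total", ])))

  empty <- sites[0, ]
  expect_identical(sum(summarize_by_function(empty)), 0L)
  expect_error(summarize_by_function(sites[, names(sites) != "functions"]),
               "overlap_sites")
})

test_that("random contingency margins equal independently recomputed sums", {
  set.seed(12)
  labels <- c("UNIVERSAL", "PAIR(Archaea+Eukaryota)", "ONLY(Eukaryota)")
  tags <- c("PTC", "BRIDGE", "A_SITE,PTC", "NONE")
  sites <- data.frame(
    column = 1:40,
    category = "x", groups = "", subtype = NA,
    label = sample(labels, 40L, replace = TRUE),
    functions = sample(tags, 40L, replace = TRUE))
  tab <- summarize_by_function(sites)
  long_n <- sum(lengths(strsplit(sites$functions, ",")))
  expect_identical(tab["Total", "Total"], long_n)
  for (lb in labels) {
    expect_identical(
      unname(tab[lb, "Total"]),
      sum(lengths(strsplit(sites$functions[sites$label == lb], ","))))
  }
})
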