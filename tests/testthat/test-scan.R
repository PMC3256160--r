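test_that("column profiles equal a brute-force per-taxon tally", {
  set.seed(77)
  n <- 9L
  taxa <- sprintf("t%02d", 1:n)
  groups <- c(rep("Bacteria", 4L), rep("Archaea", 2L), rep("Eukaryota", 3L))
  chars <- c("A", "C", "G", "T", "-", "N", "u", ".")
  seqs <- vapply(taxa, function(t)
    paste(sample(chars, 25L, replace = TRUE), collapse = ""), "")
  a <- sig_alignment(seqs)
  g <- group_map(stats::setNames(groups, taxa))
  raw <- do.call(rbind, strsplit(seqs, ""))
  for (col in c(1L, 7L, 25L)) {
    p <- column_profile(a, g, col)
    for (lb in unique(groups)) {
      members <- taxa[groups == lb]
      expected <- normalize_residue(raw[match(members, taxa), col])
      expect_identical(p$groups[[lb]]$n_missing, sum(is.na(expected)))
      expect_identical(p$groups[[lb]]$n_observed, sum(!is.na(expected)))
      expect_true(setequal(p$groups[[lb]]$set,
                           unique(expected[!is.na(expected)])))
      expect_identical(p$groups[[lb]]$n_observed + p$groups[[lb]]$n_missing,
                       length(members))
    }
  }
})

test_that("classification reproduces the published sharing patterns", {
  # archaea+eukaryote substitution: bacterial Y vs shared G
  expect_identical(
    classify_sets(list(Bacteria = c("C", "T"), Archaea = "G",
                       Eukaryota = "G"))[c("category", "groups", "subtype")],
    list(category = "PAIR", groups = c("Archaea", "Eukaryota"),
         subtype = "SUBSTITUTION"))
  # archaea+eukaryote indel: both neomuran groups gapped
  expect_identical(
    classify_sets(list(Bacteria = c("A", "C", "T"), Archaea = "-",
                       Eukaryota = "-"))[c("category", "subtype")],
    list(category = "PAIR", subtype = "INDEL"))
  # bacteria+archaea indel against an unconstrained eukaryote column
  expect_identical(
    classify_sets(list(Bacteria = "-", Archaea = "-",
                       Eukaryota = c("A", "C", "G", "T")))[
                         c("category", "groups", "subtype")],
    list(category = "PAIR", groups = c("Archaea", "Bacteria"),
         subtype = "INDEL"))
  # degenerate eukaryote consensus D overlapping archaeal G
  expect_identical(
    classify_sets(list(Bacteria = "C", Archaea = "G",
                       Eukaryota = c("A", "G", "T")))$groups,
    c("Archaea", "Eukaryota"))
  expect_identical(
    classify_sets(list(B = "G", A = "G", E = "G"))$category, "UNIVERSAL")
  # all-gap column is not a signature
  expect_identical(
    classify_sets(list(B = "-", A = "-", E = "-"))$category, "UNCLASSIFIED")
})

test_that("pair calls are symmetric and respect monotonicity", {
  base <- list(Bacteria = c("C", "T"), Archaea = "G", Eukaryota = c("A", "G"))
  swapped <- base[c(1, 3, 2)]
  expect_identical(classify_sets(base)$groups, classify_sets(swapped)$groups)

  # enlarging the excluded group's set within itself keeps the call
  grown <- base
  grown$Bacteria <- c("C", "T")   # symbol already present
  expect_identical(classify_sets(grown)$category, "PAIR")
  # an excluded-group taxon carrying the shared symbol destroys it
  broken <- base
  broken$Bacteria <- c("C", "T", "G")
  expect_false(identical(classify_sets(broken)$category, "PAIR"))
})

test_that("insufficient per-group data leaves a column unclassified", {
  toy <- toy_alignment(list(
    c("G", "G", "N", "N", "G", "G"),   # archaea all missing
    c("G", "G", "G", "G", "G", "G")))
  p <- column_profile(toy$alignment, toy$groups, 1L)
  res <- classify_profile(p, scan_config())
  expect_identical(res$category, "UNCLASSIFIED")
  expect_identical(res$reason, "insufficient data")
  expect_identical(
    classify_profile(column_profile(toy$alignment, toy$groups, 2L),
                     scan_config())$category,
    "UNIVERSAL")
})

test_that("scan output is deterministic and record-order invariant", {
  d <- generate_alignment(tiny_synth(seed = 5L))
  s1 <- scan_alignment(d$alignment, d$groups, mask = d$mask)
  perm <- sample(nrow(d$alignment))
  a2 <- unclass(d$alignment)[perm, , drop = FALSE]
  class(a2) <- class(d$alignment)
  s2 <- scan_alignment(a2, d$groups, mask = d$mask)
  expect_identical(s1, s2)

  # identical sequences scan to universal columns only
  same <- sig_alignment(c(b1 = "ACGT", b2 = "ACGT", a1 = "ACGT",
                          e1 = "ACGT"))
  gm <- group_map(c(b1 = "B", b2 = "B", a1 = "A", e1 = "E"))
  s3 <- scan_alignment(same, gm)
  expect_identical(unique(s3$category), "UNIVERSAL")
  expect_identical(nrow(s3), 4L)
  s4 <- scan_alignment(same, gm,
                       cfg = scan_config(include_universal = FALSE))
  expect_identical(nrow(s4), 0L)
})

test_that("tolerance only adds sites, never removes strict calls", {
  cfg <- tiny_synth(seed = 9L)
  cfg$noise_rate <- 0.05
  d <- generate_alignment(cfg)
  strict <- scan_alignment(d$alignment, d$groups, mask = d$mask,
                           cfg = scan_config(tolerance = 0))
  tol <- scan_alignment(d$alignment, d$groups, mask = d$mask,
                        cfg = scan_config(tolerance = 0.2))
  strict_key <- paste(strict$column, strict$label)
  tol_key <- paste(tol$column, tol$label)
  expect_true(all(strict_key %in% tol_key))
})

test_that("classification generalizes to four groups", {
  sets4 <- list(W = "C", X = c("A", "G"), Y = "A", Z = c("A", "T"))
  res <- classify_sets(sets4)
  expect_identical(res$category, "SHARED")
  expect_identical(res$groups, c("X", "Y", "Z"))

  res2 <- classify_sets(list(W = "C", X = "G", Y = c("A", "G"), Z = "T"))
  expect_identical(res2$category, "PAIR")
  expect_identical(res2$groups, c("X", "Y"))

  res3 <- classify_sets(list(W = "-", X = c("A", "G"), Y = c("C", "A"),
                             Z = c("T", "C")))
  expect_identical(res3[c("category", "groups", "subtype")],
                   list(category = "ONLY", groups = "W", subtype = "INDEL"))
})

test_that("adjacent same-category sites merge into composite loci", {
  d <- toy_alignment(list(
    c("-", "-", "C", "G", "A", "C"),   # col 1: PAIR(A,E) vs bacterial gap
    c("C", "T", "G", "G", "G", "A"),   # col 2: PAIR(A,E) substitution
    c("G", "G", "G", "G", "G", "G"),   # col 3: universal
    c("A", "A", "-", "-", "-", "-")))  # col 4: PAIR(A,E) indel
  sites <- scan_alignment(d$alignment, d$groups)
  expect_identical(sites$column, 1:4)
  merged <- merge_sites(sites)
  expect_identical(nrow(merged), 3L)
  expect_identical(merged$column_start[1], 1L)
  expect_identical(merged$column_end[1], 2L)
  expect_identical(merged$code_Bacteria[1], "-Y")
  expect_identical(merged$code_Archaea[1], "SG")
  expect_identical(merged$subtype[3], "INDEL")
  expect_identical(nrow(merge_sites(sites[0, ])), 0L)
})
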