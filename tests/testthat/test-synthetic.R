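test_that("the same seed reproduces the dataset exactly", {
  d1 <- generate_alignment(tiny_synth(seed = 123L))
  d2 <- generate_alignment(tiny_synth(seed = 123L))
  expect_identical(d1$alignment, d2$alignment)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$mask, d2$mask)
  d3 <- generate_alignment(tiny_synth(seed = 124L))
  expect_false(identical(d1$alignment, d3$alignment))
})

test_that("generated data pass alignment and group-map validation", {
  d <- generate_alignment(tiny_synth(seed = 3L))
  expect_s3_class(d$alignment, "sig_alignment")
  expect_identical(ncol(d$alignment), nrow(d$truth))
  expect_identical(nrow(d$alignment), 20L)
  expect_no_error(validate_group_map(d$groups, d$alignment,
                                     min_group_size = 5L))
  dir <- withr::local_tempdir()
  write_synthetic(d, dir)
  back <- read_alignment(file.path(dir, "alignment.fasta"))
  expect_identical(unclass(back), unclass(d$alignment))
  gm <- read_group_map(file.path(dir, "groups.tsv"))
  expect_identical(unclass(gm), unclass(d$groups))
  expect_identical(as.integer(read_mask(file.path(dir, "mask.bed"))),
                   as.integer(d$mask))
})

test_that("noise-free planted signatures are recovered exactly", {
  d <- generate_alignment(tiny_synth(seed = 21L))
  sites <- scan_alignment(d$alignment, d$groups, mask = d$mask)
  rec <- evaluate_recovery(sites, d$truth)
  expect_true(all(rec$summary$sensitivity == 1))
  expect_true(all(rec$summary$precision == 1))
  # and nothing is reported beyond the planted columns
  planted <- d$truth$column[!d$truth$category %in% c("BACKGROUND", "MASKED")]
  expect_true(all(sites$column %in% planted))
})

test_that("a signature-free alignment scans to universal columns only", {
  cfg <- synth_config(group_sizes = c(Bacteria = 6L, Archaea = 4L,
                                      Eukaryota = 5L),
                      n_universal = 10L,
                      n_pair = c("Archaea+Eukaryota" = 0L),
                      n_pair_indel = c("Archaea+Eukaryota" = 0L),
                      n_only = c(Bacteria = 0L),
                      n_only_indel = c(Bacteria = 0L),
                      n_background = 0L, n_masked = 0L, seed = 8L)
  d <- generate_alignment(cfg)
  sites <- scan_alignment(d$alignment, d$groups)
  expect_identical(unique(sites$category), "UNIVERSAL")
})

test_that("masking planted columns drops their sensitivity to zero", {
  d <- generate_alignment(tiny_synth(seed = 31L))
  pair_cols <- d$truth$column[d$truth$category == "PAIR"]
  big_mask <- structure(sort(unique(c(as.integer(d$mask), pair_cols))),
                        class = "sig_mask")
  sites <- scan_alignment(d$alignment, d$groups, mask = big_mask)
  rec <- evaluate_recovery(sites, d$truth)
  pair_rows <- rec$summary$category == "PAIR"
  expect_true(all(rec$summary$sensitivity[pair_rows] == 0))
  expect_true(all(rec$summary$sensitivity[!pair_rows] == 1))
})

test_that("tolerant scanning never loses sensitivity under matched noise", {
  for (seed in 1:5) {
    cfg <- tiny_synth(seed = seed)
    cfg$group_sizes <- c(Bacteria = 40L, Archaea = 15L, Eukaryota = 30L)
    cfg$noise_rate <- 0.02
    d <- generate_alignment(cfg)
    strict <- evaluate_recovery(
      scan_alignment(d$alignment, d$groups, mask = d$mask,
                     cfg = scan_config(tolerance = 0)), d$truth)
    tol <- evaluate_recovery(
      scan_alignment(d$alignment, d$groups, mask = d$mask,
                     cfg = scan_config(tolerance = 0.02)), d$truth)
    expect_true(all(tol$summary$sensitivity >= strict$summary$sensitivity))
  }
})

test_that("sensitivity does not increase with the noise rate", {
  sens_at <- function(noise, seed) {
    cfg <- tiny_synth(seed = seed)
    cfg$noise_rate <- noise
    d <- generate_alignment(cfg)
    rec <- evaluate_recovery(
      scan_alignment(d$alignment, d$groups, mask = d$mask), d$truth)
    mean(rec$summary$sensitivity)
  }
  for (seed in 1:5) {
    s <- vapply(c(0, 0.05, 0.25), sens_at, 0, seed = seed)
    expect_true(all(diff(s) <= 0))
  }
})

test_that("infeasible configurations are rejected before generation", {
  cfg <- synth_config(group_sizes = c(A = 3L, B = 3L, C = 3L, D = 3L,
                                      E = 3L))
  expect_error(generate_alignment(cfg), "infeasible")
  cfg0 <- synth_config(group_sizes = c(Bacteria = 4L, Archaea = 4L,
                                       Eukaryota = 4L),
                       n_universal = 0L,
                       n_pair = c("Archaea+Eukaryota" = 0L),
                       n_pair_indel = c("Archaea+Eukaryota" = 0L),
                       n_only = c(Bacteria = 0L),
                       n_only_indel = c(Bacteria = 0L),
                       n_background = 0L, n_masked = 0L)
  expect_error(generate_alignment(cfg0), "zero columns")
  expect_error(evaluate_recovery(
    data.frame(column = 999L, category = "PAIR", groups = "A,B",
               subtype = "SUBSTITUTION", label = "PAIR(A+B)"),
    generate_alignment(tiny_synth(seed = 2L))$truth), "provenance")
})
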