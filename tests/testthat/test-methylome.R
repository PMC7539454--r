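test_that("methylome files map status tokens and honour context filters", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("seqname\tposition\tstrand\tcontext\tstatus",
               "chr1\t100\t+\tCG\tM",
               "chr1\t142\t+\tCG\tU",
               "chr2\t7\t-\tCHG\tI"), f)
  s <- read_methylome(f, sample_id = "s1")
  expect_equal(unname(s$states), c(1, 0, 0.5))
  expect_equal(length(read_methylome(f, context = "CHH")$states), 0)
  expect_equal(unname(read_methylome(f, context = "CHG")$states), 0.5)

  writeLines(c("seqname\tposition\tstrand\tcontext\tstatus",
               "chr1\t100\t+\tCG\tX"), f)
  expect_error(read_methylome(f), "unknown status")
})

test_that("write/read round trip preserves the state map exactly", {
  set.seed(4)
  s <- mk_methylome("rt", sample(c(0, 0.5, 1), 500, replace = TRUE))
  f <- tempfile(fileext = ".tsv.gz")
  write_methylome(s, f)
  s2 <- read_methylome(f, sample_id = "rt")
  expect_identical(s2$states, s$states)
  expect_equal(s2$loci, s$loci)
})

test_that("duplicate loci and malformed positions are rejected", {
  loci <- data.frame(seqname = "chr1", position = c(5, 5), strand = "+",
                     context = "CG")
  expect_error(methylome("d", loci, c(0, 1)), "duplicate locus")
  expect_error(methylome("d", transform(loci, position = c(0, 1)),
                         c(0, 1)), "malformed position")
  expect_error(methylome("d", transform(loci, position = c(1, 2)),
                         c(0.3, 1)), "states must be")
})

test_that("binomial status calling uses the BY-adjusted upper tail", {
  counts <- data.frame(seqname = "chr1", position = 1:4, strand = "+",
                       context = "CG",
                       meth_reads = c(0, 20, 1, 0),
                       total_reads = c(20, 20, 20, 20))
  s <- call_states_binomial(counts, error_rate = 0.01)
  # zero successes -> p = 1 -> unmethylated; 20/20 -> p = 1e-40 -> methylated
  expect_equal(unname(s$states), c(0, 1, 0, 0))

  # all p = 1: no rejections whatever the fdr
  allu <- call_states_binomial(
    data.frame(seqname = "chr1", position = 1:10, strand = "+",
               context = "CG", meth_reads = 0, total_reads = 15),
    error_rate = 0.05, fdr = 0.99)
  expect_true(all(allu$states == 0))

  # monotone in meth_reads at fixed coverage
  mono <- call_states_binomial(
    data.frame(seqname = "chr1", position = 1:21, strand = "+",
               context = "CG", meth_reads = 0:20, total_reads = 20),
    error_rate = 0.01)
  expect_true(all(diff(unname(mono$states)) >= 0))

  expect_warning(
    call_states_binomial(
      data.frame(seqname = "chr1", position = 1:2, strand = "+",
                 context = "CG", meth_reads = c(0, 3),
                 total_reads = c(0, 10)), error_rate = 0.01),
    "zero coverage")
})

test_that("region filtering follows BED and GFF3 coordinate dialects", {
  s <- mk_methylome("r", c(1, 0, 0.5))  # positions 1, 2, 3... use custom loci
  s <- methylome("r", data.frame(seqname = "chr1",
                                 position = c(100, 150, 300),
                                 strand = "+", context = "CG"),
                 c(1, 0, 0.5))
  bed <- tempfile(fileext = ".bed")
  # BED is 0-based half-open: (99, 100) covers 1-based position 100 only
  writeLines("chr1\t99\t100", bed)
  expect_equal(unname(filter_by_regions(s, bed)$states), 1)
  writeLines("chr1\t0\t99", bed)  # 1-based 1..99: drops everything
  expect_equal(length(filter_by_regions(s, bed)$states), 0)
  writeLines("chr1\t100\t200", bed)  # 1-based 101..200: keeps 150 only
  expect_equal(filter_by_regions(s, bed)$loci$position, 150)

  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\texon\t100\t150\t.\t+\t.\tID=e1"), gff)
  expect_equal(filter_by_regions(s, gff)$loci$position, c(100, 150))

  expect_error(filter_by_regions(s, tempfile(fileext = ".xyz")),
               "unknown region file format")
  # output loci are always a subset of input loci
  kept <- filter_by_regions(s, gff)
  expect_true(all(names(kept$states) %in% names(s$states)))
})

test_that("state proportions count loci and pool p_bar_1", {
  s1 <- mk_methylome("a", c(0, 0, 1, 0.5))
  sp <- state_proportions(s1)
  expect_equal(unlist(sp$counts[, c("x1", "x2", "x3", "N")]),
               c(x1 = 2, x2 = 1, x3 = 1, N = 4))
  expect_equal(sp$p_bar_1, 0.5)

  s2 <- mk_methylome("b", c(rep(0, 6), rep(1, 4)))   # u/u proportion 0.6
  s3 <- mk_methylome("c", c(rep(0, 8), rep(1, 2)))   # u/u proportion 0.8
  expect_equal(state_proportions(list(s2, s3))$p_bar_1, 0.7)

  s4 <- mk_methylome("d", rep(0.5, 5))
  expect_equal(state_proportions(s4)$p_bar_1, 0)
  expect_error(state_proportions(mk_methylome("e", numeric(0))),
               "empty sample")
})
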