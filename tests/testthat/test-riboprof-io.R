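test_that("A-site offsets reproduce the footprint-size/frame table", {
  # (length, frame) -> offset; NA marks ambiguous cells whose reads are
  # discarded
  expected <- rbind(
    c(27, 15, 15, 18),
    c(28, 15, 15, 18),
    c(29, 15, NA, 18),
    c(30, 15, 18, 18),
    c(31, 15, 18, 18),
    c(32, NA, 18, 18),
    c(33, 18, 18, 18))
  tab <- asite_offset_table()
  for (row in seq_len(nrow(expected))) {
    len <- expected[row, 1]
    for (fr in 0:2) {
      got <- tab$offset[tab$length == len & tab$frame == fr]
      expect_identical(got, expected[row, fr + 2],
                       label = sprintf("offset(length=%d, frame=%d)", len, fr))
    }
  }
  expect_identical(nrow(tab), 21L)
  expect_identical(sum(is.na(tab$offset)), 2L)
})

test_that("footprints map to A-site codons or are discarded with a reason", {
  # length 28, frame 0 at 5' nt 0: A-site nt 15 -> codon 6
  m <- map_asite(0L, 28L)
  expect_identical(as.integer(m), 6L)
  # length 30, frame 1: offset 18
  m <- map_asite(1L, 30L)
  expect_identical(as.integer(m), (1L + 18L) %/% 3L + 1L)
  # ambiguous cells and unsupported lengths are discarded, with reasons
  m <- map_asite(c(0L, 1L, 3L), c(32L, 29L, 26L))
  expect_true(all(is.na(m)))
  expect_identical(attr(m, "discard_reason"),
                   c("ambiguous", "ambiguous", "length"))
})

test_that("aggregation reproduces a hand-filtered histogram", {
  # 10 records on a toy CDS, mapped by hand with the offset table:
  # pos5=0,len=28 (frame 0, off 15) -> codon 6   [x3]
  # pos5=12,len=27 (frame 0, off 15) -> codon 10
  # pos5=13,len=27 (frame 1, off 15) -> codon 10
  # pos5=14,len=27 (frame 2, off 18) -> codon 11
  # pos5=10,len=29 (frame 1) -> discard (ambiguous)
  # pos5=0,len=32  (frame 0) -> discard (ambiguous)
  # pos5=0,len=40  -> discard (length)
  # pos5=57,len=28 (frame 0, off 15) -> codon 25 > L -> out of range
  rec <- data.frame(
    gene_id = "toy",
    pos5   = c(0, 0, 0, 12, 13, 14, 10, 0, 0, 57),
    length = c(28, 28, 28, 27, 27, 27, 29, 32, 40, 28))
  agg <- aggregate_counts(rec, c(toy = 20L))
  counts <- agg$profiles$toy$counts
  expect_identical(agg$profiles$toy$L, 20L)
  expect_equal(counts[6 - 1], 3)
  expect_equal(counts[10 - 1], 2)
  expect_equal(counts[11 - 1], 1)
  expect_equal(sum(counts), 6)
  expect_equal(unname(agg$discards["ambiguous"]), 2L)
  expect_equal(unname(agg$discards["length"]), 1L)
  expect_equal(unname(agg$discards["out_of_range"]), 1L)
})

test_that("empty record sets give all-zero profiles", {
  agg <- aggregate_counts(data.frame(gene_id = character(),
                                     pos5 = integer(), length = integer()),
                          c(g1 = 12L))
  expect_equal(agg$profiles$g1$counts, rep(0, 11))
  expect_equal(agg$profiles$g1$total, 0)
})

test_that("normalization preserves shape and fixes the mean density", {
  # uniform counts: r_i equals the supplied mean density everywhere
  raw <- raw_profile("g", rep(7, 10))
  np <- normalize_profile(raw, 0.05)
  expect_equal(np$r, rep(0.05, 10))

  # counts (1,2,3,4) on L = 5: N = 0.05*4 = 0.2, r = (0.02,0.04,0.06,0.08)
  np <- normalize_profile(raw_profile("g", 1:4), 0.05)
  expect_equal(np$r, c(0.02, 0.04, 0.06, 0.08))
  expect_equal(np$N, 0.2)
  expect_equal(np$r_mean, 0.05, tolerance = 1e-12)
  expect_equal(sum(np$r), np$N, tolerance = 1e-12)
})

test_that("unphysical or empty profiles are rejected as genes", {
  # one codon hoarding the reads with a large ribosome load: density > 1
  raw <- raw_profile("g", c(90, rep(1, 9)) * 10)
  err <- tryCatch(normalize_profile(raw, 0.3), condition = identity)
  expect_s3_class(err, "gene_rejected")
  expect_identical(err$reason, "density>1")

  err <- tryCatch(normalize_profile(raw_profile("g", rep(0, 9)), 0.1),
                  condition = identity)
  expect_s3_class(err, "gene_rejected")
  expect_identical(err$reason, "no reads")
})

test_that("the coverage filter is boundary-inclusive", {
  L <- 11L
  expect_true(filter_gene(raw_profile("g", rep(10, L - 1)))$pass)
  expect_false(filter_gene(raw_profile("g", rep(0, L - 1)))$pass)
  expect_identical(filter_gene(raw_profile("g", rep(0, L - 1)))$reason,
                   "no reads")
  # L = 101, total 500: mean 5 < 10
  flt <- filter_gene(raw_profile("g", rep(5, 100)))
  expect_false(flt$pass)
  expect_identical(flt$reason, "low coverage")
  # zero-count codons are reported even in passing genes
  counts <- rep(20, 10); counts[4] <- 0
  flt <- filter_gene(raw_profile("g", counts))
  expect_true(flt$pass)
  expect_identical(flt$zero_codons, 5L)
})

test_that("profiles survive a TSV round trip", {
  raws <- list(a = raw_profile("a", c(3, 1, 4, 1, 5)),
               b = raw_profile("b", c(2, 7, 1, 8, 2)))
  df <- do.call(rbind, lapply(raws, function(p)
    data.frame(gene_id = p$gene_id, codon = 2:p$L, count = p$counts)))
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_counts_tsv(path)
  expect_equal(back$a$counts, raws$a$counts)
  expect_equal(back$b$counts, raws$b$counts)

  np <- list(a = normalize_profile(raws$a, 0.05))
  path2 <- tempfile(fileext = ".tsv")
  write_normalized_tsv(np, path2)
  back2 <- read_normalized_tsv(path2)
  expect_equal(back2$a$r, np$a$r)
})
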