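mk_reads <- function(seqs, counts) {
  data.table::data.table(id = sprintf("r%02d", seq_along(seqs)), seq = seqs,
                         s1 = as.integer(counts), total = as.integer(counts))
}

test_that("blacklist removal triggers on any >= 1 nt overlap, either strand", {
  reads <- mk_reads(c(strrep("A", 25), strrep("C", 25), strrep("G", 25)),
                    c(5, 5, 5))
  aln <- data.table::data.table(
    read_id = c("r01", "r02", "r03"),
    contig = "chr1",
    start = c(120L, 76L, 200L),    # r01 inside, r02 1-nt boundary, r03 clear
    end = c(145L, 101L, 225L),
    strand = c("+", "-", "+"),
    five_prime = c(120L, 100L, 200L))
  bl <- data.table::data.table(contig = "chr1", start = 100L, end = 180L,
                               strand = "+", ftype = "tRNA", id = "t1",
                               gene_id = NA, family = NA, class = NA)
  res <- blacklist_filter(reads, aln, bl)
  expect_equal(res$kept$id, "r03")
  expect_equal(res$n_removed, 2L)
})

test_that("length gate keeps the closed interval [23, 29] and whitelist filters by sequence", {
  reads <- mk_reads(c(strrep("A", 22), strrep("C", 23), strrep("G", 29),
                      strrep("T", 30)), rep(1, 4))
  res <- length_whitelist_filter(reads)
  expect_equal(nchar(res$kept$seq), c(23L, 29L))
  expect_equal(res$n_removed_length, 2L)

  wl <- strrep("C", 23)
  res2 <- length_whitelist_filter(reads, whitelist = wl)
  expect_equal(res2$kept$seq, wl)
  expect_equal(res2$n_removed_whitelist, 1L)
  expect_error(length_whitelist_filter(reads, min_len = 30, max_len = 20),
               "min_len")
})

test_that("length gate on uniform 18-35 nt lengths keeps 7/18 within 3 SE", {
  n <- 7000
  withr::with_seed(41, lens <- sample(18:35, n, replace = TRUE))
  reads <- mk_reads(vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), lens[i], TRUE), collapse = ""),
    character(1)), rep(1, n))
  reads <- reads[!duplicated(reads$seq), ]
  res <- length_whitelist_filter(reads)
  frac <- nrow(res$kept) / nrow(reads)
  se <- sqrt((7 / 18) * (11 / 18) / nrow(reads))
  expect_lt(abs(frac - 7 / 18), 3 * se)
})

test_that("minimum-count rule pools all samples and cuts exactly at the threshold", {
  reads <- data.table::data.table(
    id = sprintf("r%02d", 1:6),
    seq = strrep(c("A", "C", "G", "T", "AC", "GT"), 24),
    wt = c(1L, 5L, 5L, 6L, 20L, 1L),
    mut = c(2L, 4L, 5L, 5L, 5L, 1L))   # totals 3, 9, 10, 11, 25, 2
  reads$total <- reads$wt + reads$mut
  data.table::setattr(reads, "sample_cols", c("wt", "mut"))
  res <- mincount_filter(reads, min_total = 10)
  expect_equal(res$kept$total, c(10L, 11L, 25L))
  expect_equal(res$n_removed, 3L)
  # boundary: (4,5) removed, (5,5) kept
  two <- mk_reads(c(strrep("A", 24), strrep("C", 24)), c(9, 10))
  expect_equal(mincount_filter(two, 10)$kept$id, "r02")
  # min_total = 1 is the identity on positive totals
  expect_equal(nrow(mincount_filter(reads, 1)$kept), nrow(reads))
})

test_that("filters commute and the report conserves tallies on simulated data", {
  g <- test_genome()
  sim <- simulate_reads(g, profile_brain(), 8000, n_samples = 2, seed = 16)
  reads <- collapse_reads(reads_by_sample(sim))
  aln <- map_reads(test_index(), reads)

  scr <- filter_pirnas(reads, aln, g$features)
  r <- scr$report
  expect_equal(r$input_n, r$kept_n + r$removed_blacklist + r$removed_length +
                 r$removed_whitelist + r$removed_mincount)

  # commutation: mincount-then-blacklist equals blacklist-then-mincount
  a <- blacklist_filter(mincount_filter(reads, 10)$kept, aln, g$features)$kept
  b <- mincount_filter(blacklist_filter(reads, aln, g$features)$kept, 10)$kept
  expect_equal(sort(a$id), sort(b$id))
  # idempotence: re-screening the kept set removes nothing further
  scr2 <- filter_pirnas(scr$kept, aln, g$features)
  expect_equal(scr2$kept$id, scr$kept$id)
  expect_equal(scr2$report$kept_n, scr2$report$input_n)

  # planted 2% blacklist share is recovered within 3 SE (instance-weighted)
  bl_w <- sum(reads$total[!reads$id %in%
                            blacklist_filter(reads, aln, g$features)$kept$id])
  frac <- bl_w / sum(reads$total)
  se <- sqrt(0.02 * 0.98 / sum(reads$total))
  expect_lt(abs(frac - 0.02), 3 * se)
})
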