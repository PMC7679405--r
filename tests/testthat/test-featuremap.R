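# hand-built toy universe: one contig, one + strand LTR element, one gene
toy_features <- function() {
  data.table::data.table(
    contig = "chr1",
    start  = c(100L, 500L, 600L, 800L, 950L, 2000L),
    end    = c(400L, 600L, 800L, 950L, 1100L, 2200L),
    strand = c("+", "-", "-", "-", "-", "+"),
    ftype  = c("transposon", "utr5", "exon", "intron", "utr3", "satellite"),
    id     = c("te1", "g1_utr5", "g1_exon1", "g1_intron1", "g1_utr3", "sat1"),
    gene_id = c(NA, "g1", "g1", "g1", "g1", NA),
    family = c("famA", NA, NA, NA, NA, NA),
    class  = c("LTR", NA, NA, NA, NA, NA))
}

toy_assign <- function(aln, counts = NULL) {
  ids <- unique(aln$read_id)
  reads <- data.table::data.table(
    id = ids, seq = strrep("A", aln$end[match(ids, aln$read_id)] -
                             aln$start[match(ids, aln$read_id)]),
    s1 = if (is.null(counts)) rep(1L, length(ids)) else counts,
    total = if (is.null(counts)) rep(1L, length(ids)) else counts)
  assign_categories(reads, aln, toy_features())
}

aln_row <- function(read_id, start, end, strand = "+") {
  data.table::data.table(read_id = read_id, contig = "chr1",
                         start = as.integer(start), end = as.integer(end),
                         strand = strand,
                         five_prime = if (strand == "+") as.integer(start)
                                      else as.integer(end) - 1L)
}

test_that("category, class and sense are read off the deciding alignment", {
  a <- toy_assign(aln_row("r1", 150, 175, "+"))
  expect_equal(a$category, "transposon")
  expect_equal(a$te_class, "LTR")
  expect_equal(a$sense, "sense")
  expect_equal(a$target_id, "te1")

  b <- toy_assign(aln_row("r2", 150, 175, "-"))
  expect_equal(b$sense, "antisense")
})

test_that("transposon outranks genic across a read's alignments", {
  aln <- rbind(aln_row("r1", 650, 675, "+"),   # genic exon placement
               aln_row("r1", 150, 175, "+"))   # transposon placement
  a <- toy_assign(aln)
  expect_equal(a$category, "transposon")
  # hierarchy property: the genic overlap is ignored entirely
  expect_equal(a$target_id, "te1")
})

test_that("genic reads take the max-overlap gene part, ties by utr3 > utr5 > exon > intron", {
  # 24-nt read straddling the exon/intron boundary 12/12: tie -> exon
  a <- toy_assign(aln_row("r1", 788, 812, "-"))
  expect_equal(a$category, "genic")
  expect_equal(a$feature, "exon")
  expect_equal(a$target_id, "g1")
  expect_equal(a$sense, "sense")  # - read on - gene

  # 24-nt read straddling intron/utr3 12/12: tie -> utr3
  b <- toy_assign(aln_row("r2", 938, 962, "-"))
  expect_equal(b$feature, "utr3")

  # fully inside the CDS-exon
  d <- toy_assign(aln_row("r3", 700, 725, "+"))
  expect_equal(d$feature, "exon")
  expect_equal(d$sense, "antisense")  # + read on - gene
})

test_that("sub-threshold grazing overlaps leave a read unannotated", {
  # only 5 of 25 nt inside the element: below the 50% rule
  a <- toy_assign(aln_row("r1", 395, 420, "+"))
  expect_equal(a$category, "unannotated")
  expect_equal(a$sense, "none")
  expect_true(is.na(a$target_id))
})

test_that("composition percentages are weight-aware and sum to 100", {
  aln <- rbind(aln_row("r1", 150, 175, "+"), aln_row("r2", 700, 725, "-"))
  a <- toy_assign(aln, counts = c(1L, 3L))
  cs <- composition_summary(a)
  expect_equal(sum(cs$category$pct), 100)
  expect_equal(cs$category$pct[cs$category$category == "transposon"], 25)
  expect_equal(cs$category$pct[cs$category$category == "genic"], 75)
  expect_equal(cs$genic_features$pct[cs$genic_features$feature == "exon"], 100)

  one <- toy_assign(aln_row("r1", 700, 725, "-"))
  cs1 <- composition_summary(one)
  expect_equal(cs1$category$pct[cs1$category$category == "genic"], 100)
  expect_error(composition_summary(one[0, ]), "no assignments")
})

test_that("assignments match planted truth for at least 99% of reads end-to-end", {
  g <- test_genome()
  sim <- simulate_reads(g, profile_brain(), 10000, n_samples = 2, seed = 17)
  reads <- collapse_reads(reads_by_sample(sim))
  aln <- map_reads(test_index(), reads)
  scr <- filter_pirnas(reads, aln, g$features)
  asg <- assign_categories(scr$kept, aln, g$features)
  truth <- truth_for_reads(scr$kept, sim)
  m <- merge(asg, truth, by.x = "read_id", by.y = "id",
             suffixes = c("_call", "_true"))
  expect_gte(mean(m$category_call == m$category_true), 0.99)
  gm <- m[m$category_true == "genic", ]
  expect_gte(mean(gm$feature_call == gm$feature_true), 0.99)
  expect_gte(mean(m$sense_call == m$sense_true), 0.99)
})
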