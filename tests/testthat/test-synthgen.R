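test_that("empty-feature spec yields background sequence with no annotation", {
  g <- build_genome(genome_spec(n_genes = 0, n_te_families = 0,
                                satellite_copies = 0, n_blacklist_loci = 0,
                                seed = 2))
  expect_equal(nrow(g$features), 0L)
  expect_gt(sum(nchar(g$contigs)), 0)
})

test_that("gene models emit the expected interval counts, verified via GFF3", {
  g <- build_genome(genome_spec(n_genes = 2, exons_per_gene = 2,
                                n_te_families = 1, seed = 4))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g$features, path)
  ft <- read_gff3(path)
  cnt <- table(ft$ftype[!is.na(ft$gene_id)])
  # each gene: 1 utr5, 2 CDS-exons, 1 intron, 1 utr3
  expect_equal(unname(cnt[c("utr5", "exon", "intron", "utr3")]),
               c(2L, 4L, 2L, 2L), ignore_attr = TRUE)
  # gene parts abut without gaps inside each gene
  dt <- data.table::as.data.table(ft)[!is.na(gene_id)]
  data.table::setorder(dt, gene_id, start)
  gaps <- dt[, list(ok = all(start[-1] == end[-.N])), by = "gene_id"]
  expect_true(all(gaps$ok))
})

test_that("genome build is deterministic under a fixed seed, byte-identical on disk", {
  g1 <- build_genome(genome_spec(seed = 9))
  g2 <- build_genome(genome_spec(seed = 9))
  expect_identical(g1$contigs, g2$contigs)
  expect_equal(as.data.frame(g1$features), as.data.frame(g2$features))
  d <- withr::local_tempdir()
  write_genome(g1, file.path(d, "a.fa"), file.path(d, "a.gff3"))
  write_genome(g2, file.path(d, "b.fa"), file.path(d, "b.gff3"))
  expect_identical(unname(tools::md5sum(file.path(d, "a.fa"))),
                   unname(tools::md5sum(file.path(d, "b.fa"))))
  expect_identical(unname(tools::md5sum(file.path(d, "a.gff3"))),
                   unname(tools::md5sum(file.path(d, "b.gff3"))))
})

test_that("genomic k-mers are unique genome-wide up to reverse complement", {
  g <- test_genome()
  k <- g$spec$uniqueness_k
  km <- unlist(lapply(g$contigs, function(s) {
    n <- nchar(s) - k + 1
    substring(s, 1:n, k:nchar(s))
  }), use.names = FALSE)
  canon <- pmin(km, revcomp(km))
  expect_false(any(duplicated(canon)))
})

test_that("simulated read populations recover the planted mixtures within 3 SE", {
  g <- test_genome()
  mix <- c(exon = 0.62, intron = 0.11, utr5 = 0.05, utr3 = 0.22)
  prof <- read_profile(category_mix = c(transposon = 0, satellite = 0,
                                        genic = 1, blacklist = 0),
                       genic_feature_mix = mix, seed = 6)
  sim <- simulate_reads(g, prof, 10000)
  emp <- prop.table(table(factor(sim$feature, names(mix))))
  for (f in names(mix)) {
    se <- sqrt(mix[[f]] * (1 - mix[[f]]) / 10000)
    expect_lt(abs(emp[[f]] - mix[[f]]), 3 * se)
  }
})

test_that("degenerate profiles hit their boundaries exactly", {
  g <- test_genome()
  allbl <- read_profile(category_mix = c(transposon = 0, satellite = 0,
                                         genic = 0, blacklist = 1), seed = 8)
  sim <- simulate_reads(g, allbl, 500)
  expect_true(all(sim$category == "blacklist"))
  # the screen must then remove every read
  reads <- collapse_reads(list(sim$seq))
  aln <- map_reads(test_index(), reads)
  scr <- filter_pirnas(reads, aln, g$features, min_total = 1)
  expect_equal(nrow(scr$kept), 0L)
  expect_equal(scr$report$removed_blacklist, nrow(reads))

  allsense <- read_profile(category_mix = c(transposon = 1, satellite = 0,
                                            genic = 0, blacklist = 0),
                           te_sense_fraction = 1, seed = 9)
  sim2 <- simulate_reads(g, allsense, 500)
  expect_true(all(sim2$sense == "sense"))
})

test_that("simulate_reads rejects read lengths longer than their source features", {
  g <- build_genome(genome_spec(n_genes = 0, n_te_families = 0,
                                satellite_copies = 0, n_blacklist_loci = 2,
                                blacklist_len = 20, seed = 3))
  prof <- read_profile(category_mix = c(transposon = 0, satellite = 0,
                                        genic = 0, blacklist = 1),
                       length_dist = c(`25` = 1), seed = 1)
  expect_error(simulate_reads(g, prof, 100), "exceeds every source feature")
})

test_that("planted count matrices follow the NB mean-variance relation", {
  plan0 <- de_plan(n_features = 1000, de_fraction = 0, baseline_mean = 200,
                   dispersion = 1e-4, replicates_per_group = 6, seed = 12)
  c0 <- simulate_counts(plan0)
  expect_true(all(c0$truth$direction == "null"))
  v <- apply(c0$counts, 1, var)
  m <- rowMeans(c0$counts)
  # near-Poisson limit: variance tracks the mean
  expect_lt(abs(mean(v) / mean(m) - 1), 0.15)

  plan1 <- de_plan(n_features = 1000, de_fraction = 0, baseline_mean = 100,
                   dispersion = 0.2, replicates_per_group = 6, seed = 13)
  c1 <- simulate_counts(plan1)
  expected_var <- 100 + 0.2 * 100^2
  expect_lt(abs(mean(apply(c1$counts, 1, var)) / expected_var - 1), 0.15)
})

test_that("planted DE direction mixture is recovered within 3 SE", {
  plan <- de_plan(n_features = 2000, de_fraction = 0.3,
                  down_fraction_among_de = 0.85, seed = 14)
  cc <- simulate_counts(plan)
  de <- cc$truth[cc$truth$direction != "null", ]
  emp <- mean(de$direction == "down")
  se <- sqrt(0.85 * 0.15 / nrow(de))
  expect_lt(abs(emp - 0.85), 3 * se)
  # B-group means move by the planted fold change
  up <- cc$truth$direction == "up"
  expect_lt(abs(mean(cc$counts[up, 4:6]) / (100 * 2^3) - 1), 0.1)
})

test_that("ping-pong pairs are planted with exact 10-nt 5'-5' overlaps", {
  g <- test_genome()
  prof <- profile_ovary(seed = 15)
  sim <- simulate_reads(g, prof, 5000)
  sp <- attr(sim, "species")
  pp <- sp[sp$pingpong == TRUE, ]
  expect_gt(nrow(pp), 0)
  # members come in consecutive +/- pairs: check the overlap arithmetic
  plus <- pp[pp$strand == "+", ]
  minus <- pp[pp$strand == "-", ]
  expect_equal(nrow(plus), nrow(minus))
  expect_true(all((minus$end - 1L) - plus$start + 1L == 10L))
})
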