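toy_concord <- function() {
  pirna_de <- data.table::data.table(
    feature_id = c("p1", "p2", "p3"),
    log2fc = c(-1.5, 2.0, -0.8),
    p = c(1e-5, 1e-4, 1e-3), q = c(1e-4, 1e-3, 0.01),
    direction = c("down", "up", "down"))
  assignments <- data.table::data.table(
    read_id = c("p1", "p2", "p3", "p3"),
    category = "genic", te_class = "none", feature = "exon",
    sense = c("antisense", "sense", "antisense", "antisense"),
    target_id = c("g1", "g1", "g2", "gX"),
    weight = c(20, 15, 12, 12), read_len = 25L)
  gene_de <- data.table::data.table(
    gene_id = c("g1", "g2", "g3"),
    log2fc = c(2.0, -1.0, 0.5),
    p = c(1e-6, 1e-5, 0.4), q = c(1e-5, 1e-4, 0.6),
    direction = c("up", "down", "ns"))
  list(p = pirna_de, a = assignments, g = gene_de)
}

test_that("pairs require significance on both sides and pass the sense filter", {
  t <- toy_concord()
  suppressMessages(pairs <- antisense_pairs(t$p, t$a, t$g))
  # p1 (antisense, sig) -> g1 (sig); p3 -> g2 (sig); p3 -> gX skipped;
  # p2 is sense so excluded by the default filter
  expect_equal(pairs$pirna_id, c("p1", "p3"))
  expect_equal(pairs$gene_id, c("g1", "g2"))
  expect_equal(attr(pairs, "skipped_genes"), 1L)

  both <- suppressMessages(antisense_pairs(t$p, t$a, t$g, sense_filter = "both"))
  expect_equal(nrow(both), 3L)
})

test_that("quadrant counts and the headline fraction follow the fold-change signs", {
  one <- data.table::data.table(pirna_id = "p1", gene_id = "g1",
                                pirna_log2fc = -1, gene_log2fc = 2,
                                pirna_sense = "antisense")
  q <- quadrant_counts(one)
  expect_equal(q$quadrants$n_ud, 1L)
  expect_equal(q$headline$fraction_gene_up, 1)

  sym <- data.table::data.table(
    pirna_id = sprintf("p%d", 1:4), gene_id = sprintf("g%d", 1:4),
    pirna_log2fc = c(1, -1, 1, -1), gene_log2fc = c(1, 1, -1, -1),
    pirna_sense = "antisense")
  qs <- quadrant_counts(sym)
  expect_equal(unlist(qs$quadrants), c(n_uu = 1L, n_ud = 1L, n_du = 1L, n_dd = 1L))
  expect_equal(qs$headline$fraction_gene_up, 0.5)
  expect_error(quadrant_counts(sym[0, ]), "no pairs")
})

test_that("quadrant structure is invariant under positive rescaling of fold changes", {
  plant <- simulate_concord_plant(n_pirnas = 200, seed = 41)
  suppressMessages(pairs <- antisense_pairs(plant$pirna_de, plant$assignments,
                                            plant$gene_de))
  q1 <- quadrant_counts(pairs)$quadrants
  scaled <- data.table::copy(pairs)
  scaled$pirna_log2fc <- scaled$pirna_log2fc * 3.7
  scaled$gene_log2fc <- scaled$gene_log2fc * 0.2
  expect_equal(quadrant_counts(scaled)$quadrants, q1)
})

test_that("planted anticorrelation is recovered: pair bookkeeping and headline fraction", {
  plant <- simulate_concord_plant(n_pirnas = 500, down_fraction = 0.85,
                                  anti_fraction = 0.8, seed = 42)
  suppressMessages(pairs <- antisense_pairs(plant$pirna_de, plant$assignments,
                                            plant$gene_de))
  expect_equal(nrow(pairs), 500L)           # one planted pair per piRNA
  q <- quadrant_counts(pairs)
  n_down <- q$quadrants$n_ud + q$quadrants$n_dd
  se <- sqrt(0.8 * 0.2 / n_down)
  expect_lt(abs(q$headline$fraction_gene_up - 0.8), 3 * se)
  # planted truth agrees with the recovered quadrants exactly
  expect_equal(q$quadrants$n_ud,
               sum(plant$truth$pirna_down & plant$truth$gene_up))
})
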