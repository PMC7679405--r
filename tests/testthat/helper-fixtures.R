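# Shared fixtures and independent oracles used across test files.

# small default genome reused by most integration tests (cached per session)
test_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome(genome_spec(seed = 7))
    cache
  }
})

test_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_index(test_genome()$contigs, 16)
    cache
  }
})

# brute-force mapping oracle: scan every offset of every contig on both
# strands, independent of the k-mer index path
brute_force_map <- function(contigs, seqs) {
  out <- list()
  for (L in sort(unique(nchar(seqs)))) {
    qs <- seqs[nchar(seqs) == L]
    for (cn in names(contigs)) {
      s <- contigs[[cn]]
      n <- nchar(s) - L + 1
      if (n < 1) next
      subs <- substring(s, 1:n, L:(nchar(s)))
      for (q in qs) {
        for (hit in which(subs == q)) {
          out[[length(out) + 1L]] <- data.frame(
            seq = q, contig = cn, start = hit - 1L, end = hit - 1L + L,
            strand = "+", stringsAsFactors = FALSE)
        }
        rcq <- revcomp(q)
        for (hit in which(subs == rcq)) {
          out[[length(out) + 1L]] <- data.frame(
            seq = q, contig = cn, start = hit - 1L, end = hit - 1L + L,
            strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(seq = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0)))
  }
  do.call(rbind, out)
}

# direct Benjamini-Hochberg step-up, written independently of p.adjust
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  res <- numeric(m)
  res[o] <- q
  res
}

# brute-force NB likelihood-ratio oracle on a fixed mean grid
nb_lrt_grid_oracle <- function(y, groups, phi, grid = exp(seq(log(1e-4), log(1e4), length.out = 4000))) {
  ll <- function(yy, m) sum(dnbinom(yy, size = 1 / phi, mu = m, log = TRUE))
  g <- as.factor(groups)
  lv <- levels(g)
  ll0 <- max(vapply(grid, function(m) ll(y, m), numeric(1)))
  lla <- max(vapply(grid, function(m) ll(y[g == lv[1]], m), numeric(1))) +
    max(vapply(grid, function(m) ll(y[g == lv[2]], m), numeric(1)))
  pchisq(max(0, 2 * (lla - ll0)), df = 1, lower.tail = FALSE)
}

# assignment-shaped table straight from simulation truth (weight = instance
# count per species), for fast repeated studies of the spectrum/bias stage
truth_assignments <- function(sim) {
  dt <- data.table::as.data.table(sim)
  sp <- dt[, .N, by = .(species_id, category, feature, sense, length)]
  data.table::data.table(read_id = sp$species_id, category = sp$category,
                         te_class = "none", feature = sp$feature,
                         sense = sp$sense, target_id = NA_character_,
                         weight = as.numeric(sp$N), read_len = sp$length)
}
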