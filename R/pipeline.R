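#' Assemble and validate a pipeline configuration
#'
#' @param genome_fasta,annotation_gff3 reference genome and annotation paths.
#' @param fastq named character vector of FASTQ paths, one per sample.
#' @param outdir output directory (created if missing).
#' @param groups optional named vector mapping sample names to two group
#'   labels; enables the differential-expression stage.
#' @param gene_de_tsv optional gene-level DE table (columns `gene_id`,
#'   `log2fc`, `q`, `direction`); enables the concordance stage.
#' @param min_len,max_len,min_total,mincount_scope,whitelist_fasta screen
#'   parameters (see [filter_pirnas()]).
#' @param weighting,min_overlap_frac category-assignment parameters.
#' @param kmax,pair_weight ping-pong parameters.
#' @param alpha_mode,alpha DE significance rule.
#' @param sense_filter concordance pairing filter.
#' @param seed_k mapper seed length.
#' @param seed RNG seed recorded in the manifest.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(genome_fasta, annotation_gff3, fastq, outdir,
                            groups = NULL, gene_de_tsv = NULL,
                            min_len = 23L, max_len = 29L, min_total = 10L,
                            mincount_scope = "pooled", whitelist_fasta = NULL,
                            weighting = "count", min_overlap_frac = 0.5,
                            kmax = 20L, pair_weight = "product",
                            alpha_mode = "fdr", alpha = 0.05,
                            sense_filter = "antisense", seed_k = 16L,
                            seed = 1L) {
  for (p in c(genome_fasta, annotation_gff3, unname(fastq), gene_de_tsv,
              whitelist_fasta)) {
    if (!is.null(p) && !file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  if (is.null(names(fastq))) names(fastq) <- sprintf("sample%d", seq_along(fastq))
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full piRNA characterization pipeline
#'
#' Stages execute in fixed order: collapse, map, filter, assign,
#' spectrum/bias and ping-pong, then (when configured) differential
#' expression and antisense/gene concordance. Every table is written as TSV
#' under `outdir` together with a manifest recording the seed, a config
#' checksum, per-stage row counts and output checksums; a rerun with the
#' same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return the result bundle (tables and paths), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$outdir, f)
  # freeze the config for the manifest checksum
  cfg_lines <- vapply(names(config), function(nm)
    paste0(nm, "=", paste(deparse(config[[nm]]), collapse = "")), character(1))
  writeLines(cfg_lines, outp("config.txt"))

  genome <- .stage("load_genome", {
    contigs <- read_fasta(config$genome_fasta)
    features <- read_gff3(config$annotation_gff3)
    list(contigs = contigs, features = features)
  })
  whitelist <- if (!is.null(config$whitelist_fasta)) {
    unname(read_fasta(config$whitelist_fasta))
  } else NULL

  reads <- .stage("collapse", collapse_reads(as.list(config$fastq)))
  index <- .stage("index", build_index(genome$contigs, config$seed_k))
  alignments <- .stage("map", map_reads(index, reads))
  scr <- .stage("filter", filter_pirnas(
    reads, alignments, genome$features,
    min_len = config$min_len, max_len = config$max_len,
    whitelist = whitelist, min_total = config$min_total,
    mincount_scope = config$mincount_scope,
    groups = if (!is.null(config$groups)) config$groups[attr(reads, "sample_cols")]))
  kept <- scr$kept
  kept_aln <- alignments[alignments$read_id %in% kept$id, ]
  assignments <- .stage("assign", assign_categories(
    kept, kept_aln, genome$features,
    min_overlap_frac = config$min_overlap_frac, weighting = config$weighting))
  composition <- .stage("composition", composition_summary(assignments))
  spectrum <- .stage("spectrum", length_strand_spectrum(assignments))
  bias <- .stage("bias", if (nrow(spectrum) > 0) bias_test(spectrum) else NULL)
  wts <- setNames(assignments$weight, assignments$read_id)
  pp_hist <- .stage("pingpong", overlap_histogram(
    kept_aln, weights = wts, kmax = config$kmax,
    pair_weight = config$pair_weight))
  pp <- tryCatch(pingpong_zscore(pp_hist), error = function(e) NULL)

  de <- NULL
  if (!is.null(config$groups)) {
    de <- .stage("de", {
      m <- count_matrix(kept)
      run_de(m, config$groups[colnames(m)],
             alpha_mode = config$alpha_mode, alpha = config$alpha)
    })
  }
  concord <- NULL
  if (!is.null(config$gene_de_tsv) && !is.null(de)) {
    concord <- .stage("concord", {
      gene_de <- read_tsv(config$gene_de_tsv)
      pairs <- antisense_pairs(de, assignments, gene_de,
                               sense_filter = config$sense_filter)
      quad <- if (nrow(pairs) > 0) quadrant_counts(pairs) else NULL
      list(pairs = pairs, quad = quad)
    })
  }

  # write the bundle
  write_tsv(scr$report, outp("filter_report.tsv"))
  write_bed(kept_aln, kept, outp("alignments.bed"))
  write_tsv(assignments, outp("assignments.tsv"))
  write_tsv(composition$category, outp("composition_category.tsv"))
  write_tsv(composition$genic_features, outp("composition_genic.tsv"))
  write_tsv(spectrum, outp("spectrum.tsv"))
  if (!is.null(bias)) write_tsv(bias, outp("bias.tsv"))
  write_tsv(pp_hist, outp("pingpong_hist.tsv"))
  if (!is.null(pp)) write_tsv(pp, outp("pingpong.tsv"))
  if (!is.null(de)) write_tsv(de, outp("de_results.tsv"))
  if (!is.null(concord)) {
    write_tsv(concord$pairs, outp("concord_pairs.tsv"))
    if (!is.null(concord$quad)) {
      write_tsv(concord$quad$quadrants, outp("quadrants.tsv"))
      write_tsv(concord$quad$headline, outp("concord_headline.tsv"))
    }
  }
  stage_rows <- data.table(
    stage = c("collapse", "map", "filter_kept", "assign", "spectrum",
              "pingpong_hist", "de", "concord_pairs"),
    rows = c(nrow(reads), nrow(alignments), nrow(kept), nrow(assignments),
             nrow(spectrum), nrow(pp_hist),
             if (is.null(de)) 0L else nrow(de),
             if (is.null(concord)) 0L else nrow(concord$pairs)))
  files <- list.files(config$outdir, pattern = "\\.(tsv|bed)$",
                      full.names = TRUE)
  manifest <- data.table(
    file = basename(files), md5 = unname(md5sum(files)))
  manifest <- rbind(
    data.table(file = "config.txt", md5 = unname(md5sum(outp("config.txt")))),
    manifest)
  write_tsv(stage_rows, outp("manifest_stages.tsv"))
  write_tsv(manifest, outp("manifest_files.tsv"))
  invisible(list(reads = reads, alignments = alignments, report = scr$report,
                 kept = kept, assignments = assignments,
                 composition = composition, spectrum = spectrum, bias = bias,
                 pingpong_hist = pp_hist, pingpong = pp, de = de,
                 concord = concord, stage_rows = stage_rows,
                 manifest = manifest, outdir = config$outdir))
}

#' Simulate and characterize one piRNA library in memory
#'
#' Convenience wrapper over the full characterization path: simulate reads
#' from a profile, collapse, map, screen, assign categories, and compute the
#' composition, length-by-strand spectrum, sense-bias test and ping-pong
#' histogram/z-score, without touching the filesystem.
#'
#' @param genome an `annotated_genome`.
#' @param profile a [read_profile()].
#' @param n_reads total read instances to simulate.
#' @param n_samples samples the reads are split over (default 4).
#' @param seed RNG seed for the simulation.
#' @param index optional prebuilt [build_index()] for `genome` (rebuilt when
#'   `NULL`).
#' @param min_total minimum pooled count (default 10).
#' @param min_len,max_len length gate.
#' @param kmax ping-pong histogram extent.
#' @return list with `sim`, `reads`, `alignments`, `report`, `kept`,
#'   `assignments`, `composition`, `spectrum`, `bias`, `pingpong_hist`,
#'   `pingpong` (`NULL` when the z-score is undefined).
#' @export
characterize_library <- function(genome, profile, n_reads, n_samples = 4L,
                                 seed = profile$seed, index = NULL,
                                 min_total = 10L, min_len = 23L,
                                 max_len = 29L, kmax = 20L) {
  if (is.null(index)) index <- build_index(genome$contigs)
  sim <- simulate_reads(genome, profile, n_reads, n_samples, seed = seed)
  reads <- collapse_reads(reads_by_sample(sim))
  alignments <- map_reads(index, reads)
  scr <- filter_pirnas(reads, alignments, genome$features,
                       min_len = min_len, max_len = max_len,
                       min_total = min_total)
  kept <- scr$kept
  kept_aln <- alignments[alignments$read_id %in% kept$id, ]
  assignments <- assign_categories(kept, kept_aln, genome$features)
  composition <- composition_summary(assignments)
  spectrum <- length_strand_spectrum(assignments)
  bias <- if (nrow(spectrum) > 0) bias_test(spectrum) else NULL
  wts <- setNames(assignments$weight, assignments$read_id)
  pp_hist <- overlap_histogram(kept_aln, weights = wts, kmax = kmax)
  pp <- tryCatch(pingpong_zscore(pp_hist), error = function(e) NULL)
  list(sim = sim, reads = reads, alignments = alignments,
       report = scr$report, kept = kept, assignments = assignments,
       composition = composition, spectrum = spectrum, bias = bias,
       pingpong_hist = pp_hist, pingpong = pp)
}

#' Planted alignments and weights of a simulated library
#'
#' Collapses a simulation to its planted species placements: one alignment
#' per species (the generator knows its coordinates) weighted by the number
#' of read instances drawn from it. Blacklist species are excluded, matching
#' what survives the screen. Useful for fast repeated significance studies
#' of downstream stages without re-running the mapper.
#'
#' @param sim a table from [simulate_reads()].
#' @return list with `alignments` (read_id = species id) and `weights`
#'   (named instance counts).
#' @export
planted_alignments <- function(sim) {
  s <- as.data.table(sim)[category != "blacklist"]
  sp <- s[, .N, by = .(species_id, contig, start, end, strand)]
  aln <- sp[, .(read_id = species_id, contig, start, end, strand,
                five_prime = fifelse(strand == "+", start, end - 1L))]
  list(alignments = aln[], weights = setNames(as.numeric(sp$N), sp$species_id))
}

#' Generate the demo dataset: genome, per-tissue FASTQ samples, counts and
#' a gene DE table
#'
#' Forges a default synthetic genome and, for each tissue preset (brain and
#' ovary), simulates four samples of small-RNA reads from the wild-type
#' profile plus four from the perturbed profile (brain: sense bias
#' eliminated; ovary: unchanged profile re-drawn), writes per-sample FASTQ,
#' a planted replicate count table per tissue, and a synthetic gene-level DE
#' table over the genome's genes.
#'
#' @param outdir output directory.
#' @param seed base RNG seed; every stage's seed derives from it.
#' @param reads_per_sample read instances per sample (default 5000).
#' @return named list of generated paths, invisibly.
#' @export
make_demo <- function(outdir, seed = 1L, reads_per_sample = 5000L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  genome <- build_genome(genome_spec(seed = derive_seed(seed, 7)))
  fasta <- file.path(outdir, "genome.fa")
  gff <- file.path(outdir, "annotation.gff3")
  write_genome(genome, fasta, gff)
  paths <- list(genome_fasta = fasta, annotation_gff3 = gff)
  tissues <- list(
    brain = list(wt = profile_brain(), mut = profile_tud_brain()),
    ovary = list(wt = profile_ovary(), mut = profile_ovary())
  )
  off <- 20L
  for (tis in names(tissues)) {
    fq <- character(0)
    for (cond in c("wt", "mut")) {
      sim <- simulate_reads(genome, tissues[[tis]][[cond]],
                            n_reads = 2L * reads_per_sample, n_samples = 2L,
                            seed = derive_seed(seed, off))
      off <- off + 1L
      by_sample <- reads_by_sample(sim)
      for (j in seq_along(by_sample)) {
        f <- file.path(outdir, sprintf("%s_%s_rep%d.fastq", tis, cond, j))
        write_fastq(by_sample[[j]], f)
        fq <- c(fq, setNames(f, sprintf("%s_%s_rep%d", tis, cond, j)))
      }
    }
    paths[[paste0("fastq_", tis)]] <- fq
    plan <- if (tis == "brain") {
      de_plan_brain(seed = derive_seed(seed, 11))
    } else {
      de_plan_ovary(seed = derive_seed(seed, 13))
    }
    cnt <- simulate_counts(plan)
    cf <- file.path(outdir, sprintf("counts_%s.tsv", tis))
    write_tsv(data.table(feature_id = rownames(cnt$counts), cnt$counts), cf)
    write_tsv(cnt$truth, file.path(outdir, sprintf("counts_%s_truth.tsv", tis)))
    paths[[paste0("counts_", tis)]] <- cf
  }
  # synthetic gene-level DE table over the genome's genes
  gene_ids <- unique(genome$features$gene_id)
  gene_ids <- gene_ids[!is.na(gene_ids)]
  gene_de <- with_seed(derive_seed(seed, 31), {
    sig <- runif(length(gene_ids)) < 0.6
    lfc <- ifelse(runif(length(gene_ids)) < 0.5, -1, 1) *
      runif(length(gene_ids), 0.3, 3)
    data.table(gene_id = gene_ids, log2fc = lfc,
               p = ifelse(sig, runif(length(gene_ids), 0, 1e-3),
                          runif(length(gene_ids), 0.1, 1)),
               q = ifelse(sig, runif(length(gene_ids), 0, 0.04),
                          runif(length(gene_ids), 0.1, 1)),
               direction = ifelse(!sig, "ns", ifelse(lfc > 0, "up", "down")))
  })
  gf <- file.path(outdir, "gene_de.tsv")
  write_tsv(gene_de, gf)
  paths$gene_de_tsv <- gf
  invisible(paths)
}
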