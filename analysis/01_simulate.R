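#!/usr/bin/env Rscript
# Forge the synthetic genome and simulate the brain and ovary small-RNA
# libraries (plus planted replicate count tables and a gene-level DE table).
# All downstream drivers read from results/data/.

suppressPackageStartupMessages(library(pirnaflow))

seed <- 1
outdir <- "results/data"
paths <- make_demo(outdir, seed = seed, reads_per_sample = 5000)

genome <- read_fasta(paths$genome_fasta)
features <- read_gff3(paths$annotation_gff3)

cat("Synthetic genome:", length(genome), "contigs,",
    sum(nchar(genome)), "bp,", nrow(features), "feature intervals\n")
print(table(features$ftype))
cat("\nPer-tissue libraries (4 samples each: 2 wild-type + 2 mutant):\n")
for (t in c("brain", "ovary")) {
  fq <- paths[[paste0("fastq_", t)]]
  n <- vapply(fq, function(f) length(read_fastq(f)), integer(1))
  cat(sprintf("  %s: %s reads across %d FASTQ files\n",
              t, format(sum(n), big.mark = ","), length(fq)))
}
cat("\nPlanted count tables:", paths$counts_brain, "and", paths$counts_ovary,
    "\nGene-level DE table:", paths$gene_de_tsv, "\n")
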