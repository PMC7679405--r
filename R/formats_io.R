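#' Read a FASTA file into a named character vector
#'
#' @param path path to a FASTA file.
#' @return named character vector, one element per record (possibly empty).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  setNames(as.character(set), names(set))
}

#' Write contigs to FASTA
#'
#' @param contigs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(contigs, path) {
  set <- Biostrings::DNAStringSet(unname(as.character(contigs)))
  names(set) <- names(contigs)
  Biostrings::writeXStringSet(set, filepath = path, format = "fasta")
  invisible(path)
}

#' Read FASTQ sequences
#'
#' Sanger quality strings are ignored; only the sequences are returned.
#'
#' @param path path to a FASTQ file.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(character(0))
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  unname(as.character(set))
}

#' Write sequences to FASTQ with uniform quality
#'
#' @param seqs character vector of sequences.
#' @param path output path.
#' @param ids optional record ids; defaults to `read<i>`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(seqs))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- ids
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

# internal feature-type enum <-> GFF3 type dialect
.gff_type_of <- c(
  utr5 = "five_prime_UTR", exon = "CDS", intron = "intron",
  utr3 = "three_prime_UTR", transposon = "transposable_element",
  satellite = "satellite_DNA", tRNA = "tRNA", rRNA = "rRNA",
  snRNA = "snRNA", snoRNA = "snoRNA"
)
.ftype_of_gff <- setNames(names(.gff_type_of), unname(.gff_type_of))

blacklist_ftypes <- c("tRNA", "rRNA", "snRNA", "snoRNA")
gene_part_ftypes <- c("utr5", "exon", "intron", "utr3")

#' Read feature intervals from GFF3
#'
#' Converts the 1-based inclusive GFF3 coordinates to the 0-based half-open
#' convention used throughout this package, and maps GFF3 feature types to
#' the internal enum (`five_prime_UTR` -> `utr5`, `CDS` -> `exon`, ...).
#'
#' @param path path to a GFF3 file.
#' @return a `data.table` with columns `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `ftype`, `id`, `gene_id`, `family`, `class`,
#'   ordered by (contig, start).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  str <- as.character(strand(gr))
  if (any(!str %in% c("+", "-"))) {
    stop("GFF3 '", path, "' contains features without a +/- strand",
         call. = FALSE)
  }
  mc <- mcols(gr)
  gtype <- as.character(mc$type)
  unknown <- setdiff(unique(gtype), names(.ftype_of_gff))
  if (length(unknown)) {
    stop("GFF3 '", path, "' contains unsupported feature types: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  grab <- function(col) {
    if (col %in% names(mc)) as.character(mc[[col]]) else rep(NA_character_, length(gr))
  }
  ft <- data.table(
    contig = as.character(seqnames(gr)),
    start  = start(gr) - 1L,
    end    = end(gr),
    strand = str,
    ftype  = unname(.ftype_of_gff[gtype]),
    id      = grab("ID"),
    gene_id = grab("gene_id"),
    family  = grab("family"),
    class   = grab("class")
  )
  setorder(ft, contig, start)
  ft[]
}

#' Write feature intervals to GFF3
#'
#' The inverse of [read_gff3()]: internal 0-based half-open intervals are
#' emitted as 1-based inclusive GFF3 records with `ID`, `gene_id`, `family`
#' and `class` attributes where present.
#'
#' @param features a feature table as returned by [read_gff3()] or
#'   [build_genome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  ft <- as.data.table(features)
  gr <- GRanges(ft$contig, IRanges(ft$start + 1L, ft$end), strand = ft$strand)
  mcols(gr)$type    <- unname(.gff_type_of[ft$ftype])
  mcols(gr)$phase   <- ifelse(mcols(gr)$type == "CDS", 0L, NA_integer_)
  mcols(gr)$ID      <- ft$id
  mcols(gr)$gene_id <- ft$gene_id
  mcols(gr)$family  <- ft$family
  mcols(gr)$class   <- ft$class
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Collapse reads into unique sequences with per-sample counts
#'
#' Each distinct sequence becomes one collapsed read carrying its occurrence
#' count in every sample. Reads containing `N` are dropped (their tally is
#' kept in the `dropped_n` attribute); any character outside `A/C/G/T/N` is
#' an error. Output rows are ordered by descending pooled count, ties broken
#' lexicographically by sequence.
#'
#' @param samples a list, one element per sample, each either a character
#'   vector of read sequences or a path to a FASTQ file.
#' @param sample_names sample identifiers; default `names(samples)` or
#'   `sample1..sampleJ`.
#' @return a `data.table` with columns `id`, `seq`, one integer count column
#'   per sample, and `total`; attributes `sample_cols` (count column names)
#'   and `dropped_n` (per-sample N-drop tally).
#' @export
collapse_reads <- function(samples, sample_names = NULL) {
  if (!is.list(samples)) samples <- list(samples)
  if (is.null(sample_names)) {
    sample_names <- names(samples) %||% sprintf("sample%d", seq_along(samples))
    if (any(sample_names == "")) sample_names <- sprintf("sample%d", seq_along(samples))
  }
  stopifnot(length(sample_names) == length(samples))
  seqs <- lapply(samples, function(s) {
    if (length(s) == 1L && !grepl("^[ACGTN]*$", s) && file.exists(s)) read_fastq(s) else s
  })
  dropped <- integer(length(seqs))
  for (j in seq_along(seqs)) {
    s <- toupper(seqs[[j]])
    bad <- grepl("[^ACGTN]", s)
    if (any(bad)) {
      stop("sample '", sample_names[j], "' contains non-ACGTN characters (",
           sum(bad), " reads)", call. = FALSE)
    }
    hasN <- grepl("N", s, fixed = TRUE)
    dropped[j] <- sum(hasN)
    seqs[[j]] <- s[!hasN]
  }
  names(dropped) <- sample_names
  if (sum(dropped) > 0) {
    message("collapse_reads: dropped ", sum(dropped), " reads containing N")
  }
  long <- rbindlist(lapply(seq_along(seqs), function(j) {
    if (length(seqs[[j]]) == 0L) return(NULL)
    data.table(seq = seqs[[j]], sample_id = sample_names[j])
  }))
  if (is.null(long) || nrow(long) == 0L) {
    out <- data.table(id = character(0), seq = character(0))
    for (sn in sample_names) out[[sn]] <- integer(0)
    out$total <- integer(0)
    setattr(out, "sample_cols", sample_names)
    setattr(out, "dropped_n", dropped)
    return(out[])
  }
  tab <- long[, .N, by = .(seq, sample_id)]
  wide <- dcast(tab, seq ~ sample_id, value.var = "N", fill = 0L)
  for (sn in setdiff(sample_names, names(wide))) wide[[sn]] <- 0L
  setcolorder(wide, c("seq", sample_names))
  wide[, total := rowSums(.SD), .SDcols = sample_names]
  setorderv(wide, c("total", "seq"), order = c(-1L, 1L))
  wide[, id := sprintf("piR%06d", .I)]
  setcolorder(wide, c("id", "seq", sample_names, "total"))
  setattr(wide, "sample_cols", sample_names)
  setattr(wide, "dropped_n", dropped)
  wide[]
}

#' Extract the per-sample count matrix from a collapsed-read table
#'
#' @param reads a table from [collapse_reads()].
#' @param sample_cols count column names; default the `sample_cols` attribute.
#' @return integer matrix, features in rows (named by read id).
#' @export
count_matrix <- function(reads, sample_cols = attr(reads, "sample_cols")) {
  if (is.null(sample_cols)) {
    sample_cols <- setdiff(names(reads), c("id", "seq", "total"))
  }
  m <- as.matrix(as.data.frame(reads)[, sample_cols, drop = FALSE])
  rownames(m) <- reads$id
  storage.mode(m) <- "integer"
  m
}

#' Write a table as TSV
#' @param x a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  fwrite(as.data.table(x), path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read a TSV table
#' @param path input path.
#' @return a `data.table`.
#' @export
read_tsv <- function(path) fread(path, sep = "\t", header = TRUE)

#' Export alignments as BED6
#'
#' 0-based half-open intervals; name is the read id, score its pooled count.
#'
#' @param alignments alignment table from [map_reads()].
#' @param reads collapsed-read table supplying pooled counts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(alignments, reads, path) {
  aln <- as.data.table(alignments)
  sc <- reads$total[match(aln$read_id, reads$id)]
  bed <- data.table(aln$contig, aln$start, aln$end, aln$read_id,
                    ifelse(is.na(sc), 0L, sc), aln$strand)
  fwrite(bed, path, sep = "\t", quote = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write collapsed reads as a collapsed FASTA (`>id_x<count>` headers)
#'
#' @param reads collapsed-read table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  write_fasta(setNames(reads$seq, sprintf("%s_x%d", reads$id, reads$total)),
              path)
}
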