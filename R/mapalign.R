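#' Build a k-mer seed index over genome contigs
#'
#' Indexes every genomic k-mer position in a single deterministic pass.
#' Mapping seeds a read by its first k bases (and the first k bases of its
#' reverse complement) and verifies each candidate placement over the full
#' read length, so correctness does not depend on k beyond `k <= read
#' length`.
#'
#' @param contigs named character vector of contig sequences.
#' @param k seed length (>= 8, and no longer than the shortest contig).
#' @return an object of class `seed_index`.
#' @export
build_index <- function(contigs, k = 16L) {
  k <- as.integer(k)
  if (k < 8L) stop("seed k must be >= 8", call. = FALSE)
  if (length(contigs) == 0L) stop("no contigs to index", call. = FALSE)
  if (k > min(nchar(contigs))) {
    stop("seed k (", k, ") exceeds the shortest contig", call. = FALSE)
  }
  dt <- .genome_kmers(contigs, k)
  setkey(dt, kmer)
  structure(list(contigs = contigs, k = k, dt = dt), class = "seed_index")
}

#' Map sequences to the genome by exact matching on both strands
#'
#' Reports every placement where the genomic substring equals the read
#' (strand `+`) or its reverse complement (strand `-`). `five_prime` is the
#' genomic coordinate of the read's 5' nucleotide: `start` on `+`,
#' `end - 1` on `-`.
#'
#' @param index a [build_index()] result.
#' @param reads a collapsed-read table (columns `id`, `seq`) or a character
#'   vector of sequences (ids default to `read<i>`).
#' @return a `data.table` of alignments: `read_id`, `contig`, `start`,
#'   `end` (0-based half-open), `strand`, `five_prime`, sorted by
#'   (read_id, contig, start, strand). Unmapped reads contribute no rows.
#' @export
map_reads <- function(index, reads) {
  stopifnot(inherits(index, "seed_index"))
  if (is.character(reads)) {
    reads <- data.table(id = sprintf("read%d", seq_along(reads)), seq = reads)
  }
  reads <- as.data.table(reads)[, .(id, seq)]
  empty <- data.table(read_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), five_prime = integer(0))
  if (nrow(reads) == 0L) return(empty)
  if (any(nchar(reads$seq) < index$k)) {
    stop("all reads must be at least as long as the seed k = ", index$k,
         call. = FALSE)
  }
  k <- index$k
  queries <- rbind(
    reads[, .(read_id = id, qseq = seq, strand = "+")],
    reads[, .(read_id = id, qseq = revcomp(seq), strand = "-")]
  )
  queries[, `:=`(seed = substr(qseq, 1L, k), len = nchar(qseq))]
  hits <- index$dt[queries, on = c(kmer = "seed"), nomatch = NULL,
                   allow.cartesian = TRUE]
  if (nrow(hits) == 0L) return(empty)
  hits <- hits[pos + len <= nchar(index$contigs[contig])]
  if (nrow(hits) == 0L) return(empty)
  hits[, cand_seq := substring(index$contigs[contig], pos + 1L, pos + len)]
  hits <- hits[cand_seq == qseq]
  if (nrow(hits) == 0L) return(empty)
  out <- hits[, .(read_id, contig, start = pos, end = pos + len, strand,
                  five_prime = fifelse(strand == "+", pos, pos + len - 1L))]
  setorder(out, read_id, contig, start, strand)
  out[]
}

#' Map a single read
#'
#' @param index a [build_index()] result.
#' @param read a single sequence, or a one-row collapsed-read table.
#' @return alignment table as in [map_reads()] (possibly empty).
#' @export
map_read <- function(index, read) {
  if (is.character(read) && length(read) == 1L) {
    read <- data.table(id = "read1", seq = read)
  }
  map_reads(index, read)
}
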