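.category_rank <- c(transposon = 1L, satellite = 2L, genic = 3L)
.part_precedence <- c(utr3 = 1L, utr5 = 2L, exon = 3L, intron = 4L)

#' Assign each piRNA a hierarchical category, strand sense and gene feature
#'
#' Category is decided hierarchically over all of a read's alignments:
#' transposon if any alignment overlaps a transposable element, else
#' satellite, else genic (any gene-part overlap), else unannotated. An
#' overlap only qualifies when it covers at least `min_overlap_frac` of the
#' read's length. The deciding alignment is the one with maximal overlap to
#' a feature of the winning category (ties broken by leftmost contig/start);
#' `sense` compares the deciding alignment's strand to the feature's. For
#' genic reads, the feature class is the gene part (CDS-exon, intron, 5'UTR,
#' 3'UTR) with maximal overlap of the read span, ties broken by the fixed
#' precedence utr3 > utr5 > exon > intron.
#'
#' @param reads collapsed-read table (post-screen).
#' @param alignments alignment table from [map_reads()].
#' @param features feature table (from [build_genome()] or [read_gff3()]).
#' @param min_overlap_frac minimum fraction of the read length inside the
#'   feature for an overlap to qualify (default 0.5).
#' @param weighting `"count"` (read weight = pooled count, default) or
#'   `"unique"` (every unique sequence weighs 1).
#' @return a `data.table` with one row per read: `read_id`, `category`,
#'   `te_class`, `feature`, `sense`, `target_id`, `weight`, `read_len`.
#' @export
assign_categories <- function(reads, alignments, features,
                              min_overlap_frac = 0.5,
                              weighting = c("count", "unique")) {
  weighting <- match.arg(weighting)
  reads <- as.data.table(reads)
  aln <- as.data.table(alignments)
  ft <- as.data.table(features)[!ftype %in% blacklist_ftypes]
  base <- data.table(
    read_id = reads$id,
    category = "unannotated", te_class = "none", feature = "none",
    sense = "none", target_id = NA_character_,
    weight = if (weighting == "count") as.numeric(reads$total) else 1,
    read_len = nchar(reads$seq)
  )
  aln <- aln[read_id %in% reads$id]
  if (nrow(aln) == 0L || nrow(ft) == 0L) return(base[])
  agr <- GRanges(aln$contig, IRanges(aln$start + 1L, aln$end))
  fgr <- GRanges(ft$contig, IRanges(ft$start + 1L, ft$end))
  hit <- findOverlaps(agr, fgr, minoverlap = 1L, ignore.strand = TRUE)
  if (length(hit) == 0L) return(base[])
  ai <- queryHits(hit); fi <- subjectHits(hit)
  hits <- data.table(
    read_id = aln$read_id[ai],
    aln_idx = ai,
    aln_contig = aln$contig[ai], aln_start = aln$start[ai],
    aln_strand = aln$strand[ai],
    read_len = aln$end[ai] - aln$start[ai],
    ftype = ft$ftype[fi], feat_strand = ft$strand[fi],
    feat_id = ft$id[fi], gene_id = ft$gene_id[fi], class = ft$class[fi],
    feat_start = ft$start[fi],
    overlap = pmin(aln$end[ai], ft$end[fi]) - pmax(aln$start[ai], ft$start[fi])
  )
  hits[, category := fifelse(ftype == "transposon", "transposon",
                             fifelse(ftype == "satellite", "satellite", "genic"))]
  qual <- hits[overlap >= min_overlap_frac * read_len]
  if (nrow(qual) == 0L) return(base[])
  qual[, cat_rank := .category_rank[category]]
  # winning category per read, then the deciding alignment/feature within it
  setorder(qual, read_id, cat_rank, -overlap, aln_contig, aln_start,
           feat_start, feat_id)
  dec <- qual[, .SD[1L], by = read_id]
  # genic feature class: gene-part overlaps of the deciding alignment,
  # maximal overlap with precedence tie-break
  gdec <- dec[category == "genic"]
  if (nrow(gdec) > 0L) {
    parts <- hits[ftype %in% gene_part_ftypes &
                    aln_idx %in% gdec$aln_idx]
    parts <- merge(parts, gdec[, .(read_id, aln_idx)],
                   by = c("read_id", "aln_idx"))
    parts[, prec := .part_precedence[ftype]]
    setorder(parts, read_id, -overlap, prec)
    best <- parts[, .SD[1L], by = read_id]
    dec <- merge(dec, best[, .(read_id, part = ftype, part_gene = gene_id,
                               part_strand = feat_strand)],
                 by = "read_id", all.x = TRUE)
  } else {
    dec[, `:=`(part = NA_character_, part_gene = NA_character_,
               part_strand = NA_character_)]
  }
  out <- dec[, .(
    read_id,
    category,
    te_class = fifelse(category == "transposon", class, "none"),
    feature = fifelse(category == "genic", part, "none"),
    sense = fifelse(aln_strand == fifelse(category == "genic",
                                          part_strand, feat_strand),
                    "sense", "antisense"),
    target_id = fifelse(category == "genic", part_gene, feat_id)
  )]
  res <- merge(base[, .(read_id, weight, read_len)], out, by = "read_id",
               all.x = TRUE)
  res[is.na(category), `:=`(category = "unannotated", te_class = "none",
                            feature = "none", sense = "none")]
  res[is.na(te_class), te_class := "none"]
  res[is.na(feature), feature := "none"]
  setcolorder(res, c("read_id", "category", "te_class", "feature", "sense",
                     "target_id", "weight", "read_len"))
  setorder(res, read_id)
  res[]
}

#' Read-weighted composition percentages
#'
#' Category percentages over all assigned reads, and gene-part percentages
#' conditioned on the genic category; both sum to 100.
#'
#' @param assignments table from [assign_categories()].
#' @return list with `category` and `genic_features` tables
#'   (`data.table`s of level, summed weight, percentage).
#' @export
composition_summary <- function(assignments) {
  a <- as.data.table(assignments)
  if (nrow(a) == 0L) stop("no assignments to summarize", call. = FALSE)
  cats <- c("transposon", "satellite", "genic", "unannotated")
  by_cat <- a[, .(weight = sum(weight)), by = category]
  by_cat <- merge(data.table(category = cats), by_cat, by = "category",
                  all.x = TRUE)
  by_cat[is.na(weight), weight := 0]
  by_cat[, pct := 100 * weight / sum(weight)]
  by_cat <- by_cat[match(cats, category)]
  g <- a[category == "genic", .(weight = sum(weight)), by = feature]
  parts <- data.table(feature = gene_part_ftypes)
  g <- merge(parts, g, by = "feature", all.x = TRUE)
  g[is.na(weight), weight := 0]
  g[, pct := if (sum(weight) > 0) 100 * weight / sum(weight) else 0]
  g <- g[match(gene_part_ftypes, feature)]
  list(category = by_cat[], genic_features = g[])
}
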