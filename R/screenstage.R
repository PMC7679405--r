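#' Remove reads overlapping ncRNA blacklist loci
#'
#' A read is removed iff any of its alignments overlaps any blacklist
#' interval (tRNA/rRNA/snRNA/snoRNA) by at least 1 nt, on either strand.
#'
#' @param reads collapsed-read table.
#' @param alignments alignment table from [map_reads()].
#' @param blacklist feature table restricted to (or filtered here for)
#'   blacklist feature types.
#' @return list with `kept` (subset of `reads`) and `n_removed`.
#' @export
blacklist_filter <- function(reads, alignments, blacklist) {
  bl <- as.data.table(blacklist)
  if ("ftype" %in% names(bl)) bl <- bl[ftype %in% blacklist_ftypes]
  if (nrow(bl) == 0L || nrow(alignments) == 0L) {
    return(list(kept = reads, n_removed = 0L))
  }
  aln <- as.data.table(alignments)
  agr <- GRanges(aln$contig, IRanges(aln$start + 1L, aln$end))
  bgr <- GRanges(bl$contig, IRanges(bl$start + 1L, bl$end))
  hit <- findOverlaps(agr, bgr, minoverlap = 1L, ignore.strand = TRUE)
  bad_ids <- unique(aln$read_id[queryHits(hit)])
  kept <- reads[!reads$id %in% bad_ids, ]
  list(kept = kept, n_removed = nrow(reads) - nrow(kept))
}

#' Length gate and optional sequence whitelist
#'
#' Keeps reads with `min_len <= length <= max_len`; when a whitelist of
#' sequences is supplied (emulating membership in a curated piRNA database),
#' additionally requires exact sequence membership.
#'
#' @param reads collapsed-read table.
#' @param min_len,max_len inclusive length bounds in nt.
#' @param whitelist optional character vector of admissible sequences.
#' @return list with `kept`, `n_removed_length`, `n_removed_whitelist`.
#' @export
length_whitelist_filter <- function(reads, min_len = 23L, max_len = 29L,
                                    whitelist = NULL) {
  if (min_len > max_len) stop("min_len > max_len", call. = FALSE)
  len <- nchar(reads$seq)
  pass_len <- len >= min_len & len <= max_len
  n_len <- sum(!pass_len)
  kept <- reads[pass_len, ]
  n_wl <- 0L
  if (!is.null(whitelist)) {
    pass_wl <- kept$seq %in% whitelist
    n_wl <- sum(!pass_wl)
    kept <- kept[pass_wl, ]
  }
  list(kept = kept, n_removed_length = n_len, n_removed_whitelist = n_wl)
}

#' Minimum pooled-count filter
#'
#' Keeps reads whose counts summed over samples reach `min_total`. The
#' default scope pools every sample of both conditions; `scope =
#' "per_group"` instead requires the threshold within at least one group.
#'
#' @param reads collapsed-read table.
#' @param min_total minimum summed count (default 10).
#' @param scope `"pooled"` (default) or `"per_group"`.
#' @param groups for `per_group`, a vector of group labels per sample column.
#' @return list with `kept` and `n_removed`.
#' @export
mincount_filter <- function(reads, min_total = 10L, scope = c("pooled", "per_group"),
                            groups = NULL) {
  scope <- match.arg(scope)
  m <- count_matrix(reads)
  pass <- if (scope == "pooled") {
    rowSums(m) >= min_total
  } else {
    if (is.null(groups) || length(groups) != ncol(m)) {
      stop("per_group scope needs one group label per sample", call. = FALSE)
    }
    gsum <- vapply(split(seq_len(ncol(m)), groups),
                   function(j) rowSums(m[, j, drop = FALSE]),
                   numeric(nrow(m)))
    if (nrow(m) == 1L) gsum <- matrix(gsum, nrow = 1L)
    apply(gsum >= min_total, 1L, any)
  }
  list(kept = reads[pass, ], n_removed = sum(!pass))
}

#' Apply the full piRNA candidate screen
#'
#' Blacklist removal, length gate, optional whitelist, then the minimum
#' pooled-count rule; each filter is a pure predicate on a read's own
#' attributes or alignments, so they commute and the screen is idempotent.
#'
#' @param reads collapsed-read table.
#' @param alignments alignment table.
#' @param features feature table (blacklist types are picked out of it).
#' @param min_len,max_len length gate (default 23-29 nt).
#' @param whitelist optional sequence whitelist.
#' @param min_total minimum pooled count (default 10).
#' @param mincount_scope `"pooled"` or `"per_group"`.
#' @param groups group labels for `per_group` scope.
#' @return list with `kept` and `report`, a one-row `data.frame` with
#'   `input_n`, `removed_blacklist`, `removed_length`, `removed_whitelist`,
#'   `removed_mincount`, `kept_n` (tallies sum to `input_n`).
#' @export
filter_pirnas <- function(reads, alignments, features,
                          min_len = 23L, max_len = 29L, whitelist = NULL,
                          min_total = 10L, mincount_scope = "pooled",
                          groups = NULL) {
  input_n <- nrow(reads)
  s1 <- blacklist_filter(reads, alignments, features)
  s2 <- length_whitelist_filter(s1$kept, min_len, max_len, whitelist)
  s3 <- mincount_filter(s2$kept, min_total, mincount_scope, groups)
  report <- data.frame(input_n = input_n,
                       removed_blacklist = s1$n_removed,
                       removed_length = s2$n_removed_length,
                       removed_whitelist = s2$n_removed_whitelist,
                       removed_mincount = s3$n_removed,
                       kept_n = nrow(s3$kept))
  stopifnot(report$input_n == report$kept_n + report$removed_blacklist +
              report$removed_length + report$removed_whitelist +
              report$removed_mincount)
  list(kept = s3$kept, report = report)
}
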