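#' 5'-5' overlap histogram of opposite-strand read pairs
#'
#' For every pair of alignments on the same contig and opposite strands, the
#' overlap is `k = five_prime(minus) - five_prime(plus) + 1` shared
#' positions (1-based inclusive: k = 10 means the two 5' ends overlap by 10
#' nt, the ping-pong signature). Pairs with `1 <= k <= kmax` contribute the
#' product (or minimum) of their read weights to `O(k)`; each unordered
#' pair is counted once.
#'
#' @param alignments alignment table with `contig`, `strand`, `five_prime`.
#' @param weights numeric vector of read weights named by `read_id` (e.g.
#'   pooled counts); defaults to 1 per alignment.
#' @param kmax largest overlap tallied (default 20).
#' @param pair_weight `"product"` (default) or `"min"`.
#' @return a `data.table` with columns `k` (1..kmax) and `weight`.
#' @export
overlap_histogram <- function(alignments, weights = NULL, kmax = 20L,
                              pair_weight = c("product", "min")) {
  pair_weight <- match.arg(pair_weight)
  aln <- as.data.table(alignments)
  if (is.null(weights)) {
    aln[, w := 1]
  } else {
    aln[, w := unname(weights[read_id])]
    if (anyNA(aln$w)) stop("weights missing for some read ids", call. = FALSE)
  }
  hist <- data.table(k = seq_len(kmax), weight = 0)
  plus <- aln[strand == "+", .(contig, fp = five_prime, w)]
  minus <- aln[strand == "-", .(contig, fp = five_prime, w)]
  if (nrow(plus) == 0L || nrow(minus) == 0L) return(hist[])
  setkey(minus, contig, fp)
  for (kk in seq_len(kmax)) {
    m <- minus[plus[, .(contig, fp = fp + kk - 1L, wp = w)],
               on = c("contig", "fp"), nomatch = NULL]
    if (nrow(m) > 0L) {
      set(hist, i = kk, j = "weight",
          value = if (pair_weight == "product") sum(m$w * m$wp)
                  else sum(pmin(m$w, m$wp)))
    }
  }
  hist[]
}

#' Ping-pong z-score at overlap 10
#'
#' Standardizes the 10-nt overlap signal against the background of all other
#' overlap lengths in the histogram: `z = (O(10) - mean(bg)) / sd(bg)` with
#' the sample (n-1) standard deviation over `bg = {O(k) : k != 10}`.
#'
#' @param hist table from [overlap_histogram()]; needs `kmax >= 11`.
#' @return a one-row `data.frame`: `z`, `signal` (O(10)), `bg_mean`,
#'   `bg_sd`.
#' @export
pingpong_zscore <- function(hist) {
  h <- as.data.table(hist)
  if (max(h$k) < 11L) stop("histogram must extend to k >= 11", call. = FALSE)
  signal <- h[k == 10L, weight]
  bg <- h[k != 10L, weight]
  m <- mean(bg)
  s <- sd(bg)
  if (s == 0) {
    stop("ping-pong z undefined: background sd is 0 (all background bins ",
         "equal ", format(m), ")", call. = FALSE)
  }
  data.frame(z = (signal - m) / s, signal = signal, bg_mean = m, bg_sd = s)
}
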