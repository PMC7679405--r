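#' Length-by-strand spectrum of transposon piRNAs
#'
#' Read-weighted sense and antisense counts per read length, over the
#' display window (default 18-35 nt). The two column sums equal the total
#' transposon-assigned weight inside the window.
#'
#' @param assignments table from [assign_categories()], restricted here to
#'   `category == "transposon"`.
#' @param window inclusive length window in nt.
#' @return a `data.table` with columns `length`, `sense`, `antisense`,
#'   one row per observed length, ordered by length.
#' @export
length_strand_spectrum <- function(assignments, window = c(18L, 35L)) {
  a <- as.data.table(assignments)[category == "transposon"]
  if (nrow(a) == 0L) {
    return(data.table(length = integer(0), sense = numeric(0),
                      antisense = numeric(0)))
  }
  a <- a[read_len >= window[1] & read_len <= window[2]]
  sp <- dcast(a[, .(w = sum(weight)), by = .(length = read_len, sense)],
              length ~ sense, value.var = "w", fill = 0)
  for (col in c("sense", "antisense")) {
    if (!col %in% names(sp)) sp[[col]] <- 0
  }
  setorder(sp, length)
  sp[, .(length, sense, antisense)]
}

#' Sense-bias statistic with an exact test of strand parity
#'
#' The sense fraction of the (weighted) spectrum, with a two-sided exact
#' binomial p-value against equal sense/antisense production (weights are
#' rounded to integers for the test).
#'
#' @param spectrum table from [length_strand_spectrum()].
#' @return a one-row `data.frame`: `sense_fraction`, `p_parity`, `n_total`.
#' @export
bias_test <- function(spectrum) {
  s <- sum(spectrum$sense)
  a <- sum(spectrum$antisense)
  n <- s + a
  if (n < 1) stop("empty spectrum: no transposon-assigned weight", call. = FALSE)
  bt <- binom.test(round(s), round(s) + round(a), p = 0.5,
                   alternative = "two.sided")
  data.frame(sense_fraction = s / n, p_parity = unname(bt$p.value),
             n_total = n)
}
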