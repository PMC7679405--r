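#' Reverse complement of DNA sequences
#'
#' Vectorized over a character vector of A/C/G/T(/N) sequences.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# proportions must sum to 1 (within tolerance) and be non-negative
check_proportions <- function(p, what, tol = 1e-9) {
  if (any(p < 0)) stop(what, " contains negative proportions", call. = FALSE)
  if (abs(sum(p) - 1) > tol) {
    stop(what, " must sum to 1 (got ", format(sum(p), digits = 12), ")",
         call. = FALSE)
  }
  invisible(p)
}

# derive a child seed from a base seed, kept within 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 100 + offset) %% 2147483647)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
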