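#' @importFrom stats aggregate lm median pnorm pt quantile rbinom rmultinom
#'   rpois runif sd setNames rnorm poisson.test var coef
#' @importFrom utils read.delim write.table head tail
NULL

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Encode a nucleotide string as integers
#'
#' Maps A, C, G, T to 0..3; any other letter (N, ambiguity codes) becomes NA.
#'
#' @param seq A single character string or a `Biostrings::DNAString`.
#' @return Integer vector of the same length as the sequence.
#' @keywords internal
encode_dna <- function(seq) {
  s <- toupper(as.character(seq))
  v <- utf8ToInt(s)
  enc <- rep(NA_integer_, length(v))
  enc[v == 65L] <- 0L  # A
  enc[v == 67L] <- 1L  # C
  enc[v == 71L] <- 2L  # G
  enc[v == 84L] <- 3L  # T
  enc
}

decode_dna <- function(enc) {
  paste(BASES[enc + 1L], collapse = "")
}

#' Integer codes of the k-mer centered on every position
#'
#' Position i receives the base-4 code of the k-mer spanning
#' `[i - (k-1)/2, i + (k-1)/2]` (leftmost base most significant, matching
#' lexicographic k-mer order). Positions too close to the sequence ends, or
#' whose k-mer contains a non-ACGT base, receive NA.
#'
#' @param enc Integer-encoded sequence (from [encode_dna()]).
#' @param k Odd k-mer width.
#' @return Integer vector of length `length(enc)` with values in
#'   `0:(4^k - 1)` or NA.
#' @keywords internal
centered_kmer_codes <- function(enc, k) {
  stopifnot(k %% 2 == 1, k >= 1)
  n <- length(enc)
  if (n < k) return(rep(NA_integer_, n))
  half <- (k - 1L) %/% 2L
  m <- n - k + 1L
  codes <- integer(m)
  for (j in seq_len(k)) {
    codes <- codes * 4L + enc[j:(m + j - 1L)]
  }
  out <- rep(NA_integer_, n)
  out[(half + 1L):(n - half)] <- codes
  out
}

#' Centered k-mer codes for every chromosome of a genome
#' @keywords internal
genome_codes <- function(genome, k) {
  lapply(genome, function(s) centered_kmer_codes(encode_dna(s), k))
}

#' All k-mer strings in code (lexicographic) order
#' @keywords internal
kmer_strings <- function(k) {
  if (k == 0) return("")
  grids <- rev(expand.grid(rep(list(BASES), k), stringsAsFactors = FALSE))
  do.call(paste0, grids)
}

#' Extract the j-th digit (1 = leftmost) of base-4 k-mer codes
#' @keywords internal
kmer_digit <- function(codes, j, k) {
  (codes %/% 4L^(k - j)) %% 4L
}

complement_code <- function(b) 3L - b

revcomp_string <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# ---- interval helpers (1-based, inclusive ends) -----------------------------

#' Merge overlapping or touching intervals
#' @param df data.frame with `start`, `end` columns (1-based inclusive).
#' @keywords internal
merge_intervals <- function(df) {
  if (nrow(df) == 0) return(df[, c("start", "end")])
  ir <- IRanges::reduce(IRanges::IRanges(df$start, df$end))
  data.frame(start = IRanges::start(ir), end = IRanges::end(ir))
}

#' Total bases of overlap between two interval sets on one chromosome
#' @keywords internal
interval_overlap_bp <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(0L)
  ia <- IRanges::IRanges(a$start, a$end)
  ib <- IRanges::reduce(IRanges::IRanges(b$start, b$end))
  sum(IRanges::width(IRanges::intersect(IRanges::reduce(ia), ib)))
}

#' Does any interval in `a` overlap any interval in `b`?
#' @keywords internal
intervals_overlap_any <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(FALSE)
  ia <- IRanges::IRanges(a$start, a$end)
  ib <- IRanges::IRanges(b$start, b$end)
  length(IRanges::findOverlaps(ia, ib)) > 0
}

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
    stop(sprintf("'%s' must be a single non-negative number", name),
         call. = FALSE)
  }
}
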