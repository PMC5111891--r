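# internal helpers shared across modules

#' @importFrom Biostrings DNAString reverseComplement readDNAStringSet
#'   writeXStringSet DNAStringSet pairwiseAlignment nucleotideSubstitutionMatrix
#'   alignedPattern alignedSubject
NULL

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string
#'
#' @param x a single character string over \{A,C,G,T,N\}.
#' @return the reverse complement, as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# reverse complement of a character vector of single bases
revcomp_chars <- function(ch) {
  rev(unname(COMPLEMENT[ch]))
}

complement_chars <- function(ch) {
  unname(COMPLEMENT[ch])
}

# split a sequence string into a character vector of bases
seq_chars <- function(x) {
  strsplit(x, "", fixed = TRUE)[[1L]]
}

# 1-based circular index into 1..n
circ_index <- function(i, n) {
  ((i - 1L) %% n) + 1L
}

# length of the circular interval start..end (inclusive), wrapping allowed
circ_span <- function(start, end, n) {
  ((end - start) %% n) + 1L
}

# extract circular substring start..end (inclusive, may wrap)
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  start <- circ_index(start, n)
  end <- circ_index(end, n)
  if (start <= end) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end))
  }
}

# does circular interval [s1,e1] overlap [s2,e2]?  (all 1..n, may wrap)
circ_overlaps <- function(s1, e1, s2, e2, n) {
  pos1 <- circ_positions(s1, e1, n)
  pos2 <- circ_positions(s2, e2, n)
  length(intersect(pos1, pos2)) > 0L
}

# positions covered by circular interval
circ_positions <- function(start, end, n) {
  circ_index(seq.int(start, start + circ_span(start, end, n) - 1L), n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
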