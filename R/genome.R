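#' Circular plastome sequence
#'
#' Constructs a `CircularGenome`, the unit every analysis stage consumes: a
#' named circular DNA sequence over the alphabet \{A,C,G,T,N\}. Input is
#' case-normalized to upper case.
#'
#' @param id text label for the genome (e.g. an accession).
#' @param sequence a single character string of DNA bases.
#' @param circular logical; plastomes are circular (default `TRUE`).
#' @return an object of class `CircularGenome` with fields `id`, `seq`,
#'   `length` and `circular`.
#' @export
circular_genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n == 0L) stop("genome sequence is empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(unique(seq_chars(substr(bad, 1L, 10L))), collapse = ","))
  }
  structure(
    list(id = id, seq = sequence, length = n, circular = isTRUE(circular)),
    class = "CircularGenome"
  )
}

#' @export
print.CircularGenome <- function(x, ...) {
  cat(sprintf("CircularGenome %s: %s bp%s\n", x$id,
              format(x$length, big.mark = ","),
              if (x$circular) " (circular)" else ""))
  invisible(x)
}

#' @export
length.CircularGenome <- function(x) x$length

#' Read a plastome from a FASTA file
#'
#' Reads plain or gzipped FASTA. With a multi-record file, `id` selects the
#' record; otherwise multi-record input is an error.
#'
#' @param path FASTA file path.
#' @param id optional record name to select.
#' @return a [circular_genome()].
#' @export
read_genome <- function(path, id = NULL) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (is.null(id)) {
    if (length(set) > 1L) {
      stop("multi-record FASTA; specify `id` (records: ",
           paste(utils::head(nm, 5L), collapse = ", "), ")")
    }
    i <- 1L
  } else {
    i <- match(id, nm)
    if (is.na(i)) stop("record '", id, "' not found in ", path)
  }
  circular_genome(nm[i], as.character(set[[i]]))
}

#' Write a plastome to a FASTA file
#'
#' @param genome a [circular_genome()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  stopifnot(inherits(genome, "CircularGenome"))
  set <- Biostrings::DNAStringSet(genome$seq)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Rotate a circular genome
#'
#' Returns the genome rewritten so that original position `new_start`
#' becomes position 1.
#'
#' @param genome a [circular_genome()].
#' @param new_start 1-based position to rotate to the front.
#' @return a rotated [circular_genome()].
#' @export
rotate_genome <- function(genome, new_start) {
  stopifnot(inherits(genome, "CircularGenome"))
  n <- genome$length
  new_start <- circ_index(new_start, n)
  if (new_start == 1L) return(genome)
  circular_genome(genome$id,
                  paste0(substr(genome$seq, new_start, n),
                         substr(genome$seq, 1L, new_start - 1L)))
}

#' Reverse complement of a circular genome
#'
#' @param genome a [circular_genome()].
#' @return the reverse-complemented [circular_genome()].
#' @export
revcomp_genome <- function(genome) {
  stopifnot(inherits(genome, "CircularGenome"))
  circular_genome(genome$id, revcomp(genome$seq))
}

#' GC content of a DNA sequence
#'
#' Computes (G + C) / (A + C + G + T). `N` and any other IUPAC ambiguity
#' codes are excluded from both numerator and denominator.
#'
#' @param sequence a single DNA character string, or a [circular_genome()].
#' @return proportion in \[0, 1\].
#' @export
gc_content <- function(sequence) {
  if (inherits(sequence, "CircularGenome")) sequence <- sequence$seq
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) stop("empty sequence")
  sequence <- toupper(sequence)
  ch <- seq_chars(sequence)
  gc <- sum(ch == "G" | ch == "C")
  at <- sum(ch == "A" | ch == "T")
  if (gc + at == 0L) stop("sequence has no unambiguous A/C/G/T bases")
  gc / (gc + at)
}
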