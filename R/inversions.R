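#' Detect micro-inversions between two aligned plastomes
#'
#' Short inversions show up in an alignment of near-identical genomes as a
#' dense run of mismatching columns whose second-genome segment equals the
#' reverse complement of the standard's segment. For each maximal mismatch
#' run, the shortest gap-free window containing it that satisfies the
#' reverse-complement test (interior positions can match by coincidence) is
#' emitted; reported intervals should then be excluded from substitution
#' calling, so an inverted segment is counted once, as an inversion, rather
#' than as a cluster of SNPs. Segments that are their own reverse complement
#' (perfect palindromes) are undetectable by definition and never emitted.
#'
#' @param aln a [plastome_alignment()].
#' @param min_len minimum inversion length (default 3; a shorter
#'   revcomp-matching mismatch pair is formally ambiguous with substitutions
#'   and is left to the SNP caller).
#' @param max_len maximum inversion length considered (default 100).
#' @param features optional annotation for location labels.
#' @param genome optional standard [circular_genome()]; when given, flanking
#'   hairpin stem arms are measured with [find_stem_arms()].
#' @param max_arm,arm_mismatches stem-arm search parameters (see
#'   [find_stem_arms()]).
#' @return data.frame with columns `start`, `end`, `length` (standard-genome
#'   coordinates), `stem_arm_length` (`NA` unless `genome` given),
#'   `category`, `location`.
#' @export
detect_microinversions <- function(aln, min_len = 3L, max_len = 100L,
                                   features = NULL, genome = NULL,
                                   max_arm = 50L, arm_mismatches = 0L) {
  stopifnot(inherits(aln, "PlastomeAlignment"))
  if (min_len < 2L) stop("min_len must be >= 2")
  rc <- aln$ref_chars; ac <- aln$alt_chars
  nc <- aln$ncol
  nongap <- rc != "-" & ac != "-"
  mism <- nongap & rc != ac
  # column i of the window pairs with column j = s - i on anti-diagonal s;
  # the window is a true inversion iff alt[i] complements ref[s - i] throughout
  comp_rc <- ifelse(nongap, complement_chars(rc), NA_character_)
  r <- rle(mism)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  out <- list()
  claimed <- rep(FALSE, nc)
  for (q in runs) {
    c0 <- starts[q]; c1 <- ends[q]
    if (claimed[c0]) next
    runlen <- c1 - c0 + 1L
    if (runlen > max_len) next
    best <- NULL                       # c(a2, b2), shortest window wins
    for (s in seq.int(2L * c1 - max_len + 1L, 2L * c0 + max_len - 1L)) {
      a2 <- min(c0, s - c1)            # smallest symmetric window covering the run
      b2 <- s - a2
      if (a2 < 1L || b2 > nc) next
      w <- b2 - a2 + 1L
      if (w < max(min_len, runlen) || w > max_len) next
      if (!is.null(best) && w >= best[2L] - best[1L] + 1L) next
      i <- a2:b2
      good <- nongap[i] & !is.na(comp_rc[s - i]) & ac[i] == comp_rc[s - i]
      if (all(good)) best <- c(a2, b2)
    }
    if (is.null(best)) next
    claimed[best[1L]:best[2L]] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      start = aln$ref_coords[best[1L]], end = aln$ref_coords[best[2L]],
      length = best[2L] - best[1L] + 1L, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) unique(do.call(rbind, out)) else
    data.frame(start = integer(), end = integer(), length = integer())
  rownames(res) <- NULL
  res$stem_arm_length <- if (!is.null(genome) && nrow(res)) {
    vapply(seq_len(nrow(res)), function(i)
      find_stem_arms(genome, c(res$start[i], res$end[i]),
                     max_arm = max_arm, max_mismatches = arm_mismatches),
      integer(1L))
  } else rep(NA_integer_, nrow(res))
  res$category <- rep(NA_character_, nrow(res))
  res$location <- rep(NA_character_, nrow(res))
  if (!is.null(features) && nrow(res)) {
    cl <- classify_position(res$start, features,
                            genome_length = max(aln$ref_coords, na.rm = TRUE))
    res$category <- cl$category
    res$location <- cl$context
  }
  res
}

#' Measure the inverted-repeat stem arms flanking an inversion
#'
#' Length of the longest stretch for which the bases immediately 5' of the
#' interval are the reverse complement of the bases immediately 3' of it:
#' the stem of the hairpin the locus can fold into, measured strictly
#' outside the inverted interval. Indexing is circular.
#'
#' @param genome a [circular_genome()].
#' @param interval length-2 vector `c(start, end)`, 1-based inclusive.
#' @param max_arm longest arm considered (default 50).
#' @param max_mismatches mismatch budget inside the paired arms (default 0:
#'   hairpin stems of reported plastome micro-inversions are drawn perfect).
#' @return integer arm length (0 when even the first flanking pair does not
#'   complement).
#' @export
find_stem_arms <- function(genome, interval, max_arm = 50L, max_mismatches = 0L) {
  stopifnot(inherits(genome, "CircularGenome"), length(interval) == 2L)
  L <- genome$length
  ch <- seq_chars(genome$seq)
  t <- seq_len(min(max_arm, (L - (circ_span(interval[1L], interval[2L], L))) %/% 2L))
  if (length(t) == 0L) return(0L)
  left <- ch[circ_index(interval[1L] - t, L)]
  right <- ch[circ_index(interval[2L] + t, L)]
  match <- left == complement_chars(right)
  mis <- cumsum(!match)
  ok <- which(match & mis <= max_mismatches)
  if (length(ok) == 0L) 0L else max(ok)
}
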