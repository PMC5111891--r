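#' Construct a pairwise plastome alignment object
#'
#' Container for a gapped global alignment of two near-identical genomes.
#' Per-column source coordinates are derived from the gapped strings; a
#' column gapped in both rows is invalid.
#'
#' @param ref_id,alt_id sequence labels (ref = the designated standard).
#' @param ref_aln,alt_aln gapped sequences of equal length (`-` = gap).
#' @return an object of class `PlastomeAlignment` with fields `ref_id`,
#'   `alt_id`, `ref_chars`, `alt_chars` (per-column character vectors),
#'   `ref_coords`, `alt_coords` (source positions, `NA` at gaps), `ncol`.
#' @export
plastome_alignment <- function(ref_id, alt_id, ref_aln, alt_aln) {
  stopifnot(nchar(ref_aln) == nchar(alt_aln), nchar(ref_aln) > 0L)
  rc <- seq_chars(toupper(ref_aln))
  ac <- seq_chars(toupper(alt_aln))
  if (any(rc == "-" & ac == "-")) stop("alignment column gapped in both rows")
  ref_coords <- ifelse(rc == "-", NA_integer_, cumsum(rc != "-"))
  alt_coords <- ifelse(ac == "-", NA_integer_, cumsum(ac != "-"))
  structure(list(ref_id = ref_id, alt_id = alt_id,
                 ref_chars = rc, alt_chars = ac,
                 ref_coords = as.integer(ref_coords),
                 alt_coords = as.integer(alt_coords),
                 ncol = length(rc)),
            class = "PlastomeAlignment")
}

#' @export
print.PlastomeAlignment <- function(x, ...) {
  nmis <- sum(x$ref_chars != x$alt_chars & x$ref_chars != "-" & x$alt_chars != "-")
  ngap <- sum(x$ref_chars == "-" | x$alt_chars == "-")
  cat(sprintf("PlastomeAlignment %s vs %s: %s columns, %d mismatches, %d gap columns\n",
              x$ref_id, x$alt_id, format(x$ncol, big.mark = ","), nmis, ngap))
  invisible(x)
}

ungapped <- function(chars) paste(chars[chars != "-"], collapse = "")

#' Align two near-identical plastomes
#'
#' Anchor-based collinear aligner for genome pairs at very low divergence
#' (the regime of congeneric plastomes, ~0.03%): k-mers unique in both
#' genomes are chained collinearly (weighted longest increasing subsequence
#' over maximal co-diagonal anchor runs) and the short inter-anchor gaps are
#' resolved by optimal global alignment (match +1, mismatch -1, gap open -5,
#' gap extend -1). Both genomes should be canonically rotated first (see
#' [canonical_rotation()]).
#'
#' @param standard the designated standard [circular_genome()] (alignment
#'   reference; indel polarity is reported relative to it).
#' @param other the second [circular_genome()].
#' @param k anchor k-mer size (default 21).
#' @param max_gap maximum inter-anchor gap width the optimal filler will
#'   attempt (default 20000 bp).
#' @param min_anchor_cov minimum fraction of each genome the anchor chain
#'   must cover; below it the genomes are declared non-collinear
#'   (default 0.9).
#' @return a [plastome_alignment()].
#' @export
align_pair <- function(standard, other, k = 21L, max_gap = 20000L,
                       min_anchor_cov = 0.9) {
  stopifnot(inherits(standard, "CircularGenome"), inherits(other, "CircularGenome"))
  s1 <- standard$seq; s2 <- other$seq
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (identical(s1, s2)) {
    return(plastome_alignment(standard$id, other$id, s1, s2))
  }
  k1 <- substring(s1, 1:(n1 - k + 1L), k:n1)
  k2 <- substring(s2, 1:(n2 - k + 1L), k:n2)
  u1 <- !(duplicated(k1) | duplicated(k1, fromLast = TRUE))
  u2 <- !(duplicated(k2) | duplicated(k2, fromLast = TRUE))
  m <- match(k1, k2)
  sel <- which(u1 & !is.na(m))
  sel <- sel[u2[m[sel]]]
  if (length(sel) == 0L) stop("non-collinear genomes: no unique shared anchors")
  i <- sel; j <- m[sel]                       # ascending in i
  brk <- c(TRUE, diff(i) != 1L | diff(j) != 1L)
  seg_id <- cumsum(brk)
  segs <- data.frame(i0 = tapply(i, seg_id, min), j0 = tapply(j, seg_id, min),
                     span = tapply(i, seg_id, length) + k - 1L)
  segs <- segs[order(segs$i0), , drop = FALSE]

  # weighted LIS over anchor segments (compatible = strictly after in both)
  ns <- nrow(segs)
  best <- segs$span; prev <- rep(NA_integer_, ns)
  if (ns > 1L) {
    i_end <- segs$i0 + segs$span - 1L
    j_end <- segs$j0 + segs$span - 1L
    for (q in 2:ns) {
      ok <- which(i_end[1:(q - 1L)] < segs$i0[q] & j_end[1:(q - 1L)] < segs$j0[q])
      if (length(ok)) {
        w <- best[ok] + segs$span[q]
        b <- which.max(w)
        if (w[b] > best[q]) { best[q] <- w[b]; prev[q] <- ok[b] }
      }
    }
  }
  chain <- integer(0); q <- which.max(best)
  while (!is.na(q)) { chain <- c(q, chain); q <- prev[q] }
  ch <- segs[chain, , drop = FALSE]
  # coverage credit: chained anchors plus, for each inter-anchor gap, the
  # shorter of its two sides. Repeat-induced anchor deserts (the IR copies
  # are never unique) leave near-symmetric gaps and still count as covered;
  # a rotated or rearranged genome leaves grossly asymmetric end gaps and
  # fails the check.
  b1 <- c(ch$i0[1L] - 1L, diff(ch$i0) - ch$span[-nrow(ch)],
          n1 - (ch$i0[nrow(ch)] + ch$span[nrow(ch)] - 1L))
  b2 <- c(ch$j0[1L] - 1L, diff(ch$j0) - ch$span[-nrow(ch)],
          n2 - (ch$j0[nrow(ch)] + ch$span[nrow(ch)] - 1L))
  cov <- sum(ch$span) + sum(pmin(b1, b2))
  if (cov / n1 < min_anchor_cov || cov / n2 < min_anchor_cov) {
    stop(sprintf(paste0("non-collinear genomes: anchor chain covers %.1f%% of %s ",
                        "and %.1f%% of %s (need %.0f%%); are both canonically rotated?"),
                 100 * cov / n1, standard$id, 100 * cov / n2, other$id,
                 100 * min_anchor_cov))
  }

  fill <- function(p1, p2) {
    if (nchar(p1) == 0L && nchar(p2) == 0L) return(NULL)
    if (nchar(p1) == 0L) return(c(strrep("-", nchar(p2)), p2))
    if (nchar(p2) == 0L) return(c(p1, strrep("-", nchar(p1))))
    if (identical(p1, p2)) return(c(p1, p2))
    if (nchar(p1) > max_gap || nchar(p2) > max_gap) {
      stop("inter-anchor gap exceeds max_gap (", max_gap, " bp)")
    }
    pa <- Biostrings::pairwiseAlignment(
      p1, p2, type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -1, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 1)
    c(as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)))
  }

  pieces_r <- character(0); pieces_a <- character(0)
  pos1 <- 1L; pos2 <- 1L
  for (q in seq_len(nrow(ch))) {
    g <- fill(substr(s1, pos1, ch$i0[q] - 1L), substr(s2, pos2, ch$j0[q] - 1L))
    if (!is.null(g)) { pieces_r <- c(pieces_r, g[1L]); pieces_a <- c(pieces_a, g[2L]) }
    anc <- substr(s1, ch$i0[q], ch$i0[q] + ch$span[q] - 1L)
    pieces_r <- c(pieces_r, anc); pieces_a <- c(pieces_a, anc)
    pos1 <- ch$i0[q] + ch$span[q]
    pos2 <- ch$j0[q] + ch$span[q]
  }
  g <- fill(substr(s1, pos1, n1), substr(s2, pos2, n2))
  if (!is.null(g)) { pieces_r <- c(pieces_r, g[1L]); pieces_a <- c(pieces_a, g[2L]) }

  aln <- plastome_alignment(standard$id, other$id,
                            paste(pieces_r, collapse = ""),
                            paste(pieces_a, collapse = ""))
  # round-trip invariant: de-gapping reproduces the inputs exactly
  stopifnot(identical(ungapped(aln$ref_chars), s1),
            identical(ungapped(aln$alt_chars), s2))
  aln
}
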