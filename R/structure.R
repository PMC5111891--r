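#' @import data.table
NULL

# All maximal inverted-match pairs of a circular sequence.
#
# Works on the doubled sequence so origin-spanning repeats are found; seeds
# are shared k-mers between the doubled sequence and its reverse complement,
# merged into maximal runs per anti-diagonal and (for max_mismatches > 0)
# extended under the mismatch budget by direct character comparison.
# Returns a data.table with circle coordinates: start_a, start_b, len.
inverted_match_pairs <- function(seq, min_len, max_mismatches = 0L, k = 21L) {
  L <- nchar(seq)
  k <- as.integer(min(k, max(4L, min_len)))
  Ts <- paste0(seq, seq)
  Rs <- revcomp(Ts)
  n2 <- 2L * L
  nk <- n2 - k + 1L
  kT <- substring(Ts, 1:nk, k:n2)
  kR <- substring(Rs, 1:nk, k:n2)
  dtT <- data.table(kmer = kT, i = seq_len(nk))
  dtR <- data.table(kmer = kR, p = seq_len(nk))
  pairs <- merge(dtT, dtR, by = "kmer", allow.cartesian = TRUE)
  if (nrow(pairs) == 0L) return(data.table(start_a = integer(), start_b = integer(), len = integer()))
  pairs[, d := i - p]
  setorder(pairs, d, i)
  brk <- c(TRUE, diff(pairs$d) != 0L | diff(pairs$i) != 1L)
  pairs[, run := cumsum(brk)]
  runs <- pairs[, .(i0 = i[1L], p0 = p[1L], m = .N + k - 1L), by = run]

  if (max_mismatches > 0L) {
    tch <- seq_chars(Ts)
    rch <- seq_chars(Rs)
    ext <- function(i0, p0, m) {
      # extend left then right, greedily spending the mismatch budget;
      # trim so both flanks end on a matching character
      budget <- max_mismatches
      li <- i0; lp <- p0
      while (li > 1L && lp > 1L) {
        if (tch[li - 1L] == rch[lp - 1L]) { li <- li - 1L; lp <- lp - 1L }
        else if (budget > 0L) { budget <- budget - 1L; li <- li - 1L; lp <- lp - 1L }
        else break
      }
      while (li < i0 && tch[li] != rch[lp]) { li <- li + 1L; lp <- lp + 1L; budget <- budget + 1L }
      ri <- i0 + m - 1L; rp <- p0 + m - 1L
      while (ri < n2 && rp < n2) {
        if (tch[ri + 1L] == rch[rp + 1L]) { ri <- ri + 1L; rp <- rp + 1L }
        else if (budget > 0L) { budget <- budget - 1L; ri <- ri + 1L; rp <- rp + 1L }
        else break
      }
      while (ri > i0 + m - 1L && tch[ri] != rch[rp]) { ri <- ri - 1L; rp <- rp - 1L }
      c(li, lp, ri - li + 1L)
    }
    em <- t(mapply(ext, runs$i0, runs$p0, runs$m))
    runs <- unique(data.table(i0 = em[, 1L], p0 = em[, 2L], m = em[, 3L]))
  }

  runs <- runs[m >= min_len]
  if (nrow(runs) == 0L) return(data.table(start_a = integer(), start_b = integer(), len = integer()))
  runs[, m := pmin(m, L)]
  runs[, j2 := 2L * L - p0 - m + 2L]
  runs[, `:=`(a = circ_index(i0, L), b = circ_index(j2, L))]
  cand <- unique(runs[, .(start_a = pmin(a, b), start_b = pmax(a, b), len = m)])
  # keep the longest representation of each physical pair
  cand <- cand[, .(len = max(len)), by = .(start_a, start_b)]
  cand[]
}

#' Detect the quadripartite LSC/IRb/SSC/IRa structure
#'
#' Finds the maximal-length pair of disjoint segments of a circular plastome
#' such that one is the reverse complement of the other (the inverted
#' repeat), and labels the two intervening arcs LSC (longer) and SSC
#' (shorter). Detection is seed-and-extend on shared k-mers between the
#' doubled sequence and its reverse complement, and is invariant under
#' circular rotation of the input.
#'
#' @param genome a [circular_genome()].
#' @param min_ir_length minimum IR length to accept (default 1000 bp;
#'   plastome IRs are typically 20-30 kb).
#' @param max_mismatches mismatch budget inside the IR pair (default 0;
#'   plastome IR copies are exact).
#' @param k seed k-mer size (default 21).
#' @return a `QuadripartiteStructure`: list with `genome_id`, `regions`
#'   (data.frame name/start/end/length/gc_fraction, 1-based inclusive
#'   coordinates, end < start means the region wraps the origin),
#'   `ir_length`, `total_length`.
#' @export
detect_inverted_repeats <- function(genome, min_ir_length = 1000L,
                                    max_mismatches = 0L, k = 21L) {
  stopifnot(inherits(genome, "CircularGenome"))
  min_ir_length <- as.integer(min_ir_length)
  if (min_ir_length < 1L) stop("min_ir_length must be >= 1")
  L <- genome$length
  if (L < 2L * min_ir_length) stop("genome shorter than 2 * min_ir_length")

  cand <- inverted_match_pairs(genome$seq, min_ir_length, max_mismatches, k)
  if (nrow(cand) > 0L) {
    ok <- vapply(seq_len(nrow(cand)), function(r) {
      a <- cand$start_a[r]; b <- cand$start_b[r]; m <- cand$len[r]
      if (a == b) return(FALSE)
      !circ_overlaps(a, circ_index(a + m - 1L, L), b, circ_index(b + m - 1L, L), L)
    }, logical(1L))
    cand <- cand[ok]
  }
  if (nrow(cand) == 0L) stop("no quadripartite structure: no disjoint inverted pair >= ",
                             min_ir_length, " bp")
  best <- cand[len == max(len)]
  if (nrow(best) > 1L) {
    stop("ambiguous quadripartite structure: ", nrow(best),
         " non-equivalent maximal inverted pairs of length ", best$len[1L])
  }
  a <- best$start_a; b <- best$start_b; m <- best$len

  arc1_start <- circ_index(a + m, L); arc1_len <- (b - (a + m)) %% L
  arc2_start <- circ_index(b + m, L); arc2_len <- (a - (b + m)) %% L
  if (arc1_len == 0L || arc2_len == 0L) {
    stop("no quadripartite structure: inverted pair leaves an empty single-copy arc")
  }
  if (arc1_len == arc2_len) {
    stop("ambiguous quadripartite structure: the two single-copy arcs have equal length")
  }
  if (arc1_len > arc2_len) {
    lsc <- c(arc1_start, arc1_len); ssc <- c(arc2_start, arc2_len)
    irb <- b; ira <- a          # IR following the LSC arc is IRb
  } else {
    lsc <- c(arc2_start, arc2_len); ssc <- c(arc1_start, arc1_len)
    irb <- a; ira <- b
  }

  reg <- data.frame(
    name = c("LSC", "IRb", "SSC", "IRa"),
    start = c(lsc[1L], irb, ssc[1L], ira),
    length = c(lsc[2L], m, ssc[2L], m),
    stringsAsFactors = FALSE
  )
  reg$end <- circ_index(reg$start + reg$length - 1L, L)
  reg$gc_fraction <- vapply(seq_len(4L), function(r) {
    gc_content(circ_substr(genome$seq, reg$start[r], reg$end[r]))
  }, numeric(1L))
  reg <- reg[, c("name", "start", "end", "length", "gc_fraction")]

  out <- structure(
    list(genome_id = genome$id, regions = reg,
         ir_length = m, total_length = L),
    class = "QuadripartiteStructure"
  )
  validate_structure(out)
  out
}

validate_structure <- function(x) {
  reg <- x$regions
  if (any(reg$length < 1L)) stop("degenerate region of length 0")
  if (sum(reg$length) != x$total_length) {
    stop("regions do not tile the circle: lengths sum to ", sum(reg$length),
         " but genome is ", x$total_length, " bp")
  }
  invisible(x)
}

#' @export
print.QuadripartiteStructure <- function(x, ...) {
  cat(sprintf("QuadripartiteStructure of %s (%s bp, IR %s bp)\n", x$genome_id,
              format(x$total_length, big.mark = ","),
              format(x$ir_length, big.mark = ",")))
  reg <- x$regions
  reg$gc_percent <- sprintf("%.1f", 100 * reg$gc_fraction)
  print(reg[, c("name", "start", "end", "length", "gc_percent")], row.names = FALSE)
  invisible(x)
}

region_string <- function(structure, genome, name) {
  r <- structure$regions[structure$regions$name == name, ]
  circ_substr(genome$seq, r$start, r$end)
}

#' Rotate a plastome into the canonical LSC-first layout
#'
#' Rewrites the genome so position 1 is the first LSC base and the layout is
#' LSC, IRb, SSC, IRa. Two layouts satisfy this (the genome and its reverse
#' complement); the lexicographically smaller sequence is chosen, so the
#' result is a pure function of the circular molecule: any rotation or
#' reverse complement of the same molecule canonicalizes to the same string.
#'
#' @param structure result of [detect_inverted_repeats()] on `genome`.
#' @param genome the [circular_genome()] the structure was computed from.
#' @return the canonically rotated [circular_genome()].
#' @export
canonical_rotation <- function(structure, genome) {
  stopifnot(inherits(structure, "QuadripartiteStructure"),
            inherits(genome, "CircularGenome"))
  if (structure$total_length != genome$length) {
    stop("structure was not computed from this genome (length mismatch)")
  }
  reg <- structure$regions
  lsc <- reg[reg$name == "LSC", ]
  L <- genome$length
  cand1 <- rotate_genome(genome, lsc$start)$seq
  # forward layout of the reverse complement: rc(LSC) becomes its LSC
  rc <- revcomp_genome(genome)
  cand2 <- rotate_genome(rc, L - circ_index(lsc$start + lsc$length - 1L, L) + 1L)$seq
  circular_genome(genome$id, if (cand2 < cand1) cand2 else cand1)
}

#' Tabular report of a quadripartite structure
#'
#' @param structure a `QuadripartiteStructure`.
#' @return data.frame with columns region, start, end, length, gc_percent
#'   (one decimal, as conventionally reported).
#' @export
structure_report <- function(structure) {
  stopifnot(inherits(structure, "QuadripartiteStructure"))
  reg <- structure$regions
  data.frame(region = reg$name, start = reg$start, end = reg$end,
             length = reg$length,
             gc_percent = round(100 * reg$gc_fraction, 1L),
             stringsAsFactors = FALSE)
}
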