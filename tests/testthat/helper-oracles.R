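# independent oracles and small fixture builders used across the suite

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a small, fast synthetic pair (scaled-down genome, same architecture)
small_pair <- function(seed, n_substitutions = 25L, n_homopolymer_indels = 6L,
                       n_other_indels = 4L, n_inversions = 2L, ...) {
  plastome_pair(
    genome_spec(lsc_len = 12000L, ssc_len = 5000L, ir_len = 3000L,
                n_genes = 10L, intron_genes = 3L, seed = seed),
    mutation_spec(n_substitutions = n_substitutions,
                  n_homopolymer_indels = n_homopolymer_indels,
                  n_other_indels = n_other_indels,
                  n_inversions = n_inversions, seed = seed + 1000L, ...))
}

# exhaustive inverted-pair finder: per-diagonal equality sweep of the linear
# sequence against its reverse complement (no seeding, no doubling)
brute_force_ir <- function(seq, min_len) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  R <- rev(unname(comp[ch]))
  bestlen <- 0L; pairs <- list()
  for (d in (-(n - 1L)):(n - 1L)) {
    idx <- max(1L, 1L + d):min(n, n + d)
    eq <- ch[idx] == R[idx - d]
    r <- rle(eq)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values & r$lengths >= min_len)) {
      i <- idx[starts[q]]; m <- r$lengths[q]
      p <- i - d
      j <- n - p - m + 2L
      a <- min(i, j); b <- max(i, j)
      if (a == b || a + m - 1L >= b) next        # self-match or overlap
      if (m > bestlen) { bestlen <- m; pairs <- list(c(a, b, m)) }
      else if (m == bestlen) pairs <- c(pairs, list(c(a, b, m)))
    }
  }
  list(len = bestlen, pairs = unique(pairs))
}

# regex-backtracking SSR enumerator (R's PCRE engine as independent machinery)
ssr_oracle_regex <- function(seq, thr = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  out <- list()
  for (p in 1:6) {
    pat <- sprintf("([ACGT]{%d})\\1{%d,}", p, thr[p] - 1L)
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (q in seq_along(m)) {
      s <- m[q]
      len <- attr(m, "match.length")[q]
      motif <- substr(seq, s, s + p - 1L)
      # smallest-period rule: skip non-primitive motifs
      prim <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            identical(strrep(substr(motif, 1L, d), p / d), motif)) prim <- FALSE
      }
      if (!prim) next
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = p, n_repeats = len %/% p,
        start = s, end = s + (len %/% p) * p - 1L, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(), unit_length = integer(),
               n_repeats = integer(), start = integer(), end = integer())
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# position-by-position repeat counter for very short sequences
ssr_oracle_loop <- function(seq, thr = c(10L, 5L, 4L, 3L, 3L, 3L)) {
  ch <- strsplit(seq, "")[[1L]]
  n <- length(ch)
  out <- list()
  for (p in 1:6) {
    s <- 1L
    while (s + p - 1L <= n) {
      reps <- 1L
      while (s + (reps + 1L) * p - 1L <= n &&
             all(ch[(s + reps * p):(s + (reps + 1L) * p - 1L)] ==
                 ch[s:(s + p - 1L)])) reps <- reps + 1L
      # left-maximal? (previous base must not continue the period)
      leftmax <- s == 1L || ch[s - 1L] != ch[s - 1L + p]
      motif <- paste(ch[s:(s + p - 1L)], collapse = "")
      prim <- TRUE
      for (d in seq_len(p - 1L)) {
        if (p %% d == 0L &&
            identical(strrep(substr(motif, 1L, d), p / d), motif)) prim <- FALSE
      }
      if (reps >= thr[p] && leftmax && prim) {
        out[[length(out) + 1L]] <- data.frame(
          motif = motif, unit_length = p, n_repeats = reps, start = s,
          end = s + reps * p - 1L, stringsAsFactors = FALSE)
        s <- s + reps * p
      } else {
        s <- s + 1L
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(), unit_length = integer(),
               n_repeats = integer(), start = integer(), end = integer())
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  res
}

expect_same_loci <- function(found, oracle) {
  cols <- c("motif", "unit_length", "n_repeats", "start", "end")
  expect_equal(found[, cols], oracle[, cols], ignore_attr = TRUE)
}

# alignment columns whose standard coordinate lies inside a called inversion
in_intervals_for_test <- function(cmp) {
  aln <- cmp$alignment
  pos <- aln$ref_coords
  hit <- rep(FALSE, aln$ncol)
  for (r in seq_len(nrow(cmp$inversions))) {
    hit <- hit | (!is.na(pos) & pos >= cmp$inversions$start[r] &
                    pos <= cmp$inversions$end[r])
  }
  hit
}
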