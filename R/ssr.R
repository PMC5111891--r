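#' Class-specific SSR repeat-count thresholds
#'
#' Defaults follow the conventional plastome SSR search settings: at least
#' 10 repeats for mono-nucleotide motifs, 5 for di-, 4 for tri- and 3 for
#' tetra-, penta- and hexa-nucleotide motifs.
#'
#' @param mono,di,tri,tetra,penta,hexa minimum repeat counts per motif class.
#' @return named integer vector indexed by motif unit length 1..6.
#' @export
ssr_thresholds <- function(mono = 10L, di = 5L, tri = 4L, tetra = 3L,
                           penta = 3L, hexa = 3L) {
  thr <- as.integer(c(mono, di, tri, tetra, penta, hexa))
  stopifnot(length(thr) == 6L, all(thr >= 2L))
  names(thr) <- as.character(1:6)
  thr
}

# is a motif primitive (not itself a repetition of a shorter unit)?
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d == 0L &&
        identical(strrep(substr(motif, 1L, d), p / d), motif)) return(FALSE)
  }
  TRUE
}

#' Scan a plastome for simple sequence repeats
#'
#' Reports every maximal perfect tandem repeat of a 1-6 bp motif meeting the
#' class threshold. A run is reported under its primitive (smallest-period)
#' unit only, so a poly-A run is never also reported as an AA di-repeat.
#' Motifs are reported as they read on the forward strand, with no
#' strand canonicalization (A-runs and T-runs are distinct). Origin-spanning
#' repeats of a circular genome are found via the doubled sequence and
#' reported with a wrapped end coordinate plus a `wraps` flag.
#'
#' @param genome a [circular_genome()] (or a plain character sequence,
#'   treated as linear).
#' @param thresholds see [ssr_thresholds()].
#' @param features optional annotation (list of [gene_feature()]) used to
#'   fill the `location` columns.
#' @return data.frame with columns `motif`, `unit_length`, `n_repeats`,
#'   `start`, `end`, `wraps`, and (when `features` is given) `category`,
#'   `location`; ordered by `start`.
#' @export
find_ssrs <- function(genome, thresholds = ssr_thresholds(), features = NULL) {
  if (inherits(genome, "CircularGenome")) {
    seq <- genome$seq
    circular <- genome$circular
    L <- genome$length
  } else {
    seq <- toupper(genome)
    circular <- FALSE
    L <- nchar(seq)
  }
  stopifnot(length(thresholds) == 6L)
  ch <- seq_chars(if (circular) paste0(seq, seq) else seq)
  n <- length(ch)

  out <- list()
  for (p in 1:6) {
    if (n <= p) next
    thr <- thresholds[[p]]
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & (r$lengths + p) >= thr * p)
    for (j in keep) {
      s <- starts[j]
      span <- r$lengths[j] + p          # maximal periodic region length
      if (circular) {
        if (s > L) next                 # duplicate copy in the doubled half
        span <- min(span, L)            # fully periodic circle cap
        # require left-maximality on the circle, not just in the doubled string
        if (s == 1L && ch[L] == ch[p]) next
      }
      nrep <- span %/% p
      if (nrep < thr) next
      motif <- paste(ch[s:(s + p - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      e <- s + nrep * p - 1L
      out[[length(out) + 1L]] <- data.frame(
        motif = motif, unit_length = p, n_repeats = nrep,
        start = s, end = if (circular && e > L) e - L else e,
        wraps = circular && e > L, stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(motif = character(), unit_length = integer(),
               n_repeats = integer(), start = integer(), end = integer(),
               wraps = logical())
  res <- res[order(res$start, res$unit_length), , drop = FALSE]
  rownames(res) <- NULL
  if (!is.null(features) && nrow(res) > 0L) {
    cl <- classify_position(res$start, features, genome_length = L)
    res$category <- cl$category
    res$location <- cl$context
  }
  res
}

#' Summarize SSR loci by motif class
#'
#' @param loci data.frame from [find_ssrs()], or any data.frame with
#'   `motif` and `unit_length` columns (e.g. the packaged repeat table
#'   fixture).
#' @return list with `n_loci`, `by_class` (named counts for unit lengths
#'   1-6), `n_at` (count of A/T mono plus AT/TA di loci) and `at_share_pct`
#'   (their percentage of all loci, two decimals; `NA` when there are no
#'   loci).
#' @export
summarize_ssrs <- function(loci) {
  stopifnot(all(c("motif", "unit_length") %in% names(loci)))
  by_class <- vapply(1:6, function(p) sum(loci$unit_length == p), integer(1L))
  names(by_class) <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  n <- nrow(loci)
  n_at <- sum(loci$motif %in% c("A", "T") |
                (loci$unit_length == 2L & loci$motif %in% c("AT", "TA")))
  list(n_loci = n, by_class = by_class, n_at = n_at,
       at_share_pct = if (n > 0L) round(100 * n_at / n, 2L) else NA_real_)
}
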