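TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(ref, alt) unname(TRANSITIONS[ref] == alt)

# pooled, non-strand-specific substitution type of a directed ref>alt change
SPECTRUM_LEVELS <- c("G>A/C>T", "A>G/T>C", "C>A/G>T", "A>C/T>G",
                     "A>T/T>A", "G>C/C>G")

SPECTRUM_LOOKUP <- c("G>A" = 1L, "C>T" = 1L, "A>G" = 2L, "T>C" = 2L,
                     "C>A" = 3L, "G>T" = 3L, "A>C" = 4L, "T>G" = 4L,
                     "A>T" = 5L, "T>A" = 5L, "G>C" = 6L, "C>G" = 6L)

spectrum_type <- function(ref, alt) {
  SPECTRUM_LEVELS[SPECTRUM_LOOKUP[paste0(ref, ">", alt)]]
}

in_intervals <- function(pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(pos)))
  hit <- rep(FALSE, length(pos))
  for (r in seq_len(nrow(intervals))) {
    hit <- hit | (pos >= intervals$start[r] & pos <= intervals$end[r])
  }
  hit
}

empty_substitutions <- function() {
  data.frame(ref_pos = integer(), ref_base = character(),
             alt_base = character(), klass = character(),
             category = character(), location = character(),
             stringsAsFactors = FALSE)
}

#' Call single-nucleotide substitutions from a pairwise alignment
#'
#' One event per mismatched non-gap column, classified as transition
#' (purine-purine or pyrimidine-pyrimidine) or transversion. Columns whose
#' standard-genome position falls inside `exclude` intervals (detected
#' micro-inversions) are skipped, so an inverted segment is not also
#' reported as a cluster of spurious SNPs. Adjacent mismatch columns stay
#' separate single-base events (no MNP merging).
#'
#' @param aln a [plastome_alignment()].
#' @param features optional annotation for location labels.
#' @param exclude optional data.frame of standard-genome intervals
#'   (`start`, `end`) to mask, normally from [detect_microinversions()].
#' @return data.frame with columns `ref_pos`, `ref_base`, `alt_base`,
#'   `klass`, `category`, `location`.
#' @export
call_substitutions <- function(aln, features = NULL, exclude = NULL) {
  stopifnot(inherits(aln, "PlastomeAlignment"))
  rc <- aln$ref_chars; ac <- aln$alt_chars
  idx <- which(rc != "-" & ac != "-" & rc != ac)
  if (length(idx)) idx <- idx[!in_intervals(aln$ref_coords[idx], exclude)]
  if (length(idx) == 0L) return(empty_substitutions())
  ref <- rc[idx]; alt <- ac[idx]
  out <- data.frame(
    ref_pos = aln$ref_coords[idx], ref_base = ref, alt_base = alt,
    klass = ifelse(is_transition(ref, alt), "transition", "transversion"),
    category = NA_character_, location = NA_character_,
    stringsAsFactors = FALSE)
  if (!is.null(features)) {
    cl <- classify_position(out$ref_pos, features,
                            genome_length = max(aln$ref_coords, na.rm = TRUE))
    out$category <- cl$category
    out$location <- cl$context
  }
  out
}

empty_indels <- function() {
  data.frame(ref_pos = integer(), seq = character(), length = integer(),
             klass = character(), direction = character(),
             category = character(), location = character(),
             stringsAsFactors = FALSE)
}

#' Call indels from a pairwise alignment
#'
#' Each maximal gap run becomes one event, left-normalized (shifted as far
#' 5' as the repetitive context allows, so equivalent placements are
#' canonical). Polarity follows the standard genome: `Insertion` when the
#' standard carries the bases (gap in the other genome), `Deletion` when the
#' standard has the gap. An event is `homopolymeric` (microsatellite-related
#' slippage) iff its sequence is a run of a single base and the standard
#' genome's run of that base adjacent to the normalized position is at least
#' `homopolymer_min_run` long; otherwise `non_homopolymeric`.
#'
#' @param aln a [plastome_alignment()].
#' @param features optional annotation for location labels.
#' @param homopolymer_min_run minimum adjacent single-base run length for
#'   the homopolymeric class (default 3).
#' @return data.frame with columns `ref_pos` (base immediately left of the
#'   event on the standard), `seq`, `length`, `klass`, `direction`,
#'   `category`, `location`.
#' @export
call_indels <- function(aln, features = NULL, homopolymer_min_run = 3L) {
  stopifnot(inherits(aln, "PlastomeAlignment"))
  rc <- aln$ref_chars; ac <- aln$alt_chars
  state <- ifelse(rc == "-", 1L, ifelse(ac == "-", 2L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  std <- rc[rc != "-"]
  alt <- ac[ac != "-"]
  n_std <- length(std)
  col_of_alt <- integer(length(alt))
  col_of_alt[aln$alt_coords[!is.na(aln$alt_coords)]] <- which(!is.na(aln$alt_coords))

  rows <- list()
  for (q in which(r$values != 0L)) {
    c0 <- starts[q]; c1 <- ends[q]
    len <- c1 - c0 + 1L
    if (r$values[q] == 2L) {                      # gap in other: standard carries
      a <- aln$ref_coords[c0]
      while (a > 1L && std[a - 1L] == std[a + len - 1L]) a <- a - 1L
      sq <- std[a:(a + len - 1L)]
      ref_pos <- a - 1L
      direction <- "Insertion"
    } else {                                      # gap in standard
      b <- aln$alt_coords[c0]
      while (b > 1L && alt[b - 1L] == alt[b + len - 1L]) b <- b - 1L
      sq <- alt[b:(b + len - 1L)]
      direction <- "Deletion"
      ref_pos <- if (b == 1L) 0L else {
        col <- col_of_alt[b - 1L]
        rp <- aln$ref_coords[col]
        while (is.na(rp) && col > 1L) { col <- col - 1L; rp <- aln$ref_coords[col] }
        if (is.na(rp)) 0L else rp
      }
    }
    base <- unique(sq)
    klass <- "non_homopolymeric"
    if (length(base) == 1L) {
      run <- 0L; p <- ref_pos + 1L
      while (p <= n_std && std[p] == base) { run <- run + 1L; p <- p + 1L }
      if (run >= homopolymer_min_run) klass <- "homopolymeric"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ref_pos = ref_pos, seq = paste(sq, collapse = ""), length = len,
      klass = klass, direction = direction,
      category = NA_character_, location = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty_indels())
  out <- do.call(rbind, rows)
  out <- out[order(out$ref_pos), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(features)) {
    site <- ifelse(out$direction == "Insertion", out$ref_pos + 1L,
                   pmax(out$ref_pos, 1L))
    cl <- classify_position(site, features, genome_length = n_std)
    out$category <- cl$category
    out$location <- cl$context
  }
  out
}

#' Uncorrected pairwise genetic distance
#'
#' Proportion of mismatched sites among compared (non-gap) alignment
#' columns; gap columns are excluded (pairwise deletion of sites).
#'
#' @param aln a [plastome_alignment()].
#' @param rounding decimals to round to (default 5, the precision p-distances
#'   between congeneric plastomes are conventionally reported at).
#' @param exclude optional standard-genome intervals (`start`/`end`) whose
#'   columns are ignored, normally detected micro-inversions, so that the
#'   distance reflects substitutions only.
#' @return the rounded proportion.
#' @export
p_distance <- function(aln, rounding = 5L, exclude = NULL) {
  stopifnot(inherits(aln, "PlastomeAlignment"))
  comp <- aln$ref_chars != "-" & aln$alt_chars != "-"
  if (!is.null(exclude)) {
    comp[comp] <- !in_intervals(aln$ref_coords[comp], exclude)
  }
  n <- sum(comp)
  if (n == 0L) stop("no comparable (non-gap) columns")
  mis <- sum(aln$ref_chars[comp] != aln$alt_chars[comp])
  round(mis / n, rounding)
}

#' Summarize mutation events between two plastomes
#'
#' Totals, transition/transversion ratio, the six pooled non-strand-specific
#' substitution types, per-location breakdowns per event class, and the
#' per-gene Ts/Tv tally for coding substitutions.
#'
#' @param substitutions,indels,inversions event data.frames from
#'   [call_substitutions()], [call_indels()], [detect_microinversions()]
#'   (any may be empty).
#' @param aln optional [plastome_alignment()]; when given, the p-distance
#'   over comparable non-inversion columns is included.
#' @return a `MutationSummary` list: `n_substitutions`, `n_indels`,
#'   `n_inversions`, `n_events`, `n_ts`, `n_tv`, `ts_tv_ratio` (2 dp),
#'   `p_distance` (5 dp or `NA`), `spectrum`, `by_location`,
#'   `gene_ts_tv`.
#' @export
summarize_mutations <- function(substitutions = empty_substitutions(),
                                indels = empty_indels(),
                                inversions = NULL, aln = NULL) {
  n_sub <- nrow(substitutions)
  n_ind <- nrow(indels)
  n_inv <- if (is.null(inversions)) 0L else nrow(inversions)
  n_ts <- sum(substitutions$klass == "transition")
  n_tv <- n_sub - n_ts
  spectrum <- table(factor(
    if (n_sub) spectrum_type(substitutions$ref_base, substitutions$alt_base)
    else character(0),
    levels = SPECTRUM_LEVELS))
  cats <- c("Coding", "Intron", "Intergenic")
  by_loc <- rbind(
    substitution = table(factor(substitutions$category, levels = cats)),
    indel = table(factor(indels$category, levels = cats)),
    inversion = table(factor(if (n_inv) inversions$category else character(0),
                             levels = cats)))
  gene_ts_tv <- if (n_sub) {
    cod <- substitutions[!is.na(substitutions$category) &
                           substitutions$category == "Coding", , drop = FALSE]
    if (nrow(cod)) {
      ag <- do.call(rbind, lapply(split(cod, cod$location), function(d)
        data.frame(gene = d$location[1L],
                   ts = sum(d$klass == "transition"),
                   tv = sum(d$klass == "transversion"),
                   stringsAsFactors = FALSE)))
      rownames(ag) <- NULL
      ag[order(ag$gene), , drop = FALSE]
    } else NULL
  } else NULL
  pd <- if (!is.null(aln)) {
    excl <- if (n_inv) inversions[, c("start", "end")] else NULL
    p_distance(aln, rounding = 5L, exclude = excl)
  } else NA_real_
  structure(list(
    n_substitutions = n_sub, n_indels = n_ind, n_inversions = n_inv,
    n_events = n_sub + n_ind + n_inv,
    n_ts = n_ts, n_tv = n_tv,
    ts_tv_ratio = if (n_tv > 0L) round(n_ts / n_tv, 2L) else NA_real_,
    p_distance = pd,
    spectrum = spectrum, by_location = by_loc, gene_ts_tv = gene_ts_tv),
    class = "MutationSummary")
}

#' @export
print.MutationSummary <- function(x, ...) {
  cat(sprintf("MutationSummary: %d substitutions (%d Ts / %d Tv, ratio %s), %d indels, %d inversions\n",
              x$n_substitutions, x$n_ts, x$n_tv,
              ifelse(is.na(x$ts_tv_ratio), "NA", format(x$ts_tv_ratio)),
              x$n_indels, x$n_inversions))
  if (!is.na(x$p_distance)) cat("p-distance:", format(x$p_distance, scientific = FALSE), "\n")
  invisible(x)
}

#' Rebuild the second genome from the standard plus an event list
#'
#' Applies substitutions, indels and inversions (all in standard-genome
#' coordinates, as emitted by the callers) to the standard sequence. With a
#' complete event list this reproduces the other genome base-for-base, the
#' round-trip completeness check of the caller.
#'
#' @param standard the standard [circular_genome()].
#' @param substitutions,indels,inversions event data.frames (any may be
#'   empty or `NULL`).
#' @param id label for the rebuilt genome.
#' @return a [circular_genome()].
#' @export
reconstruct_other <- function(standard, substitutions = NULL, indels = NULL,
                              inversions = NULL, id = "reconstructed") {
  stopifnot(inherits(standard, "CircularGenome"))
  ev <- list()
  if (!is.null(substitutions) && nrow(substitutions)) {
    for (r in seq_len(nrow(substitutions))) {
      ev[[length(ev) + 1L]] <- list(pos = substitutions$ref_pos[r], kind = "sub",
                                    alt = substitutions$alt_base[r])
    }
  }
  if (!is.null(inversions) && nrow(inversions)) {
    for (r in seq_len(nrow(inversions))) {
      ev[[length(ev) + 1L]] <- list(pos = inversions$start[r], kind = "inv",
                                    end = inversions$end[r])
    }
  }
  if (!is.null(indels) && nrow(indels)) {
    for (r in seq_len(nrow(indels))) {
      ev[[length(ev) + 1L]] <- list(pos = indels$ref_pos[r], kind = "indel",
                                    seq = indels$seq[r],
                                    len = indels$length[r],
                                    direction = indels$direction[r])
    }
  }
  if (length(ev) == 0L) return(circular_genome(id, standard$seq))
  ord <- order(vapply(ev, `[[`, numeric(1L), "pos"), decreasing = TRUE)
  s <- standard$seq
  for (e in ev[ord]) {
    if (e$kind == "sub") {
      substr(s, e$pos, e$pos) <- e$alt
    } else if (e$kind == "inv") {
      s <- paste0(substr(s, 1L, e$pos - 1L),
                  revcomp(substr(s, e$pos, e$end)),
                  substr(s, e$end + 1L, nchar(s)))
    } else if (e$direction == "Insertion") {      # standard carries the bases
      s <- paste0(substr(s, 1L, e$pos), substr(s, e$pos + e$len + 1L, nchar(s)))
    } else {                                      # standard lacks the bases
      s <- paste0(substr(s, 1L, e$pos), e$seq, substr(s, e$pos + 1L, nchar(s)))
    }
  }
  circular_genome(id, s)
}
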