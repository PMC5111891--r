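BASES <- c("A", "C", "G", "T")

rand_bases <- function(n, gc) {
  sample(BASES, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Specification of a synthetic plastome
#'
#' Defaults reproduce the architecture of a typical Amaranthaceae plastome:
#' region lengths and per-region GC of a 151.6 kb genome with a 24 kb IR,
#' planted genes (some with introns), planted SSR loci of each motif class,
#' and planted hairpin sites (a short core flanked by perfect inverted-repeat
#' arms) where micro-inversions can later be placed.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bp.
#' @param gc_by_region named vector of target GC fractions for LSC, SSC, IR.
#' @param n_genes number of planted genes.
#' @param intron_genes how many of them carry introns (2-3 exons).
#' @param ssr_per_class named counts of planted SSR loci per motif class
#'   (unit lengths 1-4 by default, matching the classes observed in
#'   plastomes; 5 and 6 are allowed).
#' @param n_hairpin_sites number of planted hairpin sites.
#' @param hairpin_core_range,stem_arm_range core and arm length ranges (bp).
#' @param junction_genes plant a tRNA-like gene 1 bp downstream of the
#'   IRa/LSC junction and a ycf1-like gene crossing the SSC/IRa junction
#'   with 763 bp inside the IR (the classic border-gene configuration).
#' @param seed optional random seed applied by [generate_plastome()].
#' @return a `GenomeSpec` list.
#' @export
genome_spec <- function(lsc_len = 84214L, ssc_len = 19014L, ir_len = 24171L,
                        gc_by_region = c(LSC = 0.344, SSC = 0.297, IR = 0.430),
                        n_genes = 30L, intron_genes = 6L,
                        ssr_per_class = c(mono = 3L, di = 2L, tri = 2L, tetra = 2L),
                        n_hairpin_sites = 4L,
                        hairpin_core_range = c(3L, 14L),
                        stem_arm_range = c(19L, 27L),
                        junction_genes = TRUE, seed = NULL) {
  stopifnot(lsc_len > 0L, ssc_len > 0L, ir_len > 0L, lsc_len > ssc_len,
            all(gc_by_region >= 0 & gc_by_region <= 1),
            all(c("LSC", "SSC", "IR") %in% names(gc_by_region)))
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc_by_region = gc_by_region,
                 n_genes = as.integer(n_genes),
                 intron_genes = as.integer(intron_genes),
                 ssr_per_class = ssr_per_class,
                 n_hairpin_sites = as.integer(n_hairpin_sites),
                 hairpin_core_range = as.integer(hairpin_core_range),
                 stem_arm_range = as.integer(stem_arm_range),
                 junction_genes = isTRUE(junction_genes), seed = seed),
            class = "GenomeSpec")
}

# motif pools per unit length; all primitive
SSR_MOTIF_POOL <- list(
  `1` = c("A", "T", "C"),
  `2` = c("AT", "TA", "AG"),
  `3` = c("TAA", "TTC", "AAG"),
  `4` = c("TTGT", "TTTA", "AATC", "TAAT"),
  `5` = c("AAGAT", "TTCTA"),
  `6` = c("ATTCAG", "TTAGAC")
)

#' Generate a synthetic plastome with a known truth set
#'
#' Builds `LSC + IRb + SSC + revcomp(IRb)` from per-region base
#' compositions, then plants genes, SSR loci and hairpin sites into the
#' single-copy regions, recording everything in a truth set. The four bases
#' flanking the single-copy/IR junctions are pinned to `A` so the planted IR
#' is exactly maximal and the emitted layout is the canonical rotation.
#' Deterministic under `spec$seed`.
#'
#' @param spec a [genome_spec()].
#' @param id genome label.
#' @return list with `genome` (a [circular_genome()]), `features` (list of
#'   [gene_feature()]), and `truth` (list: `regions`, `ssr`,
#'   `hairpin_sites`, `junction_genes`).
#' @export
generate_plastome <- function(spec = genome_spec(), id = "synthetic") {
  stopifnot(inherits(spec, "GenomeSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  l <- spec$lsc_len; s <- spec$ssc_len; ir <- spec$ir_len
  L <- l + s + 2L * ir
  gc <- spec$gc_by_region
  irb <- rand_bases(ir, gc[["IR"]])
  ch <- c(rand_bases(l, gc[["LSC"]]), irb, rand_bases(s, gc[["SSC"]]),
          rev(unname(COMPLEMENT[irb])))
  # pin junction-flank bases: IR exactly maximal, layout canonical
  ch[c(1L, l, l + ir + 1L, l + ir + s)] <- "A"

  margin <- 100L
  occ <- rep(FALSE, L)
  occ[c(1L, l, l + ir + 1L, l + ir + s)] <- TRUE
  sc_zones <- rbind(c(1L + margin, l - margin),
                    c(l + ir + 1L + margin, l + ir + s - margin))

  place <- function(len, pad = 2L) {
    for (try in 1:500) {
      z <- sc_zones[sample.int(2L, 1L, prob = c(0.8, 0.2)), ]
      if (z[2L] - z[1L] + 1L <= len + 2L * pad) next
      a <- sample.int(z[2L] - z[1L] + 1L - len - 2L * pad, 1L) + z[1L] + pad - 1L
      if (!any(occ[(a - pad):(a + len + pad - 1L)])) return(a)
    }
    stop("placement failure: synthetic genome too small for requested elements")
  }

  # --- SSR loci -------------------------------------------------------------
  thr <- ssr_thresholds()
  ssr_rows <- list()
  for (cls in names(spec$ssr_per_class)) {
    p <- match(cls, c("mono", "di", "tri", "tetra", "penta", "hexa"))
    if (is.na(p)) p <- as.integer(cls)
    for (q in seq_len(spec$ssr_per_class[[cls]])) {
      motif <- sample(SSR_MOTIF_POOL[[as.character(p)]], 1L)
      nrep <- thr[[p]] + sample(0:3, 1L)
      len <- p * nrep
      a <- place(len, pad = p + 2L)
      e <- a + len - 1L
      mch <- seq_chars(motif)
      ch[a:e] <- rep(mch, nrep)
      # break periodicity on both flanks so the locus is exactly maximal
      ch[a - 1L] <- sample(setdiff(BASES, ch[a - 1L + p]), 1L)
      ch[e + 1L] <- sample(setdiff(BASES, ch[e + 1L - p]), 1L)
      occ[(a - p - 1L):(e + p + 1L)] <- TRUE
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        motif = motif, unit_length = p, n_repeats = nrep, start = a, end = e,
        stringsAsFactors = FALSE)
    }
  }
  ssr_truth <- if (length(ssr_rows)) do.call(rbind, ssr_rows) else
    data.frame(motif = character(), unit_length = integer(),
               n_repeats = integer(), start = integer(), end = integer())

  # --- hairpin sites (inverted-repeat arms around an invertible core) ------
  hp_rows <- list()
  for (q in seq_len(spec$n_hairpin_sites)) {
    core_len <- sample(seq.int(spec$hairpin_core_range[1L],
                               spec$hairpin_core_range[2L]), 1L)
    arm_len <- sample(seq.int(spec$stem_arm_range[1L],
                              spec$stem_arm_range[2L]), 1L)
    # a core over {A,C} (or {T,G}) mismatches its reverse complement at every
    # position, so an inversion there is unambiguous for the detector
    core <- sample(sample(list(c("A", "C"), c("T", "G")), 1L)[[1L]],
                   core_len, replace = TRUE)
    arm <- rand_bases(arm_len, 0.5)
    tot <- core_len + 2L * arm_len
    a <- place(tot, pad = 3L)
    cs <- a + arm_len; ce <- cs + core_len - 1L
    ch[a:(a + tot - 1L)] <- c(arm, core, rev(unname(COMPLEMENT[arm])))
    # stop the measured arm from extending past the planted length
    if (ch[a - 1L] == COMPLEMENT[[ch[a + tot]]]) {
      ch[a - 1L] <- sample(setdiff(BASES, COMPLEMENT[[ch[a + tot]]]), 1L)
    }
    occ[(a - 1L):(a + tot)] <- TRUE
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      core_start = cs, core_end = ce, core_len = core_len, arm_len = arm_len,
      stringsAsFactors = FALSE)
  }
  hp_truth <- if (length(hp_rows)) do.call(rbind, hp_rows) else
    data.frame(core_start = integer(), core_end = integer(),
               core_len = integer(), arm_len = integer())

  # --- genes ----------------------------------------------------------------
  features <- list()
  n_plain <- max(0L, spec$n_genes - spec$intron_genes)
  mk_gene <- function(nm, nexons) {
    elens <- sample(100:300, nexons, replace = TRUE)
    ilens <- if (nexons > 1L) sample(80:200, nexons - 1L, replace = TRUE) else integer(0)
    tot <- sum(elens) + sum(ilens)
    a <- place(tot, pad = 5L)
    starts <- a + cumsum(c(0L, utils::head(elens, -1L) + ilens))
    occ[a:(a + tot - 1L)] <<- TRUE
    ftype <- sample(c("CDS", "CDS", "CDS", "tRNA", "rRNA"), 1L)
    gene_feature(nm, ftype, sample(c("+", "-"), 1L),
                 data.frame(start = starts, end = starts + elens - 1L))
  }
  gi <- 0L
  for (q in seq_len(spec$intron_genes)) {
    gi <- gi + 1L
    features[[length(features) + 1L]] <- mk_gene(sprintf("g%03d", gi), sample(2:3, 1L))
  }
  for (q in seq_len(n_plain)) {
    gi <- gi + 1L
    features[[length(features) + 1L]] <- mk_gene(sprintf("g%03d", gi), 1L)
  }

  jg <- NULL
  if (spec$junction_genes) {
    # tRNA-like gene 1 bp inside the LSC from the IRa/LSC border
    trn_len <- 75L
    features[[length(features) + 1L]] <-
      gene_feature("trnH_like", "tRNA", "-",
                   data.frame(start = 2L, end = 1L + trn_len))
    occ[2L:(1L + trn_len)] <- TRUE
    # ycf1-like gene crossing the SSC/IRa border, 763 bp inside the IR
    ir_overlap <- min(763L, ir - margin)
    ssc_part <- min(1500L, s - 2L * margin)
    jssc <- l + ir + s
    features[[length(features) + 1L]] <-
      gene_feature("ycf1_like", "CDS", "+",
                   data.frame(start = jssc - ssc_part + 1L,
                              end = jssc + ir_overlap))
    occ[(jssc - ssc_part + 1L):(jssc + ir_overlap)] <- TRUE
    jg <- data.frame(gene = c("trnH_like", "ycf1_like"),
                     junction = c("IRa/LSC", "SSC/IRa"),
                     distance = c(1L, 0L), bases_in_ir = c(0L, ir_overlap),
                     stringsAsFactors = FALSE)
  }
  ord <- order(vapply(features, function(f) feature_span(f)[1L], numeric(1L)))
  features <- features[ord]

  genome <- circular_genome(id, paste(ch, collapse = ""))
  list(genome = genome, features = features,
       truth = list(regions = c(LSC = l, IRb = ir, SSC = s, IRa = ir),
                    ssr = ssr_truth, hairpin_sites = hp_truth,
                    junction_genes = jg))
}

#' Specification of a planted mutation set
#'
#' Defaults emulate the divergence observed between congeneric desert-shrub
#' plastomes: 44 substitutions at a transition fraction of 19/44 (Ts:Tv
#' 0.76), 16 homopolymer-slippage indels, 7 non-homopolymeric indels of 5-6
#' bp, and 2 micro-inversions of 3-14 bp flanked by 19-27 bp stem arms.
#'
#' @param n_substitutions substitution count.
#' @param ts_fraction probability each substitution is a transition; the
#'   realized transition count is drawn Binomial(n, ts_fraction) and
#'   recorded in the truth set.
#' @param n_homopolymer_indels single-base slippage indels at existing runs.
#' @param n_other_indels heterogeneous indels.
#' @param indel_len_range length range for non-homopolymeric indels.
#' @param n_inversions micro-inversions to place at planted hairpin sites.
#' @param min_spacing minimum distance between planted events (keeps calls
#'   unambiguous; default 50 bp).
#' @param seed optional random seed applied by [mutate_genome()].
#' @return a `MutationSpec` list.
#' @export
mutation_spec <- function(n_substitutions = 44L, ts_fraction = 19 / 44,
                          n_homopolymer_indels = 16L, n_other_indels = 7L,
                          indel_len_range = c(5L, 6L), n_inversions = 2L,
                          min_spacing = 50L, seed = NULL) {
  stopifnot(n_substitutions >= 0L, ts_fraction >= 0, ts_fraction <= 1,
            n_homopolymer_indels >= 0L, n_other_indels >= 0L,
            n_inversions >= 0L, indel_len_range[1L] >= 1L)
  structure(list(n_substitutions = as.integer(n_substitutions),
                 ts_fraction = ts_fraction,
                 n_homopolymer_indels = as.integer(n_homopolymer_indels),
                 n_other_indels = as.integer(n_other_indels),
                 indel_len_range = as.integer(indel_len_range),
                 n_inversions = as.integer(n_inversions),
                 min_spacing = as.integer(min_spacing), seed = seed),
            class = "MutationSpec")
}

#' Plant mutations into a copy of a synthetic plastome
#'
#' Returns a mutated copy of `genome` plus the exact truth set, in the same
#' format the callers emit: substitutions (classified Ts/Tv), left-normalized
#' indels with direction relative to the standard (the input genome) and
#' homopolymeric/non-homopolymeric class, and inversions placed at planted
#' hairpin sites. Events are planted in single-copy regions only, pairwise
#' separated by `spec$min_spacing` and at least 100 bp from region junctions,
#' so every call is unambiguous. Deterministic under `spec$seed`.
#'
#' @param genome the standard [circular_genome()] (left unmodified).
#' @param features its annotation (used for truth location labels; may be
#'   `NULL`).
#' @param spec a [mutation_spec()].
#' @param hairpin_sites data.frame of planted hairpin sites from
#'   [generate_plastome()] truth (required when `spec$n_inversions > 0`).
#' @param structure optional `QuadripartiteStructure`; detected from the
#'   genome when missing.
#' @param homopolymer_min_run run-length floor used when choosing slippage
#'   sites (matches the caller's classification default).
#' @return list with `genome` (the mutated [circular_genome()]) and `truth`
#'   (list: `substitutions`, `indels`, `inversions`, `n_ts_drawn`).
#' @export
mutate_genome <- function(genome, features = NULL, spec = mutation_spec(),
                          hairpin_sites = NULL, structure = NULL,
                          homopolymer_min_run = 3L) {
  stopifnot(inherits(genome, "CircularGenome"), inherits(spec, "MutationSpec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  L <- genome$length
  ch <- seq_chars(genome$seq)
  if (is.null(structure)) {
    structure <- detect_inverted_repeats(genome,
                                         min_ir_length = min(1000L, max(20L, L %/% 10L)))
  }
  reg <- structure$regions
  margin <- 100L
  allowed <- rep(FALSE, L)
  for (nm in c("LSC", "SSC")) {
    r <- reg[reg$name == nm, ]
    if (r$length > 2L * margin) {
      allowed[(r$start + margin):(r$end - margin)] <- TRUE
    }
  }
  if (!is.null(hairpin_sites) && nrow(hairpin_sites)) {
    for (q in seq_len(nrow(hairpin_sites))) {
      a <- max(1L, hairpin_sites$core_start[q] - hairpin_sites$arm_len[q] - 5L)
      b <- min(L, hairpin_sites$core_end[q] + hairpin_sites$arm_len[q] + 5L)
      allowed[a:b] <- FALSE
    }
  }
  taken <- numeric(0)
  spacing_ok <- function(a, b = a) {
    length(taken) == 0L || min(abs(c(a, b) - rep(taken, each = 2L))) >= spec$min_spacing
  }
  claim <- function(a, b = a) taken <<- c(taken, a, b)

  # --- inversions at planted hairpin sites ---------------------------------
  inv_rows <- list()
  if (spec$n_inversions > 0L) {
    if (is.null(hairpin_sites) || nrow(hairpin_sites) < spec$n_inversions) {
      stop("need at least ", spec$n_inversions,
           " planted hairpin sites to place inversions")
    }
    pick <- sample.int(nrow(hairpin_sites), spec$n_inversions)
    for (q in pick) {
      cs <- hairpin_sites$core_start[q]; ce <- hairpin_sites$core_end[q]
      claim(cs - hairpin_sites$arm_len[q], ce + hairpin_sites$arm_len[q])
      inv_rows[[length(inv_rows) + 1L]] <- data.frame(
        start = cs, end = ce, length = ce - cs + 1L,
        stem_arm_length = hairpin_sites$arm_len[q], stringsAsFactors = FALSE)
    }
  }
  inversions <- if (length(inv_rows)) do.call(rbind, inv_rows) else
    data.frame(start = integer(), end = integer(), length = integer(),
               stem_arm_length = integer())
  inversions <- inversions[order(inversions$start), , drop = FALSE]
  rownames(inversions) <- NULL

  # --- homopolymeric (slippage) indels at existing single-base runs --------
  r <- rle(ch)
  rends <- cumsum(r$lengths); rstarts <- rends - r$lengths + 1L
  run_ok <- r$lengths >= homopolymer_min_run & allowed[rstarts] &
    allowed[pmin(L, rends + 1L)]
  run_idx <- which(run_ok)
  run_idx <- run_idx[sample.int(length(run_idx))]
  hp_rows <- list()
  for (q in run_idx) {
    if (length(hp_rows) >= spec$n_homopolymer_indels) break
    rs <- rstarts[q]; re <- rends[q]
    if (!spacing_ok(rs - 1L, re + 1L)) next
    dirn <- sample(c("Insertion", "Deletion"), 1L)
    claim(rs - 1L, re + 1L)
    hp_rows[[length(hp_rows) + 1L]] <- data.frame(
      ref_pos = rs - 1L, seq = r$values[q], length = 1L,
      klass = "homopolymeric", direction = dirn, stringsAsFactors = FALSE)
  }
  if (length(hp_rows) < spec$n_homopolymer_indels) {
    stop("placement failure: not enough eligible single-base runs for ",
         spec$n_homopolymer_indels, " homopolymer indels")
  }

  # --- non-homopolymeric indels --------------------------------------------
  oth_rows <- list()
  tries <- 0L
  while (length(oth_rows) < spec$n_other_indels && tries < 2000L) {
    tries <- tries + 1L
    len <- sample(seq.int(spec$indel_len_range[1L], spec$indel_len_range[2L]), 1L)
    dirn <- sample(c("Insertion", "Deletion"), 1L)
    a <- sample.int(L - len - 2L, 1L) + 1L
    if (!all(allowed[(a - 1L):(a + len + 1L)]) || !spacing_ok(a - 1L, a + len + 1L)) next
    if (dirn == "Insertion") {            # standard carries ch[a..a+len-1]
      sq <- ch[a:(a + len - 1L)]
      if (len > 1L && length(unique(sq)) < 2L) next
      if (len == 1L && (ch[a + 1L] == sq[1L] || ch[a - 1L] == sq[1L])) next
      if (ch[a - 1L] == ch[a + len - 1L]) next         # must be left-normal
      ref_pos <- a - 1L
      seqstr <- paste(sq, collapse = "")
    } else {                              # the copy gains a novel segment
      sq <- rand_bases(len, 0.4)
      if (len > 1L && length(unique(sq)) < 2L) next
      if (sq[len] == ch[a]) next                       # must be left-normal
      if (len == 1L && (ch[a + 1L] == sq[1L] || ch[a] == sq[1L])) next
      ref_pos <- a
      seqstr <- paste(sq, collapse = "")
    }
    claim(a - 1L, a + len + 1L)
    oth_rows[[length(oth_rows) + 1L]] <- data.frame(
      ref_pos = ref_pos, seq = seqstr, length = len,
      klass = "non_homopolymeric", direction = dirn, stringsAsFactors = FALSE)
  }
  if (length(oth_rows) < spec$n_other_indels) {
    stop("placement failure: could not place ", spec$n_other_indels,
         " non-homopolymeric indels")
  }
  indels <- if (length(hp_rows) + length(oth_rows) > 0L) {
    do.call(rbind, c(hp_rows, oth_rows))
  } else {
    data.frame(ref_pos = integer(), seq = character(), length = integer(),
               klass = character(), direction = character(),
               stringsAsFactors = FALSE)
  }
  indels <- indels[order(indels$ref_pos), , drop = FALSE]
  rownames(indels) <- NULL

  # --- substitutions --------------------------------------------------------
  n_ts <- stats::rbinom(1L, spec$n_substitutions, spec$ts_fraction)
  sub_pos <- integer(0)
  tries <- 0L
  while (length(sub_pos) < spec$n_substitutions && tries < 20000L) {
    tries <- tries + 1L
    p <- sample.int(L, 1L)
    if (!allowed[p] || !spacing_ok(p)) next
    claim(p)
    sub_pos <- c(sub_pos, p)
  }
  if (length(sub_pos) < spec$n_substitutions) {
    stop("placement failure: could not place ", spec$n_substitutions,
         " substitutions")
  }
  sub_pos <- sort(sub_pos)
  is_ts <- rep(FALSE, spec$n_substitutions)
  if (spec$n_substitutions > 0L) is_ts[sample.int(spec$n_substitutions, n_ts)] <- TRUE
  subs <- if (spec$n_substitutions > 0L) {
    ref <- ch[sub_pos]
    alt <- vapply(seq_along(sub_pos), function(q) {
      if (is_ts[q]) unname(TRANSITIONS[ref[q]])
      else sample(setdiff(BASES, c(ref[q], TRANSITIONS[[ref[q]]])), 1L)
    }, character(1L))
    data.frame(ref_pos = sub_pos, ref_base = ref, alt_base = alt,
               klass = ifelse(is_ts, "transition", "transversion"),
               stringsAsFactors = FALSE)
  } else empty_substitutions()[, 1:4]

  # --- location labels and the mutated copy --------------------------------
  add_loc <- function(df, site) {
    if (!is.null(features) && nrow(df)) {
      cl <- classify_position(site, features, genome_length = L)
      df$category <- cl$category; df$location <- cl$context
    } else {
      df$category <- rep(NA_character_, nrow(df))
      df$location <- rep(NA_character_, nrow(df))
    }
    df
  }
  subs <- add_loc(subs, subs$ref_pos)
  indels <- add_loc(indels, ifelse(indels$direction == "Insertion",
                                   indels$ref_pos + 1L, pmax(indels$ref_pos, 1L)))
  inversions <- add_loc(inversions, inversions$start)

  mutated <- reconstruct_other(genome, subs, indels, inversions,
                               id = paste0(genome$id, "_alt"))
  list(genome = mutated,
       truth = list(substitutions = subs, indels = indels,
                    inversions = inversions, n_ts_drawn = n_ts))
}

#' Generate a synthetic plastome pair with full truth
#'
#' Convenience wrapper: [generate_plastome()] then [mutate_genome()], wiring
#' the planted hairpin sites through.
#'
#' @param gspec a [genome_spec()].
#' @param mspec a [mutation_spec()].
#' @param id label for the standard genome.
#' @return list with `standard`, `other` (genomes), `features`, `truth`
#'   (generation truth plus mutation truth).
#' @export
plastome_pair <- function(gspec = genome_spec(), mspec = mutation_spec(),
                          id = "synthetic") {
  gen <- generate_plastome(gspec, id = id)
  mut <- mutate_genome(gen$genome, gen$features, mspec,
                       hairpin_sites = gen$truth$hairpin_sites)
  list(standard = gen$genome, other = mut$genome, features = gen$features,
       truth = c(gen$truth, mut$truth))
}

#' Write a simulated plastome pair to disk
#'
#' Emits `standard.fasta`, `other.fasta`, `features.gff3` and `truth.json`
#' into a directory; outputs are byte-identical for identical specs and
#' seeds.
#'
#' @param pair result of [plastome_pair()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
simulate_to_dir <- function(pair, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(pair$standard, file.path(dir, "standard.fasta"))
  write_genome(pair$other, file.path(dir, "other.fasta"))
  write_gff3(pair$features, file.path(dir, "features.gff3"),
             seqid = pair$standard$id)
  truth <- pair$truth
  truth$regions <- as.list(truth$regions)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
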