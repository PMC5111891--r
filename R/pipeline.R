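#' Compare two near-identical plastomes
#'
#' The core comparison: aligns the pair, detects micro-inversions, then
#' calls substitutions (outside inversions) and indels, and summarizes.
#' Both genomes are expected on the canonical rotation (see
#' [canonical_rotation()]); [run_pipeline()] handles that automatically.
#'
#' @param standard the standard [circular_genome()] (event polarity and
#'   coordinates are relative to it).
#' @param other the second [circular_genome()].
#' @param features optional annotation of the standard, for location labels.
#' @param k anchor k-mer size for [align_pair()].
#' @param inv_min_len,inv_max_len micro-inversion length bounds.
#' @param homopolymer_min_run homopolymer classification threshold for
#'   [call_indels()].
#' @param max_arm stem-arm search bound for [find_stem_arms()].
#' @return list with `alignment`, `substitutions`, `indels`, `inversions`,
#'   `summary` (a `MutationSummary`).
#' @export
compare_plastomes <- function(standard, other, features = NULL, k = 21L,
                              inv_min_len = 3L, inv_max_len = 100L,
                              homopolymer_min_run = 3L, max_arm = 50L) {
  aln <- align_pair(standard, other, k = k)
  inversions <- detect_microinversions(aln, min_len = inv_min_len,
                                       max_len = inv_max_len,
                                       features = features, genome = standard,
                                       max_arm = max_arm)
  substitutions <- call_substitutions(aln, features = features,
                                      exclude = inversions[, c("start", "end")])
  indels <- call_indels(aln, features = features,
                        homopolymer_min_run = homopolymer_min_run)
  summary <- summarize_mutations(substitutions, indels, inversions, aln)
  list(alignment = aln, substitutions = substitutions, indels = indels,
       inversions = inversions, summary = summary)
}

summary_as_list <- function(s) {
  list(n_substitutions = s$n_substitutions, n_indels = s$n_indels,
       n_inversions = s$n_inversions, n_events = s$n_events,
       n_ts = s$n_ts, n_tv = s$n_tv, ts_tv_ratio = s$ts_tv_ratio,
       p_distance = s$p_distance,
       spectrum = as.list(stats::setNames(as.integer(s$spectrum), names(s$spectrum))),
       by_location = apply(s$by_location, 1L, as.list))
}

#' Run the full comparison pipeline and write a report bundle
#'
#' Orchestrates structure detection, canonical rotation, SSR scanning,
#' pairwise comparison and junction analysis, writing `structure.tsv`,
#' `ssr.tsv`, `substitutions.tsv`, `indels.tsv`, `inversions.tsv`,
#' `junctions.tsv`, `gene_ts_tv.tsv` and `summary.json` into `out_dir`.
#' Reports are deterministic for identical inputs and parameters. On any
#' stage failure the partial outputs are removed and a stage-named error is
#' signalled.
#'
#' @param standard,other genomes: [circular_genome()] objects or FASTA
#'   paths.
#' @param features annotation of the standard genome: a feature list, a
#'   GFF3/GenBank path, or `NULL`. Coordinates must be on the standard's
#'   canonical rotation.
#' @param out_dir output directory (created if needed).
#' @param min_ir_length IR detection threshold.
#' @param thresholds SSR thresholds, see [ssr_thresholds()].
#' @param k,inv_min_len,inv_max_len,homopolymer_min_run,max_arm
#'   comparison parameters, see [compare_plastomes()].
#' @param verbose log each stage and every parameter used (default TRUE).
#' @return (invisibly) list with `structures`, `canonical` genomes, `ssr`,
#'   `comparison`, `junctions`, and `files` written.
#' @export
run_pipeline <- function(standard, other, features = NULL, out_dir,
                         min_ir_length = 1000L,
                         thresholds = ssr_thresholds(), k = 21L,
                         inv_min_len = 3L, inv_max_len = 100L,
                         homopolymer_min_run = 3L, max_arm = 50L,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message("[plastomeDiff] ", sprintf(...))
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  say("parameters: min_ir_length=%d k=%d inv_len=[%d,%d] homopolymer_min_run=%d max_arm=%d ssr_thresholds=%s",
      min_ir_length, k, inv_min_len, inv_max_len, homopolymer_min_run, max_arm,
      paste(thresholds, collapse = ","))

  std <- stage("input", if (inherits(standard, "CircularGenome")) standard
               else read_genome(standard))
  oth <- stage("input", if (inherits(other, "CircularGenome")) other
               else read_genome(other))
  feats <- stage("input", {
    if (is.null(features) || is.list(features)) features
    else read_annotations(features, genome_length = std$length)
  })
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, path)
    path
  }

  say("detecting quadripartite structure")
  res <- stage("structure", {
    st_std <- detect_inverted_repeats(std, min_ir_length = min_ir_length)
    can_std <- canonical_rotation(st_std, std)
    if (!identical(can_std$seq, std$seq) && !is.null(feats)) {
      warning("standard genome was not canonically rotated; supplied feature ",
              "coordinates may not match the rotated output")
    }
    st_oth <- detect_inverted_repeats(oth, min_ir_length = min_ir_length)
    can_oth <- canonical_rotation(st_oth, oth)
    st_std <- detect_inverted_repeats(can_std, min_ir_length = min_ir_length)
    st_oth <- detect_inverted_repeats(can_oth, min_ir_length = min_ir_length)
    list(st_std = st_std, st_oth = st_oth, can_std = can_std, can_oth = can_oth)
  })
  stage("structure", {
    rep1 <- cbind(genome_id = std$id, structure_report(res$st_std))
    rep2 <- cbind(genome_id = oth$id, structure_report(res$st_oth))
    emit(rbind(rep1, rep2), "structure.tsv")
  })

  say("scanning SSRs")
  ssr <- stage("ssr", find_ssrs(res$can_std, thresholds, features = feats))
  stage("ssr", emit(ssr, "ssr.tsv"))

  say("aligning and calling mutations")
  cmp <- stage("compare", compare_plastomes(
    res$can_std, res$can_oth, features = feats, k = k,
    inv_min_len = inv_min_len, inv_max_len = inv_max_len,
    homopolymer_min_run = homopolymer_min_run, max_arm = max_arm))
  stage("compare", {
    emit(cmp$substitutions, "substitutions.tsv")
    emit(cmp$indels, "indels.tsv")
    emit(cmp$inversions, "inversions.tsv")
    gt <- cmp$summary$gene_ts_tv
    emit(gt %||% data.frame(gene = character(), ts = integer(), tv = integer()),
         "gene_ts_tv.tsv")
  })

  say("analyzing IR junctions")
  jx <- stage("junctions", {
    if (is.null(feats)) NULL
    else junction_gene_distance(res$st_std, feats)
  })
  stage("junctions", emit(
    jx %||% data.frame(genome_id = character(), junction = character(),
                       position = integer(), nearest_gene = character(),
                       distance = integer(), genes_cut = character()),
    "junctions.tsv"))

  stage("summary", {
    path <- file.path(out_dir, "summary.json")
    jsonlite::write_json(summary_as_list(cmp$summary), path,
                         auto_unbox = TRUE, digits = NA)
    written <<- c(written, path)
  })
  say("done: %d substitutions, %d indels, %d inversions",
      cmp$summary$n_substitutions, cmp$summary$n_indels, cmp$summary$n_inversions)
  invisible(list(structures = list(standard = res$st_std, other = res$st_oth),
                 canonical = list(standard = res$can_std, other = res$can_oth),
                 ssr = ssr, comparison = cmp, junctions = jx, files = written))
}

#' Recompute the study's headline statistics from the packaged tables
#'
#' Fixtures-only mode: every statistic that is derivable from the shipped
#' table transcriptions is recomputed by the package's own classifiers, with
#' no sequence data. Substitution pairs are (re)classified by the transition
#' rule; SSR classes are summarized from the repeat table; the p-distance
#' uses the printed genome length as the comparable-site count.
#'
#' @return list: `n_substitutions`, `n_ts`, `n_tv`, `ts_tv_ratio`,
#'   `by_location` (substitution counts), `coding_ts`, `coding_tv`,
#'   `gene_ts_tv` (per-gene tally from the substitution table),
#'   `p_distance`, `region_length_sum`, `total_length`, `ssr` (class
#'   summary), `n_indels`, `indel_noncoding`, `n_inversions`,
#'   `n_sub_plus_indel`, `spectrum`.
#' @export
paper_check <- function() {
  t1 <- load_paper_fixture("table1")
  t3 <- load_paper_fixture("table3")
  t4 <- load_paper_fixture("table4")
  t6 <- load_paper_fixture("table6")

  subs <- data.frame(ref_pos = seq_len(nrow(t4)), ref_base = t4$ha,
                     alt_base = t4$hp,
                     klass = ifelse(is_transition(t4$ha, t4$hp),
                                    "transition", "transversion"),
                     category = t4$location, location = t4$region,
                     stringsAsFactors = FALSE)
  smry <- summarize_mutations(subs)

  ha <- function(f) t1$H_ammodendron[t1$feature == f]
  total <- ha("total_cpdna_size")
  reg_sum <- ha("lsc_length") + ha("ssc_length") + 2 * ha("ir_length")

  coding <- subs[subs$category == "Coding", ]
  list(
    n_substitutions = nrow(t4),
    n_ts = smry$n_ts, n_tv = smry$n_tv, ts_tv_ratio = smry$ts_tv_ratio,
    by_location = table(factor(subs$category,
                               levels = c("Coding", "Intron", "Intergenic"))),
    coding_ts = sum(coding$klass == "transition"),
    coding_tv = sum(coding$klass == "transversion"),
    gene_ts_tv = smry$gene_ts_tv,
    p_distance = round(nrow(t4) / total, 5L),
    region_length_sum = reg_sum, total_length = total,
    ssr = summarize_ssrs(t6),
    n_indels = nrow(t3),
    indel_noncoding = sum(t3$location != "Coding"),
    n_inversions = 2L,   # the study's two micro-inversions (14 bp and 3 bp)
    n_sub_plus_indel = nrow(t4) + nrow(t3),
    spectrum = smry$spectrum
  )
}
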