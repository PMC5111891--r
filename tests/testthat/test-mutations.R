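toy_aln <- function(ref, alt) plastome_alignment("std", "alt", ref, alt)

test_that("substitutions classify by the transition rule", {
  aln <- toy_aln("ACGTACGT", "GCGTACTT")
  subs <- call_substitutions(aln)
  expect_equal(subs$ref_pos, c(1L, 7L))
  expect_equal(subs$klass, c("transition", "transversion"))  # A>G, G>T
  expect_equal(nrow(call_substitutions(toy_aln("ACGT", "ACGT"))), 0L)
})

test_that("columns inside detected inversions are excluded from SNP calls", {
  aln <- toy_aln("AACCCCAA", "AAGGGGAA")
  excl <- data.frame(start = 3L, end = 6L)
  expect_equal(nrow(call_substitutions(aln, exclude = excl)), 0L)
  expect_equal(nrow(call_substitutions(aln)), 4L)
})

test_that("homopolymer-run indels are left-normalized and classified", {
  # standard has one extra A in a run: Insertion, homopolymeric
  aln <- toy_aln("CCTAAAACG", "CCTAAA-CG")
  ind <- call_indels(aln)
  expect_equal(ind$direction, "Insertion")
  expect_equal(ind$klass, "homopolymeric")
  expect_equal(ind$ref_pos, 3L)          # shifted to the run start
  expect_equal(ind$seq, "A")
  # two-base AA event adjacent to a run is still homopolymeric slippage
  aln2 <- toy_aln("CGAAAATT", "CGAA--TT")
  ind2 <- call_indels(aln2)
  expect_equal(ind2$length, 2L)
  expect_equal(ind2$klass, "homopolymeric")
  expect_equal(ind2$seq, "AA")
  expect_equal(ind2$ref_pos, 2L)
})

test_that("heterogeneous and isolated single-base indels are non-homopolymeric", {
  aln <- toy_aln("GGTACAATT", "GG-----TT")
  ind <- call_indels(aln)
  expect_equal(ind$direction, "Insertion")
  expect_equal(ind$seq, "TACAA")
  expect_equal(ind$length, 5L)
  expect_equal(ind$klass, "non_homopolymeric")
  # single G deleted from the standard with no flanking G run
  aln2 <- toy_aln("AT-CA", "ATGCA")
  ind2 <- call_indels(aln2)
  expect_equal(ind2$direction, "Deletion")
  expect_equal(ind2$seq, "G")
  expect_equal(ind2$klass, "non_homopolymeric")
  expect_equal(ind2$ref_pos, 2L)
  expect_equal(nrow(call_indels(toy_aln("ACGT", "ACGT"))), 0L)
})

test_that("emitted indels are already left-normal (re-normalizing is a no-op)", {
  pr <- small_pair(61)
  cmp <- compare_plastomes(pr$standard, pr$other)
  std <- strsplit(pr$standard$seq, "")[[1L]]
  for (r in seq_len(nrow(cmp$indels))) {
    e <- cmp$indels[r, ]
    last <- substr(e$seq, e$length, e$length)
    if (e$ref_pos >= 1L) expect_false(std[e$ref_pos] == last)
  }
})

test_that("p-distance uses pairwise deletion of gap sites", {
  expect_equal(p_distance(toy_aln("AAAA", "AAAT")), 0.25)
  expect_equal(p_distance(toy_aln("ACGT", "ACGT")), 0)
  expect_equal(p_distance(toy_aln("AC-T", "ACTT")), 0)   # gap column dropped
  expect_equal(p_distance(toy_aln("AACCCCAA", "AAGGGGAA"),
                          exclude = data.frame(start = 3, end = 6)), 0)
})

test_that("alignment of identical and collinear mutated genomes is exact", {
  g <- circular_genome("a", rand_dna(4000))
  aln <- align_pair(g, circular_genome("b", g$seq))
  expect_equal(sum(aln$ref_chars == "-") + sum(aln$alt_chars == "-"), 0L)
  expect_equal(p_distance(aln), 0)
})

test_that("unrotated (shifted) input is reported as non-collinear", {
  set.seed(62)
  g <- circular_genome("a", rand_dna(30000))
  shifted <- rotate_genome(g, 15001L)
  shifted$id <- "b"
  expect_error(align_pair(g, shifted), "non-collinear")
})

test_that("summary totals, spectrum and per-gene tallies are consistent", {
  subs <- data.frame(
    ref_pos = c(10L, 20L, 30L, 40L),
    ref_base = c("A", "T", "C", "G"), alt_base = c("G", "G", "T", "C"),
    klass = c("transition", "transversion", "transition", "transversion"),
    category = c("Coding", "Coding", "Intron", "Intergenic"),
    location = c("gene1", "gene1", "gene2 intron", "gene2-gene3"),
    stringsAsFactors = FALSE)
  s <- summarize_mutations(subs)
  expect_equal(s$n_substitutions, 4L)
  expect_equal(s$n_ts + s$n_tv, s$n_substitutions)
  expect_equal(s$ts_tv_ratio, 1)
  expect_equal(sum(s$spectrum), s$n_substitutions)
  expect_equal(unname(s$spectrum[c("A>G/T>C", "A>C/T>G", "G>A/C>T", "G>C/C>G")]),
               c(1L, 1L, 1L, 1L), ignore_attr = TRUE)
  expect_equal(s$gene_ts_tv$gene, "gene1")
  expect_equal(s$gene_ts_tv$ts, 1L)
  expect_equal(s$gene_ts_tv$tv, 1L)
  empty <- summarize_mutations()
  expect_equal(empty$n_events, 0L)
  expect_true(is.na(empty$ts_tv_ratio))
})

test_that("standard plus called events rebuilds the other genome", {
  pr <- small_pair(63)
  cmp <- compare_plastomes(pr$standard, pr$other)
  rec <- reconstruct_other(pr$standard, cmp$substitutions, cmp$indels,
                           cmp$inversions)
  expect_identical(rec$seq, pr$other$seq)
})
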