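test_that("mono-nucleotide runs are reported at and above threshold only", {
  hit <- find_ssrs(paste0("CCGT", strrep("A", 11), "GGTC"))
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "A")
  expect_equal(hit$n_repeats, 11L)
  expect_equal(c(hit$start, hit$end), c(5L, 15L))

  expect_equal(nrow(find_ssrs(paste0("CCGT", strrep("A", 9), "GGTC"))), 0L)
  at10 <- find_ssrs(paste0("CCGT", strrep("A", 10), "GGTC"))
  expect_equal(at10$n_repeats, 10L)
})

test_that("tetra-nucleotide repeat is reported with its forward-strand motif", {
  hit <- find_ssrs("CCAGTTGTTTGTTTGTCCAG")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$motif, "TTGT")
  expect_equal(hit$n_repeats, 3L)
  expect_equal(hit$end - hit$start + 1L, 12L)
})

test_that("a run is reported under its primitive smallest period only", {
  hits <- find_ssrs(paste0("CCGT", strrep("A", 12), "GGTC"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$unit_length, 1L)
  # ATAT... unit is non-primitive at period 4, primitive at period 2
  hits2 <- find_ssrs(paste0("GGC", strrep("AT", 6), "GGC"))
  expect_equal(hits2$motif, "AT")
  expect_equal(hits2$n_repeats, 6L)
})

test_that("origin-spanning repeats on a circular genome wrap correctly", {
  set.seed(31)
  mid <- gsub("A", "G", rand_dna(200))      # no A runs in the middle
  g <- circular_genome("c", paste0(strrep("A", 5), "C", mid, "C", strrep("A", 6)))
  hits <- find_ssrs(g)
  wrap <- hits[hits$wraps, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$motif, "A")
  expect_equal(wrap$n_repeats, 11L)
  expect_equal(wrap$start, g$length - 5L)
  expect_equal(wrap$end, 5L)
})

test_that("scanner equals both independent oracles on random sequences", {
  set.seed(32)
  for (q in 1:25) {
    s <- rand_dna(sample(150:500, 1), gc = 0.3)
    expect_same_loci(find_ssrs(s), ssr_oracle_regex(s))
  }
  for (q in 1:10) {
    s <- rand_dna(sample(60:200, 1), gc = 0.25)
    expect_same_loci(find_ssrs(s), ssr_oracle_loop(s))
  }
})

test_that("every reported locus is maximal on both flanks", {
  set.seed(33)
  s <- rand_dna(4000, gc = 0.25)
  ch <- strsplit(s, "")[[1L]]
  hits <- find_ssrs(s)
  expect_gt(nrow(hits), 0L)
  for (r in seq_len(nrow(hits))) {
    p <- hits$unit_length[r]; a <- hits$start[r]; e <- hits$end[r]
    if (a > p) expect_false(all(ch[(a - p):(a - 1L)] == ch[a:(a + p - 1L)]))
    if (e + p <= length(ch)) {
      expect_false(all(ch[(e + 1L):(e + p)] == ch[(e - p + 1L):e]))
    }
  }
})

test_that("class summary counts and A/T share follow the reported convention", {
  loci <- data.frame(motif = c("A", "T", "C", "AT", "TA", "AG", "TAA", "TTGT"),
                     unit_length = c(1, 1, 1, 2, 2, 2, 3, 4))
  s <- summarize_ssrs(loci)
  expect_equal(unname(s$by_class[1:4]), c(3L, 3L, 1L, 1L))
  expect_equal(s$n_at, 4L)
  expect_equal(s$at_share_pct, 50)
  empty <- summarize_ssrs(loci[0, ])
  expect_equal(empty$n_loci, 0L)
  expect_true(is.na(empty$at_share_pct))
})

test_that("location labels are attached when annotation is supplied", {
  gen <- generate_plastome(genome_spec(lsc_len = 12000, ssc_len = 5000,
                                       ir_len = 3000, n_genes = 10,
                                       intron_genes = 3, seed = 34))
  hits <- find_ssrs(gen$genome, features = gen$features)
  expect_true(all(c("category", "location") %in% names(hits)))
  expect_true(all(hits$category %in% c("Coding", "Intron", "Intergenic")))
})
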