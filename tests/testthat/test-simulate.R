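test_that("generation is deterministic under the seed", {
  gs <- genome_spec(lsc_len = 12000, ssc_len = 5000, ir_len = 3000, n_genes = 10,
                              intron_genes = 3, seed = 91)
  a <- generate_plastome(gs); b <- generate_plastome(gs)
  expect_identical(a$genome$seq, b$genome$seq)
  expect_identical(a$truth, b$truth)
  expect_identical(features_table(a$features), features_table(b$features))
})

test_that("simulated bundles on disk are byte-identical across runs", {
  pr1 <- small_pair(92); pr2 <- small_pair(92)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_to_dir(pr1, d1); simulate_to_dir(pr2, d2)
  for (f in c("standard.fasta", "other.fasta", "features.gff3", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("realized per-region GC hits the target composition", {
  gen <- generate_plastome(genome_spec(seed = 93))      # full default scale
  st <- detect_inverted_repeats(gen$genome)
  reg <- st$regions
  expect_equal(reg$gc_fraction[reg$name == "LSC"], 0.344, tolerance = 0.01 / 0.344)
  expect_equal(reg$gc_fraction[reg$name == "SSC"], 0.297, tolerance = 0.01 / 0.297)
  expect_equal(reg$gc_fraction[reg$name == "IRb"], 0.430, tolerance = 0.01 / 0.430)
  expect_equal(reg$length, c(84214L, 24171L, 19014L, 24171L))
})

test_that("a zero-event mutation spec returns the genome unchanged", {
  gen <- generate_plastome(genome_spec(lsc_len = 12000, ssc_len = 5000,
                                       ir_len = 3000, n_genes = 10,
                                       intron_genes = 3, seed = 94))
  mut <- mutate_genome(gen$genome, gen$features,
                       mutation_spec(n_substitutions = 0,
                                     n_homopolymer_indels = 0,
                                     n_other_indels = 0, n_inversions = 0,
                                     seed = 1))
  expect_identical(mut$genome$seq, gen$genome$seq)
  expect_equal(nrow(mut$truth$substitutions), 0L)
  expect_equal(nrow(mut$truth$indels), 0L)
  expect_equal(nrow(mut$truth$inversions), 0L)
})

test_that("the drawn transition count is binomial and recorded in truth", {
  pr <- small_pair(95)
  tr <- pr$truth
  expect_equal(sum(tr$substitutions$klass == "transition"), tr$n_ts_drawn)
  expect_true(all(tr$substitutions$ref_base != tr$substitutions$alt_base))
  ts_rows <- tr$substitutions$klass == "transition"
  expect_true(all(ifelse(tr$substitutions$ref_base[ts_rows] %in% c("A", "G"),
                         tr$substitutions$alt_base[ts_rows] %in% c("A", "G"),
                         tr$substitutions$alt_base[ts_rows] %in% c("C", "T"))))
})

test_that("across seeds the mean called Ts/Tv tracks the planted 2:1 spectrum", {
  ratios <- vapply(1:12, function(seed) {
    pr <- small_pair(200 + seed, n_substitutions = 60L, ts_fraction = 2 / 3,
                     n_homopolymer_indels = 0L, n_other_indels = 0L,
                     n_inversions = 0L)
    cmp <- compare_plastomes(pr$standard, pr$other)
    cmp$summary$n_ts / cmp$summary$n_tv
  }, numeric(1L))
  # binomial sampling noise around Ts:Tv = 2; allow 3 standard errors
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 2), 3 * max(se, 0.05))
})

test_that("inversions require planted hairpin sites", {
  gen <- generate_plastome(genome_spec(lsc_len = 12000, ssc_len = 5000,
                                       ir_len = 3000, n_genes = 10, intron_genes = 3,
                                       n_hairpin_sites = 0, seed = 96))
  expect_error(
    mutate_genome(gen$genome, gen$features,
                  mutation_spec(n_inversions = 2, seed = 1),
                  hairpin_sites = gen$truth$hairpin_sites),
    "hairpin")
})

test_that("events are spaced apart and avoid junction margins", {
  pr <- small_pair(97)
  tr <- pr$truth
  pos <- sort(c(tr$substitutions$ref_pos, tr$indels$ref_pos,
                tr$inversions$start))
  expect_true(all(diff(pos) >= 40L))     # arms may sit between cores
  st <- detect_inverted_repeats(pr$standard)
  jp <- junction_positions(st)
  for (j in jp) expect_true(all(abs(pos - j) > 50L))
})
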