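test_that("GFF3 written by the package round-trips exactly", {
  gen <- generate_plastome(genome_spec(lsc_len = 12000, ssc_len = 5000,
                                       ir_len = 3000, n_genes = 30,
                                       intron_genes = 8, seed = 41))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(gen$features, path, seqid = gen$genome$id)
  back <- read_annotations(path, fmt = "gff3")
  expect_equal(length(back), length(gen$features))
  expect_equal(features_table(back), features_table(gen$features))
  for (q in seq_along(back)) {
    expect_equal(back[[q]]$exons, gen$features[[q]]$exons)
    expect_equal(back[[q]]$ftype, gen$features[[q]]$ftype)
  }
})

test_that("a bare two-exon CDS GFF3 record becomes one two-exon feature", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr\tsrc\tCDS\t100\t200\t.\t+\t0\tID=cds1;gene=petB",
               "chr\tsrc\tCDS\t300\t400\t.\t+\t0\tID=cds1;gene=petB"),
             path)
  f <- read_annotations(path)
  expect_equal(length(f), 1L)
  expect_equal(nrow(f[[1L]]$exons), 2L)
  expect_equal(f[[1L]]$exons$start, c(100L, 300L))
  expect_error(read_annotations(path, genome_length = 350L), "beyond")
})

test_that("missing GFF3 version pragma is rejected", {
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines("chr\tsrc\tCDS\t1\t10\t.\t+\t0\tID=x", path)
  expect_error(read_annotations(path), "gff-version")
})

test_that("minimal GenBank feature tables parse join, complement and pseudo", {
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       TEST                 5000 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     gene            complement(200..900)",
    "                     /gene=\"ndhA\"",
    "     CDS             complement(join(200..400,700..900))",
    "                     /gene=\"ndhA\"",
    "     tRNA            1000..1075",
    "                     /gene=\"trnH\"",
    "     gene            2000..2500",
    "                     /gene=\"rpl23\"",
    "                     /pseudo",
    "ORIGIN",
    "//"), path)
  f <- read_annotations(path, fmt = "genbank")
  tab <- features_table(f)
  ndh <- f[[which(tab$name == "ndhA")]]
  expect_equal(ndh$strand, "-")
  expect_equal(nrow(ndh$exons), 2L)
  expect_equal(ndh$exons$start, c(200L, 700L))
  expect_equal(tab$ftype[tab$name == "trnH"], "tRNA")
  expect_equal(tab$ftype[tab$name == "rpl23"], "pseudogene")
})

test_that("positions classify as coding, intron or intergenic with context", {
  feats <- list(
    gene_feature("g1", "CDS", "+", data.frame(start = 100, end = 200)),
    gene_feature("g2", "CDS", "-", data.frame(start = c(400, 700),
                                              end = c(500, 800))))
  cl <- classify_position(c(150, 600, 300, 50), feats, genome_length = 1000)
  expect_equal(cl$category, c("Coding", "Intron", "Intergenic", "Intergenic"))
  expect_equal(cl$context, c("g1", "g2 intron", "g1-g2", "g2-g1"))
  # circular flanking context past the last gene
  cl2 <- classify_position(900, feats, genome_length = 1000)
  expect_equal(cl2$context, "g2-g1")
  # no annotation at all
  cl3 <- classify_position(10, list(), genome_length = 1000)
  expect_equal(cl3$category, "Intergenic")
  expect_equal(cl3$context, "NA-NA")
})

test_that("every position falls in exactly one category", {
  gen <- generate_plastome(genome_spec(lsc_len = 12000, ssc_len = 5000,
                                       ir_len = 3000, n_genes = 10,
                                       intron_genes = 3, seed = 42))
  pos <- sample.int(gen$genome$length, 50)
  cl <- classify_position(pos, gen$features, genome_length = gen$genome$length)
  expect_true(all(cl$category %in% c("Coding", "Intron", "Intergenic")))
  expect_equal(nrow(cl), 50L)
})

test_that("intron inventory reports transcript-order exon/intron lengths", {
  # clpP-style three-exon gene: exons 71, 292, 228 with introns 951, 601
  clp <- gene_feature("clpP_like", "CDS", "+",
                      data.frame(start = c(1001, 2023, 2916),
                                 end = c(1071, 2314, 3143)))
  single <- gene_feature("psbA_like", "CDS", "+",
                         data.frame(start = 5000, end = 6000))
  rps12 <- gene_feature("rps12_like", "CDS", "+",
                        data.frame(start = c(8000, 9000, 9400),
                                   end = c(8113, 9230, 9426)),
                        trans_spliced = TRUE)
  inv <- intron_inventory(list(clp, single, rps12))
  expect_equal(inv$gene, c("clpP_like", "rps12_like"))
  expect_equal(inv$exon_lengths[[1L]], c(71L, 292L, 228L))
  expect_equal(inv$intron_lengths[[1L]], c(951L, 601L))
  expect_true(all(is.na(inv$intron_lengths[[2L]])))
  # exons plus introns reconstruct the genomic span
  expect_equal(sum(inv$exon_lengths[[1L]]) + sum(inv$intron_lengths[[1L]]),
               3143L - 1001L + 1L)
})

test_that("minus-strand introns come out in transcript order", {
  g <- gene_feature("g", "CDS", "-",
                    data.frame(start = c(100, 400), end = c(150, 600)))
  inv <- intron_inventory(list(g))
  expect_equal(inv$exon_lengths[[1L]], c(201L, 51L))   # 3'-most exon first
  expect_equal(inv$intron_lengths[[1L]], 249L)
})
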