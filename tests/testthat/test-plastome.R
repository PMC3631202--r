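test_that("annotation complement is implicitly intergenic", {
  p <- toy_plastome()
  cx <- context_of(p, 1:20)
  expect_equal(cx$context[4:9], rep("coding", 6))
  expect_equal(cx$context[c(1:3, 10:20)], rep("IGS", 14))
  expect_equal(cx$feature[5], "gA")

  empty <- plastome("bare", "ACGTACGTAC")
  expect_true(all(context_of(empty, 1:10)$context == "IGS"))
})

test_that("invalid sequences and features are rejected with detail", {
  expect_error(plastome("x", "ACGTX"), "position 5")
  expect_error(plastome("x", "ACGT",
                        features = data.frame(name = "g", kind = "gene_exon",
                                              start = 3, end = 2,
                                              strand = "+", phase = 0)),
               "start > end")
  expect_error(plastome("x", strrep("A", 30),
                        features = data.frame(name = "g", kind = "gene_exon",
                                              start = c(1, 5), end = c(9, 12),
                                              strand = "+", phase = 0)),
               "overlapping exons")
  # N is legal
  expect_silent(plastome("x", "ACGNNT"))
})

test_that("region lookup honours partition boundaries inclusively", {
  p <- plastome("x", strrep("A", 100),
                partition = data.frame(region = c("LSC", "IR"),
                                       start = c(1, 81), end = c(80, 100)))
  expect_equal(region_of(p, 81), "IR")
  expect_equal(region_of(p, 80), "LSC")
  expect_equal(region_of(p, c(1, 80, 81, 100)), c("LSC", "LSC", "IR", "IR"))
  expect_error(region_of(p, 0), "out of range")
  expect_error(region_of(p, 101), "out of range")
  expect_error(context_of(p, 0), "out of range")
})

test_that("context distinguishes coding, intron and flanking-gene IGS", {
  p <- plastome("x", strrep("ACGT", 25),
                features = data.frame(
                  name = c("rps16", "rps16", "rps16", "rpoC2"),
                  kind = c("gene_exon", "intron", "gene_exon", "gene_exon"),
                  start = c(5, 15, 31, 61), end = c(14, 30, 40, 80),
                  strand = "+", phase = c(0, NA, 0, 0)))
  expect_equal(unlist(context_of(p, 20)[, c("context", "feature")]),
               c(context = "intron", feature = "rps16"))
  expect_equal(context_of(p, 70)$context, "coding")
  expect_equal(context_of(p, 70)$feature, "rpoC2")
  igs <- context_of(p, 50)
  expect_equal(igs$context, "IGS")
  expect_equal(igs$feature, "rps16-rpoC2")
})

test_that("feature table round-trips through write and reload", {
  p <- generate_plastome(6000, ir_fraction = 0.2, gene_density = 0.4,
                         seed = 11)
  ft <- tempfile(fileext = ".tsv")
  fa <- write_tmp_fasta(list(synth = p$sequence))
  write_feature_table(p, ft)
  p2 <- read_plastome(fa, ft)
  pos <- seq(1L, p$length, by = 7L)
  expect_equal(region_of(p2, pos), region_of(p, pos))
  expect_equal(context_of(p2, pos), context_of(p, pos))
  expect_equal(p2$length, p$length)
})

test_that("every position has exactly one region and context", {
  p <- generate_plastome(4000, ir_fraction = 0.25, gene_density = 0.5,
                         seed = 5)
  regs <- region_of(p, seq_len(p$length))
  expect_true(all(regs %in% c("LSC", "SSC", "IR")))
  cx <- context_of(p, seq_len(p$length))
  expect_true(all(cx$context %in% c("coding", "intron", "IGS")))
  expect_equal(nrow(cx), p$length)
})
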