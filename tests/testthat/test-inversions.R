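test_that("reverse-complement mismatch blocks are detected as inversions", {
  pr <- toy_pair("AACCGTACCTT", "AACCTACCCTT")   # GTA -> TAC at cols 5..7
  cands <- detect_minute_inversions(pr)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$alleles, c("GTA", "TAC"))
  expect_equal(cands[[1]]$loop_bp, 3L)
  expect_equal(c(cands[[1]]$col_start, cands[[1]]$col_end), c(5L, 7L))
  expect_false(cands[[1]]$potential)
  expect_length(detect_minute_inversions(toy_pair("ACGT", "ACGT")), 0L)
})

test_that("reversed palindromic blocks are reported as potential inversions", {
  pr <- toy_pair("TTACGTT", "TTAGCTT")           # CG -> GC at cols 4..5
  cands <- detect_minute_inversions(pr)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$alleles, c("CG", "GC"))
  expect_equal(cands[[1]]$loop_bp, 2L)
  expect_true(cands[[1]]$potential)
})

test_that("plain mismatch runs are not inversions", {
  # AG -> GA is a reversal but CC -> AA is neither reversal nor revcomp
  expect_length(detect_minute_inversions(toy_pair("TTCCTT", "TTAATT")), 0L)
  # partial reverse-complement does not count
  expect_length(detect_minute_inversions(toy_pair("TTGTACTT", "TTTACGTT")),
                0L)
})

test_that("hairpin test measures perfect stems and applies min_stem", {
  p <- generate_plastome(8000, ir_fraction = 0.2, gene_density = 0.3,
                         seed = 31)
  inv <- data.frame(loop_seq = c("GTA", "CG"), stem_bp = c(8L, 2L),
                    type = c("revcomp", "reverse"), context = "IGS")
  pm <- plant_mutations(p, mutation_spec(inversions = inv, seed = 32))
  cands <- find_inversions(pm$pair)
  expect_length(cands, 2L)
  stems <- vapply(cands, function(cd)
    if (is.null(cd$hairpin)) NA_integer_ else cd$hairpin$stem_bp, 1L)
  loops <- vapply(cands, function(cd) cd$loop_bp, 1L)
  expect_setequal(paste(loops, stems), c("3 8", "2 NA"))
  hp <- cands[[which(loops == 3L)]]$hairpin
  expect_equal(hp$loop_seqs, c("GTA", "TAC"))
  expect_false(hp$truncated)
  # the 2-bp stem is measurable when min_stem allows it
  weak <- hairpin_test(cands[[which(loops == 2L)]], pm$pair, min_stem = 1L)
  expect_equal(weak$stem_bp, 2L)
})

test_that("search truncates at the alignment edge and reports it", {
  # complementary flanks right up to the sequence ends
  pr <- toy_pair("ACGTAGT", "ACTACGT")   # block GTA/TAC at cols 3..5
  cand <- detect_minute_inversions(pr)[[1]]
  hp <- hairpin_test(cand, pr, min_stem = 1L, max_stem_search = 10L)
  expect_true(hp$truncated)
  expect_equal(hp$stem_bp, 2L)
})

test_that("masked inversion columns never yield SNPs downstream", {
  set.seed(55)
  for (s in 1:5) {
    p <- generate_plastome(9000, ir_fraction = 0.2, gene_density = 0.3,
                           seed = 500 + s)
    inv <- data.frame(loop_seq = c("GTA", "TAT"), stem_bp = c(6L, 12L),
                      type = "revcomp", context = "IGS")
    pm <- plant_mutations(p, mutation_spec(n_snps = 25, inversions = inv,
                                           seed = 600 + s))
    cands <- find_inversions(pm$pair)
    expect_length(cands, 2L)
    for (cd in cands) {
      # definitional check: re-complementing the block restores a match
      expect_true(identical(
        strsplit(cd$alleles[2L], "")[[1]],
        rev(unname(c(A = "T", C = "G", G = "C", T = "A")[
          strsplit(cd$alleles[1L], "")[[1]]]))))
    }
    vs <- scan_variants(pm$pair, inversions = cands)
    masked <- inversion_columns(cands)
    snp_cols <- vs$variants$col_start[vs$variants$kind == "SNP"]
    expect_length(intersect(snp_cols, masked), 0L)
    expect_equal(vs$totals$snps, 25L)
    expect_equal(vs$totals$inversions, 2L)
  }
})
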