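test_that("identical rows yield an empty variant set", {
  vs <- scan_variants(toy_pair("ACGT", "ACGT"))
  expect_equal(vs$totals$n_variants, 0L)
  expect_equal(nrow(vs$variants), 0L)
})

test_that("SNPs and maximal gap runs are enumerated by definition", {
  vs <- scan_variants(toy_pair("AC-GTA", "ATTGCA"))
  v <- vs$variants
  expect_equal(vs$totals$snps, 2L)
  expect_equal(vs$totals$indels, 1L)
  snp <- v[v$kind == "SNP", ]
  expect_equal(snp$col_start, c(2L, 5L))
  expect_equal(snp$ref_allele, c("C", "T"))
  expect_equal(snp$alt_allele, c("T", "C"))
  idl <- v[v$kind == "indel", ]
  expect_equal(idl$col_start, 3L)
  expect_equal(idl$length, 1L)
  expect_equal(idl$alt_allele, "T")   # insertion in row 2
  expect_equal(idl$ref_allele, "")
  # one maximal run = one event, regardless of length
  vs2 <- scan_variants(toy_pair("AAAA----TTTT", "AAAACCCCTTTT"))
  expect_equal(vs2$totals$indels, 1L)
  expect_equal(vs2$variants$length[vs2$variants$kind == "indel"], 4L)
})

test_that("transition/transversion classification follows base chemistry", {
  expect_equal(classify_substitution("A", "G"), "transition")
  expect_equal(classify_substitution("C", "T"), "transition")
  expect_equal(classify_substitution("A", "T"), "transversion")
  expect_equal(classify_substitution("G", "C"), "transversion")
  expect_error(classify_substitution("A", "A"), "differ")
  expect_error(classify_substitution("A", "N"), "bases")
})

test_that("uncallable (N) columns yield no variants", {
  vs <- scan_variants(toy_pair("ANGT-C", "ACGTNC"))
  expect_equal(vs$totals$n_variants, 0L)
  # N inside a gap run voids the indel
  vs2 <- scan_variants(toy_pair("AA--TT", "AACNTT"))
  expect_equal(vs2$totals$indels, 0L)
})

test_that("coding effect reconstructs codons strand- and phase-aware", {
  # gene 4..12 on +: codons GAT|CTT|CGA
  p <- codon_plastome("ACCGATCTTCGAACGTACGT")
  expect_equal(classify_coding_effect(p, 6, "A"), "nonsynonymous")  # GAT->GAA
  expect_equal(classify_coding_effect(p, 9, "C"), "synonymous")     # CTT->CTC
  expect_equal(classify_coding_effect(p, 4, "T"), "nonsynonymous")  # Asp->Tyr

  # same codons encoded on the minus strand: CDS = revcomp(positions 4..12)
  # sequence 4..12 = TCGAAGATC -> CDS GAT CTT CGA
  pm <- codon_plastome("ACCTCGAAGATCACGTACGT", strand = "-")
  expect_equal(classify_coding_effect(pm, 10, "T"), "nonsynonymous") # GAT->GAA
  expect_equal(classify_coding_effect(pm, 7, "G"), "synonymous")     # CTT->CTC

  # incomplete codon at the feature edge is unresolved, not guessed
  pt <- plastome("t", "ACCGATCTTCGAACGTACGT",
                 features = data.frame(name = "gX", kind = "gene_exon",
                                       start = 4L, end = 11L, strand = "+",
                                       phase = 0L))
  expect_equal(classify_coding_effect(pt, 11, "A"), "unresolved")
  expect_error(classify_coding_effect(pt, 15, "A"), "not in any gene_exon")
})

test_that("effect classification splices exons across an intron", {
  # exons 4..6 and 13..18 with intron 7..12; CDS = GAT CTT CGA
  p <- plastome("spl", "ACCGATAAAAAACTTCGAACGT",
                features = data.frame(
                  name = c("gS", "gS", "gS"),
                  kind = c("gene_exon", "intron", "gene_exon"),
                  start = c(4L, 7L, 13L), end = c(6L, 12L, 18L),
                  strand = "+", phase = c(0L, NA, 0L)))
  expect_equal(classify_coding_effect(p, 15, "C"), "synonymous")   # CTT->CTC
  expect_equal(classify_coding_effect(p, 6, "A"), "nonsynonymous") # GAT->GAA
})

test_that("scan agrees with the brute-force oracle on small alignments", {
  set.seed(404)
  for (rep in 1:25) {
    pr <- random_small_pair(50)
    oracle <- brute_force_scan(pr)
    vs <- scan_variants(pr)   # no masks: oracle has no inversion concept
    v <- vs$variants
    expect_setequal(v$col_start[v$kind == "SNP"], oracle$snp_cols)
    idl <- v[v$kind == "indel", ]
    expect_equal(nrow(idl), length(oracle$indels))
    if (length(oracle$indels)) {
      o <- do.call(rbind, oracle$indels)
      expect_setequal(paste(idl$col_start, idl$col_end),
                      paste(o[, "start"], o[, "end"]))
    }
    # totals are recounts of the table
    expect_identical(vs$totals, variant_totals(v))
  }
})

test_that("variant counts and Tn/Tv split are symmetric in row order", {
  set.seed(77)
  for (rep in 1:10) {
    pr <- random_small_pair(60)
    sw <- toy_pair(pr$rows[2], pr$rows[1])
    a <- scan_variants(pr)$totals
    b <- scan_variants(sw)$totals
    expect_equal(a$n_variants, b$n_variants)
    expect_equal(a$transitions, b$transitions)
    expect_equal(a$transversions, b$transversions)
  }
})

test_that("per-feature summary is self-consistent and totals conserve", {
  ep <- elodea_pair(seed = 3)
  invs <- find_inversions(ep$pair)
  vs <- scan_variants(ep$pair, inversions = invs, plastome = ep$plastome)
  t <- vs$totals
  expect_equal(t$n_variants, t$snps + t$indels + t$inversions)
  expect_equal(t$snps, t$transitions + t$transversions)
  expect_equal(t$coding_snps, t$synonymous + t$nonsynonymous + t$unresolved)
  tab <- summarize_by_feature(vs, ep$plastome)
  tot <- tab[tab$gene == "Total", ]
  expect_equal(tot$total, t$n_variants)
  expect_equal(tot$tn, t$transitions)
  expect_equal(tot$tv, t$transversions)
  cod <- tab[tab$gene == "Subtotal coding", ]
  non <- tab[tab$gene == "Subtotal noncoding", ]
  expect_equal(cod$total + non$total, tot$total)
  gene_rows <- tab[!grepl("^Subtotal|^Total", tab$gene), ]
  expect_equal(sum(gene_rows$total), cod$total)
  expect_true(all(gene_rows$total >= 1L))
})

test_that("empty variant set summarizes to an all-zero total row", {
  vs <- scan_variants(toy_pair("ACGT", "ACGT"))
  tab <- summarize_by_feature(vs)
  expect_equal(tab$total[tab$gene == "Total"], 0L)
  expect_equal(nrow(tab), 3L)
})
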