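test_that("plastome generation is deterministic and respects knobs", {
  p1 <- generate_plastome(20000, seed = 7)
  p2 <- generate_plastome(20000, seed = 7)
  expect_identical(p1, p2)
  p3 <- generate_plastome(20000, seed = 8)
  expect_false(identical(p1$sequence, p3$sequence))

  flat <- generate_plastome(5000, gene_density = 0, seed = 9)
  expect_equal(nrow(flat$features), 0L)
  expect_true(all(context_of(flat, 1:5000)$context == "IGS"))

  pir <- generate_plastome(20000, ir_fraction = 0.15, seed = 10)
  ir <- pir$partition[pir$partition$region == "IR", ]
  expect_equal(ir$end - ir$start + 1L, 3000L)
  expect_error(generate_plastome(20000, gene_density = 0.95), "infeasible")
})

test_that("simple mutation specs plant exactly what they say", {
  p <- generate_plastome(10000, gene_density = 0, seed = 11)
  pm <- plant_mutations(p, mutation_spec(n_snps = 10, tn_fraction = 1,
                                         seed = 12))
  expect_equal(nrow(pm$truth), 10L)
  expect_true(all(pm$truth$kind == "SNP"))
  expect_true(all(pm$truth$change == "transition"))

  inv <- data.frame(loop_seq = "GTA", stem_bp = 8L, type = "revcomp",
                    context = "IGS")
  pm2 <- plant_mutations(p, mutation_spec(inversions = inv, seed = 13))
  cands <- find_inversions(pm2$pair)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$hairpin$stem_bp, 8L)
  expect_equal(cands[[1]]$loop_bp, 3L)

  pm3 <- plant_mutations(p, mutation_spec(n_snps = 10, tn_fraction = 1,
                                          seed = 12))
  expect_identical(pm$pair, pm3$pair)    # same seed, same output
  expect_identical(pm$truth, pm3$truth)
})

test_that("full pipeline recovers the planted truth over many seeds", {
  for (s in 1:8) {
    p <- generate_plastome(15000, ir_fraction = 0.22, gene_density = 0.45,
                           seed = 900 + s)
    spec <- mutation_spec(
      n_snps = 30, tn_fraction = 0.5, n_indels = 5,
      ssr_loci = data.frame(motif = c("T", "TA"), unit = c(1, 2),
                            count_ref = c(9, 6), count_alt = c(11, 5)),
      inversions = data.frame(loop_seq = "GTA", stem_bp = 6L,
                              type = "revcomp", context = "IGS"),
      seed = 950 + s)
    pm <- plant_mutations(p, spec)
    invs <- find_inversions(pm$pair)
    vs <- scan_variants(pm$pair, inversions = invs, plastome = pm$plastome)
    v <- vs$variants
    tr <- pm$truth
    key <- function(d) paste(d$kind, d$ref_pos, d$alt_pos, d$length,
                             d$ref_allele, d$alt_allele)
    expect_setequal(key(v), key(tr))     # no misses, no spurious events
    m <- merge(v, tr, by = c("kind", "ref_pos"),
               suffixes = c(".scan", ".truth"))
    snp <- m[m$kind == "SNP", ]
    expect_equal(snp$change.scan, snp$change.truth)
    expect_equal(snp$region.scan, snp$region.truth)
    expect_equal(snp$context.scan, snp$context.truth)
    cod <- snp[snp$context.truth == "coding", ]
    if (nrow(cod))                        # independent codon-table paths agree
      expect_equal(cod$effect.scan, cod$effect.truth)
    loci <- polymorphic_ssrs(pm$pair, vs, pm$plastome)
    expect_equal(nrow(loci), 2L)
  }
})

test_that("empirical transition fraction converges to tn_fraction", {
  p <- generate_plastome(150000, ir_fraction = 0.2, gene_density = 0,
                         seed = 33)
  pm <- plant_mutations(p, mutation_spec(n_snps = 10000,
                                         tn_fraction = 0.42, seed = 34))
  frac <- mean(pm$truth$change == "transition")
  # 3 binomial standard errors at n = 10000
  expect_lt(abs(frac - 0.42), 3 * sqrt(0.42 * 0.58 / 10000))
})

test_that("haplotype sample generation honours plans and members", {
  plan <- list(X = list(snps = integer(), indels = list()),
               Y = list(snps = 50L, indels = list()))
  hs <- generate_haplotype_samples(200L, plan, c(X = 3L, Y = 1L), seed = 3)
  coll <- collapse_haplotypes(hs$samples)
  expect_equal(coll$haplotypes$n_members, c(3L, 1L))
  d <- step_distance_matrix(coll$haplotypes)
  expect_equal(d[1, 2], 1L)
  # collapse-expand identity: memberships recovered exactly
  expect_equal(as.integer(table(coll$assignment$haplotype_id)[c("H1", "H2")]),
               c(3L, 1L))
  hs2 <- generate_haplotype_samples(200L, plan, c(X = 3L, Y = 1L), seed = 3)
  expect_identical(hs, hs2)
  # conflicting plans at adjacent columns are rejected
  bad <- list(X = list(snps = c(50L, 51L), indels = list()))
  expect_error(generate_haplotype_samples(200L, bad, c(X = 1L), seed = 1),
               "closer than 2")
})
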