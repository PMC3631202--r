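test_that("rates use reference region lengths and pool single-copy", {
  p <- generate_plastome(20000, ir_fraction = 0.15, gene_density = 0.3,
                         seed = 41)
  pm <- plant_mutations(p, mutation_spec(n_snps = 40, seed = 42))
  vs <- scan_variants(pm$pair, plastome = pm$plastome)
  r <- substitution_rate(vs, pm$plastome)
  tr <- pm$truth
  expect_equal(r$ir_snps, sum(tr$region == "IR"))
  expect_equal(r$sc_snps, sum(tr$region != "IR"))
  expect_equal(r$sc_snps + r$ir_snps, vs$totals$snps)
  expect_equal(r$sc_len + r$ir_len, pm$plastome$length)
  expect_equal(r$single_copy, r$sc_snps / r$sc_len)
  expect_equal(r$ir, r$ir_snps / r$ir_len)
})

test_that("densities use context lengths and pool noncoding", {
  p <- generate_plastome(10000, ir_fraction = 0.2, gene_density = 0.4,
                         seed = 43)
  pm <- plant_mutations(p, mutation_spec(n_snps = 10, seed = 44))
  vs <- scan_variants(pm$pair, plastome = pm$plastome)
  d <- snp_density(vs, pm$plastome)
  expect_equal(d$overall, pm$plastome$length / 10)
  expect_equal(d$coding_len + d$noncoding_len, pm$plastome$length)
  expect_equal(d$coding_snps + d$noncoding_snps, 10L)
  # zero SNPs in a class gives an infinite density, zero rate
  vs0 <- scan_variants(toy_pair("ACGT", "ACGT"),
                       plastome = plastome("z", "ACGT"))
  expect_equal(substitution_rate(vs0, plastome("z", "ACGT"))$single_copy, 0)
  expect_true(is.infinite(snp_density(vs0, plastome("z", "ACGT"))$overall))
})

test_that("Tn/Tv ratio handles the degenerate zero-transversion case", {
  p <- generate_plastome(6000, gene_density = 0, seed = 45)
  pm <- plant_mutations(p, mutation_spec(n_snps = 10, tn_fraction = 0.5,
                                         seed = 46))
  vs <- scan_variants(pm$pair)
  t <- vs$totals
  expect_equal(tn_tv_ratio(vs), t$transitions / t$transversions)
  pm2 <- plant_mutations(p, mutation_spec(n_snps = 5, tn_fraction = 1,
                                          seed = 47))
  vs2 <- scan_variants(pm2$pair)
  expect_warning(r2 <- tn_tv_ratio(vs2), "undefined")
  expect_true(is.na(r2))
})

test_that("relative excess reports both conventions explicitly", {
  re <- relative_excess(50, 100)
  expect_equal(re$excess_over_large, 0.5)
  expect_equal(re$excess_over_small, 1.0)
  expect_equal(relative_excess(0, 0)$excess_over_large, 0)
})

test_that("marker-set comparison tabulates per-locus counts with totals", {
  p <- generate_plastome(3000, ir_fraction = 0, gene_density = 0, seed = 48)
  pm1 <- plant_mutations(p, mutation_spec(n_snps = 6, n_indels = 2,
                                          seed = 49))
  same <- toy_pair("ACGTACGTAC", "ACGTACGTAC")
  tab <- compare_marker_sets(list(locusA = pm1$pair, locusB = same),
                             label = "X vs Y")
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$snps[tab$locus == "locusA"], 6L)
  expect_equal(tab$snps[tab$locus == "locusB"], 0L)
  expect_equal(tab$indels[tab$locus == "locusB"], 0L)
  expect_equal(tab$snps[tab$locus == "Total"], 6L)
  expect_equal(tab$length_bp[tab$locus == "Total"],
               3000L + 10L)
  expect_equal(attr(tab, "label"), "X vs Y")
})

test_that("window ranking orders by count with deterministic ties", {
  p <- generate_plastome(5000, gene_density = 0, seed = 50)
  # cluster 10 SNPs into one 400 bp window by planting then filtering
  pm <- plant_mutations(p, mutation_spec(n_snps = 30, seed = 51))
  vs <- scan_variants(pm$pair, plastome = pm$plastome)
  rk <- rank_variable_windows(vs, window_bp = 400L, step_bp = 100L,
                              ref_length = pm$plastome$length)
  expect_true(all(diff(rk$variant_count) <= 0))
  ties <- rk[rk$variant_count == rk$variant_count[1], ]
  expect_true(all(diff(ties$start) > 0))
  expect_equal(rk$variant_count,
               rk$snps + rk$indels + rk$inversions)
  # permutation invariance of variant order
  vs_perm <- vs
  set.seed(1)
  vs_perm$variants <- vs$variants[sample.int(nrow(vs$variants)), ]
  rk2 <- rank_variable_windows(vs_perm, window_bp = 400L, step_bp = 100L,
                               ref_length = pm$plastome$length)
  expect_equal(rk, rk2)
  # zero variants -> empty ranking
  vs0 <- scan_variants(toy_pair("ACGT", "ACGT"))
  expect_equal(nrow(rank_variable_windows(vs0, 400L, 100L, 5000L)), 0L)
})
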