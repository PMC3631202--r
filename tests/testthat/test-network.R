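test_that("haplotype collapsing partitions by identity with gap as a state", {
  samples <- data.frame(
    sample_id = paste0("s", 1:4),
    population = paste0("p", 1:4),
    sequence = c("ACGT-A", "ACGT-A", "ACGT-A", "ACGTTA"))
  coll <- collapse_haplotypes(samples)
  expect_equal(coll$haplotypes$haplotype_id, c("H1", "H2"))
  expect_equal(coll$haplotypes$n_members, c(3L, 1L))
  expect_equal(coll$assignment$haplotype_id, c("H1", "H1", "H1", "H2"))
  expect_error(collapse_haplotypes(samples[0, ]), "nrow")
})

test_that("N-containing columns are dropped before comparison", {
  samples <- data.frame(sample_id = c("a", "b"),
                        sequence = c("ANGTA", "ACGTA"))
  coll <- collapse_haplotypes(samples)
  expect_equal(nrow(coll$haplotypes), 1L)   # differ only at the N column
  expect_equal(coll$dropped_columns, 2L)
})

test_that("mutation steps decompose into SNP, indel and inversion events", {
  expect_equal(mutation_steps("ACGT", "ACGT")$total, 0L)
  st <- mutation_steps("AC--GTA", "ACTTG-A")
  expect_equal(st$snp_steps, 0L)
  expect_equal(st$indel_steps, 2L)     # one run per gapped side
  expect_equal(st$total, 2L)
  # a long gap run is still one event
  expect_equal(mutation_steps("A------T", "AACGTACT")$total, 1L)
  # inversion block counted once, not as three SNPs
  st2 <- mutation_steps("AACCGTACCTT", "AACCTACCCTT")
  expect_equal(st2$inversion_steps, 1L)
  expect_equal(st2$snp_steps, 0L)
})

test_that("step distance is a metric on synthetic haplotype triples", {
  hp <- elodea_haplotype_plan()
  for (s in 1:5) {
    hs <- generate_haplotype_samples(hp$base_length, hp$plan, hp$members,
                                     hp$species, seed = 100 + s)
    coll <- collapse_by_species(hs$samples)
    d <- step_distance_matrix(coll$haplotypes)
    expect_true(all(d == t(d)))                       # symmetry
    expect_true(all(diag(d) == 0L))                   # identity
    n <- nrow(d)
    trips <- utils::combn(n, 3L)
    for (k in seq_len(ncol(trips))) {                 # triangle inequality
      i <- trips[1, k]; j <- trips[2, k]; l <- trips[3, k]
      expect_lte(d[i, j], d[i, l] + d[l, j])
    }
  }
})

test_that("planned distances are reproduced exactly", {
  hp <- elodea_haplotype_plan()
  hs <- generate_haplotype_samples(hp$base_length, hp$plan, hp$members,
                                   hp$species, seed = 7)
  coll <- collapse_by_species(hs$samples)
  d <- step_distance_matrix(coll$haplotypes)
  ids <- rownames(hs$planned)
  expect_equal(d[ids, ids], hs$planned)
})

test_that("connection limit is monotone and collapses at high confidence", {
  lim <- connection_limit(4072, 0.95)
  expect_gte(lim, 12L)
  expect_lte(lim, 47L)
  # non-decreasing in sequence length
  lens <- c(500L, 1000L, 2000L, 4072L, 8144L, 16000L)
  lims <- vapply(lens, connection_limit, 1L, confidence = 0.95)
  expect_true(all(diff(lims) >= 0L))
  # non-increasing in confidence
  confs <- c(0.5, 0.8, 0.9, 0.95, 0.99, 0.9999)
  limc <- vapply(confs, function(cf) connection_limit(4072, cf), 1L)
  expect_true(all(diff(limc) <= 0L))
  expect_equal(connection_limit(4072, 0.999999), 1L)
  expect_error(connection_limit(4072, 1), "between 0 and 1")
  expect_error(connection_limit(4072, 0), "between 0 and 1")
  # one step is always parsimonious
  expect_equal(parsimony_probability(1, 10), 1)
  expect_lt(parsimony_probability(2, 10), 1)
})

test_that("network assembly connects within the limit only", {
  haps <- data.frame(haplotype_id = c("X", "Y"),
                     sequence = c("ACGTACGT", "ACGTACGA"),
                     n_members = c(3L, 1L), n_populations = c(3L, 1L))
  net <- build_network(haps, limit = 10L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 1L)
  expect_equal(max(net$components), 1L)
  # beyond the limit: no edge, two components
  net2 <- build_network(haps, limit = 0L)
  expect_equal(nrow(net2$edges), 0L)
  expect_equal(max(net2$components), 2L)
})

test_that("every non-bridge edge is within the limit and spans components", {
  hp <- elodea_haplotype_plan()
  hs <- generate_haplotype_samples(hp$base_length, hp$plan, hp$members,
                                   hp$species, seed = 13)
  coll <- collapse_by_species(hs$samples)
  lim <- connection_limit(hp$base_length, 0.95)
  net <- build_network(coll$haplotypes, lim)
  expect_true(all(net$edges$steps[!net$edges$bridge] <= lim))
  n_comp <- max(net$components)
  expect_gte(nrow(net$edges), nrow(net$nodes) - n_comp)
  # determinism: identical inputs give identical edge lists
  net2 <- build_network(coll$haplotypes, lim)
  expect_identical(net$edges, net2$edges)
})

test_that("manual bridges are flagged and carry observed steps", {
  hp <- elodea_haplotype_plan()
  hs <- generate_haplotype_samples(hp$base_length, hp$plan, hp$members,
                                   hp$species, seed = 17)
  coll <- collapse_by_species(hs$samples)
  net <- build_network(coll$haplotypes, connection_limit(4072, 0.95))
  comp_before <- net$components
  net <- add_bridge(net, "H1", "H2")
  b <- net$edges[net$edges$bridge, ]
  expect_equal(nrow(b), 1L)
  expect_equal(b$steps, 48L)
  expect_equal(net$components, comp_before)   # bridges never merge
  g <- as_igraph(net)
  expect_equal(igraph::ecount(g), nrow(net$edges))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_true(file.exists(gml) && file.size(gml) > 0)
})
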