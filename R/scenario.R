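## Study-condition scenario: a deterministic 112,193 bp annotated plastome
## and the mutation specification that reproduces the divergence profile of
## the published Elodea canadensis FIN/USA plastome comparison, with every
## event planted and therefore fully known.
##
## Geometry (chosen once, from the printed summary statistics):
##   partition  LSC 1..60,543 | IR 60,544..87,543 (27,000 bp) | SSC ..112,193
##   exon total 66,450 bp  ->  77 coding SNPs = 863.0 bp/SNP,
##                             109 noncoding SNPs over 45,743 bp = 420 bp/SNP
##   SNPs 154 single-copy / 32 IR -> rates 0.00181 / 0.00119 (5 decimals)

ELODEA_LENGTH <- 112193L
ELODEA_PARTITION <- data.frame(
  region = c("LSC", "IR", "SSC"),
  start = c(1L, 60544L, 87544L),
  end = c(60543L, 87543L, 112193L), stringsAsFactors = FALSE)

#' Deterministic annotated plastome at the package's study conditions
#'
#' A 112,193 bp genome (single IR copy modeled) with 56 genes laid out on a
#' fixed grid: 26 full plus 2 intron-split plus 1 short (450 bp) gene in the
#' LSC, 13 in the IR and 14 in the SSC, totalling 66,450 bp of exon sequence.
#' Only the sequence is random; the annotation grid is fixed so that the
#' region and context denominators of the divergence statistics are exact.
#'
#' @param seed Integer seed for the sequence.
#' @param name Genome label (default `"FIN"`).
#' @return A [plastome()].
#' @export
elodea_plastome <- function(seed = 1L, name = "FIN") {
  set.seed(seed)
  rows <- list()
  add <- function(nm, kind, s, e, strand = "+", phase = 0L)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = nm, kind = kind, start = s, end = e, strand = strand,
      phase = if (kind == "gene_exon") phase else NA_integer_,
      stringsAsFactors = FALSE)
  gi <- 0L
  strand_of <- function() if (gi %% 2L) "+" else "-"
  # LSC: 26 x 1200 on a 2080 grid
  for (i in 1:26) {
    gi <- gi + 1L
    s <- 200L + (i - 1L) * 2080L
    add(sprintf("lscA%02d", i), "gene_exon", s, s + 1199L, strand_of())
  }
  # 2 intron-split genes (600 + 300 intron + 600)
  for (i in 1:2) {
    gi <- gi + 1L
    s <- 53700L + (i - 1L) * 1700L
    nm <- sprintf("lscB%02d", i)
    st <- strand_of()
    add(nm, "gene_exon", s, s + 599L, st)
    add(nm, "intron", s + 600L, s + 899L, st)
    add(nm, "gene_exon", s + 900L, s + 1499L, st)
  }
  # short 450 bp gene
  gi <- gi + 1L
  add("lscC01", "gene_exon", 57400L, 57849L, strand_of())
  # IR: 13 x 1200 on a 2050 grid
  for (i in 1:13) {
    gi <- gi + 1L
    s <- 60844L + (i - 1L) * 2050L
    add(sprintf("irA%02d", i), "gene_exon", s, s + 1199L, strand_of())
  }
  # SSC: 14 x 1200 on a 1720 grid
  for (i in 1:14) {
    gi <- gi + 1L
    s <- 87844L + (i - 1L) * 1720L
    add(sprintf("sscA%02d", i), "gene_exon", s, s + 1199L, strand_of())
  }
  plastome(name, paste(random_dna(ELODEA_LENGTH), collapse = ""),
           features = do.call(rbind, rows), partition = ELODEA_PARTITION)
}

#' SSR polymorphism plan at the study conditions (28 loci)
#'
#' The published 28-locus table of length-polymorphic cpSSRs: 25
#' mononucleotide loci (4xA, 19xT, 1xC, 1xG; pooled mean tract 8.32 bp) and
#' 3 dinucleotide loci (pooled mean tract 13 bp). `count_ref` is the FIN
#' (reference) repeat count, `count_alt` the USA count.
#'
#' @return `data.frame` with columns `motif`, `unit`, `count_ref`,
#'   `count_alt`.
#' @export
elodea_ssr_plan <- function() {
  loci <- read_ssr_table(system.file("extdata", "elodea_polymorphic_ssrs.tsv",
                                     package = "cpdiff", mustWork = TRUE))
  data.frame(motif = loci$motif, unit = loci$unit,
             count_ref = loci$count_ref, count_alt = loci$count_alt,
             stringsAsFactors = FALSE)
}

#' Mutation specification at the study conditions
#'
#' 186 SNPs with the exact published class composition (region x context x
#' transition/transversion x coding effect), 47 indels (the 28 SSR loci of
#' [elodea_ssr_plan()] plus 19 others, longest 141/38/23 bp, 4 coding and 4
#' intronic), and two minute inversions: a 3-bp GTA loop with an 8-bp stem
#' (hairpin) and a 2-bp CG reversal block with a 2-bp stem (no hairpin).
#'
#' @param seed Integer seed.
#' @return A [mutation_spec()].
#' @export
elodea_mutation_spec <- function(seed = 1L) {
  cell <- function(n, region, context, change, effect = NA_character_)
    data.frame(region = rep(region, n), context = rep(context, n),
               change = rep(change, n), effect = rep(effect, n),
               stringsAsFactors = FALSE)
  snp_targets <- rbind(
    ## coding, single-copy: 57 (15+17 nonsyn, 12+13 syn)
    cell(15L, "SC", "coding", "transition", "nonsynonymous"),
    cell(17L, "SC", "coding", "transversion", "nonsynonymous"),
    cell(12L, "SC", "coding", "transition", "synonymous"),
    cell(13L, "SC", "coding", "transversion", "synonymous"),
    ## coding, IR: 20 (5/5/5/5)
    cell(5L, "IR", "coding", "transition", "nonsynonymous"),
    cell(5L, "IR", "coding", "transversion", "nonsynonymous"),
    cell(5L, "IR", "coding", "transition", "synonymous"),
    cell(5L, "IR", "coding", "transversion", "synonymous"),
    ## noncoding: SC 38 Tn + 59 Tv, IR 4 Tn + 8 Tv
    cell(38L, "SC", "noncoding", "transition"),
    cell(59L, "SC", "noncoding", "transversion"),
    cell(4L, "IR", "noncoding", "transition"),
    cell(8L, "IR", "noncoding", "transversion"))
  indel_targets <- data.frame(
    length = c(141L, 38L, 23L, 10L, 9L, 8L, 8L, 7L, 6L, 6L, 5L, 5L, 4L,
               4L, 3L, 3L, 2L, 2L, 1L),
    context = c("IGS", "IGS", "IGS", "IGS", "coding", "IGS", "intron",
                "IGS", "coding", "intron", "IGS", "coding", "IGS",
                "intron", "coding", "IGS", "intron", "IGS", "IGS"),
    direction = c("del", "ins", "del", "ins", "del", "del", "ins", "del",
                  "del", "del", "ins", "del", "del", "ins", "del", "ins",
                  "del", "ins", "del"),
    stringsAsFactors = FALSE)
  inversions <- data.frame(
    loop_seq = c("GTA", "CG"), stem_bp = c(8L, 2L),
    type = c("revcomp", "reverse"), context = c("IGS", "coding"),
    stringsAsFactors = FALSE)
  mutation_spec(snp_targets = snp_targets, indel_targets = indel_targets,
                ssr_loci = elodea_ssr_plan(), inversions = inversions,
                seed = seed)
}

#' Synthetic plastome pair at the study conditions
#'
#' Convenience wrapper: [elodea_plastome()] + [plant_mutations()] with
#' [elodea_mutation_spec()]. The resulting pair carries 235 planted variable
#' sites (186 SNPs, 47 indels, 2 inversions) with the full published class
#' composition.
#'
#' @param seed Integer seed (sequence and event placement).
#' @return List with `pair`, `truth`, `plastome`, `spec`
#'   (see [plant_mutations()]).
#' @export
elodea_pair <- function(seed = 1L) {
  p <- elodea_plastome(seed = seed)
  plant_mutations(p, elodea_mutation_spec(seed = seed + 1L),
                  alt_name = "USA")
}

#' Generate aligned haplotype sample sets with known step distances
#'
#' Each haplotype is defined by an edit plan against one base sequence:
#' substituted columns (`snps`) and deleted runs (`indels`, gap columns).
#' Shared edits produce identical states, so the pairwise
#' [mutation_steps()] distance between two haplotypes is the size of the
#' symmetric difference of their edit sets. Edit columns must be >= 2 columns
#' apart; deletion runs must not touch.
#'
#' @param base_length Number of alignment columns.
#' @param plan Named list; each element is a list with integer vector `snps`
#'   (edited columns) and `indels` (list of `c(start, length)` runs).
#' @param members Named integer vector: samples per haplotype.
#' @param species Optional named character vector: species label per
#'   haplotype.
#' @param seed Integer seed.
#' @return List with `samples` (`data.frame`: `sample_id`, `population`,
#'   `region`, `species`, `sequence`), `haplotype_of` (named vector),
#'   `planned` (planned pairwise distance matrix), `base` (the base
#'   sequence).
#' @export
generate_haplotype_samples <- function(base_length, plan, members,
                                       species = NULL, seed = 1L) {
  set.seed(seed)
  stopifnot(length(plan) >= 1L, all(names(plan) %in% names(members)))
  base <- random_dna(base_length)
  # conflict checks: any column edited by two haplotypes must be a shared
  # edit (identical resulting state); we enforce the simpler global rule
  all_snps <- sort(unique(unlist(lapply(plan, `[[`, "snps"))))
  if (length(all_snps) > 1L && any(diff(all_snps) < 2L))
    stop("edit columns closer than 2 apart would merge into blocks")
  sub_base <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  seq_of <- function(edits) {
    s <- base
    if (length(edits$snps)) for (col in edits$snps)
      s[col] <- sub_base(base[col])
    if (length(edits$indels)) for (run in edits$indels)
      s[run[1L]:(run[1L] + run[2L] - 1L)] <- "-"
    paste(s, collapse = "")
  }
  hap_seqs <- vapply(plan, seq_of, "")
  edit_key <- function(edits)
    c(if (length(edits$snps)) paste0("s", edits$snps) else character(),
      vapply(edits$indels, function(r) paste0("i", r[1L], ".", r[2L]), ""))
  keys <- lapply(plan, edit_key)
  n <- length(plan)
  planned <- matrix(0L, n, n, dimnames = list(names(plan), names(plan)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    planned[i, j] <- planned[j, i] <-
      length(c(setdiff(keys[[i]], keys[[j]]), setdiff(keys[[j]], keys[[i]])))
  }
  rows <- list()
  si <- 0L
  for (h in names(plan)) {
    for (m in seq_len(members[[h]])) {
      si <- si + 1L
      rows[[si]] <- data.frame(
        sample_id = sprintf("s%03d", si),
        population = sprintf("%s_pop%02d", h, m),
        region = if (m %% 3L == 0L) "introduced" else "native",
        species = if (!is.null(species)) species[[h]] else "sp",
        sequence = hap_seqs[[h]], stringsAsFactors = FALSE)
    }
  }
  samples <- do.call(rbind, rows)
  list(samples = samples,
       haplotype_of = stats::setNames(
         rep(names(plan), members[names(plan)]), samples$sample_id),
       planned = planned, base = paste(base, collapse = ""))
}

#' Haplotype edit plan at the study conditions (seven haplotypes)
#'
#' Reproduces the published step structure over a 4072-bp concatenated
#' marker alignment: within the first species H1 differs from H2 by 40 SNPs
#' plus 8 indels (48 steps) and H2 from H3 by one SNP; within the second
#' species A and B differ by 2, C and D by 2, and the A/B group is 12 steps
#' (11 SNPs + 1 indel) from C. Cross-species distances are large (~80+).
#'
#' @return List with `plan`, `members`, `species`, `base_length` suitable
#'   for [generate_haplotype_samples()].
#' @export
elodea_haplotype_plan <- function() {
  slot <- function(i) 10L + 3L * i        # spaced edit columns
  a_edits <- list(snps = slot(100:179), indels = list())
  c_extra <- list(snps = slot(210:220), indels = list(c(3000L, 2L)))
  plan <- list(
    H2 = list(snps = integer(), indels = list()),
    H1 = list(snps = slot(1:40),
              indels = list(c(1500L, 1L), c(1540L, 1L), c(1580L, 2L),
                            c(1620L, 2L), c(1660L, 3L), c(1700L, 3L),
                            c(1740L, 4L), c(1780L, 6L))),
    H3 = list(snps = slot(45), indels = list()),
    A = a_edits,
    B = list(snps = c(a_edits$snps, slot(200:201)), indels = list()),
    C = list(snps = c(a_edits$snps, c_extra$snps), indels = c_extra$indels),
    D = list(snps = c(a_edits$snps, c_extra$snps, slot(230:231)),
             indels = c_extra$indels))
  members <- c(H1 = 29L, H2 = 1L, H3 = 1L, A = 22L, B = 1L, C = 1L, D = 1L)
  species <- c(H1 = "E. canadensis", H2 = "E. canadensis",
               H3 = "E. canadensis", A = "E. nuttallii", B = "E. nuttallii",
               C = "E. nuttallii", D = "E. nuttallii")
  list(plan = plan, members = members, species = species,
       base_length = 4072L)
}

#' Collapse haplotypes per species with species-specific naming
#'
#' The first species (alphabetically) gets `H1, H2, ...`, the second
#' `A, B, ...`, echoing the conventional dual naming of two-species
#' phylogeographic surveys.
#'
#' @param samples Sample `data.frame` with a `species` column.
#' @return List with combined `haplotypes`, `assignment` and per-species
#'   collapse results.
#' @export
collapse_by_species <- function(samples) {
  stopifnot("species" %in% names(samples))
  sp <- sort(unique(samples$species))
  res <- lapply(seq_along(sp), function(i) {
    sub <- samples[samples$species == sp[i], , drop = FALSE]
    if (i == 1L) collapse_haplotypes(sub, prefix = "H")
    else collapse_haplotypes(sub, labels = LETTERS)
  })
  names(res) <- sp
  haps <- do.call(rbind, lapply(res, `[[`, "haplotypes"))
  rownames(haps) <- NULL
  assignment <- do.call(rbind, lapply(res, `[[`, "assignment"))
  rownames(assignment) <- NULL
  list(haplotypes = haps, assignment = assignment, per_species = res)
}
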