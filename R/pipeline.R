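#' Run configuration for the comparison and network pipelines
#'
#' Plain named-list configuration with documented defaults; can be loaded
#' from / saved to a YAML file and overridden per call. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param alignment Path to the pairwise genome alignment (FASTA/NEXUS).
#' @param features Path to the reference feature table TSV (or GFF3).
#' @param samples Path to the multi-sample marker alignment (FASTA/NEXUS).
#' @param sample_sheet Path to the sample sheet TSV (`sample_id`,
#'   `population`, `region`, `species`).
#' @param out Output directory.
#' @param ssr_min_mono,ssr_min_di SSR repeat-count thresholds (longer
#'   allele).
#' @param max_loop Maximum minute-inversion block length (bp).
#' @param min_stem Minimum stem length to call a hairpin (bp).
#' @param max_stem_search Maximum stem extension searched (bp).
#' @param confidence Statistical-parsimony connection confidence.
#' @param window,step Variable-window ranking size and step (bp).
#' @param seed Seed for the synthetic subcommands.
#' @return A named list of class `cp_config`.
#' @export
run_config <- function(alignment = NULL, features = NULL, samples = NULL,
                       sample_sheet = NULL, out = ".",
                       ssr_min_mono = 5L, ssr_min_di = 5L,
                       max_loop = 30L, min_stem = 4L, max_stem_search = 25L,
                       confidence = 0.95, window = 400L, step = 100L,
                       seed = 1L) {
  stopifnot(ssr_min_mono >= 2L, ssr_min_di >= 2L, max_loop >= 2L,
            min_stem >= 1L, max_stem_search >= 1L,
            confidence > 0, confidence < 1, window >= step, step >= 1L)
  structure(list(alignment = alignment, features = features,
                 samples = samples, sample_sheet = sample_sheet, out = out,
                 ssr_min_mono = as.integer(ssr_min_mono),
                 ssr_min_di = as.integer(ssr_min_di),
                 max_loop = as.integer(max_loop),
                 min_stem = as.integer(min_stem),
                 max_stem_search = as.integer(max_stem_search),
                 confidence = confidence, window = as.integer(window),
                 step = as.integer(step), seed = as.integer(seed)),
            class = "cp_config")
}

#' Load a run configuration from a YAML file
#' @param path YAML file with any subset of [run_config()]'s keys.
#' @return A `cp_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Save a run configuration to YAML (round-trips through [read_config()])
#' @param config A `cp_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "cp_config"))
  yaml::write_yaml(config[!vapply(config, is.null, TRUE)], path)
  invisible(path)
}

#' Full pairwise comparison in memory
#'
#' The core pipeline behind [run_compare()]: inversion detection and hairpin
#' tests, masked variant scan with classification, SSR survey, divergence
#' statistics and window ranking.
#'
#' @param pair An [aligned_pair()] (row 1 = reference).
#' @param plastome The reference [plastome()].
#' @param config A [run_config()] (paths ignored).
#' @return List with `inversions`, `variants`, `ssrs`, `summary`,
#'   `divergence`, `windows`.
#' @export
compare_plastomes <- function(pair, plastome, config = run_config()) {
  invs <- find_inversions(pair, max_loop = config$max_loop,
                          max_stem_search = config$max_stem_search,
                          min_stem = config$min_stem)
  vs <- scan_variants(pair, inversions = invs, plastome = plastome)
  ssrs <- polymorphic_ssrs(pair, vs, plastome,
                           min_mono = config$ssr_min_mono,
                           min_di = config$ssr_min_di)
  list(inversions = invs, variants = vs, ssrs = ssrs,
       summary = summarize_by_feature(vs, plastome),
       divergence = divergence_report(vs, plastome),
       windows = rank_variable_windows(vs, window_bp = config$window,
                                       step_bp = config$step,
                                       ref_length = plastome$length))
}

#' Run the comparison pipeline from files and write the report bundle
#'
#' Reads the pairwise alignment and reference annotation named in the
#' config, runs [compare_plastomes()] and writes `variants.tsv`,
#' `summary_by_feature.tsv`, `ssr_loci.tsv`, `inversions.tsv`,
#' `divergence.json`, `totals.json` and `window_ranking.tsv` into the output
#' directory. Stage counts are logged to `stderr`. Outputs are deterministic
#' for identical inputs and config.
#'
#' @param config A [run_config()] with `alignment` and `features` set.
#' @return The [compare_plastomes()] result, invisibly.
#' @export
run_compare <- function(config) {
  stopifnot(inherits(config, "cp_config"))
  for (f in c("alignment", "features")) {
    if (is.null(config[[f]])) stop("config lacks required path: ", f)
    if (!file.exists(config[[f]]))
      stop("compare: missing ", f, " file: ", config[[f]])
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[compare] ", ...)
  pair <- read_pair_alignment(config$alignment)
  log_msg("alignment: ", pair$ncol, " columns (",
          paste(pair$names, collapse = " vs "), ")")
  ref <- read_plastome_for_pair(config, pair)
  res <- compare_plastomes(pair, ref, config)
  t <- res$variants$totals
  log_msg("variants: ", t$n_variants, " (", t$snps, " SNPs, ", t$indels,
          " indels, ", t$inversions, " inversions)")
  log_msg("SSR loci: ", nrow(res$ssrs))
  out <- function(x) file.path(config$out, x)
  write_variants_tsv(res$variants, out("variants.tsv"))
  utils::write.table(res$summary, out("summary_by_feature.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(res$ssrs, out("ssr_loci.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(inversions_table(res$inversions), out("inversions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$windows, out("window_ranking.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$divergence, out("divergence.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  jsonlite::write_json(t, out("totals.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_msg("reports written to ", config$out)
  invisible(res)
}

# the feature file may describe the ungapped reference row; sequence comes
# from the alignment itself
read_plastome_for_pair <- function(config, pair) {
  ref_seq <- ungapped_seq(pair, 1L)
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  writeLines(c(paste0(">", pair$names[1L]), ref_seq), tmp)
  read_plastome(tmp, config$features)
}

#' Run the haplotype-network pipeline from files and write the bundle
#'
#' Reads a multi-sample marker alignment plus its sample sheet, collapses
#' haplotypes (per species when a `species` column is present), computes the
#' step-distance matrix and the statistical-parsimony connection limit, and
#' assembles the network. Writes `haplotypes.tsv`, `assignment.tsv`,
#' `distances.tsv`, `network_edges.tsv`, `components.tsv` and
#' `network.graphml` into the output directory, with deterministic ordering.
#'
#' @param config A [run_config()] with `samples` and `sample_sheet` set.
#' @return List with `collapse`, `dist`, `limit`, `network`, invisibly.
#' @export
run_network <- function(config) {
  stopifnot(inherits(config, "cp_config"))
  for (f in c("samples", "sample_sheet")) {
    if (is.null(config[[f]])) stop("config lacks required path: ", f)
    if (!file.exists(config[[f]]))
      stop("network: missing ", f, " file: ", config[[f]])
  }
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[network] ", ...)
  seqs <- read_sample_alignment(config$samples)
  sheet <- utils::read.delim(config$sample_sheet, stringsAsFactors = FALSE)
  if (!all(c("sample_id") %in% names(sheet)))
    stop("sample sheet needs a sample_id column")
  miss <- setdiff(sheet$sample_id, names(seqs))
  if (length(miss)) stop("samples absent from alignment: ",
                         paste(miss, collapse = ", "))
  samples <- sheet
  samples$sequence <- unname(seqs[sheet$sample_id])
  coll <- if ("species" %in% names(samples) &&
              length(unique(samples$species)) > 1L)
    collapse_by_species(samples) else collapse_haplotypes(samples)
  haps <- coll$haplotypes
  log_msg(nrow(samples), " samples -> ", nrow(haps), " haplotypes")
  d <- step_distance_matrix(haps)
  limit <- connection_limit(nchar(haps$sequence[1L]),
                            confidence = config$confidence)
  net <- build_network(haps, limit, dist = d)
  log_msg("connection limit ", limit, " steps; ",
          max(net$components), " components")
  out <- function(x) file.path(config$out, x)
  utils::write.table(haps[, c("haplotype_id", "n_members", "n_populations")],
                     out("haplotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(coll$assignment, out("assignment.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(d), out("distances.tsv"), sep = "\t",
                     quote = FALSE, row.names = TRUE, col.names = NA)
  utils::write.table(net$edges, out("network_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(haplotype_id = names(net$components),
               component = unname(net$components)),
    out("components.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_network_graphml(net, out("network.graphml"))
  log_msg("reports written to ", config$out)
  invisible(list(collapse = coll, dist = d, limit = limit, network = net))
}

#' Read a multi-sample alignment (FASTA or NEXUS) as a named vector
#' @param path Input path.
#' @return Named character vector of aligned sequences (uppercased, gaps
#'   normalized to `-`).
#' @export
read_sample_alignment <- function(path) {
  head1 <- readLines(path, n = 50L, warn = FALSE)
  head1 <- head1[nzchar(trimws(head1))]
  if (length(head1) && grepl("^#NEXUS", head1[1L], ignore.case = TRUE)) {
    dat <- ape::read.nexus.data(path)
    seqs <- vapply(dat, paste, "", collapse = "")
  } else {
    seqs <- read_fasta_text(path)
  }
  seqs <- toupper(seqs)
  seqs <- gsub("[.~]", "-", seqs)
  if (length(unique(nchar(seqs))) != 1L)
    stop("sample sequences have unequal column counts")
  seqs
}
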