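#' Substitution rate by region class (single-copy vs inverted repeat)
#'
#' SNP count divided by the reference-genome (non-gap) length of each region
#' class; LSC and SSC are pooled as "single-copy". Rates are per nucleotide.
#'
#' @param vs A classified `cp_variant_set`.
#' @param plastome The reference [plastome()] (denominator authority).
#' @return List with `single_copy`, `ir` (rates) and the underlying counts
#'   and lengths (`sc_snps`, `ir_snps`, `sc_len`, `ir_len`).
#' @export
substitution_rate <- function(vs, plastome) {
  stopifnot(inherits(vs, "cp_variant_set"), inherits(plastome, "cp_plastome"))
  v <- vs$variants
  snps <- v[v$kind == "SNP", , drop = FALSE]
  if (nrow(snps) && all(is.na(snps$region)))
    stop("variant set is unclassified; rerun scan_variants() with a plastome")
  part <- plastome$partition
  lens <- part$end - part$start + 1L
  ir_len <- sum(lens[part$region == "IR"])
  sc_len <- sum(lens[part$region != "IR"])
  ir_snps <- sum(snps$region == "IR")
  sc_snps <- sum(snps$region %in% c("LSC", "SSC"))
  list(single_copy = if (sc_len > 0L) sc_snps / sc_len else NA_real_,
       ir = if (ir_len > 0L) ir_snps / ir_len else NA_real_,
       sc_snps = sc_snps, ir_snps = ir_snps,
       sc_len = sc_len, ir_len = ir_len)
}

#' SNP density (bp per SNP) by genic context
#'
#' Context length divided by SNP count for coding (gene exons), non-coding
#' (introns and intergenic pooled) and overall; lengths are measured on the
#' reference genome. Zero SNPs in a class gives `Inf` (flagged by the
#' caller's discretion).
#'
#' @param vs A classified `cp_variant_set`.
#' @param plastome The reference [plastome()].
#' @return List with `coding`, `noncoding`, `overall` (bp per SNP) and the
#'   underlying counts and lengths.
#' @export
snp_density <- function(vs, plastome) {
  stopifnot(inherits(vs, "cp_variant_set"), inherits(plastome, "cp_plastome"))
  v <- vs$variants
  snps <- v[v$kind == "SNP", , drop = FALSE]
  if (nrow(snps) && all(is.na(snps$context)))
    stop("variant set is unclassified; rerun scan_variants() with a plastome")
  ft <- plastome$features
  ex <- ft[ft$kind == "gene_exon", , drop = FALSE]
  coding_len <- if (nrow(ex)) {
    cov <- rep(FALSE, plastome$length)
    for (i in seq_len(nrow(ex))) cov[ex$start[i]:ex$end[i]] <- TRUE
    sum(cov)
  } else 0L
  noncoding_len <- plastome$length - coding_len
  n_cod <- sum(snps$context == "coding")
  n_non <- sum(snps$context %in% c("intron", "IGS"))
  n_all <- nrow(snps)
  list(coding = coding_len / n_cod, noncoding = noncoding_len / n_non,
       overall = plastome$length / n_all,
       coding_len = coding_len, noncoding_len = noncoding_len,
       coding_snps = n_cod, noncoding_snps = n_non, snps = n_all)
}

#' Transition/transversion ratio R = Tn / Tv
#' @param vs A `cp_variant_set`.
#' @return The ratio as a number; `NA` (with a warning) when there are no
#'   transversions.
#' @export
tn_tv_ratio <- function(vs) {
  stopifnot(inherits(vs, "cp_variant_set"))
  t <- vs$totals
  if (t$transversions == 0L) {
    warning("no transversions: Tn/Tv ratio undefined")
    return(NA_real_)
  }
  t$transitions / t$transversions
}

#' Bundle of region/context divergence summaries
#'
#' Report rounding matches conventional display precision: rates to 5
#' decimals, densities to integer bp, R to 2 decimals; raw values are kept
#' alongside.
#'
#' @param vs A classified `cp_variant_set`.
#' @param plastome The reference [plastome()].
#' @return List (`rate_by_region`, `density_by_context`, `tn_tv_ratio`,
#'   `totals`, plus `display` with rounded values), JSON-serializable.
#' @export
divergence_report <- function(vs, plastome) {
  r <- substitution_rate(vs, plastome)
  d <- snp_density(vs, plastome)
  rr <- tn_tv_ratio(vs)
  list(rate_by_region = r, density_by_context = d, tn_tv_ratio = rr,
       totals = vs$totals,
       display = list(rate_single_copy = round(r$single_copy, 5L),
                      rate_ir = round(r$ir, 5L),
                      density_coding = round(d$coding),
                      density_noncoding = round(d$noncoding),
                      density_overall = round(d$overall),
                      tn_tv_ratio = round(rr, 2L)))
}

#' Relative excess of the larger of two counts, both conventions
#'
#' Cross-comparison percentages of the form "x% higher" are ambiguous between
#' (large - small) / large and (large - small) / small; both are returned with
#' explicit labels.
#'
#' @param a,b Two non-negative counts.
#' @return List with `excess_over_large` and `excess_over_small` (fractions).
#' @export
relative_excess <- function(a, b) {
  large <- max(a, b); small <- min(a, b)
  list(excess_over_large = if (large > 0) (large - small) / large else 0,
       excess_over_small = if (small > 0) (large - small) / small else Inf)
}

#' Per-locus polymorphism table over a set of marker alignments
#'
#' Runs the full variant scan (inversion detection, SNP/indel enumeration,
#' SSR test) on each small marker alignment and tabulates counts per locus
#' plus a totals row -- one invocation per genome pair.
#'
#' @param pairs Named list of [aligned_pair()] objects, one per marker locus.
#' @param label Label for the comparison (e.g. `"FIN vs USA"`).
#' @param min_mono,min_di SSR thresholds (see [polymorphic_ssrs()]).
#' @return `data.frame` with columns `locus`, `length_bp` (reference-genome
#'   bp), `snps`, `ssrs`, `indels`, `inversions` and a final `Total` row;
#'   attribute `label` carries the comparison label.
#' @export
compare_marker_sets <- function(pairs, label = "", min_mono = 5L,
                                min_di = 5L) {
  stopifnot(is.list(pairs), length(pairs) >= 1L)
  nms <- names(pairs)
  if (is.null(nms)) nms <- paste0("locus", seq_along(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    invs <- find_inversions(pr)
    vs <- scan_variants(pr, inversions = invs)
    ssrs <- polymorphic_ssrs(pr, vs, min_mono = min_mono, min_di = min_di)
    n_ssr <- nrow(ssrs)
    data.frame(locus = nms[i],
               length_bp = length(pr$pos_to_col[[1L]]),
               snps = vs$totals$snps,
               ssrs = n_ssr,
               indels = vs$totals$indels - n_ssr,
               inversions = vs$totals$inversions,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(locus = "Total",
                               length_bp = sum(out$length_bp),
                               snps = sum(out$snps), ssrs = sum(out$ssrs),
                               indels = sum(out$indels),
                               inversions = sum(out$inversions),
                               stringsAsFactors = FALSE))
  attr(out, "label") <- label
  out
}

#' Rank sliding windows of the reference genome by variant count
#'
#' Scores windows by the number of variants whose reference anchor falls
#' inside, sorts descending (ties by ascending start) and drops empty
#' windows. The top windows are the candidate regions for marker/primer
#' design.
#'
#' @param vs A `cp_variant_set`.
#' @param window_bp Window size in bp.
#' @param step_bp Step between window starts (<= `window_bp`).
#' @param ref_length Reference genome length (defaults to the maximum
#'   variant coordinate).
#' @return `data.frame` with columns `start`, `end`, `variant_count`, `snps`,
#'   `indels`, `inversions`, ordered by rank.
#' @export
rank_variable_windows <- function(vs, window_bp = 400L, step_bp = 100L,
                                  ref_length = NULL) {
  stopifnot(inherits(vs, "cp_variant_set"),
            window_bp >= step_bp, step_bp >= 1L)
  v <- vs$variants
  if (!nrow(v))
    return(data.frame(start = integer(), end = integer(),
                      variant_count = integer(), snps = integer(),
                      indels = integer(), inversions = integer(),
                      stringsAsFactors = FALSE))
  pos <- pmax(v$ref_pos, 1L)
  if (is.null(ref_length)) ref_length <- max(pos)
  starts <- seq.int(1L, max(1L, ref_length - window_bp + 1L), by = step_bp)
  rows <- lapply(starts, function(s) {
    e <- min(s + window_bp - 1L, ref_length)
    inw <- pos >= s & pos <= e
    if (!any(inw)) return(NULL)
    data.frame(start = s, end = e, variant_count = sum(inw),
               snps = sum(inw & v$kind == "SNP"),
               indels = sum(inw & v$kind == "indel"),
               inversions = sum(inw & v$kind == "inversion"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      variant_count = integer(), snps = integer(),
                      indels = integer(), inversions = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(-out$variant_count, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
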