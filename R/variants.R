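#' Transition or transversion?
#'
#' @param a,b Single bases in `A,C,G,T`, unequal.
#' @return `"transition"` if the change is purine-purine (`A<->G`) or
#'   pyrimidine-pyrimidine (`C<->T`), else `"transversion"`. Vectorized.
#' @export
classify_substitution <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (any(!a %in% c("A", "C", "G", "T")) || any(!b %in% c("A", "C", "G", "T")))
    stop("bases must be A, C, G or T")
  if (any(a == b)) stop("bases must differ")
  pur <- c("A", "G")
  ifelse((a %in% pur) == (b %in% pur), "transition", "transversion")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

revcomp_chars <- function(chars) rev(unname(COMPLEMENT[chars]))
revcomp_str <- function(s) paste(revcomp_chars(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = "")

#' Enumerate and classify all mutational differences in a pairwise alignment
#'
#' One SNP per mismatching non-gap column (adjacent mismatch columns are
#' separate SNPs), one indel per maximal single-row gap run, and one inversion
#' per detected minute-inversion block. Inversion blocks must be detected
#' first ([detect_minute_inversions()]) and passed in: their internal
#' mismatches are masked so they are not double-counted as SNPs. Columns with
#' `N` in either row are uncallable and yield no variant; a gap run containing
#' an uncallable column is dropped.
#'
#' @param pair An [aligned_pair()]; row 1 is the reference genome for
#'   coordinates and classification.
#' @param inversions Result of [detect_minute_inversions()] (or `NULL`).
#' @param plastome Optional [plastome()] matching the ungapped reference row;
#'   when supplied, every variant is classified (region, context, feature,
#'   transition/transversion, coding effect).
#' @return A `cp_variant_set`: list with `variants` (data.frame, one row per
#'   variant, ordered by alignment column) and `totals` (named list of
#'   self-consistent counts).
#' @export
scan_variants <- function(pair, inversions = NULL, plastome = NULL) {
  stopifnot(inherits(pair, "aligned_pair"))
  m <- pair$mat
  nc <- pair$ncol
  masked <- rep(FALSE, nc)
  if (!is.null(inversions) && length(inversions)) {
    for (iv in inversions) masked[iv$col_start:iv$col_end] <- TRUE
  }
  callable <- m[1L, ] != "N" & m[2L, ] != "N"
  gap1 <- m[1L, ] == "-"
  gap2 <- m[2L, ] == "-"

  rows <- list()

  ## SNPs
  snp_cols <- which(!gap1 & !gap2 & m[1L, ] != m[2L, ] & callable & !masked)
  if (length(snp_cols)) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "SNP", col_start = snp_cols, col_end = snp_cols,
      ref_pos = pair$col_to_pos[[1L]][snp_cols],
      alt_pos = pair$col_to_pos[[2L]][snp_cols],
      ref_allele = m[1L, snp_cols], alt_allele = m[2L, snp_cols],
      length = 1L, stringsAsFactors = FALSE)
  }

  ## indels: maximal gap runs per row (no column is gap in both rows)
  for (r in 1:2) {
    gap <- if (r == 1L) gap1 else gap2
    gap <- gap & !masked
    if (!any(gap)) next
    rle_runs <- rle(gap)
    ends <- cumsum(rle_runs$lengths)
    starts <- ends - rle_runs$lengths + 1L
    keep <- rle_runs$values
    for (i in which(keep)) {
      s <- starts[i]; e <- ends[i]
      if (any(!callable[s:e])) next   # N inside the event: uncallable
      other <- 3L - r
      seqs <- paste(m[other, s:e], collapse = "")
      # 5' flanking residue position on each genome (0 when run at edge)
      flank_ref <- if (s > 1L) pair$col_to_pos[[1L]][s - 1L] else NA_integer_
      flank_alt <- if (s > 1L) pair$col_to_pos[[2L]][s - 1L] else NA_integer_
      flank_ref <- if (is.na(flank_ref)) 0L else flank_ref
      flank_alt <- if (is.na(flank_alt)) 0L else flank_alt
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "indel", col_start = s, col_end = e,
        ref_pos = if (r == 2L) pair$col_to_pos[[1L]][s] else flank_ref,
        alt_pos = if (r == 1L) pair$col_to_pos[[2L]][s] else flank_alt,
        ref_allele = if (r == 2L) seqs else "",
        alt_allele = if (r == 1L) seqs else "",
        length = e - s + 1L, stringsAsFactors = FALSE)
    }
  }

  ## inversions
  if (!is.null(inversions) && length(inversions)) {
    for (iv in inversions) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "inversion", col_start = iv$col_start, col_end = iv$col_end,
        ref_pos = pair$col_to_pos[[1L]][iv$col_start],
        alt_pos = pair$col_to_pos[[2L]][iv$col_start],
        ref_allele = iv$alleles[1L], alt_allele = iv$alleles[2L],
        length = iv$loop_bp, stringsAsFactors = FALSE)
    }
  }

  v <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), col_start = integer(), col_end = integer(),
               ref_pos = integer(), alt_pos = integer(),
               ref_allele = character(), alt_allele = character(),
               length = integer(), stringsAsFactors = FALSE)
  v <- v[order(v$col_start, v$kind), , drop = FALSE]
  rownames(v) <- NULL

  nv <- nrow(v)
  v$change <- rep(NA_character_, nv)
  is_snp <- v$kind == "SNP"
  if (any(is_snp))
    v$change[is_snp] <- classify_substitution(v$ref_allele[is_snp],
                                              v$alt_allele[is_snp])
  v$region <- rep(NA_character_, nv)
  v$context <- rep(NA_character_, nv)
  v$feature <- rep(NA_character_, nv)
  v$effect <- ifelse(is_snp, "not_applicable", NA_character_)

  if (!is.null(plastome)) {
    stopifnot(inherits(plastome, "cp_plastome"))
    if (length(pair$pos_to_col[[1L]]) != plastome$length)
      stop("reference row ungapped length (", length(pair$pos_to_col[[1L]]),
           ") differs from plastome length (", plastome$length, ")")
    # classification anchor: SNP/inversion at its first reference base,
    # indel at the 5' flanking reference base of the gap
    anchor <- v$ref_pos
    anchor[anchor == 0L] <- 1L
    if (nrow(v)) {
      v$region <- region_of(plastome, anchor)
      cx <- context_of(plastome, anchor)
      v$context <- cx$context
      v$feature <- cx$feature
      cod_snp <- is_snp & v$context == "coding"
      if (any(cod_snp)) {
        cache <- new.env(parent = emptyenv())
        v$effect[cod_snp] <- vapply(which(cod_snp), function(i) {
          classify_coding_effect(plastome, v$ref_pos[i], v$alt_allele[i],
                                 gene = v$feature[i], cds_cache = cache)
        }, "")
      }
    }
  }

  new_variant_set(v)
}

new_variant_set <- function(v) {
  structure(list(variants = v, totals = variant_totals(v)),
            class = "cp_variant_set")
}

#' Recount totals of a variant table (self-consistency authority)
#' @param v The `variants` data.frame of a `cp_variant_set`.
#' @return Named list of counts.
#' @export
variant_totals <- function(v) {
  is_snp <- v$kind == "SNP"
  list(
    n_variants = nrow(v),
    snps = sum(is_snp),
    indels = sum(v$kind == "indel"),
    inversions = sum(v$kind == "inversion"),
    transitions = sum(v$change == "transition", na.rm = TRUE),
    transversions = sum(v$change == "transversion", na.rm = TRUE),
    synonymous = sum(is_snp & v$effect == "synonymous", na.rm = TRUE),
    nonsynonymous = sum(is_snp & v$effect == "nonsynonymous", na.rm = TRUE),
    unresolved = sum(is_snp & v$effect == "unresolved", na.rm = TRUE),
    coding_snps = sum(is_snp & v$context == "coding", na.rm = TRUE),
    noncoding_snps = sum(is_snp & v$context %in% c("intron", "IGS"),
                         na.rm = TRUE),
    longest_indel = if (any(v$kind == "indel"))
      max(v$length[v$kind == "indel"]) else 0L
  )
}

#' @export
print.cp_variant_set <- function(x, ...) {
  t <- x$totals
  cat("cp_variant_set: ", t$n_variants, " variants (", t$snps, " SNPs, ",
      t$indels, " indels, ", t$inversions, " inversions); Tn ",
      t$transitions, " / Tv ", t$transversions, "\n", sep = "")
  invisible(x)
}

#' Synonymous or nonsynonymous effect of a coding SNP
#'
#' Reconstructs the reference codon of the gene containing `position`
#' (splicing the gene's exons in order, strand- and phase-aware), substitutes
#' the single alternate base, and compares the encoded amino acids under the
#' standard genetic code. All other positions are held at reference state, so
#' each SNP in a multiply-hit codon is evaluated independently. Stop gain or
#' loss counts as nonsynonymous.
#'
#' @param p A [plastome()].
#' @param position Reference position of the SNP (must lie in a `gene_exon`).
#' @param alt_base Alternate base on the reference (plus) strand.
#' @param gene Optional gene symbol (skips the containing-feature lookup).
#' @param cds_cache Internal environment for memoized spliced gene models.
#' @return `"synonymous"`, `"nonsynonymous"`, or `"unresolved"` when the codon
#'   is incomplete at a feature edge.
#' @export
classify_coding_effect <- function(p, position, alt_base, gene = NULL,
                                   cds_cache = NULL) {
  stopifnot(inherits(p, "cp_plastome"))
  position <- as.integer(position)
  alt_base <- toupper(alt_base)
  ft <- p$features
  ex_all <- ft[ft$kind == "gene_exon", , drop = FALSE]
  if (is.null(gene) || is.na(gene)) {
    hit <- ex_all$start <= position & ex_all$end >= position
    if (!any(hit)) stop("position ", position, " is not in any gene_exon")
    gene <- ex_all$name[which(hit)[1L]]
  }
  mdl <- NULL
  if (!is.null(cds_cache) && !is.null(cds_cache[[gene]]))
    mdl <- cds_cache[[gene]]
  if (is.null(mdl)) {
    ex <- ex_all[ex_all$name == gene, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    gpos <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE),
                   use.names = FALSE)
    strand <- ex$strand[1L]
    if (strand == "-") gpos <- rev(gpos)
    phase <- if (strand == "+") ex$phase[1L] else ex$phase[nrow(ex)]
    chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]][gpos]
    if (strand == "-") chars <- unname(COMPLEMENT[chars])
    mdl <- list(gpos = gpos, chars = chars, strand = strand,
                phase = as.integer(phase))
    if (!is.null(cds_cache)) cds_cache[[gene]] <- mdl
  }
  i <- match(position, mdl$gpos)
  if (is.na(i)) stop("position ", position, " is not in an exon of ", gene)
  # frame: first phase bases are a codon remainder, codons start at phase + 1
  off <- i - mdl$phase - 1L
  if (off < 0L) return("unresolved")
  c0 <- mdl$phase + (off %/% 3L) * 3L + 1L
  if (c0 + 2L > length(mdl$chars)) return("unresolved")
  cod_ref <- mdl$chars[c0:(c0 + 2L)]
  if (any(cod_ref == "N")) return("unresolved")
  cod_alt <- cod_ref
  sub_base <- if (mdl$strand == "-") unname(COMPLEMENT[alt_base]) else alt_base
  cod_alt[i - c0 + 1L] <- sub_base
  gc <- Biostrings::GENETIC_CODE
  aa_ref <- gc[[paste(cod_ref, collapse = "")]]
  aa_alt <- gc[[paste(cod_alt, collapse = "")]]
  if (identical(aa_ref, aa_alt)) "synonymous" else "nonsynonymous"
}

#' Per-gene summary of differences (counts by kind and class)
#'
#' One row per gene with at least one variant (a variant is charged to the
#' gene whose exon or intron contains it, intergenic variants to
#' `"noncoding"`), plus subtotal rows for coding and noncoding and a grand
#' total. Columns mirror the conventional plastome-comparison summary:
#' `indel`, `inversion`, `tn`, `tv`, `nonsyn`, `total`.
#'
#' @param vs A classified `cp_variant_set` (from [scan_variants()] with a
#'   plastome).
#' @param plastome The [plastome()] used for classification (kept for
#'   interface symmetry; classification is read from `vs`).
#' @return `data.frame` with columns `gene`, `indel`, `inversion`, `tn`, `tv`,
#'   `nonsyn`, `total`.
#' @export
summarize_by_feature <- function(vs, plastome = NULL) {
  stopifnot(inherits(vs, "cp_variant_set"))
  v <- vs$variants
  zero_row <- function(gene) data.frame(gene = gene, indel = 0L,
                                        inversion = 0L, tn = 0L, tv = 0L,
                                        nonsyn = 0L, total = 0L,
                                        stringsAsFactors = FALSE)
  if (!nrow(v)) {
    out <- rbind(zero_row("Subtotal coding"), zero_row("Subtotal noncoding"),
                 zero_row("Total"))
    return(out)
  }
  if (all(is.na(v$context)))
    stop("variant set is unclassified; rerun scan_variants() with a plastome")
  charge <- ifelse(v$context %in% c("coding", "intron") & !is.na(v$feature),
                   v$feature, "noncoding")
  tally <- function(idx) {
    vv <- v[idx, , drop = FALSE]
    data.frame(indel = sum(vv$kind == "indel"),
               inversion = sum(vv$kind == "inversion"),
               tn = sum(vv$change == "transition", na.rm = TRUE),
               tv = sum(vv$change == "transversion", na.rm = TRUE),
               nonsyn = sum(vv$effect == "nonsynonymous", na.rm = TRUE),
               total = length(idx))
  }
  genes <- sort(unique(charge[charge != "noncoding"]))
  rows <- lapply(genes, function(g) cbind(gene = g, tally(which(charge == g))))
  coding_idx <- which(charge != "noncoding")
  noncod_idx <- which(charge == "noncoding")
  rows[[length(rows) + 1L]] <- cbind(gene = "Subtotal coding",
                                     tally(coding_idx))
  rows[[length(rows) + 1L]] <- cbind(gene = "Subtotal noncoding",
                                     tally(noncod_idx))
  rows[[length(rows) + 1L]] <- cbind(gene = "Total", tally(seq_len(nrow(v))))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a variant table as TSV
#' @param vs A `cp_variant_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(vs, path) {
  stopifnot(inherits(vs, "cp_variant_set"))
  utils::write.table(vs$variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
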