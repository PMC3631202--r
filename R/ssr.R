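#' Find mono- and dinucleotide tandem tracts in a sequence
#'
#' Maximal perfect tracts only. A mononucleotide tract is a run of one base
#' repeated at least `min_mono` times. A dinucleotide tract is treated
#' phase-free: a maximal run of two distinct alternating bases (so TA/AT
#' phasing is irrelevant), with repeat count `floor(run_length / 2)`, reported
#' when the count reaches `min_di`. A tract reported under unit 2 is not also
#' reported as its unit-1 sub-tracts.
#'
#' @param sequence Nucleotide string.
#' @param min_mono Minimum repeat count for mononucleotide tracts (>= 2).
#' @param min_di Minimum repeat count for dinucleotide tracts (>= 2).
#' @return `data.frame` with columns `motif` (unit as observed at tract
#'   start), `unit` (1 or 2), `count`, `start`, `end` (1-based, inclusive).
#' @examples
#' find_ssr_tracts("GAAAAAC", min_mono = 5)   # (A)5 at 2..6
#' find_ssr_tracts("GTATATATAC", min_di = 4)  # (TA)4 at 2..9
#' @export
find_ssr_tracts <- function(sequence, min_mono = 5L, min_di = 5L) {
  stopifnot(min_mono >= 2L, min_di >= 2L)
  s <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(s)
  empty <- data.frame(motif = character(), unit = integer(),
                      count = integer(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  out <- list()

  ## dinucleotide (phase-free alternating runs)
  di_span <- matrix(integer(), ncol = 2L)
  if (n >= 4L) {
    ok <- s[seq_len(n - 2L)] == s[3:n] &
      s[seq_len(n - 2L)] != s[2:(n - 1L)] &
      s[seq_len(n - 2L)] %in% c("A", "C", "G", "T") &
      s[2:(n - 1L)] %in% c("A", "C", "G", "T")
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values)) {
      st <- starts[i]; en <- ends[i] + 2L       # alternating span
      len <- en - st + 1L
      count <- len %/% 2L
      if (count >= min_di) {
        out[[length(out) + 1L]] <- data.frame(
          motif = paste0(s[st], s[st + 1L]), unit = 2L, count = count,
          start = st, end = st + 2L * count - 1L, stringsAsFactors = FALSE)
        di_span <- rbind(di_span, c(st, en))
      }
    }
  }

  ## mononucleotide
  runs <- rle(s)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (i in which(runs$lengths >= min_mono &
                  runs$values %in% c("A", "C", "G", "T"))) {
    st <- starts[i]; en <- ends[i]
    inside_di <- nrow(di_span) > 0L &&
      any(st >= di_span[, 1L] & en <= di_span[, 2L])
    if (inside_di) next
    out[[length(out) + 1L]] <- data.frame(
      motif = runs$values[i], unit = 1L, count = runs$lengths[i],
      start = st, end = en, stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Length-polymorphic cpSSR loci between the two genomes
#'
#' For each indel in the variant set, tests whether the longer allele's local
#' context forms a perfect mono- or dinucleotide tract meeting the thresholds
#' and whether the indel changes that tract's repeat count (indel length a
#' whole number of repeat units). One locus is emitted per qualifying indel,
#' with both genomes' repeat counts and reference-genome coordinates spanning
#' the union of the two alleles' tracts.
#'
#' @param pair The [aligned_pair()] (row 1 = reference genome).
#' @param variants A `cp_variant_set` from [scan_variants()].
#' @param plastome The reference [plastome()] (for location context).
#' @param min_mono,min_di Repeat-count thresholds applied to the longer
#'   allele (defaults 5 and 5).
#' @return `data.frame` with one row per locus: `context`, `feature`,
#'   `motif`, `unit`, `count_ref`, `count_alt`, `tract_ref`, `tract_alt`
#'   (tract lengths in bp), `ref_start`, `ref_end`, `indel_ref_pos`.
#' @export
polymorphic_ssrs <- function(pair, variants, plastome = NULL,
                             min_mono = 5L, min_di = 5L) {
  stopifnot(inherits(pair, "aligned_pair"), inherits(variants, "cp_variant_set"))
  v <- variants$variants
  idl <- v[v$kind == "indel", , drop = FALSE]
  empty <- data.frame(context = character(), feature = character(),
                      motif = character(), unit = integer(),
                      count_ref = integer(), count_alt = integer(),
                      tract_ref = integer(), tract_alt = integer(),
                      ref_start = integer(), ref_end = integer(),
                      indel_ref_pos = integer(), stringsAsFactors = FALSE)
  if (!nrow(idl)) return(empty)
  ref_seq <- ungapped_seq(pair, 1L)
  alt_seq <- ungapped_seq(pair, 2L)
  out <- list()
  for (i in seq_len(nrow(idl))) {
    len <- idl$length[i]
    deletion <- idl$alt_allele[i] == ""      # reference carries the segment
    long_seq <- if (deletion) ref_seq else alt_seq
    seg_start <- if (deletion) idl$ref_pos[i] else idl$alt_pos[i]
    win_lo <- max(1L, seg_start - 40L)
    win_hi <- min(nchar(long_seq), seg_start + len - 1L + 40L)
    tracts <- find_ssr_tracts(substr(long_seq, win_lo, win_hi),
                              min_mono = min_mono, min_di = min_di)
    if (!nrow(tracts)) next
    tracts$start <- tracts$start + win_lo - 1L
    tracts$end <- tracts$end + win_lo - 1L
    # tract must contain the indel segment (the expanded allele's extra
    # copies lie within the tract)
    hit <- tracts$start <= seg_start & tracts$end >= seg_start + len - 1L
    if (!any(hit)) next
    tr <- tracts[which(hit)[1L], ]
    if (len %% tr$unit != 0L) next
    c_long <- tr$count
    c_short <- c_long - len %/% tr$unit
    if (c_short == c_long) next
    count_ref <- if (deletion) c_long else c_short
    count_alt <- if (deletion) c_short else c_long
    # reference coordinates of the union tract (longer-allele extent,
    # anchored at the reference tract start)
    if (deletion) {
      ref_start <- tr$start
    } else {
      # locate the reference tract via the indel's 5' flank
      flank <- idl$ref_pos[i]                 # last ref base before gap
      rt <- find_ssr_tracts(substr(ref_seq, max(1L, flank - 40L),
                                   min(nchar(ref_seq), flank + 41L)),
                            min_mono = 2L, min_di = 2L)
      ref_start <- flank + 1L
      if (nrow(rt)) {
        rt$start <- rt$start + max(1L, flank - 40L) - 1L
        rt$end <- rt$end + max(1L, flank - 40L) - 1L
        cand <- rt[rt$motif == tr$motif | (tr$unit == 2L & rt$unit == 2L &
                     sort_motif(rt$motif) == sort_motif(tr$motif)), ,
                   drop = FALSE]
        cand <- cand[cand$start <= flank + 1L & cand$end >= flank, ,
                     drop = FALSE]
        if (nrow(cand)) ref_start <- cand$start[1L]
      }
    }
    ref_end <- ref_start + tr$unit * max(count_ref, count_alt) - 1L
    ctx <- "IGS"; feat <- NA_character_
    if (!is.null(plastome)) {
      cx <- context_of(plastome, min(ref_start, plastome$length))
      ctx <- cx$context; feat <- cx$feature
    }
    out[[length(out) + 1L]] <- data.frame(
      context = ctx, feature = feat, motif = tr$motif, unit = tr$unit,
      count_ref = count_ref, count_alt = count_alt,
      tract_ref = tr$unit * count_ref, tract_alt = tr$unit * count_alt,
      ref_start = ref_start, ref_end = ref_end,
      indel_ref_pos = idl$ref_pos[i], stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$ref_start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

sort_motif <- function(m) vapply(strsplit(m, "", fixed = TRUE),
                                 function(x) paste(sort(x), collapse = ""), "")

#' Motif tally and mean tract lengths of a set of polymorphic SSR loci
#'
#' Mean tract lengths are pooled over both genomes' alleles (both allele
#' lengths of every locus enter the mean).
#'
#' @param loci `data.frame` as returned by [polymorphic_ssrs()] (columns
#'   `motif`, `unit`, `count_ref`, `count_alt` required; tract lengths are
#'   recomputed as `unit * count`).
#' @return List with `n_loci`, `n_mono`, `n_di`, `mono_motif_tally` (named
#'   integer vector over A/C/G/T), `mean_mono_bp`, `mean_di_bp`, `empty`.
#' @export
ssr_summary <- function(loci) {
  if (is.null(loci) || !nrow(loci)) {
    return(list(n_loci = 0L, n_mono = 0L, n_di = 0L,
                mono_motif_tally = c(A = 0L, C = 0L, G = 0L, T = 0L),
                mean_mono_bp = 0, mean_di_bp = 0, empty = TRUE))
  }
  mono <- loci[loci$unit == 1L, , drop = FALSE]
  di <- loci[loci$unit == 2L, , drop = FALSE]
  tally <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  if (nrow(mono)) {
    tb <- table(mono$motif)
    tally[names(tb)] <- as.integer(tb)
  }
  pool <- function(d) if (!nrow(d)) 0 else
    mean(c(d$unit * d$count_ref, d$unit * d$count_alt))
  list(n_loci = nrow(loci), n_mono = nrow(mono), n_di = nrow(di),
       mono_motif_tally = tally,
       mean_mono_bp = pool(mono), mean_di_bp = pool(di), empty = FALSE)
}

#' Read a polymorphic-SSR locus table (published-table format)
#'
#' Loads a TSV with columns `context`, `motif`, `unit`, `usa_count`,
#' `fin_count`, `start`, `end` into the [polymorphic_ssrs()] column layout
#' (FIN is the reference genome).
#'
#' @param path TSV path.
#' @return `data.frame` in the [polymorphic_ssrs()] layout.
#' @export
read_ssr_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(context = tab$context, feature = NA_character_,
             motif = tab$motif, unit = as.integer(tab$unit),
             count_ref = as.integer(tab$fin_count),
             count_alt = as.integer(tab$usa_count),
             tract_ref = as.integer(tab$unit * tab$fin_count),
             tract_alt = as.integer(tab$unit * tab$usa_count),
             ref_start = as.integer(tab$start), ref_end = as.integer(tab$end),
             indel_ref_pos = NA_integer_, stringsAsFactors = FALSE)
}
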