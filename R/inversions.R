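#' Detect minute inversions between the two aligned genomes
#'
#' A minute inversion shows up in a pairwise alignment as a short block where
#' one genome carries the reverse complement of the other. Candidates are the
#' maximal runs of at least two consecutive gap-free mismatch columns whose
#' block in row 2 equals the reverse complement of the block in row 1.
#' A block whose row-2 allele equals the plain base-order reversal of the
#' row-1 allele is also reported (flagged `potential`): for a
#' self-reverse-complementary segment a true inversion is invisible in the
#' alignment, and reversed-order blocks such as CG/GC are the classic
#' "potential inversion" signature of such sites. Detected blocks are the
#' mask input to [scan_variants()], so their internal mismatches are never
#' double-counted as SNPs.
#'
#' @param pair An [aligned_pair()].
#' @param max_loop Maximum block length considered (default 30 bp).
#' @return List of candidates, each a list with `col_start`, `col_end`,
#'   `ref_start` (reference coordinate), `alleles` (oriented block sequences),
#'   `loop_bp`, `potential` (logical: reversal-only match), `hairpin`
#'   (`NULL` until [hairpin_test()] is run).
#' @export
detect_minute_inversions <- function(pair, max_loop = 30L) {
  stopifnot(inherits(pair, "aligned_pair"), max_loop >= 2L)
  m <- pair$mat
  mism <- m[1L, ] != m[2L, ] & m[1L, ] != "-" & m[2L, ] != "-" &
    m[1L, ] != "N" & m[2L, ] != "N"
  if (!any(mism)) return(list())
  runs <- rle(mism)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (i in which(runs$values & runs$lengths >= 2L &
                  runs$lengths <= max_loop)) {
    s <- starts[i]; e <- ends[i]
    a1 <- m[1L, s:e]
    a2 <- m[2L, s:e]
    is_rc <- identical(a2, revcomp_chars(a1))
    is_rev <- identical(a2, rev(a1))
    if (is_rc || is_rev) {
      out[[length(out) + 1L]] <- list(
        col_start = s, col_end = e,
        ref_start = pair$col_to_pos[[1L]][s],
        alleles = c(paste(a1, collapse = ""), paste(a2, collapse = "")),
        loop_bp = e - s + 1L,
        potential = !is_rc,
        hairpin = NULL)
    }
  }
  out
}

#' Alignment columns covered by inversion candidates
#' @param inversions Result of [detect_minute_inversions()].
#' @return Integer vector of masked columns.
#' @export
inversion_columns <- function(inversions) {
  if (!length(inversions)) return(integer())
  unlist(lapply(inversions, function(iv) iv$col_start:iv$col_end))
}

#' Test whether a minute inversion sits in a hairpin
#'
#' Extends outward symmetrically from the inverted block on the designated
#' genome while the 5' flank base is the Watson-Crick complement of the
#' matching 3' flank base; the extension length is the stem. A hairpin is
#' returned when the stem reaches `min_stem` (default 4 bp), otherwise
#' `NULL` ("does not form a hairpin"). Stems are measured on both genomes
#' and reported separately when they differ.
#'
#' @param candidate One element of [detect_minute_inversions()] output.
#' @param pair The [aligned_pair()] the candidate came from.
#' @param max_stem_search Maximum stem length searched (default 25 bp).
#' @param min_stem Minimum stem length to call a hairpin (default 4 bp).
#' @return A list with `stem_bp`, `loop_bp`, `loop_seqs`, `stem_bp_other`
#'   (other genome's stem, when different), `truncated` (search hit the
#'   alignment edge), or `NULL` when `stem_bp < min_stem`.
#' @export
hairpin_test <- function(candidate, pair, max_stem_search = 25L,
                         min_stem = 4L) {
  stopifnot(inherits(pair, "aligned_pair"), max_stem_search >= 1L,
            min_stem >= 1L)
  s1 <- stem_length(pair$mat[1L, ], candidate$col_start, candidate$col_end,
                    max_stem_search)
  s2 <- stem_length(pair$mat[2L, ], candidate$col_start, candidate$col_end,
                    max_stem_search)
  if (s1$len < min_stem) return(NULL)
  list(stem_bp = s1$len, loop_bp = candidate$loop_bp,
       loop_seqs = candidate$alleles,
       stem_bp_other = if (s2$len != s1$len) s2$len else NULL,
       truncated = s1$trunc)
}

# perfect complementary extension outward from block [s, e] on one gapped row
stem_length <- function(chars, s, e, max_stem) {
  n <- length(chars)
  len <- 0L
  trunc <- FALSE
  for (k in seq_len(max_stem)) {
    li <- s - k; ri <- e + k
    if (li < 1L || ri > n) { trunc <- TRUE; break }
    b5 <- chars[li]; b3 <- chars[ri]
    if (b5 == "-" || b3 == "-") break
    if (!b5 %in% c("A", "C", "G", "T") || !b3 %in% c("A", "C", "G", "T")) break
    if (unname(COMPLEMENT[b5]) != b3) break
    len <- k
  }
  list(len = len, trunc = trunc)
}

#' Detect minute inversions and run the hairpin test on each
#'
#' Convenience wrapper: [detect_minute_inversions()] followed by
#' [hairpin_test()] per candidate.
#'
#' @inheritParams detect_minute_inversions
#' @inheritParams hairpin_test
#' @return Candidate list with the `hairpin` slot filled in.
#' @export
find_inversions <- function(pair, max_loop = 30L, max_stem_search = 25L,
                            min_stem = 4L) {
  cands <- detect_minute_inversions(pair, max_loop = max_loop)
  lapply(cands, function(cd) {
    cd$hairpin <- hairpin_test(cd, pair, max_stem_search = max_stem_search,
                               min_stem = min_stem)
    cd
  })
}

#' Inversion candidates as a report table
#' @param inversions Candidate list (ideally from [find_inversions()]).
#' @return `data.frame` with reference coordinates, loop alleles, loop and
#'   stem lengths (`NA` stem means no hairpin).
#' @export
inversions_table <- function(inversions) {
  if (!length(inversions))
    return(data.frame(ref_start = integer(), ref_end = integer(),
                      allele_ref = character(), allele_alt = character(),
                      loop_bp = integer(), stem_bp = integer(),
                      potential = logical(), stringsAsFactors = FALSE))
  do.call(rbind, lapply(inversions, function(iv) {
    data.frame(ref_start = iv$ref_start,
               ref_end = iv$ref_start + iv$loop_bp - 1L,
               allele_ref = iv$alleles[1L], allele_alt = iv$alleles[2L],
               loop_bp = iv$loop_bp,
               stem_bp = if (is.null(iv$hairpin)) NA_integer_ else
                 iv$hairpin$stem_bp,
               potential = iv$potential, stringsAsFactors = FALSE)
  }))
}
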