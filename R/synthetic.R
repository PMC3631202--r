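## Synthetic plastome pairs and haplotype samples with fully known planted
## truth. The generator is the package's study-condition authority: its
## defaults mirror a published intraspecific plastome comparison (112,193 bp
## working sequence, 186 SNPs / 47 indels / 2 inversions, Tn 79 / Tv 107,
## 42 nonsynonymous / 35 synonymous coding SNPs, 28 length-polymorphic cpSSRs,
## a stem-8/loop-3 GTA/TAC hairpin inversion and a CG/GC block with no
## hairpin, longest indels 141/38/23 bp).

# literal 64-entry codon table: the truth-side genetic code, deliberately a
# separate code path from the scanner's Biostrings::GENETIC_CODE
CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

random_dna <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

#' Generate a random annotated plastome
#'
#' Random sequence with non-overlapping single- or two-exon genes (strand
#' alternating, phase 0, introns inserted into a subset), and a single
#' modeled IR interval in an LSC/IR/SSC partition. Deterministic given the
#' seed.
#'
#' @param length Genome length in bp (>= 1000).
#' @param ir_fraction Fraction of the genome in the (single-copy-modeled) IR
#'   interval, in `[0, 1)`.
#' @param gene_density Target fraction of the genome covered by gene exons,
#'   in `[0, 0.85]`.
#' @param seed Integer seed.
#' @param name Genome label.
#' @return A [plastome()].
#' @export
generate_plastome <- function(length, ir_fraction = 0.24,
                              gene_density = 0.5, seed = 1L,
                              name = "synth") {
  stopifnot(length >= 1000L, ir_fraction >= 0, ir_fraction < 1)
  if (gene_density < 0 || gene_density > 0.85)
    stop("infeasible gene_density ", gene_density, " (must be in [0, 0.85])")
  set.seed(seed)
  length <- as.integer(length)
  seq_chars <- random_dna(length)
  ir_len <- as.integer(round(length * ir_fraction))
  lsc_len <- as.integer(round((length - ir_len) * 0.6))
  ssc_len <- length - ir_len - lsc_len
  part <- if (ir_len > 0L) {
    data.frame(region = c("LSC", "IR", "SSC"),
               start = c(1L, lsc_len + 1L, lsc_len + ir_len + 1L),
               end = c(lsc_len, lsc_len + ir_len, length),
               stringsAsFactors = FALSE)
  } else NULL
  feats <- NULL
  if (gene_density > 0) {
    target <- gene_density * length
    rows <- list()
    pos <- 101L
    exon_total <- 0L
    gi <- 0L
    bounds <- if (!is.null(part)) part$end[-nrow(part)] else integer()
    while (exon_total < target && pos < length - 1600L) {
      glen <- 3L * sample(120:400, 1L)
      # keep genes inside one partition region
      crossing <- bounds[pos <= bounds & pos + glen - 1L > bounds]
      if (length(crossing)) { pos <- crossing[1L] + 51L; next }
      gi <- gi + 1L
      strand <- if (gi %% 2L) "+" else "-"
      nm <- sprintf("g%03d", gi)
      if (stats::runif(1) < 0.2 && glen >= 600L) {
        half <- 3L * (glen %/% 6L)
        intron_len <- sample(120:260, 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "gene_exon", start = pos,
          end = pos + half - 1L, strand = strand, phase = 0L,
          stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "intron", start = pos + half,
          end = pos + half + intron_len - 1L, strand = strand,
          phase = NA_integer_, stringsAsFactors = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "gene_exon", start = pos + half + intron_len,
          end = pos + glen + intron_len - 1L, strand = strand, phase = 0L,
          stringsAsFactors = FALSE)
        exon_total <- exon_total + glen
        pos <- pos + glen + intron_len + sample(120:400, 1L)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          name = nm, kind = "gene_exon", start = pos, end = pos + glen - 1L,
          strand = strand, phase = 0L, stringsAsFactors = FALSE)
        exon_total <- exon_total + glen
        pos <- pos + glen + sample(120:400, 1L)
      }
    }
    feats <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  plastome(name, paste(seq_chars, collapse = ""), features = feats,
           partition = part)
}

#' Specification of mutations to plant between a plastome pair
#'
#' Either give plain counts (classes are then drawn at random) or explicit
#' per-event target tables for exact class compositions.
#'
#' @param n_snps Number of SNPs (ignored when `snp_targets` given).
#' @param tn_fraction Probability that a random SNP is a transition.
#' @param snp_targets Optional `data.frame` with one row per SNP and columns
#'   `region` (`"SC"`, `"IR"` or `NA` = any), `context` (`"coding"`,
#'   `"noncoding"` or `NA`), `change` (`"transition"`, `"transversion"` or
#'   `NA`), `effect` (`"synonymous"`, `"nonsynonymous"` or `NA`; coding only).
#' @param n_indels Number of non-SSR indels (ignored when `indel_targets`
#'   given).
#' @param indel_lengths Length pool for random indels (default 1:10 bp).
#' @param indel_targets Optional `data.frame` with columns `length`,
#'   `context` (`"coding"`, `"intron"`, `"IGS"` or `NA`), `direction`
#'   (`"del"` = reference keeps the segment, `"ins"` = other genome gains
#'   it, or `NA`).
#' @param ssr_loci Optional `data.frame` of SSR polymorphisms to plant:
#'   columns `motif` (1 or 2 distinct bases), `count_ref`, `count_alt`.
#' @param inversions Optional `data.frame` with columns `loop_seq`,
#'   `stem_bp`, `type` (`"revcomp"` or `"reverse"`), `context` (`"coding"`
#'   or `"IGS"`, optional).
#' @param seed Integer seed.
#' @return A `cp_mutation_spec` list.
#' @export
mutation_spec <- function(n_snps = 0L, tn_fraction = 0.5, snp_targets = NULL,
                          n_indels = 0L, indel_lengths = 1:10,
                          indel_targets = NULL, ssr_loci = NULL,
                          inversions = NULL, seed = 1L) {
  stopifnot(tn_fraction >= 0, tn_fraction <= 1, n_snps >= 0L, n_indels >= 0L)
  structure(list(n_snps = as.integer(n_snps), tn_fraction = tn_fraction,
                 snp_targets = snp_targets, n_indels = as.integer(n_indels),
                 indel_lengths = indel_lengths, indel_targets = indel_targets,
                 ssr_loci = ssr_loci, inversions = inversions,
                 seed = as.integer(seed)),
            class = "cp_mutation_spec")
}

# truth-side coding effect: literal codon table + its own splicing
truth_effect <- function(chars, features, gene, position, alt_base) {
  ex <- features[features$kind == "gene_exon" & features$name == gene, ,
                 drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  gpos <- unlist(mapply(seq, ex$start, ex$end, SIMPLIFY = FALSE),
                 use.names = FALSE)
  strand <- ex$strand[1L]
  phase <- if (strand == "+") ex$phase[1L] else ex$phase[nrow(ex)]
  if (strand == "-") gpos <- rev(gpos)
  cds <- chars[gpos]
  if (strand == "-") cds <- unname(COMPLEMENT[cds])
  i <- match(position, gpos)
  if (is.na(i)) return(NA_character_)
  off <- i - phase - 1L
  if (off < 0L) return("unresolved")
  c0 <- phase + (off %/% 3L) * 3L + 1L
  if (c0 + 2L > length(cds)) return("unresolved")
  ref_cod <- paste(cds[c0:(c0 + 2L)], collapse = "")
  cds[i - c0 + 1L + (c0 - 1L)] <- if (strand == "-")
    unname(COMPLEMENT[alt_base]) else alt_base
  alt_cod <- paste(cds[c0:(c0 + 2L)], collapse = "")
  if (CODON_TABLE[[ref_cod]] == CODON_TABLE[[alt_cod]])
    "synonymous" else "nonsynonymous"
}

#' Plant a known mutation set into a plastome, yielding the true alignment
#'
#' Produces a mutated copy of the genome together with the TRUE pairwise
#' alignment (gap columns exactly at planted indels, inversion blocks
#' substituted in place) and a truth table recording every event with its
#' expected coordinates, alleles and classification. Planted events never
#' overlap and never touch feature or partition boundaries. SSR loci and
#' hairpin stems are written into the base sequence first, so the returned
#' (possibly locally rewritten) reference plastome is the coordinate
#' authority for the pair. Deterministic given `spec$seed`.
#'
#' @param p A [plastome()] (the reference / row-1 genome).
#' @param spec A [mutation_spec()].
#' @param alt_name Label for the mutated genome (default `"ALT"`).
#' @return List with `pair` ([aligned_pair()]), `truth` (`data.frame`),
#'   `plastome` (reference with any local rewrites applied), `spec`.
#' @export
plant_mutations <- function(p, spec, alt_name = "ALT") {
  stopifnot(inherits(p, "cp_plastome"), inherits(spec, "cp_mutation_spec"))
  set.seed(spec$seed)
  L <- p$length
  chars <- strsplit(p$sequence, "", fixed = TRUE)[[1L]]
  ft <- p$features

  ## per-position context and region
  ctx <- rep("IGS", L)
  gene_at <- rep(NA_character_, L)
  if (nrow(ft)) for (i in seq_len(nrow(ft))) {
    span <- ft$start[i]:ft$end[i]
    ctx[span] <- if (ft$kind[i] == "gene_exon") "coding" else
      if (ft$kind[i] == "intron") "intron" else "IGS"
    if (ft$kind[i] != "IGS") gene_at[span] <- ft$name[i]
  }
  reg <- p$partition$region[findInterval(seq_len(L), p$partition$start)]

  ## reservation mask: feature + partition boundaries and genome ends
  used <- rep(FALSE, L)
  used[c(1:30, (L - 30L):L)] <- TRUE
  bump <- function(x) pmin(pmax(x, 1L), L)
  if (nrow(ft)) for (b in c(ft$start, ft$end))
    used[bump((b - 3L):(b + 3L))] <- TRUE
  for (b in c(p$partition$start, p$partition$end))
    used[bump((b - 3L):(b + 3L))] <- TRUE

  free_window <- function(lo, hi) lo >= 1L && hi <= L && !any(used[lo:hi])
  reserve <- function(lo, hi) used[bump(lo):bump(hi)] <<- TRUE

  events <- list()
  push <- function(ev) events[[length(events) + 1L]] <<- ev

  ## ---- SSR loci (rewrite base tract, plant count difference) ----
  ssr <- spec$ssr_loci
  if (!is.null(ssr) && nrow(ssr)) {
    igs_lsc <- which(ctx == "IGS" & reg == "LSC" & !used)
    for (k in seq_len(nrow(ssr))) {
      motif <- strsplit(toupper(ssr$motif[k]), "", fixed = TRUE)[[1L]]
      unit <- length(motif)
      stopifnot(unit %in% 1:2)
      c_ref <- as.integer(ssr$count_ref[k])
      c_alt <- as.integer(ssr$count_alt[k])
      stopifnot(c_ref != c_alt, c_ref >= 1L, c_alt >= 1L)
      w_ref <- unit * c_ref
      w_max <- unit * max(c_ref, c_alt)
      others <- setdiff(c("A", "C", "G", "T"), motif)
      placed <- FALSE
      for (try in 1:200) {
        pos <- sample(igs_lsc, 1L)
        if (!free_window(pos - 8L, pos + w_max + 8L)) next
        if (!all(ctx[(pos - 8L):(pos + w_max + 8L)] == "IGS") ||
            !all(reg[(pos - 8L):(pos + w_max + 8L)] == "LSC")) next
        # write tract + breakers
        chars[pos:(pos + w_ref - 1L)] <- rep(motif, length.out = w_ref)
        chars[pos - 1L] <- others[1L]
        chars[pos - 2L] <- others[length(others)]
        chars[pos + w_ref] <- others[length(others)]
        chars[pos + w_ref + 1L] <- others[1L]
        # verify exactly the intended tract is present locally
        win <- paste(chars[(pos - 8L):(pos + w_ref + 8L)], collapse = "")
        tr <- find_ssr_tracts(win, min_mono = 3L, min_di = 3L)
        tr <- tr[tr$start + pos - 9L == pos, , drop = FALSE]
        if (!nrow(tr) || tr$count[1L] != c_ref || tr$unit[1L] != unit) next
        d_units <- abs(c_ref - c_alt)
        if (c_alt < c_ref) {
          push(list(kind = "indel", ssr = TRUE, direction = "del",
                    pos = pos + w_ref - d_units * unit,
                    len = d_units * unit,
                    motif = paste(motif, collapse = ""), unit = unit,
                    count_ref = c_ref, count_alt = c_alt,
                    ssr_start = pos,
                    ssr_end = pos + w_max - 1L))
        } else {
          push(list(kind = "indel", ssr = TRUE, direction = "ins",
                    flank = pos + w_ref - 1L,
                    seg = paste(rep(motif, length.out = d_units * unit),
                                collapse = ""),
                    len = d_units * unit,
                    motif = paste(motif, collapse = ""), unit = unit,
                    count_ref = c_ref, count_alt = c_alt,
                    ssr_start = pos,
                    ssr_end = pos + w_max - 1L))
        }
        reserve(pos - 8L, pos + w_max + 8L)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place SSR locus ", k,
                        " after bounded retries")
    }
  }

  ## ---- minute inversions (rewrite stems into base) ----
  inv <- spec$inversions
  if (!is.null(inv) && nrow(inv)) {
    for (k in seq_len(nrow(inv))) {
      loop <- strsplit(toupper(inv$loop_seq[k]), "", fixed = TRUE)[[1L]]
      kl <- length(loop)
      stopifnot(kl >= 2L)
      type <- inv$type[k]
      alt_loop <- if (type == "revcomp") revcomp_chars(loop) else rev(loop)
      if (any(alt_loop == loop))
        stop("inversion loop ", inv$loop_seq[k],
             " does not mismatch at every position")
      stem <- as.integer(inv$stem_bp[k])
      want_ctx <- if (!is.null(inv$context)) inv$context[k] else "IGS"
      if (is.na(want_ctx)) want_ctx <- "IGS"
      pool <- which(ctx == want_ctx & !used)
      placed <- FALSE
      for (try in 1:500) {
        pos <- sample(pool, 1L)          # loop start
        lo <- pos - stem - 2L
        hi <- pos + kl - 1L + stem + 2L
        if (!free_window(lo, hi)) next
        if (!all(ctx[lo:hi] == want_ctx)) next
        chars[pos:(pos + kl - 1L)] <- loop
        if (stem > 0L) for (j in seq_len(stem)) {
          b <- sample(c("A", "C", "G", "T"), 1L)
          chars[pos - j] <- b
          chars[pos + kl - 1L + j] <- unname(COMPLEMENT[b])
        }
        # terminate the stem exactly: next outward pair must not be
        # complementary (A opposite A)
        chars[pos - stem - 1L] <- "A"
        chars[pos + kl + stem] <- "A"
        push(list(kind = "inversion", pos = pos, len = kl,
                  ref_allele = paste(loop, collapse = ""),
                  alt_allele = paste(alt_loop, collapse = ""),
                  stem_bp = stem, type = type))
        reserve(lo, hi)
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place inversion ", k,
                        " after bounded retries")
    }
  }

  ## ---- non-SSR indels ----
  itg <- spec$indel_targets
  if (is.null(itg) && spec$n_indels > 0L) {
    itg <- data.frame(length = sample(spec$indel_lengths, spec$n_indels,
                                      replace = TRUE),
                      context = NA_character_, direction = NA_character_,
                      stringsAsFactors = FALSE)
  }
  # mirror of the survey predicate: an indel qualifies as an SSR
  # polymorphism when a thresholded tract in the longer allele contains the
  # whole inserted/deleted segment; plain indels must not do that
  looks_ssr <- function(window, seg_lo, seg_hi) {
    tr <- find_ssr_tracts(window, min_mono = 5L, min_di = 5L)
    nrow(tr) > 0L && any(tr$start <= seg_lo & tr$end >= seg_hi)
  }
  if (!is.null(itg) && nrow(itg)) {
    for (k in seq_len(nrow(itg))) {
      len <- as.integer(itg$length[k])
      want_ctx <- itg$context[k]
      dir <- itg$direction[k]
      if (is.na(dir)) dir <- sample(c("del", "ins"), 1L)
      pool <- if (is.na(want_ctx)) which(!used) else
        which(ctx == want_ctx & !used)
      placed <- FALSE
      for (try in 1:500) {
        pos <- sample(pool, 1L)
        if (dir == "del") {
          if (!free_window(pos - 2L, pos + len + 1L)) next
          if (!is.na(want_ctx) && !all(ctx[pos:(pos + len - 1L)] == want_ctx))
            next
          if (is.na(want_ctx) &&
              length(unique(ctx[(pos - 1L):(pos + len - 1L)])) > 1L) next
          win_lo <- max(1L, pos - 12L)
          win <- paste(chars[win_lo:min(L, pos + len + 11L)], collapse = "")
          rel <- pos - win_lo + 1L
          if (looks_ssr(win, rel, rel + len - 1L)) next
          push(list(kind = "indel", ssr = FALSE, direction = "del",
                    pos = pos, len = len))
          reserve(pos - 2L, pos + len + 1L)
        } else {
          if (!free_window(pos - 2L, pos + 3L)) next
          if (!is.na(want_ctx) && ctx[pos] != want_ctx) next
          seg <- random_dna(len)
          win <- paste(c(chars[max(1L, pos - 12L):pos], seg,
                         chars[(pos + 1L):min(L, pos + 12L)]), collapse = "")
          rel <- pos - max(1L, pos - 12L) + 2L   # first inserted base
          if (looks_ssr(win, rel, rel + len - 1L)) next
          push(list(kind = "indel", ssr = FALSE, direction = "ins",
                    flank = pos, seg = paste(seg, collapse = ""), len = len))
          reserve(pos - 2L, pos + 3L)
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("could not place indel of length ", len,
                        " after bounded retries")
    }
  }

  ## ---- SNPs ----
  stg <- spec$snp_targets
  if (is.null(stg) && spec$n_snps > 0L) {
    stg <- data.frame(region = NA_character_, context = NA_character_,
                      change = ifelse(stats::runif(spec$n_snps) <
                                        spec$tn_fraction,
                                      "transition", "transversion"),
                      effect = NA_character_, stringsAsFactors = FALSE)
  }
  snp_events <- list()
  if (!is.null(stg) && nrow(stg)) {
    na_chr <- function(x) ifelse(is.na(x), "any", x)
    grp_key <- paste(na_chr(stg$region), na_chr(stg$context))
    for (gk in unique(grp_key)) {
      rows_k <- which(grp_key == gk)
      want_reg <- stg$region[rows_k[1L]]
      want_ctx <- stg$context[rows_k[1L]]
      sel <- !used & chars != "N"
      if (!is.na(want_ctx))
        sel <- sel & (if (want_ctx == "coding") ctx == "coding" else
                        ctx != "coding")
      if (!is.na(want_reg))
        sel <- sel & (if (want_reg == "IR") reg == "IR" else reg != "IR")
      pool <- which(sel)
      if (length(pool) < length(rows_k))
        stop("no free positions for SNP class ", gk)
      pool <- pool[sample.int(length(pool))]    # one shared permutation
      ptr <- 0L
      for (k in rows_k) {
        change <- stg$change[k]
        if (is.na(change))
          change <- if (stats::runif(1) < spec$tn_fraction) "transition"
                    else "transversion"
        effect <- stg$effect[k]
        placed <- FALSE
        while (ptr < length(pool)) {
          ptr <- ptr + 1L
          pos <- pool[ptr]
          if (used[pos]) next
          ref_b <- chars[pos]
          alts <- if (change == "transition") TRANSITION_OF[[ref_b]] else
            setdiff(c("A", "C", "G", "T"), c(ref_b, TRANSITION_OF[[ref_b]]))
          if (length(alts) > 1L) alts <- sample(alts, length(alts))
          for (ab in alts) {
            ev_eff <- if (ctx[pos] == "coding")
              truth_effect(chars, ft, gene_at[pos], pos, ab) else
                "not_applicable"
            if (!is.na(effect) && !identical(ev_eff, effect)) next
            snp_events[[length(snp_events) + 1L]] <- list(
              kind = "SNP", pos = pos, ref_allele = ref_b, alt_allele = ab,
              change = change, effect = ev_eff)
            reserve(pos - 1L, pos + 1L)
            placed <- TRUE
            break
          }
          if (placed) break
        }
        if (!placed) stop("could not place SNP target ", k,
                          " after exhausting candidate positions")
      }
    }
  }
  events <- c(events, snp_events)

  ## ---- assemble the true alignment ----
  sortkey <- vapply(events, function(e)
    if (!is.null(e$pos)) e$pos else e$flank + 0.5, 1)
  events <- events[order(sortkey)]

  alt_chars <- chars
  for (e in events) {
    if (e$kind == "SNP") alt_chars[e$pos] <- e$alt_allele
    if (e$kind == "inversion")
      alt_chars[e$pos:(e$pos + e$len - 1L)] <-
        strsplit(e$alt_allele, "", fixed = TRUE)[[1L]]
    if (e$kind == "indel" && e$direction == "del")
      alt_chars[e$pos:(e$pos + e$len - 1L)] <- "-"
  }
  ins <- Filter(function(e) e$kind == "indel" && e$direction == "ins", events)
  row1 <- character(0); row2 <- character(0)
  cursor <- 1L
  for (e in ins) {
    row1 <- c(row1, chars[cursor:e$flank], rep("-", e$len))
    row2 <- c(row2, alt_chars[cursor:e$flank],
              strsplit(e$seg, "", fixed = TRUE)[[1L]])
    cursor <- e$flank + 1L
  }
  row1 <- c(row1, chars[cursor:L])
  row2 <- c(row2, alt_chars[cursor:L])
  pair <- aligned_pair(c(p$name, alt_name),
                       c(paste(row1, collapse = ""),
                         paste(row2, collapse = "")))

  ## ---- truth table (scanner-facing coordinates via the pair's maps) ----
  truth <- lapply(events, function(e) {
    if (e$kind == "SNP") {
      col <- to_column(pair, e$pos, 1L)
      data.frame(kind = "SNP", ref_pos = e$pos,
                 alt_pos = pair$col_to_pos[[2L]][col],
                 length = 1L, ref_allele = e$ref_allele,
                 alt_allele = e$alt_allele, change = e$change,
                 effect = e$effect, region = reg[e$pos],
                 context = ctx[e$pos], feature = gene_at[e$pos],
                 ssr = FALSE, motif = NA_character_, unit = NA_integer_,
                 count_ref = NA_integer_, count_alt = NA_integer_,
                 ssr_start = NA_integer_, ssr_end = NA_integer_,
                 stem_bp = NA_integer_, stringsAsFactors = FALSE)
    } else if (e$kind == "inversion") {
      col <- to_column(pair, e$pos, 1L)
      data.frame(kind = "inversion", ref_pos = e$pos,
                 alt_pos = pair$col_to_pos[[2L]][col],
                 length = e$len, ref_allele = e$ref_allele,
                 alt_allele = e$alt_allele, change = NA_character_,
                 effect = NA_character_, region = reg[e$pos],
                 context = ctx[e$pos], feature = gene_at[e$pos],
                 ssr = FALSE, motif = NA_character_, unit = NA_integer_,
                 count_ref = NA_integer_, count_alt = NA_integer_,
                 ssr_start = NA_integer_, ssr_end = NA_integer_,
                 stem_bp = e$stem_bp, stringsAsFactors = FALSE)
    } else if (e$direction == "del") {
      col <- to_column(pair, e$pos, 1L)
      flank_alt <- if (col > 1L) pair$col_to_pos[[2L]][col - 1L] else 0L
      anchor <- e$pos
      data.frame(kind = "indel", ref_pos = e$pos,
                 alt_pos = if (is.na(flank_alt)) 0L else flank_alt,
                 length = e$len,
                 ref_allele = paste(chars[e$pos:(e$pos + e$len - 1L)],
                                    collapse = ""),
                 alt_allele = "", change = NA_character_,
                 effect = NA_character_, region = reg[anchor],
                 context = ctx[anchor], feature = gene_at[anchor],
                 ssr = isTRUE(e$ssr),
                 motif = if (isTRUE(e$ssr)) e$motif else NA_character_,
                 unit = if (isTRUE(e$ssr)) e$unit else NA_integer_,
                 count_ref = if (isTRUE(e$ssr)) e$count_ref else NA_integer_,
                 count_alt = if (isTRUE(e$ssr)) e$count_alt else NA_integer_,
                 ssr_start = if (isTRUE(e$ssr)) e$ssr_start else NA_integer_,
                 ssr_end = if (isTRUE(e$ssr)) e$ssr_end else NA_integer_,
                 stem_bp = NA_integer_, stringsAsFactors = FALSE)
    } else {
      col <- to_column(pair, e$flank, 1L)   # column of the 5' flank
      alt_pos <- pair$col_to_pos[[2L]][col + 1L]
      data.frame(kind = "indel", ref_pos = e$flank, alt_pos = alt_pos,
                 length = e$len, ref_allele = "", alt_allele = e$seg,
                 change = NA_character_, effect = NA_character_,
                 region = reg[e$flank], context = ctx[e$flank],
                 feature = gene_at[e$flank],
                 ssr = isTRUE(e$ssr),
                 motif = if (isTRUE(e$ssr)) e$motif else NA_character_,
                 unit = if (isTRUE(e$ssr)) e$unit else NA_integer_,
                 count_ref = if (isTRUE(e$ssr)) e$count_ref else NA_integer_,
                 count_alt = if (isTRUE(e$ssr)) e$count_alt else NA_integer_,
                 ssr_start = if (isTRUE(e$ssr)) e$ssr_start else NA_integer_,
                 ssr_end = if (isTRUE(e$ssr)) e$ssr_end else NA_integer_,
                 stem_bp = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(), stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth <- truth[order(truth$ref_pos, truth$kind), , drop = FALSE]
    rownames(truth) <- NULL
  }

  p2 <- plastome(p$name, paste(chars, collapse = ""), features = ft,
                 partition = p$partition)
  list(pair = pair, truth = truth, plastome = p2, spec = spec)
}
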