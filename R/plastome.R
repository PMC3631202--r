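#' Annotated plastome: sequence, features and LSC/IR/SSC partition
#'
#' Constructs the coordinate authority used by every downstream report: one
#' plastid genome sequence (a single IR copy is modeled, so the partition is a
#' linear LSC/IR/SSC tiling), an ordered feature list (gene exons, introns,
#' intergenic spacers), and the region partition. All coordinates are 1-based
#' and inclusive.
#'
#' @param name Text label for the genome (e.g. `"FIN"`).
#' @param sequence Nucleotide string over `A,C,G,T,N` (case-insensitive).
#'   `N` positions are legal but uncallable for variant scanning.
#' @param features `data.frame` with columns `name`, `kind` (one of
#'   `gene_exon`, `intron`, `IGS`), `start`, `end`, `strand` (`+`/`-`),
#'   `phase` (0..2, gene exons only). May be `NULL` or empty: every position
#'   is then implicitly intergenic.
#' @param partition `data.frame` with columns `region` (`LSC`, `SSC`, `IR`),
#'   `start`, `end`; intervals must tile `[1, length]` without overlap.
#'   Default: a single LSC interval spanning the genome.
#' @return An object of class `cp_plastome` with elements `name`, `sequence`,
#'   `length`, `features`, `partition`.
#' @examples
#' p <- plastome("toy", "ACGTACGTACGTACGTACGT",
#'               features = data.frame(name = "gA", kind = "gene_exon",
#'                                     start = 4, end = 9, strand = "+",
#'                                     phase = 0))
#' region_of(p, 5)
#' context_of(p, 5)
#' @export
plastome <- function(name, sequence, features = NULL, partition = NULL) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("A", "C", "G", "T", "N"))
  if (length(bad))
    stop("invalid character '", chars[bad[1L]], "' at position ", bad[1L],
         " of sequence '", name, "'")
  len <- length(chars)
  if (len < 1L) stop("empty sequence")

  features <- normalize_features(features, len)
  partition <- normalize_partition(partition, len)

  structure(list(name = name, sequence = sequence, length = len,
                 features = features, partition = partition),
            class = "cp_plastome")
}

normalize_features <- function(features, len) {
  empty <- data.frame(name = character(), kind = character(),
                      start = integer(), end = integer(),
                      strand = character(), phase = integer(),
                      stringsAsFactors = FALSE)
  if (is.null(features) || nrow(features) == 0L) return(empty)
  needed <- c("name", "kind", "start", "end")
  miss <- setdiff(needed, names(features))
  if (length(miss)) stop("feature table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(features$strand)) features$strand <- NA_character_
  if (is.null(features$phase)) features$phase <- NA_integer_
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$phase <- suppressWarnings(as.integer(features$phase))
  if (any(!features$kind %in% c("gene_exon", "intron", "IGS")))
    stop("feature kind must be gene_exon, intron or IGS")
  if (any(features$start > features$end))
    stop("feature with start > end: ",
         features$name[which(features$start > features$end)[1L]])
  if (any(features$start < 1L) || any(features$end > len))
    stop("feature outside [1, ", len, "]")
  cod <- features$kind == "gene_exon"
  if (any(cod & (is.na(features$strand) | !features$strand %in% c("+", "-"))))
    stop("gene_exon features need strand '+' or '-'")
  if (any(cod & (is.na(features$phase) | features$phase < 0L | features$phase > 2L)))
    stop("gene_exon features need phase 0..2")
  features$phase[!cod] <- NA_integer_
  # exons of one gene must not overlap each other
  for (g in unique(features$name[cod])) {
    ex <- features[cod & features$name == g, , drop = FALSE]
    if (nrow(ex) > 1L) {
      ex <- ex[order(ex$start), ]
      if (any(ex$start[-1L] <= ex$end[-nrow(ex)]))
        stop("overlapping exons within gene ", g)
    }
  }
  features[order(features$start, features$end), , drop = FALSE]
}

normalize_partition <- function(partition, len) {
  if (is.null(partition))
    partition <- data.frame(region = "LSC", start = 1L, end = len,
                            stringsAsFactors = FALSE)
  needed <- c("region", "start", "end")
  miss <- setdiff(needed, names(partition))
  if (length(miss)) stop("partition lacks column(s): ",
                         paste(miss, collapse = ", "))
  partition$start <- as.integer(partition$start)
  partition$end <- as.integer(partition$end)
  if (any(!partition$region %in% c("LSC", "SSC", "IR")))
    stop("partition regions must be LSC, SSC or IR")
  partition <- partition[order(partition$start), , drop = FALSE]
  if (partition$start[1L] != 1L || partition$end[nrow(partition)] != len ||
      (nrow(partition) > 1L &&
       any(partition$start[-1L] != partition$end[-nrow(partition)] + 1L)))
    stop("partition intervals must tile [1, ", len, "] without gaps/overlap")
  rownames(partition) <- NULL
  partition
}

#' Read an annotated plastome from FASTA plus a feature table
#'
#' The sequence file must be single-record FASTA. The feature file is either
#' the package's tab-separated feature table (header `name`, `kind`, `start`,
#' `end`, `strand`, `phase`; rows with `kind` in `LSC`/`SSC`/`IR` define the
#' region partition) or a GFF3 file (`.gff`/`.gff3`; gene/exon/intron rows are
#' kept, everything unannotated is implicitly intergenic).
#'
#' @param sequence_path Path to a single-record FASTA file.
#' @param feature_path Path to a feature table TSV or GFF3 file; `NULL` for an
#'   unannotated genome.
#' @return A [plastome()] object.
#' @export
read_plastome <- function(sequence_path, feature_path = NULL) {
  seqs <- Biostrings::readDNAStringSet(sequence_path)
  if (length(seqs) != 1L)
    stop("expected exactly one FASTA record in ", sequence_path,
         ", found ", length(seqs))
  nm <- sub("\\s.*$", "", names(seqs)[1L])
  feats <- NULL
  part <- NULL
  if (!is.null(feature_path)) {
    if (grepl("\\.gff3?$", feature_path, ignore.case = TRUE)) {
      feats <- read_features_gff3(feature_path)
    } else {
      tab <- utils::read.delim(feature_path, stringsAsFactors = FALSE)
      is_part <- tab$kind %in% c("LSC", "SSC", "IR")
      if (any(is_part))
        part <- data.frame(region = tab$kind[is_part],
                           start = tab$start[is_part],
                           end = tab$end[is_part], stringsAsFactors = FALSE)
      feats <- tab[!is_part, , drop = FALSE]
    }
  }
  plastome(nm, as.character(seqs[[1L]]), features = feats, partition = part)
}

#' Write a plastome's feature table (round-trip companion of [read_plastome()])
#'
#' Partition intervals are written as extra rows with `kind` set to the region
#' label, so the written table reloads to an identical annotation.
#'
#' @param p A [plastome()] object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(p, path) {
  stopifnot(inherits(p, "cp_plastome"))
  ft <- p$features
  pt <- data.frame(name = p$partition$region, kind = p$partition$region,
                   start = p$partition$start, end = p$partition$end,
                   strand = NA_character_, phase = NA_integer_,
                   stringsAsFactors = FALSE)
  out <- rbind(ft[, c("name", "kind", "start", "end", "strand", "phase")], pt)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GFF3 convenience reader; keeps gene/exon/intron rows (CDS treated as exon).
read_features_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  keep <- type %in% c("exon", "CDS", "gene", "intron")
  df <- df[keep, , drop = FALSE]
  type <- type[keep]
  nm <- if (!is.null(df$gene)) as.character(df$gene) else
    if (!is.null(df$Name)) as.character(df$Name) else as.character(df$ID)
  kind <- ifelse(type == "intron", "intron", "gene_exon")
  # prefer CDS/exon rows over whole-gene rows when both are present
  has_sub <- nm %in% nm[type %in% c("exon", "CDS")]
  drop_gene <- type == "gene" & has_sub
  phase <- if (!is.null(df$phase)) suppressWarnings(as.integer(as.character(df$phase))) else 0L
  out <- data.frame(name = nm, kind = kind, start = df$start, end = df$end,
                    strand = as.character(df$strand),
                    phase = ifelse(kind == "gene_exon",
                                   ifelse(is.na(phase), 0L, phase), NA_integer_),
                    stringsAsFactors = FALSE)
  out <- out[!drop_gene, , drop = FALSE]
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out
}

#' Region (LSC/SSC/IR) of one or more genome positions
#'
#' @param p A [plastome()] object.
#' @param position Integer vector of 1-based positions.
#' @return Character vector of region labels.
#' @export
region_of <- function(p, position) {
  stopifnot(inherits(p, "cp_plastome"))
  position <- as.integer(position)
  if (any(position < 1L | position > p$length))
    stop("position out of range [1, ", p$length, "]")
  idx <- findInterval(position, p$partition$start)
  p$partition$region[idx]
}

#' Genic context (coding/intron/IGS) of genome positions
#'
#' Positions inside a `gene_exon` feature are `coding`; inside an `intron`
#' feature, `intron`; anything else is intergenic (`IGS`). For intergenic
#' positions the flanking-gene pair (e.g. `"gA-gB"`) is reported as the
#' feature name when derivable.
#'
#' @param p A [plastome()] object.
#' @param position Integer vector of 1-based positions.
#' @return `data.frame` with columns `position`, `context`, `feature`.
#' @export
context_of <- function(p, position) {
  stopifnot(inherits(p, "cp_plastome"))
  position <- as.integer(position)
  if (any(position < 1L | position > p$length))
    stop("position out of range [1, ", p$length, "]")
  ft <- p$features
  ctx <- rep("IGS", length(position))
  feat <- rep(NA_character_, length(position))
  if (nrow(ft)) {
    for (k in c("intron", "gene_exon")) {   # exon wins if both ever overlap
      rows <- ft[ft$kind == k, , drop = FALSE]
      if (!nrow(rows)) next
      for (i in seq_len(nrow(rows))) {
        hit <- position >= rows$start[i] & position <= rows$end[i]
        ctx[hit] <- if (k == "gene_exon") "coding" else "intron"
        feat[hit] <- rows$name[i]
      }
    }
    igs <- ctx == "IGS"
    if (any(igs)) {
      gf <- ft[ft$kind == "gene_exon", , drop = FALSE]
      if (nrow(gf)) {
        # flanking gene pair by nearest exon on each side
        for (j in which(igs)) {
          pos <- position[j]
          left <- gf$name[gf$end < pos]
          right <- gf$name[gf$start > pos]
          lg <- if (length(left)) left[length(left)] else NA_character_
          rg <- if (length(right)) right[1L] else NA_character_
          if (!is.na(lg) && !is.na(rg)) feat[j] <- paste0(lg, "-", rg)
        }
      }
    }
  }
  data.frame(position = position, context = ctx, feature = feat,
             stringsAsFactors = FALSE)
}

#' @export
print.cp_plastome <- function(x, ...) {
  cat("cp_plastome '", x$name, "': ", x$length, " bp, ",
      nrow(x$features), " features, partition ",
      paste(sprintf("%s %d..%d", x$partition$region, x$partition$start,
                    x$partition$end), collapse = " | "), "\n", sep = "")
  invisible(x)
}
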