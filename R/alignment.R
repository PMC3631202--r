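#' Two-sequence alignment with column/residue coordinate maps
#'
#' Container for a pairwise plastome alignment. Rows are gapped sequences of
#' equal column count over `A,C,G,T,N,-`; the constructor validates that no
#' column is gap in both rows and precomputes column-to-residue and
#' residue-to-column maps for both rows. Columns and residue positions are
#' both 1-based.
#'
#' @param names Character vector of two row labels.
#' @param rows Character vector of two gapped sequences (equal nchar).
#' @return An `aligned_pair` object with elements `names`, `rows`,
#'   `mat` (2 x ncol character matrix), `ncol`, `col_to_pos`, `pos_to_col`.
#' @export
aligned_pair <- function(names, rows) {
  stopifnot(length(names) == 2L, length(rows) == 2L)
  rows <- unname(toupper(rows))
  rows <- gsub("[.~]", "-", rows)
  if (nchar(rows[1L]) != nchar(rows[2L]))
    stop("alignment rows have unequal lengths: ", nchar(rows[1L]), " vs ",
         nchar(rows[2L]))
  m <- rbind(strsplit(rows[1L], "", fixed = TRUE)[[1L]],
             strsplit(rows[2L], "", fixed = TRUE)[[1L]])
  bad <- which(!m %in% c("A", "C", "G", "T", "N", "-"))
  if (length(bad))
    stop("invalid alignment character '", m[bad[1L]], "'")
  allgap <- m[1L, ] == "-" & m[2L, ] == "-"
  if (any(allgap))
    stop("column ", which(allgap)[1L], " is gap in both rows")
  col_to_pos <- lapply(1:2, function(i) {
    gap <- m[i, ] == "-"
    p <- cumsum(!gap)
    p[gap] <- NA_integer_
    as.integer(p)
  })
  pos_to_col <- lapply(col_to_pos, function(cp) which(!is.na(cp)))
  structure(list(names = as.character(names), rows = rows, mat = m,
                 ncol = ncol(m), col_to_pos = col_to_pos,
                 pos_to_col = pos_to_col),
            class = "aligned_pair")
}

#' Read a two-sequence alignment from aligned FASTA or NEXUS
#'
#' Accepts aligned FASTA (2 records) or a NEXUS data/characters block
#' (2 taxa, sequential or interleaved). Input is uppercased and the gap
#' symbols `.` and `~` are normalized to `-`.
#'
#' @param path Input file path.
#' @param format `"auto"` (sniff first non-blank character), `"fasta"` or
#'   `"nexus"`.
#' @return An [aligned_pair()].
#' @export
read_pair_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "auto") {
    head1 <- readLines(path, n = 50L, warn = FALSE)
    head1 <- head1[nzchar(trimws(head1))]
    format <- if (length(head1) && grepl("^#NEXUS", head1[1L],
                                         ignore.case = TRUE)) "nexus" else "fasta"
  }
  if (format == "fasta") {
    # read as plain text: Biostrings rejects '.' and '~' gap dialects
    recs <- read_fasta_text(path)
    if (length(recs) != 2L)
      stop("expected 2 aligned FASTA records, found ", length(recs))
    aligned_pair(names(recs), unname(recs))
  } else {
    dat <- ape::read.nexus.data(path)
    if (length(dat) != 2L)
      stop("expected 2 taxa in NEXUS alignment, found ", length(dat))
    aligned_pair(names(dat), vapply(dat, paste, "", collapse = ""))
  }
}

read_fasta_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no FASTA records in ", path)
  starts <- hdr + 1L
  ends <- c(hdr[-1L] - 1L, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    paste(lines[seq(starts[i], max(starts[i], ends[i]))], collapse = "")
  }, "")
  seqs <- gsub("\\s", "", seqs)
  names(seqs) <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  seqs
}

#' Write an [aligned_pair()] as aligned FASTA
#' @param pair An [aligned_pair()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pair_alignment <- function(pair, path) {
  stopifnot(inherits(pair, "aligned_pair"))
  writeLines(c(paste0(">", pair$names[1L]), pair$rows[1L],
               paste0(">", pair$names[2L]), pair$rows[2L]), path)
  invisible(path)
}

#' Residue position at an alignment column
#'
#' @param pair An [aligned_pair()].
#' @param column Integer vector of 1-based columns.
#' @param row Row index (1 or 2).
#' @return Integer vector of 1-based residue positions; `NA` where the row is
#'   gapped at that column.
#' @export
to_position <- function(pair, column, row) {
  stopifnot(inherits(pair, "aligned_pair"), row %in% 1:2)
  column <- as.integer(column)
  if (any(column < 1L | column > pair$ncol))
    stop("column out of range [1, ", pair$ncol, "]")
  pair$col_to_pos[[row]][column]
}

#' Alignment column of a residue position
#'
#' Inverse of [to_position()]; identity holds on every non-gap residue.
#'
#' @param pair An [aligned_pair()].
#' @param position Integer vector of 1-based residue positions in `row`.
#' @param row Row index (1 or 2).
#' @return Integer vector of columns.
#' @export
to_column <- function(pair, position, row) {
  stopifnot(inherits(pair, "aligned_pair"), row %in% 1:2)
  position <- as.integer(position)
  n <- length(pair$pos_to_col[[row]])
  if (any(position < 1L | position > n))
    stop("position out of range [1, ", n, "]")
  pair$pos_to_col[[row]][position]
}

#' Number of non-gap residues of one row within a column interval
#'
#' Denominator service for divergence statistics ("per nucleotide" uses
#' genome lengths, not column counts).
#'
#' @param pair An [aligned_pair()].
#' @param row Row index (1 or 2).
#' @param from,to Column interval (inclusive).
#' @return Integer count of non-gap characters.
#' @export
ungapped_span_length <- function(pair, row, from, to) {
  stopifnot(inherits(pair, "aligned_pair"), row %in% 1:2)
  from <- as.integer(from); to <- as.integer(to)
  if (from > to) stop("inverted interval ", from, "..", to)
  if (from < 1L || to > pair$ncol)
    stop("interval outside [1, ", pair$ncol, "]")
  sum(pair$mat[row, from:to] != "-")
}

#' Ungapped sequence of one alignment row
#' @param pair An [aligned_pair()].
#' @param row Row index (1 or 2).
#' @return The row's sequence with gaps removed.
#' @export
ungapped_seq <- function(pair, row) {
  stopifnot(inherits(pair, "aligned_pair"), row %in% 1:2)
  gsub("-", "", pair$rows[row], fixed = TRUE)
}

#' @export
print.aligned_pair <- function(x, ...) {
  cat("aligned_pair: ", x$ncol, " columns; ",
      x$names[1L], " (", length(x$pos_to_col[[1L]]), " bp) vs ",
      x$names[2L], " (", length(x$pos_to_col[[2L]]), " bp)\n", sep = "")
  invisible(x)
}
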