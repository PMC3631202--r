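# shared fixture builders; everything is generated in code

toy_pair <- function(r1, r2, names = c("REF", "ALT")) {
  aligned_pair(names, c(r1, r2))
}

# 20 bp toy genome, one gene exon 4..9 (+, phase 0)
toy_plastome <- function() {
  plastome("toy", "ACGTACGTACGTACGTACGT",
           features = data.frame(name = "gA", kind = "gene_exon",
                                 start = 4L, end = 9L, strand = "+",
                                 phase = 0L, stringsAsFactors = FALSE))
}

# plastome whose coding sequence is explicit, for codon-effect checks:
# gene "gX" occupies 4..12 (3 codons) on the given strand
codon_plastome <- function(seq20, strand = "+") {
  plastome("cod", seq20,
           features = data.frame(name = "gX", kind = "gene_exon",
                                 start = 4L, end = 12L, strand = strand,
                                 phase = 0L, stringsAsFactors = FALSE))
}

# random gapped pair without N and without both-gap columns, for oracle tests
random_small_pair <- function(ncol = 40L) {
  repeat {
    r1 <- sample(c("A", "C", "G", "T", "-"), ncol, replace = TRUE,
                 prob = c(.22, .22, .22, .22, .12))
    r2 <- sample(c("A", "C", "G", "T", "-"), ncol, replace = TRUE,
                 prob = c(.22, .22, .22, .22, .12))
    both <- r1 == "-" & r2 == "-"
    r2[both] <- sample(c("A", "C", "G", "T"), sum(both), replace = TRUE)
    if (any(r1 != "-") && any(r2 != "-")) break
  }
  toy_pair(paste(r1, collapse = ""), paste(r2, collapse = ""))
}

# independent column-by-column re-derivation of the variant scan (the
# brute-force oracle for small alignments); inversions ignored by design
brute_force_scan <- function(pair) {
  m <- pair$mat
  nc <- pair$ncol
  snps <- integer()
  indels <- list()
  for (col in seq_len(nc)) {
    c1 <- m[1L, col]; c2 <- m[2L, col]
    if (c1 != "-" && c2 != "-" && c1 != c2 && c1 != "N" && c2 != "N")
      snps <- c(snps, col)
  }
  for (row in 1:2) {
    col <- 1L
    while (col <= nc) {
      if (m[row, col] == "-") {
        s <- col
        while (col <= nc && m[row, col] == "-") col <- col + 1L
        e <- col - 1L
        other <- m[3L - row, s:e]
        if (!any(other == "N"))
          indels[[length(indels) + 1L]] <- c(row = row, start = s, end = e)
      } else col <- col + 1L
    }
  }
  list(snp_cols = snps, indels = indels)
}

write_tmp_fasta <- function(recs, ext = ".fa") {
  path <- tempfile(fileext = ext)
  writeLines(unlist(lapply(names(recs), function(n)
    c(paste0(">", n), recs[[n]]))), path)
  path
}
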