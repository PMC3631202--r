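#' Collapse aligned samples into haplotypes
#'
#' Samples are partitioned by exact sequence identity over `A,C,G,T,-` (the
#' gap is a fifth state). Columns containing `N` in any sample are dropped
#' before comparison and reported. Haplotype ids are assigned by descending
#' member count, ties broken by first-seen order.
#'
#' @param samples `data.frame` with columns `sample_id` and `sequence`
#'   (aligned, equal column counts); optional metadata columns (`population`,
#'   `region`, `species`) are carried through.
#' @param prefix Haplotype id prefix (default `"H"`); set e.g. `prefix = ""`
#'   and `labels = LETTERS` for letter naming.
#' @param labels Optional explicit label vector used in rank order instead of
#'   `prefix + number`.
#' @return List with `haplotypes` (`data.frame`: `haplotype_id`, `sequence`,
#'   `n_members`, `n_populations`), `assignment` (`sample_id` ->
#'   `haplotype_id`), `dropped_columns` (integer vector).
#' @export
collapse_haplotypes <- function(samples, prefix = "H", labels = NULL) {
  stopifnot(is.data.frame(samples), nrow(samples) >= 1L,
            all(c("sample_id", "sequence") %in% names(samples)))
  seqs <- toupper(samples$sequence)
  ncols <- unique(nchar(seqs))
  if (length(ncols) != 1L)
    stop("all sample sequences must share one column count")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  dropped <- which(apply(m == "N", 2L, any))
  if (length(dropped)) m <- m[, -dropped, drop = FALSE]
  key <- apply(m, 1L, paste, collapse = "")
  first_seen <- match(unique(key), key)
  counts <- table(key)[unique(key)]
  ord <- order(-as.integer(counts), first_seen)
  uniq <- unique(key)[ord]
  ids <- if (!is.null(labels)) {
    if (length(labels) < length(uniq)) stop("not enough labels")
    labels[seq_along(uniq)]
  } else paste0(prefix, seq_along(uniq))
  hap_of <- ids[match(key, uniq)]
  npop <- if ("population" %in% names(samples)) {
    vapply(uniq, function(u)
      length(unique(samples$population[key == u])), 1L)
  } else as.integer(counts[uniq])
  haps <- data.frame(haplotype_id = ids,
                     sequence = vapply(match(uniq, key), function(i)
                       seqs[i], ""),
                     n_members = as.integer(table(key)[uniq]),
                     n_populations = as.integer(npop),
                     stringsAsFactors = FALSE)
  assignment <- data.frame(sample_id = samples$sample_id,
                           haplotype_id = hap_of, stringsAsFactors = FALSE)
  for (col in intersect(c("population", "region", "species"),
                        names(samples)))
    assignment[[col]] <- samples[[col]]
  list(haplotypes = haps, assignment = assignment,
       dropped_columns = dropped)
}

#' Mutation-step distance between two aligned haplotype sequences
#'
#' SNP steps are columns where both sequences are non-gap and unequal
#' (minute-inversion blocks, where one sequence carries the reverse
#' complement or reversal of the other, are counted as one inversion step per
#' block instead). Indel steps count maximal runs of columns where exactly
#' one sequence is gapped -- one step per run regardless of length (each
#' indel is a single mutational event). Runs are counted per gapped side, so
#' overlapping-but-unequal gap runs are separate events.
#'
#' @param s1,s2 Aligned sequences of equal length over `A,C,G,T,N,-`.
#' @param count_inversions Detect inversion blocks (default `TRUE`).
#' @return List with `snp_steps`, `indel_steps`, `inversion_steps`, `total`.
#' @export
mutation_steps <- function(s1, s2, count_inversions = TRUE) {
  s1 <- toupper(s1); s2 <- toupper(s2)
  if (nchar(s1) != nchar(s2)) stop("sequences must have equal column counts")
  a <- strsplit(s1, "", fixed = TRUE)[[1L]]
  b <- strsplit(s2, "", fixed = TRUE)[[1L]]
  callable <- a != "N" & b != "N"
  mism <- a != b & a != "-" & b != "-" & callable
  inv_steps <- 0L
  if (count_inversions && any(mism)) {
    runs <- rle(mism)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (i in which(runs$values & runs$lengths >= 2L)) {
      x <- a[starts[i]:ends[i]]; y <- b[starts[i]:ends[i]]
      if (identical(y, revcomp_chars(x)) || identical(y, rev(x))) {
        inv_steps <- inv_steps + 1L
        mism[starts[i]:ends[i]] <- FALSE
      }
    }
  }
  snp_steps <- sum(mism)
  indel_steps <- 0L
  for (g in list(a == "-" & b != "-" & callable,
                 b == "-" & a != "-" & callable)) {
    if (any(g)) {
      runs <- rle(g)
      indel_steps <- indel_steps + sum(runs$values)
    }
  }
  list(snp_steps = snp_steps, indel_steps = indel_steps,
       inversion_steps = inv_steps,
       total = snp_steps + indel_steps + inv_steps)
}

#' Pairwise step-distance matrix over haplotypes
#' @param haplotypes `haplotypes` data.frame from [collapse_haplotypes()].
#' @return Symmetric integer matrix of total steps with haplotype ids as
#'   dimnames; attribute `"steps"` holds the full per-pair decomposition.
#' @export
step_distance_matrix <- function(haplotypes) {
  n <- nrow(haplotypes)
  ids <- haplotypes$haplotype_id
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  decomp <- list()
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      st <- mutation_steps(haplotypes$sequence[i], haplotypes$sequence[j])
      d[i, j] <- d[j, i] <- st$total
      decomp[[paste(ids[i], ids[j], sep = "|")]] <- st
    }
  }
  attr(d, "steps") <- decomp
  d
}

#' Statistical-parsimony probability that j steps involve no multiple hits
#'
#' Default estimator: the probability that `j` mutations scattered uniformly
#' and independently over `sequence_length` sites all strike distinct sites,
#' `P(j) = prod_{i=0}^{j-1} (1 - i / L)`. Under this infinite-sites-style
#' approximation, `j` observed differences are exactly `j` mutational steps
#' with probability `P(j)`.
#'
#' @param j Number of mutational steps (>= 0).
#' @param sequence_length Alignment length L in bp.
#' @return Probability in (0, 1].
#' @export
parsimony_probability <- function(j, sequence_length) {
  stopifnot(j >= 0L, sequence_length >= 1L)
  if (j <= 1L) return(1)
  i <- seq_len(j - 1L)
  if (j > sequence_length) return(0)
  prod(1 - i / sequence_length)
}

#' Statistical-parsimony connection limit
#'
#' The largest step count `j` whose no-multiple-hit probability
#' ([parsimony_probability()], or a user-supplied estimator) is at least
#' `confidence`. Monotone non-decreasing in `sequence_length` and
#' non-increasing in `confidence`; haplotype pairs farther apart than the
#' limit are not connected by the network builder.
#'
#' @param sequence_length Alignment length in bp.
#' @param confidence Connection confidence in (0, 1); default 0.95.
#' @param estimator Function `(j, sequence_length) -> probability`;
#'   swappable strategy, defaults to [parsimony_probability()].
#' @return Integer step limit (>= 1; one step is always parsimonious).
#' @export
connection_limit <- function(sequence_length, confidence = 0.95,
                             estimator = parsimony_probability) {
  stopifnot(sequence_length >= 1L)
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie strictly between 0 and 1")
  j <- 1L
  while (j < sequence_length &&
         estimator(j + 1L, sequence_length) >= confidence)
    j <- j + 1L
  j
}

#' Assemble a statistical-parsimony haplotype network
#'
#' Haplotype pairs are connected in ascending step-distance order when the
#' distance is within the connection limit and the pair is not already
#' connected through edges of strictly smaller distance (minimum-spanning
#' behavior; ties at one distance level are all retained). Pairs beyond the
#' limit stay in separate components. Bridges added afterwards with
#' [add_bridge()] are flagged and never merge components.
#'
#' @param haplotypes `haplotypes` data.frame from [collapse_haplotypes()].
#' @param limit Connection limit in steps (see [connection_limit()]).
#' @param dist Optional precomputed [step_distance_matrix()].
#' @return A `cp_network`: list with `nodes`, `edges` (`from`, `to`, `steps`,
#'   `bridge`), `limit`, `components` (named membership vector), `dist`.
#' @export
build_network <- function(haplotypes, limit, dist = NULL) {
  if (is.null(dist)) dist <- step_distance_matrix(haplotypes)
  ids <- haplotypes$haplotype_id
  n <- length(ids)
  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), bridge = logical(),
                      stringsAsFactors = FALSE)
  if (n > 1L) {
    pairs <- which(upper.tri(dist), arr.ind = TRUE)
    pd <- data.frame(i = pairs[, 1L], j = pairs[, 2L],
                     d = dist[pairs])
    # deterministic: ascending distance, then lexicographic ids
    pd <- pd[order(pd$d, ids[pd$i], ids[pd$j]), , drop = FALSE]
    pd <- pd[pd$d <= limit, , drop = FALSE]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    igraph::V(g)$name <- ids
    for (lev in unique(pd$d)) {
      comp_before <- igraph::components(g)$membership
      lv <- pd[pd$d == lev, , drop = FALSE]
      for (r in seq_len(nrow(lv))) {
        if (comp_before[lv$i[r]] != comp_before[lv$j[r]]) {
          g <- igraph::add_edges(g, c(lv$i[r], lv$j[r]))
          edges <- rbind(edges, data.frame(
            from = ids[lv$i[r]], to = ids[lv$j[r]],
            steps = as.integer(lev), bridge = FALSE,
            stringsAsFactors = FALSE))
        }
      }
    }
    comp <- igraph::components(g)$membership
  } else {
    comp <- stats::setNames(1L, ids)
  }
  names(comp) <- ids
  structure(list(nodes = haplotypes, edges = edges, limit = as.integer(limit),
                 components = comp, dist = dist),
            class = "cp_network")
}

#' Add a manual bridge between unconnected haplotypes
#'
#' The edge carries the observed step count and is flagged `bridge = TRUE`;
#' it demonstrates the minimum distance between components and does not merge
#' them.
#'
#' @param net A `cp_network`.
#' @param from,to Haplotype ids.
#' @return The updated network.
#' @export
add_bridge <- function(net, from, to) {
  stopifnot(inherits(net, "cp_network"))
  ids <- net$nodes$haplotype_id
  if (!from %in% ids || !to %in% ids) stop("unknown haplotype id")
  steps <- net$dist[from, to]
  net$edges <- rbind(net$edges,
                     data.frame(from = from, to = to,
                                steps = as.integer(steps), bridge = TRUE,
                                stringsAsFactors = FALSE))
  net
}

#' Convert a haplotype network to igraph
#' @param net A `cp_network`.
#' @param include_bridges Keep flagged bridge edges (default `TRUE`).
#' @return An igraph graph with `steps` and `bridge` edge attributes and
#'   `n_members` vertex attribute.
#' @export
as_igraph <- function(net, include_bridges = TRUE) {
  stopifnot(inherits(net, "cp_network"))
  e <- net$edges
  if (!include_bridges) e <- e[!e$bridge, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e, directed = FALSE,
    vertices = data.frame(name = net$nodes$haplotype_id,
                          n_members = net$nodes$n_members))
  g
}

#' Write a haplotype network as GraphML
#' @param net A `cp_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @export
print.cp_network <- function(x, ...) {
  cat("cp_network: ", nrow(x$nodes), " haplotypes, ",
      sum(!x$edges$bridge), " edges (+", sum(x$edges$bridge),
      " bridges), limit ", x$limit, " steps, ",
      max(x$components), " components\n", sep = "")
  invisible(x)
}
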