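#' Build a raw node-centric de Bruijn graph
#'
#' Nodes are the distinct kmers, drawn from the reads and their reverse
#' complements, whose count reaches `min_count`. A directed edge a -> b exists
#' iff the (k-1)-suffix of a equals the (k-1)-prefix of b, both survive the
#' count filter, and the joining (k+1)-mer is witnessed in the
#' strand-augmented reads (mere overlap without a witnessed junction does not
#' create an edge). Inserting both strands guarantees the target's forward
#' strand is a directed path, so anchors can be searched in their given
#' orientation only.
#'
#' @param reads character vector of reads.
#' @param k_g graph kmer size (odd by convention; default 31, below the 110 bp
#'   read length and above the 12 bp anchor length).
#' @param min_count minimum kmer count to keep a node (default 2: at
#'   ultra-high depth singleton kmers are overwhelmingly sequencing errors).
#' @return a `raw_dbg` list: `kmers`, `counts`, `edges` (2-column matrix of
#'   node indices), `k`.
#' @export
build_dbg <- function(reads, k_g = 31L, min_count = 2L) {
  stopifnot(k_g >= 3, min_count >= 1)
  reads <- toupper(as.character(reads))
  g <- build_dbg_cpp(reads, as.integer(k_g), as.integer(min_count))
  if (length(g$kmers) == 0)
    stopf("graph empty: no kmer reaches min_count = %d", min_count,
          class = "anchorasm_graph_empty")
  class(g) <- "raw_dbg"
  g
}

#' Compact a raw de Bruijn graph into a weighted unitig graph
#'
#' Maximal non-branching paths are merged into unitigs; member kmers overlap
#' by k-1 bases and the unitig weight is the arithmetic mean of their counts.
#' Self-adjacencies and cycles are kept (a perfect cycle becomes one unitig
#' with a self-edge), never unrolled. Total kmer content is preserved:
#' sum(length - k + 1) over unitigs equals the raw node count.
#'
#' @param raw a `raw_dbg` from [build_dbg()].
#' @return a `cdbg`: list with `seq`, `weight`, `length` (parallel unitig
#'   vectors), `edges` (2-column matrix of unitig indices), `n_kmers`, `k`.
#' @export
compact_dbg <- function(raw) {
  stopifnot(inherits(raw, "raw_dbg"))
  g <- compact_cpp(raw$kmers, raw$counts, raw$edges, raw$k)
  g$seq <- as.character(g$seq)
  class(g) <- "cdbg"
  g
}

#' Build a compacted de Bruijn graph from reads
#'
#' @inheritParams build_dbg
#' @return a `cdbg` (see [compact_dbg()]).
#' @export
build_cdbg <- function(reads, k_g = 31L, min_count = 2L) {
  compact_dbg(build_dbg(reads, k_g = k_g, min_count = min_count))
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf("Compacted de Bruijn graph (k = %d): %d unitigs, %d edges, %d kmers\n",
              x$k, length(x$seq), nrow(x$edges), x$n_kmers))
  invisible(x)
}

#' Length added by traversing an edge
#'
#' Expanding a path by edge (u, v) appends length(v) - (k - 1) bases.
#'
#' @param g a `cdbg`.
#' @param u,v unitig indices; (u, v) must be an edge of `g`.
#' @return integer added length in bp (>= 1).
#' @export
edge_added_length <- function(g, u, v) {
  if (!any(g$edges[, 1] == u & g$edges[, 2] == v))
    stopf("no such edge: (%d, %d)", u, v, class = "anchorasm_no_edge")
  g$length[v] - (g$k - 1L)
}

#' Write a compacted de Bruijn graph as GFA 1.0
#'
#' S-lines carry the unitig sequence and a `dp:f:` coverage tag; L-lines use a
#' (k-1)M overlap CIGAR on + orientations.
#'
#' @param g a `cdbg`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gfa <- function(g, path) {
  ids <- sprintf("utg%06d", seq_along(g$seq))
  lines <- c(
    "H\tVN:Z:1.0",
    sprintf("S\t%s\t%s\tdp:f:%.6g", ids, g$seq, g$weight),
    if (nrow(g$edges) > 0)
      sprintf("L\t%s\t+\t%s\t+\t%dM", ids[g$edges[, 1]], ids[g$edges[, 2]], g$k - 1L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a GFA 1.0 file written by [write_gfa()]
#'
#' @param path GFA file path.
#' @return a `cdbg` (weights from `dp:f:` tags; `n_kmers` recomputed from
#'   unitig lengths).
#' @export
read_gfa <- function(path) {
  lines <- readLines(path)
  recs <- strsplit(lines, "\t", fixed = TRUE)
  type <- vapply(recs, `[[`, character(1), 1)
  s <- recs[type == "S"]
  ids <- vapply(s, `[[`, character(1), 2)
  seqs <- vapply(s, `[[`, character(1), 3)
  dp <- vapply(s, function(r) {
    tag <- grep("^dp:f:", r[-(1:3)], value = TRUE)
    if (length(tag)) as.numeric(sub("^dp:f:", "", tag[1])) else NA_real_
  }, numeric(1))
  l <- recs[type == "L"]
  k <- NA_integer_
  edges <- matrix(integer(0), 0, 2)
  if (length(l) > 0) {
    from <- match(vapply(l, `[[`, character(1), 2), ids)
    to <- match(vapply(l, `[[`, character(1), 4), ids)
    k <- as.integer(sub("M$", "", vapply(l, `[[`, character(1), 6))) + 1L
    stopifnot(length(unique(k)) == 1)
    k <- k[1]
    edges <- cbind(from, to)
  }
  g <- list(seq = seqs, weight = dp, length = nchar(seqs), edges = edges,
            n_kmers = if (is.na(k)) NA_integer_ else sum(nchar(seqs) - k + 1L),
            k = k)
  class(g) <- "cdbg"
  g
}
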