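#' Spell the sequence of a path through the unitig graph
#'
#' Consecutive unitigs are concatenated with their (k-1)-base overlap removed;
#' the overlap is verified character-for-character and a mismatch raises an
#' internal-corruption error. With `trim`, the result is sliced from the start
#' hit's matched span on the first unitig to the end hit's matched span on the
#' last unitig (offsets mapped through the concatenation; for a path visiting
#' the last node repeatedly, the end span refers to its final visit).
#'
#' @param g a `cdbg`.
#' @param path ordered unitig indices.
#' @param start_hit,end_hit single-row hit tables ([find_anchor_nodes()]);
#'   required when `trim = TRUE`.
#' @param trim slice to the anchor spans?
#' @return the spelled DNA string, or NULL when `trim = TRUE` and the anchor
#'   spans are out of order on this path (no valid anchored read-out).
#' @export
read_out_sequence <- function(g, path, start_hit = NULL, end_hit = NULL,
                              trim = FALSE) {
  ov <- g$k - 1L
  seqs <- g$seq[path]
  if (length(path) > 1) {
    for (i in seq_len(length(path) - 1)) {
      a <- seqs[i]; b <- seqs[i + 1]
      if (substr(a, nchar(a) - ov + 1L, nchar(a)) != substr(b, 1L, ov))
        stopf("graph corruption: overlap mismatch between path nodes %d and %d",
              path[i], path[i + 1], class = "anchorasm_internal")
    }
  }
  full <- paste0(seqs[1],
                 paste(vapply(seqs[-1], function(s) substr(s, ov + 1L, nchar(s)),
                              character(1)), collapse = ""))
  if (!trim) return(full)
  stopifnot(!is.null(start_hit), !is.null(end_hit),
            start_hit$node == path[1],
            end_hit$node == path[length(path)])
  gstart <- start_hit$start_offset + 1L               # 1-based inclusive
  gend <- nchar(full) - g$length[path[length(path)]] + end_hit$end_offset
  if (gend <= gstart) return(NULL)
  substr(full, gstart, gend)
}

# replace the (possibly error-bearing or tip-truncated) matched anchor spans
# of a trimmed read-out by the known synthetic anchor sequences
restore_anchor_ends <- function(seq, start_hit, end_hit, a_s, a_t) {
  span_s <- start_hit$end_offset - start_hit$start_offset
  span_t <- end_hit$end_offset - end_hit$start_offset
  if (span_s + span_t >= nchar(seq)) return(seq) # anchors overlap: leave as-is
  paste0(a_s, substr(seq, span_s + 1L, nchar(seq) - span_t), a_t)
}

#' Assemble one molecule from its read cloud
#'
#' End-to-end anchor-guided assembly: estimate the molecule length from the
#' N50 kmer frequency, build the weighted compacted de Bruijn graph, search
#' both anchors at edit-distance tolerance e = 0, 1, ..., `max_edit`, score
#' every start/end node pair with the length-constrained maximin DP, and read
#' out the best path. Ranked candidates are tried in order until one yields
#' consistent anchor-span coordinates (relevant when a circular read-through
#' collapses the graph to a single rotated unitig, where the valid read-out
#' takes the self-edge). The first tolerance round producing an assembly
#' terminates the search.
#'
#' @param reads character vector of reads (pool both mates).
#' @param a_s,a_t start/end anchor sequences.
#' @param k_est kmer size for length estimation (default 33).
#' @param k_g graph kmer size (default 31).
#' @param min_count kmer count filter for the graph (default 2).
#' @param max_edit anchor edit-distance ceiling (default 2).
#' @param top_c DP queue capacity (default 30).
#' @param lower_frac,upper_frac admissible length range as fractions of the
#'   point estimate (defaults 0.5 and 2.0).
#' @param trim slice the output to the anchor spans (default TRUE).
#' @param restore_anchors when trimming, rewrite the matched anchor spans with
#'   the supplied anchor sequences — they are known synthetic constants, so
#'   sequencing errors or coverage-filtered molecule tips inside the anchor
#'   copy need not propagate into the output (default TRUE).
#' @param lex_refine see [connect()].
#' @param max_candidates cap on fallback candidates tried per round.
#' @return an `assembly_result`: `status` ("ok" or a failure stage:
#'   "no_kmers", "no_anchors", "no_path"), `sequence`, `path`, `z_star`,
#'   `L_star`, `e_used`, `trimmed`, `restored`, `start_hit`, `end_hit`,
#'   `estimate`, `graph`.
#' @export
assemble_molecule <- function(reads,
                              a_s = default_anchors()[["start"]],
                              a_t = default_anchors()[["end"]],
                              k_est = 33L, k_g = 31L, min_count = 2L,
                              max_edit = 2L, top_c = 30L,
                              lower_frac = 0.5, upper_frac = 2.0,
                              trim = TRUE, restore_anchors = TRUE,
                              lex_refine = TRUE, max_candidates = 50L) {
  fail <- function(status, est = NULL, g = NULL) {
    structure(list(status = status, sequence = NULL, path = NULL,
                   z_star = NA_real_, L_star = NA_real_, e_used = NA_integer_,
                   trimmed = trim, restored = FALSE,
                   start_hit = NULL, end_hit = NULL,
                   estimate = est, graph = g),
              class = "assembly_result")
  }

  est <- tryCatch(
    estimate_length_from_reads(reads, k = k_est,
                               lower_frac = lower_frac, upper_frac = upper_frac),
    anchorasm_insufficient_data = function(e) NULL,
    anchorasm_no_reliable_kmers = function(e) NULL)
  if (is.null(est)) return(fail("no_kmers"))

  g <- tryCatch(build_cdbg(reads, k_g = k_g, min_count = min_count),
                anchorasm_graph_empty = function(e) NULL)
  if (is.null(g)) return(fail("no_kmers", est = est))

  query <- anchor_query(a_s, a_t, max_edit = max_edit)
  bounds <- c(est$Ml, est$Mu)
  saw_anchors <- FALSE

  for (e in 0:query$max_edit) {
    S <- find_anchor_nodes(g, query$a_s, e, role = "start")
    T <- find_anchor_nodes(g, query$a_t, e, role = "end")
    if (nrow(S) == 0 || nrow(T) == 0) next
    saw_anchors <- TRUE
    cand <- score_pairs(g, S, T, bounds, c = top_c, m_mid = est$M,
                        lex_refine = lex_refine)
    for (cc in head(cand, max_candidates)) {
      seq <- read_out_sequence(g, cc$path$nodes,
                               start_hit = cc$start_hit, end_hit = cc$end_hit,
                               trim = trim)
      if (is.null(seq)) next
      restored <- FALSE
      if (trim && restore_anchors) {
        seq <- restore_anchor_ends(seq, cc$start_hit, cc$end_hit,
                                   query$a_s, query$a_t)
        restored <- TRUE
      }
      return(structure(list(status = "ok", sequence = seq,
                            path = cc$path$nodes, z_star = cc$z, L_star = cc$L,
                            e_used = e, trimmed = trim, restored = restored,
                            start_hit = cc$start_hit, end_hit = cc$end_hit,
                            estimate = est, graph = g),
                       class = "assembly_result"))
    }
  }
  fail(if (saw_anchors) "no_path" else "no_anchors", est = est, g = g)
}

#' @export
print.assembly_result <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("Assembly: %d bp, z* = %.3g, L* = %.0f, e = %d (M_est = %.0f)\n",
                nchar(x$sequence), x$z_star, x$L_star, x$e_used,
                if (!is.null(x$estimate)) x$estimate$M else NA_real_))
  } else {
    cat(sprintf("Assembly failed at stage: %s\n", x$status))
  }
  invisible(x)
}

#' Write an assembly result as a single-record FASTA
#'
#' Header carries `z=`, `len=`, `e=`, `M_est=` fields.
#'
#' @param res an `assembly_result` with status "ok".
#' @param path output path.
#' @param name record base name.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(res, path, name = "assembly") {
  stopifnot(inherits(res, "assembly_result"), res$status == "ok")
  hdr <- sprintf("%s z=%.6g len=%d e=%d M_est=%.6g", name, res$z_star,
                 nchar(res$sequence), res$e_used, res$estimate$M)
  write_fasta(setNames(res$sequence, hdr), path)
}
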