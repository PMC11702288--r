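#' Locate anchor occurrences in the unitigs of a graph
#'
#' Infix search: a unitig is a hit if some substring of it lies within unit-cost
#' Levenshtein distance `e` (substitutions and indels) of the anchor. Per
#' unitig the minimal-distance occurrence is reported; among equal-distance
#' occurrences the leftmost is kept for `role = "start"` (maximizing the
#' sequence downstream of the anchor) and the rightmost for `role = "end"`.
#' The search is orientation-specific: the anchor is never reverse
#' complemented (the graph carries both strands, so the anchored orientation
#' is always present).
#'
#' @param g a `cdbg`.
#' @param anchor anchor DNA string (shorter than the graph kmer size).
#' @param e edit-distance tolerance (>= 0).
#' @param role `"start"` or `"end"`; controls occurrence selection.
#' @param boundary also recover boundary-truncated anchor occurrences
#'   (default TRUE). Coverage decays toward the tips of a linear template, so
#'   the count filter can drop the outermost kmers and leave a unitig that
#'   begins mid-anchor. Such a unitig is a graph tip (no in-edge for the
#'   start role, no out-edge for the end role) whose boundary carries an
#'   exact remnant of the known synthetic anchor; a remnant of at least
#'   `min_overlap` bases is accepted as an occurrence (edit distance 0,
#'   span = the remnant) when no within-tolerance infix occurrence exists.
#' @param min_overlap minimum exact remnant length for boundary recovery.
#' @return data.frame of hits: `node`, `start_offset`, `end_offset` (0-based
#'   half-open span within the unitig), `edit_distance`, `role`. Zero rows if
#'   no unitig matches.
#' @export
find_anchor_nodes <- function(g, anchor, e, role = c("start", "end"),
                              boundary = TRUE, min_overlap = 6L) {
  role <- match.arg(role)
  stopifnot(e >= 0, nchar(anchor) >= 1)
  anchor <- toupper(anchor)
  a <- infix_align_batch_cpp(g$seq, anchor)
  keep <- which(a$dist <= e)
  hits <- if (role == "start")
    data.frame(node = keep, start_offset = a$ls_start[keep],
               end_offset = a$ls_end[keep], edit_distance = a$dist[keep],
               role = rep_len(role, length(keep)))
  else
    data.frame(node = keep, start_offset = a$re_start[keep],
               end_offset = a$re_end[keep], edit_distance = a$dist[keep],
               role = rep_len(role, length(keep)))

  if (boundary && nchar(anchor) > min_overlap) {
    n <- length(g$seq)
    la <- nchar(anchor)
    if (role == "start") {
      tips <- setdiff(which(tabulate(g$edges[, 2], n) == 0), keep)
      for (j in seq_len(la - min_overlap)) { # longest remnant first
        if (length(tips) == 0) break
        remnant <- substring(anchor, j + 1, la)
        found <- tips[startsWith(g$seq[tips], remnant)]
        if (length(found)) {
          hits <- rbind(hits, data.frame(
            node = found, start_offset = 0L, end_offset = la - j,
            edit_distance = 0L, role = role))
          tips <- setdiff(tips, found)
        }
      }
    } else {
      tips <- setdiff(which(tabulate(g$edges[, 1], n) == 0), keep)
      for (j in seq_len(la - min_overlap)) {
        if (length(tips) == 0) break
        remnant <- substring(anchor, 1, la - j)
        found <- tips[endsWith(g$seq[tips], remnant)]
        if (length(found)) {
          hits <- rbind(hits, data.frame(
            node = found, start_offset = g$length[found] - (la - j),
            end_offset = g$length[found], edit_distance = 0L, role = role))
          tips <- setdiff(tips, found)
        }
      }
    }
  }
  hits
}

#' Anchor query parameters
#'
#' @param a_s,a_t start/end anchor DNA strings.
#' @param max_edit edit-distance ceiling for the escalating search (default 2;
#'   for 12 bp anchors shorter than the graph kmer, 2 edits suffice to absorb
#'   sequencing errors in the anchor copy).
#' @return an `anchor_query` list.
#' @export
anchor_query <- function(a_s, a_t, max_edit = 2L) {
  stopifnot(nchar(a_s) >= 1, nchar(a_t) >= 1, max_edit >= 0)
  list(a_s = toupper(a_s), a_t = toupper(a_t), max_edit = as.integer(max_edit))
}

#' The 12 bp start/end anchors used by LoopSeq-style libraries
#'
#' @return named character vector with elements `start` and `end`.
#' @export
default_anchors <- function() {
  c(start = "CGCAGAGTACAT", end = "TTGGAGTTAAAG")
}

#' Escalating-tolerance anchor search
#'
#' Runs [find_anchor_nodes()] for both anchors at e = 0, 1, ..., `max_edit`
#' and hands each round to `callback`; iteration stops at the first round for
#' which `callback` returns non-NULL (the caller's "assembly succeeded"
#' signal). Rounds where either anchor has no hit are still reported (with
#' empty hit tables) so callers can distinguish failure modes.
#'
#' @param g a `cdbg`.
#' @param query an [anchor_query()].
#' @param callback `function(e, S, T)` returning NULL to continue escalating.
#' @return list(e = round, value = callback result), or NULL if every round
#'   was exhausted.
#' @export
iterate_tolerance <- function(g, query, callback) {
  for (e in 0:query$max_edit) {
    S <- find_anchor_nodes(g, query$a_s, e, role = "start")
    T <- find_anchor_nodes(g, query$a_t, e, role = "end")
    res <- callback(e, S, T)
    if (!is.null(res)) return(list(e = e, value = res))
  }
  NULL
}
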