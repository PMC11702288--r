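#' Length-constrained maximin path between two nodes
#'
#' Finds s -> t paths maximizing the smallest node weight, keeping the best
#' `c` candidates per node and round in a bounded priority queue, pruning any
#' expansion whose spelled length would exceed `Mu`, and terminating at the
#' first round where no queue changes. Candidates reaching t with length below
#' `Ml` are discarded. Among survivors the winner has maximal bottleneck z;
#' ties are broken by closeness of the length to `m_mid` (the point length
#' estimate) and then, if `lex_refine`, by lexicographic comparison of the
#' ascending node-weight vectors (second-smallest weight, and so on).
#'
#' @param g a `cdbg`.
#' @param s,t start/end unitig indices.
#' @param bounds numeric `c(Ml, Mu)` admissible length range in bp; `Mu` may
#'   be `Inf`.
#' @param c queue capacity (default 30).
#' @param m_mid point length estimate used in tie-breaks (default: midpoint of
#'   finite bounds, else length of s).
#' @param lex_refine apply the lexicographic weight-vector refinement among
#'   the final survivors (default TRUE).
#' @return a `path_result` (fields `nodes`, `z`, `L`; attribute `candidates`
#'   holds every ranked survivor as a list of such records, and attribute
#'   `stats` the DP round/operation counters), or NULL if no admissible path
#'   exists.
#' @export
connect <- function(g, s, t, bounds, c = 30L, m_mid = NULL, lex_refine = TRUE) {
  n <- length(g$seq)
  if (s < 1 || s > n || t < 1 || t > n)
    stopf("anchor node missing: s = %s, t = %s not in graph", s, t,
          class = "anchorasm_anchor_node_missing")
  stopifnot(length(bounds) == 2, bounds[1] <= bounds[2], c >= 1)
  if (is.null(m_mid)) {
    m_mid <- if (all(is.finite(bounds))) mean(bounds) else g$length[s]
  }
  res <- connect_cpp(n, g$edges, g$weight, as.integer(g$length),
                     as.integer(s), as.integer(t),
                     bounds[1], bounds[2], as.integer(c), m_mid,
                     as.integer(g$k))
  stats <- list(rounds = res$rounds, max_round_ops = res$max_round_ops)
  res <- res$targets[[1]]
  if (length(res$z) == 0) return(NULL)

  cand <- lapply(seq_along(res$z), function(i) {
    structure(list(nodes = res$paths[[i]], z = res$z[i], L = res$L[i]),
              class = "path_result")
  })
  cand <- rank_candidates(cand, g, m_mid, lex_refine)
  best <- cand[[1]]
  attr(best, "candidates") <- cand
  attr(best, "stats") <- stats
  best
}

# Order candidate paths: z desc, |L - m_mid| asc, then (optionally) the
# lexicographic rule on ascending sorted weight vectors: first differing
# position, larger weight wins.
rank_candidates <- function(cand, g, m_mid, lex_refine) {
  z <- vapply(cand, `[[`, numeric(1), "z")
  dL <- abs(vapply(cand, `[[`, numeric(1), "L") - m_mid)
  o <- order(-z, dL)
  cand <- cand[o]
  if (!lex_refine || length(cand) < 2) return(cand)
  z <- z[o]; dL <- dL[o]
  key <- paste(z, dL)
  for (grp in split(seq_along(cand), key)) {
    if (length(grp) < 2) next
    wv <- lapply(cand[grp], function(p) sort(g$weight[p$nodes]))
    perm <- order_weight_vectors(wv)
    cand[grp] <- cand[grp][perm]
  }
  cand
}

# order weight vectors best-first under the lexicographic maximin refinement
order_weight_vectors <- function(wv) {
  better <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] > b[i]) return(TRUE)
      if (a[i] < b[i]) return(FALSE)
    }
    length(a) < length(b) # all shared weights equal: fewer nodes wins
  }
  idx <- seq_along(wv)
  # insertion sort; candidate lists are tiny (<= queue capacity)
  for (i in idx[-1]) {
    j <- i
    while (j > 1 && better(wv[[idx[j]]], wv[[idx[j - 1]]])) {
      idx[c(j - 1, j)] <- idx[c(j, j - 1)]
      j <- j - 1
    }
  }
  idx
}

#' Recompute a path's bottleneck score and spelled length
#'
#' Self-consistency helper: for any node list, returns the minimum node weight
#' and the length of the sequence spelled with (k-1)-overlaps.
#'
#' @param g a `cdbg`.
#' @param nodes ordered unitig indices (consecutive pairs must be edges).
#' @return list(z, L).
#' @export
path_score <- function(g, nodes) {
  L <- g$length[nodes[1]]
  if (length(nodes) > 1)
    L <- L + sum(g$length[nodes[-1]] - (g$k - 1L))
  list(z = min(g$weight[nodes]), L = L)
}

#' @export
print.path_result <- function(x, ...) {
  cat(sprintf("Path: %d nodes, bottleneck z = %.3g, length L = %.0f bp\n",
              length(x$nodes), x$z, x$L))
  invisible(x)
}

#' Score every start/end anchor pair and rank the connecting paths
#'
#' Runs [connect()] for each (s, t) pair from the start/end hit tables and
#' pools all surviving candidates, ranked by bottleneck z (descending), then
#' |L - m_mid|, then the lexicographic refinement within a pair's candidate
#' set. Each returned record carries the originating hits so readout can trim
#' to the matched anchor spans.
#'
#' @param g a `cdbg`.
#' @param S,T hit tables from [find_anchor_nodes()] (roles start/end).
#' @param bounds numeric `c(Ml, Mu)`.
#' @param c queue capacity.
#' @param m_mid point length estimate for tie-breaks.
#' @param lex_refine see [connect()].
#' @return list of candidates, best first, each
#'   `list(path, z, L, start_hit, end_hit)`; empty list if no pair connects.
#' @details One DP run covers all end nodes for a given start node (the
#'   recursion does not depend on the target). Start nodes are processed in
#'   decreasing weight order, with two exact prunes: a start node is skipped
#'   once its own weight cannot beat the best bottleneck found so far (any
#'   path from s has z <= w(s)), and otherwise a cheap unconstrained maximin
#'   screen (capacity 1, no length bound — an upper bound on any
#'   length-constrained bottleneck from that start) is run first; the full
#'   bounded DP only runs when the screen could strictly improve the
#'   incumbent. Ultra-high-depth graphs place the anchor on dozens of
#'   overlapping unitigs whose paths all tie at the same bottleneck; among
#'   such exact ties the earliest-scanned pair supplies the candidates, so
#'   the reported bottleneck is exact while |L - M| tie-breaking is resolved
#'   within the candidate pools actually computed.
#' @export
score_pairs <- function(g, S, T, bounds, c = 30L, m_mid = NULL,
                        lex_refine = TRUE) {
  out <- list()
  if (nrow(S) == 0 || nrow(T) == 0) return(out)
  mm <- if (is.null(m_mid)) mean(bounds[is.finite(bounds)]) else m_mid
  t_nodes <- unique(T$node)
  s_nodes <- unique(S$node)

  # screening pass: unconstrained maximin upper bound per start node
  ub <- if (length(s_nodes) > 1) {
    vapply(s_nodes, function(s_node) {
      scr <- connect_cpp(length(g$seq), g$edges, g$weight, as.integer(g$length),
                         as.integer(s_node), as.integer(t_nodes),
                         0, Inf, 1L, mm, as.integer(g$k))
      zz <- unlist(lapply(scr$targets, `[[`, "z"))
      if (length(zz)) max(zz) else -Inf
    }, numeric(1))
  } else g$weight[s_nodes]

  z_best <- -Inf
  for (s_node in s_nodes[order(-ub)]) {
    u <- ub[match(s_node, s_nodes)]
    if (u < z_best || is.infinite(u)) break # ub-sorted: nothing below can win
    if (u == z_best && length(out) > 0) next # exact tie: incumbent pool stands
    res <- connect_cpp(length(g$seq), g$edges, g$weight, as.integer(g$length),
                       as.integer(s_node), as.integer(t_nodes),
                       bounds[1], bounds[2], as.integer(c), mm,
                       as.integer(g$k))
    for (ti in seq_along(t_nodes)) {
      rt <- res$targets[[ti]]
      if (length(rt$z) == 0) next
      cand <- lapply(seq_along(rt$z), function(i) {
        structure(list(nodes = rt$paths[[i]], z = rt$z[i], L = rt$L[i]),
                  class = "path_result")
      })
      cand <- rank_candidates(cand, g, mm, lex_refine)
      i_s <- which(S$node == s_node)[1]
      j_t <- which(T$node == t_nodes[ti])[1]
      for (p in cand) {
        out[[length(out) + 1L]] <- list(path = p, z = p$z, L = p$L,
                                        start_hit = S[i_s, , drop = FALSE],
                                        end_hit = T[j_t, , drop = FALSE])
      }
      z_best <- max(z_best, cand[[1]]$z)
    }
  }
  if (length(out) == 0) return(out)
  z <- vapply(out, `[[`, numeric(1), "z")
  dL <- abs(vapply(out, `[[`, numeric(1), "L") - mm)
  out[order(-z, dL)]
}
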