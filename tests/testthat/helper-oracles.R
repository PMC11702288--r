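# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (dictionary counting, exhaustive enumeration, quadratic
# DP) and never call the code paths they are checking.

# canonical kmer counting by dictionary over all windows
oracle_kmer_hist <- function(reads, k) {
  counts <- new.env(parent = emptyenv())
  rc1 <- function(s) {
    paste(rev(chartr("ACGT", "TGCA", strsplit(s, "")[[1]])), collapse = "")
  }
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (j in 1:(n - k + 1)) {
      km <- substr(r, j, j + k - 1)
      if (grepl("[^ACGT]", km)) next
      can <- min(km, rc1(km))
      counts[[can]] <- (if (is.null(counts[[can]])) 0 else counts[[can]]) + 1
    }
  }
  vals <- unlist(as.list(counts))
  if (length(vals) == 0) return(NULL)
  tab <- table(vals)
  data.frame(frequency = as.integer(names(tab)), count = as.integer(tab))
}

# brute-force N50 kmer frequency: try every frequency as threshold
oracle_n50 <- function(freq, count) {
  total <- sum(freq * count)
  fs <- sort(unique(freq), decreasing = TRUE)
  for (f in fs) {
    if (sum(freq[freq >= f] * count[freq >= f]) >= 0.5 * total) return(f)
  }
  stop("unreachable")
}

# exhaustive simple-path maximin bottleneck (node weights), NA if no path
oracle_maximin <- function(edges, w, s, t) {
  n <- length(w)
  adj <- lapply(seq_len(n), function(u) edges[edges[, 1] == u, 2])
  best <- -Inf
  rec <- function(u, visited, z) {
    if (u == t) { best <<- max(best, z); return(invisible()) }
    for (v in adj[[u]]) {
      if (!visited[v]) {
        visited[v] <- TRUE
        rec(v, visited, min(z, w[v]))
        visited[v] <- FALSE
      }
    }
  }
  visited <- rep(FALSE, n)
  visited[s] <- TRUE
  rec(s, visited, w[s])
  if (is.infinite(best)) NA_real_ else best
}

# exhaustive enumeration of all s->t walks with spelled length <= Mu;
# returns data.frame of (z, L) pairs (possibly with duplicates)
oracle_bounded_walks <- function(edges, w, len, k, s, t, Ml, Mu) {
  adj <- lapply(seq_along(w), function(u) edges[edges[, 1] == u, 2])
  res <- list()
  rec <- function(u, z, L) {
    if (L > Mu) return(invisible())
    if (u == t && L >= Ml) res[[length(res) + 1L]] <<- c(z, L)
    for (v in adj[[u]]) rec(v, min(z, w[v]), L + len[v] - (k - 1))
  }
  if (len[s] <= Mu) rec(s, w[s], len[s])
  if (length(res) == 0)
    return(data.frame(z = numeric(0), L = numeric(0)))
  m <- do.call(rbind, res)
  data.frame(z = m[, 1], L = m[, 2])
}

# quadratic-DP edit distance (utils::adist) minimized over all substrings
oracle_infix_dist <- function(subject, pattern) {
  n <- nchar(subject)
  best <- nchar(pattern) # empty substring
  for (i in 1:n) {
    for (j in i:n) {
      d <- utils::adist(substr(subject, i, j), pattern)[1, 1]
      if (d < best) best <- d
    }
  }
  best
}

# random weighted digraph as a cdbg-like object with consistent unitig
# sequences is not needed for the DP tests: the DP reads only weights,
# lengths, edges and k
random_graph <- function(n, p = 2 / n, k = 5L, min_len = k, max_len = 40L) {
  em <- which(matrix(runif(n * n) < p, n, n), arr.ind = TRUE)
  edges <- unname(cbind(em[, 1], em[, 2]))
  g <- list(seq = rep(strrep("A", k), n),
            weight = round(runif(n, 1, 100)),
            length = sample(min_len:max_len, n, replace = TRUE),
            edges = edges, n_kmers = NA_integer_, k = k)
  class(g) <- "cdbg"
  g
}

# error-free reads tiling a molecule end to end (every adjacent (k+1)-mer
# witnessed), for graph reconstruction checks
tiling_reads <- function(mol, read_len = 40L, step = 5L) {
  n <- nchar(mol)
  starts <- unique(c(seq(1, n - read_len + 1, by = step), n - read_len + 1))
  substring(mol, starts, starts + read_len - 1L)
}
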