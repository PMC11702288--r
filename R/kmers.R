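#' Count canonical kmers and build the frequency histogram
#'
#' Every length-`k` window free of ambiguous bases contributes one occurrence;
#' a kmer and its reverse complement are counted as one canonical kmer (the
#' lexicographic minimum of the two), so reads from both strands and both
#' mates accumulate into a single histogram.
#'
#' @param reads character vector of reads (A/C/G/T/N).
#' @param k kmer size (default 33, tuned for ~110 bp SLR reads).
#' @return a `kmer_histogram`: data.frame with columns `frequency` (occurrence
#'   count of a distinct kmer) and `count` (number of distinct kmers with that
#'   frequency), sorted by frequency.
#' @examples
#' count_kmers("ACGT", k = 4)   # one window, one canonical kmer
#' @export
count_kmers <- function(reads, k = 33L) {
  stopifnot(k >= 1)
  reads <- toupper(as.character(reads))
  if (length(reads) == 0 || !any(nchar(reads) >= k))
    stopf("insufficient data: no read of length >= k = %d", k,
          class = "anchorasm_insufficient_data")
  counts <- count_kmers_cpp(reads, as.integer(k))
  if (length(counts) == 0)
    stopf("insufficient data: no valid kmer window (ambiguous bases only?)",
          class = "anchorasm_insufficient_data")
  tab <- table(counts)
  kmer_histogram(frequency = as.integer(names(tab)), count = as.integer(tab))
}

#' Construct a kmer frequency histogram
#'
#' @param frequency integer vector of kmer frequencies (>= 1).
#' @param count number of distinct kmers at each frequency (>= 1). Duplicate
#'   frequency rows are summed, so a histogram split across bins is equivalent
#'   to its merged form.
#' @return a `kmer_histogram` data.frame.
#' @export
kmer_histogram <- function(frequency, count) {
  stopifnot(length(frequency) == length(count),
            all(frequency >= 1), all(count >= 1))
  agg <- tapply(as.numeric(count), as.integer(frequency), sum)
  h <- data.frame(frequency = as.integer(names(agg)),
                  count = as.numeric(agg), row.names = NULL)
  h <- h[order(h$frequency), , drop = FALSE]
  class(h) <- c("kmer_histogram", "data.frame")
  h
}

#' N50 kmer frequency
#'
#' The largest frequency f* such that kmers of frequency f* or higher account
#' for at least half of all kmer occurrences. Scanning frequencies in
#' descending order, this is the first crossing of the 50% mark (inclusive:
#' exactly 50% qualifies).
#'
#' @param hist a `kmer_histogram` (or data.frame with `frequency`, `count`).
#' @return integer N50 kmer frequency.
#' @export
n50_frequency <- function(hist) {
  if (is.null(hist) || nrow(hist) == 0)
    stopf("insufficient data: empty kmer histogram",
          class = "anchorasm_insufficient_data")
  hist <- kmer_histogram(hist$frequency, hist$count)
  occ <- as.numeric(hist$frequency) * hist$count
  total <- sum(occ)
  o <- order(hist$frequency, decreasing = TRUE)
  cum <- cumsum(occ[o])
  hist$frequency[o][which(cum >= 0.5 * total)[1]]
}

#' Summary statistics of a read set
#'
#' @param reads character vector of reads.
#' @param k_est kmer size used for length estimation.
#' @return list with `N` (read count), `R` (mean read length, rounded) and
#'   `k_est`.
#' @export
read_set_stats <- function(reads, k_est = 33L) {
  N <- length(reads)
  R <- if (N > 0) as.integer(round(mean(nchar(reads)))) else 0L
  stopifnot(N == 0 || k_est <= R)
  list(N = N, R = R, k_est = as.integer(k_est))
}

#' Estimate the target molecule length from the N50 kmer frequency
#'
#' Under uniform coverage of a repeat-free molecule with error-free reads,
#' every kmer occurs F = N * (R - k + 1) / M times, so M is recovered as
#' M = N * (R - k + 1) / F with the N50 kmer frequency substituted for F.
#' The interval `[Ml, Mu]` (default 50% and 200% of M) bounds the admissible
#' assembly length downstream.
#'
#' @param stats a [read_set_stats()] list (fields `N`, `R`, `k_est`).
#' @param f_n50 N50 kmer frequency (positive integer).
#' @param lower_frac,upper_frac fractions of M defining `Ml` and `Mu`.
#' @return a `length_estimate` list: `M`, `F_n50`, `Ml`, `Mu`, `lower_frac`,
#'   `upper_frac`.
#' @examples
#' estimate_length(list(N = 100, R = 110, k_est = 33), f_n50 = 10)
#' @export
estimate_length <- function(stats, f_n50, lower_frac = 0.5, upper_frac = 2.0) {
  if (is.null(f_n50) || length(f_n50) != 1 || is.na(f_n50) || f_n50 < 1)
    stopf("no reliable kmers: N50 kmer frequency is %s", format(f_n50),
          class = "anchorasm_no_reliable_kmers")
  stopifnot(lower_frac > 0, upper_frac >= lower_frac)
  M <- stats$N * (stats$R - stats$k_est + 1) / f_n50
  out <- list(M = M, F_n50 = as.integer(f_n50),
              Ml = lower_frac * M, Mu = upper_frac * M,
              lower_frac = lower_frac, upper_frac = upper_frac)
  class(out) <- "length_estimate"
  out
}

#' @export
print.length_estimate <- function(x, ...) {
  cat(sprintf("Length estimate: M = %.1f bp (F_n50 = %d), bounds [%.1f, %.1f]\n",
              x$M, x$F_n50, x$Ml, x$Mu))
  invisible(x)
}

#' One-call length estimation from reads
#'
#' Convenience wrapper: counts kmers, takes the N50 frequency, applies the
#' length formula.
#'
#' @inheritParams count_kmers
#' @inheritParams estimate_length
#' @return a `length_estimate`.
#' @export
estimate_length_from_reads <- function(reads, k = 33L,
                                       lower_frac = 0.5, upper_frac = 2.0) {
  stats <- read_set_stats(reads, k_est = k)
  hist <- count_kmers(reads, k = k)
  estimate_length(stats, n50_frequency(hist),
                  lower_frac = lower_frac, upper_frac = upper_frac)
}
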