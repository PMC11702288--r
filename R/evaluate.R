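#' Score an assembly against its ground-truth molecule
#'
#' Simplified reference-based evaluation for single-molecule assemblies
#' (<= a few kb). Each contig at least `min_contig` bp long is locally aligned
#' to the reference in both orientations (unit scoring: match +1, mismatch -2,
#' gap open -4, gap extend -1) and the better orientation kept. Metrics:
#' genome fraction percentage (GFP) — percent of reference positions covered
#' by the union of alignment reference spans; largest alignment ratio (LAR) —
#' the single largest alignment's contig span as a percent of total assembly
#' length; mismatches per kb and indel events per 100 kb, both over aligned
#' columns.
#'
#' @param assembly character vector of contig sequences.
#' @param reference the ground-truth DNA string.
#' @param min_contig drop contigs shorter than this (default 200 bp).
#' @return an `eval_report` list: `gfp`, `lar`, `mismatches_per_kb`,
#'   `indels_per_100kb`, `n_contigs`, `no_contigs` flag.
#' @export
align_and_score <- function(assembly, reference, min_contig = 200L) {
  stopifnot(nchar(reference) > 0)
  assembly <- assembly[nchar(assembly) >= min_contig]
  if (length(assembly) == 0) {
    return(structure(list(gfp = 0, lar = 0, mismatches_per_kb = 0,
                          indels_per_100kb = 0, n_contigs = 0L,
                          no_contigs = TRUE), class = "eval_report"))
  }
  ref <- Biostrings::DNAString(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)

  spans <- IRanges::IRanges()
  total_asm <- sum(nchar(assembly))
  largest_span <- 0
  mism <- 0
  indel_events <- 0
  aligned_cols <- 0

  for (ctg in assembly) {
    best <- NULL
    for (s in c(ctg, revcomp(ctg))) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(s), ref, type = "local",
        substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
      if (is.null(best) || Biostrings::score(aln) > Biostrings::score(best))
        best <- aln
    }
    pat <- Biostrings::pattern(best)  # contig side
    sub <- Biostrings::subject(best)  # reference side
    spans <- c(spans, IRanges::IRanges(Biostrings::start(sub),
                                       Biostrings::end(sub)))
    largest_span <- max(largest_span,
                        Biostrings::end(pat) - Biostrings::start(pat) + 1L)
    mism <- mism + Biostrings::nmismatch(best)
    ni <- Biostrings::nindel(best)
    indel_events <- indel_events +
      sum(Biostrings::insertion(ni)[, "Length"] > 0) +
      sum(Biostrings::deletion(ni)[, "Length"] > 0)
    aligned_cols <- aligned_cols + Biostrings::nchar(best)
  }

  covered <- sum(IRanges::width(IRanges::reduce(spans)))
  structure(list(
    gfp = 100 * covered / nchar(reference),
    lar = 100 * largest_span / total_asm,
    mismatches_per_kb = if (aligned_cols > 0) 1000 * mism / aligned_cols else 0,
    indels_per_100kb = if (aligned_cols > 0) 1e5 * indel_events / aligned_cols else 0,
    n_contigs = length(assembly),
    no_contigs = FALSE), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("GFP %.2f%%  LAR %.2f%%  mismatches/kb %.3f  indels/100kb %.3f  (%d contig%s)\n",
              x$gfp, x$lar, x$mismatches_per_kb, x$indels_per_100kb,
              x$n_contigs, if (x$n_contigs == 1) "" else "s"))
  invisible(x)
}

#' Global alignment identity between two sequences
#'
#' Percent identity of a global (Needleman-Wunsch) alignment: matches divided
#' by alignment columns, end gaps included — terminal truncation therefore
#' counts against identity.
#'
#' @param a,b DNA strings.
#' @return identity in percent.
#' @export
alignment_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = 4, gapExtension = 1)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  # the aligner leaves terminal overhangs out of its column count; fold the
  # unaligned sequence ends back into the denominator
  ov <- (nchar(a) - (Biostrings::end(pat) - Biostrings::start(pat) + 1L)) +
        (nchar(b) - (Biostrings::end(sub) - Biostrings::start(sub) + 1L))
  100 * Biostrings::nmatch(aln) / (Biostrings::nchar(aln) + ov)
}
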