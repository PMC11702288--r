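#' Simulation configuration for an anchored SLR read cloud
#'
#' Defaults mirror a LoopSeq-style library: 110 bp paired-end reads, 0.5%
#' uniform substitution error, fragment length Normal(250, 25) truncated to
#' [2 * read_len, template length]. `depth` is the nominal fold coverage of
#' the template reads are drawn from (conventional values 50, 100, 500, 3000).
#' Artifact regimes: `"read_through"` draws reads from the molecule
#' self-concatenated `rt_copies` times (circular-amplicon read-through);
#' `"repeat"` copies a random contiguous `repeat_frac` slice of the molecule
#' and inserts it back at a random interior position (the mutated molecule
#' becomes the ground truth); `"chimera"` splices `chimera_rate` of fragments
#' onto a second template.
#'
#' @param read_len read length in bp.
#' @param error_rate per-base substitution probability.
#' @param depth fold coverage of the template.
#' @param fragment_len_mean,fragment_len_sd fragment length distribution (bp).
#' @param artifact one of "none", "read_through", "repeat", "chimera".
#' @param rt_copies self-concatenation count for read-through (default 5).
#' @param repeat_frac fraction of the molecule copied in the repeat regime.
#' @param chimera_rate fraction of fragments forming inter-molecular chimeras.
#' @param layout `"fragment"` (paired-end fragments fully inside the template)
#'   or `"uniform"` (single reads at uniform start positions with circular
#'   wrap-around: the idealized uniform-coverage regime assumed by the length
#'   estimator).
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_len = 110L, error_rate = 0.005, depth = 500,
                       fragment_len_mean = 250, fragment_len_sd = 25,
                       artifact = c("none", "read_through", "repeat", "chimera"),
                       rt_copies = 5L, repeat_frac = 0.10, chimera_rate = 0.01,
                       layout = c("fragment", "uniform")) {
  artifact <- match.arg(artifact)
  layout <- match.arg(layout)
  stopifnot(error_rate >= 0, error_rate < 1, depth > 0, rt_copies >= 1,
            repeat_frac > 0, repeat_frac < 1)
  structure(list(read_len = as.integer(read_len), error_rate = error_rate,
                 depth = depth, fragment_len_mean = fragment_len_mean,
                 fragment_len_sd = fragment_len_sd, artifact = artifact,
                 rt_copies = as.integer(rt_copies), repeat_frac = repeat_frac,
                 chimera_rate = chimera_rate, layout = layout),
            class = "sim_config")
}

#' Build an anchored ground-truth molecule
#'
#' molecule = a_s + core + a_t. The core is drawn uniformly over A/C/G/T when
#' only a length is given.
#'
#' @param core_len core length in bp (ignored when `core_seq` given; >= 100).
#' @param core_seq explicit core sequence.
#' @param a_s,a_t anchor sequences (defaults: [default_anchors()]).
#' @param seed optional RNG seed for the random core.
#' @return a `ground_truth` list: `molecule`, `template` (initially equal),
#'   `a_s`, `a_t`, `artifact = "none"`.
#' @export
make_molecule <- function(core_len = NULL, core_seq = NULL,
                          a_s = default_anchors()[["start"]],
                          a_t = default_anchors()[["end"]],
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(core_seq)) {
    stopifnot(!is.null(core_len), core_len >= 100)
    core_seq <- random_dna(core_len)
  }
  mol <- paste0(toupper(a_s), toupper(core_seq), toupper(a_t))
  structure(list(molecule = mol, template = mol,
                 a_s = toupper(a_s), a_t = toupper(a_t), artifact = "none"),
            class = "ground_truth")
}

#' Apply an artifact regime to a ground-truth molecule
#'
#' `read_through`: the template becomes the molecule concatenated
#' `rt_copies` times (the molecule itself is unchanged and remains the
#' assembly target). `repeat`: a random contiguous `repeat_frac` slice is
#' reinserted at a random position strictly inside the core, mutating both
#' molecule and template — the repeat-bearing molecule is the new ground
#' truth. `none`/`chimera` leave the sequences untouched (chimeras act at
#' fragment sampling time).
#'
#' @param gt a `ground_truth`.
#' @param cfg a `sim_config`.
#' @return the updated `ground_truth`.
#' @export
apply_artifact <- function(gt, cfg) {
  gt$artifact <- cfg$artifact
  if (cfg$artifact == "read_through") {
    gt$template <- paste(rep(gt$molecule, cfg$rt_copies), collapse = "")
  } else if (cfg$artifact == "repeat") {
    n <- nchar(gt$molecule)
    rep_len <- max(1L, round(cfg$repeat_frac * n))
    src <- sample.int(n - rep_len + 1L, 1)
    slice <- substr(gt$molecule, src, src + rep_len - 1L)
    # insertion point strictly between the anchors so the molecule still
    # begins with a_s and ends with a_t
    lo <- nchar(gt$a_s) + 1L
    hi <- n - nchar(gt$a_t)
    at <- sample(lo:hi, 1)
    gt$molecule <- paste0(substr(gt$molecule, 1, at - 1L), slice,
                          substr(gt$molecule, at, n))
    gt$template <- gt$molecule
  }
  gt
}

# vectorised i.i.d. substitution errors preserving read length and alphabet
add_substitutions <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- which(runif(length(flat)) < rate)
  if (length(hit) > 0) {
    bases <- c("A", "C", "G", "T")
    # substitute with a uniformly chosen *different* base
    repl <- vapply(flat[hit], function(b) sample(setdiff(bases, b), 1), character(1))
    flat[hit] <- repl
  }
  grp <- rep.int(seq_along(lens), lens)
  unname(vapply(split(flat, grp), paste, character(1), collapse = ""))
}

#' Sample reads from a ground-truth template
#'
#' Fragment layout: `ceil(depth * len(template) / (2 * read_len))` fragments,
#' lengths Normal(mean, sd) truncated to [2 * read_len, len(template)], start
#' positions uniform; mate 1 is the fragment prefix, mate 2 the reverse
#' complement of the fragment suffix, each `read_len` long. Uniform layout:
#' `ceil(depth * len(template) / read_len)` single reads at uniform starts
#' with circular wrap-around (every position equally covered). Substitution
#' errors are applied i.i.d. at `error_rate`. In the chimera regime a
#' `chimera_rate` share of fragments splice a prefix of the template onto a
#' suffix of `chimera_partner` (junctions uniform in the middle 80% of each).
#'
#' @param gt a `ground_truth` (after [apply_artifact()]).
#' @param cfg a `sim_config`.
#' @param chimera_partner second template (DNA string) for `artifact="chimera"`.
#' @return list `reads1`, `reads2` (NULL for uniform layout), `provenance`
#'   data.frame (fragment start/length, chimeric flag).
#' @export
sample_reads <- function(gt, cfg, chimera_partner = NULL) {
  tmpl <- gt$template
  n <- nchar(tmpl)
  rl <- cfg$read_len

  if (cfg$layout == "uniform") {
    nr <- as.integer(ceiling(cfg$depth * n / rl))
    starts <- sample.int(n, nr, replace = TRUE)
    wrapped <- paste0(tmpl, substr(tmpl, 1, rl))
    reads <- substring(wrapped, starts, starts + rl - 1L)
    reads <- add_substitutions(reads, cfg$error_rate)
    return(list(reads1 = reads, reads2 = NULL,
                provenance = data.frame(start = starts, frag_len = rl,
                                        chimeric = FALSE)))
  }

  if (n < 2L * rl)
    stopf("template too short: %d bp < fragment minimum %d bp", n, 2L * rl,
          class = "anchorasm_template_too_short")
  nf <- as.integer(ceiling(cfg$depth * n / (2 * rl)))
  flen <- pmin(pmax(round(rnorm(nf, cfg$fragment_len_mean, cfg$fragment_len_sd)),
                    2L * rl), n)
  starts <- vapply(n - flen + 1L, function(m) sample.int(m, 1), integer(1))
  frags <- substring(tmpl, starts, starts + flen - 1L)

  chim <- rep(FALSE, nf)
  if (cfg$artifact == "chimera" && !is.null(chimera_partner)) {
    nb <- nchar(chimera_partner)
    chim <- runif(nf) < cfg$chimera_rate
    for (i in which(chim)) {
      ja <- sample(seq(round(0.1 * n), round(0.9 * n)), 1)
      jb <- sample(seq(round(0.1 * nb), round(0.9 * nb)), 1)
      fr <- paste0(substr(tmpl, max(1L, ja - flen[i] + 1L), ja),
                   substr(chimera_partner, jb, min(nb, jb + flen[i] - 1L)))
      if (nchar(fr) < 2L * rl) fr <- paste0(fr, substr(chimera_partner, 1, 2L * rl))
      frags[i] <- substr(fr, 1, flen[i])
    }
  }

  reads1 <- substr(frags, 1L, rl)
  reads2 <- revcomp(substring(frags, nchar(frags) - rl + 1L, nchar(frags)))
  reads1 <- add_substitutions(reads1, cfg$error_rate)
  reads2 <- add_substitutions(reads2, cfg$error_rate)
  list(reads1 = reads1, reads2 = reads2,
       provenance = data.frame(start = starts, frag_len = flen, chimeric = chim))
}

#' Simulate a complete anchored read cloud
#'
#' make molecule -> apply artifact -> sample reads, under one seed.
#'
#' @param core_len,core_seq,a_s,a_t see [make_molecule()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed (controls molecule, artifact placement and reads).
#' @param chimera_partner see [sample_reads()].
#' @return list `truth` (ground_truth), `reads1`, `reads2`, `provenance`.
#' @export
simulate_read_cloud <- function(core_len = 1500L, core_seq = NULL,
                                a_s = default_anchors()[["start"]],
                                a_t = default_anchors()[["end"]],
                                cfg = sim_config(), seed = NULL,
                                chimera_partner = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gt <- make_molecule(core_len = core_len, core_seq = core_seq,
                      a_s = a_s, a_t = a_t)
  gt <- apply_artifact(gt, cfg)
  rd <- sample_reads(gt, cfg, chimera_partner = chimera_partner)
  c(list(truth = gt), rd)
}

#' Write reads as FASTQ (optionally gzipped)
#'
#' Constant quality 'I'; deterministic bytes for identical input.
#'
#' @param reads character vector of reads.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @param prefix read-name prefix.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, prefix = "read") {
  qual <- vapply(nchar(reads), function(n) strrep("I", n), character(1))
  lines <- as.vector(rbind(sprintf("@%s_%d", prefix, seq_along(reads)),
                           reads, "+", qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read FASTQ (plain or gzip) into a character vector
#'
#' @param path FASTQ file path.
#' @return character vector of read sequences.
#' @export
read_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- names(seqs)
  if (is.null(nm)) nm <- sprintf("seq%d", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), unname(seqs))), path)
  invisible(path)
}

#' Read FASTA into a named character vector
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
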