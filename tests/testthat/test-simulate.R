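test_that("molecule construction concatenates anchors around the core", {
  gt <- make_molecule(core_seq = strrep("ACGT", 50))
  expect_equal(nchar(gt$molecule), 200 + 24)
  expect_true(startsWith(gt$molecule, default_anchors()[["start"]]))
  expect_true(endsWith(gt$molecule, default_anchors()[["end"]]))

  gt1 <- make_molecule(core_len = 500, seed = 99)
  gt2 <- make_molecule(core_len = 500, seed = 99)
  expect_identical(gt1$molecule, gt2$molecule)

  gt <- make_molecule(core_seq = "GATTACA", a_s = "AA", a_t = "TT")
  expect_equal(gt$molecule, "AAGATTACATT")
})

test_that("artifact regimes transform molecule and template as specified", {
  gt <- make_molecule(core_len = 1500, seed = 1)
  expect_equal(nchar(gt$molecule), 1524)

  rt <- apply_artifact(gt, sim_config(artifact = "read_through", rt_copies = 5))
  expect_equal(nchar(rt$template), 5 * 1524)
  expect_identical(rt$molecule, gt$molecule) # the target is unchanged

  set.seed(2)
  gt1k <- make_molecule(core_len = 976, seed = 3) # 1000 bp with anchors
  rep_gt <- apply_artifact(gt1k, sim_config(artifact = "repeat", repeat_frac = 0.10))
  expect_equal(nchar(rep_gt$molecule), 1100)
  expect_identical(rep_gt$template, rep_gt$molecule) # mutated truth
  expect_true(startsWith(rep_gt$molecule, default_anchors()[["start"]]))
  expect_true(endsWith(rep_gt$molecule, default_anchors()[["end"]]))

  none <- apply_artifact(gt, sim_config(artifact = "none"))
  expect_identical(none$template, none$molecule)
})

test_that("fragment counts and read geometry follow the coverage formula", {
  gt <- make_molecule(core_len = 1076, seed = 5) # 1100 bp
  cfg <- sim_config(depth = 50, error_rate = 0)
  set.seed(5)
  rd <- sample_reads(gt, cfg)
  expect_length(rd$reads1, ceiling(50 * 1100 / 220)) # 250 pairs
  expect_true(all(nchar(rd$reads1) == 110))
  expect_true(all(nchar(rd$reads2) == 110))

  # error-free reads are exact substrings (mate 2 reverse complemented)
  expect_true(all(vapply(rd$reads1[1:50], grepl, logical(1), x = gt$template,
                         fixed = TRUE)))
  expect_true(all(vapply(revcomp(rd$reads2[1:50]), grepl, logical(1),
                         x = gt$template, fixed = TRUE)))

  expect_error(sample_reads(make_molecule(core_seq = random_dna(150)), cfg),
               class = "anchorasm_template_too_short")
})

test_that("substitution process hits the nominal rate, alphabet and length", {
  gt <- make_molecule(core_len = 976, seed = 8)
  cfg <- sim_config(depth = 100, error_rate = 0.005)
  set.seed(88)
  rd <- sample_reads(gt, cfg)
  reads <- c(rd$reads1, rd$reads2)
  expect_false(any(grepl("[^ACGT]", reads)))
  expect_true(all(nchar(reads) == 110))
  # realized mismatch rate against the provenance-located template substring
  mism <- sum(vapply(seq_along(rd$reads1), function(i) {
    s <- rd$provenance$start[i]
    sum(utf8ToInt(rd$reads1[i]) !=
        utf8ToInt(substr(gt$template, s, s + 109)))
  }, numeric(1)))
  rate <- mism / (length(rd$reads1) * 110)
  expect_gt(rate, 0.004)
  expect_lt(rate, 0.006)
})

test_that("interior positions are fully covered at moderate depth", {
  # fragment sampling on a linear template necessarily leaves the first and
  # last few positions thinly covered (only fragments starting exactly at the
  # tip reach them); complete coverage is asserted for the interior, and for
  # every position under the uniform wrap-around layout
  ok_frag <- 0L; ok_unif <- 0L
  for (trial in 1:20) {
    cl <- simulate_read_cloud(core_len = 576, cfg = sim_config(depth = 100),
                              seed = 400 + trial)
    n <- nchar(cl$truth$molecule)
    cov <- integer(n)
    for (i in seq_along(cl$reads1)) {
      s <- cl$provenance$start[i]
      f <- cl$provenance$frag_len[i]
      cov[s:min(n, s + 109)] <- cov[s:min(n, s + 109)] + 1L
      e2 <- s + f - 1L
      cov[max(1, e2 - 109):min(n, e2)] <- cov[max(1, e2 - 109):min(n, e2)] + 1L
    }
    if (all(cov[110:(n - 110)] >= 1)) ok_frag <- ok_frag + 1L

    clu <- simulate_read_cloud(core_len = 576,
                               cfg = sim_config(depth = 100, layout = "uniform"),
                               seed = 500 + trial)
    covu <- integer(n)
    for (s in clu$provenance$start) {
      idx <- ((s - 1):(s + 108)) %% n + 1L
      covu[idx] <- covu[idx] + 1L
    }
    if (all(covu >= 1)) ok_unif <- ok_unif + 1L
  }
  expect_gte(ok_frag, 19L)
  expect_gte(ok_unif, 20L)
})

test_that("chimeric fragments splice in the partner template", {
  set.seed(12)
  gt <- make_molecule(core_len = 976, seed = 12)
  partner <- random_dna(1200)
  cfg <- sim_config(depth = 200, error_rate = 0, artifact = "chimera",
                    chimera_rate = 0.05)
  rd <- sample_reads(gt, cfg, chimera_partner = partner)
  expect_gt(sum(rd$provenance$chimeric), 0)
  i <- which(rd$provenance$chimeric)[1]
  # mate 2 of a chimeric fragment derives from the partner suffix
  expect_true(grepl(revcomp(rd$reads2[i]), partner, fixed = TRUE) ||
              grepl(rd$reads1[i], gt$template, fixed = TRUE))
})

test_that("identical seed and config give byte-identical FASTQ", {
  f1 <- tempfile(fileext = ".fastq.gz"); f2 <- tempfile(fileext = ".fastq.gz")
  for (f in c(f1, f2)) {
    cl <- simulate_read_cloud(core_len = 300, cfg = sim_config(depth = 50),
                              seed = 77)
    write_fastq(cl$reads1, f)
  }
  expect_identical(readLines(gzfile(f1)), readLines(gzfile(f2)))
  cl <- simulate_read_cloud(core_len = 300, cfg = sim_config(depth = 50), seed = 77)
  expect_identical(unname(read_fastq(f1)), cl$reads1)
  unlink(c(f1, f2))
})

test_that("uniform layout covers every position evenly including the tips", {
  cl <- simulate_read_cloud(core_len = 476,
                            cfg = sim_config(depth = 100, error_rate = 0,
                                             layout = "uniform"),
                            seed = 13)
  expect_null(cl$reads2)
  n <- nchar(cl$truth$molecule)
  # wrap-around reads cover position 1 from starts near the end as well
  cov1 <- sum(cl$provenance$start == 1 | cl$provenance$start > n - 109)
  expect_gt(cov1, 0)
})
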