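test_that("error-free pairs reconstruct the template with the right overlap", {
  set.seed(11)
  tmpl <- rand_seq(90, DNA)
  fwd <- substr(tmpl, 1, 60)
  rev <- revcomp(substr(tmpl, 41, 90)) # 50-mer, 20-base overlap with fwd
  m <- merge_read_pairs(fwd, rev, strrep("I", 60), strrep("I", 50))
  expect_true(m$joined)
  expect_identical(m$seq, tmpl)
  expect_identical(m$overlap, 20L)
  expect_identical(m$mismatches, 0L)
  expect_identical(nchar(m$seq), nchar(fwd) + nchar(rev) - m$overlap)
})

test_that("the 25% mismatch-rate ceiling is enforced on a 10-base overlap", {
  set.seed(12)
  core <- rand_seq(30, DNA)
  tail10 <- substr(core, 21, 30)
  make_rev <- function(n_sub) {
    ov <- if (n_sub > 0) mutate_seq(tail10, n_sub, DNA) else tail10
    revcomp(paste0(ov, rand_seq(20, DNA)))
  }
  ok <- merge_read_pairs(core, make_rev(2), strrep("I", 30), strrep("I", 30))
  expect_true(ok$joined) # 2/10 = 0.20 <= 0.25
  expect_identical(ok$overlap, 10L)
  expect_identical(ok$mismatches, 2L)
  bad <- merge_read_pairs(core, make_rev(3), strrep("I", 30), strrep("I", 30))
  expect_false(bad$joined) # 3/10 = 0.30 > 0.25
})

test_that("quality-aware overlap merging reconstructs noisy templates", {
  # 200 pairs fully covering their template; per-base substitutions at 0.005
  # are flagged by low quality, so the overlap vote recovers the template
  set.seed(13)
  n <- 200
  good <- 0
  for (i in seq_len(n)) {
    tmpl <- rand_seq(200, DNA)
    noisy <- function() {
      ch <- strsplit(tmpl, "", fixed = TRUE)[[1]]
      q <- rep(40L, 200)
      hit <- which(runif(200) < 0.005)
      for (p in hit) {
        ch[p] <- sample(setdiff(DNA, ch[p]), 1)
        q[p] <- 10L
      }
      list(seq = paste(ch, collapse = ""), qual = intToUtf8(33L + q))
    }
    f <- noisy()
    r <- noisy()
    m <- merge_read_pairs(f$seq, revcomp(r$seq), f$qual,
                          paste(rev(strsplit(r$qual, "")[[1]]), collapse = ""))
    if (isTRUE(m$joined) && identical(m$seq, tmpl)) good <- good + 1
  }
  expect_gte(good / n, 0.99)
})

test_that("disagreeing overlap bases take the higher-quality call", {
  tmpl <- strrep("ACGT", 10)
  fwd <- tmpl
  rev_seq <- substr(tmpl, 11, 40)
  ch <- strsplit(rev_seq, "", fixed = TRUE)[[1]]
  ch[5] <- setdiff(DNA, ch[5])[1] # error in the reverse mate
  q_rev <- rep(40L, 30); q_rev[5] <- 12L
  m <- merge_read_pairs(fwd, revcomp(paste(ch, collapse = "")),
                        strrep("I", 40),
                        intToUtf8(33L + rev(q_rev)))
  expect_identical(m$seq, tmpl) # forward Q40 beats reverse Q12
  q <- utf8ToInt(m$qual) - 33L
  expect_identical(q[15], 40L - 12L) # |q1 - q2| at the disagreement
})

test_that("mean-Phred and length gates discard exactly the stated reads", {
  q40 <- strrep(intToUtf8(33 + 40), 200)
  q30 <- strrep(intToUtf8(33 + 30), 200)
  expect_true(as.logical(quality_length_filter(strrep("A", 200), q40)))
  expect_false(as.logical(quality_length_filter(strrep("A", 200), q30)))
  f <- quality_length_filter(strrep("A", 149), strrep(intToUtf8(33 + 40), 149))
  expect_false(as.logical(f))
  expect_identical(attr(f, "reason"), "length")
  expect_true(as.logical(quality_length_filter(strrep("A", 150),
                                               strrep(intToUtf8(33 + 40), 150))))
})

test_that("orientation is idempotent, strand-symmetric and honors W degeneracy", {
  set.seed(14)
  for (w in c("T", "A")) { # FR4 primer W position: both A and T amplicons
    amp <- random_amplicon(40, fr4 = w)
    o1 <- orient_reads(amp)
    expect_identical(o1$status, "oriented")
    expect_identical(o1$seq, amp)
    o2 <- orient_reads(revcomp(amp))
    expect_identical(o2$seq, amp)
    expect_true(o2$flipped)
  }
  no <- orient_reads(rand_seq(100, DNA))
  expect_identical(no$status, "no_primer")
  partial <- orient_reads(paste0("GAGGTGCAGCTGGTGGAGTCT", rand_seq(100, DNA)))
  expect_identical(partial$status, "partial_amplicon")
})

test_that("translation validates frame and stops, and trims 7+7 residues", {
  set.seed(15)
  amp <- random_amplicon(106) # 360 nt
  tr <- translate_reads(amp)
  expect_identical(tr$status, "valid")
  expect_identical(nchar(tr$full), 120L)
  expect_identical(nchar(tr$trimmed), 106L)
  expect_true(startsWith(tr$full, "EVQLVES"))
  expect_identical(tr$trimmed, substr(tr$full, 8, 113))

  del1 <- paste0(substr(amp, 1, 150), substr(amp, 152, 360))
  expect_identical(translate_reads(del1)$status, "frameshift")

  stopamp <- amp
  substr(stopamp, 148, 150) <- "TAG" # codon 50
  expect_identical(translate_reads(stopamp)$status, "premature_stop")

  namp <- amp
  substr(namp, 90, 90) <- "N"
  expect_identical(translate_reads(namp)$status, "ambiguous")
})

test_that("every read pair is accounted for exactly once across stages", {
  truth <- simulate_repertoire(sim_config(
    n_lineages = 20, n_binders = 2, reads_per_sample = 2000, seed = 5))
  reads <- simulate_reads(truth)
  for (s in names(reads)) {
    pr <- process_reads(sample = s, reads = reads[[s]])
    cc <- pr$counts
    expect_identical(cc[["raw"]], cc[["joined"]] + cc[["unjoinable"]])
    expect_identical(cc[["joined"]], cc[["qc_pass"]] + cc[["qc_fail"]])
    expect_identical(cc[["qc_pass"]], cc[["oriented"]] + cc[["orient_fail"]])
    expect_identical(cc[["oriented"]],
                     cc[["validated"]] + cc[["frameshift"]] +
                     cc[["premature_stop"]] + cc[["ambiguous"]] +
                     cc[["too_short"]])
    # rejection log covers everything that did not validate
    expect_identical(nrow(pr$rejections) + cc[["validated"]], cc[["raw"]])
    expect_identical(anyDuplicated(c(pr$ids, pr$rejections$id)), 0L)
  }
})

test_that("error-free pairs round-trip to the template translation", {
  set.seed(16)
  for (i in 1:20) {
    amp <- random_amplicon(sample(40:110, 1))
    pair <- template_pair(amp, 250)
    pr <- process_reads(sample = "s", reads = list(
      id = "r1", fwd = pair$fwd, rev = pair$rev,
      fwd_qual = pair$qual, rev_qual = pair$qual))
    expect_identical(pr$counts[["validated"]], 1L)
    want <- as.character(Biostrings::translate(Biostrings::DNAString(amp)))
    expect_identical(pr$full, want)
    expect_identical(pr$trimmed, substr(want, 8, nchar(want) - 7))
  }
})

test_that("quality/length and primer/frame checks commute on pass/fail", {
  truth <- simulate_repertoire(sim_config(
    n_lineages = 10, n_binders = 1, reads_per_sample = 500, seed = 6,
    phred_profile = "decay"))
  reads <- simulate_reads(truth)$SEL
  m <- merge_read_pairs(reads$fwd, reads$rev, reads$fwd_qual, reads$rev_qual)
  m <- m[m$joined, ]
  qc <- as.logical(quality_length_filter(m$seq, m$qual))
  ori <- orient_reads(m$seq, m$qual)
  frame_ok <- rep(FALSE, nrow(m))
  ok <- ori$status == "oriented"
  frame_ok[ok] <- translate_reads(ori$seq[ok])$status == "valid"
  # valid set is the intersection whichever gate runs first
  expect_identical(which(qc & frame_ok), which(frame_ok & qc))
  pr <- process_reads(sample = "SEL", reads = reads)
  expect_identical(pr$counts[["validated"]], sum(qc & frame_ok))
})
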