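test_that("pairwise identity matches direct cases and the alignment oracle", {
  expect_identical(seq_identity("PEPTIDE", "PEPTIDE"), 1.0)
  expect_identical(seq_identity("ACDEFGHIKL", "ACDEFGHIKV"), 0.9)
  # adjacent swap: a gapped alignment beats the position-wise count (8/10)
  expect_identical(seq_identity("ACDEFGHIKL", "ACDEGFHIKL"), 0.9)
  expect_identical(seq_identity("ACDEFGHIKL", "ACDEGFHIKL"),
                   lcs_identity("ACDEFGHIKL", "ACDEGFHIKL"))
  expect_error(seq_identity("", "A"), "empty")

  set.seed(21)
  for (i in 1:100) {
    a <- rand_seq(sample(10:60, 1))
    b <- if (runif(1) < 0.5) mutate_seq(a, sample(1:6, 1)) else rand_seq(nchar(a))
    expect_equal(seq_identity(a, b), lcs_identity(a, b), tolerance = 1e-12)
    expect_equal(seq_identity(a, b), seq_identity(b, a))
  }
})

test_that("greedy clustering follows the representative-only comparison rule", {
  # identical peptides tally as one entry regardless of read count
  cl <- cluster_peptides(tally_from_peptides(list(s = rep("PEPTIDEPEP", 3))), 0.9)
  expect_identical(nrow(cl$representatives), 1L)
  expect_identical(cl$representatives$s, 3L)

  # B (1 mismatch vs A) joins A; C (3 mismatches vs A, len 20) founds its own
  # cluster even if closer to B, because only representatives are compared
  set.seed(22)
  A <- rand_seq(20)
  B <- mutate_seq(A, 1)
  chA <- strsplit(A, "", fixed = TRUE)[[1]]
  pos <- sample(20, 3)
  chC <- chA
  for (p in pos) chC[p] <- sample(setdiff(AA, chA[p]), 1)
  C <- paste(chC, collapse = "")
  stopifnot(seq_identity(A, C) < 0.9, seq_identity(B, C) <= 1)
  cl <- cluster_peptides(tally_from_peptides(
    list(s = c(rep(A, 5), rep(B, 2), C))), 0.9)
  reps <- cl$representatives
  expect_identical(nrow(reps), 2L)
  expect_identical(reps$peptide[1], A) # highest count founds first
  expect_setequal(cl$members$peptide[cl$members$cluster == 0], c(A, B))
  expect_identical(cl$members$peptide[cl$members$cluster == 1], C)
})

test_that("identity 1.0 reduces clustering to exact duplicates", {
  set.seed(23)
  peps <- replicate(30, rand_seq(15))
  cl <- cluster_peptides(tally_from_peptides(list(s = sample(rep(peps, 2)))), 1.0)
  expect_identical(nrow(cl$representatives), length(unique(peps)))
})

test_that("clustering recovers planted lineages at the working threshold", {
  set.seed(24)
  fam <- make_families(10, 10, len = 106, max_sub = 5) # <= 5% divergence
  cl <- cluster_peptides(tally_from_peptides(list(s = fam$peptides)), 0.9)
  expect_identical(nrow(cl$representatives), 10L)
  got <- split(cl$members$peptide, cl$members$cluster)
  want <- split(fam$peptides, fam$family)
  expect_identical(canon_partition(got), canon_partition(want))
})

test_that("the grid runs one independent clustering per threshold", {
  set.seed(25)
  fam <- make_families(6, 6, len = 40, max_sub = 2)
  grid <- cluster_grid(tally_from_peptides(list(s = fam$peptides)))
  expect_length(grid, 7L)
  expect_named(grid, c("0.70", "0.75", "0.80", "0.85", "0.90", "0.95", "1.00"))
  one <- cluster_grid("SINGLETONPEPTIDE", c(0.7, 0.9, 1.0))
  expect_true(all(vapply(one, function(cl) nrow(cl$representatives), integer(1)) == 1L))
  # cluster count never increases as the threshold loosens (on this fixture)
  counts <- vapply(grid, function(cl) nrow(cl$representatives), integer(1))
  expect_true(all(diff(counts) >= 0))
  expect_error(cluster_grid(fam$peptides, numeric(0)), "empty")
})

test_that("partition matches an independent naive reference implementation", {
  set.seed(26)
  for (case in 1:4) {
    fams <- make_families(sample(4:8, 1), sample(4:8, 1),
                          len = sample(c(25, 40), 1), max_sub = 4)
    peps <- unique(c(fams$peptides, replicate(40, rand_seq(sample(c(25, 40), 1)))))
    stopifnot(length(peps) <= 200)
    counts <- sample(1:60, length(peps), replace = TRUE)
    th <- sample(c(0.7, 0.8, 0.9, 1.0), 1)
    cl <- cluster_peptides(tally_from_peptides(list(s = rep(peps, counts))), th)
    got <- split(cl$members$peptide, cl$members$cluster)
    want <- naive_greedy(peps, counts, th)
    expect_identical(canon_partition(got), canon_partition(want))
  }
})

test_that("membership soundness, representative separation and count conservation", {
  set.seed(27)
  fam <- make_families(8, 8, len = 50, max_sub = 4)
  counts <- sample(1:30, length(fam$peptides), replace = TRUE)
  tal <- tally_from_peptides(list(
    x = rep(fam$peptides, counts),
    y = rep(rev(fam$peptides), rev(counts))))
  th <- 0.85
  cl <- cluster_peptides(tal, th)
  m <- cl$members
  rep_of <- setNames(cl$representatives$peptide, cl$representatives$cluster)
  # every member reaches the threshold against its representative, and the
  # stored identity is the exact alignment identity
  recomputed <- seq_identity(m$peptide, rep_of[as.character(m$cluster)])
  expect_equal(m$identity, recomputed, tolerance = 1e-12)
  expect_true(all(m$identity >= th - 1e-9))
  # any two equal-length representatives stay below the threshold
  reps <- cl$representatives
  for (i in seq_len(nrow(reps) - 1)) {
    same_len <- which(reps$length[-seq_len(i)] == reps$length[i]) + i
    if (length(same_len))
      expect_true(all(seq_identity(reps$peptide[i],
                                   reps$peptide[same_len]) < th))
  }
  # per-sample counts are conserved cluster-by-cluster and in total
  for (s in c("x", "y")) {
    expect_identical(sum(m[[s]]), as.integer(attr(tal, "sample_totals")[s]))
    expect_identical(as.integer(rowsum(m[[s]], m$cluster)[, 1]), reps[[s]])
  }
})

test_that("clustering and its report are byte-identical across runs", {
  set.seed(28)
  fam <- make_families(5, 8, len = 30, max_sub = 3)
  tal <- tally_from_peptides(list(s = rep(fam$peptides, 2)))
  cl1 <- cluster_peptides(tal, 0.9)
  cl2 <- cluster_peptides(tal, 0.9)
  expect_identical(cl1$members, cl2$members)
  f1 <- tempfile(fileext = ".clstr"); f2 <- tempfile(fileext = ".clstr")
  write_clstr(cl1, f1); write_clstr(cl2, f2)
  expect_identical(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  expect_match(readLines(f1)[1], "^>Cluster 0$")
})
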