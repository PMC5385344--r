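small_cfg <- function(seed = 61, ...) {
  sim_config(n_lineages = 20, n_binders = 2, variants_per_lineage = 5,
             reads_per_sample = 1500, seed = seed, ...)
}

test_that("the simulator is fully deterministic under the seed", {
  t1 <- simulate_repertoire(small_cfg())
  t2 <- simulate_repertoire(small_cfg())
  expect_identical(t1$variants, t2$variants)
  r1 <- simulate_reads(t1)
  r2 <- simulate_reads(t2)
  expect_identical(r1$SEL, r2$SEL)
  expect_identical(r1$CTRL, r2$CTRL)
  t3 <- simulate_repertoire(small_cfg(seed = 62))
  expect_false(identical(t1$lineages$founder, t3$lineages$founder))

  # written FASTQ is byte-identical across runs
  d1 <- tempfile(); d2 <- tempfile()
  simulate_reads(t1, dir = d1)
  simulate_reads(t2, dir = d2)
  f1 <- file.path(d1, "sample_SEL_R1.fastq.gz")
  f2 <- file.path(d2, "sample_SEL_R1.fastq.gz")
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("truth structure matches the configuration", {
  cfg <- small_cfg()
  truth <- simulate_repertoire(cfg)
  v <- truth$variants
  expect_identical(nrow(v), 20L * 5L)
  expect_identical(nchar(v$peptide), rep(106L, nrow(v)))
  expect_identical(nchar(v$dna), rep(360L, nrow(v)))
  # per-sample abundances are proper distributions
  expect_equal(sum(v$p_ctrl), 1)
  expect_equal(sum(v$p_sel), 1)
  # DNA templates translate to the full peptide
  got <- as.character(Biostrings::translate(Biostrings::DNAStringSet(v$dna[1:10])))
  expect_identical(got, v$full_peptide[1:10])

  one <- simulate_repertoire(sim_config(n_lineages = 1, n_binders = 0,
                                        variants_per_lineage = 1, seed = 9))
  expect_identical(nrow(one$variants), 1L)
})

test_that("variants stay within the configured divergence of their founder", {
  cfg <- small_cfg(intra_lineage_divergence = 0.05)
  truth <- simulate_repertoire(cfg)
  max_sub <- ceiling(0.05 * 106)
  for (i in seq_len(nrow(truth$variants))) {
    v <- truth$variants[i, ]
    founder <- truth$lineages$founder[v$lineage]
    d <- sum(strsplit(v$peptide, "")[[1]] != strsplit(founder, "")[[1]])
    expect_lte(d, max_sub)
  }
})

test_that("binder lineages realize the configured enrichment ratio", {
  truth <- simulate_repertoire(small_cfg(binder_enrichment = 50,
                                         binder_base_share = 0.01))
  l <- truth$lineages
  ratio <- l$sel_share / l$ctrl_share
  expect_equal(ratio[l$is_binder], rep(50, sum(l$is_binder)), tolerance = 1e-9)
  expect_true(all(ratio[!l$is_binder] < 1))
  expect_equal(sum(l$ctrl_share[l$is_binder]), 0.01)
  # infeasible combinations are refused up front
  expect_error(sim_config(binder_enrichment = 50, binder_base_share = 0.05),
               "infeasible")
})

test_that("every emitted read resolves in the provenance table", {
  reads <- simulate_reads(simulate_repertoire(small_cfg()))
  prov <- attr(reads, "provenance")
  for (s in c("SEL", "CTRL")) {
    expect_identical(length(reads[[s]]$id), 1500L)
    expect_true(all(reads[[s]]$id %in% prov$id))
  }
  expect_identical(anyDuplicated(prov$id), 0L)
  # drawn counts aggregate consistently with provenance
  counts <- attr(reads, "counts")
  expect_identical(sum(counts$SEL), 1500L)
  agg <- table(prov$key[prov$sample == "SEL"])
  expect_identical(as.integer(agg[counts$key[counts$SEL > 0]]),
                   counts$SEL[counts$SEL > 0])
})

test_that("selection reduces unique-sequence diversity when binders enrich", {
  # sampling-limited regime: far fewer reads than distinct variants would
  # need for saturation, so concentrating reads into binder lineages lowers
  # the unique fraction of the selection sample
  cfg <- sim_config(n_lineages = 150, n_binders = 15, variants_per_lineage = 8,
                    reads_per_sample = 3000, substitution_rate = 0,
                    frameshift_indel_rate = 0, premature_stop_rate = 0,
                    unjoinable_rate = 0, binder_enrichment = 50,
                    binder_base_share = 0.01, seed = 63)
  reads <- simulate_reads(simulate_repertoire(cfg))
  uf <- vapply(c("SEL", "CTRL"), function(s) {
    pr <- process_reads(sample = s, reads = reads[[s]])
    length(unique(pr$trimmed)) / length(pr$trimmed)
  }, numeric(1))
  expect_lt(uf[["SEL"]], uf[["CTRL"]])
})

test_that("injected frameshifts surface as frameshift rejections", {
  cfg <- sim_config(n_lineages = 15, n_binders = 1, variants_per_lineage = 4,
                    reads_per_sample = 4000, substitution_rate = 0,
                    frameshift_indel_rate = 0.1, premature_stop_rate = 0,
                    unjoinable_rate = 0, seed = 64)
  reads <- simulate_reads(simulate_repertoire(cfg))
  prov <- attr(reads, "provenance")
  pr <- process_reads(sample = "SEL", reads = reads$SEL)
  fs_flagged <- prov$id[prov$sample == "SEL" & prov$frameshift]
  fs_rejected <- pr$rejections$id[pr$rejections$reason == "frameshift"]
  # the injected per-read rate is recovered within binomial noise
  expect_equal(length(fs_flagged) / 4000, 0.1, tolerance = 0.02)
  # frameshift rejections trace back to injected indels...
  expect_true(all(fs_rejected %in% fs_flagged))
  # ...and most injected indels are caught at the translation stage (a few
  # fall inside a primer region and fail orientation instead)
  expect_gte(length(fs_rejected) / length(fs_flagged), 0.8)
  not_fs <- setdiff(pr$ids, fs_flagged)
  expect_identical(sum(pr$rejections$reason == "premature_stop"), 0L)
  expect_true(all(not_fs %in% prov$id))
})

test_that("injected premature stops surface as premature_stop rejections", {
  cfg <- sim_config(n_lineages = 15, n_binders = 1, variants_per_lineage = 4,
                    reads_per_sample = 2000, substitution_rate = 0,
                    frameshift_indel_rate = 0, premature_stop_rate = 0.1,
                    unjoinable_rate = 0, seed = 65)
  reads <- simulate_reads(simulate_repertoire(cfg))
  prov <- attr(reads, "provenance")
  pr <- process_reads(sample = "CTRL", reads = reads$CTRL)
  stop_flagged <- prov$id[prov$sample == "CTRL" & prov$stop]
  stop_rejected <- pr$rejections$id[pr$rejections$reason == "premature_stop"]
  expect_true(all(stop_rejected %in% stop_flagged))
  expect_gte(length(stop_rejected) / length(stop_flagged), 0.8)
})

test_that("unjoinable mates are rejected at the merge stage", {
  cfg <- sim_config(n_lineages = 15, n_binders = 1, variants_per_lineage = 4,
                    reads_per_sample = 2000, substitution_rate = 0,
                    frameshift_indel_rate = 0, premature_stop_rate = 0,
                    unjoinable_rate = 0.1, seed = 66)
  reads <- simulate_reads(simulate_repertoire(cfg))
  prov <- attr(reads, "provenance")
  pr <- process_reads(sample = "SEL", reads = reads$SEL)
  unj_flagged <- prov$id[prov$sample == "SEL" & prov$unjoinable]
  unj_rejected <- pr$rejections$id[pr$rejections$reason == "unjoinable"]
  expect_equal(length(unj_rejected), length(unj_flagged), tolerance = 0.05)
  expect_gte(mean(unj_rejected %in% unj_flagged), 0.99)
})
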