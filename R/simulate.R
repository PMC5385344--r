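#' Simulation configuration for a two-sample phage-display NGS experiment
#'
#' Defines the ground-truth repertoire and error model the simulator
#' emulates: clonal lineages shared by a selection and a negative-control
#' sample, selection-driven enrichment of a binder subset, heavy-tailed
#' abundances, and PCR/sequencing errors (substitutions, frameshift indels,
#' premature stops, unjoinable pairs).
#'
#' `binder_enrichment` is the realized per-lineage selection:control
#' abundance ratio: binder lineages jointly occupy `binder_base_share` of the
#' control sample and `binder_base_share * binder_enrichment` of the
#' selection sample (background lineages renormalized), so
#' `binder_base_share * binder_enrichment` must stay below 1.
#'
#' @param n_lineages number of clonal lineages.
#' @param n_binders number of binder lineages (must not exceed
#'   `n_lineages`).
#' @param variants_per_lineage clonal variants per lineage (the founder
#'   included).
#' @param intra_lineage_divergence maximum fraction of residues a variant may
#'   differ from its founder (each variant draws 1..ceiling(d*L)
#'   substitutions).
#' @param scaffold_len nanobody length in residues including the 7+7
#'   primer-encoded flanks.
#' @param binder_enrichment selection:control abundance ratio of binder
#'   lineages.
#' @param binder_base_share aggregate share of the control sample held by
#'   binder lineages (binders are rare before selection).
#' @param reads_per_sample read pairs emitted per sample.
#' @param substitution_rate per-base substitution rate per mate.
#' @param frameshift_indel_rate per-read probability of a 1-nt indel.
#' @param premature_stop_rate per-read probability of an injected internal
#'   stop codon.
#' @param unjoinable_rate per-read probability that the reverse mate is
#'   unrelated (cannot be overlap-merged).
#' @param read_len mate length in bases.
#' @param abundance_law `"lognormal"` (default) or `"zipf"`.
#' @param abundance_sdlog log-sd of the lineage abundance law.
#' @param phred_profile `"constant"` (Q40 everywhere) or `"decay"` (linear
#'   3' decay to Q20, so the mean-Phred filter is exercisable both ways).
#' @param sample_names labels for the selection/control samples.
#' @param seed integer seed; everything the simulator emits is reproducible
#'   given the seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_lineages = 440L, n_binders = 40L,
                       variants_per_lineage = 10L,
                       intra_lineage_divergence = 0.05,
                       scaffold_len = 120L,
                       binder_enrichment = 50,
                       binder_base_share = 0.01,
                       reads_per_sample = 2e5,
                       substitution_rate = 0.005,
                       frameshift_indel_rate = 0.02,
                       premature_stop_rate = 0.01,
                       unjoinable_rate = 0.05,
                       read_len = 250L,
                       abundance_law = c("lognormal", "zipf"),
                       abundance_sdlog = 1.25,
                       phred_profile = c("constant", "decay"),
                       sample_names = c(sel = "SEL", ctrl = "CTRL"),
                       seed = 1L) {
  rates <- c(intra_lineage_divergence, substitution_rate,
             frameshift_indel_rate, premature_stop_rate, unjoinable_rate)
  if (any(rates < 0 | rates > 1)) stop_input("rates must be in [0, 1]")
  if (n_binders > n_lineages)
    stop_input("n_binders must not exceed n_lineages")
  if (n_binders > 0L && binder_base_share * binder_enrichment >= 1)
    stop_input("infeasible enrichment: binder_base_share * binder_enrichment must be < 1")
  structure(list(
    n_lineages = as.integer(n_lineages), n_binders = as.integer(n_binders),
    variants_per_lineage = as.integer(variants_per_lineage),
    intra_lineage_divergence = intra_lineage_divergence,
    scaffold_len = as.integer(scaffold_len),
    binder_enrichment = binder_enrichment,
    binder_base_share = binder_base_share,
    reads_per_sample = as.integer(reads_per_sample),
    substitution_rate = substitution_rate,
    frameshift_indel_rate = frameshift_indel_rate,
    premature_stop_rate = premature_stop_rate,
    unjoinable_rate = unjoinable_rate,
    read_len = as.integer(read_len),
    abundance_law = match.arg(abundance_law),
    abundance_sdlog = abundance_sdlog,
    phred_profile = match.arg(phred_profile),
    sample_names = sample_names, seed = as.integer(seed)),
    class = "sim_config")
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# synonymous codons per residue, standard genetic code, stops excluded
codons_by_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[AA20]
}

fr4_tail_dna <- function(variant) {
  w <- if (variant == "L") "T" else "A"
  paste0("ACCC", w, "GGTCACCGTCTCCTCA")
}

# interior positions (1-based) of the three CDR-like hypervariable windows
cdr_windows <- function(interior_len) {
  at <- function(fr, w) {
    s <- max(1L, round(interior_len * fr))
    s:min(interior_len, s + w - 1L)
  }
  unique(c(at(0.18, 8L), at(0.42, 10L), at(0.76, 16L)))
}

#' Simulate a ground-truth nanobody repertoire
#'
#' Generates lineage founder peptides on a shared framework scaffold with
#' randomized CDR-like hypervariable windows (so unrelated lineages sit near
#' ~70% identity, as real nanobody framework conservation does), clonal
#' variants by point substitutions within the stated divergence, a
#' DNA template per variant (random synonymous codons between the fixed
#' FR1-primer and FR4-primer ends), and heavy-tailed per-sample abundances
#' with binder lineages enriched in the selection sample.
#'
#' @param config a [sim_config()].
#' @param max_retries regenerations allowed when founder lineages collide
#'   (any inter-lineage identity at or above 0.95).
#' @return An object of class `nb_sim_truth`: list with `config`, `lineages`
#'   (data frame: `lineage`, `is_binder`, `fr4`, `founder`, `ctrl_share`,
#'   `sel_share`) and `variants` (data frame: `key`, `lineage`, `variant`,
#'   `peptide` (trimmed interior), `full_peptide`, `dna` (full amplicon),
#'   `is_binder`, `p_ctrl`, `p_sel`).
#' @export
simulate_repertoire <- function(config = sim_config(), max_retries = 5L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$scaffold_len - 14L
  if (L < 20L) stop_input("scaffold too short")
  nl <- config$n_lineages
  windows <- cdr_windows(L)

  founders <- NULL
  for (try in seq_len(max_retries)) {
    framework <- sample(AA20, L, replace = TRUE)
    f <- vapply(seq_len(nl), function(i) {
      x <- framework
      x[windows] <- sample(AA20, length(windows), replace = TRUE)
      drift <- setdiff(which(runif(L) < 0.02), windows)
      if (length(drift)) x[drift] <- sample(AA20, length(drift), replace = TRUE)
      paste(x, collapse = "")
    }, character(1))
    if (nl < 2L || !.any_identity_ge_cpp(f, 0.95)) { founders <- f; break }
  }
  if (is.null(founders))
    stop_input("lineage founders kept colliding (identity >= 0.95) after ",
               max_retries, " attempts")

  is_binder <- seq_len(nl) <= config$n_binders
  fr4 <- sample(c("L", "Q"), nl, replace = TRUE)
  cba <- codons_by_aa()
  max_sub <- max(1L, ceiling(config$intra_lineage_divergence * L))
  k <- config$variants_per_lineage

  sample_codons <- function(aa_chars)
    vapply(aa_chars, function(a) sample(cba[[a]], 1L), character(1),
           USE.NAMES = FALSE)

  var_rows <- vector("list", nl)
  for (i in seq_len(nl)) {
    faa <- strsplit(founders[i], "", fixed = TRUE)[[1]]
    fcod <- sample_codons(faa)
    peptides <- character(k); dnas <- character(k)
    for (v in seq_len(k)) {
      aa <- faa; cod <- fcod
      if (v > 1L) {
        ns <- sample.int(max_sub, 1L)
        pos <- sample.int(L, ns)
        for (p in pos) {
          aa[p] <- sample(setdiff(AA20, aa[p]), 1L)
          cod[p] <- sample(cba[[aa[p]]], 1L)
        }
      }
      peptides[v] <- paste(aa, collapse = "")
      dnas[v] <- paste0("GAGGTGCAGCTGGTGGAGTCT", paste(cod, collapse = ""),
                        fr4_tail_dna(fr4[i]))
    }
    # founder dominates its clonal expansion; variant weights heavy-tailed
    w <- rlnorm(k, 0, 0.8)
    w[1] <- w[1] * 4
    var_rows[[i]] <- data.frame(
      key = sprintf("L%03dV%02d", i, seq_len(k)),
      lineage = i, variant = seq_len(k), peptide = peptides, dna = dnas,
      is_binder = is_binder[i], vfrac = w / sum(w),
      stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, var_rows)

  # lineage abundances: heavy-tailed within each block (binder/background);
  # binders jointly take binder_base_share of the control and
  # binder_base_share * binder_enrichment of the selection sample
  w <- switch(config$abundance_law,
    lognormal = rlnorm(nl, 0, config$abundance_sdlog),
    zipf = (1 / seq_len(nl))[sample.int(nl)])
  b0 <- if (config$n_binders > 0L) config$binder_base_share else 0
  b1 <- b0 * config$binder_enrichment
  ctrl_share <- sel_share <- numeric(nl)
  if (config$n_binders > 0L) {
    wb <- w[is_binder] / sum(w[is_binder])
    ctrl_share[is_binder] <- b0 * wb
    sel_share[is_binder] <- b1 * wb
  }
  if (any(!is_binder)) {
    wn <- w[!is_binder] / sum(w[!is_binder])
    ctrl_share[!is_binder] <- (1 - b0) * wn
    sel_share[!is_binder] <- (1 - b1) * wn
  }
  lineages <- data.frame(lineage = seq_len(nl), is_binder = is_binder,
                         fr4 = fr4, founder = founders,
                         ctrl_share = ctrl_share, sel_share = sel_share,
                         stringsAsFactors = FALSE)
  variants$p_ctrl <- ctrl_share[variants$lineage] * variants$vfrac
  variants$p_sel <- sel_share[variants$lineage] * variants$vfrac
  variants$full_peptide <- paste0("EVQLVES", variants$peptide,
                                  "T", fr4[variants$lineage], "VTVSS")
  variants$vfrac <- NULL
  structure(list(config = config, lineages = lineages, variants = variants),
            class = "nb_sim_truth")
}

#' @export
print.nb_sim_truth <- function(x, ...) {
  cat(sprintf("Simulated repertoire: %d lineages (%d binders) x %d variants, seed %d\n",
              x$config$n_lineages, x$config$n_binders,
              x$config$variants_per_lineage, x$config$seed))
  invisible(x)
}

#' Ground-truth majority peptide per lineage
#'
#' Column-wise majority vote over a lineage's true variant peptides,
#' weighted by the true per-variant abundance in the chosen sample. This is
#' what an error-free, abundance-weighted consensus of a pure lineage
#' cluster should reproduce.
#'
#' @param truth an `nb_sim_truth`.
#' @param sample `"sel"` or `"ctrl"`.
#' @return Character vector of majority peptides, named by lineage.
#' @export
truth_consensus <- function(truth, sample = c("sel", "ctrl")) {
  sample <- match.arg(sample)
  wcol <- if (sample == "sel") "p_sel" else "p_ctrl"
  v <- truth$variants
  out <- vapply(split(seq_len(nrow(v)), v$lineage), function(ix) {
    majority_consensus(v$peptide[ix], v[[wcol]][ix],
                       representative = v$peptide[ix][which.max(v[[wcol]][ix])]
                       )$consensus
  }, character(1))
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

qual_string <- function(len, profile, q_high = 40L, q_low = 20L) {
  q <- if (profile == "constant") rep(q_high, len)
       else round(seq(q_high, q_low, length.out = len))
  intToUtf8(33L + q)
}

#' Simulate selection and sequencing: paired FASTQ for both samples
#'
#' Draws each sample's reads multinomially from the truth abundances,
#' injects errors (per-mate substitutions; per-read 1-nt frameshift indels,
#' premature stop codons, unjoinable reverse mates) at the configured rates,
#' fragments each amplicon into overlapping paired mates, and optionally
#' writes gzipped FASTQ plus truth tables. Every read id encodes its truth
#' key (`sample|index|lineage-variant key`), so any emitted read resolves in
#' the provenance table.
#'
#' @param truth an `nb_sim_truth` from [simulate_repertoire()].
#' @param dir optional output directory; when given, writes
#'   `sample_<NAME>_R1.fastq.gz` / `_R2.fastq.gz` per sample plus
#'   `truth_variants.tsv` and `truth_provenance.tsv`.
#' @return A list of class `nb_sim_reads` with one element per sample
#'   (named as in the config), each a list `id`, `fwd`, `rev`, `fwd_qual`,
#'   `rev_qual`; plus attributes `provenance` (data frame: `id`, `sample`,
#'   `lineage`, `variant`, `key`, `n_sub_fwd`, `n_sub_rev`, `frameshift`,
#'   `stop`, `unjoinable`), `counts` (true reads drawn per variant and
#'   sample) and `files` (paths, when written).
#' @export
simulate_reads <- function(truth, dir = NULL) {
  stopifnot(inherits(truth, "nb_sim_truth"))
  cfg <- truth$config
  if (cfg$reads_per_sample <= 0L) stop_input("reads_per_sample must be positive")
  set.seed(cfg$seed + 1L)
  v <- truth$variants
  samples <- cfg$sample_names
  out <- list()
  prov <- list()
  counts_tab <- list()
  files <- character()

  for (role in names(samples)) {
    sname <- samples[[role]]
    p <- if (role == "sel") v$p_sel else v$p_ctrl
    cnt <- as.integer(rmultinom(1, cfg$reads_per_sample, p))
    counts_tab[[role]] <- cnt
    idx <- rep.int(seq_len(nrow(v)), cnt)
    n <- length(idx)
    amp <- v$dna[idx]

    stop_hit <- runif(n) < cfg$premature_stop_rate
    for (i in which(stop_hit)) {
      ncod <- nchar(amp[i]) %/% 3L
      cpos <- sample(8:(ncod - 8L), 1L) # internal codon
      substr(amp[i], 3L * cpos - 2L, 3L * cpos) <- sample(c("TAA", "TAG", "TGA"), 1L)
    }
    fs_hit <- runif(n) < cfg$frameshift_indel_rate
    for (i in which(fs_hit)) {
      pos <- sample.int(nchar(amp[i]) - 2L, 1L) + 1L
      if (runif(1) < 0.5) {
        amp[i] <- paste0(substr(amp[i], 1L, pos - 1L),
                         substr(amp[i], pos + 1L, nchar(amp[i])))
      } else {
        amp[i] <- paste0(substr(amp[i], 1L, pos - 1L),
                         sample(c("A", "C", "G", "T"), 1L),
                         substr(amp[i], pos, nchar(amp[i])))
      }
    }

    alen <- nchar(amp)
    rl <- pmin(cfg$read_len, alen)
    fwd <- substr(amp, 1L, rl)
    rev_raw <- substr(amp, alen - rl + 1L, alen)
    rev <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(rev_raw)))

    sub_f <- .inject_substitutions_cpp(fwd, cfg$substitution_rate)
    sub_r <- .inject_substitutions_cpp(rev, cfg$substitution_rate)
    fwd <- sub_f$seq; rev <- sub_r$seq

    # amplicons enter the sequencer on either strand with equal probability;
    # swapping the mates emits the merged read on the opposite strand
    flip <- runif(n) < 0.5
    if (any(flip)) {
      tmp <- fwd[flip]; fwd[flip] <- rev[flip]; rev[flip] <- tmp
    }

    unj <- runif(n) < cfg$unjoinable_rate
    if (any(unj))
      rev[unj] <- random_dna(sum(unj), cfg$read_len)

    id <- sprintf("%s_%07d|%s", sname, seq_len(n), v$key[idx])
    qlen <- sort(unique(c(nchar(fwd), nchar(rev))))
    qmap <- setNames(vapply(qlen, qual_string, character(1),
                            profile = cfg$phred_profile), qlen)
    out[[sname]] <- list(id = id, fwd = fwd, rev = rev,
                         fwd_qual = unname(qmap[as.character(nchar(fwd))]),
                         rev_qual = unname(qmap[as.character(nchar(rev))]))
    prov[[sname]] <- data.frame(
      id = id, sample = sname, lineage = v$lineage[idx],
      variant = v$variant[idx], key = v$key[idx],
      n_sub_fwd = sub_f$n_sub, n_sub_rev = sub_r$n_sub,
      frameshift = fs_hit, stop = stop_hit, unjoinable = unj,
      stringsAsFactors = FALSE)

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      r1 <- file.path(dir, sprintf("sample_%s_R1.fastq.gz", sname))
      r2 <- file.path(dir, sprintf("sample_%s_R2.fastq.gz", sname))
      write_fastq(id, out[[sname]]$fwd, out[[sname]]$fwd_qual, r1)
      write_fastq(id, out[[sname]]$rev, out[[sname]]$rev_qual, r2)
      files <- c(files, setNames(c(r1, r2),
                                 paste0(sname, c("_R1", "_R2"))))
    }
  }
  counts <- data.frame(key = v$key, lineage = v$lineage, variant = v$variant,
                       stringsAsFactors = FALSE)
  for (role in names(samples)) counts[[samples[[role]]]] <- counts_tab[[role]]
  provenance <- do.call(rbind, unname(prov))
  rownames(provenance) <- NULL
  if (!is.null(dir)) {
    write_tsv(truth$variants, file.path(dir, "truth_variants.tsv"))
    write_tsv(provenance, file.path(dir, "truth_provenance.tsv"))
    files <- c(files, variants = file.path(dir, "truth_variants.tsv"),
               provenance = file.path(dir, "truth_provenance.tsv"))
  }
  structure(out, provenance = provenance, counts = counts, files = files,
            class = "nb_sim_reads")
}

#' Score a pipeline run against simulation ground truth
#'
#' For every binder lineage planted by the simulator, locates its cluster in
#' a pipeline run (the cluster containing the lineage's founder peptide),
#' checks whether that cluster was selected as a candidate, and compares the
#' candidate's abundance-weighted consensus with the lineage's true majority
#' peptide (see [truth_consensus()]); a consensus also counts as exact when
#' it equals the founder itself.
#'
#' @param run an `nb_run` from [run_pipeline()] on reads simulated from
#'   `truth`.
#' @param truth the `nb_sim_truth` the reads were simulated from.
#' @return A list: `n_binders`, `n_recovered` (binder lineages whose cluster
#'   is a candidate), `recall`, `consensus_exact` (fraction of recovered
#'   binder clusters whose consensus equals the truth majority or founder),
#'   and `n_candidates` (total candidate clusters in the run).
#' @export
binder_recovery <- function(run, truth) {
  stopifnot(inherits(run, "nb_run"), inherits(truth, "nb_sim_truth"))
  lin <- truth$lineages
  binders <- lin$lineage[lin$is_binder]
  v <- truth$variants
  founders <- v$peptide[v$variant == 1L][match(binders,
                                               v$lineage[v$variant == 1L])]
  m <- run$clusters$members
  cl_of <- m$cluster[match(founders, m$peptide)]
  in_cand <- !is.na(cl_of) & cl_of %in% run$candidates$cluster
  tc <- truth_consensus(truth, "sel")[as.character(binders)]
  cons <- run$consensus$consensus_trimmed[match(cl_of,
                                                run$consensus$cluster)]
  exact <- !is.na(cons) & (cons == tc | cons == founders)
  list(n_binders = length(binders),
       n_recovered = sum(in_cand),
       recall = if (length(binders)) mean(in_cand) else NA_real_,
       consensus_exact = if (any(in_cand)) mean(exact[in_cand]) else NA_real_,
       n_candidates = nrow(run$candidates))
}
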