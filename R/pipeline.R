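#' Run the full mining pipeline: process, cluster, enrich, consensus
#'
#' Orchestrates the end-to-end analysis for a selection/control sample pair:
#' per-sample read processing, pooled peptide tally, greedy clustering at the
#' working identity threshold, cross-sample enrichment with candidate
#' selection, and majority-rule consensus building for the candidates. All
#' stages are deterministic, so identical inputs and configuration give
#' byte-identical outputs.
#'
#' @param config a list (or path to a YAML file with the same structure)
#'   with elements:
#'   \describe{
#'     \item{samples}{named list: per sample, a list with `r1`/`r2` FASTQ
#'       paths or an in-memory `reads` list (see [process_reads()]).}
#'     \item{sel, ctrl}{names of the selection and control samples.}
#'     \item{identity}{clustering identity threshold (default 0.9).}
#'     \item{min_size, min_ef}{candidate gates (default 10, 10).}
#'     \item{min_mean_phred, min_len, min_overlap, max_mismatch_rate,
#'       max_primer_mismatches}{read-processing parameters (defaults 38,
#'       150, 10, 0.25, 0).}
#'     \item{weighting, fr4_variant}{consensus options (defaults "reads",
#'       "L").}
#'     \item{selection_output_size}{optional named numeric, phage output
#'       sizes (cfu) per sample, reported in the run summary when given.}
#'     \item{outdir}{optional output directory; when present all standard
#'       artifacts are written there.}
#'   }
#' @param quiet suppress stage messages.
#' @return An object of class `nb_run`: list with `processed` (per sample),
#'   `tally`, `clusters`, `enrichment`, `candidates`, `consensus`,
#'   `manifest` and `files`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$samples) || length(config$samples) < 2L)
    stop_input("config must define at least two samples")
  sel <- config$sel %||% names(config$samples)[1]
  ctrl <- config$ctrl %||% names(config$samples)[2]
  say <- function(...) if (!quiet) message(...)

  processed <- list()
  for (s in names(config$samples)) {
    cs <- config$samples[[s]]
    say("processing sample ", s)
    processed[[s]] <- process_reads(
      r1 = cs$r1, r2 = cs$r2, sample = s, reads = cs$reads,
      min_overlap = config$min_overlap %||% 10L,
      max_mismatch_rate = config$max_mismatch_rate %||% 0.25,
      min_mean_phred = config$min_mean_phred %||% 38,
      min_len = config$min_len %||% 150L,
      max_primer_mismatches = config$max_primer_mismatches %||% 0L)
    say("  validated ", processed[[s]]$counts[["validated"]], " of ",
        processed[[s]]$counts[["raw"]], " read pairs")
  }
  tally <- peptide_tally(processed)
  say("pooled tally: ", nrow(tally), " unique peptides")

  identity <- config$identity %||% 0.9
  clusters <- cluster_peptides(tally, identity)
  say("clustered at ", identity, ": ", nrow(clusters$representatives),
      " clusters")

  enrichment <- enrich_clusters(clusters, sel = sel, ctrl = ctrl,
                                min_size = config$min_size %||% 10,
                                min_ef = config$min_ef %||% 10)
  cand <- candidates(enrichment)
  say(nrow(cand), " candidate clusters")

  consensus <- if (nrow(cand) > 0L)
    consensus_sequences(clusters, ids = cand$cluster,
                        weighting = config$weighting %||% "reads",
                        sample = sel,
                        fr4_variant = config$fr4_variant %||% "L")
  else NULL

  manifest <- build_manifest(processed, tally, clusters, enrichment, config)
  files <- character()
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$outdir, f)
    write_tally(tally, tsv = p("tally.tsv"), fasta = p("peptides.fasta"))
    write_clusters(clusters, tsv = p("clusters.tsv"),
                   fasta = p("representatives.fasta"))
    write_clstr(clusters, p("clusters.clstr"))
    write_enrichment(enrichment, p("enrichment.tsv"), p("candidates.tsv"))
    if (!is.null(consensus))
      write_consensus(consensus, p("consensus_peptides.fasta"),
                      p("consensus_dna.fasta"), p("consensus_support.tsv"))
    rej <- do.call(rbind, lapply(unname(processed), function(x)
      if (nrow(x$rejections)) cbind(sample = x$sample, x$rejections) else NULL))
    if (is.null(rej))
      rej <- data.frame(sample = character(), id = character(),
                        stage = character(), reason = character())
    write_tsv(rej, p("rejected_reads.tsv"))
    yaml::write_yaml(manifest, p("manifest.yaml"))
    files <- list.files(config$outdir, full.names = TRUE)
  }
  structure(list(processed = processed, tally = tally, clusters = clusters,
                 enrichment = enrichment, candidates = cand,
                 consensus = consensus, manifest = manifest, files = files),
            class = "nb_run")
}

build_manifest <- function(processed, tally, clusters, enrichment, config) {
  per_sample <- lapply(processed, function(x) {
    cc <- as.list(x$counts)
    s <- x$sample
    cc$unique <- sum(tally[[s]] > 0L)
    cc$joinable_pct <- round_half_up(100 * cc$joined / cc$raw)
    cc$unique_pct <- round_half_up(100 * cc$unique / cc$validated)
    sos <- config$selection_output_size[[s]]
    if (!is.null(sos))
      cc$unique_per_output_pct <- round_half_up(100 * cc$unique / sos)
    cc
  })
  list(tool = "nbmine",
       version = as.character(utils::packageVersion("nbmine")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       parameters = list(
         identity = config$identity %||% 0.9,
         min_size = config$min_size %||% 10,
         min_ef = config$min_ef %||% 10,
         min_mean_phred = config$min_mean_phred %||% 38,
         min_len = config$min_len %||% 150,
         norm_factor = attr(enrichment, "norm_factor")),
       samples = per_sample,
       clusters = list(n = nrow(clusters$representatives),
                       n_candidates = sum(enrichment$is_candidate)))
}

#' Processing summary table (raw counts and derived percentages)
#'
#' Per-sample summary of the read-processing chain: raw and joined pair
#' counts, joinable fraction, full-length (validated) and unique sequence
#' counts, the unique fraction, and (when selection output sizes were
#' configured) unique sequences per selection output size. Percentages are
#' always recomputed from the integer counts, rounded half-up.
#'
#' @param run an `nb_run` from [run_pipeline()].
#' @return A data frame, metrics as rows and samples as columns.
#' @export
report_table1 <- function(run) {
  stopifnot(inherits(run, "nb_run"))
  ms <- run$manifest$samples
  metrics <- c("raw", "joined", "joinable_pct", "validated", "unique",
               "unique_pct")
  if (any(vapply(ms, function(x) !is.null(x$unique_per_output_pct), logical(1))))
    metrics <- c(metrics, "unique_per_output_pct")
  out <- data.frame(metric = c(
    raw = "Raw reads (counts)", joined = "Joined reads (counts)",
    joinable_pct = "Joinable fraction (%)",
    validated = "Full-length nanobody sequences (counts)",
    unique = "Unique sequences (counts)",
    unique_pct = "Fraction unique sequences (%)",
    unique_per_output_pct = "Unique sequences/selection output size (%)"
  )[metrics], stringsAsFactors = FALSE)
  for (s in names(ms))
    out[[s]] <- vapply(metrics, function(m) as.numeric(ms[[s]][[m]] %||% NA),
                       numeric(1))
  rownames(out) <- NULL
  out
}

#' @export
print.nb_run <- function(x, ...) {
  cat("nbmine run\n")
  print(report_table1(x), row.names = FALSE)
  cat(sprintf("clusters: %d at identity %.2f; candidates: %d\n",
              nrow(x$clusters$representatives), x$clusters$threshold,
              nrow(x$candidates)))
  invisible(x)
}
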