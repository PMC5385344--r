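#' Tally unique trimmed peptides across samples
#'
#' Pools validated peptides from one or more processed samples into a table of
#' unique trimmed peptides with per-sample read counts. Samples are pooled
#' before clustering so that a cluster's per-sample counts are directly
#' comparable.
#'
#' @param ... objects of class `nb_processed` (see [process_reads()]), or a
#'   single list of them.
#' @return An object of class `nb_tally`: a data frame with columns `id`
#'   (stable `U`-prefixed identifier), `peptide`, `length`, and one integer
#'   count column per sample. Attributes: `samples` (sample labels) and
#'   `sample_totals` (validated read counts per sample, the column sums).
#' @export
peptide_tally <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "nb_processed")) xs <- xs[[1]]
  stopifnot(all(vapply(xs, inherits, logical(1), "nb_processed")))
  samples <- vapply(xs, `[[`, character(1), "sample")
  if (anyDuplicated(samples))
    stop_input("duplicate sample labels in tally")
  peps <- unique(unlist(lapply(xs, `[[`, "trimmed"), use.names = FALSE))
  if (length(peps) == 0L)
    stop_input("no validated peptides to tally")
  peps <- peps[order_c(peps)]
  tab <- data.frame(id = sprintf("U%06d", seq_along(peps)),
                    peptide = peps, length = nchar(peps),
                    stringsAsFactors = FALSE)
  for (i in seq_along(xs)) {
    cnt <- integer(length(peps))
    t_i <- table(factor(xs[[i]]$trimmed, levels = peps))
    cnt <- as.integer(t_i)
    tab[[samples[i]]] <- cnt
  }
  structure(tab, samples = samples,
            sample_totals = setNames(
              vapply(samples, function(s) sum(tab[[s]]), numeric(1)), samples),
            class = c("nb_tally", "data.frame"))
}

#' Build a tally directly from peptide vectors
#'
#' Convenience constructor used when peptides come from somewhere other than
#' [process_reads()] (e.g. a reference set, or tests).
#'
#' @param peptides named list mapping sample label to a character vector of
#'   trimmed peptides (one entry per read).
#' @return An `nb_tally`, see [peptide_tally()].
#' @export
tally_from_peptides <- function(peptides) {
  stopifnot(is.list(peptides), !is.null(names(peptides)))
  xs <- lapply(names(peptides), function(s)
    structure(list(sample = s, trimmed = peptides[[s]]),
              class = "nb_processed"))
  peptide_tally(xs)
}

#' @export
print.nb_tally <- function(x, ...) {
  cat("Peptide tally:", nrow(x), "unique peptides,",
      length(attr(x, "samples")), "sample(s)\n")
  tot <- attr(x, "sample_totals")
  for (s in names(tot))
    cat(sprintf("  %s: %d reads, %.0f%% unique\n", s, tot[s],
                100 * sum(x[[s]] > 0) / tot[s]))
  invisible(x)
}

#' Write a tally as TSV and FASTA
#'
#' @param tally an `nb_tally`.
#' @param tsv,fasta output paths (either may be `NULL` to skip). FASTA headers
#'   carry `id|sample=count` pairs.
#' @return `invisible(tally)`.
#' @export
write_tally <- function(tally, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) write_tsv(as.data.frame(tally), tsv)
  if (!is.null(fasta)) {
    samples <- attr(tally, "samples")
    hdr <- tally$id
    for (s in samples) hdr <- paste0(hdr, "|", s, "=", tally[[s]])
    aa <- Biostrings::AAStringSet(tally$peptide)
    names(aa) <- hdr
    Biostrings::writeXStringSet(aa, fasta)
  }
  invisible(tally)
}
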