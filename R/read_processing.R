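#' Read a FASTQ file (plain or gzipped)
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning plain
#' character vectors, the representation used throughout the pipeline.
#'
#' @param path FASTQ file, optionally gzip-compressed; qualities must be
#'   Phred+33 encoded.
#' @return A list with character vectors `id`, `seq` and `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(id = sub("\\s.*$", "", names(x)),
       seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities))
}

#' Write a FASTQ file
#'
#' @param id,seq,qual read identifiers, sequences and Phred+33 quality strings.
#' @param path output file; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(id, seq, qual, path) {
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(qual),
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Merge paired-end reads by overlap
#'
#' Reverse-complements the reverse mate and scans all suffix/prefix overlaps
#' of at least `min_overlap` bases; the overlap with the lowest mismatch
#' fraction is chosen, ties going to the longer overlap. A pair is rejected
#' as unjoinable when the best overlap's mismatch fraction exceeds
#' `max_mismatch_rate`. At overlapping positions the higher-quality base is
#' kept, with quality `max(q1, q2)` where the mates agree and `|q1 - q2|`
#' where they disagree; `N` never counts as a match and always loses to a
#' called base.
#'
#' @param fwd,rev character vectors of forward/reverse read sequences
#'   (alphabet A, C, G, T, N).
#' @param fwd_qual,rev_qual Phred+33 quality strings, same lengths as the
#'   sequences.
#' @param min_overlap minimum admissible overlap length in bases.
#' @param max_mismatch_rate maximum mismatch fraction within the overlap.
#' @return A data frame with columns `seq`, `qual`, `overlap`, `mismatches`
#'   and logical `joined`; rejected pairs carry `NA` sequences.
#' @examples
#' tmpl <- paste(rep("ACGT", 25), collapse = "")
#' fwd <- substr(tmpl, 1, 60)
#' rev <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(substr(tmpl, 41, 100))))
#' merge_read_pairs(fwd, rev, strrep("I", 60), strrep("I", 60))
#' @export
merge_read_pairs <- function(fwd, rev, fwd_qual, rev_qual,
                             min_overlap = 10L, max_mismatch_rate = 0.25) {
  if (length(fwd) != length(rev))
    stop_input("forward and reverse mates differ in number")
  if (any(nchar(fwd) == 0L) || any(nchar(rev) == 0L))
    stop_input("empty sequence in read pair")
  if (any(grepl("[^ACGTN]", c(fwd, rev))))
    stop_input("read alphabet must be A, C, G, T, N")
  res <- .merge_pairs_cpp(fwd, rev, fwd_qual, rev_qual,
                          as.integer(min_overlap), max_mismatch_rate)
  data.frame(seq = res$seq, qual = res$qual, overlap = res$overlap,
             mismatches = res$mismatches, joined = res$joined,
             stringsAsFactors = FALSE)
}

#' Mean Phred score of quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return Numeric vector of arithmetic mean Phred scores (`NA` for empty
#'   strings).
#' @export
mean_phred <- function(qual) .mean_phred_cpp(qual)

#' Quality and length filter for merged reads
#'
#' A read passes when its arithmetic mean Phred score is at least
#' `min_mean_phred` and its length at least `min_len` bases.
#'
#' @param seq character vector of merged read sequences.
#' @param qual matching Phred+33 quality strings.
#' @param min_mean_phred minimum mean Phred score.
#' @param min_len minimum read length in bases.
#' @return Logical vector, `TRUE` for reads that pass; attribute `"reason"`
#'   holds `"quality"`, `"length"` or `"empty"` for failing reads and `NA`
#'   for passing ones.
#' @export
quality_length_filter <- function(seq, qual, min_mean_phred = 38, min_len = 150L) {
  len <- nchar(seq)
  mq <- mean_phred(qual)
  pass <- !is.na(mq) & mq >= min_mean_phred & len >= min_len
  reason <- rep(NA_character_, length(seq))
  reason[len == 0L] <- "empty"
  reason[is.na(reason) & len < min_len] <- "length"
  reason[is.na(reason) & !is.na(mq) & mq < min_mean_phred] <- "quality"
  reason[pass] <- NA_character_
  structure(pass, reason = reason)
}

#' Orient merged reads on the FR1/FR4 primers
#'
#' Turns every read into forward (FR1 primer) to reverse (FR4 primer)
#' orientation: an accepted read starts with the FR1 primer and ends with the
#' reverse complement of the FR4 primer. Reads matching on the reverse-
#' complement strand are flipped; primer matching honors IUPAC degeneracy
#' (W = A/T) and never counts `N` as a match.
#'
#' @param seq character vector of merged read sequences.
#' @param qual optional matching quality strings, reversed together with
#'   flipped reads.
#' @param primers a [primer_spec()].
#' @param max_mismatches mismatches tolerated per primer (0 = exact).
#' @return A data frame with columns `seq`, `qual` (both `NA` for rejected
#'   reads), `flipped` and `status` (`"oriented"`, `"partial_amplicon"` or
#'   `"no_primer"`).
#' @export
orient_reads <- function(seq, qual = NULL, primers = primer_spec(),
                         max_mismatches = 0L) {
  n <- length(seq)
  if (is.null(qual)) qual <- strrep("I", nchar(seq))
  len <- nchar(seq)
  p1 <- nchar(primers$fr1); p4 <- nchar(primers$fr4_rc)

  fr1_fwd <- primer_mismatches(substr(seq, 1L, p1), primers$fr1) <= max_mismatches
  fr4_fwd <- primer_mismatches(substr(seq, len - p4 + 1L, len), primers$fr4_rc) <= max_mismatches
  ok_fwd <- fr1_fwd & fr4_fwd
  # only reads failing on the forward strand need the reverse complement
  chk <- which(!ok_fwd)
  fr1_rev <- fr4_rev <- logical(n)
  rc <- character(n)
  if (length(chk)) {
    rc[chk] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seq[chk])))
    lc <- len[chk]
    fr1_rev[chk] <- primer_mismatches(substr(rc[chk], 1L, p1), primers$fr1) <= max_mismatches
    fr4_rev[chk] <- primer_mismatches(substr(rc[chk], lc - p4 + 1L, lc), primers$fr4_rc) <= max_mismatches
  }

  ok_rev <- !ok_fwd & fr1_rev & fr4_rev
  any_primer <- fr1_fwd | fr4_fwd | fr1_rev | fr4_rev
  status <- ifelse(ok_fwd | ok_rev, "oriented",
                   ifelse(any_primer, "partial_amplicon", "no_primer"))

  out_seq <- ifelse(ok_fwd, seq, ifelse(ok_rev, rc, NA_character_))
  out_qual <- ifelse(ok_fwd, qual, NA_character_)
  if (any(ok_rev))
    out_qual[ok_rev] <- vapply(strsplit(qual[ok_rev], "", fixed = TRUE),
                               function(x) paste(rev(x), collapse = ""),
                               character(1))
  data.frame(seq = out_seq, qual = out_qual, flipped = ok_rev,
             status = status, stringsAsFactors = FALSE)
}

#' Translate oriented amplicons and validate the reading frame
#'
#' Translates each oriented read in frame +1 from the first base of the FR1
#' primer with the standard genetic code. A read is valid when its length is
#' a multiple of 3 (the FR4 primer end is in frame with the FR1 start), no
#' stop codon occurs anywhere in the span, and no codon is ambiguous
#' (contains `N`). The trimmed peptide removes the 7 primer-encoded residues
#' from each terminus.
#'
#' @param seq character vector of oriented amplicon sequences.
#' @param trim residues stripped from each peptide terminus.
#' @param min_trimmed_len shortest trimmed peptide accepted (guards against
#'   degenerate amplicons).
#' @return A data frame with columns `full`, `trimmed` (both `NA` for
#'   rejected reads) and `status` (`"valid"`, `"frameshift"`,
#'   `"premature_stop"`, `"ambiguous"` or `"too_short"`).
#' @export
translate_reads <- function(seq, trim = 7L, min_trimmed_len = 36L) {
  n <- length(seq)
  status <- rep(NA_character_, n)
  full <- rep(NA_character_, n)

  in_frame <- nchar(seq) %% 3L == 0L
  status[!in_frame] <- "frameshift"
  if (any(in_frame)) {
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(seq[in_frame]), if.fuzzy.codon = "X"))
    st <- rep("valid", length(aa))
    st[grepl("*", aa, fixed = TRUE)] <- "premature_stop"
    st[st == "valid" & grepl("X", aa, fixed = TRUE)] <- "ambiguous"
    st[st == "valid" & nchar(aa) < min_trimmed_len + 2L * trim] <- "too_short"
    status[in_frame] <- st
    full[in_frame][st == "valid"] <- aa[st == "valid"]
  }
  trimmed <- rep(NA_character_, n)
  ok <- !is.na(full)
  trimmed[ok] <- substr(full[ok], trim + 1L, nchar(full[ok]) - trim)
  data.frame(full = full, trimmed = trimmed, status = status,
             stringsAsFactors = FALSE)
}

#' Process one sample's paired FASTQ into validated nanobody peptides
#'
#' Runs the per-sample read-processing chain: overlap merging, mean-Phred and
#' length filtering, primer orientation, translation and frame validation.
#' Every input pair is accounted for exactly once, either as a validated
#' peptide or in the rejection log.
#'
#' @param r1,r2 paths to the forward/reverse FASTQ files (may be gzipped), or
#'   `NULL` when `reads` is given.
#' @param sample sample label attached to the peptides.
#' @param reads optionally, a list with components `id`, `fwd`, `rev`,
#'   `fwd_qual`, `rev_qual` to process in-memory reads instead of files.
#' @param min_overlap,max_mismatch_rate overlap-merging parameters, see
#'   [merge_read_pairs()].
#' @param min_mean_phred,min_len quality/length filter thresholds, see
#'   [quality_length_filter()].
#' @param primers a [primer_spec()].
#' @param max_primer_mismatches mismatches tolerated per primer.
#' @param trim,min_trimmed_len translation parameters, see
#'   [translate_reads()].
#' @return An object of class `nb_processed`: a list with `sample`, character
#'   vectors `full` and `trimmed` (one entry per validated read), `ids` of
#'   validated reads, per-stage `counts`, and a `rejections` data frame
#'   (`id`, `stage`, `reason`).
#' @seealso [peptide_tally()] to aggregate several samples.
#' @export
process_reads <- function(r1 = NULL, r2 = NULL, sample = "sample",
                          reads = NULL,
                          min_overlap = 10L, max_mismatch_rate = 0.25,
                          min_mean_phred = 38, min_len = 150L,
                          primers = primer_spec(), max_primer_mismatches = 0L,
                          trim = 7L, min_trimmed_len = 36L) {
  if (is.null(reads)) {
    if (is.null(r1) || is.null(r2))
      stop_input("either r1/r2 files or in-memory reads are required")
    f <- read_fastq(r1); r <- read_fastq(r2)
    if (length(f$seq) != length(r$seq))
      stop_input("R1 and R2 differ in read count")
    reads <- list(id = f$id, fwd = f$seq, rev = r$seq,
                  fwd_qual = f$qual, rev_qual = r$qual)
  }
  n_raw <- length(reads$fwd)
  if (n_raw == 0L)
    stop_input("empty sample: no reads in ", sample)
  id <- reads$id %||% sprintf("read%06d", seq_len(n_raw))

  rej <- list()
  merged <- merge_read_pairs(reads$fwd, reads$rev, reads$fwd_qual,
                             reads$rev_qual, min_overlap, max_mismatch_rate)
  keep <- merged$joined
  if (any(!keep))
    rej$merge <- data.frame(id = id[!keep], stage = "merge",
                            reason = "unjoinable", stringsAsFactors = FALSE)
  id <- id[keep]; mseq <- merged$seq[keep]; mqual <- merged$qual[keep]
  n_joined <- length(mseq)

  qc <- quality_length_filter(mseq, mqual, min_mean_phred, min_len)
  if (any(!qc))
    rej$qc <- data.frame(id = id[!qc], stage = "quality_length",
                         reason = attr(qc, "reason")[!qc],
                         stringsAsFactors = FALSE)
  id <- id[qc]; mseq <- mseq[qc]; mqual <- mqual[qc]
  n_qc <- length(mseq)

  ori <- if (n_qc > 0L) orient_reads(mseq, mqual, primers, max_primer_mismatches)
         else data.frame(seq = character(), status = character())
  keep <- ori$status == "oriented"
  if (any(!keep))
    rej$orient <- data.frame(id = id[!keep], stage = "orient",
                             reason = ori$status[!keep],
                             stringsAsFactors = FALSE)
  id <- id[keep]; oseq <- ori$seq[keep]
  n_oriented <- length(oseq)

  tr <- if (n_oriented > 0L) translate_reads(oseq, trim, min_trimmed_len)
        else data.frame(full = character(), trimmed = character(),
                        status = character())
  keep <- tr$status == "valid"
  if (any(!keep))
    rej$translate <- data.frame(id = id[!keep], stage = "translate",
                                reason = tr$status[!keep],
                                stringsAsFactors = FALSE)
  rejections <- if (length(rej)) do.call(rbind, unname(rej))
                else data.frame(id = character(), stage = character(),
                                reason = character(), stringsAsFactors = FALSE)

  counts <- c(raw = n_raw, joined = n_joined,
              unjoinable = n_raw - n_joined,
              qc_pass = n_qc, qc_fail = n_joined - n_qc,
              oriented = n_oriented, orient_fail = n_qc - n_oriented,
              validated = sum(keep),
              frameshift = sum(tr$status == "frameshift"),
              premature_stop = sum(tr$status == "premature_stop"),
              ambiguous = sum(tr$status == "ambiguous"),
              too_short = sum(tr$status == "too_short"))
  structure(list(sample = sample, ids = id[keep], full = tr$full[keep],
                 trimmed = tr$trimmed[keep], counts = counts,
                 rejections = rejections),
            class = "nb_processed")
}

#' @export
print.nb_processed <- function(x, ...) {
  cat("Processed sample", sQuote(x$sample), "\n")
  cc <- x$counts
  cat(sprintf("  raw pairs      %d\n  joined         %d (%.1f%%)\n",
              cc["raw"], cc["joined"], 100 * cc["joined"] / cc["raw"]))
  cat(sprintf("  passed QC      %d\n  oriented       %d\n  validated      %d\n",
              cc["qc_pass"], cc["oriented"], cc["validated"]))
  cat(sprintf("  unique peptides %d\n", length(unique(x$trimmed))))
  invisible(x)
}
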