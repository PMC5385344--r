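# Most-used codon per residue in E. coli K-12 (standard usage tables);
# deterministic reverse translation for gene synthesis.
ECOLI_TOP_CODON <- c(
  A = "GCG", R = "CGC", N = "AAC", D = "GAT", C = "TGC", Q = "CAG",
  E = "GAA", G = "GGC", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTT", P = "CCG", S = "AGC", T = "ACC", W = "TGG",
  Y = "TAT", V = "GTG")

#' Majority-rule consensus of one cluster
#'
#' Per-column vote over a cluster's equal-length members (no multiple
#' alignment needed since the clustering forbids length differences). The
#' residue with the greatest weight wins each column; weights are
#' selection-sample read counts by default (`"reads"`), or one per unique
#' member (`"unique"`). Ties break to the representative's residue, then
#' lexicographically. Abundance weighting captures the enriched sequences
#' while averaging out PCR and sequencing read errors.
#'
#' @param peptides character vector of equal-length member peptides.
#' @param weights numeric member weights (read counts); recycled 1 for
#'   unique-member voting.
#' @param representative the cluster representative, used for tie-breaks
#'   (defaults to the heaviest member).
#' @return A list with `consensus` (peptide string) and `support`, a list of
#'   per-column named numeric vectors of weight fractions (each summing
#'   to 1).
#' @examples
#' majority_consensus(c("PEPTIDE", "PEPTIDA", "PEPTIDQ"), c(5, 1, 1))
#' @export
majority_consensus <- function(peptides, weights = 1,
                               representative = NULL) {
  if (length(peptides) == 0L) stop_input("empty cluster")
  if (length(unique(nchar(peptides))) != 1L)
    stop_input("cluster members must have equal length")
  weights <- rep_len(as.numeric(weights), length(peptides))
  if (all(weights <= 0)) weights <- rep(1, length(peptides))
  if (is.null(representative))
    representative <- peptides[which.max(weights)]
  m <- seq_char_matrix(peptides)
  rep_chars <- strsplit(representative, "", fixed = TRUE)[[1]]
  total <- sum(weights)
  cols <- ncol(m)
  out <- character(cols)
  support <- vector("list", cols)
  for (j in seq_len(cols)) {
    w <- rowsum(weights, m[, j])
    frac <- sort(setNames(w[, 1] / total, rownames(w)), decreasing = TRUE)
    top <- names(frac)[frac >= max(frac) - 1e-12]
    out[j] <- if (rep_chars[j] %in% top) rep_chars[j] else min(top)
    support[[j]] <- frac
  }
  list(consensus = paste(out, collapse = ""), support = support)
}

#' Restore primer-encoded flanks on a trimmed consensus
#'
#' Prepends the FR1-encoded heptapeptide `EVQLVES` and appends the
#' FR4-encoded tail `TLVTVSS` or `TQVTVSS`; the degenerate primer base W
#' realizes either L or Q at the second FR4 position.
#'
#' @param consensus_trimmed trimmed consensus peptide(s).
#' @param fr4_variant `"L"` or `"Q"`.
#' @return Full-length peptide(s).
#' @examples
#' restore_flanks("GGSGG")            # EVQLVESGGSGGTLVTVSS
#' restore_flanks("GGSGG", "Q")
#' @export
restore_flanks <- function(consensus_trimmed, fr4_variant = c("L", "Q")) {
  if (any(nchar(consensus_trimmed) == 0L))
    stop_input("empty trimmed consensus")
  fr4_variant <- match.arg(fr4_variant)
  tail <- if (fr4_variant == "L") "TLVTVSS" else "TQVTVSS"
  paste0("EVQLVES", consensus_trimmed, tail)
}

#' Deterministic reverse translation for gene synthesis
#'
#' Maps each residue to the most frequently used codon of the chosen
#' organism (packaged static table; currently E. coli). Exact round trip:
#' translating the result reproduces the input peptide.
#'
#' @param peptide character vector of peptides (standard residues only).
#' @param codon_table named character vector residue -> codon.
#' @return DNA string(s).
#' @examples
#' reverse_translate("MW") # "ATGTGG"
#' @export
reverse_translate <- function(peptide, codon_table = ECOLI_TOP_CODON) {
  vapply(strsplit(toupper(peptide), "", fixed = TRUE), function(aa) {
    bad <- setdiff(aa, names(codon_table))
    if (length(bad))
      stop_input("non-standard residue(s): ", paste(unique(bad), collapse = ", "))
    paste(codon_table[aa], collapse = "")
  }, character(1))
}

#' Consensus sequences for a set of clusters
#'
#' Builds the majority-rule consensus for each requested cluster, restores
#' the primer-encoded flanks and reverse-translates to synthesis-ready DNA.
#'
#' @param clusters an `nb_clusters`.
#' @param ids integer cluster ids to process (default: all).
#' @param weighting `"reads"` (abundance-weighted, the default) or
#'   `"unique"` (one vote per unique member).
#' @param sample sample whose read counts weight the vote; defaults to the
#'   first sample in the tally. Candidates are selection-driven, so pass the
#'   selection sample.
#' @param fr4_variant FR4 degenerate residue, `"L"` or `"Q"`.
#' @return An object of class `nb_consensus`: data frame with columns
#'   `cluster`, `consensus_trimmed`, `consensus_full`, `dna` and
#'   `n_members`; attribute `"support"` holds the per-cluster per-column
#'   weight fractions.
#' @export
consensus_sequences <- function(clusters, ids = NULL,
                                weighting = c("reads", "unique"),
                                sample = NULL, fr4_variant = c("L", "Q")) {
  stopifnot(inherits(clusters, "nb_clusters"))
  weighting <- match.arg(weighting)
  fr4_variant <- match.arg(fr4_variant)
  sample <- sample %||% clusters$samples[1]
  if (!sample %in% clusters$samples) stop_input("unknown sample ", sample)
  if (is.null(ids)) ids <- clusters$representatives$cluster
  m <- clusters$members
  rep_pep <- setNames(clusters$representatives$peptide,
                      clusters$representatives$cluster)
  rows <- lapply(ids, function(cl) {
    mm <- m[m$cluster == cl, , drop = FALSE]
    if (nrow(mm) == 0L) stop_input("no such cluster: ", cl)
    w <- if (weighting == "reads") mm[[sample]] else rep(1, nrow(mm))
    cons <- majority_consensus(mm$peptide, w, rep_pep[as.character(cl)])
    list(cluster = cl, consensus_trimmed = cons$consensus,
         n_members = nrow(mm), support = cons$support)
  })
  out <- data.frame(
    cluster = vapply(rows, `[[`, numeric(1), "cluster"),
    consensus_trimmed = vapply(rows, `[[`, character(1), "consensus_trimmed"),
    n_members = vapply(rows, `[[`, numeric(1), "n_members"),
    stringsAsFactors = FALSE)
  out$consensus_full <- restore_flanks(out$consensus_trimmed, fr4_variant)
  out$dna <- reverse_translate(out$consensus_full)
  out <- out[, c("cluster", "consensus_trimmed", "consensus_full", "dna",
                 "n_members")]
  structure(out, support = setNames(lapply(rows, `[[`, "support"), out$cluster),
            weighting = weighting, sample = sample,
            class = c("nb_consensus", "data.frame"))
}

#' Write consensus peptide/DNA FASTA files and a support table
#'
#' @param consensus an `nb_consensus`.
#' @param peptide_fasta,dna_fasta,support_tsv output paths (`NULL` skips).
#' @return `invisible(consensus)`.
#' @export
write_consensus <- function(consensus, peptide_fasta = NULL, dna_fasta = NULL,
                            support_tsv = NULL) {
  hdr <- sprintf("cluster%d|consensus", consensus$cluster)
  if (!is.null(peptide_fasta)) {
    aa <- Biostrings::AAStringSet(consensus$consensus_full)
    names(aa) <- hdr
    Biostrings::writeXStringSet(aa, peptide_fasta)
  }
  if (!is.null(dna_fasta)) {
    dna <- Biostrings::DNAStringSet(consensus$dna)
    names(dna) <- hdr
    Biostrings::writeXStringSet(dna, dna_fasta)
  }
  if (!is.null(support_tsv)) {
    sup <- attr(consensus, "support")
    rows <- do.call(rbind, lapply(names(sup), function(cl) {
      cols <- sup[[cl]]
      do.call(rbind, lapply(seq_along(cols), function(j)
        data.frame(cluster = cl, column = j,
                   residue = names(cols[[j]]),
                   fraction = as.numeric(cols[[j]]),
                   stringsAsFactors = FALSE)))
    }))
    write_tsv(rows, support_tsv)
  }
  invisible(consensus)
}
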