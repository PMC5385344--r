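#' Pairwise sequence identity
#'
#' Fraction of identical aligned residue pairs, maximized over all global
#' alignments, divided by the (common) sequence length. With free gaps this
#' maximum equals the longest-common-subsequence length, so alignments with
#' compensating gaps may score above the position-wise (Hamming) identity:
#' two sequences differing by an adjacent swap align 9/10 rather than 8/10.
#' Intended for equal-length peptides (the clustering engine never compares
#' sequences of unequal length); for unequal lengths the shorter length is
#' the denominator.
#'
#' @param a,b character vectors of uppercase peptide sequences, recycled to a
#'   common length.
#' @return Numeric vector of identities in `[0, 1]`.
#' @examples
#' seq_identity("ACDEFGHIKL", "ACDEGFHIKL") # 0.9, via a gapped alignment
#' @export
seq_identity <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  if (any(nchar(a) == 0L) || any(nchar(b) == 0L))
    stop_input("empty sequence")
  .seq_identity_cpp(a, b)
}

#' Greedy incremental clustering of trimmed peptides
#'
#' Reimplements the classic greedy incremental algorithm in its slow/accurate
#' variant with no length differences allowed: sequences are sorted (length
#' descending, then pooled read count descending, then lexicographic), the
#' first founds cluster 0, and each subsequent sequence is compared against
#' *all* earlier-founded representatives of the same length, joining the one
#' with the highest identity at or above the threshold (ties to the
#' lowest-numbered cluster) or founding a new cluster. Clustering operates on
#' unique peptides; read counts are carried as metadata and never affect the
#' geometry. The ordering and tie rules are total, so the partition is
#' deterministic across runs and platforms.
#'
#' @param x an `nb_tally` (see [peptide_tally()]), or a character vector of
#'   unique peptides (counted once each in a sample named `"all"`).
#' @param identity sequence identity threshold in `(0, 1]`.
#' @return An object of class `nb_clusters`: a list with
#'   \describe{
#'     \item{members}{data frame `cluster`, `id`, `peptide`, `length`,
#'       `identity` (to the representative), plus per-sample count columns;}
#'     \item{representatives}{data frame `cluster`, `id`, `peptide`,
#'       `length`, `n_members`, plus per-sample count sums;}
#'     \item{threshold, samples, sample_totals}{parameters and pooled
#'       totals.}
#'   }
#' @examples
#' cl <- cluster_peptides(c("PEPTIDEAAA", "PEPTIDEAAV", "AAAAAAAAAA"), 0.9)
#' cl$representatives
#' @export
cluster_peptides <- function(x, identity = 0.9) {
  if (!is.numeric(identity) || length(identity) != 1L ||
      identity <= 0 || identity > 1)
    stop_input("identity threshold must be a single value in (0, 1]")
  tally <- if (inherits(x, "nb_tally")) x
           else tally_from_peptides(list(all = x))
  if (nrow(tally) == 0L) stop_input("empty tally")
  if (any(grepl("[^A-Z]", tally$peptide)))
    stop_input("peptides must be uppercase A-Z")
  samples <- attr(tally, "samples")
  total <- rowSums(as.matrix(as.data.frame(tally)[, samples, drop = FALSE]))
  ord <- order_c(-tally$length, -total, tally$peptide)
  tt <- as.data.frame(tally)[ord, , drop = FALSE]
  res <- .greedy_cluster_cpp(tt$peptide, identity)
  members <- data.frame(cluster = res$cluster, id = tt$id,
                        peptide = tt$peptide, length = tt$length,
                        identity = res$identity,
                        stringsAsFactors = FALSE)
  for (s in samples) members[[s]] <- tt[[s]]
  members <- members[order(members$cluster, -members$identity,
                           members$peptide, method = "radix"), ]
  rownames(members) <- NULL
  rep_rows <- tt[res$rep_index + 1L, , drop = FALSE]
  reps <- data.frame(cluster = seq_len(nrow(rep_rows)) - 1L,
                     id = rep_rows$id, peptide = rep_rows$peptide,
                     length = rep_rows$length,
                     n_members = as.integer(table(factor(res$cluster,
                       levels = seq_len(nrow(rep_rows)) - 1L))),
                     stringsAsFactors = FALSE)
  for (s in samples)
    reps[[s]] <- as.integer(rowsum(members[[s]], members$cluster)[, 1])
  rownames(reps) <- NULL
  structure(list(members = members, representatives = reps,
                 threshold = identity, samples = samples,
                 sample_totals = attr(tally, "sample_totals")),
            class = "nb_clusters")
}

#' Cluster one tally at a grid of identity thresholds
#'
#' Runs one independent clustering per threshold on the identical input
#' ordering, as done when scanning thresholds for calibration.
#'
#' @param x an `nb_tally` or character vector, see [cluster_peptides()].
#' @param thresholds numeric vector of identity thresholds in `(0, 1]`.
#' @return Named list of `nb_clusters`, one per threshold.
#' @export
cluster_grid <- function(x, thresholds = seq(0.70, 1.00, by = 0.05)) {
  if (length(thresholds) == 0L)
    stop_input("empty threshold grid")
  out <- lapply(thresholds, function(th) cluster_peptides(x, th))
  names(out) <- formatC(thresholds, format = "f", digits = 2)
  out
}

#' @export
print.nb_clusters <- function(x, ...) {
  cat(sprintf("Greedy clustering at identity %.2f: %d clusters from %d unique peptides\n",
              x$threshold, nrow(x$representatives), nrow(x$members)))
  invisible(x)
}

#' @export
summary.nb_clusters <- function(object, ...) {
  sz <- object$representatives$n_members
  cat(sprintf("Clusters: %d (threshold %.2f)\n", length(sz), object$threshold))
  cat(sprintf("  members per cluster: mean %.2f, max %d; singletons %d\n",
              mean(sz), max(sz), sum(sz == 1L)))
  invisible(object)
}

#' Write clusters in CD-HIT-compatible `.clstr` format
#'
#' @param clusters an `nb_clusters`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clusters, path) {
  m <- clusters$members
  rep_id <- setNames(clusters$representatives$id,
                     clusters$representatives$cluster)
  con <- file(path, "w")
  on.exit(close(con))
  for (cl in clusters$representatives$cluster) {
    writeLines(sprintf(">Cluster %d", cl), con)
    mm <- m[m$cluster == cl, , drop = FALSE]
    is_rep <- mm$id == rep_id[as.character(cl)]
    mm <- mm[order(-is_rep, -mm$identity, mm$peptide, method = "radix"), ]
    is_rep <- mm$id == rep_id[as.character(cl)]
    tail <- ifelse(is_rep, "*", sprintf("at %.2f%%", 100 * mm$identity))
    writeLines(sprintf("%d\t%daa, >%s... %s",
                       seq_len(nrow(mm)) - 1L, mm$length, mm$id, tail), con)
  }
  invisible(path)
}

#' Write a cluster report TSV and representative FASTA
#'
#' @param clusters an `nb_clusters`.
#' @param tsv,fasta output paths (`NULL` skips).
#' @return `invisible(clusters)`.
#' @export
write_clusters <- function(clusters, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) write_tsv(clusters$representatives, tsv)
  if (!is.null(fasta)) {
    aa <- Biostrings::AAStringSet(clusters$representatives$peptide)
    names(aa) <- sprintf("cluster%d|%s", clusters$representatives$cluster,
                         clusters$representatives$id)
    Biostrings::writeXStringSet(aa, fasta)
  }
  invisible(clusters)
}
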