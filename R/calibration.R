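#' Read a labeled reference nanobody set
#'
#' Loads a peptide FASTA plus a metadata table carrying the three relatedness
#' labels used for threshold calibration: target antigen, source publication
#' and database submission (date/authors). Unknown labels are `NA`.
#'
#' @param fasta path to a peptide FASTA; record names must match `meta$id`.
#' @param meta a data frame (or TSV path) with columns `id`, `antigen`,
#'   `publication`, `submission`.
#' @param trim residues stripped from each terminus before clustering
#'   (primer-encoded/partial framework positions); 0 to disable.
#' @return A data frame of class `nb_reference` with columns `id`, `peptide`,
#'   and list columns `antigen`, `publication`, `submission` (character
#'   vectors, so merged duplicates can carry several labels).
#' @export
read_reference_set <- function(fasta, meta, trim = 7L) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  if (is.character(meta))
    meta <- utils::read.table(meta, sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("id", "antigen", "publication", "submission")
  if (!all(need %in% names(meta)))
    stop_input("metadata must have columns ", paste(need, collapse = ", "))
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  if (anyNA(meta$id)) stop_input("metadata missing for some FASTA records")
  pep <- as.character(aa)
  if (trim > 0L) pep <- trim_termini(pep, trim)
  out <- data.frame(id = ids, peptide = pep, stringsAsFactors = FALSE)
  for (f in c("antigen", "publication", "submission"))
    out[[f]] <- lapply(meta[[f]], function(v) as.character(v[!is.na(v)]))
  class(out) <- c("nb_reference", "data.frame")
  out
}

#' Build a reference set from vectors (used by simulations and tests)
#'
#' @param id,peptide,antigen,publication,submission equal-length vectors;
#'   label vectors may contain `NA` for unknown.
#' @return An `nb_reference`, see [read_reference_set()].
#' @export
reference_set <- function(id, peptide, antigen = NA, publication = NA,
                          submission = NA) {
  n <- length(peptide)
  as_labels <- function(v) lapply(rep_len(v, n),
                                  function(x) as.character(x[!is.na(x)]))
  out <- data.frame(id = rep_len(id, n), peptide = peptide,
                    stringsAsFactors = FALSE)
  out$antigen <- as_labels(antigen)
  out$publication <- as_labels(publication)
  out$submission <- as_labels(submission)
  class(out) <- c("nb_reference", "data.frame")
  out
}

#' Collapse exact-duplicate peptides, merging their labels
#'
#' Entries with identical peptide sequences are merged into one
#' non-redundant entry whose label sets are the unions of the duplicates'
#' labels.
#'
#' @param entries an `nb_reference`.
#' @return A deduplicated `nb_reference` (first-seen ids kept).
#' @export
deduplicate_entries <- function(entries) {
  stopifnot(inherits(entries, "nb_reference"))
  groups <- split(seq_len(nrow(entries)), entries$peptide)
  first <- vapply(groups, `[[`, integer(1), 1L)
  ord <- sort(first)
  out <- entries[ord, , drop = FALSE]
  for (f in c("antigen", "publication", "submission")) {
    merged <- lapply(groups, function(ix)
      unique(unlist(entries[[f]][ix], use.names = FALSE)))
    out[[f]] <- merged[match(entries$peptide[ord], names(groups))]
  }
  rownames(out) <- NULL
  class(out) <- c("nb_reference", "data.frame")
  out
}

#' Relatedness partition of one cluster's members
#'
#' Two members are directly related when they share a target antigen, a
#' source publication or a database submission. Relatedness is taken
#' transitively (connected components of the sharing graph); members with
#' all labels unknown relate to nothing. The number of unrelated members is
#' the cluster size minus the largest connected component.
#'
#' @param members an `nb_reference` subset (one cluster's members).
#' @return List with `largest_related` (size of the largest component) and
#'   `n_unrelated`.
#' @export
relatedness_partition <- function(members) {
  n <- nrow(members)
  if (n == 0L) stop_input("empty cluster")
  if (n == 1L) return(list(largest_related = 1L, n_unrelated = 0L))
  share <- function(f) {
    lab <- members[[f]]
    m <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      if (length(intersect(lab[[i]], lab[[j]])))
        m[i, j] <- m[j, i] <- TRUE
    m
  }
  adj <- share("antigen") | share("publication") | share("submission")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  largest <- max(comp$csize)
  list(largest_related = as.integer(largest),
       n_unrelated = as.integer(n - largest))
}

#' Calibrate the clustering identity threshold on a labeled reference set
#'
#' Clusters the (deduplicated) reference peptides at each threshold with the
#' same greedy engine as the main pipeline and counts, per cluster, how many
#' members are unrelated to the cluster's main related group. The summary
#' curve (threshold versus number of clusters containing unrelated members)
#' shows where unrelated sequences start co-clustering, justifying the
#' working threshold.
#'
#' @param entries an `nb_reference` (deduplicate first with
#'   [deduplicate_entries()]; done here if duplicates remain).
#' @param thresholds identity threshold grid.
#' @return An object of class `nb_calibration`: list with `summary` (data
#'   frame `threshold`, `n_clusters`, `n_multi_member`,
#'   `n_with_unrelated`, `n_unrelated_total`) and `per_cluster`, a list (per
#'   threshold) of data frames `cluster`, `size`, `n_unrelated`.
#' @export
calibrate_thresholds <- function(entries,
                                 thresholds = seq(0.70, 1.00, by = 0.05)) {
  stopifnot(inherits(entries, "nb_reference"))
  if (length(thresholds) == 0L) stop_input("empty threshold grid")
  if (anyDuplicated(entries$peptide)) entries <- deduplicate_entries(entries)
  grid <- cluster_grid(entries$peptide, thresholds)
  per_cluster <- lapply(grid, function(cl) {
    mm <- cl$members
    idx <- match(mm$peptide, entries$peptide)
    by_cl <- split(idx, mm$cluster)
    res <- lapply(by_cl, function(ix)
      relatedness_partition(entries[ix, , drop = FALSE]))
    data.frame(cluster = as.integer(names(by_cl)),
               size = lengths(by_cl),
               n_unrelated = vapply(res, `[[`, integer(1), "n_unrelated"),
               row.names = NULL)
  })
  summary <- data.frame(
    threshold = thresholds,
    n_clusters = vapply(per_cluster, nrow, integer(1)),
    n_multi_member = vapply(per_cluster, function(d) sum(d$size > 1L), integer(1)),
    n_with_unrelated = vapply(per_cluster, function(d) sum(d$n_unrelated > 0L), integer(1)),
    n_unrelated_total = vapply(per_cluster, function(d) sum(d$n_unrelated), integer(1)),
    row.names = NULL)
  structure(list(summary = summary, per_cluster = per_cluster,
                 n_entries = nrow(entries)),
            class = "nb_calibration")
}

#' @export
print.nb_calibration <- function(x, ...) {
  cat("Threshold calibration on", x$n_entries, "non-redundant reference peptides\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Calibration curve plot
#'
#' Number of clusters containing unrelated members against the identity
#' threshold (plus total cluster counts on the labels).
#'
#' @param x an `nb_calibration`.
#' @param ... passed to [graphics::plot()].
#' @return `invisible(x)`.
#' @export
plot.nb_calibration <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$threshold, s$n_with_unrelated, type = "b", pch = 19,
                 xlab = "sequence identity threshold",
                 ylab = "clusters containing unrelated members", ...)
  invisible(x)
}
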