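#' Sequencing-depth normalization factor
#'
#' Ratio of the reference (control) sample's total validated sequence count
#' to the selection sample's, used to scale selection-sample cluster counts
#' before computing enrichment factors. For the published totals
#' `3.4e6 / 2.8e6` this reports 1.21 at two decimals; full precision is used
#' internally.
#'
#' @param ref_total,sel_total total validated sequence counts of the
#'   reference (control) and selection samples.
#' @return The factor `ref_total / sel_total`, with attribute `"report"`
#'   holding the value rounded half-up to two decimals.
#' @examples
#' normalization_factor(3.4e6, 2.8e6)
#' @export
normalization_factor <- function(ref_total, sel_total) {
  if (ref_total <= 0 || sel_total <= 0)
    stop_input("sample totals must be positive")
  f <- ref_total / sel_total
  structure(f, report = round_half_up(f, 2))
}

#' Cluster enrichment factor
#'
#' Normalized selection-sample count divided by the pseudocounted
#' control-sample count: `EF = (count_sel * f) / max(count_ctrl, 1)`. The
#' pseudocount applies only to the denominator, so clusters absent from the
#' control still receive a finite enrichment factor while selection-side
#' zeros yield 0.
#'
#' @param count_sel,count_ctrl per-cluster read counts in the selection and
#'   control samples.
#' @param f normalization factor, see [normalization_factor()].
#' @return Numeric vector of enrichment factors.
#' @examples
#' enrichment_factor(100, 0, 1.21) # 121
#' @export
enrichment_factor <- function(count_sel, count_ctrl, f) {
  if (any(count_sel < 0) || any(count_ctrl < 0))
    stop_input("counts must be non-negative")
  if (any(f <= 0)) stop_input("normalization factor must be positive")
  (count_sel * f) / pmax(count_ctrl, 1)
}

#' Cross-sample enrichment analysis of clusters
#'
#' Computes, for every cluster, the selection and control read counts, the
#' depth-normalized selection count, the pseudocounted enrichment factor,
#' and the candidate flag `count_sel >= min_size & EF >= min_ef` (boundary
#' values included). Cluster size for gating is the raw selection-sample
#' count, before normalization.
#'
#' @param clusters an `nb_clusters` from [cluster_peptides()] whose tally
#'   contains both samples.
#' @param sel,ctrl sample labels of the selection and negative-control
#'   samples.
#' @param min_size minimum selection-sample cluster size for candidacy.
#' @param min_ef minimum enrichment factor for candidacy.
#' @param f optional normalization factor; defaults to
#'   `ctrl_total / sel_total` of the validated counts carried by the tally.
#' @return An object of class `nb_enrichment`: a data frame with columns
#'   `cluster`, `representative`, `count_sel`, `count_ctrl`,
#'   `count_ctrl_adj`, `count_sel_norm`, `ef` and `is_candidate`, ordered by
#'   `ef` then `count_sel` descending. Attributes: `sel`, `ctrl`,
#'   `norm_factor`, `min_size`, `min_ef`.
#' @export
enrich_clusters <- function(clusters, sel, ctrl, min_size = 10, min_ef = 10,
                            f = NULL) {
  stopifnot(inherits(clusters, "nb_clusters"))
  if (!all(c(sel, ctrl) %in% clusters$samples))
    stop_input("samples ", sel, " and ", ctrl, " must both be in the clustering")
  totals <- clusters$sample_totals
  if (is.null(f)) f <- normalization_factor(totals[[ctrl]], totals[[sel]])
  reps <- clusters$representatives
  cs <- reps[[sel]]
  cc <- reps[[ctrl]]
  ef <- enrichment_factor(cs, cc, as.numeric(f))
  out <- data.frame(cluster = reps$cluster, representative = reps$peptide,
                    count_sel = cs, count_ctrl = cc,
                    count_ctrl_adj = pmax(cc, 1L),
                    count_sel_norm = cs * as.numeric(f), ef = ef,
                    is_candidate = cs >= min_size & ef >= min_ef,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$ef, -out$count_sel, out$cluster), ]
  rownames(out) <- NULL
  structure(out, sel = sel, ctrl = ctrl, norm_factor = as.numeric(f),
            min_size = min_size, min_ef = min_ef,
            class = c("nb_enrichment", "data.frame"))
}

#' Candidate subset of an enrichment table
#'
#' @param enrichment an `nb_enrichment`.
#' @return The candidate rows (already sorted by enrichment factor, then
#'   selection count, descending).
#' @export
candidates <- function(enrichment) {
  stopifnot(inherits(enrichment, "nb_enrichment"))
  out <- as.data.frame(enrichment)[enrichment$is_candidate, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.nb_enrichment <- function(x, ...) {
  cat(sprintf("Enrichment of %s over %s: %d clusters, %d candidates (size >= %g, EF >= %g)\n",
              attr(x, "sel"), attr(x, "ctrl"), nrow(x),
              sum(x$is_candidate), attr(x, "min_size"), attr(x, "min_ef")))
  cat(sprintf("  normalization factor %.2f\n",
              round_half_up(attr(x, "norm_factor"), 2)))
  if (nrow(x)) print(utils::head(as.data.frame(x), 5))
  invisible(x)
}

#' Scatter plot of cluster size against enrichment factor
#'
#' Log-log scatter of selection-sample cluster size versus enrichment
#' factor, highlighting candidates; the standard view for picking binder
#' clusters.
#'
#' @param x an `nb_enrichment`.
#' @param ... passed to [graphics::plot()].
#' @return `invisible(x)`.
#' @export
plot.nb_enrichment <- function(x, ...) {
  keep <- x$count_sel > 0 & x$ef > 0
  d <- x[keep, ]
  graphics::plot(d$count_sel, d$ef, log = "xy",
                 xlab = "cluster size (selection counts)",
                 ylab = "enrichment factor",
                 col = ifelse(d$is_candidate, "firebrick", adjustcolor("grey40", 0.5)),
                 pch = 20, ...)
  graphics::abline(h = attr(x, "min_ef"), v = attr(x, "min_size"), lty = 2)
  invisible(x)
}

#' Cluster size census for one sample
#'
#' Summarizes clusters by size class, where a cluster's size is its read
#' count in the given sample: orphan (size 1), medium (2-10) and large (>10)
#' clusters, each with count, fraction of the sample's total sequences, and
#' mean size. Clusters without reads in the sample are excluded.
#'
#' @param clusters an `nb_clusters`.
#' @param sample sample label.
#' @return An object of class `nb_cluster_summary`: list with `sample`,
#'   `n_clusters`, `mean_size`, `total_sequences` and a data frame `classes`
#'   (`class`, `n_clusters`, `fraction_sequences`, `mean_size`).
#' @export
summarize_clusters <- function(clusters, sample) {
  stopifnot(inherits(clusters, "nb_clusters"))
  if (!sample %in% clusters$samples)
    stop_input("unknown sample ", sample)
  sizes <- clusters$representatives[[sample]]
  sizes <- sizes[sizes > 0]
  total <- sum(sizes)
  cls <- cut(sizes, c(0, 1, 10, Inf), labels = c("orphan", "medium", "large"))
  classes <- data.frame(
    class = c("orphan", "medium", "large"),
    n_clusters = as.integer(table(cls)),
    fraction_sequences = as.numeric(tapply(sizes, cls, sum, default = 0)) / total,
    mean_size = as.numeric(tapply(sizes, cls, mean, default = NaN)),
    stringsAsFactors = FALSE)
  structure(list(sample = sample, n_clusters = length(sizes),
                 mean_size = mean(sizes), total_sequences = total,
                 classes = classes),
            class = "nb_cluster_summary")
}

#' @export
print.nb_cluster_summary <- function(x, ...) {
  cat(sprintf("Cluster census for %s: %d clusters, mean size %.2f, %d sequences\n",
              x$sample, x$n_clusters, x$mean_size, x$total_sequences))
  cl <- x$classes
  for (i in seq_len(nrow(cl)))
    cat(sprintf("  %-6s %7d clusters, %3.0f%% of sequences, mean size %.1f\n",
                cl$class[i], cl$n_clusters[i],
                round_half_up(100 * cl$fraction_sequences[i]), cl$mean_size[i]))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial proportion confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles: the lower
#' bound is `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`) and the upper
#' bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). For hit-rate
#' reporting (e.g. 25 binders of 28 tested) the bounds round half-up to
#' whole percentages: 72-98%.
#'
#' @param successes,n number of successes and trials.
#' @param confidence confidence level (default 0.95).
#' @return Named numeric vector `c(lower, upper)` with attributes
#'   `"estimate"` (the point proportion) and `"percent"` (bounds as
#'   half-up-rounded whole percentages).
#' @examples
#' proportion_ci(25, 28)
#' @export
proportion_ci <- function(successes, n, confidence = 0.95) {
  if (n <= 0) stop_input("n must be positive")
  if (successes < 0 || successes > n)
    stop_input("successes must lie in [0, n]")
  alpha <- 1 - confidence
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  structure(c(lower = lower, upper = upper),
            estimate = successes / n,
            percent = c(lower = round_half_up(100 * lower),
                        upper = round_half_up(100 * upper)))
}

#' Write the enrichment table
#'
#' @param enrichment an `nb_enrichment`.
#' @param tsv output path for the full table (full precision).
#' @param candidates_tsv optional output path for the candidate subset.
#' @return `invisible(enrichment)`.
#' @export
write_enrichment <- function(enrichment, tsv, candidates_tsv = NULL) {
  write_tsv(as.data.frame(enrichment), tsv)
  if (!is.null(candidates_tsv))
    write_tsv(as.data.frame(candidates(enrichment)), candidates_tsv)
  invisible(enrichment)
}
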