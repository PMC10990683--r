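#' Fit a cell-lineage expression profiler
#'
#' The one-stop fitting function of the expression side: takes long-format
#' single-cell nTPM records (or a TSV in the HPA dialect), collapses
#' cluster replicates by median, pivots to a dense lineage-by-gene matrix,
#' drops contrast-free genes, Min-Max normalizes every feature to [0, 1]
#' and precomputes the pairwise lineage distance matrix. The returned
#' object is the fitted classifier: [predict()][predict.lineage_profiler]
#' assigns query expression vectors to their nearest lineages by Manhattan
#' distance.
#'
#' @param records A data frame from [read_expression_table()], or a path /
#'   TSV text accepted by it.
#' @param cluster_mode `"merge"` (clusters collapse into their lineage) or
#'   `"retain"` (each cluster is its own row, keyed `"... c-<cluster>"`).
#' @param metric Distance metric for the precomputed lineage distance
#'   matrix: `"L1"` (Manhattan, default) or `"L2"` (Euclidean).
#' @return An object of class `"lineage_profiler"` with components
#'   `matrix` (raw median nTPM, lineages x genes), `norm` (Min-Max
#'   normalized matrix carrying stored per-gene min/max), `dist` (lineage
#'   distance matrix), `stats` (per gene/lineage dispersion from
#'   [cluster_stats()]), `dropped_genes`, `cluster_mode`, `metric`, `call`.
#' @export
#' @examples
#' tab <- simulate_expression_table(n_lineages = 4, n_genes = 40, seed = 1)
#' fit <- lineage_profiler(tab$records)
#' fit
#' predict(fit, tab$records[tab$records$tissue == tab$records$tissue[1], ] |>
#'   (\(d) tapply(d$ntpm, d$gene_symbol, median))(), top_k = 3)
lineage_profiler <- function(records, cluster_mode = c("merge", "retain"),
                             metric = c("L1", "L2")) {
  cluster_mode <- match.arg(cluster_mode)
  metric <- match.arg(metric)
  if (is.character(records)) records <- read_expression_table(records)
  stats <- cluster_stats(records)
  agg <- aggregate_median(records, cluster_mode)
  m <- build_expression_matrix(agg)
  norm <- minmax_normalize(m)
  structure(
    list(matrix = m, norm = norm, dist = distance_matrix(norm, metric),
         stats = stats, dropped_genes = attr(m, "dropped_genes"),
         cluster_mode = cluster_mode, metric = metric,
         call = match.call()),
    class = "lineage_profiler"
  )
}

#' @export
print.lineage_profiler <- function(x, ...) {
  cat("Cell-lineage expression profiler\n")
  cat("  lineages: ", nrow(x$matrix), " (", x$cluster_mode, " cluster mode)\n", sep = "")
  cat("  genes:    ", ncol(x$matrix), " (", length(x$dropped_genes),
      " constant gene(s) dropped)\n", sep = "")
  cat("  metric:   ", x$metric, " on Min-Max normalized features\n", sep = "")
  invisible(x)
}

#' @export
summary.lineage_profiler <- function(object, ...) {
  disp <- summarize_dispersion(object$stats)
  structure(
    list(n_lineages = nrow(object$matrix), n_genes = ncol(object$matrix),
         n_dropped = length(object$dropped_genes),
         cluster_mode = object$cluster_mode, metric = object$metric,
         dispersion = disp,
         dist_range = range(object$dist[upper.tri(object$dist)])),
    class = "summary.lineage_profiler"
  )
}

#' @export
print.summary.lineage_profiler <- function(x, ...) {
  cat("Cell-lineage expression profiler\n")
  cat(sprintf("  %d lineages x %d genes (%d constant gene(s) dropped; %s clusters)\n",
              x$n_lineages, x$n_genes, x$n_dropped, x$cluster_mode))
  cat(sprintf("  replicate dispersion: mean sd %.4g, mean CV %.4g%% (%d / %d groups NA-excluded)\n",
              x$dispersion$mean_sd, x$dispersion$mean_cv_percent,
              x$dispersion$n_sd_excluded, x$dispersion$n_cv_excluded))
  cat(sprintf("  %s lineage distances in [%.4g, %.4g]\n",
              x$metric, x$dist_range[1], x$dist_range[2]))
  invisible(x)
}

#' Classify query expression vectors against a fitted profiler
#'
#' @param object A [lineage_profiler()] fit.
#' @param newdata A named nTPM vector (gene symbols as names), or a list of
#'   such vectors for several queries.
#' @param top_k Nearest lineages to report per query (default 5).
#' @param ... Unused.
#' @return For a single query, a data frame `rank`, `lineage`, `distance`;
#'   for a list of queries, the row-bound data frame with a leading
#'   `query` column.
#' @export
predict.lineage_profiler <- function(object, newdata, top_k = 5L, ...) {
  if (is.list(newdata) && !is.data.frame(newdata)) {
    nms <- names(newdata) %||% as.character(seq_along(newdata))
    out <- lapply(seq_along(newdata), function(i) {
      r <- classify_lineage(object$norm, newdata[[i]], top_k)
      cbind(query = nms[i], r, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, out))
  }
  classify_lineage(object$norm, newdata, top_k)
}

#' Histogram of expression levels across lineages
#'
#' Plots the distribution of `log10(nTPM + 1)` over all (lineage, gene)
#' matrix cells, the at-a-glance view of how expression is spread across
#' the cell types.
#'
#' @param x A [lineage_profiler()] fit.
#' @param n_bins Number of equal-width bins.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.lineage_profiler <- function(x, n_bins = 30L, ...) {
  vals <- log10(as.numeric(x$matrix) + 1)
  h <- histogram_bins(vals, n_bins)
  mids <- (utils::head(h$edges, -1) + utils::tail(h$edges, -1)) / 2
  graphics::barplot(h$counts, names.arg = sprintf("%.1f", mids),
                    xlab = "log10(nTPM + 1)", ylab = "matrix cells",
                    main = "Expression distribution across lineages", ...)
  invisible(h)
}

#' Extract the z-score profile of a gene from a fit
#'
#' Convenience accessor; equivalent to `gene_zscores(fit$matrix, gene)`.
#'
#' @param fit A [lineage_profiler()] fit.
#' @param gene Gene symbol.
#' @param thresholds Tier thresholds, see [gene_zscores()].
#' @return A `"gene_zprofile"`.
#' @export
profile_gene <- function(fit, gene, thresholds = c(2, 3)) {
  stopifnot(inherits(fit, "lineage_profiler"))
  gene_zscores(fit$matrix, gene, thresholds)
}
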