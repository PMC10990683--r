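#' Read an HPA-style single-cell expression table
#'
#' Expects the seven-column tab-separated dialect of
#' `rna_single_cell_type_tissue.tsv`: `Gene` (Ensembl id), `Gene.name`
#' (gene symbol), `Tissue`, `Cluster`, `Cell.type`, `Read.count`, `nTPM`.
#' Header order is irrelevant. Rows whose nTPM is missing, non-numeric or
#' negative are rejected; the rejected count is reported via a message and
#' attached as attribute `"rejected"`.
#'
#' @param x TSV text (string or lines) or a path to a file.
#' @return A data frame of expression records with columns `ensembl_id`,
#'   `gene_symbol`, `tissue`, `cluster`, `cell_type`, `read_count`, `ntpm`.
#' @export
read_expression_table <- function(x) {
  con <- if (length(x) == 1L && !grepl("[\t\n]", x) && file.exists(x)) x else textConnection(paste(x, collapse = "\n"))
  df <- utils::read.delim(con, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("Gene", "Gene.name", "Tissue", "Cluster", "Cell.type",
                "Read.count", "nTPM")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("expression table format error: missing header '", missing[1L], "'",
         call. = FALSE)
  }
  ntpm <- suppressWarnings(as.numeric(df$nTPM))
  keep <- !is.na(ntpm) & ntpm >= 0 & nzchar(df$Gene.name)
  if (any(!keep)) {
    message("expression table: rejected ", sum(!keep), " row(s) with invalid nTPM")
  }
  out <- data.frame(
    ensembl_id = as.character(df$Gene[keep]),
    gene_symbol = as.character(df$Gene.name[keep]),
    tissue = as.character(df$Tissue[keep]),
    cluster = as.character(df$Cluster[keep]),
    cell_type = as.character(df$Cell.type[keep]),
    read_count = suppressWarnings(as.numeric(df$Read.count[keep])),
    ntpm = ntpm[keep],
    stringsAsFactors = FALSE
  )
  attr(out, "rejected") <- sum(!keep)
  out
}

# Lineage key: "<Tissue> <Cell.type>", with the cluster appended as
# " c-<cluster>" when clusters are retained as separate rows.
lineage_key <- function(tissue, cell_type, cluster = NULL) {
  key <- paste(tissue, cell_type)
  if (!is.null(cluster)) key <- paste0(key, " c-", cluster)
  key
}

#' Per (gene, lineage) dispersion statistics over cluster replicates
#'
#' Cluster rows sharing a gene and lineage (tissue + cell type) are treated
#' as replicate measurements of that lineage's expression. For each group
#' the mean, median, sample standard deviation (n - 1 denominator) and
#' coefficient of variation (`100 * sd / mean`, percent) are computed.
#' Singleton groups get `NA` sd and cv; cv is also `NA` when the group mean
#' is zero.
#'
#' @param records Data frame from [read_expression_table()].
#' @return A data frame with columns `gene_symbol`, `lineage`, `n`,
#'   `ntpm_list` (list column), `mean`, `median`, `sd`, `cv_percent`.
#' @export
#' @examples
#' recs <- data.frame(ensembl_id = "", gene_symbol = "DEFA5",
#'                    tissue = "Small intestine", cluster = c("c-1", "c-2", "c-3"),
#'                    cell_type = "undifferentiated cells", read_count = 0,
#'                    ntpm = c(882, 5116.4, 941045))
#' cluster_stats(recs)$sd  # 541585.1, the n - 1 convention
cluster_stats <- function(records) {
  key <- paste(records$gene_symbol, lineage_key(records$tissue, records$cell_type),
               sep = "\r")
  groups <- split(records$ntpm, key)
  labels <- strsplit(names(groups), "\r", fixed = TRUE)
  out <- data.frame(
    gene_symbol = vapply(labels, `[[`, character(1), 1L),
    lineage = vapply(labels, `[[`, character(1), 2L),
    n = lengths(groups),
    stringsAsFactors = FALSE
  )
  out$ntpm_list <- unname(groups)
  out$mean <- vapply(groups, mean, numeric(1))
  out$median <- vapply(groups, stats::median, numeric(1))
  out$sd <- vapply(groups, function(v) if (length(v) < 2L) NA_real_ else stats::sd(v),
                   numeric(1))
  out$cv_percent <- ifelse(is.na(out$sd) | out$mean == 0, NA_real_,
                           100 * out$sd / out$mean)
  rownames(out) <- NULL
  out
}

#' Corpus-wide dispersion summary
#'
#' Arithmetic means of the per-group standard deviation and coefficient of
#' variation, with `NA` entries (singleton or zero-mean groups) excluded,
#' mirroring `na.rm = TRUE` aggregation. The exclusion counts are returned
#' alongside the means.
#'
#' @param stats Data frame from [cluster_stats()].
#' @return A list with `mean_sd`, `mean_cv_percent`, `n_sd_excluded`,
#'   `n_cv_excluded`.
#' @export
summarize_dispersion <- function(stats) {
  list(
    mean_sd = if (all(is.na(stats$sd))) NA_real_ else mean(stats$sd, na.rm = TRUE),
    mean_cv_percent = if (all(is.na(stats$cv_percent))) NA_real_ else mean(stats$cv_percent, na.rm = TRUE),
    n_sd_excluded = sum(is.na(stats$sd)),
    n_cv_excluded = sum(is.na(stats$cv_percent))
  )
}

#' Collapse cluster replicates to one value per lineage
#'
#' In `"merge"` mode cluster rows of the same gene and lineage collapse to
#' their median (even-sized lists take the mean of the two central values,
#' the standard median). In `"retain"` mode each cluster keeps its own row
#' under the key `"<Tissue> <Cell.type> c-<cluster>"`; duplicates within a
#' cluster still collapse by median.
#'
#' @param records Data frame from [read_expression_table()].
#' @param cluster_mode `"merge"` or `"retain"`.
#' @return A long data frame with columns `lineage`, `gene_symbol`, `value`.
#' @export
aggregate_median <- function(records, cluster_mode = c("merge", "retain")) {
  cluster_mode <- match.arg(cluster_mode)
  lin <- if (cluster_mode == "merge") {
    lineage_key(records$tissue, records$cell_type)
  } else {
    lineage_key(records$tissue, records$cell_type, records$cluster)
  }
  key <- paste(lin, records$gene_symbol, sep = "\r")
  med <- vapply(split(records$ntpm, key), stats::median, numeric(1))
  labels <- strsplit(names(med), "\r", fixed = TRUE)
  out <- data.frame(
    lineage = vapply(labels, `[[`, character(1), 1L),
    gene_symbol = vapply(labels, `[[`, character(1), 2L),
    value = unname(med),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Pivot aggregated expression into a lineage-by-gene matrix
#'
#' Rows are lineage keys, columns genes. Combinations absent from the input
#' are filled with 0 nTPM (absence of reads, not missingness -- the
#' classifier needs a dense feature vector). Columns whose values are all
#' identical, including all-zero columns, carry no contrast and are
#' dropped; the dropped gene list is attached as attribute
#' `"dropped_genes"`.
#'
#' @param aggregated Data frame from [aggregate_median()].
#' @return A numeric matrix (lineages x genes).
#' @export
build_expression_matrix <- function(aggregated) {
  lineages <- sort(unique(aggregated$lineage))
  genes <- sort(unique(aggregated$gene_symbol))
  if (length(lineages) < 2L) {
    stop("pipeline error: need at least 2 lineages (distances undefined)",
         call. = FALSE)
  }
  m <- matrix(0, nrow = length(lineages), ncol = length(genes),
              dimnames = list(lineages, genes))
  m[cbind(match(aggregated$lineage, lineages),
          match(aggregated$gene_symbol, genes))] <- aggregated$value
  constant <- apply(m, 2L, function(col) length(unique(col)) == 1L)
  dropped <- colnames(m)[constant]
  m <- m[, !constant, drop = FALSE]
  attr(m, "dropped_genes") <- dropped
  m
}

#' Min-Max normalize matrix columns to [0, 1]
#'
#' `x' = (x - min) / (max - min)` per column (feature), so every feature
#' attains both 0 and 1 and large-range genes cannot dominate the distance.
#' The per-column minima and maxima are stored as attributes `"min"` and
#' `"max"` for normalizing later query vectors. Constant columns are an
#' invariant breach (cleaning was skipped) and raise an error.
#'
#' @param m Matrix from [build_expression_matrix()].
#' @return The normalized matrix with attributes `"min"` and `"max"`.
#' @export
minmax_normalize <- function(m) {
  mins <- apply(m, 2L, min)
  maxs <- apply(m, 2L, max)
  if (any(maxs == mins)) {
    stop("invariant error: constant column '",
         colnames(m)[which(maxs == mins)[1L]],
         "' encountered; run build_expression_matrix() cleaning first",
         call. = FALSE)
  }
  norm <- sweep(sweep(m, 2L, mins, "-"), 2L, maxs - mins, "/")
  attr(norm, "min") <- mins
  attr(norm, "max") <- maxs
  attr(norm, "dropped_genes") <- attr(m, "dropped_genes")
  norm
}

#' Pairwise lineage distance matrix
#'
#' Full symmetric matrix of L1 (Manhattan) or L2 (Euclidean) distances
#' between lineage feature vectors, computed on the normalized matrix.
#'
#' @param norm Normalized matrix from [minmax_normalize()].
#' @param metric `"L1"` (default) or `"L2"`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(norm, metric = c("L1", "L2")) {
  metric <- match.arg(metric)
  d <- stats::dist(norm, method = if (metric == "L1") "manhattan" else "euclidean")
  as.matrix(d)
}

#' Classify a query expression vector to its nearest lineages
#'
#' The query (named nTPM vector, gene symbols as names) is aligned to the
#' matrix features: matrix genes absent from the query are treated as 0
#' nTPM before normalization; query genes absent from the matrix are
#' dropped with a warning. The aligned vector is Min-Max normalized with
#' the stored training minima/maxima and clamped to [0, 1] (new data may
#' exceed the stored range), then ranked against all lineages by Manhattan
#' distance, ties broken by lineage key.
#'
#' @param norm Normalized matrix from [minmax_normalize()] (carrying the
#'   stored min/max attributes).
#' @param query Named numeric vector of nTPM values.
#' @param top_k Number of nearest lineages to return (default 5).
#' @return A data frame with columns `rank`, `lineage`, `distance`.
#' @export
classify_lineage <- function(norm, query, top_k = 5L) {
  mins <- attr(norm, "min"); maxs <- attr(norm, "max")
  if (is.null(mins) || is.null(maxs)) {
    stop("normalization parameters missing: pass a minmax_normalize() matrix",
         call. = FALSE)
  }
  genes <- colnames(norm)
  extra <- setdiff(names(query), genes)
  shared <- intersect(names(query), genes)
  if (!length(shared)) {
    stop("input error: no query genes overlap the matrix features", call. = FALSE)
  }
  if (length(extra)) {
    warning("ignoring ", length(extra), " query gene(s) absent from the matrix",
            call. = FALSE)
  }
  q <- stats::setNames(numeric(length(genes)), genes)
  q[shared] <- as.numeric(query[shared])
  qn <- (q - mins) / (maxs - mins)
  qn <- pmin(pmax(qn, 0), 1)
  dist <- rowSums(abs(sweep(norm, 2L, qn, "-")))
  ord <- order(dist, rownames(norm))
  top <- utils::head(ord, top_k)
  data.frame(rank = seq_along(top), lineage = rownames(norm)[top],
             distance = unname(dist[top]), stringsAsFactors = FALSE)
}

#' Per-gene z-score differential expression profile
#'
#' Standardizes one gene's expression across lineages,
#' `z = (x - mean) / sd` with the sample standard deviation, and tiers each
#' lineage by threshold: `|z| >= z_very` is `very_significant`,
#' `|z| >= z_sig` is `significant`, else `none`. A constant gene
#' (`sd = 0`) yields all-zero z and tier `none` everywhere. Because
#' z-scores are relative to the sampled lineages, a gene expressed at trace
#' levels everywhere but one missing tissue can still look significant --
#' coverage of the lineage panel matters.
#'
#' @param m Raw (unnormalized) matrix from [build_expression_matrix()].
#' @param gene Gene symbol (column of `m`).
#' @param thresholds Numeric `c(z_sig, z_very)`; default `c(2, 3)`.
#' @return An object of class `"gene_zprofile"`: list with `gene_symbol`,
#'   `table` (data frame `lineage`, `ntpm`, `z`, `tier`, sorted by `z`
#'   descending), `gene_mean`, `gene_sd`.
#' @export
gene_zscores <- function(m, gene, thresholds = c(2, 3)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] <= thresholds[2])
  if (!gene %in% colnames(m)) {
    near <- utils::head(agrep(gene, colnames(m), value = TRUE,
                              ignore.case = TRUE, max.distance = 0.2), 5L)
    stop("unknown gene '", gene, "'",
         if (length(near)) paste0("; did you mean: ", paste(near, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(m) < 3L) stop("need at least 3 lineages for z-scores", call. = FALSE)
  x <- m[, gene]
  mu <- mean(x)
  s <- stats::sd(x)
  z <- if (s > 0) (x - mu) / s else rep(0, length(x))
  tier <- ifelse(s > 0 & abs(z) >= thresholds[2], "very_significant",
                 ifelse(s > 0 & abs(z) >= thresholds[1], "significant", "none"))
  ord <- order(-z, rownames(m))
  structure(
    list(gene_symbol = gene,
         table = data.frame(lineage = rownames(m)[ord], ntpm = unname(x[ord]),
                            z = unname(z[ord]), tier = unname(tier[ord]),
                            stringsAsFactors = FALSE),
         gene_mean = mu, gene_sd = s),
    class = "gene_zprofile"
  )
}

#' @export
print.gene_zprofile <- function(x, n = 10L, ...) {
  cat("<gene_zprofile> ", x$gene_symbol,
      sprintf("  (mean %.3g, sd %.3g over %d lineages)\n",
              x$gene_mean, x$gene_sd, nrow(x$table)), sep = "")
  print(utils::head(x$table, n), row.names = FALSE)
  if (nrow(x$table) > n) cat("  ... ", nrow(x$table) - n, " more lineage(s)\n", sep = "")
  invisible(x)
}

#' Ordinary least-squares fit with R-squared
#'
#' Thin wrapper over [stats::lm()] used to quantify how weakly nTPM tracks
#' raw read counts.
#'
#' @param x,y Equal-length numeric vectors, `length >= 3`; `x` must vary.
#' @return A list with `slope`, `intercept`, `r_squared`.
#' @export
regression_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    stop("x and y must have equal length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate input: x is constant", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Equal-width histogram bins
#'
#' Bins span `[min, max]` of the data in `n_bins` equal widths; bins are
#' right-open except the last, which includes the maximum. When all values
#' coincide the single occupied bin is the first.
#'
#' @param values Non-empty numeric vector.
#' @param n_bins Number of bins, `>= 1`.
#' @return A list with `edges` (length `n_bins + 1`) and `counts`
#'   (length `n_bins`, summing to `length(values)`).
#' @export
histogram_bins <- function(values, n_bins) {
  if (!length(values)) stop("input error: empty values", call. = FALSE)
  stopifnot(n_bins >= 1L)
  lo <- min(values); hi <- max(values)
  if (lo == hi) {
    edges <- seq(lo, lo + 1, length.out = n_bins + 1L)
    counts <- c(length(values), rep(0L, n_bins - 1L))
    return(list(edges = edges, counts = as.integer(counts)))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(values, edges, rightmost.closed = TRUE)
  counts <- tabulate(idx, nbins = n_bins)
  list(edges = edges, counts = as.integer(counts))
}

#' Export pre-processed expression profiles
#'
#' Writes one TSV per lineage (genes ranked by nTPM descending), one TSV
#' per gene (lineages ranked by z-score descending, matching
#' [gene_zscores()] order), and the lineage distance matrix, plus a JSON
#' manifest of counts. Formatting is deterministic, so re-export is
#' byte-identical.
#'
#' @param fit A [lineage_profiler()] fit.
#' @param out_dir Output directory (created if needed).
#' @param thresholds z-score tier thresholds, as in [gene_zscores()].
#' @return The manifest, invisibly: list with `n_lineage_files`,
#'   `n_gene_files`, `n_files`, `files`.
#' @export
export_profiles <- function(fit, out_dir, thresholds = c(2, 3)) {
  stopifnot(inherits(fit, "lineage_profiler"))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("I/O error: cannot create '", out_dir, "'", call. = FALSE)
  m <- fit$matrix
  safe <- function(x) gsub("[^A-Za-z0-9._-]", "_", x)
  files <- character()

  for (lin in rownames(m)) {
    v <- m[lin, ]
    ord <- order(-v, colnames(m))
    df <- data.frame(gene = colnames(m)[ord], ntpm = unname(v[ord]))
    path <- file.path(out_dir, paste0("lineage_", safe(lin), ".tsv"))
    utils::write.table(format(df, trim = TRUE, scientific = FALSE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  for (g in colnames(m)) {
    zp <- gene_zscores(m, g, thresholds)
    path <- file.path(out_dir, paste0("gene_", safe(g), ".tsv"))
    utils::write.table(format(zp$table, trim = TRUE, scientific = FALSE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, path)
  }
  dpath <- file.path(out_dir, "distance_matrix.tsv")
  utils::write.table(format(as.data.frame(fit$dist), trim = TRUE, scientific = FALSE),
                     dpath, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  files <- c(files, dpath)

  manifest <- list(n_lineage_files = nrow(m), n_gene_files = ncol(m),
                   n_files = length(files), files = basename(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
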