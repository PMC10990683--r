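table1_tsv <- paste(
  "Gene\tGene.name\tTissue\tCluster\tCell.type\tRead.count\tnTPM",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-1\tsmooth muscle cells\t100\t62.3",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-2\tt-cells\t100\t3.3",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-3\tsmooth muscle cells\t100\t19.3",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-4\tendothelial cells\t100\t50.1",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-5\tfibroblasts\t100\t44.9",
  "ENSG00000000003\tTSPAN6\tPlacenta\tc-6\tmixed immune cells\t100\t11.7",
  sep = "\n"
)

test_that("the expression reader accepts the seven-column dialect", {
  recs <- read_expression_table(table1_tsv)
  expect_equal(nrow(recs), 6L)
  expect_equal(recs$gene_symbol[1], "TSPAN6")
  expect_equal(recs$ntpm[1], 62.3)

  # header order is irrelevant
  lines <- strsplit(table1_tsv, "\n")[[1]]
  fields <- strsplit(lines, "\t")
  perm <- c(7, 2, 1, 3, 5, 4, 6)
  permuted <- paste(vapply(fields, function(f) paste(f[perm], collapse = "\t"),
                           character(1)), collapse = "\n")
  expect_equal(read_expression_table(permuted), recs, ignore_attr = TRUE)

  # invalid nTPM rows are rejected, not fatal
  bad <- paste(table1_tsv, "E1\tG1\tT\tc-1\tct\t1\t-5", "E2\tG2\tT\tc-1\tct\t1\tNaN?",
               sep = "\n")
  expect_message(recs2 <- read_expression_table(bad), "rejected 2")
  expect_equal(nrow(recs2), 6L)

  expect_error(read_expression_table("Gene\tnTPM\nE\t1"), "Gene.name")
})

test_that("cluster dispersion uses the sample standard deviation", {
  st <- cluster_stats(defa5_records())
  expect_equal(nrow(st), 1L)
  expect_equal(st$lineage, "Small intestine undifferentiated cells")
  expect_equal(st$sd, 541585.1, tolerance = 0.5 / 541585)
  # the population (n denominator) value must NOT match
  expect_gt(abs(st$sd - 442202.4), 0.5)
  expect_equal(st$cv_percent, 171.56, tolerance = 1e-2)
  expect_equal(st$median, 5116.4)

  single <- cluster_stats(placenta_records()[2, ])
  expect_true(is.na(single$sd) && is.na(single$cv_percent))

  const <- defa5_records(); const$ntpm <- c(5, 5, 5)
  stc <- cluster_stats(const)
  expect_equal(stc$sd, 0)
  expect_equal(stc$cv_percent, 0)
})

test_that("dispersion summaries exclude NA groups and report the exclusions", {
  st <- data.frame(gene_symbol = c("a", "b", "c"), lineage = "L", n = c(2, 2, 1),
                   mean = 1, median = 1, sd = c(2, 4, NA),
                   cv_percent = c(10, 20, NA))
  s <- summarize_dispersion(st)
  expect_equal(s$mean_sd, 3)
  expect_equal(s$mean_cv_percent, 15)
  expect_equal(s$n_sd_excluded, 1L)

  allna <- st; allna$sd <- NA_real_; allna$cv_percent <- NA_real_
  expect_true(is.na(summarize_dispersion(allna)$mean_sd))

  # brute-force agreement on generated data
  synth <- simulate_expression_table(n_lineages = 4, n_genes = 40, seed = 21)
  st <- cluster_stats(synth$records)
  brute <- tapply(synth$records$ntpm,
                  paste(synth$records$gene_symbol, synth$records$tissue,
                        synth$records$cell_type),
                  stats::sd)
  expect_equal(summarize_dispersion(st)$mean_sd, mean(brute, na.rm = TRUE))
})

test_that("merge-mode aggregation medians the placenta smooth muscle clusters", {
  agg <- aggregate_median(placenta_records(), "merge")
  sm <- agg$value[agg$lineage == "Placenta smooth muscle cells"]
  expect_equal(sm, 40.8)  # median of 62.3 and 19.3
  expect_equal(nrow(agg), 5L)

  ret <- aggregate_median(placenta_records(), "retain")
  expect_equal(nrow(ret), 6L)  # no merging across clusters
  expect_true(all(grepl(" c-", ret$lineage)))

  one <- aggregate_median(placenta_records()[1, ], "merge")
  expect_equal(one$value, 62.3)
})

test_that("the pivoted matrix zero-fills gaps and drops constant columns", {
  agg <- data.frame(
    lineage = c("L1", "L1", "L2", "L2", "L2"),
    gene_symbol = c("g1", "gz", "g1", "gz", "gonly"),
    value = c(1, 0, 2, 0, 7)
  )
  m <- build_expression_matrix(agg)
  expect_equal(attr(m, "dropped_genes"), "gz")      # all-zero column
  expect_equal(m["L1", "gonly"], 0)                 # zero-filled gap
  expect_equal(sort(colnames(m)), c("g1", "gonly"))

  # constant non-zero columns are dropped and listed too
  agg$value[agg$gene_symbol == "gz"] <- 3
  m2 <- build_expression_matrix(agg)
  expect_false("gz" %in% colnames(m2))
  expect_true("gz" %in% attr(m2, "dropped_genes"))

  expect_error(build_expression_matrix(agg[agg$lineage == "L1", ]),
               "at least 2 lineages")
})

test_that("Min-Max normalization maps every feature onto [0, 1]", {
  m <- matrix(c(0, 5, 10, 1, 2, 4), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("g1", "g2")))
  norm <- minmax_normalize(m)
  expect_equal(unname(norm[, "g1"]), c(0, 0.5, 1))
  expect_equal(attr(norm, "min")[["g1"]], 0)
  expect_equal(attr(norm, "max")[["g1"]], 10)

  # idempotent on already-normalized columns; monotone within columns
  norm2 <- minmax_normalize(norm)
  expect_equal(unclass(norm2), unclass(norm), ignore_attr = TRUE)
  expect_equal(order(norm[, "g2"]), order(m[, "g2"]))

  const <- cbind(m, gc = c(2, 2, 2))
  expect_error(minmax_normalize(const), "constant column")

  synth <- simulate_expression_table(n_lineages = 4, n_genes = 40, seed = 3)
  sm <- minmax_normalize(build_expression_matrix(
    aggregate_median(synth$records, "merge")))
  expect_true(all(sm >= 0 & sm <= 1))
  expect_equal(unname(apply(sm, 2, min)), rep(0, ncol(sm)))
  expect_equal(unname(apply(sm, 2, max)), rep(1, ncol(sm)))
})

test_that("distance matrices agree with the double-loop oracle", {
  m <- matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE,
              dimnames = list(c("r1", "r2"), c("g1", "g2")))
  expect_equal(distance_matrix(m, "L1")["r1", "r2"], 2)
  expect_equal(distance_matrix(m, "L2")["r1", "r2"], sqrt(2))

  set.seed(42)
  r <- matrix(runif(20), nrow = 5, dimnames = list(paste0("l", 1:5), paste0("g", 1:4)))
  for (metric in c("L1", "L2")) {
    d <- distance_matrix(r, metric)
    expect_equal(d, oracle_distances(r, metric), tolerance = 1e-12)
  }

  # metric axioms on random triples
  set.seed(7)
  big <- matrix(runif(30 * 8), nrow = 30)
  rownames(big) <- paste0("l", 1:30)
  d <- distance_matrix(big, "L1")
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 30))
  for (k in 1:1000) {
    ijk <- sample(30, 3)
    expect_lte(d[ijk[1], ijk[3]],
               d[ijk[1], ijk[2]] + d[ijk[2], ijk[3]] + 1e-12)
  }
})

test_that("the classifier recovers a lineage from its own raw vector", {
  synth <- simulate_expression_table(n_lineages = 6, n_genes = 60, seed = 5)
  fit <- lineage_profiler(synth$records)
  for (lin in rownames(fit$matrix)) {
    res <- predict(fit, fit$matrix[lin, ], top_k = 1)
    expect_equal(res$lineage, lin)
    expect_lt(res$distance, 1e-12)
  }
})

test_that("query alignment zero-fills, warns on extras, clamps out-of-range", {
  synth <- simulate_expression_table(n_lineages = 4, n_genes = 40, seed = 5)
  fit <- lineage_profiler(synth$records)
  lin <- rownames(fit$matrix)[1]
  full <- fit$matrix[lin, ]

  # dropping a gene from the query treats it as 0 before normalization
  partial <- full[-1]
  res <- classify_lineage(fit$norm, partial, top_k = nrow(fit$matrix))
  manual <- full; manual[1] <- 0
  res2 <- classify_lineage(fit$norm, manual, top_k = nrow(fit$matrix))
  expect_equal(res, res2)

  # unknown genes are ignored with a warning
  extra <- c(full, UNKNOWN_GENE = 5)
  expect_warning(res3 <- classify_lineage(fit$norm, extra, top_k = 1),
                 "ignoring 1")
  expect_equal(res3$lineage, lin)

  # out-of-range values clamp, so a huge query stays comparable
  huge <- full * 1e6
  expect_silent(res4 <- classify_lineage(fit$norm, huge, top_k = 1))
  expect_true(res4$distance <= ncol(fit$norm))

  expect_error(classify_lineage(fit$norm, c(NOPE = 1)), "no query genes")
})

test_that("gene z-scores standardize exactly and tier extremes", {
  # one lineage expressing among twelve silent ones: unique maximal z,
  # past the very-significant threshold (z = 11/sqrt(12.83) ~ 3.17)
  m <- matrix(c(rep(0, 11), 100), ncol = 1, dimnames = list(paste0("l", 1:12), "g"))
  m <- cbind(m, filler = 1:12)
  zp <- gene_zscores(m, "g")
  expect_equal(zp$table$lineage[1], "l12")
  expect_equal(zp$table$tier[1], "very_significant")
  expect_gt(zp$table$z[1], max(zp$table$z[-1]))
  expect_true(all(zp$table$tier[-1] == "none"))
  # standardization identity
  expect_lt(abs(mean(zp$table$z)), 1e-9)
  expect_lt(abs(stats::sd(zp$table$z) - 1), 1e-9)

  mc <- cbind(m, const = rep(3, 12))
  # constant columns never reach gene_zscores in the pipeline, but the
  # operation itself degrades gracefully
  zc <- gene_zscores(mc, "const")
  expect_true(all(zc$table$z == 0))
  expect_true(all(zc$table$tier == "none"))

  expect_error(gene_zscores(m, "gz"), "unknown gene")
})

test_that("least-squares r-squared behaves like a goodness of fit", {
  x <- 1:20
  fit <- suppressWarnings(regression_r2(x, 2 * x + 1))  # exact fit by design
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 1)

  set.seed(11)
  xr <- rnorm(1000); yr <- rnorm(1000)
  expect_lt(regression_r2(xr, yr)$r_squared, 0.05)

  # invariant under affine rescaling of x
  y <- 2 * x + rnorm(20, sd = 3)
  expect_equal(regression_r2(10 * x - 7, y)$r_squared,
               regression_r2(x, y)$r_squared)

  expect_error(regression_r2(rep(1, 5), 1:5), "constant")
})

test_that("histogram bins cover the range and conserve counts", {
  h <- histogram_bins(0:9, 2L)
  expect_equal(h$counts, c(5L, 5L))
  expect_equal(h$edges, c(0, 4.5, 9))

  hc <- histogram_bins(rep(2, 7), 4L)
  expect_equal(sum(hc$counts > 0), 1L)
  expect_equal(sum(hc$counts), 7L)

  set.seed(3)
  v <- rnorm(500)
  expect_equal(sum(histogram_bins(v, 13L)$counts), 500L)
})

test_that("collapsing a retain-mode matrix by median equals merge mode", {
  synth <- simulate_expression_table(n_lineages = 4, n_clusters = 3,
                                     n_genes = 40, seed = 13)
  merge_m <- build_expression_matrix(aggregate_median(synth$records, "merge"))
  retain_m <- build_expression_matrix(aggregate_median(synth$records, "retain"))
  base_key <- sub(" c-.*$", "", rownames(retain_m))
  collapsed <- do.call(rbind, lapply(split(seq_len(nrow(retain_m)), base_key),
    function(ix) apply(retain_m[ix, , drop = FALSE], 2, stats::median)))
  expect_equal(collapsed[rownames(merge_m), colnames(merge_m)],
               unclass(merge_m), ignore_attr = TRUE)
})

test_that("profile export writes one file per lineage, gene, and the matrix", {
  synth <- simulate_expression_table(n_lineages = 4, n_clusters = 2,
                                     n_genes = 40, seed = 2)
  # shrink to 3 lineages x 4 genes for the count rule
  recs <- synth$records[synth$records$gene_symbol %in%
                          c("GENE0001", "GENE0002", "GENE0021", "GENE0022") &
                        paste(synth$records$tissue, synth$records$cell_type) %in%
                          unique(paste(synth$records$tissue, synth$records$cell_type))[1:3], ]
  fit <- lineage_profiler(recs)
  out <- file.path(tempdir(), "gep-export-test")
  unlink(out, recursive = TRUE)
  manifest <- export_profiles(fit, out)
  expect_equal(manifest$n_files,
               nrow(fit$matrix) + ncol(fit$matrix) + 1L)

  # per-gene file ordering matches the z-score ranking
  g <- colnames(fit$matrix)[1]
  ranked <- utils::read.delim(file.path(out, paste0("gene_", g, ".tsv")))
  expect_equal(ranked$lineage, gene_zscores(fit$matrix, g)$table$lineage)

  # deterministic re-export is byte-identical
  before <- lapply(manifest$files, function(f) readLines(file.path(out, f)))
  export_profiles(fit, out)
  after <- lapply(manifest$files, function(f) readLines(file.path(out, f)))
  expect_identical(before, after)
})

test_that("the fitted profiler prints and summarizes coherently", {
  synth <- simulate_expression_table(n_lineages = 4, n_genes = 40, seed = 1)
  fit <- lineage_profiler(synth$records)
  expect_output(print(fit), "4")
  s <- summary(fit)
  expect_equal(s$n_lineages, 4L)
  expect_output(print(s), "dispersion")
  expect_s3_class(profile_gene(fit, colnames(fit$matrix)[1]), "gene_zprofile")
})
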