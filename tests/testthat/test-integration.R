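test_that("methylation-expression overlap classifies relations exhaustively", {
  dmc_sum <- tibble::tibble(gene = c("A", "B", "C", "D", "E"),
                            n_dmc = c(3L, 2L, 4L, 1L, 2L),
                            direction = c("hypo", "hyper", "hypo", "hyper",
                                          "mixed"))
  de <- tibble::tibble(gene = c("A", "B", "C", "D", "E", "F"),
                       direction = c("up", "down", "down", "up", "up", "up"))
  res <- overlap_dmc_de(dmc_sum, de)
  expect_equal(res$overlap$relation,
               c("inverse", "inverse", "concordant", "concordant",
                 "ambiguous"))
  # relations partition the overlap: counts sum to the overlap size
  s <- res$summary
  expect_equal(s$n_inverse + s$n_concordant + s$n_ambiguous, s$n_overlap)
  expect_equal(s$n_overlap, 5)
  # genes only on one side never appear
  expect_false("F" %in% res$overlap$gene)
  empty <- overlap_dmc_de(dmc_sum[0, ], de)
  expect_true(is.na(empty$summary$inverse_fraction))
})

test_that("the planted inverse fraction is recovered end to end", {
  ig <- simulate_integrated(seed = 19)
  dm <- call_dmcs(ig$meth$beta, ig$meth$samples, "DUX4_IGH")
  dg <- dmc_genes(dm, ig$meth$annotation)
  cd <- consensus_de(ig$expr$fpkm, ig$expr$samples, "DUX4_IGH",
                     c("ZNF384_r", "t1221", "t922", "MLL_r", "HeH",
                       "normal_CD19B"))
  ov <- overlap_dmc_de(dg, cd)
  expect_gte(ov$summary$n_overlap, 90)
  expect_lt(abs(ov$summary$inverse_fraction - 0.85), 0.05)
})

test_that("copy-number segments corroborate fusion loci within the window", {
  gm <- tibble::tibble(gene = c("GA", "GB", "GC"),
                       chrom = c("chr1", "chr2", "chr3"),
                       start = c(1e6, 5e6, 9e6), end = c(1.1e6, 5.1e6, 9.1e6))
  calls <- tibble::tibble(sample_id = c("s1", "s1", "s2"),
                          gene5 = c("GA", "GC", "GA"),
                          gene3 = c("GB", "GB", "GB"))
  segments <- tibble::tibble(
    sample_id = c("s1", "s1", "s2"),
    chrom = c("chr1", "chr3", "chr1"),
    start = c(1.05e6, 9.15e6, 1.7e6),
    end = c(1.2e6, 9.2e6, 1.8e6),
    state = c("deletion", "amplification", "deletion")
  )
  res <- cna_corroborate(calls, segments, gm, window = 1e5)
  # direct overlap of the gene body
  expect_true(res$corroborated[1])
  expect_equal(res$segment_state[1], "deletion")
  # segment in the 100 kb window but not the body still corroborates
  expect_true(res$corroborated[2])
  # nearest segment 500 kb away does not
  expect_false(res$corroborated[3])
  # monotone in window: enlarging it can only add corroborations
  wide <- cna_corroborate(calls, segments, gm, window = 1e6)
  expect_true(all(res$corroborated <= wide$corroborated))

  expect_error(cna_corroborate(calls, dplyr::mutate(segments, end = start),
                               gm), "start < end")
  expect_error(cna_corroborate(dplyr::mutate(calls, gene5 = "NOPE"),
                               segments, gm), "NOPE")
})

test_that("alteration co-occurrence reproduces the compiled case table", {
  alt <- all_alterations()
  co <- cooccurrence_table(alt$calls, alt$mutations, alt$cna_flags)

  # 7 of the 9 DUX4-IGH cases carry an ERG deletion
  erg <- co$cna_counts[co$cna_counts$family == "DUX4_IGH" &
                         co$cna_counts$cna == "ERG deletion", ]
  expect_equal(erg$n_samples, 7L)
  expect_equal(nrow(alt$calls[alt$calls$family == "DUX4_IGH", ]), 9L)

  # all 5 assessed DUX4-IGH cases carry an NRAS p.G12 hotspot variant
  nras <- co$mutation_counts[co$mutation_counts$family == "DUX4_IGH" &
                               co$mutation_counts$gene == "NRAS" &
                               co$mutation_counts$pattern == "p.G12", ]
  expect_equal(nras$n_samples, 5L)
  expect_equal(nras$n_assessed, 5L)

  # both TCF3-ZNF384 cases: PTPN11 mutation plus chr7q deletion
  tcf3 <- alt$calls$sample_id[alt$calls$fusion_gene == "TCF3-ZNF384"]
  tab <- co$table[co$table$sample_id %in% tcf3, ]
  expect_equal(nrow(tab), 2)
  expect_true(all(grepl("PTPN11", tab$mutations)))
  expect_true(all(tab$cna == "chr7q deletion"))
  ptpn11 <- co$gene_counts[co$gene_counts$family == "ZNF384_r" &
                             co$gene_counts$gene == "PTPN11", ]
  expect_equal(ptpn11$n_samples, 2L)

  # hotspot collapsing: G12D and G12S are one pattern
  expect_equal(sum(co$mutation_counts$pattern == "p.G12" &
                     co$mutation_counts$family == "DUX4_IGH"), 1)

  # malformed protein-change strings are row errors
  bad <- alt$mutations
  bad$protein_change[1] <- "G12D"
  expect_error(cooccurrence_table(alt$calls, bad, alt$cna_flags), "Malformed")
})

test_that("cluster profiles separate planted groups and match an eigen oracle", {
  set.seed(23)
  # two planted clusters, 12 samples, 60 features (20 informative)
  centers <- cbind(matrix(0, 60, 6), matrix(0, 60, 6))
  centers[1:20, 7:12] <- 3
  mat <- centers + matrix(rnorm(60 * 12, 0, 0.5), 60, 12)
  dimnames(mat) <- list(sprintf("f%02d", 1:60), sprintf("s%02d", 1:12))
  emb <- cluster_profiles(mat, n_top = 30)
  labels <- rep(c("a", "b"), each = 6)
  expect_gt(silhouette_1d(emb$scores$PC1, labels), 0.5)
  # variance fractions are proper and non-increasing
  expect_true(all(emb$var_explained >= 0 & emb$var_explained <= 1))
  expect_true(diff(emb$var_explained) <= 0)

  # PCA agrees with an independent eigendecomposition of the covariance
  sub <- mat[emb$top_features, ]
  centred <- scale(t(sub), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centred))$values
  expect_equal(emb$var_explained, (ev / sum(ev))[1:2], tolerance = 1e-8)

  # a duplicated sample gets identical coordinates
  dup <- cbind(mat, s13 = mat[, "s01"])
  emb2 <- cluster_profiles(dup, n_top = 30)
  expect_equal(unlist(emb2$scores[emb2$scores$sample_id == "s13", -1]),
               unlist(emb2$scores[emb2$scores$sample_id == "s01", -1]))
  # dendrogram covers every sample exactly once
  expect_setequal(emb2$dendrogram_order, colnames(dup))

  expect_error(cluster_profiles(mat, n_top = 1000), "exceeds")
  expect_error(cluster_profiles(mat[, 1:2], n_top = 10), "3 samples")
  expect_error(cluster_profiles(matrix(1, 5, 5), n_top = 2), "Constant")
})

test_that("plots and tidiers produce the expected object shapes", {
  sim <- simulate_candidates(seed = 2)
  res <- apply_filter_cascade(sim$candidates, sim$config)
  expect_s3_class(glance(res), "tbl_df")
  expect_equal(nrow(tidy(res)), nrow(sim$candidates))

  ms <- simulate_methylation(n_cpg = 400, n_dmc = 100, seed = 3)
  dm <- call_dmcs(ms$beta, ms$samples, "DUX4_IGH")
  expect_s3_class(autoplot(dm), "ggplot")
  enr <- context_enrichment(dm, ms$annotation)
  expect_s3_class(plot_enrichment(enr), "ggplot")

  mat <- matrix(rnorm(200), 20, 10,
                dimnames = list(sprintf("f%d", 1:20), sprintf("s%d", 1:10)))
  emb <- cluster_profiles(mat, n_top = 10)
  expect_s3_class(autoplot(emb), "ggplot")
  expect_named(glance(emb), c("n_samples", "n_features", "var_PC1", "var_PC2"))

  g <- build_fusion_graph(tibble::tibble(
    sample_id = c("s1", "s2", "s3"), gene5 = c("A", "A", "B"),
    gene3 = c("B", "C", "C"), subtype = "BCP_other"))
  expect_s3_class(plot_fusion_graph(g), "ggplot")
})
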