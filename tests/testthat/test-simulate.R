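test_that("transcriptome simulation is deterministic and validates its config", {
  b1 <- simulate_transcriptome(n_genes = 10, seed = 1)
  b2 <- simulate_transcriptome(n_genes = 10, seed = 1)
  f1 <- tempfile(fileext = ".fa"); m1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fa"); m2 <- tempfile(fileext = ".tsv")
  write_transcriptome(b1, f1, m1)
  write_transcriptome(b2, f2, m2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_identical(b1$gene_models, b2$gene_models)

  b3 <- simulate_transcriptome(n_genes = 10, seed = 2)
  expect_false(identical(b1$transcripts, b3$transcripts))

  expect_error(simulate_transcriptome(n_genes = 0), "at least 2")
  expect_error(simulate_transcriptome(exon_length = 30, read_length = 50),
               "read_length")
})

test_that("planted paralogs share the configured high-identity region", {
  b <- simulate_transcriptome(n_genes = 6, n_paralog_pairs = 1,
                              paralog_identity = 1, paralog_length = 100,
                              seed = 4)
  pp <- b$paralog_pairs
  expect_equal(nrow(pp), 1)
  expect_equal(pp$identity, 1)
  # an identical substring of the planted length must exist in both
  a <- b$transcripts[[pp$gene_a]]
  bb <- b$transcripts[[pp$gene_b]]
  shared <- any(vapply(1:(nchar(a) - 99), function(s) {
    grepl(substring(a, s, s + 99), bb, fixed = TRUE)
  }, logical(1)))
  expect_true(shared)

  # round-trip through FASTA + model table preserves the bundle
  fa <- tempfile(fileext = ".fa"); mo <- tempfile(fileext = ".tsv")
  write_transcriptome(b, fa, mo)
  expect_identical(read_transcripts(fa), b$transcripts)
  expect_equal(as.data.frame(read_gene_models(mo)),
               as.data.frame(b$gene_models))
})

test_that("fusion read simulation plants exactly the requested junction support", {
  b <- simulate_transcriptome(n_genes = 6, seed = 1)
  fus <- tibble::tibble(gene5 = c("G001", "G003"), gene3 = c("G002", "G004"),
                        n_support = c(5L, 0L))
  rs <- simulate_fusion_reads(b, fus, n_background = 50, error_rate = 0, seed = 2)
  expect_equal(sum(rs$truth$origin == "G001-G002"), 5)
  expect_equal(sum(rs$truth$origin == "G003-G004"), 0)
  expect_equal(nrow(rs$reads), 55)
  # truth labels are embedded in the read names
  expect_true(all(grepl("origin=", rs$reads$read_id)))

  # same seed -> byte-identical FASTQ
  rs2 <- simulate_fusion_reads(b, fus, n_background = 50, error_rate = 0, seed = 2)
  p1 <- tempfile(); p2 <- tempfile(); q1 <- tempfile(); q2 <- tempfile()
  write_fastq(rs, p1, p2)
  write_fastq(rs2, q1, q2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(q1, "raw", file.size(q1)))
  expect_identical(readBin(p2, "raw", file.size(p2)),
                   readBin(q2, "raw", file.size(q2)))
  # and the FASTQ round-trips into the same sequences
  back <- read_fastq_pairs(p1, p2)
  expect_equal(back$reads$seq1, rs$reads$seq1)

  # junction flank shorter than the read length is a configuration error
  expect_error(
    simulate_fusion_reads(b, tibble::tibble(gene5 = "G001", gene3 = "G002",
                                            n_support = 1, break5 = 20,
                                            break3 = 180), seed = 1),
    "flank")
})

test_that("planted junction mates really span with the promised anchors", {
  b <- simulate_transcriptome(n_genes = 4, seed = 9)
  rs <- simulate_fusion_reads(b, tibble::tibble(gene5 = "G001", gene3 = "G002",
                                                n_support = 8),
                              n_background = 0, anchor_min = 10, seed = 3)
  fus_seq <- paste0(substring(b$transcripts[["G001"]], 1, 180),
                    substring(b$transcripts[["G002"]], 181, 360))
  for (s1 in rs$reads$seq1) {
    pos <- regexpr(s1, fus_seq, fixed = TRUE)[1]
    expect_gte(pos, 1)
    left <- 180 - (pos - 1)           # bases before the junction
    expect_gte(left, 10)
    expect_gte(nchar(s1) - left, 10)
  }
})

test_that("methylation simulation honours planted means, fractions and bounds", {
  # noise sd = 0: group means equal planted means exactly, so every planted
  # DMC shows |delta beta| exactly >= delta against each reference
  ms <- simulate_methylation(n_cpg = 200, n_dmc = 50, noise_sd = 0,
                             delta = 0.3, seed = 5)
  bm <- as.matrix(ms$beta[-1]); rownames(bm) <- ms$beta$cpg_id
  tgt <- ms$samples$sample_id[ms$samples$group == "DUX4_IGH"]
  for (rg in c("remission", "CD19_B", "CD34_prog")) {
    ref <- ms$samples$sample_id[ms$samples$group == rg]
    d <- rowMeans(bm[ms$truth$cpg_id, tgt, drop = FALSE]) -
      rowMeans(bm[ms$truth$cpg_id, ref, drop = FALSE])
    expect_equal(unname(abs(d)), rep(0.3, nrow(ms$truth)), tolerance = 1e-12)
    expect_true(all((d < 0) == (ms$truth$direction == "hypo")))
  }
  expect_true(all(bm >= 0 & bm <= 1))

  # the hypo/hyper split is exact
  ms2 <- simulate_methylation(n_cpg = 1200, n_dmc = 1000, hypo_fraction = 0.88,
                              seed = 6)
  expect_equal(sum(ms2$truth$direction == "hypo"), 880)
  expect_equal(sum(ms2$truth$direction == "hyper"), 120)

  expect_error(simulate_methylation(delta = 0), "delta")
  expect_error(simulate_methylation(n_target = 1), "2 samples")
})

test_that("expression simulation plants folds, low-expression genes and errors", {
  es <- simulate_expression(groups = c(A = 8, B = 8, C = 8), n_genes = 300,
                            n_de = 30, fold = 4, target_group = "A",
                            low_expr_fraction = 0.1, seed = 7)
  fpkm <- as.matrix(es$fpkm[-1]); rownames(fpkm) <- es$fpkm$gene
  tgt <- es$samples$sample_id[es$samples$group == "A"]
  oth <- es$samples$sample_id[es$samples$group != "A"]
  up <- es$truth$gene[es$truth$direction == "up"]
  ratio <- rowMeans(fpkm[up, tgt, drop = FALSE]) /
    rowMeans(fpkm[up, oth, drop = FALSE])
  expect_true(all(ratio >= 2))
  expect_equal(nrow(es$planted_low), 30)

  # counts and FPKM are consistent up to the fixed scaling
  cm <- as.matrix(es$counts[-1])
  expect_equal(unname(as.matrix(es$fpkm[-1])), unname(cm), tolerance = 1e-12)
  expect_true(all(cm >= 0))

  expect_error(simulate_expression(dispersion = -1), "dispersion")
  expect_error(simulate_expression(groups = c(DUX4_IGH = 1, B = 5)), ">= 2")
})

test_that("cohort simulation respects the subtype vocabulary and normal samples", {
  co <- simulate_cohort(seed = 2)
  expect_true(all(co$samples$subtype %in% subtype_levels()))
  normals <- co$samples$sample_id[co$samples$is_normal]
  expect_length(normals, 10)
  expect_false(any(co$truth_fusions$sample_id %in% normals))
  expect_true(all(co$truth_fusions$n_support >= 3))
  expect_error(simulate_cohort(sizes = c(badlabel = 3)), "Unknown subtype")
})
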