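# Small deterministic beta matrix: `n_rows` CpGs sharing the same group
# means plus one probe row per extra pattern supplied.
flat_beta <- function(target_mean, ref_means, n_rows = 40, noise = 1e-3,
                      n_target = 8, n_ref = 5, seed = 1) {
  set.seed(seed)
  groups <- tibble::tibble(
    sample_id = c(sprintf("T%02d", 1:n_target),
                  sprintf("R1_%02d", 1:n_ref), sprintf("R2_%02d", 1:n_ref),
                  sprintf("R3_%02d", 1:n_ref)),
    group = rep(c("DUX4_IGH", "remission", "CD19_B", "CD34_prog"),
                c(n_target, n_ref, n_ref, n_ref))
  )
  means <- c(rep(target_mean, n_target),
             rep(ref_means, each = n_ref))
  mat <- t(vapply(seq_len(n_rows), function(i) {
    means + rnorm(length(means), 0, noise)
  }, numeric(length(means))))
  colnames(mat) <- groups$sample_id
  rownames(mat) <- sprintf("cg%04d", seq_len(n_rows))
  list(beta = mat, groups = groups)
}

test_that("DMC calling applies the delta and significance thresholds", {
  # target 0.75 vs refs 0.50/0.52/0.48: all deltas >= 0.2, called hyper
  hi <- flat_beta(0.75, c(0.50, 0.52, 0.48))
  res <- call_dmcs(hi$beta, hi$groups, "DUX4_IGH")
  expect_equal(nrow(res$dmcs), 40)
  expect_true(all(res$dmcs$direction == "hyper"))
  expect_true(all(res$dmcs$delta_remission > 0.2))

  # target 0.65: the smallest |delta| is 0.13 < 0.2, nothing called
  lo <- flat_beta(0.65, c(0.50, 0.52, 0.48))
  expect_equal(nrow(call_dmcs(lo$beta, lo$groups, "DUX4_IGH")$dmcs), 0)

  # a group left with < 2 samples is an error naming the group
  keep <- setdiff(colnames(hi$beta), sprintf("R1_%02d", 1:4))
  expect_error(call_dmcs(hi$beta[, keep], hi$groups, "DUX4_IGH"),
               "remission.*fewer than 2")
})

test_that("specificity groups subtract DMCs shared with other subtypes", {
  ms <- simulate_methylation(n_cpg = 600, n_dmc = 150, noise_sd = 0.05,
                             other_groups = c(ZNF384_r = 6), seed = 31)
  base <- call_dmcs(ms$beta, ms$samples, "DUX4_IGH")
  # ZNF384_r is simulated with reference-like means, so subtraction
  # changes (almost) nothing
  spec <- call_dmcs(ms$beta, ms$samples, "DUX4_IGH",
                    dmc_params(specificity_groups = "ZNF384_r"))
  expect_gte(nrow(base$dmcs), nrow(spec$dmcs))
  expect_gte(nrow(spec$dmcs), 0.95 * nrow(base$dmcs))
})

test_that("raising delta_min never grows the DMC set", {
  ms <- simulate_methylation(n_cpg = 800, n_dmc = 200, seed = 17)
  sets <- lapply(c(0.1, 0.2, 0.3), function(d) {
    call_dmcs(ms$beta, ms$samples, "DUX4_IGH",
              dmc_params(delta_min = d))$dmcs$cpg_id
  })
  expect_true(all(sets[[2]] %in% sets[[1]]))
  expect_true(all(sets[[3]] %in% sets[[2]]))
})

test_that("direction summary partitions DMCs exhaustively", {
  d <- tibble::tibble(direction = rep(c("hypo", "hyper"), c(880, 120)))
  ds <- direction_summary(d)
  expect_equal(ds$fraction[ds$direction == "hypo"], 0.88)
  expect_equal(sum(ds$n), 1000)
  empty <- direction_summary(tibble::tibble(direction = character()))
  expect_equal(empty$n, c(0L, 0L))
  expect_true(all(is.na(empty$fraction)))
})

test_that("context enrichment matches the exact hypergeometric oracle", {
  set.seed(5)
  n <- 1000
  annot <- tibble::tibble(
    cpg_id = sprintf("cg%04d", 1:n),
    island_context = rep(c("island", "open_sea"), c(300, 700)),
    gene_region = sample(c("body", "TSS200"), n, TRUE),
    chromatin_state = sample(c("bivalent", "quiescent"), n, TRUE)
  )
  # 100 DMCs all in islands: +70 percentage points, flagged
  dmcs <- tibble::tibble(cpg_id = annot$cpg_id[1:100], direction = "hypo")
  enr <- context_enrichment(dmcs, annot, directions = "hypo")
  isl <- enr[enr$axis == "island_context" & enr$category == "island", ]
  expect_equal(isl$proportion_difference, 70)
  expect_true(isl$flagged)
  # Fisher p equals the independent enumeration on every row
  for (i in seq_len(nrow(enr))) {
    expect_equal(enr$p[i],
                 oracle_fisher2x2(enr$n_dmc_in[i], enr$n_dmc_out[i],
                                  enr$n_array_in[i], enr$n_array_out[i]),
                 tolerance = 1e-9)
  }

  # identity case: DMC set = all probes, nothing deviates, nothing flagged
  all_d <- tibble::tibble(cpg_id = annot$cpg_id, direction = "hyper")
  ident <- context_enrichment(all_d, annot, directions = "hyper")
  expect_true(all(ident$proportion_difference == 0))
  expect_false(any(ident$flagged))

  # conjunctive flag: an 8-point depletion with large counts has a tiny p
  # but fails the > 10-point rule
  big_annot <- tibble::tibble(cpg_id = sprintf("bg%05d", 1:20000),
                              island_context = rep(c("island", "open_sea"),
                                                   c(6000, 14000)))
  big_dmc <- tibble::tibble(
    cpg_id = c(big_annot$cpg_id[big_annot$island_context == "island"][1:2200],
               big_annot$cpg_id[big_annot$island_context == "open_sea"][1:7800]),
    direction = "hypo")
  enr_big <- context_enrichment(big_dmc, big_annot, directions = "hypo",
                                axes = "island_context")
  isl_big <- enr_big[enr_big$category == "island", ]
  expect_equal(isl_big$proportion_difference, -8)
  expect_lt(isl_big$p_bonf, 0.01)
  expect_false(isl_big$flagged)

  expect_error(context_enrichment(
    tibble::tibble(cpg_id = "cg_missing", direction = "hypo"), annot),
    "cg_missing")
})

test_that("DMCs aggregate to genes with direction labels", {
  annot <- tibble::tibble(cpg_id = sprintf("cg%02d", 1:8),
                          gene = c("G", "G", "G", "H", "H", "H", "H", NA))
  d3 <- tibble::tibble(cpg_id = sprintf("cg%02d", 1:3), direction = "hypo")
  expect_equal(dmc_genes(d3, annot),
               tibble::tibble(gene = "G", n_dmc = 3L, direction = "hypo"))
  mixed <- tibble::tibble(cpg_id = sprintf("cg%02d", 4:7),
                          direction = c("hypo", "hypo", "hyper", "hyper"))
  expect_equal(dmc_genes(mixed, annot)$direction, "mixed")
  intergenic <- tibble::tibble(cpg_id = "cg08", direction = "hypo")
  expect_equal(nrow(dmc_genes(intergenic, annot)), 0)
})
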