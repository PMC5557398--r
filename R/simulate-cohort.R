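#' Simulate an ALL cohort sample table with planted fusion truth
#'
#' Builds a cohort of BCP-ALL, T-ALL and normal reference samples with
#' subtype labels drawn from the closed vocabulary ([subtype_levels()])
#' and a per-sample truth table of planted fusion events. The default
#' sizes mirror the study design this package models: 18 t(12;21),
#' 6 t(9;22), 7 11q23/MLL, 42 high-hyperdiploid, 42 BCP-ALL "other",
#' 18 T-ALL, plus 5 + 5 normal B/T references. Canonical subtype-defining
#' fusions are planted in the cytogenetic subtypes; the "other" group
#' receives the recurrent DUX4-IGH, ZNF384- and PAX5-rearranged events.
#' Normal samples never carry truth fusions.
#'
#' @param sizes Named integer vector of group sizes over the subtype
#'   vocabulary.
#' @param support_range Range of planted unique-support read counts for
#'   true fusions.
#' @param seed Integer seed.
#' @return Object of class `cohort_sim`: list with `samples` (tibble:
#'   sample_id, immunophenotype, subtype, is_normal) and `truth_fusions`
#'   (tibble: sample_id, gene5, gene3, n_support).
#' @export
simulate_cohort <- function(sizes = c(t1221 = 18, t922 = 6, MLL_r = 7,
                                      HeH = 42, BCP_other = 42, T_ALL = 18,
                                      normal_CD19B = 5, normal_CD3T = 5),
                            support_range = c(3, 50), seed = 1) {
  unknown <- setdiff(names(sizes), subtype_levels())
  if (length(unknown) > 0) {
    abort(paste0("Unknown subtype label(s): ", paste(unknown, collapse = ", ")))
  }
  with_seed_(seed, {
    samples <- tibble(
      sample_id = sprintf("ALL_%03d", seq_len(sum(sizes))),
      subtype = rep(names(sizes), sizes)
    ) |>
      mutate(
        is_normal = .data$subtype %in% c("normal_CD19B", "normal_CD3T"),
        immunophenotype = dplyr::case_when(
          .data$subtype %in% c("T_ALL", "normal_CD3T") ~ "T",
          TRUE ~ "B"
        )
      ) |>
      select("sample_id", "immunophenotype", "subtype", "is_normal")

    canonical <- list(
      t1221 = c("ETV6", "RUNX1"),
      t922 = c("BCR", "ABL1"),
      MLL_r = c("KMT2A", "AFF1")
    )
    truth <- list()
    draw_support <- function(n) {
      sample(seq(support_range[1], support_range[2]), n, replace = TRUE)
    }
    for (st in names(canonical)) {
      ids <- samples$sample_id[samples$subtype == st]
      if (length(ids) > 0) {
        truth[[st]] <- tibble(sample_id = ids,
                              gene5 = canonical[[st]][1],
                              gene3 = canonical[[st]][2],
                              n_support = draw_support(length(ids)))
      }
    }
    other_ids <- samples$sample_id[samples$subtype == "BCP_other"]
    recurrent_other <- tibble(
      gene5 = c(rep("DUX4", 8), rep("EP300", 3), rep("TCF3", 2), rep("PAX5", 2)),
      gene3 = c(rep("IGH", 8), rep("ZNF384", 3), rep("ZNF384", 2), rep("ETV6", 2))
    )
    n_other <- min(nrow(recurrent_other), length(other_ids))
    if (n_other > 0) {
      truth[["other"]] <- tibble(
        sample_id = sample(other_ids, n_other),
        gene5 = recurrent_other$gene5[seq_len(n_other)],
        gene3 = recurrent_other$gene3[seq_len(n_other)],
        n_support = draw_support(n_other)
      )
    }
    truth_fusions <- if (length(truth) > 0) bind_rows(truth) else {
      tibble(sample_id = character(), gene5 = character(),
             gene3 = character(), n_support = integer())
    }
    structure(list(samples = samples, truth_fusions = truth_fusions),
              class = "cohort_sim")
  })
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat("<cohort_sim>", nrow(x$samples), "samples;",
      nrow(x$truth_fusions), "planted fusions\n")
  invisible(x)
}

#' Simulate a de novo fusion-candidate table with planted noise classes
#'
#' Builds a cohort-wide candidate table in the internal candidate dialect
#' together with the matching filter configuration and a truth table
#' saying, for each candidate, whether the filter cascade should keep it
#' or which rule should remove it. Noise classes use disjoint gene pools
#' so each candidate's fate is decided by exactly one rule:
#' clean true fusions; blacklisted pairs; artifacts also seen in the
#' normal B/T samples; multi-mapping-dominated candidates; partners of a
#' planted promiscuous hub gene; low-support candidates; and a
#' known-ALL-gene candidate below the support threshold that the
#' exemption must keep.
#'
#' @param n_true Clean candidates the cascade must keep.
#' @param n_blacklist,n_normal,n_common,n_promiscuous,n_low Candidates per
#'   noise class. `n_promiscuous` must exceed the promiscuity threshold
#'   for the class to be removable.
#' @param n_known_lowsupport Known-ALL-gene candidates with sub-threshold
#'   support (kept via the exemption).
#' @param promiscuity_threshold,min_unique_reads Passed into the returned
#'   [filter_config()].
#' @param n_samples Cohort size over which candidates are scattered.
#' @param seed Integer seed.
#' @return List with `candidates` (tibble in the internal dialect),
#'   `config` (a `filter_config`) and `truth` (tibble: row_id, expected —
#'   "kept" or the removing rule's name).
#' @export
simulate_candidates <- function(n_true = 6, n_blacklist = 3, n_normal = 3,
                                n_common = 3, n_promiscuous = 7, n_low = 4,
                                n_known_lowsupport = 1,
                                promiscuity_threshold = 5, min_unique_reads = 3,
                                n_samples = 10, seed = 1) {
  if (n_promiscuous > 0 && n_promiscuous <= promiscuity_threshold) {
    abort("`n_promiscuous` must exceed `promiscuity_threshold` to be removable.")
  }
  with_seed_(seed, {
    sample_ids <- sprintf("ALL_%03d", seq_len(n_samples))
    known <- c("ETV6", "RUNX1", "KMT2A", "AFF1", "BCR", "ABL1", "PAX5", "ZNF384")
    pool <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

    mk <- function(g5, g3, n_unique, n_common_map, expected) {
      tibble(sample_id = sample(sample_ids, length(g5), replace = TRUE),
             gene5 = g5, gene3 = g3,
             n_unique_spanning = n_unique, n_common_mapping = n_common_map,
             expected = expected)
    }

    parts <- list()
    if (n_true > 0) {
      g <- pool("TRU", 2 * n_true)
      parts$true <- mk(g[seq_len(n_true)], g[n_true + seq_len(n_true)],
                       sample(3:40, n_true, replace = TRUE), 0L, "kept")
    }
    if (n_blacklist > 0) {
      g <- pool("BLK", 2 * n_blacklist)
      parts$blacklist <- mk(g[seq_len(n_blacklist)],
                            g[n_blacklist + seq_len(n_blacklist)],
                            sample(3:40, n_blacklist, replace = TRUE), 0L,
                            "blacklist")
    }
    if (n_normal > 0) {
      g <- pool("NRM", 2 * n_normal)
      parts$normal <- mk(g[seq_len(n_normal)], g[n_normal + seq_len(n_normal)],
                         sample(3:40, n_normal, replace = TRUE), 0L,
                         "normal_subtraction")
    }
    if (n_common > 0) {
      g <- pool("CMN", 2 * n_common)
      nu <- sample(3:10, n_common, replace = TRUE)
      parts$common <- mk(g[seq_len(n_common)], g[n_common + seq_len(n_common)],
                         nu, nu + sample(0:20, n_common, replace = TRUE),
                         "common_mapping")
    }
    if (n_promiscuous > 0) {
      partners <- pool("PRM", n_promiscuous)
      parts$prom <- mk(rep("PRMHUB", n_promiscuous), partners,
                       sample(3:40, n_promiscuous, replace = TRUE), 0L,
                       "promiscuity")
    }
    if (n_low > 0) {
      g <- pool("LOW", 2 * n_low)
      parts$low <- mk(g[seq_len(n_low)], g[n_low + seq_len(n_low)],
                      sample(seq_len(max(1, min_unique_reads - 1)), n_low,
                             replace = TRUE), 0L, "low_support")
    }
    if (n_known_lowsupport > 0) {
      parts$known <- mk(rep("ETV6", n_known_lowsupport),
                        rep("RUNX1", n_known_lowsupport),
                        rep(min_unique_reads - 1L, n_known_lowsupport), 0L,
                        "kept")
    }

    cand <- bind_rows(parts) |>
      mutate(row_id = row_number(),
             chrom5 = "chr1", pos5 = 1000L * row_number(), strand5 = "+",
             chrom3 = "chr2", pos3 = 2000L * row_number(), strand3 = "+",
             predicted_frame = "unknown", source = "de_novo")

    blk <- parts$blacklist
    nrm <- parts$normal
    config <- filter_config(
      blacklist_pairs = if (is.null(blk)) NULL else
        tibble(gene_a = blk$gene5, gene_b = blk$gene3),
      normal_fusions = if (is.null(nrm)) NULL else
        tibble(gene5 = nrm$gene5, gene3 = nrm$gene3),
      promiscuity_threshold = promiscuity_threshold,
      min_unique_reads = min_unique_reads,
      known_all_genes = known
    )

    list(candidates = select(cand, -"expected"),
         config = config,
         truth = select(cand, "row_id", "expected"))
  })
}

#' Simulate coupled methylation and expression data for one subgroup
#'
#' Generates a methylation simulation and an expression simulation whose
#' planted effects share gene symbols: a set of overlap genes carries
#' both planted DMCs (all CpGs of a gene in one direction) and a planted
#' expression shift, with an exact fraction of the genes coupled
#' inversely (hypomethylated and up-regulated, or hypermethylated and
#' down-regulated) and the rest concordantly. Used to test the
#' methylation-expression overlap analysis against planted truth.
#'
#' @param n_overlap Overlap genes carrying both effects.
#' @param inverse_fraction Exact fraction of overlap genes coupled
#'   inversely (rounded to a whole number of genes).
#' @param hypo_fraction Fraction of overlap genes hypomethylated.
#' @param cpgs_per_gene Planted DMCs per overlap gene.
#' @param n_cpg,n_genes Total CpGs / genes in the two matrices.
#' @param fold Planted expression fold change.
#' @param seed Integer seed.
#' @return List with `meth` (a `meth_sim`), `expr` (an `expr_sim`) and
#'   `truth_overlap` (tibble: gene, meth_direction, expr_direction,
#'   relation).
#' @export
simulate_integrated <- function(n_overlap = 100, inverse_fraction = 0.85,
                                hypo_fraction = 0.5, cpgs_per_gene = 3,
                                n_cpg = 1500, n_genes = 1500, fold = 4,
                                seed = 1) {
  with_seed_(seed, {
    ov <- sprintf("OV%04d", seq_len(n_overlap))
    n_hypo <- round(hypo_fraction * n_overlap)
    meth_dir <- rep("hyper", n_overlap)
    if (n_hypo > 0) meth_dir[seq_len(n_hypo)] <- "hypo"
    n_inverse <- round(inverse_fraction * n_overlap)
    inverse <- sample(rep(c(TRUE, FALSE), c(n_inverse, n_overlap - n_inverse)))
    expr_dir <- ifelse(meth_dir == "hypo",
                       ifelse(inverse, "up", "down"),
                       ifelse(inverse, "down", "up"))
    truth_overlap <- tibble(gene = ov, meth_direction = meth_dir,
                            expr_direction = expr_dir,
                            relation = ifelse(inverse, "inverse", "concordant"))

    meth <- simulate_methylation(
      n_cpg = n_cpg, n_dmc = cpgs_per_gene * n_overlap,
      planted_genes = tibble(gene = ov, direction = meth_dir),
      seed = seed + 101L
    )
    expr <- simulate_expression(
      n_genes = n_genes, low_expr_fraction = 0, fold = fold,
      planted_genes = tibble(gene = sprintf("EG%05d", seq_len(n_overlap)),
                             direction = expr_dir),
      seed = seed + 202L
    )
    # Rename the planted expression genes to the shared overlap symbols.
    relabel <- function(x) { x[seq_len(n_overlap)] <- ov; x }
    expr$fpkm$gene <- relabel(expr$fpkm$gene)
    expr$counts$gene <- relabel(expr$counts$gene)
    expr$truth$gene <- ov

    list(meth = meth, expr = expr, truth_overlap = truth_overlap)
  })
}
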