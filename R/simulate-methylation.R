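#' Simulate a 450k-style beta-value matrix with planted DMCs
#'
#' Emulates array methylation data for one ALL subgroup against three
#' reference cell populations (remission bone marrow, CD19+ B cells,
#' CD34+ progenitor cells). A chosen number of CpGs are planted as
#' differentially methylated in the target group: the three reference
#' groups share a common per-CpG mean and the target mean is shifted by
#' at least `delta` in the planted direction. Per-sample noise is
#' truncated-normal: Gaussian with the betas clipped to \[0, 1\]; planted
#' means are kept away from the bounds so clipping is negligible.
#'
#' @param n_cpg Total CpG probes.
#' @param n_dmc Planted differentially methylated CpGs.
#' @param hypo_fraction Fraction of planted DMCs that are hypomethylated
#'   in the target group (the remainder are hypermethylated).
#' @param delta Planted absolute group-mean shift (> 0).
#' @param noise_sd Per-CpG per-sample Gaussian noise SD before clipping.
#' @param n_target Samples in the target subgroup (>= 2).
#' @param n_ref Named integer vector of reference group sizes (each >= 2).
#' @param target_group Label for the target subgroup.
#' @param other_groups Optional named integer vector of additional ALL
#'   subgroup sizes simulated with reference-like means (used to exercise
#'   specificity subtraction).
#' @param context_props Marginal proportions for the CpG-island context
#'   annotation (island, shore, shelf, open_sea).
#' @param genes_per_cpg Average CpGs per annotated gene (controls how many
#'   gene symbols the annotation uses).
#' @param intergenic_fraction Fraction of probes left without a gene symbol.
#' @param planted_genes Optional tibble (gene, direction) forcing planted
#'   DMCs to be grouped into these genes with the given direction; used by
#'   the integrated simulator to couple methylation to expression truth.
#' @param seed Integer seed.
#'
#' @return Object of class `meth_sim`: list with `beta` (tibble: cpg_id +
#'   one column per sample), `samples` (tibble: sample_id, group),
#'   `annotation` (tibble: cpg_id, chrom, start, end, island_context,
#'   gene_region, chromatin_state, gene) and `truth` (tibble: cpg_id,
#'   direction, gene).
#' @export
simulate_methylation <- function(n_cpg = 5000, n_dmc = 1000,
                                 hypo_fraction = 0.88, delta = 0.3,
                                 noise_sd = 0.05, n_target = 8,
                                 n_ref = c(remission = 5, CD19_B = 5, CD34_prog = 5),
                                 target_group = "DUX4_IGH",
                                 other_groups = NULL,
                                 context_props = c(island = 0.3, shore = 0.25,
                                                   shelf = 0.15, open_sea = 0.3),
                                 genes_per_cpg = 5, intergenic_fraction = 0.2,
                                 planted_genes = NULL, seed = 1) {
  if (delta <= 0) abort("Planted `delta` must be > 0.")
  if (n_target < 2 || any(n_ref < 2)) {
    abort("Target and every reference group need >= 2 samples.")
  }
  if (n_dmc > n_cpg) abort("`n_dmc` cannot exceed `n_cpg`.")

  with_seed_(seed, {
    cpgs <- sprintf("cg%07d", seq_len(n_cpg))
    group_sizes <- c(setNames(n_target, target_group), n_ref, other_groups)
    samples <- tibble(
      sample_id = unlist(purrr::imap(as.list(group_sizes), function(nn, g) {
        sprintf("%s_s%02d", g, seq_len(nn))
      }), use.names = FALSE),
      group = rep(names(group_sizes), group_sizes)
    )

    # Planted truth: which CpGs shift, and which way.
    dmc_idx <- sort(sample.int(n_cpg, n_dmc))
    n_hypo <- round(hypo_fraction * n_dmc)
    direction <- rep("hyper", n_dmc)
    if (n_hypo > 0) direction[seq_len(n_hypo)] <- "hypo"

    # Reference (shared) means; DMC reference means placed so the shifted
    # target mean stays within [0.05, 0.95].
    base_mean <- runif(n_cpg, 0.15, 0.85)
    base_mean[dmc_idx[direction == "hypo"]] <-
      runif(sum(direction == "hypo"), delta + 0.05, 0.95)
    base_mean[dmc_idx[direction == "hyper"]] <-
      runif(sum(direction == "hyper"), 0.05, 0.95 - delta)

    target_mean <- base_mean
    shift <- ifelse(direction == "hypo", -delta, delta)
    target_mean[dmc_idx] <- base_mean[dmc_idx] + shift

    mean_mat <- matrix(base_mean, nrow = n_cpg, ncol = nrow(samples))
    mean_mat[, samples$group == target_group] <- target_mean
    noise <- if (noise_sd > 0) {
      matrix(rnorm(n_cpg * nrow(samples), 0, noise_sd), nrow = n_cpg)
    } else 0
    beta_mat <- pmin(pmax(mean_mat + noise, 0), 1)
    dimnames(beta_mat) <- list(cpgs, samples$sample_id)

    # Probe annotation: genomic placement is schematic (one probe per 100 bp
    # along chr1); the categorical labels are what downstream analyses use.
    n_genes <- max(1L, ceiling(n_cpg * (1 - intergenic_fraction) / genes_per_cpg))
    gene_pool <- sprintf("MG%05d", seq_len(n_genes))
    gene <- rep(NA_character_, n_cpg)
    annotated <- runif(n_cpg) >= intergenic_fraction
    gene[annotated] <- sample(gene_pool, sum(annotated), replace = TRUE)

    # Optionally force planted DMCs into given genes with fixed directions.
    truth_gene <- gene[dmc_idx]
    if (!is.null(planted_genes)) {
      planted_genes <- as_tibble(planted_genes)
      k <- ceiling(n_dmc / nrow(planted_genes))
      assigned <- rep(seq_len(nrow(planted_genes)), each = k)[seq_len(n_dmc)]
      direction <- planted_genes$direction[assigned]
      truth_gene <- planted_genes$gene[assigned]
      gene[dmc_idx] <- truth_gene
      # re-plant means to honour the forced directions
      base_mean[dmc_idx] <- runif(n_dmc, delta + 0.05, 0.95 - delta)
      target_mean <- base_mean
      target_mean[dmc_idx] <- base_mean[dmc_idx] +
        ifelse(direction == "hypo", -delta, delta)
      mean_mat <- matrix(base_mean, nrow = n_cpg, ncol = nrow(samples))
      mean_mat[, samples$group == target_group] <- target_mean
      beta_mat <- pmin(pmax(mean_mat + noise, 0), 1)
      dimnames(beta_mat) <- list(cpgs, samples$sample_id)
    }

    annotation <- tibble(
      cpg_id = cpgs,
      chrom = "chr1",
      start = 100 * (seq_len(n_cpg) - 1),
      end = 100 * (seq_len(n_cpg) - 1) + 2,
      island_context = sample(names(context_props), n_cpg, replace = TRUE,
                              prob = context_props),
      gene_region = sample(c("TSS1500", "TSS200", "UTR5", "body", "UTR3",
                             "intergenic"), n_cpg, replace = TRUE,
                           prob = c(0.12, 0.08, 0.08, 0.42, 0.08, 0.22)),
      chromatin_state = sample(c("active_promoter", "bivalent", "enhancer",
                                 "transcribed", "heterochromatin", "quiescent"),
                               n_cpg, replace = TRUE,
                               prob = c(0.12, 0.08, 0.15, 0.25, 0.2, 0.2)),
      gene = gene
    )

    structure(list(
      beta = bind_cols(tibble(cpg_id = cpgs), as_tibble(beta_mat)),
      samples = samples,
      annotation = annotation,
      truth = tibble(cpg_id = cpgs[dmc_idx], direction = direction,
                     gene = truth_gene)
    ), class = "meth_sim")
  })
}

#' @export
print.meth_sim <- function(x, ...) {
  cat("<meth_sim>", nrow(x$beta), "CpGs x", nrow(x$samples), "samples;",
      nrow(x$truth), "planted DMCs\n")
  invisible(x)
}

#' Write a methylation simulation to disk
#'
#' Beta matrix and sample map as TSV, probe annotation as BED-style TSV.
#'
#' @param sim A `meth_sim`.
#' @param beta_path,groups_path,annot_path,truth_path Output paths
#'   (`truth_path` optional).
#' @return Invisibly, the simulation.
#' @export
write_methylation <- function(sim, beta_path, groups_path, annot_path,
                              truth_path = NULL) {
  stopifnot(inherits(sim, "meth_sim"))
  readr::write_tsv(sim$beta, beta_path)
  readr::write_tsv(sim$samples, groups_path)
  readr::write_tsv(sim$annotation, annot_path)
  if (!is.null(truth_path)) readr::write_tsv(sim$truth, truth_path)
  invisible(sim)
}
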