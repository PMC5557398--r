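#' Simulate count and FPKM matrices with planted subgroup effects
#'
#' Emulates a bulk RNA-seq expression study across ALL subgroups with a
#' gamma-Poisson (negative-binomial) count model per gene and an
#' FPKM-like matrix derived from the counts, so both the heavy-tailed
#' count structure and the FPKM < 5 low-expression filter can be
#' exercised. Planted differentially expressed genes are shifted by
#' `fold` in the target subgroup relative to every other group; a
#' configurable fraction of genes is given a planted mean FPKM below 5.
#'
#' @param groups Named integer vector of group sizes (each >= 2). The
#'   default mirrors the study's expression comparison groups.
#' @param n_genes Total genes.
#' @param n_de Planted differentially expressed genes in the target group.
#' @param fold Planted fold change (>= 2) applied in the target group.
#' @param up_fraction Fraction of planted DE genes shifted up (the rest
#'   down).
#' @param dispersion Negative-binomial dispersion (>= 0; 0 gives Poisson).
#' @param low_expr_fraction Fraction of genes given planted mean FPKM < 5.
#' @param target_group Which group carries the planted effects.
#' @param gene_length Transcript length in bases used for the FPKM scaling.
#' @param lib_size Per-sample sequenced fragments.
#' @param planted_genes Optional tibble (gene, direction) naming which
#'   genes carry the planted effect and which way; used by the integrated
#'   simulator.
#' @param seed Integer seed.
#'
#' @return Object of class `expr_sim`: list with `fpkm` and `counts`
#'   (tibbles: gene + one column per sample), `samples` (tibble:
#'   sample_id, group) and `truth` (tibble: gene, direction, fold).
#' @export
simulate_expression <- function(groups = c(DUX4_IGH = 8, ZNF384_r = 6,
                                           t1221 = 18, t922 = 6, MLL_r = 7,
                                           HeH = 42, normal_CD19B = 5),
                                n_genes = 2000, n_de = 150, fold = 4,
                                up_fraction = 0.5, dispersion = 0.1,
                                low_expr_fraction = 0.1,
                                target_group = "DUX4_IGH",
                                gene_length = 1000, lib_size = 1e6,
                                planted_genes = NULL, seed = 1) {
  if (dispersion < 0) abort("`dispersion` must be >= 0.")
  if (any(groups < 2)) abort("Every group needs >= 2 samples.")
  if (!target_group %in% names(groups)) abort("`target_group` not among `groups`.")
  if (n_de > n_genes) abort("`n_de` cannot exceed `n_genes`.")

  with_seed_(seed, {
    genes <- sprintf("EG%05d", seq_len(n_genes))
    samples <- tibble(
      sample_id = unlist(purrr::imap(as.list(groups), function(nn, g) {
        sprintf("%s_s%02d", g, seq_len(nn))
      }), use.names = FALSE),
      group = rep(names(groups), groups)
    )

    # Planted mean FPKM per gene: lognormal body plus a low-expression tail.
    base_fpkm <- exp(rnorm(n_genes, log(25), 0.6))
    n_low <- round(low_expr_fraction * n_genes)
    low_idx <- if (n_low > 0) sample.int(n_genes, n_low) else integer()
    base_fpkm[low_idx] <- runif(n_low, 0.2, 4)

    # Planted DE genes: drawn from genes with comfortable baseline
    # expression so the effect, not the FPKM filter, decides detection.
    if (!is.null(planted_genes)) {
      planted_genes <- as_tibble(planted_genes)
      de_idx <- match(planted_genes$gene, genes)
      if (anyNA(de_idx)) abort("`planted_genes` contains unknown gene ids.")
      de_dir <- planted_genes$direction
      n_de <- length(de_idx)
    } else {
      eligible <- setdiff(which(base_fpkm >= 10), low_idx)
      if (length(eligible) < n_de) abort("Too few well-expressed genes to plant DE into.")
      de_idx <- sort(sample(eligible, n_de))
      n_up <- round(up_fraction * n_de)
      de_dir <- rep("down", n_de)
      if (n_up > 0) de_dir[seq_len(n_up)] <- "up"
    }
    base_fpkm[de_idx] <- pmax(base_fpkm[de_idx], 20)

    fpkm_mean <- matrix(base_fpkm, nrow = n_genes, ncol = nrow(samples))
    tgt <- samples$group == target_group
    mult <- rep(1, n_genes)
    mult[de_idx] <- ifelse(de_dir == "up", fold, 1 / fold)
    fpkm_mean[, tgt] <- fpkm_mean[, tgt] * mult

    # Gamma-Poisson counts; FPKM derived back from the counts so the two
    # matrices are consistent.
    mu <- fpkm_mean * (gene_length / 1000) * (lib_size / 1e6)
    counts <- if (dispersion > 0) {
      matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion), nrow = n_genes)
    } else {
      matrix(rpois(length(mu), mu), nrow = n_genes)
    }
    fpkm <- counts / ((gene_length / 1000) * (lib_size / 1e6))
    dimnames(counts) <- dimnames(fpkm) <- list(genes, samples$sample_id)

    structure(list(
      fpkm = bind_cols(tibble(gene = genes), as_tibble(fpkm)),
      counts = bind_cols(tibble(gene = genes), as_tibble(counts)),
      samples = samples,
      truth = tibble(gene = genes[de_idx], direction = de_dir, fold = fold),
      planted_low = tibble(gene = genes[low_idx])
    ), class = "expr_sim")
  })
}

#' @export
print.expr_sim <- function(x, ...) {
  cat("<expr_sim>", nrow(x$fpkm), "genes x", nrow(x$samples), "samples;",
      nrow(x$truth), "planted DE genes\n")
  invisible(x)
}

#' Write an expression simulation to disk as TSV matrices
#'
#' @param sim An `expr_sim`.
#' @param fpkm_path,counts_path,groups_path,truth_path Output paths
#'   (`truth_path` optional).
#' @return Invisibly, the simulation.
#' @export
write_expression <- function(sim, fpkm_path, counts_path, groups_path,
                             truth_path = NULL) {
  stopifnot(inherits(sim, "expr_sim"))
  readr::write_tsv(sim$fpkm, fpkm_path)
  readr::write_tsv(sim$counts, counts_path)
  readr::write_tsv(sim$samples, groups_path)
  if (!is.null(truth_path)) readr::write_tsv(sim$truth, truth_path)
  invisible(sim)
}
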