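#' Parameters for the consensus differential-expression rule
#'
#' @param q_max FDR-adjusted p threshold per pairwise comparison
#'   (default 0.1).
#' @param min_fold Minimum fold difference in group mean FPKM (default 2;
#'   a gene passes at fold >= `min_fold` or <= 1/`min_fold`).
#' @param min_mean_fpkm Low-expression exclusion: genes with mean FPKM
#'   below this (default 5) are excluded before testing.
#' @param min_passing_comparisons Pairwise comparisons a gene must pass,
#'   in a consistent direction, to be called (default 3).
#' @return A list of class `de_params`.
#' @export
de_params <- function(q_max = 0.1, min_fold = 2, min_mean_fpkm = 5,
                      min_passing_comparisons = 3) {
  if (min_fold < 1) abort("`min_fold` must be >= 1.")
  if (min_passing_comparisons < 1) abort("`min_passing_comparisons` must be >= 1.")
  structure(list(q_max = q_max, min_fold = min_fold,
                 min_mean_fpkm = min_mean_fpkm,
                 min_passing_comparisons = min_passing_comparisons),
            class = "de_params")
}

#' Pairwise differential expression between two groups
#'
#' Tests every gene between two sample groups with Welch's t-test on
#' log2(FPKM + 1), after excluding genes whose mean FPKM across the two
#' groups is below `min_mean_fpkm`. Fold change is the ratio of group
#' mean FPKMs with a 0.1 pseudo-count on both sides (so equal means give
#' fold exactly 1 and empty denominators are safe); q-values are
#' Benjamini-Hochberg adjusted across the genes tested in this
#' comparison.
#'
#' @param fpkm FPKM matrix: tibble with a gene id first column and one
#'   column per sample, or a numeric matrix with gene rownames.
#' @param groups Sample-to-group map (tibble `sample_id`/`group` or
#'   named vector).
#' @param group_a,group_b Group labels to compare (fold is a over b).
#' @param params A [de_params()].
#' @return Tibble: gene, mean_a, mean_b, fold, statistic, p, q.
#' @export
pairwise_de <- function(fpkm, groups, group_a, group_b, params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  mat <- as_feature_matrix(fpkm)
  gm <- group_map(groups)
  gm <- gm[intersect(names(gm), colnames(mat))]
  cols_a <- names(gm)[gm == group_a]
  cols_b <- names(gm)[gm == group_b]
  if (length(cols_a) < 2 || length(cols_b) < 2) {
    abort("Both groups need at least 2 samples.")
  }
  a <- mat[, cols_a, drop = FALSE]
  b <- mat[, cols_b, drop = FALSE]
  keep <- rowMeans(cbind(a, b)) >= params$min_mean_fpkm
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  test <- row_welch(log2(a + 1), log2(b + 1))
  tibble(
    gene = rownames(a),
    mean_a = unname(rowMeans(a)),
    mean_b = unname(rowMeans(b)),
    fold = unname((rowMeans(a) + 0.1) / (rowMeans(b) + 0.1)),
    statistic = unname(test$statistic),
    p = unname(test$p),
    q = unname(p.adjust(test$p, method = "BH"))
  )
}

#' Consensus differential expression across pairwise comparisons
#'
#' Runs [pairwise_de()] of the target group against each comparison
#' group and applies the consensus rule: a gene is differentially
#' expressed in the target subgroup only when it passes — q below
#' `q_max` and at least a `min_fold` difference in mean FPKM — in at
#' least `min_passing_comparisons` comparisons, all in the same
#' direction. Genes whose mean FPKM over all involved samples is below
#' `min_mean_fpkm` are excluded up front; genes passing in both
#' directions are never called.
#'
#' @param fpkm FPKM matrix (tibble or matrix, as in [pairwise_de()]).
#' @param groups Sample-to-group map.
#' @param target_group Subgroup the signature is called for.
#' @param comparison_groups Groups to compare against (must not include
#'   the target; needs at least `min_passing_comparisons` of them).
#' @param params A [de_params()].
#' @return Object of class `consensus_de_result`: list with `genes`
#'   (tibble: gene, direction, n_passing, mean_fpkm), `comparisons`
#'   (named list of per-comparison tibbles) and `params`.
#' @export
consensus_de <- function(fpkm, groups, target_group, comparison_groups,
                         params = de_params()) {
  stopifnot(inherits(params, "de_params"))
  if (target_group %in% comparison_groups) {
    abort("`target_group` must not be among `comparison_groups`.")
  }
  if (length(comparison_groups) < params$min_passing_comparisons) {
    abort("Need at least `min_passing_comparisons` comparison groups.")
  }
  mat <- as_feature_matrix(fpkm)
  gm <- group_map(groups)
  gm <- gm[intersect(names(gm), colnames(mat))]
  involved <- names(gm)[gm %in% c(target_group, comparison_groups)]
  overall_mean <- rowMeans(mat[, involved, drop = FALSE])
  eligible <- rownames(mat)[overall_mean >= params$min_mean_fpkm]

  comparisons <- purrr::map(comparison_groups, function(g) {
    pairwise_de(mat, gm, target_group, g, params) |>
      filter(.data$gene %in% eligible) |>
      mutate(
        passes = .data$q < params$q_max &
          (.data$fold >= params$min_fold | .data$fold <= 1 / params$min_fold),
        direction = if_else(.data$fold >= 1, "up", "down")
      )
  })
  names(comparisons) <- comparison_groups

  passes <- purrr::imap_dfr(comparisons, function(cmp, g) {
    cmp |> filter(.data$passes) |> mutate(comparison = g)
  })
  genes <- if (nrow(passes) == 0) {
    tibble(gene = character(), direction = character(),
           n_passing = integer(), mean_fpkm = double())
  } else {
    passes |>
      group_by(.data$gene) |>
      summarise(
        n_up = sum(.data$direction == "up"),
        n_down = sum(.data$direction == "down"),
        .groups = "drop"
      ) |>
      filter(pmin(.data$n_up, .data$n_down) == 0,
             pmax(.data$n_up, .data$n_down) >= params$min_passing_comparisons) |>
      mutate(direction = if_else(.data$n_up > 0, "up", "down"),
             n_passing = pmax(.data$n_up, .data$n_down),
             mean_fpkm = overall_mean[.data$gene]) |>
      select("gene", "direction", "n_passing", "mean_fpkm") |>
      arrange(dplyr::desc(.data$n_passing), .data$gene)
  }

  structure(list(genes = genes, comparisons = comparisons, params = params,
                 target_group = target_group),
            class = "consensus_de_result")
}

#' @export
print.consensus_de_result <- function(x, ...) {
  cat("<consensus_de_result>", nrow(x$genes), "consensus DE genes for",
      x$target_group, "(", sum(x$genes$direction == "up"), "up /",
      sum(x$genes$direction == "down"), "down )\n")
  invisible(x)
}
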