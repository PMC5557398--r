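#' Parameters for subgroup-specific DMC calling
#'
#' @param delta_min Minimum mean absolute beta difference versus every
#'   reference group (default 0.2), in (0, 1).
#' @param q_max FDR threshold for the per-CpG test in every reference
#'   comparison (default 0.01).
#' @param reference_groups Ordered reference group labels; the study
#'   design this models uses remission bone marrow, CD19+ B cells, and
#'   CD34+ progenitor cells.
#' @param specificity_groups Other ALL subgroups a DMC must not replicate
#'   in (same direction); `NULL` disables the subtraction.
#' @return A list of class `dmc_params`.
#' @export
dmc_params <- function(delta_min = 0.2, q_max = 0.01,
                       reference_groups = c("remission", "CD19_B", "CD34_prog"),
                       specificity_groups = NULL) {
  if (delta_min <= 0 || delta_min >= 1) abort("`delta_min` must be in (0, 1).")
  structure(list(delta_min = delta_min, q_max = q_max,
                 reference_groups = reference_groups,
                 specificity_groups = specificity_groups),
            class = "dmc_params")
}

# Per-CpG statistics for target vs one reference group: signed delta-beta,
# exact rank-sum p, and BH q across CpGs within the comparison.
dmc_one_comparison <- function(beta_mat, target_cols, ref_cols) {
  tgt <- beta_mat[, target_cols, drop = FALSE]
  ref <- beta_mat[, ref_cols, drop = FALSE]
  delta <- rowMeans(tgt) - rowMeans(ref)
  test <- row_ranksum(tgt, ref)
  tibble(cpg_id = rownames(beta_mat), delta = delta,
         p = test$p, q = p.adjust(test$p, method = "BH"))
}

#' Call subgroup-specific differentially methylated CpGs
#'
#' A CpG is a DMC for the target subgroup when, versus every reference
#' group: the signed mean beta difference has the same sign, its
#' magnitude is at least `delta_min`, and the per-comparison rank-sum
#' test is significant at `q_max` after Benjamini-Hochberg adjustment
#' (computed across CpGs within each comparison). When
#' `specificity_groups` are given, CpGs that would also be called — in
#' the same direction — with any of those groups as the target are
#' dropped, so the result is specific to the target subgroup.
#'
#' @param beta Beta matrix: tibble whose first column is the CpG id and
#'   remaining columns are samples (values in \[0, 1\]), or an equivalent
#'   numeric matrix with CpG rownames.
#' @param groups Sample-to-group map: tibble with `sample_id`, `group`
#'   columns or a named character vector.
#' @param target_group The subgroup to call DMCs for.
#' @param params A [dmc_params()].
#' @return Object of class `dmc_result`: list with `dmcs` (tibble:
#'   cpg_id, mean_target, one `delta_*` and `q_*` column per reference
#'   group, direction), `stats` (the same columns for every CpG plus a
#'   `called` flag), `params`, `target_group` and `group_sizes`.
#' @export
call_dmcs <- function(beta, groups, target_group, params = dmc_params()) {
  stopifnot(inherits(params, "dmc_params"))
  beta_mat <- as_feature_matrix(beta)
  gm <- group_map(groups)
  gm <- gm[intersect(names(gm), colnames(beta_mat))]

  cols_of <- function(g) names(gm)[gm == g]
  for (g in c(target_group, params$reference_groups)) {
    if (length(cols_of(g)) < 2) {
      abort(paste0("Group `", g, "` has fewer than 2 samples."))
    }
  }

  call_for_target <- function(tg) {
    tgt_cols <- cols_of(tg)
    per_ref <- purrr::map(params$reference_groups, function(rg) {
      dmc_one_comparison(beta_mat, tgt_cols, cols_of(rg))
    })
    deltas <- do.call(cbind, purrr::map(per_ref, "delta"))
    qs <- do.call(cbind, purrr::map(per_ref, "q"))
    same_sign <- apply(sign(deltas), 1, function(s) all(s > 0) || all(s < 0))
    min_abs_delta <- apply(abs(deltas), 1, min)
    max_q <- apply(qs, 1, max)
    called <- same_sign & min_abs_delta >= params$delta_min &
      max_q <= params$q_max
    direction <- if_else(rowMeans(deltas) < 0, "hypo", "hyper")
    stats <- tibble(cpg_id = rownames(beta_mat),
                    mean_target = rowMeans(beta_mat[, tgt_cols, drop = FALSE]))
    for (k in seq_along(params$reference_groups)) {
      stats[[paste0("delta_", params$reference_groups[k])]] <- deltas[, k]
      stats[[paste0("q_", params$reference_groups[k])]] <- qs[, k]
    }
    stats$direction <- direction
    stats$called <- called
    stats
  }

  stats <- call_for_target(target_group)

  if (!is.null(params$specificity_groups)) {
    for (sg in params$specificity_groups) {
      if (length(cols_of(sg)) < 2) {
        abort(paste0("Specificity group `", sg, "` has fewer than 2 samples."))
      }
      other <- call_for_target(sg)
      shared <- other$called & stats$called & other$direction == stats$direction
      stats$called <- stats$called & !shared
    }
  }

  structure(list(
    dmcs = filter(stats, .data$called) |> select(-"called"),
    stats = stats,
    params = params,
    target_group = target_group,
    group_sizes = table(gm)
  ), class = "dmc_result")
}

#' @export
print.dmc_result <- function(x, ...) {
  cat("<dmc_result>", nrow(x$dmcs), "DMCs for", x$target_group,
      "(", sum(x$dmcs$direction == "hypo"), "hypo /",
      sum(x$dmcs$direction == "hyper"), "hyper )\n")
  invisible(x)
}

#' Hypo/hyper direction breakdown of a DMC set
#'
#' @param dmcs A `dmc_result` or a tibble with a `direction` column.
#' @return Tibble: direction, n, fraction (fractions sum to 1 when any
#'   DMCs exist; an empty set reports both directions with n = 0).
#' @export
direction_summary <- function(dmcs) {
  d <- if (inherits(dmcs, "dmc_result")) dmcs$dmcs else as_tibble(dmcs)
  out <- tibble(direction = c("hypo", "hyper")) |>
    left_join(count(d, .data$direction, name = "n"), by = "direction") |>
    mutate(n = dplyr::coalesce(.data$n, 0L),
           fraction = if (sum(.data$n) > 0) .data$n / sum(.data$n) else NA_real_)
  out
}

#' Genomic-context enrichment of DMCs versus the array background
#'
#' For each annotation category (CpG-island context, gene region,
#' chromatin state) and each requested direction, compares the fraction
#' of DMCs in the category with the fraction of all array probes in the
#' category: a two-sided Fisher's exact test on the 2x2 table (DMC set
#' vs all probes, in vs out of category), Bonferroni-corrected over all
#' tests in the run. A category is flagged when the corrected p-value is
#' below `p_max` and the difference in proportion exceeds
#' `min_prop_diff` percentage points — both conditions are required.
#'
#' @param dmcs A `dmc_result` or tibble with `cpg_id` and `direction`.
#' @param annotation Probe annotation tibble (cpg_id plus the annotation
#'   axis columns); defines the array background.
#' @param directions Directions to test (default both).
#' @param axes Annotation columns treated as category axes.
#' @param p_max Bonferroni-corrected p threshold for flagging.
#' @param min_prop_diff Minimum absolute proportion difference
#'   (percentage points) for flagging.
#' @return Tibble: axis, category, direction, the four 2x2 counts,
#'   prop_dmc, prop_array, proportion_difference (percentage points),
#'   p, p_bonf, flagged.
#' @export
context_enrichment <- function(dmcs, annotation,
                               directions = c("hypo", "hyper"),
                               axes = c("island_context", "gene_region",
                                        "chromatin_state"),
                               p_max = 0.01, min_prop_diff = 10) {
  d <- if (inherits(dmcs, "dmc_result")) dmcs$dmcs else as_tibble(dmcs)
  annotation <- as_tibble(annotation)
  missing <- setdiff(d$cpg_id, annotation$cpg_id)
  if (length(missing) > 0) {
    abort(paste0("DMC CpG(s) absent from the annotation: ",
                 paste(head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) ", ..." else ""))
  }
  axes <- intersect(axes, names(annotation))
  n_array <- nrow(annotation)

  rows <- list()
  for (dir in directions) {
    dmc_ids <- d$cpg_id[d$direction == dir]
    dmc_annot <- annotation[annotation$cpg_id %in% dmc_ids, , drop = FALSE]
    n_dmc <- nrow(dmc_annot)
    for (ax in axes) {
      for (cat in sort(unique(annotation[[ax]]))) {
        dmc_in <- sum(dmc_annot[[ax]] == cat)
        array_in <- sum(annotation[[ax]] == cat)
        tab <- matrix(c(dmc_in, n_dmc - dmc_in,
                        array_in, n_array - array_in), nrow = 2, byrow = TRUE)
        p <- if (n_dmc == 0) NA_real_ else fisher.test(tab)$p.value
        rows[[length(rows) + 1]] <- tibble(
          axis = ax, category = cat, direction = dir,
          n_dmc_in = dmc_in, n_dmc_out = n_dmc - dmc_in,
          n_array_in = array_in, n_array_out = n_array - array_in,
          prop_dmc = if (n_dmc == 0) NA_real_ else dmc_in / n_dmc,
          prop_array = array_in / n_array,
          p = p
        )
      }
    }
  }
  out <- bind_rows(rows) |>
    mutate(
      proportion_difference = 100 * (.data$prop_dmc - .data$prop_array),
      p_bonf = pmin(1, .data$p * dplyr::n()),
      flagged = !is.na(.data$p_bonf) & .data$p_bonf < p_max &
        abs(.data$proportion_difference) > min_prop_diff
    )
  out
}

#' Per-gene summary of a DMC set
#'
#' Maps called DMCs to gene symbols through the probe annotation and
#' summarises per gene: number of DMCs and the dominant direction
#' (`"mixed"` when both directions occur). CpGs without a gene symbol
#' are excluded.
#'
#' @param dmcs A `dmc_result` or tibble with `cpg_id` and `direction`.
#' @param annotation Probe annotation with `cpg_id` and `gene` columns.
#' @return Tibble: gene, n_dmc, direction.
#' @export
dmc_genes <- function(dmcs, annotation) {
  d <- if (inherits(dmcs, "dmc_result")) dmcs$dmcs else as_tibble(dmcs)
  d |>
    inner_join(select(as_tibble(annotation), "cpg_id", "gene"), by = "cpg_id") |>
    filter(!is.na(.data$gene)) |>
    group_by(.data$gene) |>
    summarise(
      n_dmc = n(),
      direction = if (n_distinct(.data$direction) > 1) "mixed"
                  else first(.data$direction),
      .groups = "drop"
    ) |>
    arrange(dplyr::desc(.data$n_dmc), .data$gene)
}
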