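# broom-style tidiers for the package's result objects.

#' Tidy a filter-cascade result into one audit row per candidate
#'
#' @param x A `fusion_filter_result`.
#' @param ... Unused.
#' @return Tibble of all input candidates with `status`
#'   (`"kept"`/`"removed"`) and `rule` (NA for kept candidates).
#' @method tidy fusion_filter_result
#' @export
tidy.fusion_filter_result <- function(x, ...) {
  bind_rows(
    mutate(x$kept, status = "kept", rule = NA_character_),
    mutate(x$removed, status = "removed")
  )
}

#' One-row summary of a filter-cascade result
#'
#' @param x A `fusion_filter_result`.
#' @param ... Unused.
#' @return One-row tibble: n_input, n_kept, n_removed and one `n_<rule>`
#'   column per cascade rule.
#' @method glance fusion_filter_result
#' @export
glance.fusion_filter_result <- function(x, ...) {
  counts <- setNames(as.list(x$per_rule_counts$n),
                     paste0("n_", x$per_rule_counts$rule))
  bind_cols(tibble(n_input = nrow(x$kept) + nrow(x$removed),
                   n_kept = nrow(x$kept), n_removed = nrow(x$removed)),
            as_tibble(counts))
}

#' Tidy a targeted-screen result into one row per assay
#'
#' @param x A `targeted_screen_result`.
#' @param ... Unused.
#' @return Tibble: assay_id, gene5, gene3, n_support, called.
#' @method tidy targeted_screen_result
#' @export
tidy.targeted_screen_result <- function(x, ...) {
  x$support |>
    select("assay_id", "gene5", "gene3", "n_support") |>
    mutate(called = .data$n_support >= x$params$min_support)
}

#' Tidy a DMC result into its called-CpG table
#'
#' @param x A `dmc_result`.
#' @param ... Unused.
#' @return The DMC tibble (cpg_id, mean_target, per-reference deltas and
#'   q-values, direction).
#' @method tidy dmc_result
#' @export
tidy.dmc_result <- function(x, ...) x$dmcs

#' One-row summary of a DMC result
#'
#' @param x A `dmc_result`.
#' @param ... Unused.
#' @return One-row tibble: target_group, n_dmc, n_hypo, n_hyper,
#'   hypo_fraction.
#' @method glance dmc_result
#' @export
glance.dmc_result <- function(x, ...) {
  n_hypo <- sum(x$dmcs$direction == "hypo")
  n_hyper <- sum(x$dmcs$direction == "hyper")
  tibble(target_group = x$target_group,
         n_dmc = nrow(x$dmcs), n_hypo = n_hypo, n_hyper = n_hyper,
         hypo_fraction = if (nrow(x$dmcs) > 0) n_hypo / nrow(x$dmcs) else NA_real_)
}

#' Tidy a consensus DE result into its gene table
#'
#' @param x A `consensus_de_result`.
#' @param ... Unused.
#' @return Tibble: gene, direction, n_passing, mean_fpkm.
#' @method tidy consensus_de_result
#' @export
tidy.consensus_de_result <- function(x, ...) x$genes

#' One-row summary of a consensus DE result
#'
#' @param x A `consensus_de_result`.
#' @param ... Unused.
#' @return One-row tibble: target_group, n_genes, n_up, n_down,
#'   n_comparisons.
#' @method glance consensus_de_result
#' @export
glance.consensus_de_result <- function(x, ...) {
  tibble(target_group = x$target_group,
         n_genes = nrow(x$genes),
         n_up = sum(x$genes$direction == "up"),
         n_down = sum(x$genes$direction == "down"),
         n_comparisons = length(x$comparisons))
}

#' Tidy a profile embedding into its score table
#'
#' @param x A `profile_embedding`.
#' @param ... Unused.
#' @return Tibble: sample_id plus one column per reported component.
#' @method tidy profile_embedding
#' @export
tidy.profile_embedding <- function(x, ...) x$scores

#' One-row summary of a profile embedding
#'
#' @param x A `profile_embedding`.
#' @param ... Unused.
#' @return One-row tibble: n_samples, n_features and the variance
#'   fraction of each reported component.
#' @method glance profile_embedding
#' @export
glance.profile_embedding <- function(x, ...) {
  vf <- setNames(as.list(x$var_explained),
                 paste0("var_PC", seq_along(x$var_explained)))
  bind_cols(tibble(n_samples = nrow(x$scores),
                   n_features = length(x$top_features)),
            as_tibble(vf))
}
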