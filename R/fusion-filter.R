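#' Filter configuration for the fusion-candidate cascade
#'
#' Bundles the reference lists and thresholds the filter cascade uses.
#' Blacklists and the promiscuous-gene threshold default to empty /
#' permissive because the reference lists are tool- and cohort-specific
#' and are expected to be user-supplied.
#'
#' @param blacklist_pairs Data frame with columns `gene_a`, `gene_b`
#'   (unordered pair match), or `NULL`.
#' @param blacklist_genes Character vector of single blacklisted genes.
#' @param promiscuity_threshold Maximum distinct fusion partners a gene
#'   may have in the cohort candidate set before its candidates are
#'   removed (>= 2).
#' @param min_unique_reads Minimum uniquely aligned fusion-supporting
#'   read pairs (default 3: candidates with fewer than three are removed).
#' @param known_all_genes Genes with described ALL fusion involvement;
#'   candidates touching any of them are exempt from every removal rule.
#' @param normal_fusions Data frame with columns `gene5`, `gene3`: fusion
#'   pairs observed in the normal B/T reference samples, matched as
#'   unordered pairs.
#' @param count_common_dominance Remove a candidate when its
#'   multi-mapping ("common mapping") read count reaches or exceeds its
#'   unique-read count (and is non-zero).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(blacklist_pairs = NULL, blacklist_genes = character(),
                          promiscuity_threshold = 5, min_unique_reads = 3,
                          known_all_genes = character(),
                          normal_fusions = NULL,
                          count_common_dominance = TRUE) {
  if (min_unique_reads < 1) abort("`min_unique_reads` must be >= 1.")
  if (promiscuity_threshold < 2) abort("`promiscuity_threshold` must be >= 2.")
  norm_pairs <- function(df, a, b) {
    if (is.null(df) || nrow(df) == 0) return(character())
    unique(pair_key(df[[a]], df[[b]]))
  }
  structure(list(
    blacklist_pair_keys = norm_pairs(blacklist_pairs, "gene_a", "gene_b"),
    blacklist_genes = unique(blacklist_genes),
    promiscuity_threshold = promiscuity_threshold,
    min_unique_reads = min_unique_reads,
    known_all_genes = unique(known_all_genes),
    normal_pair_keys = norm_pairs(normal_fusions, "gene5", "gene3"),
    count_common_dominance = isTRUE(count_common_dominance)
  ), class = "filter_config")
}

#' Read a tab-separated de novo fusion-candidate table
#'
#' Parses the documented candidate dialect (one row per putative chimeric
#' transcript per sample, FusionCatcher-style columns) into the internal
#' representation. Reported 1-based breakpoint positions are converted to
#' the internal 0-based convention; a missing `predicted_frame` column
#' defaults to `"unknown"`.
#'
#' Required columns: `sample_id`, `gene5`, `gene3`, `chrom5`, `pos5`,
#' `strand5`, `chrom3`, `pos3`, `strand3`, `n_unique_spanning`,
#' `n_common_mapping`. Optional: `predicted_frame`.
#'
#' @param path Path to the tab-separated table.
#' @return Tibble of candidates with `source = "de_novo"`.
#' @export
read_candidate_table <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
                "chrom3", "pos3", "strand3", "n_unique_spanning",
                "n_common_mapping")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(paste0("Candidate table is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  check_num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Non-numeric value in column `%s` at line %d: \"%s\"",
                    col, bad[1] + 1L, raw[[col]][bad[1]]))
    }
    v
  }
  out <- raw |>
    mutate(
      pos5 = check_num("pos5") - 1,
      pos3 = check_num("pos3") - 1,
      n_unique_spanning = check_num("n_unique_spanning"),
      n_common_mapping = check_num("n_common_mapping"),
      predicted_frame = if ("predicted_frame" %in% names(raw)) {
        dplyr::coalesce(raw$predicted_frame, "unknown")
      } else "unknown",
      source = "de_novo"
    )
  if (any(out$gene5 == "" | out$gene3 == "", na.rm = TRUE)) {
    abort("Candidate rows with empty gene symbols are not allowed.")
  }
  select(out, all_of(required), "predicted_frame", "source")
}

#' Distinct fusion-partner count per gene
#'
#' Counts, for every gene appearing in a cohort-wide candidate set, the
#' number of distinct partner genes it is fused with, pooling the 5' and
#' 3' roles (a reciprocal orientation is the same partner, not a new one).
#'
#' @param candidates Data frame with columns `gene5`, `gene3`.
#' @return Tibble with columns `gene`, `n_partners`.
#' @export
promiscuity_index <- function(candidates) {
  candidates <- as_tibble(candidates)
  if (nrow(candidates) == 0) {
    return(tibble(gene = character(), n_partners = integer()))
  }
  pairs <- candidates |>
    mutate(gene_a = pmin(.data$gene5, .data$gene3),
           gene_b = pmax(.data$gene5, .data$gene3)) |>
    distinct(.data$gene_a, .data$gene_b)
  bind_rows(
    tibble(gene = pairs$gene_a, partner = pairs$gene_b),
    tibble(gene = pairs$gene_b, partner = pairs$gene_a)
  ) |>
    distinct() |>
    count(.data$gene, name = "n_partners") |>
    arrange(.data$gene)
}

#' Apply the fusion-candidate filter cascade
#'
#' Removes candidates matching any of the removal criteria, in a fixed
#' order that decides only the audit attribution (the kept set is
#' order-independent because a candidate is removed if any rule fires):
#'
#' 1. `blacklist` — unordered pair match against the blacklist, then
#'    single-gene match;
#' 2. `normal_subtraction` — the unordered pair was also called in the
#'    normal B/T reference samples;
#' 3. `common_mapping` — multi-mapping fusion-supporting reads dominate
#'    the unique evidence (`n_common_mapping >= n_unique_spanning > 0`
#'    counts as dominated, as does any candidate with common-mapping
#'    reads and zero unique ones);
#' 4. `promiscuity` — either partner exceeds the distinct-partner
#'    threshold, computed cohort-wide on the post-blacklist candidate set;
#' 5. `low_support` — fewer than `min_unique_reads` uniquely aligned
#'    supporting read pairs.
#'
#' Candidates whose 5' or 3' gene is a known ALL fusion gene are exempt
#' from all rules and always kept.
#'
#' @param candidates Cohort-wide candidate tibble (see
#'   [read_candidate_table()] for the columns).
#' @param config A [filter_config()].
#' @return Object of class `fusion_filter_result`: list with `kept`,
#'   `removed` (candidates plus a `rule` column naming the first rule
#'   fired) and `per_rule_counts` tibbles, plus the `config` used.
#' @export
apply_filter_cascade <- function(candidates, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  candidates <- as_tibble(candidates)
  rules <- c("blacklist", "normal_subtraction", "common_mapping",
             "promiscuity", "low_support")
  if (nrow(candidates) == 0) {
    return(structure(list(
      kept = candidates,
      removed = mutate(candidates, rule = character(0)),
      per_rule_counts = tibble(rule = rules, n = 0L),
      config = config
    ), class = "fusion_filter_result"))
  }

  key <- pair_key(candidates$gene5, candidates$gene3)
  exempt <- candidates$gene5 %in% config$known_all_genes |
    candidates$gene3 %in% config$known_all_genes

  hit_blacklist <- key %in% config$blacklist_pair_keys |
    candidates$gene5 %in% config$blacklist_genes |
    candidates$gene3 %in% config$blacklist_genes

  # Promiscuity over the post-blacklist cohort candidate set.
  post_blacklist <- candidates[!(hit_blacklist & !exempt), , drop = FALSE]
  prom <- promiscuity_index(post_blacklist)
  prom_genes <- prom$gene[prom$n_partners > config$promiscuity_threshold]

  hit_normal <- key %in% config$normal_pair_keys
  hit_common <- config$count_common_dominance &
    candidates$n_common_mapping > 0 &
    candidates$n_common_mapping >= candidates$n_unique_spanning
  hit_prom <- candidates$gene5 %in% prom_genes |
    candidates$gene3 %in% prom_genes
  hit_low <- candidates$n_unique_spanning < config$min_unique_reads

  first_rule <- rep(NA_character_, nrow(candidates))
  for (r in rev(rules)) {
    hit <- switch(r,
      blacklist = hit_blacklist, normal_subtraction = hit_normal,
      common_mapping = hit_common, promiscuity = hit_prom,
      low_support = hit_low)
    first_rule[hit] <- r
  }
  first_rule[exempt] <- NA_character_

  removed <- candidates[!is.na(first_rule), , drop = FALSE]
  removed$rule <- first_rule[!is.na(first_rule)]
  counts <- tibble(rule = rules) |>
    left_join(count(removed, .data$rule, name = "n"), by = "rule") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))

  structure(list(
    kept = candidates[is.na(first_rule), , drop = FALSE],
    removed = removed,
    per_rule_counts = counts,
    config = config
  ), class = "fusion_filter_result")
}

#' @export
print.fusion_filter_result <- function(x, ...) {
  cat("<fusion_filter_result>", nrow(x$kept) + nrow(x$removed), "candidates ->",
      nrow(x$kept), "kept,", nrow(x$removed), "removed\n")
  print(x$per_rule_counts)
  invisible(x)
}

#' Write filter-cascade outputs
#'
#' Kept table and removal log as TSV, per-rule counts as JSON.
#'
#' @param result A `fusion_filter_result`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the result.
#' @export
write_filter_result <- function(result, dir) {
  stopifnot(inherits(result, "fusion_filter_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_tsv(result$kept, file.path(dir, "kept.tsv"))
  readr::write_tsv(result$removed, file.path(dir, "removal_log.tsv"))
  jsonlite::write_json(
    as.list(setNames(result$per_rule_counts$n, result$per_rule_counts$rule)),
    file.path(dir, "per_rule_counts.json"), auto_unbox = TRUE)
  invisible(result)
}
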