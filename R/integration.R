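#' Overlap differentially methylated genes with consensus DE genes
#'
#' Intersects the gene sets and classifies each shared gene's
#' methylation/expression relation: `inverse` for hypomethylated +
#' up-regulated or hypermethylated + down-regulated, `concordant` for
#' the matching directions, and `ambiguous` when the gene's DMCs mix
#' directions. The summary reports the inverse fraction among overlap
#' genes.
#'
#' @param dmc_gene_summary Tibble from [dmc_genes()] (gene, n_dmc,
#'   direction).
#' @param consensus A `consensus_de_result` or its `genes` tibble
#'   (gene, direction).
#' @return List with `overlap` (tibble: gene, meth_direction,
#'   expr_direction, relation) and `summary` (tibble: n_overlap,
#'   n_inverse, n_concordant, n_ambiguous, inverse_fraction).
#' @export
overlap_dmc_de <- function(dmc_gene_summary, consensus) {
  de <- if (inherits(consensus, "consensus_de_result")) consensus$genes
        else as_tibble(consensus)
  overlap <- as_tibble(dmc_gene_summary) |>
    select("gene", meth_direction = "direction") |>
    inner_join(select(de, "gene", expr_direction = "direction"), by = "gene") |>
    mutate(relation = dplyr::case_when(
      .data$meth_direction == "mixed" ~ "ambiguous",
      .data$meth_direction == "hypo" & .data$expr_direction == "up" ~ "inverse",
      .data$meth_direction == "hyper" & .data$expr_direction == "down" ~ "inverse",
      TRUE ~ "concordant"
    )) |>
    arrange(.data$gene)
  summary <- tibble(
    n_overlap = nrow(overlap),
    n_inverse = sum(overlap$relation == "inverse"),
    n_concordant = sum(overlap$relation == "concordant"),
    n_ambiguous = sum(overlap$relation == "ambiguous"),
    inverse_fraction = if (nrow(overlap) > 0) {
      sum(overlap$relation == "inverse") / nrow(overlap)
    } else NA_real_
  )
  list(overlap = overlap, summary = summary)
}

#' Corroborate fusion calls with copy-number segments
#'
#' A fusion call is corroborated when any copy-number segment
#' (deletion or amplification) in the same sample overlaps either
#' partner's gene body extended by `window` on both sides. Intervals are
#' 0-based half-open; corroboration is monotone in `window`.
#'
#' @param calls Tibble with `sample_id`, `gene5`, `gene3`.
#' @param segments Tibble with `sample_id`, `chrom`, `start`, `end`,
#'   `state` (`"deletion"` / `"amplification"`).
#' @param gene_models Gene-model tibble with `gene`, `chrom`, `start`,
#'   `end`.
#' @param window Proximity window in bp (default 100 kb).
#' @return The calls tibble with `corroborated` (logical),
#'   `supporting_gene`, `segment_state` columns (NA when not
#'   corroborated).
#' @export
cna_corroborate <- function(calls, segments, gene_models, window = 1e5) {
  calls <- as_tibble(calls)
  segments <- as_tibble(segments)
  if (any(segments$start >= segments$end)) {
    abort("Segments must satisfy start < end.")
  }
  gm <- as_tibble(gene_models)
  missing <- setdiff(unique(c(calls$gene5, calls$gene3)), gm$gene)
  if (length(missing) > 0) {
    abort(paste0("Gene(s) absent from the gene models: ",
                 paste(missing, collapse = ", ")))
  }
  lookup <- function(i) {
    call <- calls[i, ]
    for (role in c("gene5", "gene3")) {
      g <- gm[gm$gene == call[[role]], ][1, ]
      hit <- segments |>
        filter(.data$sample_id == call$sample_id,
               .data$chrom == g$chrom,
               .data$start < g$end + window,
               .data$end > g$start - window)
      if (nrow(hit) > 0) {
        return(tibble(corroborated = TRUE, supporting_gene = call[[role]],
                      segment_state = hit$state[1]))
      }
    }
    tibble(corroborated = FALSE, supporting_gene = NA_character_,
           segment_state = NA_character_)
  }
  bind_cols(calls, purrr::map_dfr(seq_len(nrow(calls)), lookup))
}

# Hotspot pattern of a protein change: gene + reference residue prefix,
# e.g. "NRAS p.G12D" and "NRAS p.G12S" both collapse to "NRAS p.G12".
protein_change_pattern <- function(protein_change) {
  m <- stringr::str_match(protein_change, "^p\\.([A-Z])(\\d+)")
  if (any(is.na(m[, 1]))) {
    bad <- protein_change[is.na(m[, 1])][1]
    abort(paste0("Malformed protein-change string: \"", bad,
                 "\" (expected e.g. p.G12D)."))
  }
  paste0("p.", m[, 2], m[, 3])
}

#' Alteration co-occurrence by fusion family
#'
#' Combines fusion calls, driver-gene mutations and copy-number flags
#' into a per-sample alteration table and counts, per fusion family, how
#' many samples carry each mutation pattern (gene plus protein-change
#' residue prefix, so hotspot variants like p.G12D and p.G12S aggregate)
#' and each copy-number flag. Samples without targeted sequencing data
#' (`na` mutations) are marked not assessed and excluded from mutation
#' denominators, but stay in copy-number denominators; inconclusive
#' copy-number profiles are likewise excluded from CNA denominators.
#'
#' @param calls Tibble with `sample_id`, `family` (fusion family label)
#'   and optionally `fusion_gene`.
#' @param mutations Tibble with `sample_id`, `gene`, `protein_change`;
#'   a row with gene `"na"` (or an absent sample) marks no targeted
#'   sequencing data.
#' @param cna_flags Tibble with `sample_id`, `cna` (a free-text flag such
#'   as `"ERG deletion"`; `"none"` for a clean profile, `"inconclusive"`
#'   when the assay failed).
#' @return List with `table` (per-sample alteration rows),
#'   `mutation_counts` (family, gene, pattern, n_samples, n_assessed),
#'   `gene_counts` (the same aggregated over patterns within a gene) and
#'   `cna_counts` (family, cna, n_samples, n_assessed).
#' @export
cooccurrence_table <- function(calls, mutations, cna_flags) {
  calls <- as_tibble(calls)
  mutations <- as_tibble(mutations) |>
    filter(!is.na(.data$gene), .data$gene != "na")
  if (nrow(mutations) > 0) {
    mutations <- mutate(mutations,
                        pattern = protein_change_pattern(.data$protein_change))
  } else {
    mutations$pattern <- character(0)
  }
  cna_flags <- as_tibble(cna_flags)

  # Assessed samples are those with real mutation rows; a gene == "na" row
  # marks a sample with no targeted sequencing data.
  assessed_mut <- unique(mutations$sample_id)

  per_sample <- calls |>
    left_join(
      mutations |>
        group_by(.data$sample_id) |>
        summarise(mutations = paste(.data$gene, .data$protein_change,
                                    collapse = "; "), .groups = "drop"),
      by = "sample_id") |>
    left_join(cna_flags, by = "sample_id") |>
    mutate(mutation_assessed = .data$sample_id %in% assessed_mut,
           cna = dplyr::coalesce(.data$cna, "none"),
           cna_assessed = .data$cna != "inconclusive")

  n_assessed_mut <- per_sample |>
    group_by(.data$family) |>
    summarise(n_assessed = sum(.data$mutation_assessed), .groups = "drop")
  mutation_counts <- calls |>
    inner_join(distinct(mutations, .data$sample_id, .data$gene, .data$pattern),
               by = "sample_id") |>
    group_by(.data$family, .data$gene, .data$pattern) |>
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    left_join(n_assessed_mut, by = "family") |>
    arrange(.data$family, dplyr::desc(.data$n_samples))

  gene_counts <- calls |>
    inner_join(distinct(mutations, .data$sample_id, .data$gene),
               by = "sample_id") |>
    group_by(.data$family, .data$gene) |>
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    left_join(n_assessed_mut, by = "family") |>
    arrange(.data$family, dplyr::desc(.data$n_samples))

  n_assessed_cna <- per_sample |>
    group_by(.data$family) |>
    summarise(n_assessed = sum(.data$cna_assessed), .groups = "drop")
  cna_counts <- per_sample |>
    filter(.data$cna_assessed, .data$cna != "none") |>
    group_by(.data$family, .data$cna) |>
    summarise(n_samples = n_distinct(.data$sample_id), .groups = "drop") |>
    left_join(n_assessed_cna, by = "family") |>
    arrange(.data$family, dplyr::desc(.data$n_samples))

  list(table = per_sample, mutation_counts = mutation_counts,
       gene_counts = gene_counts, cna_counts = cna_counts)
}

#' Compiled alteration table for DUX4-IGH and ZNF384-rearranged cases
#'
#' Reported driver-gene mutations and copy-number alterations in the
#' DUX4-IGH and ZNF384-rearranged BCP-ALL cases this package's
#' integration analyses model, shipped as a plain-text table. Returns
#' the three inputs [cooccurrence_table()] expects.
#'
#' @return List with `calls`, `mutations`, `cna_flags` tibbles.
#' @export
all_alterations <- function() {
  path <- system.file("extdata", "dux4_znf384_alterations.tsv",
                      package = "leukfuse", mustWork = TRUE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  calls <- select(raw, "sample_id", "family", "fusion_gene")
  mutations <- raw |>
    filter(.data$mutations != "na") |>
    tidyr::separate_rows("mutations", sep = ";") |>
    tidyr::separate("mutations", into = c("gene", "protein_change"),
                    sep = " ", extra = "merge") |>
    select("sample_id", "gene", "protein_change")
  cna_flags <- select(raw, "sample_id", "cna")
  list(calls = calls, mutations = mutations, cna_flags = cna_flags)
}
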