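# ggplot2 views of the main result types.

#' Plot a PCA embedding of sample profiles
#'
#' @param object A `profile_embedding`.
#' @param groups Optional sample-to-group map used to colour points.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot profile_embedding
#' @export
autoplot.profile_embedding <- function(object, groups = NULL, ...) {
  df <- object$scores
  if (!is.null(groups)) {
    gm <- group_map(groups)
    df$group <- unname(gm[df$sample_id])
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%% of variance)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%% of variance)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(groups)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' Volcano-style view of a DMC calling run
#'
#' Plots, per CpG, the smallest-magnitude delta-beta across reference
#' comparisons against the worst (largest) adjusted p-value, marking
#' called DMCs by direction.
#'
#' @param object A `dmc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dmc_result
#' @export
autoplot.dmc_result <- function(object, ...) {
  delta_cols <- grep("^delta_", names(object$stats), value = TRUE)
  q_cols <- grep("^q_", names(object$stats), value = TRUE)
  df <- object$stats |>
    mutate(
      delta = apply(across_mat(object$stats, delta_cols), 1,
                    function(z) z[which.min(abs(z))]),
      max_q = apply(across_mat(object$stats, q_cols), 1, max),
      status = dplyr::case_when(
        .data$called & .data$direction == "hypo" ~ "hypo DMC",
        .data$called & .data$direction == "hyper" ~ "hyper DMC",
        TRUE ~ "not called"
      )
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta,
                                   y = -log10(pmax(.data$max_q, 1e-12)),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c("hypo DMC" = "#2166ac",
                                            "hyper DMC" = "#b2182b",
                                            "not called" = "grey70")) +
    ggplot2::labs(x = expression(Delta * beta ~ "(vs references)"),
                  y = expression(-log[10] ~ "max adjusted p"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

# internal: matrix view of selected numeric columns
across_mat <- function(df, cols) as.matrix(df[cols])

#' Bar plot of genomic-context enrichment results
#'
#' Proportion differences (DMC minus array, percentage points) per
#' annotation category, split by direction, with flagged categories
#' filled and unflagged ones greyed.
#'
#' @param enrichment Output of [context_enrichment()].
#' @return A ggplot.
#' @export
plot_enrichment <- function(enrichment) {
  df <- as_tibble(enrichment) |>
    mutate(label = paste(.data$axis, .data$category, sep = ": "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$proportion_difference,
                                   y = .data$label,
                                   fill = ifelse(.data$flagged,
                                                 .data$direction, "ns"))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::scale_fill_manual(values = c(hypo = "#2166ac", hyper = "#b2182b",
                                          ns = "grey75"), guide = "none") +
    ggplot2::labs(x = "Difference in proportion (DMC - array, % points)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the fusion-partner graph
#'
#' Force-directed layout of the undirected partner graph with node size
#' by partner count and promiscuous genes highlighted.
#'
#' @param graph A `fusion_graph`.
#' @param min_partners Promiscuity threshold used for highlighting.
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_fusion_graph <- function(graph, min_partners = 2, seed = 1) {
  stopifnot(inherits(graph, "fusion_graph"))
  ig <- as_igraph_(graph)
  lay <- with_seed_(seed, igraph::layout_with_fr(ig))
  nodes <- tibble(gene = igraph::V(ig)$name,
                  x = lay[, 1], y = lay[, 2],
                  n_partners = as.integer(igraph::degree(ig))) |>
    mutate(promiscuous = .data$n_partners >= min_partners)
  edges <- graph$edges |>
    left_join(select(nodes, gene, xa = "x", ya = "y"),
              by = c(gene_a = "gene")) |>
    left_join(select(nodes, gene, xb = "x", yb = "y"),
              by = c(gene_b = "gene"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb,
                                       linewidth = .data$n_patients),
                          colour = "grey60") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$n_partners,
                                     colour = .data$promiscuous)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$gene),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::scale_linewidth_continuous(range = c(0.3, 2)) +
    ggplot2::theme_void()
}
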