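#' Build the fusion-partner graph from validated fusion calls
#'
#' Genes are nodes; an undirected edge joins two genes observed fused in
#' at least one patient. Reciprocal orientations (A->B and B->A) collapse
#' to one edge; edge multiplicity counts distinct patients, not calls.
#' The original orientations are retained for reciprocal analysis.
#'
#' @param calls Tibble with columns `sample_id`, `gene5`, `gene3` and
#'   optionally `subtype`, `source`.
#' @return Object of class `fusion_graph`: list with `edges` (tibble:
#'   gene_a, gene_b, n_patients), `edge_subtypes` (tibble: gene_a,
#'   gene_b, subtype, n_patients; empty when no subtype column),
#'   `orientations` (the input calls) and `nodes` (character).
#' @export
build_fusion_graph <- function(calls) {
  calls <- as_tibble(calls)
  keyed <- calls |>
    mutate(gene_a = pmin(.data$gene5, .data$gene3),
           gene_b = pmax(.data$gene5, .data$gene3))
  edges <- keyed |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(n_patients = n_distinct(.data$sample_id), .groups = "drop") |>
    arrange(.data$gene_a, .data$gene_b)
  edge_subtypes <- if ("subtype" %in% names(calls) && nrow(calls) > 0) {
    keyed |>
      group_by(.data$gene_a, .data$gene_b, .data$subtype) |>
      summarise(n_patients = n_distinct(.data$sample_id), .groups = "drop")
  } else {
    tibble(gene_a = character(), gene_b = character(),
           subtype = character(), n_patients = integer())
  }
  structure(list(
    edges = edges,
    edge_subtypes = edge_subtypes,
    orientations = calls,
    nodes = sort(unique(c(edges$gene_a, edges$gene_b)))
  ), class = "fusion_graph")
}

#' @export
print.fusion_graph <- function(x, ...) {
  cat("<fusion_graph>", length(x$nodes), "genes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# igraph view of the partner graph (internal).
as_igraph_ <- function(graph) {
  igraph::graph_from_data_frame(
    graph$edges[c("gene_a", "gene_b")], directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
}

#' Promiscuous genes of the fusion-partner graph
#'
#' A gene is promiscuous when it has at least `min_partners` distinct
#' fusion partners. The result partitions promiscuous genes into the
#' exactly-two-partner and the three-or-more classes.
#'
#' @param graph A `fusion_graph`.
#' @param min_partners Minimum distinct partners (default 2).
#' @return Tibble: gene, n_partners, partner_class
#'   (`"two_partners"` / `"three_plus"`).
#' @export
promiscuous_nodes <- function(graph, min_partners = 2) {
  stopifnot(inherits(graph, "fusion_graph"))
  if (nrow(graph$edges) == 0) {
    return(tibble(gene = character(), n_partners = integer(),
                  partner_class = character()))
  }
  deg <- igraph::degree(as_igraph_(graph))
  tibble(gene = names(deg), n_partners = as.integer(deg)) |>
    filter(.data$n_partners >= min_partners) |>
    mutate(partner_class = if_else(.data$n_partners >= 3,
                                   "three_plus", "two_partners")) |>
    arrange(dplyr::desc(.data$n_partners), .data$gene)
}

#' Independent node groups of the fusion-partner graph
#'
#' Connected components of the undirected partner graph that contain at
#' least one promiscuous gene, ordered deterministically by their
#' smallest gene symbol.
#'
#' @param graph A `fusion_graph`.
#' @param min_partners Promiscuity threshold forwarded to
#'   [promiscuous_nodes()].
#' @return Tibble: group_id, gene (one row per gene, long format).
#' @export
node_groups <- function(graph, min_partners = 2) {
  stopifnot(inherits(graph, "fusion_graph"))
  if (nrow(graph$edges) == 0) {
    return(tibble(group_id = integer(), gene = character()))
  }
  comp <- igraph::components(as_igraph_(graph))
  prom <- promiscuous_nodes(graph, min_partners)$gene
  members <- split(names(comp$membership), comp$membership)
  members <- members[vapply(members, function(g) any(g %in% prom), logical(1))]
  if (length(members) == 0) {
    return(tibble(group_id = integer(), gene = character()))
  }
  members <- lapply(members, sort)
  members <- members[order(vapply(members, function(g) g[1], character(1)))]
  purrr::map2_dfr(members, seq_along(members), function(genes, i) {
    tibble(group_id = i, gene = genes)
  })
}

#' Pair reciprocal fusion orientations within samples
#'
#' Within one sample, calls A->B and B->A form one reciprocal pair; each
#' call belongs to at most one pair. Calls in different samples never
#' pair.
#'
#' @param calls Tibble with columns `sample_id`, `gene5`, `gene3`.
#' @return List with `pairs` (tibble: sample_id, gene_a, gene_b) and
#'   `singletons` (tibble: the unpaired calls).
#' @export
pair_reciprocals <- function(calls) {
  calls <- as_tibble(calls)
  keyed <- calls |>
    mutate(gene_a = pmin(.data$gene5, .data$gene3),
           gene_b = pmax(.data$gene5, .data$gene3))
  status <- keyed |>
    group_by(.data$sample_id, .data$gene_a, .data$gene_b) |>
    summarise(n_orientations = n_distinct(paste(.data$gene5, .data$gene3)),
              .groups = "drop")
  pairs <- status |>
    filter(.data$n_orientations == 2) |>
    select("sample_id", "gene_a", "gene_b")
  singletons <- keyed |>
    anti_join(pairs, by = c("sample_id", "gene_a", "gene_b")) |>
    select(all_of(names(calls)))
  list(pairs = pairs, singletons = singletons)
}

#' Classify fusion events by chromosomal locality and reading frame
#'
#' Locality comes from the gene models: partners on different chromosome
#' labels are inter-chromosomal; intra-chromosomal events get a genomic
#' distance (by default between gene-body midpoints) and a `far_apart`
#' flag for events whose partners lie more than 1 Mbp apart. Frame is
#' classified from CDS phase arithmetic when transcript breakpoints are
#' provided: the event is in frame when the coding length retained on
#' the 5' side is congruent (mod 3) with the 3' partner's CDS phase at
#' its breakpoint; otherwise `unknown` is reported rather than a guess.
#'
#' @param events Tibble with columns `gene5`, `gene3` and optional
#'   `break5`, `break3` (0-based transcript breakpoints).
#' @param gene_models Gene-model tibble (see [read_gene_models()]).
#' @param distance_method `"midpoint"` (default) or `"edge"`
#'   (nearest-edge distance, 0 when gene bodies overlap).
#' @param far_threshold Distance above which an intra-chromosomal event
#'   counts as far apart (default 1 Mbp).
#' @return Tibble: gene5, gene3, locality, genomic_distance (NA when
#'   inter-chromosomal), far_apart, frame.
#' @export
classify_event <- function(events, gene_models,
                           distance_method = c("midpoint", "edge"),
                           far_threshold = 1e6) {
  distance_method <- match.arg(distance_method)
  events <- as_tibble(events)
  missing <- setdiff(unique(c(events$gene5, events$gene3)), gene_models$gene)
  if (length(missing) > 0) {
    abort(paste0("Gene(s) absent from the gene models: ",
                 paste(missing, collapse = ", ")))
  }
  gm <- gene_models |>
    mutate(midpoint = (.data$start + .data$end) / 2)
  g5 <- gm[match(events$gene5, gm$gene), ]
  g3 <- gm[match(events$gene3, gm$gene), ]

  intra <- g5$chrom == g3$chrom
  dist <- rep(NA_real_, nrow(events))
  if (distance_method == "midpoint") {
    dist[intra] <- abs(g5$midpoint - g3$midpoint)[intra]
  } else {
    gap <- pmax(g5$start, g3$start) - pmin(g5$end, g3$end)
    dist[intra] <- pmax(0, gap)[intra]
  }

  frame <- rep("unknown", nrow(events))
  if (all(c("break5", "break3") %in% names(events)) &&
      "cds_start" %in% names(gm)) {
    have <- !is.na(events$break5) & !is.na(events$break3) &
      !is.na(g5$cds_start) & !is.na(g3$cds_start)
    coding5 <- events$break5 - g5$cds_start
    phase3 <- (events$break3 - g3$cds_start) %% 3
    ok <- have & coding5 >= 0 & (events$break3 - g3$cds_start) >= 0
    frame[ok] <- if_else((coding5[ok] %% 3) == phase3[ok],
                         "in_frame", "out_of_frame")
  }

  tibble(
    gene5 = events$gene5, gene3 = events$gene3,
    locality = if_else(intra, "intra_chromosomal", "inter_chromosomal"),
    genomic_distance = dist,
    far_apart = !is.na(dist) & dist > far_threshold,
    frame = frame
  )
}

#' Recurrence summary of fusion calls
#'
#' Tabulates patients per fusion event and subtype (oriented rows, so a
#' reciprocal orientation is its own row), per-sample fusion counts, and
#' the recurrent-event subset: undirected events seen in at least
#' `min_patients` BCP-ALL patients.
#'
#' @param calls Tibble with columns `sample_id`, `gene5`, `gene3`,
#'   `subtype` (every sample must carry a subtype label).
#' @param min_patients Patients required for an event to count as
#'   recurrent (default 2).
#' @param bcp_subtypes Subtype labels counted as BCP-ALL for the
#'   recurrence subset.
#' @return List with `events` (tibble: gene5, gene3, subtype,
#'   n_patients), `per_sample` (tibble: sample_id, n_fusions) and
#'   `recurrent` (tibble: gene_a, gene_b, n_patients).
#' @export
recurrence_summary <- function(calls, min_patients = 2,
                               bcp_subtypes = c("t1221", "t922", "MLL_r",
                                                "HeH", "dic920", "BCP_other")) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0) {
    return(list(
      events = tibble(gene5 = character(), gene3 = character(),
                      subtype = character(), n_patients = integer()),
      per_sample = tibble(sample_id = character(), n_fusions = integer()),
      recurrent = tibble(gene_a = character(), gene_b = character(),
                         n_patients = integer())
    ))
  }
  if (!"subtype" %in% names(calls) || anyNA(calls$subtype)) {
    abort("Every call needs a `subtype` label.")
  }
  events <- calls |>
    group_by(.data$gene5, .data$gene3, .data$subtype) |>
    summarise(n_patients = n_distinct(.data$sample_id), .groups = "drop") |>
    arrange(dplyr::desc(.data$n_patients), .data$gene5, .data$gene3)
  per_sample <- calls |>
    group_by(.data$sample_id) |>
    summarise(n_fusions = n(), .groups = "drop")
  recurrent <- calls |>
    filter(.data$subtype %in% bcp_subtypes) |>
    mutate(gene_a = pmin(.data$gene5, .data$gene3),
           gene_b = pmax(.data$gene5, .data$gene3)) |>
    group_by(.data$gene_a, .data$gene_b) |>
    summarise(n_patients = n_distinct(.data$sample_id), .groups = "drop") |>
    filter(.data$n_patients >= min_patients) |>
    arrange(dplyr::desc(.data$n_patients), .data$gene_a)
  list(events = events, per_sample = per_sample, recurrent = recurrent)
}
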