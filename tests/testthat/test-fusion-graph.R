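calls_tbl <- function(...) {
  df <- tibble::tribble(...)
  if (!"subtype" %in% names(df)) df$subtype <- "BCP_other"
  df
}

test_that("graph construction collapses reciprocals and counts patients", {
  g <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B",
    "s2", "A", "B"
  ))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$n_patients, 2L)

  # reciprocal orientations in the same patient are one edge, one patient
  g2 <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B",
    "s1", "B", "A"
  ))
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$n_patients, 1L)

  # the t(12;21)-family events form a single connected component
  g3 <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "ETV6", "RUNX1",
    "s2", "DCAF5", "ETV6",
    "s3", "RUNX1", "PTPRO"
  ))
  comp <- node_groups(g3)
  expect_equal(sort(unique(comp$gene)),
               c("DCAF5", "ETV6", "PTPRO", "RUNX1"))
  expect_equal(unique(comp$group_id), 1L)

  # input order does not matter
  calls <- calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B", "s2", "C", "D", "s3", "A", "C", "s4", "E", "F"
  )
  ga <- build_fusion_graph(calls)
  gb <- build_fusion_graph(calls[sample.int(nrow(calls)), ])
  expect_equal(ga$edges, gb$edges)
})

test_that("promiscuous genes and node groups follow the partner-count rules", {
  star <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B",
    "s2", "A", "C"
  ))
  p <- promiscuous_nodes(star)
  expect_equal(p$gene, "A")
  expect_equal(p$partner_class, "two_partners")

  hub <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B", "s2", "A", "C", "s3", "A", "D"
  ))
  p3 <- promiscuous_nodes(hub)
  expect_equal(p3$partner_class[p3$gene == "A"], "three_plus")

  single <- build_fusion_graph(calls_tbl(~sample_id, ~gene5, ~gene3,
                                         "s1", "A", "B"))
  expect_equal(nrow(promiscuous_nodes(single)), 0)
  expect_equal(nrow(node_groups(single)), 0)

  # two hubs, two groups; the isolated promiscuity-free edge is excluded
  two <- build_fusion_graph(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "A", "B", "s2", "A", "C", "s3", "D", "E", "s4", "D", "F",
    "s5", "X", "Y"
  ))
  ng <- node_groups(two)
  expect_equal(max(ng$group_id), 2)
  expect_false("X" %in% ng$gene)
})

test_that("components and degrees agree with brute-force reachability", {
  for (seed in 1:10) {
    calls <- random_calls(25, seed = seed)
    g <- build_fusion_graph(calls)
    comp <- oracle_components(g$edges)
    ng <- node_groups(g, min_partners = 1) # every node promiscuous at 1
    # every brute-force component appears as exactly one group
    split_oracle <- lapply(split(names(comp), comp), sort)
    split_pkg <- lapply(split(ng$gene, ng$group_id), sort)
    expect_setequal(unname(vapply(split_oracle, paste, "", collapse = ",")),
                    unname(vapply(split_pkg, paste, "", collapse = ",")))
    # degrees match a hand count of distinct neighbours
    pn <- promiscuous_nodes(g, min_partners = 1)
    for (i in seq_len(nrow(pn))) {
      ggene <- pn$gene[i]
      nb <- unique(c(g$edges$gene_b[g$edges$gene_a == ggene],
                     g$edges$gene_a[g$edges$gene_b == ggene]))
      expect_equal(pn$n_partners[i], length(nb))
    }
  }
})

test_that("reciprocal pairing is per sample and exclusive", {
  res <- pair_reciprocals(calls_tbl(
    ~sample_id, ~gene5, ~gene3,
    "s1", "KMT2A", "AFF1",
    "s1", "AFF1", "KMT2A",
    "s2", "ETV6", "RUNX1",
    "s3", "A", "B",
    "s4", "B", "A"
  ))
  expect_equal(nrow(res$pairs), 1)
  expect_equal(res$pairs$sample_id, "s1")
  # calls in different samples stay singletons
  expect_equal(nrow(res$singletons), 3)
})

test_that("event classification reports locality, distance and frame", {
  gm <- tibble::tibble(
    gene = c("ETV6", "PTPRO", "DCAF5"),
    chrom = c("chr12", "chr12", "chr14"),
    start = c(1e6, 4.55e6, 2e6),
    end = c(1.1e6, 4.65e6, 2.1e6),
    cds_start = c(10L, 10L, 10L)
  )
  ev <- classify_event(tibble::tibble(gene5 = c("ETV6", "DCAF5"),
                                      gene3 = c("PTPRO", "ETV6")), gm)
  expect_equal(ev$locality, c("intra_chromosomal", "inter_chromosomal"))
  expect_equal(ev$genomic_distance[1], 3.55e6)
  expect_true(ev$far_apart[1])
  expect_true(is.na(ev$genomic_distance[2]))
  expect_false(ev$far_apart[2])
  # locality and distance are symmetric in the partners
  ev_sw <- classify_event(tibble::tibble(gene5 = "PTPRO", gene3 = "ETV6"), gm)
  expect_equal(ev_sw$genomic_distance, ev$genomic_distance[1])

  # codon-boundary breakpoints on both sides are in frame
  fr <- classify_event(tibble::tibble(
    gene5 = c("ETV6", "ETV6"), gene3 = c("PTPRO", "PTPRO"),
    break5 = c(10 + 9, 10 + 9), break3 = c(10 + 12, 10 + 13)
  ), gm)
  expect_equal(fr$frame, c("in_frame", "out_of_frame"))
  # missing breakpoints give unknown, not a guess
  fr2 <- classify_event(tibble::tibble(gene5 = "ETV6", gene3 = "PTPRO"), gm)
  expect_equal(fr2$frame, "unknown")

  expect_error(classify_event(tibble::tibble(gene5 = "NOPE", gene3 = "ETV6"),
                              gm), "NOPE")
})

test_that("recurrence summary counts patients and flags recurrent events", {
  calls <- calls_tbl(
    ~sample_id, ~gene5, ~gene3, ~subtype,
    "s1", "A", "B", "BCP_other",
    "s2", "A", "B", "BCP_other",
    "s3", "A", "B", "BCP_other",
    "s4", "C", "D", "T_ALL",
    "s5", "C", "D", "T_ALL",
    "s1", "E", "F", "BCP_other",
    "s1", "G", "H", "BCP_other",
    "s1", "I", "J", "BCP_other"
  )
  rs <- recurrence_summary(calls)
  expect_equal(rs$events$n_patients[rs$events$gene5 == "A"], 3L)
  # a sample can carry several co-expressed fusions
  expect_equal(rs$per_sample$n_fusions[rs$per_sample$sample_id == "s1"], 4L)
  # recurrence is restricted to BCP-ALL subtypes
  expect_true(all(rs$recurrent$gene_a == "A"))
  empty <- recurrence_summary(calls[0, ])
  expect_equal(nrow(empty$events), 0)
  expect_error(recurrence_summary(dplyr::mutate(calls, subtype = NA)),
               "subtype")
})
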