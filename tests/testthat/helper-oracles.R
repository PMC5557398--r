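# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive results from first principles and share no
# code with the package internals.

# Rule-by-rule evaluation of one candidate against the filter config;
# returns "kept" or the name of the first rule that fires.
oracle_filter_one <- function(cand, config, all_candidates) {
  known <- config$known_all_genes
  if (cand$gene5 %in% known || cand$gene3 %in% known) return("kept")
  key <- paste(sort(c(cand$gene5, cand$gene3)), collapse = "--")
  if (key %in% config$blacklist_pair_keys ||
      cand$gene5 %in% config$blacklist_genes ||
      cand$gene3 %in% config$blacklist_genes) return("blacklist")
  if (key %in% config$normal_pair_keys) return("normal_subtraction")
  if (config$count_common_dominance && cand$n_common_mapping > 0 &&
      cand$n_common_mapping >= cand$n_unique_spanning) return("common_mapping")
  # promiscuity over the post-blacklist cohort set, counted by hand
  keys <- paste(pmin(all_candidates$gene5, all_candidates$gene3),
                pmax(all_candidates$gene5, all_candidates$gene3), sep = "--")
  exempt <- all_candidates$gene5 %in% known | all_candidates$gene3 %in% known
  blk <- keys %in% config$blacklist_pair_keys |
    all_candidates$gene5 %in% config$blacklist_genes |
    all_candidates$gene3 %in% config$blacklist_genes
  pool <- all_candidates[!(blk & !exempt), , drop = FALSE]
  partners_of <- function(g) {
    p <- c(pool$gene3[pool$gene5 == g], pool$gene5[pool$gene3 == g])
    length(unique(p))
  }
  if (partners_of(cand$gene5) > config$promiscuity_threshold ||
      partners_of(cand$gene3) > config$promiscuity_threshold) {
    return("promiscuity")
  }
  if (cand$n_unique_spanning < config$min_unique_reads) return("low_support")
  "kept"
}

oracle_filter <- function(candidates, config) {
  vapply(seq_len(nrow(candidates)), function(i) {
    oracle_filter_one(as.list(candidates[i, ]), config, candidates)
  }, character(1))
}

# Naive reverse complement, independent of the package helper.
oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force best junction-spanning mismatch count: every offset, both
# orientations, then the anchor rule applied by window arithmetic.
oracle_junction_mm <- function(seq, contig, junction_offset, anchor_min) {
  L <- nchar(seq)
  M <- nchar(contig)
  best <- Inf
  for (s in c(seq, oracle_revcomp(seq))) {
    sc <- strsplit(s, "")[[1]]
    cc <- strsplit(contig, "")[[1]]
    for (o in 0:(M - L)) {
      left <- junction_offset - o
      right <- o + L - junction_offset
      if (left < anchor_min || right < anchor_min) next
      mm <- sum(sc != cc[(o + 1):(o + L)])
      best <- min(best, mm)
    }
  }
  best
}

# Brute-force best mismatch count against a whole transcript.
oracle_tx_mm <- function(seq, tx) {
  L <- nchar(seq)
  M <- nchar(tx)
  if (M < L) return(Inf)
  best <- Inf
  cc <- strsplit(tx, "")[[1]]
  for (s in c(seq, oracle_revcomp(seq))) {
    sc <- strsplit(s, "")[[1]]
    for (o in 0:(M - L)) {
      best <- min(best, sum(sc != cc[(o + 1):(o + L)]))
    }
  }
  best
}

# Full support decision for one read pair, by brute force.
oracle_pair_supports <- function(seq1, seq2, contig, junction_offset,
                                 transcripts, params) {
  for (seq in c(seq1, seq2)) {
    mm <- oracle_junction_mm(seq, contig, junction_offset, params$anchor_min)
    if (mm > params$max_mismatches) next
    if (params$uniqueness) {
      ref_best <- min(vapply(transcripts, function(tx) oracle_tx_mm(seq, tx),
                             double(1)))
      if (ref_best <= mm) next
    }
    return(TRUE)
  }
  FALSE
}

# Two-sided Fisher p for a 2x2 table by exact hypergeometric enumeration:
# sum of the probabilities of all tables (with the same margins) whose
# probability does not exceed the observed one.
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  obs <- dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Connected components by breadth-first reachability over an edge list.
oracle_components <- function(edges) {
  nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  comp <- setNames(rep(NA_integer_, length(nodes)), nodes)
  cid <- 0L
  for (start in nodes) {
    if (!is.na(comp[start])) next
    cid <- cid + 1L
    queue <- start
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      nb <- c(edges$gene_b[edges$gene_a == v], edges$gene_a[edges$gene_b == v])
      queue <- c(queue, nb[is.na(comp[nb])])
    }
  }
  comp
}

# Mean silhouette width for a 1-d embedding with two known clusters.
silhouette_1d <- function(x, labels) {
  sil <- vapply(seq_along(x), function(i) {
    own <- abs(x[i] - x[labels == labels[i]])
    a <- sum(own) / (length(own) - 1)
    b <- mean(abs(x[i] - x[labels != labels[i]]))
    (b - a) / max(a, b)
  }, double(1))
  mean(sil)
}

# Random validated-call table for graph property tests.
random_calls <- function(n_calls, n_genes = 12, n_samples = 8, seed = 1) {
  set.seed(seed)
  genes <- sprintf("RG%02d", seq_len(n_genes))
  tibble::tibble(
    sample_id = sample(sprintf("S%02d", seq_len(n_samples)), n_calls,
                       replace = TRUE),
    gene5 = sample(genes, n_calls, replace = TRUE),
    gene3 = sample(genes, n_calls, replace = TRUE),
    subtype = sample(c("t1221", "BCP_other", "HeH"), n_calls, replace = TRUE)
  ) |>
    dplyr::filter(gene5 != gene3) |>
    dplyr::distinct(sample_id, gene5, gene3, .keep_all = TRUE)
}
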