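#' Screening parameters for the targeted junction search
#'
#' @param anchor_min Minimum bases a matching read must have on each side
#'   of the junction (>= 1).
#' @param max_mismatches Maximum mismatches allowed in a read's contig
#'   match (>= 0).
#' @param min_support Read pairs required to call a targeted candidate.
#' @param uniqueness When `TRUE`, a junction match is discarded if any
#'   single reference transcript matches the read with as few or fewer
#'   mismatches (single-best-hit notion of "uniquely aligned").
#' @return A list of class `screen_params`.
#' @export
screen_params <- function(anchor_min = 10, max_mismatches = 2,
                          min_support = 3, uniqueness = TRUE) {
  if (anchor_min < 1) abort("`anchor_min` must be >= 1.")
  if (max_mismatches < 0) abort("`max_mismatches` must be >= 0.")
  structure(list(anchor_min = anchor_min, max_mismatches = max_mismatches,
                 min_support = min_support, uniqueness = isTRUE(uniqueness)),
            class = "screen_params")
}

#' Build a fusion-junction contig from spliced transcript sequence
#'
#' Concatenates the last `flank` bases of the 5' partner before its
#' breakpoint with the first `flank` bases of the 3' partner from its
#' breakpoint, both on the sense strand of the (spliced) transcript. The
#' junction offset — the 0-based index of the first 3'-partner base — is
#' always equal to `flank`.
#'
#' @param bundle A `transcriptome_bundle` (or any list with a
#'   `transcripts` named character vector).
#' @param gene5,gene3 Partner gene ids present in the bundle.
#' @param break5,break3 0-based transcript breakpoints: `break5` bases of
#'   the 5' partner are retained; the 3' partner is joined from position
#'   `break3` on.
#' @param flank Bases taken from each side (default 40, sized so a 50 bp
#'   read can span the junction with 10 bp anchors).
#' @param assay_id Assay identifier; defaults to `"<gene5>-<gene3>"`.
#' @return One-row tibble: assay_id, gene5, gene3, contig,
#'   junction_offset, flank.
#' @export
build_junction_contig <- function(bundle, gene5, break5, gene3, break3,
                                  flank = 40, assay_id = NULL) {
  tx <- bundle$transcripts
  for (g in c(gene5, gene3)) {
    if (!g %in% names(tx)) abort(paste0("Gene not in reference bundle: ", g))
  }
  if (break5 < flank) {
    abort(sprintf("5' side of %s-%s: only %d bases before the breakpoint (< flank %d).",
                  gene5, gene3, break5, flank))
  }
  if (nchar(tx[[gene3]]) - break3 < flank) {
    abort(sprintf("3' side of %s-%s: only %d bases after the breakpoint (< flank %d).",
                  gene5, gene3, nchar(tx[[gene3]]) - break3, flank))
  }
  contig <- paste0(substring(tx[[gene5]], break5 - flank + 1, break5),
                   substring(tx[[gene3]], break3 + 1, break3 + flank))
  tibble(assay_id = assay_id %||% paste0(gene5, "-", gene3),
         gene5 = gene5, gene3 = gene3, contig = contig,
         junction_offset = as.integer(flank), flank = as.integer(flank))
}

# Minimum mismatch count of `seq` against `target` over the given 0-based
# offsets (both already on the same strand). Inf when no offset allowed.
min_mismatches_at <- function(seq_chars, target_chars, offsets) {
  if (length(offsets) == 0) return(Inf)
  L <- length(seq_chars)
  best <- Inf
  for (o in offsets) {
    mm <- sum(seq_chars != target_chars[(o + 1):(o + L)])
    if (mm < best) best <- mm
    if (best == 0) break
  }
  best
}

# Best junction-spanning mismatch count of a read against a contig,
# testing the read as given and reverse-complemented. Only offsets where
# the read covers >= anchor_min bases on both sides of junction_offset
# are admissible.
junction_match <- function(seq, contig_chars, junction_offset, anchor_min) {
  L <- nchar(seq)
  M <- length(contig_chars)
  lo <- max(0L, junction_offset - (L - anchor_min))
  hi <- min(M - L, junction_offset - anchor_min)
  if (hi < lo) return(Inf)
  offsets <- seq.int(lo, hi)
  fwd <- strsplit(seq, "", fixed = TRUE)[[1]]
  rev_ <- strsplit(revcomp(seq), "", fixed = TRUE)[[1]]
  min(min_mismatches_at(fwd, contig_chars, offsets),
      min_mismatches_at(rev_, contig_chars, offsets))
}

# Best mismatch count of a read against one reference transcript over all
# offsets and both strands, with early exit at `stop_at`.
reference_match <- function(seq, tx_chars, stop_at = 0) {
  L <- nchar(seq)
  M <- length(tx_chars)
  if (M < L) return(Inf)
  offsets <- seq.int(0L, M - L)
  best <- Inf
  for (s in c(seq, revcomp(seq))) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (o in offsets) {
      mm <- sum(chars != tx_chars[(o + 1):(o + L)])
      if (mm < best) best <- mm
      if (best <= stop_at) return(best)
    }
  }
  best
}

#' Count read pairs supporting a fusion-junction assay
#'
#' A read supports the assay if it matches the junction contig (either
#' strand, ungapped, at any admissible offset) with at most
#' `max_mismatches` mismatches while covering at least `anchor_min` bases
#' on each side of the junction, and — when uniqueness is required — no
#' single reference transcript matches the read with as few or fewer
#' mismatches. Both mates of a pair are tested; a pair is counted once.
#'
#' @param assay One-row tibble from [build_junction_contig()].
#' @param reads A `read_set` (or its `reads` tibble with columns
#'   `read_id`, `seq1`, `seq2`).
#' @param reference The `transcriptome_bundle` used for the uniqueness
#'   check; may be `NULL` when `params$uniqueness` is `FALSE`.
#' @param params A [screen_params()].
#' @return One-row tibble: `assay_id`, `n_support`,
#'   `supporting_read_ids` (list column).
#' @export
count_supporting_reads <- function(assay, reads, reference = NULL,
                                   params = screen_params()) {
  stopifnot(inherits(params, "screen_params"))
  rd <- if (inherits(reads, "read_set")) reads$reads else as_tibble(reads)
  contig_chars <- strsplit(assay$contig[1], "", fixed = TRUE)[[1]]
  j <- assay$junction_offset[1]
  if (params$uniqueness && is.null(reference)) {
    abort("`reference` is required when `params$uniqueness` is TRUE.")
  }
  ref_chars <- if (params$uniqueness) {
    lapply(reference$transcripts, function(s) strsplit(s, "", fixed = TRUE)[[1]])
  } else NULL

  supports <- logical(nrow(rd))
  for (i in seq_len(nrow(rd))) {
    for (seq in c(rd$seq1[i], rd$seq2[i])) {
      mm <- junction_match(seq, contig_chars, j, params$anchor_min)
      if (mm > params$max_mismatches) next
      if (params$uniqueness) {
        beaten <- FALSE
        for (txc in ref_chars) {
          if (reference_match(seq, txc, stop_at = mm) <= mm) {
            beaten <- TRUE
            break
          }
        }
        if (beaten) next
      }
      supports[i] <- TRUE
      break
    }
  }
  tibble(assay_id = assay$assay_id[1],
         n_support = sum(supports),
         supporting_read_ids = list(rd$read_id[supports]))
}

#' Targeted screen of a predefined fusion panel
#'
#' Builds a junction assay for every panel entry and counts uniquely
#' matching junction-spanning read pairs. Assays reaching `min_support`
#' become targeted fusion candidates in the same dialect the de novo
#' filter uses; assays below threshold are reported in a sub-threshold
#' log with their counts, so near-miss cases (e.g. a canonical fusion
#' supported by only two reads in a shallow library) remain visible.
#'
#' @param panel Tibble with columns `assay_id`, `gene5`, `break5`,
#'   `gene3`, `break3` (0-based breakpoints; see [read_fusion_panel()]
#'   for the 1-based file dialect).
#' @param reads A `read_set`.
#' @param bundle The reference `transcriptome_bundle`.
#' @param params A [screen_params()].
#' @param sample_id Sample label attached to emitted candidates.
#' @param flank Contig flank passed to [build_junction_contig()].
#' @return Object of class `targeted_screen_result`: list with
#'   `candidates` (tibble, `source = "targeted"`), `subthreshold`
#'   (tibble: assay_id, gene5, gene3, n_support) and `support` (all
#'   per-assay counts).
#' @export
targeted_screen <- function(panel, reads, bundle, params = screen_params(),
                            sample_id = "sample_1", flank = 40) {
  panel <- as_tibble(panel)
  if (nrow(panel) == 0) abort("The fusion panel is empty.")
  if (anyDuplicated(panel$assay_id)) {
    abort(paste0("Duplicate assay_id in panel: ",
                 panel$assay_id[duplicated(panel$assay_id)][1]))
  }
  support <- purrr::pmap_dfr(panel, function(assay_id, gene5, break5, gene3,
                                             break3, ...) {
    assay <- build_junction_contig(bundle, gene5, break5, gene3, break3,
                                   flank = flank, assay_id = assay_id)
    cnt <- count_supporting_reads(assay, reads, bundle, params)
    mutate(cnt, gene5 = gene5, gene3 = gene3)
  })
  called <- filter(support, .data$n_support >= params$min_support)
  candidates <- tibble(
    sample_id = sample_id,
    gene5 = called$gene5, gene3 = called$gene3,
    n_unique_spanning = called$n_support,
    n_common_mapping = 0,
    predicted_frame = "unknown",
    source = "targeted",
    assay_id = called$assay_id
  )
  structure(list(
    candidates = candidates,
    subthreshold = filter(support, .data$n_support < params$min_support) |>
      select("assay_id", "gene5", "gene3", "n_support"),
    support = select(support, "assay_id", "gene5", "gene3", "n_support",
                     "supporting_read_ids"),
    params = params
  ), class = "targeted_screen_result")
}

#' @export
print.targeted_screen_result <- function(x, ...) {
  cat("<targeted_screen_result>", nrow(x$support), "assays;",
      nrow(x$candidates), "called,", nrow(x$subthreshold), "sub-threshold\n")
  invisible(x)
}

#' Read a targeted fusion panel file
#'
#' Tab-separated with columns `assay_id`, `gene5`, `break5`, `gene3`,
#' `break3`; breakpoints 1-based inclusive in the file and converted to
#' the internal 0-based convention.
#'
#' @param path Panel file path.
#' @return Tibble with 0-based breakpoints.
#' @export
read_fusion_panel <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    assay_id = "c", gene5 = "c", break5 = "i", gene3 = "c", break3 = "i"
  )) |>
    mutate(break5 = .data$break5, break3 = .data$break3 - 1L)
}
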