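#' Simulate paired-end reads with planted fusion junctions
#'
#' Emulates a 50 bp paired-end RNA-seq library in transcript space: for
#' each requested fusion, exactly `n_support` read pairs have one mate
#' spanning the fusion junction with at least `anchor_min` bases on each
#' side; the remaining pairs are background drawn uniformly from normal
#' transcripts. Every read carries a truth label in its name
#' (`origin=gene:<id>` or `origin=junction:<id>`) so support counting can
#' be audited without alignment. Sequencing errors (uniform per-base
#' substitutions) are applied after truth labelling: truth records where
#' a read came from, not whether it still matches.
#'
#' @param bundle A [simulate_transcriptome()] bundle.
#' @param fusions Tibble with columns `gene5`, `gene3`, `n_support` and
#'   optional `break5`, `break3` (0-based transcript coordinates: number
#'   of 5'-partner bases retained / first retained base of the 3'
#'   partner; default is the transcript midpoint).
#' @param n_background Background read pairs drawn from normal transcripts.
#' @param read_length Read length in bases.
#' @param insert_size Outer fragment length for a pair.
#' @param anchor_min Minimum bases a junction mate has on each side of the
#'   junction.
#' @param error_rate Per-base substitution probability, applied last.
#' @param seed Integer seed; FASTQ output is byte-identical per seed.
#'
#' @return Object of class `read_set`: list with `reads` (tibble:
#'   read_id, seq1, seq2) and `truth` (tibble: read_id, origin_type,
#'   origin, junction_mate).
#' @export
simulate_fusion_reads <- function(bundle, fusions, n_background = 200,
                                  read_length = 50, insert_size = 150,
                                  anchor_min = 10, error_rate = 0, seed = 1) {
  stopifnot(inherits(bundle, "transcriptome_bundle"))
  fusions <- as_tibble(fusions)
  if (nrow(fusions) > 0) {
    missing <- setdiff(c(fusions$gene5, fusions$gene3), names(bundle$transcripts))
    if (length(missing) > 0) {
      abort(paste0("Fusion partner gene(s) not in bundle: ",
                   paste(unique(missing), collapse = ", ")))
    }
    if (any(fusions$n_support < 0)) abort("`n_support` must be >= 0.")
  }

  with_seed_(seed, {
    tx <- bundle$transcripts
    reads <- list()
    truth <- list()
    idx <- 0L

    emit_pair <- function(frag_seq, frag_start, origin_type, origin, junction_mate) {
      idx <<- idx + 1L
      id <- sprintf("frag%06d|origin=%s:%s", idx, origin_type, origin)
      seq1 <- substring(frag_seq, frag_start + 1, frag_start + read_length)
      frag_end <- frag_start + min(insert_size, nchar(frag_seq) - frag_start)
      seq2 <- revcomp(substring(frag_seq, frag_end - read_length + 1, frag_end))
      reads[[idx]] <<- tibble(read_id = id, seq1 = seq1, seq2 = seq2)
      truth[[idx]] <<- tibble(read_id = id, origin_type = origin_type,
                              origin = origin, junction_mate = junction_mate)
    }

    if (nrow(fusions) > 0) {
      for (j in seq_len(nrow(fusions))) {
        g5 <- fusions$gene5[j]
        g3 <- fusions$gene3[j]
        len5 <- nchar(tx[[g5]])
        len3 <- nchar(tx[[g3]])
        b5 <- if ("break5" %in% names(fusions) && !is.na(fusions$break5[j])) {
          fusions$break5[j]
        } else len5 %/% 2
        b3 <- if ("break3" %in% names(fusions) && !is.na(fusions$break3[j])) {
          fusions$break3[j]
        } else len3 %/% 2
        if (b5 < read_length) {
          abort(sprintf("5' junction flank of %s-%s (%d bases) shorter than the read length.",
                        g5, g3, b5))
        }
        if (len3 - b3 < read_length) {
          abort(sprintf("3' junction flank of %s-%s (%d bases) shorter than the read length.",
                        g5, g3, len3 - b3))
        }
        fus_seq <- paste0(substring(tx[[g5]], 1, b5),
                          substring(tx[[g3]], b3 + 1, len3))
        jid <- paste0(g5, "-", g3)
        n_sup <- fusions$n_support[j]
        if (n_sup > 0) {
          # Mate 1 starts so it spans the junction with >= anchor_min each side.
          s_lo <- max(0L, b5 - (read_length - anchor_min))
          s_hi <- min(b5 - anchor_min, nchar(fus_seq) - insert_size)
          if (s_hi < s_lo) {
            abort(sprintf("No valid junction-spanning placement for %s-%s; shorten `insert_size` or move the breakpoints.",
                          g5, g3))
          }
          span <- seq.int(s_lo, s_hi)
          starts <- span[sample.int(length(span), n_sup, replace = TRUE)]
          for (s in starts) emit_pair(fus_seq, s, "junction", jid, 1L)
        }
      }
    }

    if (n_background > 0) {
      bg_genes <- sample(names(tx), n_background, replace = TRUE)
      for (g in bg_genes) {
        s <- sample.int(nchar(tx[[g]]) - insert_size + 1, 1) - 1L
        emit_pair(tx[[g]], s, "gene", g, NA_integer_)
      }
    }

    reads <- if (idx > 0) bind_rows(reads) else {
      tibble(read_id = character(), seq1 = character(), seq2 = character())
    }
    truth <- if (idx > 0) bind_rows(truth) else {
      tibble(read_id = character(), origin_type = character(),
             origin = character(), junction_mate = integer())
    }

    if (error_rate > 0 && nrow(reads) > 0) {
      reads$seq1 <- apply_errors(reads$seq1, error_rate)
      reads$seq2 <- apply_errors(reads$seq2, error_rate)
    }

    structure(list(reads = reads, truth = truth), class = "read_set")
  })
}

# Uniform per-base substitution noise.
apply_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- runif(length(chars)) < rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.read_set <- function(x, ...) {
  cat("<read_set>", nrow(x$reads), "pairs;",
      sum(x$truth$origin_type == "junction"), "junction-spanning\n")
  invisible(x)
}

#' Write a read set as paired FASTQ files
#'
#' Read names carry the truth label; mates get `/1` and `/2` suffixes and
#' uniform maximal base qualities (quality simulation is out of scope).
#'
#' @param read_set A [simulate_fusion_reads()] result.
#' @param path1,path2 Output FASTQ paths for mates 1 and 2.
#' @return Invisibly, the read set.
#' @export
write_fastq <- function(read_set, path1, path2) {
  stopifnot(inherits(read_set, "read_set"))
  r <- read_set$reads
  write_one <- function(seqs, ids, path) {
    s <- Biostrings::DNAStringSet(seqs)
    names(s) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(s, path, format = "fastq", qualities = q)
  }
  write_one(r$seq1, paste0(r$read_id, "/1"), path1)
  write_one(r$seq2, paste0(r$read_id, "/2"), path2)
  invisible(read_set)
}

#' Read paired FASTQ files into a read-set tibble
#'
#' @param path1,path2 FASTQ paths for mates 1 and 2 (same order).
#' @return Object of class `read_set` (truth table absent).
#' @export
read_fastq_pairs <- function(path1, path2) {
  s1 <- Biostrings::readDNAStringSet(path1, format = "fastq")
  s2 <- Biostrings::readDNAStringSet(path2, format = "fastq")
  if (length(s1) != length(s2)) abort("Mate files differ in read count.")
  ids <- sub("/1$", "", names(s1))
  structure(list(
    reads = tibble(read_id = ids, seq1 = unname(as.character(s1)),
                   seq2 = unname(as.character(s2))),
    truth = NULL
  ), class = "read_set")
}
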