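#' Simulate a toy reference transcriptome
#'
#' Generates a small spliced reference: one transcript per gene, multi-exon
#' gene models laid out on a handful of chromosomes, and (optionally)
#' planted paralog pairs that share a high-identity region. The bundle
#' stands in for a genome-scale reference so that junction screening and
#' uniqueness filtering can be exercised end to end, including the
#' homology failure mode that multi-mapping filters exist for.
#'
#' @param n_genes Number of genes (>= 2).
#' @param n_exons Exons per gene.
#' @param exon_length Exon length in bases; must be >= `read_length`.
#' @param read_length Read length the downstream read simulator will use;
#'   only used to validate `exon_length`.
#' @param n_paralog_pairs Number of gene pairs to plant a shared region into.
#' @param paralog_identity Per-base identity of the planted shared region,
#'   in (0, 1].
#' @param paralog_length Length in bases of the planted shared region.
#' @param n_chromosomes Chromosomes to distribute genes over.
#' @param cds_offset 0-based transcript coordinate where the CDS starts
#'   (same for every gene; kept small so most of the transcript is coding).
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#'
#' @return An object of class `transcriptome_bundle`: a list with
#'   `transcripts` (named character vector of transcript sequences),
#'   `gene_models` (tibble: gene, chrom, strand, start, end, exon_starts,
#'   exon_ends, cds_start; 0-based half-open genomic intervals), and
#'   `paralog_pairs` (tibble: gene_a, gene_b, identity, region_length).
#' @export
simulate_transcriptome <- function(n_genes = 10, n_exons = 3, exon_length = 120,
                                   read_length = 50, n_paralog_pairs = 0,
                                   paralog_identity = 0.95, paralog_length = 120,
                                   n_chromosomes = 4, cds_offset = 12, seed = 1) {
  if (n_genes < 2) abort("`n_genes` must be at least 2.")
  if (exon_length < read_length) {
    abort("`exon_length` must be at least `read_length` (reads must fit in one exon).")
  }
  if (n_paralog_pairs > 0) {
    if (paralog_identity <= 0 || paralog_identity > 1) {
      abort("`paralog_identity` must be in (0, 1].")
    }
    tx_len <- n_exons * exon_length
    if (paralog_length > tx_len) abort("`paralog_length` exceeds transcript length.")
    if (2 * n_paralog_pairs > n_genes) abort("Not enough genes for the requested paralog pairs.")
  }

  with_seed_(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    tx_len <- n_exons * exon_length
    transcripts <- setNames(vapply(genes, function(g) random_dna(tx_len),
                                   character(1)), genes)

    # Plant paralog regions: copy a substring from gene_a into gene_b,
    # degrading it to the requested identity.
    paralogs <- tibble(gene_a = character(), gene_b = character(),
                       identity = double(), region_length = integer())
    if (n_paralog_pairs > 0) {
      for (k in seq_len(n_paralog_pairs)) {
        ga <- genes[2 * k - 1]
        gb <- genes[2 * k]
        start <- sample.int(tx_len - paralog_length + 1, 1)
        region <- substring(transcripts[[ga]], start, start + paralog_length - 1)
        chars <- strsplit(region, "", fixed = TRUE)[[1]]
        n_mut <- round((1 - paralog_identity) * paralog_length)
        if (n_mut > 0) {
          pos <- sample.int(paralog_length, n_mut)
          chars[pos] <- vapply(chars[pos], function(b) {
            sample(setdiff(c("A", "C", "G", "T"), b), 1)
          }, character(1))
        }
        sb <- transcripts[[gb]]
        substr(sb, start, start + paralog_length - 1) <- paste(chars, collapse = "")
        transcripts[[gb]] <- sb
        paralogs <- bind_rows(paralogs, tibble(
          gene_a = ga, gene_b = gb,
          identity = 1 - n_mut / paralog_length,
          region_length = as.integer(paralog_length)
        ))
      }
    }

    # Lay genes out along chromosomes: introns of 500 bp, 10 kb between genes.
    chroms <- sprintf("chr%d", rep_len(seq_len(n_chromosomes), n_genes))
    models <- purrr::map2_dfr(genes, seq_len(n_genes), function(g, i) {
      gene_start <- 1e5 * ((i - 1) %/% n_chromosomes + 1) +
        1e4 * ((i - 1) %% n_chromosomes)
      ex_starts <- gene_start + (seq_len(n_exons) - 1) * (exon_length + 500L)
      ex_ends <- ex_starts + exon_length
      tibble(
        gene = g, chrom = chroms[i],
        strand = if (i %% 2 == 0) "-" else "+",
        start = ex_starts[1], end = ex_ends[n_exons],
        exon_starts = paste(ex_starts, collapse = ","),
        exon_ends = paste(ex_ends, collapse = ","),
        cds_start = as.integer(cds_offset)
      )
    })

    structure(list(transcripts = transcripts, gene_models = models,
                   paralog_pairs = paralogs),
              class = "transcriptome_bundle")
  })
}

#' @export
print.transcriptome_bundle <- function(x, ...) {
  cat("<transcriptome_bundle>", length(x$transcripts), "genes,",
      nrow(x$paralog_pairs), "paralog pair(s)\n")
  invisible(x)
}

#' Write a transcriptome bundle to FASTA and a gene-model table
#'
#' @param bundle A `transcriptome_bundle`.
#' @param fasta_path Output FASTA path for the transcript sequences.
#' @param models_path Output tab-separated gene-model table
#'   (gene, chrom, strand, start, end, exon_starts, exon_ends, cds_start;
#'   exon coordinates comma-separated, 0-based half-open).
#' @return Invisibly, the bundle.
#' @export
write_transcriptome <- function(bundle, fasta_path, models_path) {
  stopifnot(inherits(bundle, "transcriptome_bundle"))
  seqs <- Biostrings::DNAStringSet(bundle$transcripts)
  Biostrings::writeXStringSet(seqs, fasta_path)
  readr::write_tsv(bundle$gene_models, models_path)
  invisible(bundle)
}

#' Read a gene-model table
#'
#' Parses the tab-separated gene-model dialect written by
#' [write_transcriptome()].
#'
#' @param path Path to the table.
#' @return Tibble with one row per gene.
#' @export
read_gene_models <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene = "c", chrom = "c", strand = "c",
    start = "d", end = "d", exon_starts = "c", exon_ends = "c",
    cds_start = "i"
  ))
}

#' Read a transcript FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_transcripts <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  setNames(as.character(seqs), names(seqs))
}
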