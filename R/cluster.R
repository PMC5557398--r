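#' Top-variance PCA embedding and hierarchical clustering of samples
#'
#' Ranks features by variance across samples, keeps the `n_top` most
#' variable, and computes a principal-component embedding on the
#' centered data together with a hierarchical clustering of the samples
#' (average linkage on 1 - Pearson correlation, ties broken by sample
#' order). The matrix should already be on the scale used for
#' clustering — raw beta values for methylation, log2(FPKM + 1) for
#' expression.
#'
#' @param x Feature-by-sample tibble (first column = feature id) or
#'   numeric matrix.
#' @param n_top Most-variable features to retain (default 1000; must not
#'   exceed the feature count).
#' @param n_components Principal components to report (default 2).
#' @return Object of class `profile_embedding`: list with `scores`
#'   (tibble: sample_id, PC1, PC2, ...), `var_explained` (fraction of
#'   variance per reported component), `dendrogram_order` (sample ids in
#'   leaf order), `top_features` (character) and `hclust` (the tree).
#' @export
cluster_profiles <- function(x, n_top = 1000, n_components = 2) {
  mat <- as_feature_matrix(x)
  if (ncol(mat) < 3) abort("Need at least 3 samples.")
  if (n_top > nrow(mat)) {
    abort(sprintf("`n_top` (%d) exceeds the number of features (%d).",
                  n_top, nrow(mat)))
  }
  v <- apply(mat, 1, var)
  if (all(v == 0)) abort("Constant matrix: no variance to rank features by.")
  # deterministic tie-break: variance, then row order
  top_idx <- order(-v, seq_along(v))[seq_len(n_top)]
  sub <- mat[top_idx, , drop = FALSE]

  pc <- prcomp(t(sub), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols(tibble(sample_id = colnames(sub)), scores)
  var_explained <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]

  cors <- suppressWarnings(cor(sub))
  cors[is.na(cors)] <- 0
  diag(cors) <- 1
  hc <- hclust(as.dist(1 - cors), method = "average")

  structure(list(
    scores = scores,
    var_explained = var_explained,
    dendrogram_order = colnames(sub)[hc$order],
    top_features = rownames(sub),
    hclust = hc
  ), class = "profile_embedding")
}

#' @export
print.profile_embedding <- function(x, ...) {
  cat("<profile_embedding>", nrow(x$scores), "samples;",
      length(x$top_features), "features; PC variance:",
      paste(sprintf("%.1f%%", 100 * x$var_explained), collapse = ", "), "\n")
  invisible(x)
}
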