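# Internal helpers shared across modules.

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number.")
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Canonical unordered key for a gene pair; vectorised.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "--")
}

# Reverse complement of DNA strings (plain character vector in, out).
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Random DNA of length n using the current RNG stream.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Coerce a feature-by-sample tibble (first column = feature id) to a
# numeric matrix with feature rownames. Accepts a matrix unchanged.
as_feature_matrix <- function(x, id_col = NULL) {
  if (is.matrix(x)) return(x)
  if (!is.data.frame(x)) abort("Expected a data frame or matrix.")
  id_col <- id_col %||% names(x)[1]
  m <- as.matrix(x[setdiff(names(x), id_col)])
  rownames(m) <- as.character(x[[id_col]])
  storage.mode(m) <- "double"
  m
}

# Validate a sample->group map and return it as a named character vector.
group_map <- function(groups) {
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      abort("`groups` must have columns `sample_id` and `group`.")
    }
    setNames(as.character(groups$group), as.character(groups$sample_id))
  } else if (!is.null(names(groups))) {
    setNames(as.character(groups), names(groups))
  } else {
    abort("`groups` must be a data frame or a named vector.")
  }
}

# Vectorised exact two-sided rank-sum (Mann-Whitney) test by matrix row.
# x, y: matrices with equal row count (features x samples). Average ranks
# on ties; exact null from pwilcox (valid without ties, which only arise
# here from beta clipping at the [0,1] bounds).
row_ranksum <- function(x, y) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  stat <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    r <- rank(c(x[i, ], y[i, ]))
    stat[i] <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  }
  lo <- pwilcox(floor(stat), n1, n2)
  hi <- pwilcox(n1 * n2 - ceiling(stat), n1, n2)
  p <- pmin(1, 2 * pmin(lo, hi))
  list(statistic = stat, p = p)
}

# Vectorised Welch two-sample t-test by matrix row; returns statistic, df, p.
row_welch <- function(x, y) {
  n1 <- ncol(x)
  n2 <- ncol(y)
  m1 <- rowMeans(x)
  m2 <- rowMeans(y)
  v1 <- apply(x, 1, var)
  v2 <- apply(y, 1, var)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  zero <- se2 == 0
  stat[zero] <- 0
  df[zero] <- n1 + n2 - 2
  p <- 2 * pt(-abs(stat), df)
  list(statistic = stat, df = df, p = p)
}
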