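#' Convert raw counts to transcripts per million
#'
#' Per sample, each gene's count is divided by its length in base pairs, and
#' the resulting rates are rescaled to sum to one million:
#' TPM_g = 1e6 * (count_g / length_g) / sum_h (count_h / length_h).
#'
#' @param counts Genes x samples matrix of non-negative counts.
#' @param lengths Numeric vector of gene lengths in bp, named by gene or in
#'   row order of `counts`.
#' @return A TPM matrix of the same shape; every column sums to 1e6.
#' @examples
#' m <- matrix(c(10, 10), ncol = 1, dimnames = list(c("a", "b"), "s1"))
#' tpm_from_counts(m, c(a = 1000, b = 2000))
#' @export
tpm_from_counts <- function(counts, lengths) {
  counts <- check_matrix(counts, "counts")
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts)) {
    stop("need one gene length per row of the count matrix", call. = FALSE)
  }
  expressed <- rowSums(counts) > 0
  if (any(expressed & (is.na(lengths) | lengths <= 0))) {
    stop("non-positive or missing length for expressed gene(s): ",
         paste(head(rownames(counts)[expressed & (is.na(lengths) | lengths <= 0)], 5),
               collapse = ", "), call. = FALSE)
  }
  lengths[is.na(lengths) | lengths <= 0] <- 1  # only all-zero genes reach this
  zero_samples <- colSums(counts) == 0
  if (any(zero_samples)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero_samples], collapse = ", "), call. = FALSE)
  }
  rate <- counts / lengths
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Log2-transform an expression matrix unless it already is on log scale
#'
#' Applies log2(x + offset) elementwise. Deposited matrices are often already
#' log scale; the heuristic used here skips the transform when the matrix
#' maximum is at most `logged_threshold` (linear-scale intensities and TPMs
#' exceed it, log-scale data do not).
#'
#' @param x Genes x samples numeric matrix.
#' @param offset Pseudo-value added before the log; default 1. With offset 0
#'   all values must be strictly positive.
#' @param logged_threshold Maximum value at or below which the matrix is
#'   treated as already logged; default 50.
#' @return The transformed (or untouched) matrix with attribute
#'   `already_logged` recording whether the heuristic fired.
#' @export
log_transform <- function(x, offset = 1, logged_threshold = 50) {
  x <- check_matrix(x)
  stopifnot(offset >= 0)
  if (max(x, na.rm = TRUE) <= logged_threshold) {
    message("matrix maximum <= ", logged_threshold,
            "; treated as already log-scale, no transform applied")
    attr(x, "already_logged") <- TRUE
    return(x)
  }
  if (offset == 0 && any(x <= 0, na.rm = TRUE)) {
    stop("non-positive values with offset 0; supply a positive offset",
         call. = FALSE)
  }
  out <- log2(x + offset)
  attr(out, "already_logged") <- FALSE
  out
}

#' Quantile-normalize samples of an expression matrix
#'
#' Forces every sample (column) to share the same distribution: each column's
#' sorted values are replaced by the cross-sample mean of sorted values. Tied
#' values within a column receive the mean of the reference values their
#' positions span.
#'
#' @param x Genes x samples numeric matrix, at least two samples.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(x) {
  x <- check_matrix(x)
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples", call. = FALSE)
  sorted <- apply(x, 2, sort)
  reference <- rowMeans(sorted)
  out <- apply(x, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- reference
    # tied values share the mean of the reference values their positions span
    stats::ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  out
}

#' Remove outlier samples by hierarchical clustering
#'
#' Samples are clustered by average-linkage on Euclidean distance; the tree
#' is cut at `cut_height` and only the largest resulting cluster is retained,
#' automating the per-experiment manual outlier cut of the standard WGCNA
#' protocol. If removal leaves six or fewer samples, the experiment fails the
#' more-than-six-samples inclusion rule and is marked excluded.
#'
#' @param x Genes x samples matrix, at least three samples.
#' @param cut_height Height at which the sample dendrogram is cut.
#' @return A list with `matrix` (retained samples), `removed` (sample names),
#'   and `excluded` (TRUE when <= 6 samples survive).
#' @export
remove_outlier_samples <- function(x, cut_height) {
  x <- check_matrix(x)
  stopifnot(cut_height > 0)
  if (ncol(x) < 3) stop("outlier detection needs >= 3 samples", call. = FALSE)
  tree <- hclust(dist(t(x)), method = "average")
  if (cut_height >= max(tree$height)) {
    cl <- rep(1L, ncol(x))
  } else {
    cl <- cutree(tree, h = cut_height)
  }
  sizes <- table(cl)
  keep_cluster <- as.integer(names(sizes)[which.max(sizes)])
  keep <- cl == keep_cluster
  removed <- colnames(x)[!keep]
  kept <- x[, keep, drop = FALSE]
  excluded <- ncol(kept) <= 6
  if (excluded) {
    warning("only ", ncol(kept), " samples retained; experiment fails the ",
            "more-than-six-samples inclusion rule", call. = FALSE)
  }
  list(matrix = kept, removed = removed, excluded = excluded)
}

#' Filter genes with low expression
#'
#' Keeps genes whose value is at least `min_value` in at least `min_fraction`
#' of samples; the low-count filter applied before network construction on
#' count-based platforms.
#'
#' @param x Genes x samples matrix.
#' @param min_value Expression threshold; 0 keeps everything.
#' @param min_fraction Required fraction of samples meeting the threshold.
#' @return The filtered matrix.
#' @export
filter_low_expression <- function(x, min_value = 1, min_fraction = 0.5) {
  x <- check_matrix(x)
  stopifnot(min_value >= 0, min_fraction >= 0, min_fraction <= 1)
  keep <- rowMeans(x >= min_value) >= min_fraction
  if (!any(keep)) stop("no genes survive the low-expression filter", call. = FALSE)
  x[keep, , drop = FALSE]
}

#' Read / write genes-by-samples TSV
#'
#' The exchange format: first column the gene identifier, remaining columns
#' one per sample, header row of sample IDs.
#'
#' @param path File path.
#' @return `read_expression_tsv` returns a numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' @rdname read_expression_tsv
#' @param x Genes x samples matrix.
#' @export
write_expression_tsv <- function(x, path) {
  x <- check_matrix(x)
  df <- tibble::as_tibble(x, rownames = "gene")
  readr::write_tsv(df, path)
  invisible(path)
}
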