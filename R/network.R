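#' Pearson correlation matrix across genes
#'
#' Correlates every pair of gene expression profiles across samples, the
#' substrate of the weighted co-expression network. Constant genes have an
#' undefined correlation and are dropped with a warning before computing.
#'
#' @param x Genes x samples numeric matrix with at least 3 samples.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  x <- check_matrix(x)
  if (ncol(x) < 3) stop("correlation needs >= 3 samples", call. = FALSE)
  constant <- apply(x, 1, sd) == 0
  if (any(constant)) {
    warning("dropping ", sum(constant), " constant gene(s): ",
            paste(head(rownames(x)[constant], 5), collapse = ", "),
            call. = FALSE)
    x <- x[!constant, , drop = FALSE]
  }
  cor(t(x))
}

#' Unsigned weighted adjacency
#'
#' Raises absolute correlations to the soft-threshold power:
#' a_ij = |cor_ij|^beta, with unit diagonal. The unsigned form keeps both
#' positively and negatively correlated gene pairs connected.
#'
#' @param cor_mat Genes x genes correlation matrix.
#' @param power Positive integer soft-threshold exponent (beta).
#' @return Adjacency matrix with entries in \[0, 1\].
#' @export
adjacency_matrix <- function(cor_mat, power) {
  stopifnot(is.matrix(cor_mat), power >= 1, power == as.integer(power))
  a <- abs(cor_mat)^power
  diag(a) <- 1
  a
}

#' Soft connectivity
#'
#' Per-gene sum of adjacencies to all other genes, k_i = sum_{j != i} a_ij.
#' The most connected genes of a module are its hub genes.
#'
#' @param adj Adjacency matrix.
#' @return Named numeric vector of connectivities.
#' @export
soft_connectivity <- function(adj) {
  stopifnot(is.matrix(adj))
  rowSums(adj) - diag(adj)
}

#' Topological overlap matrix
#'
#' Scores each gene pair by how similarly they connect to the rest of the
#' network: TOM_ij = (sum_{u != i,j} a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij), with unit diagonal. High overlap means two
#' genes correlate in the same fashion, in direction and magnitude, with the
#' other genes.
#'
#' @param adj Symmetric adjacency matrix, entries in \[0, 1\].
#' @return TOM matrix, symmetric, entries in \[0, 1\], diagonal 1.
#' @export
topological_overlap <- function(adj) {
  stopifnot(is.matrix(adj), isTRUE(all.equal(adj, t(adj), tolerance = 1e-8)))
  a0 <- adj
  diag(a0) <- 0
  k <- rowSums(a0)
  shared <- a0 %*% a0              # sum_u a_iu a_uj over u != i, j handled below
  kmin <- outer(k, k, pmin)
  tom <- (shared + a0) / (kmin + 1 - a0)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adj)
  tom
}

# scale-free topology fit for one connectivity vector: bin k, regress
# log10 p(k) on log10 mean(k). Equal-width binning over the k range, empty
# bins dropped; signed R^2 convention (negative slope required for a
# scale-free call) as in the standard soft-threshold diagnostics.
scale_free_fit_stats <- function(k, nbins = 10) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(k)) == 0) {
    return(list(r_squared = NA_real_, slope = NA_real_, nbins_used = 0L))
  }
  breaks <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tapply(k, bin, length)
  mean_k <- tapply(k, bin, mean)
  ok <- !is.na(counts) & counts > 0
  counts <- counts[ok]
  mean_k <- mean_k[ok]
  if (length(counts) < 3) {
    return(list(r_squared = NA_real_, slope = NA_real_,
                nbins_used = length(counts)))
  }
  p_k <- counts / sum(counts)
  fit <- lm(log10(p_k) ~ log10(mean_k))
  list(
    r_squared = summary(fit)$r.squared,
    slope = unname(stats::coef(fit)[2]),
    nbins_used = length(counts)
  )
}

#' Choose the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency is formed, connectivities
#' are binned, and the fraction of genes per connectivity bin is regressed on
#' mean connectivity in log10-log10 space. A scale-free network has
#' p(k) proportional to k^-gamma, i.e. a straight line of negative slope;
#' the chosen power is the smallest candidate whose fit reaches `target_r2`
#' with a negative slope. When no candidate qualifies the R^2-maximizing
#' power is returned with `scale_free = FALSE`, the signal that an experiment
#' should be skipped ("no modules found").
#'
#' @param cor_mat Genes x genes correlation matrix (>= 30 genes advised).
#' @param candidates Integer powers to try.
#' @param target_r2 Required fit R^2; default 0.80.
#' @param nbins Number of connectivity bins for the fit.
#' @return An object of class `scale_free_fit`: a list with `fits` (tibble of
#'   per-power R^2 and slope), `power`, `scale_free`, `target_r2`.
#' @export
pick_soft_power <- function(cor_mat, candidates = 1:20, target_r2 = 0.80,
                            nbins = 10) {
  stopifnot(is.matrix(cor_mat))
  if (nrow(cor_mat) < 30) {
    warning("fewer than 30 genes; the degree distribution is hardly meaningful",
            call. = FALSE)
  }
  abs_cor <- abs(cor_mat)
  diag(abs_cor) <- 0
  fits <- purrr::map_dfr(candidates, function(beta) {
    k <- rowSums(abs_cor^beta)
    s <- scale_free_fit_stats(k, nbins = nbins)
    tibble::tibble(power = beta, r_squared = s$r_squared, slope = s$slope,
                   nbins_used = s$nbins_used)
  })
  qualifies <- !is.na(fits$r_squared) & fits$r_squared >= target_r2 &
    !is.na(fits$slope) & fits$slope < 0
  if (any(qualifies)) {
    power <- fits$power[which(qualifies)[1]]
    scale_free <- TRUE
  } else if (all(is.na(fits$r_squared))) {
    power <- candidates[1]
    scale_free <- FALSE
  } else {
    power <- fits$power[which.max(fits$r_squared)]
    scale_free <- FALSE
  }
  structure(
    list(fits = fits, power = power, scale_free = scale_free,
         target_r2 = target_r2, nbins = nbins),
    class = "scale_free_fit"
  )
}

#' @export
print.scale_free_fit <- function(x, ...) {
  cat("<scale_free_fit> chosen power:", x$power,
      if (x$scale_free) "(scale-free)" else "(NOT scale-free)", "\n")
  row <- x$fits[x$fits$power == x$power, ]
  cat("  R^2 =", signif(row$r_squared, 3), " slope =", signif(row$slope, 3),
      " target R^2 =", x$target_r2, "\n")
  invisible(x)
}

#' @method tidy scale_free_fit
#' @export
tidy.scale_free_fit <- function(x, ...) x$fits

#' @rdname pick_soft_power
#' @param object A `scale_free_fit`.
#' @param ... Unused.
#' @method autoplot scale_free_fit
#' @export
autoplot.scale_free_fit <- function(object, ...) {
  ggplot2::ggplot(object$fits,
                  ggplot2::aes(x = .data$power, y = .data$r_squared)) +
    ggplot2::geom_hline(yintercept = object$target_r2, linetype = "dashed") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$power == object$power),
                        show.legend = FALSE) +
    ggplot2::labs(x = "soft-threshold power", y = "scale-free fit R²") +
    ggplot2::theme_minimal()
}

#' Detect co-expression modules from a TOM
#'
#' Genes are clustered by average linkage on the dissimilarity 1 - TOM and
#' the dendrogram is cut adaptively: candidate cut heights are scanned and
#' the height yielding the most clusters of at least `min_module_size` genes
#' is kept (ties resolved toward the lower, finer cut). Clusters below the
#' minimum size are pooled into the unassigned label 0. Module labels are
#' integers ordered by decreasing module size.
#'
#' @param tom TOM matrix.
#' @param min_module_size Smallest admissible module; default 30.
#' @return Named integer vector of module labels (0 = unassigned).
#' @export
detect_modules <- function(tom, min_module_size = 30) {
  stopifnot(is.matrix(tom))
  genes <- rownames(tom) %||% paste0("g", seq_len(nrow(tom)))
  n <- nrow(tom)
  if (n < min_module_size) {
    warning("fewer genes than the minimum module size; all unassigned",
            call. = FALSE)
    return(setNames(rep(0L, n), genes))
  }
  diss <- 1 - tom
  tree <- hclust(stats::as.dist(diss), method = "average")
  heights <- sort(unique(tree$height))
  # collapse numerically tied merge heights so candidate cuts never fall
  # inside a block of simultaneous merges
  if (length(heights) > 1) {
    tol <- 1e-8 * max(1, max(heights))
    heights <- heights[c(TRUE, diff(heights) > tol)]
  }
  # midpoints between successive merge heights are the distinct cuts
  cuts <- if (length(heights) > 1) {
    (heights[-1] + heights[-length(heights)]) / 2
  } else {
    heights / 2
  }
  cuts <- c(cuts, max(heights) * 1.01 + 1e-12)  # allow the one-cluster cut
  best <- NULL
  best_big <- 0
  for (h in cuts) {
    cl <- cutree(tree, h = h)
    n_big <- sum(table(cl) >= min_module_size)
    if (n_big > best_big) {
      best_big <- n_big
      best <- cl
    }
  }
  if (is.null(best) || best_big == 0) {
    return(setNames(rep(0L, n), genes))
  }
  sizes <- table(best)
  big <- as.integer(names(sizes)[sizes >= min_module_size])
  # order surviving clusters by decreasing size, ties by first-gene position
  ord <- order(-sizes[as.character(big)],
               vapply(big, function(b) which(best == b)[1], integer(1)))
  big <- big[ord]
  labels <- setNames(rep(0L, n), genes)
  for (i in seq_along(big)) labels[best == big[i]] <- i
  labels
}

#' Module eigengene
#'
#' The first principal component, across samples, of the gene-standardized
#' module submatrix: a per-sample summary profile that best represents the
#' module's expression pattern. The eigengene has unit norm and is oriented
#' to correlate positively with the module's mean standardized expression.
#'
#' @param x Genes x samples expression matrix.
#' @param genes Character vector of the module's gene IDs (>= 2).
#' @return A list of class `eigengene_profile` with `eigengene` (named,
#'   unit-norm, one value per sample), `var_explained`, and `flipped`
#'   (whether the orientation rule reversed the raw singular vector).
#' @export
module_eigengene <- function(x, genes) {
  x <- check_matrix(x)
  stopifnot(length(genes) >= 2, ncol(x) >= 3)
  missing_genes <- setdiff(genes, rownames(x))
  if (length(missing_genes) > 0) {
    stop("module genes absent from the matrix: ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  sub <- x[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    stop("module contains constant gene(s); eigengene undefined", call. = FALSE)
  }
  z <- (sub - rowMeans(sub)) / sds
  sv <- svd(z, nu = 0, nv = 1)
  eig <- sv$v[, 1]
  flipped <- FALSE
  avg <- colMeans(z)
  orient <- sum(eig * avg)
  if (orient < 0 || (orient == 0 && eig[which(eig != 0)[1]] < 0)) {
    eig <- -eig
    flipped <- TRUE
  }
  var_explained <- sv$d[1]^2 / sum(sv$d^2)
  structure(
    list(eigengene = setNames(eig, colnames(x)),
         var_explained = var_explained, flipped = flipped,
         n_genes = length(genes)),
    class = "eigengene_profile"
  )
}

#' @export
print.eigengene_profile <- function(x, ...) {
  cat("<eigengene_profile>", x$n_genes, "genes,",
      length(x$eigengene), "samples, variance explained",
      signif(x$var_explained, 3), "\n")
  invisible(x)
}

#' Module membership (kME)
#'
#' Signed Pearson correlation of every gene's expression with a module
#' eigengene. Genes correlating most strongly with the eigengene are the
#' module-membership gene list; the correlation is taken to the eigengene,
#' not to the health phenotype score.
#'
#' @param x Genes x samples matrix.
#' @param eigengene An `eigengene_profile` or a numeric per-sample vector.
#' @return Named numeric vector of kME values (NA for constant genes).
#' @export
module_membership <- function(x, eigengene) {
  x <- check_matrix(x)
  e <- if (inherits(eigengene, "eigengene_profile")) eigengene$eigengene else eigengene
  stopifnot(length(e) == ncol(x))
  sds <- apply(x, 1, sd)
  kme <- rep(NA_real_, nrow(x))
  ok <- sds > 0
  kme[ok] <- as.numeric(cor(t(x[ok, , drop = FALSE]), e))
  setNames(kme, rownames(x))
}

#' Build a weighted co-expression network
#'
#' One call from expression matrix to fitted network: correlation, automated
#' (or fixed) soft-threshold power, adjacency, topological overlap, adaptive
#' module detection, per-module eigengenes, soft connectivity and kME.
#'
#' @param x Genes x samples expression matrix (preprocessed).
#' @param power Fixed soft-threshold power; `NULL` (default) selects it by
#'   scale-free fit via [pick_soft_power()].
#' @param candidates,target_r2,nbins Passed to [pick_soft_power()].
#' @param min_module_size Minimum module size; default 30.
#' @param min_interaction Minimum interaction score used when exporting the
#'   network edge list; default 0.2.
#' @return An object of class `coexpression_network` with components
#'   `genes`, `correlation`, `power`, `scale_free_fit`, `scale_free`,
#'   `adjacency`, `tom`, `modules` (named integer vector), `eigengenes`
#'   (list of `eigengene_profile` keyed by module label), `connectivity`,
#'   `kme` (genes x modules matrix), `min_interaction`.
#' @export
build_network <- function(x, power = NULL, candidates = 1:20, target_r2 = 0.80,
                          nbins = 10, min_module_size = 30,
                          min_interaction = 0.2) {
  x <- check_matrix(x)
  cm <- correlation_matrix(x)
  x <- x[rownames(cm), , drop = FALSE]  # constant genes were dropped
  fit <- NULL
  scale_free <- TRUE
  if (is.null(power)) {
    fit <- pick_soft_power(cm, candidates = candidates, target_r2 = target_r2,
                           nbins = nbins)
    power <- fit$power
    scale_free <- fit$scale_free
  }
  adj <- adjacency_matrix(cm, power)
  tom <- topological_overlap(adj)
  modules <- detect_modules(tom, min_module_size = min_module_size)
  labels <- sort(unique(modules[modules > 0]))
  eigengenes <- lapply(labels, function(m) {
    module_eigengene(x, names(modules)[modules == m])
  })
  names(eigengenes) <- as.character(labels)
  kme <- if (length(labels) > 0) {
    do.call(cbind, lapply(eigengenes, function(e) module_membership(x, e)))
  } else {
    matrix(numeric(0), nrow = nrow(x), ncol = 0,
           dimnames = list(rownames(x), NULL))
  }
  structure(
    list(genes = rownames(cm), expression = x, correlation = cm, power = power,
         scale_free_fit = fit, scale_free = scale_free, adjacency = adj,
         tom = tom, modules = modules, eigengenes = eigengenes,
         connectivity = soft_connectivity(adj), kme = kme,
         min_module_size = min_module_size, min_interaction = min_interaction),
    class = "coexpression_network"
  )
}

#' @export
print.coexpression_network <- function(x, ...) {
  n_mod <- length(x$eigengenes)
  cat("<coexpression_network>", length(x$genes), "genes,",
      ncol(x$expression), "samples\n")
  cat("  power:", x$power,
      if (x$scale_free) "(scale-free)" else "(NOT scale-free)", "\n")
  cat("  modules:", n_mod, "assigned,",
      sum(x$modules == 0), "unassigned genes\n")
  invisible(x)
}

#' Tidy a fitted co-expression network
#'
#' @param x A `coexpression_network`.
#' @param ... Unused.
#' @return A tibble with one row per gene: module label, soft connectivity,
#'   and kME to the gene's own module (NA for unassigned genes).
#' @method tidy coexpression_network
#' @export
tidy.coexpression_network <- function(x, ...) {
  own_kme <- vapply(seq_along(x$genes), function(i) {
    m <- x$modules[i]
    if (m == 0 || ncol(x$kme) == 0) NA_real_ else x$kme[i, as.character(m)]
  }, numeric(1))
  tibble::tibble(
    gene = x$genes,
    module = unname(x$modules),
    connectivity = unname(x$connectivity),
    kme = own_kme
  )
}

#' @rdname tidy.coexpression_network
#' @return `glance()` returns a one-row tibble summarizing the fit: gene and
#'   sample counts, chosen power, scale-free flag and fit R^2, module count,
#'   unassigned count.
#' @method glance coexpression_network
#' @export
glance.coexpression_network <- function(x, ...) {
  r2 <- if (!is.null(x$scale_free_fit)) {
    f <- x$scale_free_fit
    f$fits$r_squared[f$fits$power == f$power]
  } else {
    NA_real_
  }
  tibble::tibble(
    n_genes = length(x$genes),
    n_samples = ncol(x$expression),
    power = x$power,
    scale_free = x$scale_free,
    fit_r_squared = r2,
    n_modules = length(x$eigengenes),
    n_unassigned = sum(x$modules == 0)
  )
}

#' Plot module sizes of a fitted network
#'
#' @param object A `coexpression_network`.
#' @param ... Unused.
#' @method autoplot coexpression_network
#' @export
autoplot.coexpression_network <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::count(.data$module) |>
    dplyr::mutate(module = factor(.data$module))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "module (0 = unassigned)", y = "genes") +
    ggplot2::theme_minimal()
}

#' Export the thresholded edge list of a network
#'
#' All gene pairs whose interaction score passes the minimum (default 0.2).
#' The score is the topological overlap by default; set `basis = "adjacency"`
#' to threshold the powered correlation instead.
#'
#' @param network A `coexpression_network`.
#' @param min_score Minimum interaction score; defaults to the network's
#'   `min_interaction`.
#' @param basis `"tom"` (default) or `"adjacency"`.
#' @return Tibble with `gene_a`, `gene_b`, `adjacency`, `tom`.
#' @export
network_edges <- function(network, min_score = NULL, basis = c("tom", "adjacency")) {
  stopifnot(inherits(network, "coexpression_network"))
  basis <- match.arg(basis)
  min_score <- min_score %||% network$min_interaction
  score <- if (basis == "tom") network$tom else network$adjacency
  ut <- upper.tri(score)
  keep <- ut & score >= min_score
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(
    gene_a = network$genes[idx[, 1]],
    gene_b = network$genes[idx[, 2]],
    adjacency = network$adjacency[keep],
    tom = network$tom[keep]
  ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}
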