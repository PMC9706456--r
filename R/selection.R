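#' Correlate module eigengenes with the health phenotype score
#'
#' For every module eigengene, the Pearson correlation with the per-sample
#' health score and its two-sided p-value from the Student-t transform
#' (t = r * sqrt(n-2) / sqrt(1-r^2), df = n-2). Modules with p < alpha are
#' flagged health-associated and retained downstream; the filter uses raw
#' p-values by default, with optional Benjamini-Hochberg adjustment.
#'
#' @param network A `coexpression_network`.
#' @param phenotype Tibble from [score_samples()] (columns `sample_id`,
#'   `score`) or a named numeric vector over the network's samples.
#' @param alpha Significance threshold; default 0.05.
#' @param adjust Apply Benjamini-Hochberg across modules before flagging;
#'   default FALSE (raw p-value filter).
#' @return Tibble with one row per module: `module`, `size`, `r`, `p_value`,
#'   `flagged`.
#' @export
module_trait_association <- function(network, phenotype, alpha = 0.05,
                                     adjust = FALSE) {
  stopifnot(inherits(network, "coexpression_network"))
  score <- phenotype_as_vector(phenotype, colnames(network$expression))
  if (length(unique(score)) <= 1) {
    stop("phenotype scores are constant (see the scorecard warning); ",
         "eigengene-trait correlation is undefined", call. = FALSE)
  }
  labels <- names(network$eigengenes)
  rows <- purrr::map_dfr(labels, function(m) {
    e <- network$eigengenes[[m]]$eigengene
    ct <- cor_test_t(e, score)
    tibble::tibble(module = as.integer(m),
                   size = sum(network$modules == as.integer(m)),
                   r = ct$r, p_value = ct$p)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(module = integer(), size = integer(), r = numeric(),
                          p_value = numeric(), flagged = logical()))
  }
  p_used <- if (adjust) stats::p.adjust(rows$p_value, "BH") else rows$p_value
  rows$flagged <- p_used < alpha
  rows
}

# two-sided p for a given r at sample size n (t transform, df = n - 2)
cor_test_t_from_r <- function(r, n) {
  2 * pt(-abs(r * sqrt(n - 2) / sqrt(1 - r^2)), df = n - 2)
}

# Pearson r with two-sided p from the t transform; df = n - 2
cor_test_t <- function(x, y) {
  n <- length(x)
  r <- cor(x, y)
  if (abs(r) >= 1) {
    p <- if (n > 2) 0 else 1
  } else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p)
}

phenotype_as_vector <- function(phenotype, sample_ids) {
  if (is.data.frame(phenotype)) {
    stopifnot(all(c("sample_id", "score") %in% names(phenotype)))
    v <- setNames(phenotype$score, phenotype$sample_id)
  } else {
    v <- phenotype
  }
  if (!is.null(names(v))) {
    missing_s <- setdiff(sample_ids, names(v))
    if (length(missing_s) > 0) {
      stop("phenotype lacks scores for sample(s): ",
           paste(head(missing_s, 5), collapse = ", "), call. = FALSE)
    }
    v <- v[sample_ids]
  } else {
    stopifnot(length(v) == length(sample_ids))
  }
  unname(v)
}

#' Top hub genes of a health-associated module
#'
#' The module's genes ranked by soft connectivity, truncated at `cut`
#' (default 30, the hub-gene list). Ties are broken lexicographically by
#' gene ID and recorded in the `tie` column. Only modules flagged by
#' [module_trait_association()] may be ranked.
#'
#' @param network A `coexpression_network`.
#' @param module Integer module label.
#' @param associations Tibble from [module_trait_association()].
#' @param cut List size; default 30.
#' @return Tibble `gene`, `rank`, `score` (connectivity), `basis`, `module`,
#'   `tie`.
#' @export
top_hub_genes <- function(network, module, associations, cut = 30) {
  check_flagged(associations, module)
  genes <- names(network$modules)[network$modules == module]
  k <- network$connectivity[genes]
  ranked_gene_list(genes, k, cut, basis = "hub", module = module)
}

#' Top module-membership genes of a health-associated module
#'
#' The module's genes ranked by |kME| (absolute correlation with the module
#' eigengene), truncated at `cut` (default 30). The signed kME is retained
#' for direction-of-correlation computation.
#'
#' @inheritParams top_hub_genes
#' @return Tibble `gene`, `rank`, `score` (|kME|), `kme` (signed), `basis`,
#'   `module`, `tie`.
#' @export
top_membership_genes <- function(network, module, associations, cut = 30) {
  check_flagged(associations, module)
  genes <- names(network$modules)[network$modules == module]
  kme <- network$kme[genes, as.character(module)]
  out <- ranked_gene_list(genes, abs(kme), cut, basis = "membership",
                          module = module)
  out$kme <- kme[out$gene]
  out
}

check_flagged <- function(associations, module) {
  row <- associations[associations$module == module, ]
  if (nrow(row) == 0) {
    stop("module ", module, " has no trait association record", call. = FALSE)
  }
  if (!row$flagged) {
    stop("module ", module, " is not health-associated (p = ",
         signif(row$p_value, 3), "); ranked lists are only extracted from ",
         "retained modules", call. = FALSE)
  }
  invisible(TRUE)
}

ranked_gene_list <- function(genes, scores, cut, basis, module) {
  scores <- scores[!is.na(scores)]
  genes <- names(scores)
  ord <- order(-scores, genes)
  genes <- genes[ord]
  scores <- scores[ord]
  dup <- duplicated(scores) | duplicated(scores, fromLast = TRUE)
  if (any(dup[seq_len(min(cut, length(dup)))])) {
    message("tie(s) in ", basis, " ranking broken lexicographically")
  }
  n <- min(cut, length(genes))
  tibble::tibble(
    gene = genes[seq_len(n)],
    rank = seq_len(n),
    score = unname(scores[seq_len(n)]),
    basis = basis,
    module = module,
    tie = dup[seq_len(n)]
  )
}

#' Direction of a gene's correlation with the health score
#'
#' A gene's observed direction is the product of the sign of its kME (its
#' correlation with the module eigengene) and the sign of the module's
#' eigengene-trait correlation: a positively loading gene in a negatively
#' health-correlated module is reported as `negative` (the inverted
#' direction), and so on. Zero signs yield `undetermined` and are excluded
#' from cross-experiment aggregation.
#'
#' @param kme_sign Sign(s) of the gene's kME.
#' @param trait_sign Sign(s) of the module-trait correlation.
#' @return Character vector in `positive`, `negative`, `undetermined`.
#' @export
gene_direction <- function(kme_sign, trait_sign) {
  s <- sign(kme_sign) * sign(trait_sign)
  dplyr::case_when(
    s > 0 ~ "positive",
    s < 0 ~ "negative",
    TRUE ~ "undetermined"
  )
}

#' Extract both ranked gene lists for all retained modules
#'
#' Convenience wrapper: runs [module_trait_association()], then for every
#' flagged module extracts the hub list (soft connectivity) and the
#' module-membership list (|kME|), attaching each gene's direction of
#' correlation with the health score.
#'
#' @inheritParams module_trait_association
#' @param cut List size per module; default 30.
#' @return A list with `associations` and `gene_lists` (tibble over all
#'   flagged modules and both bases, with a `direction` column).
#' @export
select_modules <- function(network, phenotype, alpha = 0.05, cut = 30,
                           adjust = FALSE) {
  associations <- module_trait_association(network, phenotype, alpha = alpha,
                                           adjust = adjust)
  flagged <- associations$module[associations$flagged]
  lists <- purrr::map_dfr(flagged, function(m) {
    r_sign <- sign(associations$r[associations$module == m])
    hubs <- top_hub_genes(network, m, associations, cut = cut)
    hubs$kme <- network$kme[hubs$gene, as.character(m)]
    memb <- top_membership_genes(network, m, associations, cut = cut)
    out <- dplyr::bind_rows(hubs, memb)
    out$direction <- gene_direction(out$kme, r_sign)
    out
  })
  if (nrow(lists) == 0) {
    lists <- tibble::tibble(gene = character(), rank = integer(),
                            score = numeric(), basis = character(),
                            module = integer(), tie = logical(),
                            kme = numeric(), direction = character())
  }
  list(associations = associations, gene_lists = lists)
}
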