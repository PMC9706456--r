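#' Quantile table of a permutation sample
#'
#' Linear-interpolation quantiles at the 14 report probabilities
#' 0, 1, 5, 10, 25, 50, 75, 90, 95, 97.5, 99, 99.5, 99.9 and 100 percent.
#'
#' @param samples Numeric vector of sampled statistics.
#' @param probs Probabilities; default the 14-entry layout.
#' @return Tibble with `prob` and `value`.
#' @export
quantile_table <- function(samples,
                           probs = c(0, .01, .05, .10, .25, .50, .75, .90,
                                     .95, .975, .99, .995, .999, 1)) {
  stopifnot(length(samples) > 0)
  tibble::tibble(
    prob = probs,
    value = unname(quantile(samples, probs = probs, type = 7))
  )
}

new_permutation_null <- function(observed, samples, p, n_perm, seed,
                                 statistic) {
  structure(
    list(observed = observed, samples = samples,
         quantiles = quantile_table(samples), p = p, n_perm = n_perm,
         seed = seed, statistic = statistic),
    class = "permutation_null"
  )
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("<permutation_null>", x$statistic, "\n")
  cat("  observed:", x$observed, " permutations:", x$n_perm,
      " empirical p:", format(x$p, digits = 4), "\n")
  qt <- x$quantiles
  cat("  ", paste0(format(qt$prob * 100, trim = TRUE), "%", collapse = "\t"), "\n")
  cat("  ", paste(format(qt$value, trim = TRUE, digits = 4), collapse = "\t"), "\n")
  invisible(x)
}

#' @method tidy permutation_null
#' @export
tidy.permutation_null <- function(x, ...) x$quantiles

#' @method glance permutation_null
#' @export
glance.permutation_null <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, observed = x$observed,
                 n_perm = x$n_perm, p = x$p, seed = x$seed)
}

#' @rdname consensus_count_null
#' @param object A `permutation_null`.
#' @param ... Unused.
#' @method autoplot permutation_null
#' @export
autoplot.permutation_null <- function(object, ...) {
  df <- tibble::tibble(stat = object$samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stat)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = object$statistic, y = "permutations",
                  subtitle = paste0("observed = ", object$observed,
                                    ", empirical p = ",
                                    format(object$p, digits = 3))) +
    ggplot2::theme_minimal()
}

#' Permutation null for the cross-species consensus count
#'
#' Assesses how many consensus genes arise by chance: each permutation
#' replaces every experiment's ranked list with an equal number of genes
#' drawn uniformly (without replacement within a list, independently across
#' lists) from that species' gene universe, maps them through the ortholog
#' table, reruns the consensus intersection, and records the consensus gene
#' count. The empirical p is the fraction of permutations reaching at least
#' the observed count (upper tail); optionally the (b+1)/(n+1) corrected
#' fraction.
#'
#' @param list_sizes Tibble with one row per (experiment, module) list:
#'   columns `experiment`, `species`, `size`.
#' @param universes Named list: species -> character vector of that species'
#'   gene universe.
#' @param orthologs Ortholog tibble (`species`, `gene`, `human_symbol`);
#'   `NULL` treats gene IDs as already-shared symbols.
#' @param observed Observed consensus gene count.
#' @param n_perm Number of permutations; default 10000.
#' @param min_species Species support required for consensus; default 2.
#' @param seed RNG seed.
#' @param corrected Use (b+1)/(n+1) instead of the plain fraction; default
#'   FALSE.
#' @return A `permutation_null` object.
#' @export
consensus_count_null <- function(list_sizes, universes, orthologs = NULL,
                                 observed, n_perm = 10000, min_species = 2,
                                 seed = 1, corrected = FALSE) {
  list_sizes <- tibble::as_tibble(list_sizes)
  stopifnot(all(c("experiment", "species", "size") %in% names(list_sizes)),
            n_perm >= 1)
  for (i in seq_len(nrow(list_sizes))) {
    sp <- list_sizes$species[i]
    if (is.null(universes[[sp]])) {
      stop("no gene universe for species ", sp, call. = FALSE)
    }
    if (list_sizes$size[i] > length(universes[[sp]])) {
      stop("list size ", list_sizes$size[i], " exceeds the ", sp,
           " universe (", length(universes[[sp]]), " genes)", call. = FALSE)
    }
  }
  # precompute symbol lookup per species for speed
  lookup <- lapply(names(universes), function(sp) {
    if (is.null(orthologs)) {
      setNames(as.list(universes[[sp]]), universes[[sp]])
    } else {
      sub <- orthologs[orthologs$species == sp, ]
      split(sub$human_symbol, sub$gene)
    }
  })
  names(lookup) <- names(universes)
  counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      per_species_symbols <- list()
      for (i in seq_len(nrow(list_sizes))) {
        sp <- list_sizes$species[i]
        draw <- sample(universes[[sp]], list_sizes$size[i])
        syms <- unique(unlist(lookup[[sp]][draw], use.names = FALSE))
        per_species_symbols[[sp]] <- c(per_species_symbols[[sp]], syms)
      }
      sym_species <- lapply(per_species_symbols, unique)
      tab <- table(unlist(sym_species, use.names = FALSE))
      sum(tab >= min_species)
    }, numeric(1))
  })
  hits <- sum(counts >= observed)
  p <- if (corrected) (hits + 1) / (n_perm + 1) else hits / n_perm
  new_permutation_null(observed, counts, p, n_perm, seed,
                       statistic = "consensus gene count")
}

#' Degree rank-sum permutation test
#'
#' Tests whether a gene selection is unusually well connected in an external
#' interaction network (e.g. a protein-protein interaction database): all
#' genes in the degree table are ranked ascending by degree (ties get the
#' average rank), the selection's rank sum is computed, and `n_perm` random
#' equal-size selections are drawn. The empirical p is the fraction of
#' random selections with a strictly higher rank sum.
#'
#' @param selection Character vector of gene symbols, all present in the
#'   table.
#' @param degree_table Tibble with `gene` and `degree` (sum of incoming and
#'   outgoing connections), unique genes, degrees >= 0.
#' @param n_perm Number of random selections; default 10000.
#' @param seed RNG seed.
#' @param corrected Use (b+1)/(n+1); default FALSE.
#' @param exhaustive Enumerate every equal-size selection instead of Monte
#'   Carlo sampling; only sensible when `choose(n, m)` is small. The p is
#'   then exact.
#' @return A `permutation_null` object (observed = the selection's rank sum).
#' @export
degree_rank_sum_test <- function(selection, degree_table, n_perm = 10000,
                                 seed = 1, corrected = FALSE,
                                 exhaustive = FALSE) {
  degree_table <- tibble::as_tibble(degree_table)
  stopifnot(all(c("gene", "degree") %in% names(degree_table)),
            !anyDuplicated(degree_table$gene), all(degree_table$degree >= 0))
  missing_genes <- setdiff(selection, degree_table$gene)
  if (length(missing_genes) > 0) {
    stop("selection gene(s) missing from the degree table: ",
         paste(head(missing_genes, 5), collapse = ", "), call. = FALSE)
  }
  ranks <- rank(degree_table$degree, ties.method = "average")
  names(ranks) <- degree_table$gene
  observed <- sum(ranks[selection])
  m <- length(selection)
  if (exhaustive) {
    if (choose(length(ranks), m) > 1e5) {
      stop("too many combinations to enumerate; use Monte Carlo",
           call. = FALSE)
    }
    sums <- utils::combn(ranks, m, sum)
    n_perm <- length(sums)
  } else {
    sums <- with_seed(seed, {
      vapply(seq_len(n_perm), function(b) sum(sample(ranks, m)), numeric(1))
    })
  }
  hits <- sum(sums > observed)
  p <- if (corrected) (hits + 1) / (n_perm + 1) else hits / n_perm
  new_permutation_null(observed, sums, p, n_perm, seed,
                       statistic = "degree rank sum")
}

#' Read a degree table TSV (gene, degree)
#'
#' @param path File path.
#' @export
read_degree_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(gene = readr::col_character(),
                                          degree = readr::col_double()))
}

#' Write a permutation null report
#'
#' Writes the quantile table as TSV in the 14-column one-row layout and the
#' full report (observed statistic, p, seed, quantiles) as JSON.
#'
#' @param x A `permutation_null`.
#' @param quantile_path,json_path Output paths (`NULL` skips).
#' @export
write_null_report <- function(x, quantile_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "permutation_null"))
  if (!is.null(quantile_path)) {
    qt <- x$quantiles
    wide <- setNames(as.data.frame(t(qt$value)),
                     paste0(qt$prob * 100, "%"))
    readr::write_tsv(wide, quantile_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(statistic = x$statistic, observed = x$observed, p = x$p,
           n_perm = x$n_perm, seed = x$seed,
           quantiles = setNames(as.list(x$quantiles$value),
                                paste0(x$quantiles$prob * 100, "%"))),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(x)
}
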