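#' Run the full per-experiment analysis
#'
#' Preprocessing (log transform with already-logged detection, optional
#' quantile normalization, optional outlier-sample removal, low-expression
#' filter on count platforms), health-phenotype scoring, network
#' construction, health-associated module selection, and interaction export
#' at the experiment-wide adjacency quantile. Experiments that fail an
#' inclusion rule come back as exclusion records rather than errors: too
#' few samples, a constant phenotype score, a network that cannot be made
#' scale-free ("no modules found"), or no health-associated module.
#'
#' @param experiment A list with `id`, `species`, `platform`
#'   (`"log-intensity"`/`"counts"`), `expression` (genes x samples matrix)
#'   and `metadata` (tibble with `sample_id` and factor columns), as
#'   produced by [simulate_experiment()] or assembled from TSVs.
#' @param card A [scorecard()]; default the standard card.
#' @param quantile_norm Apply [quantile_normalize()]; default FALSE (data
#'   are used as deposited).
#' @param cut_height Outlier cut height for [remove_outlier_samples()];
#'   `NULL` (default) skips outlier removal.
#' @param low_expr_min,low_expr_fraction Low-expression filter applied to
#'   count platforms before the log transform.
#' @param power,target_r2,min_module_size,min_interaction Passed to
#'   [build_network()].
#' @param alpha Module-trait significance threshold; default 0.05.
#' @param cut Ranked-list size; default 30.
#' @param adjacency_q Quantile for the interaction-export threshold;
#'   default 0.95.
#' @param orthologs Optional ortholog tibble for mapping exported edges to
#'   human symbols.
#' @return An object of class `experiment_bundle` (fields `id`, `species`,
#'   `phenotype`, `network`, `associations`, `gene_lists`, `threshold`,
#'   `edges`, `removed_samples`, `params`) or of class `exclusion_record`
#'   (fields `id`, `species`, `reason`).
#' @export
run_experiment <- function(experiment, card = scorecard(),
                           quantile_norm = FALSE, cut_height = NULL,
                           low_expr_min = 1, low_expr_fraction = 0.5,
                           power = NULL, target_r2 = 0.80,
                           min_module_size = 30, min_interaction = 0.2,
                           alpha = 0.05, cut = 30, adjacency_q = 0.95,
                           orthologs = NULL) {
  stopifnot(is.list(experiment),
            all(c("id", "species", "expression", "metadata") %in%
                  names(experiment)))
  id <- experiment$id
  species <- experiment$species
  x <- check_matrix(experiment$expression)
  if (ncol(x) <= 6) {
    return(exclusion_record(id, species, paste0(
      "only ", ncol(x), " samples; the inclusion rule requires more than six"
    )))
  }
  platform <- experiment$platform %||% "log-intensity"
  if (platform == "counts") {
    x <- filter_low_expression(x, min_value = low_expr_min,
                               min_fraction = low_expr_fraction)
  }
  x <- suppressMessages(log_transform(x))
  if (quantile_norm) x <- quantile_normalize(x)
  removed <- character()
  if (!is.null(cut_height)) {
    pruned <- remove_outlier_samples(x, cut_height)
    removed <- pruned$removed
    if (pruned$excluded) {
      return(exclusion_record(id, species, paste0(
        "outlier removal left ", ncol(pruned$matrix),
        " samples; the inclusion rule requires more than six"
      )))
    }
    x <- pruned$matrix
  }
  metadata <- experiment$metadata[
    experiment$metadata$sample_id %in% colnames(x), , drop = FALSE]
  phenotype <- withCallingHandlers(
    score_samples(metadata, card),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (isTRUE(attr(phenotype, "constant"))) {
    return(exclusion_record(id, species,
                            "constant phenotype score (scorecard warning)"))
  }
  network <- suppressWarnings(suppressMessages(
    build_network(x, power = power, target_r2 = target_r2,
                  min_module_size = min_module_size,
                  min_interaction = min_interaction)
  ))
  if (!network$scale_free) {
    return(exclusion_record(id, species, "no modules found (not scale-free)"))
  }
  selection <- suppressMessages(
    select_modules(network, phenotype, alpha = alpha, cut = cut)
  )
  threshold <- adjacency_threshold(network$adjacency, q = adjacency_q)
  hub_lists <- selection$gene_lists[selection$gene_lists$basis == "hub", ]
  edges <- purrr::map_dfr(unique(hub_lists$module), function(m) {
    export_interactions(
      hub_lists$gene[hub_lists$module == m], network$adjacency, threshold,
      species = species, orthologs = orthologs, experiment = id, module = m
    )
  })
  if (nrow(edges) == 0) edges <- empty_edges()
  structure(
    list(id = id, species = species, phenotype = phenotype,
         network = network, associations = selection$associations,
         gene_lists = selection$gene_lists, threshold = threshold,
         edges = edges, removed_samples = removed,
         params = list(quantile_norm = quantile_norm,
                       cut_height = cut_height, power = network$power,
                       target_r2 = target_r2,
                       min_module_size = min_module_size,
                       min_interaction = min_interaction, alpha = alpha,
                       cut = cut, adjacency_q = adjacency_q)),
    class = "experiment_bundle"
  )
}

exclusion_record <- function(id, species, reason) {
  structure(list(id = id, species = species, reason = reason),
            class = "exclusion_record")
}

#' @export
print.exclusion_record <- function(x, ...) {
  cat("<exclusion_record>", x$id, "-", x$reason, "\n")
  invisible(x)
}

#' @export
print.experiment_bundle <- function(x, ...) {
  cat("<experiment_bundle>", x$id, "(", x$species, ")\n")
  cat("  flagged modules:", sum(x$associations$flagged), "of",
      nrow(x$associations), " edges exported:", nrow(x$edges), "\n")
  invisible(x)
}

#' Run the cross-species meta-study
#'
#' Runs [run_experiment()] over a collection, maps every retained
#' experiment's ranked lists to human symbols, intersects them across
#' species (hub-based and membership-based consensus tables), assembles the
#' consensus hub-and-connector graph, and evaluates both permutation nulls
#' for the observed consensus counts.
#'
#' @param experiments List of experiment objects (see [run_experiment()]),
#'   or a `simulated_collection`.
#' @param orthologs Ortholog tibble; taken from the collection when one is
#'   supplied.
#' @param n_perm Permutations for the consensus-count nulls; default 10000.
#' @param min_species Species support for consensus; default 2.
#' @param seed Seed for the permutation draws.
#' @param ... Passed to [run_experiment()].
#' @return A list of class `meta_study` with `bundles`, `exclusions`,
#'   `consensus_hub`, `consensus_membership`, `graph`, `null_hub`,
#'   `null_membership`, `provenance`.
#' @export
run_meta <- function(experiments, orthologs = NULL, n_perm = 10000,
                     min_species = 2, seed = 1, ...) {
  if (inherits(experiments, "simulated_collection")) {
    orthologs <- orthologs %||% experiments$orthologs
    experiments <- experiments$experiments
  }
  results <- lapply(experiments, run_experiment, orthologs = orthologs, ...)
  bundles <- Filter(function(r) inherits(r, "experiment_bundle"), results)
  exclusions <- Filter(function(r) inherits(r, "exclusion_record"), results)
  species_ok <- unique(vapply(bundles, function(b) b$species, character(1)))
  if (length(bundles) < 2 || length(species_ok) < min_species) {
    warning("fewer than ", min_species, " species with usable experiments; ",
            "meta stage skipped", call. = FALSE)
    return(structure(
      list(bundles = bundles, exclusions = exclusions,
           consensus_hub = empty_consensus(),
           consensus_membership = empty_consensus(), graph = NULL,
           null_hub = NULL, null_membership = NULL,
           provenance = NULL),
      class = "meta_study"
    ))
  }
  mapped <- purrr::map_dfr(bundles, function(b) {
    lists <- b$gene_lists
    if (nrow(lists) == 0) return(NULL)
    if (is.null(orthologs)) {
      lists$human_symbol <- lists$gene
    } else {
      mapping <- map_to_human(lists$gene, b$species, orthologs)$mapped
      lists <- dplyr::inner_join(lists, mapping, by = "gene",
                                 relationship = "many-to-many")
    }
    dplyr::mutate(lists, experiment = b$id, species = b$species)
  })
  consensus_for <- function(basis) {
    sub <- mapped[mapped$basis == basis, , drop = FALSE]
    if (nrow(sub) == 0) return(empty_consensus())
    suppressWarnings(cross_species_consensus(sub, min_species = min_species))
  }
  consensus_hub <- consensus_for("hub")
  consensus_membership <- consensus_for("membership")
  # consensus graph from the thresholded hub-pair edges of all experiments
  all_edges <- purrr::map_dfr(bundles, function(b) b$edges)
  graph <- build_consensus_graph(all_edges, consensus_hub$human_symbol)
  # permutation nulls: same list sizes, same universes, same ortholog map
  universes <- lapply(stats::setNames(species_ok, species_ok), function(sp) {
    unique(unlist(lapply(bundles[vapply(bundles, function(b) b$species,
                                        character(1)) == sp],
                         function(b) b$network$genes), use.names = FALSE))
  })
  null_for <- function(basis, observed) {
    sizes <- mapped[mapped$basis == basis, , drop = FALSE] |>
      dplyr::distinct(.data$experiment, .data$species, .data$module,
                      .data$gene) |>
      dplyr::count(.data$experiment, .data$species, .data$module,
                   name = "size")
    if (nrow(sizes) == 0) return(NULL)
    consensus_count_null(sizes, universes, orthologs = orthologs,
                         observed = observed, n_perm = n_perm,
                         min_species = min_species,
                         seed = stable_seed(seed, basis))
  }
  null_hub <- null_for("hub", nrow(consensus_hub))
  null_membership <- null_for("membership", nrow(consensus_membership))
  structure(
    list(bundles = bundles, exclusions = exclusions,
         consensus_hub = consensus_hub,
         consensus_membership = consensus_membership, graph = graph,
         null_hub = null_hub, null_membership = null_membership,
         provenance = mapped),
    class = "meta_study"
  )
}

#' @export
print.meta_study <- function(x, ...) {
  cat("<meta_study>", length(x$bundles), "experiments analyzed,",
      length(x$exclusions), "excluded\n")
  cat("  hub consensus:", nrow(x$consensus_hub), "genes",
      if (!is.null(x$null_hub)) paste0("(empirical p = ",
                                       format(x$null_hub$p, digits = 3), ")"),
      "\n")
  cat("  membership consensus:", nrow(x$consensus_membership), "genes",
      if (!is.null(x$null_membership)) {
        paste0("(empirical p = ", format(x$null_membership$p, digits = 3), ")")
      },
      "\n")
  invisible(x)
}

#' @method glance meta_study
#' @export
glance.meta_study <- function(x, ...) {
  tibble::tibble(
    n_experiments = length(x$bundles),
    n_excluded = length(x$exclusions),
    n_hub_consensus = nrow(x$consensus_hub),
    n_membership_consensus = nrow(x$consensus_membership),
    p_hub = if (is.null(x$null_hub)) NA_real_ else x$null_hub$p,
    p_membership = if (is.null(x$null_membership)) NA_real_ else
      x$null_membership$p
  )
}

#' Read a study manifest
#'
#' A YAML manifest lists the experiments of a study: each entry has `id`,
#' `species`, `platform`, `expression` (TSV path), `metadata` (TSV path)
#' and optionally `scorecard` (YAML path); top-level keys `orthologs`
#' (TSV path) and `seed`. Paths are resolved relative to the manifest.
#'
#' @param path Manifest YAML path.
#' @return List with `experiments` (loaded experiment objects), `cards`
#'   (scorecards keyed by experiment ID), `orthologs`, `seed`.
#' @export
read_manifest <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- dirname(path)
  resolve <- function(p) if (is.null(p)) NULL else file.path(base, p)
  ids <- vapply(raw$experiments, function(e) e$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate experiment IDs in manifest: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  experiments <- lapply(raw$experiments, function(e) {
    list(id = e$id, species = e$species,
         platform = e$platform %||% "log-intensity",
         expression = read_expression_tsv(resolve(e$expression)),
         metadata = readr::read_tsv(resolve(e$metadata),
                                    show_col_types = FALSE))
  })
  names(experiments) <- ids
  cards <- lapply(raw$experiments, function(e) {
    if (is.null(e$scorecard)) scorecard() else read_scorecard(resolve(e$scorecard))
  })
  names(cards) <- ids
  orthologs <- if (is.null(raw$orthologs)) NULL else
    read_ortholog_tsv(resolve(raw$orthologs))
  list(experiments = experiments, cards = cards, orthologs = orthologs,
       seed = raw$seed %||% 1)
}
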