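#' Map native gene identifiers to human symbols
#'
#' Applies an ortholog table (columns `species`, `gene`, `human_symbol`;
#' many-to-one and one-to-many both permitted) to a set of native gene IDs.
#' Unmapped IDs are reported, not fatal; duplicate symbol hits are collapsed
#' so each human symbol counts once per input list.
#'
#' @param genes Character vector of native gene IDs.
#' @param species Species tag of those genes.
#' @param orthologs Ortholog tibble.
#' @return List with `mapped` (tibble `gene`, `human_symbol`) and `unmapped`
#'   (character).
#' @export
map_to_human <- function(genes, species, orthologs) {
  orthologs <- check_ortholog_map(orthologs)
  sub <- orthologs[orthologs$species == species, ]
  hits <- dplyr::inner_join(tibble::tibble(gene = genes), sub, by = "gene") |>
    dplyr::distinct(.data$gene, .data$human_symbol)
  list(
    mapped = hits[, c("gene", "human_symbol")],
    unmapped = setdiff(genes, hits$gene)
  )
}

check_ortholog_map <- function(orthologs) {
  orthologs <- tibble::as_tibble(orthologs)
  if (nrow(orthologs) == 0) stop("empty ortholog map", call. = FALSE)
  stopifnot(all(c("species", "gene", "human_symbol") %in% names(orthologs)))
  if (any(is.na(orthologs$human_symbol) | orthologs$human_symbol == "")) {
    stop("ortholog map contains empty human symbols", call. = FALSE)
  }
  orthologs
}

#' Cross-species consensus of ranked gene lists
#'
#' After ortholog mapping, a human symbol enters the consensus report iff it
#' appears in ranked lists from at least `min_species` distinct species.
#' The report records the species, the number of supporting experiments,
#' per-experiment directions, the aggregate direction (`positive` or
#' `negative` when all experiments agree, `mixed` otherwise), and the source
#' modules for provenance.
#'
#' @param lists Tibble with one row per (experiment, gene) holding columns
#'   `experiment`, `species`, `module`, `human_symbol`, and optionally
#'   `direction` (`positive`/`negative`/`undetermined`).
#' @param min_species Minimum number of distinct species; default 2.
#' @return Tibble with `human_symbol`, `species` (collapsed, sorted),
#'   `n_species`, `n_experiments`, `direction` (aggregate), `directions`
#'   (per-experiment, collapsed), `provenance` (experiment:module pairs).
#' @export
cross_species_consensus <- function(lists, min_species = 2) {
  lists <- tibble::as_tibble(lists)
  needed <- c("experiment", "species", "human_symbol")
  stopifnot(all(needed %in% names(lists)))
  if (nrow(lists) == 0 || dplyr::n_distinct(lists$species) < min_species) {
    if (dplyr::n_distinct(lists$species) < min_species) {
      warning("fewer than ", min_species,
              " species supplied; consensus is empty", call. = FALSE)
    }
    return(empty_consensus())
  }
  if (!"direction" %in% names(lists)) lists$direction <- "undetermined"
  if (!"module" %in% names(lists)) lists$module <- NA
  lists |>
    dplyr::distinct(.data$experiment, .data$species, .data$module,
                    .data$human_symbol, .data$direction) |>
    dplyr::arrange(.data$species, .data$experiment, .data$module) |>
    dplyr::group_by(.data$human_symbol) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      n_experiments = dplyr::n_distinct(.data$experiment),
      directions = paste(.data$species, .data$direction,
                         sep = ":", collapse = ";"),
      provenance = paste(.data$experiment, .data$module,
                         sep = ":", collapse = ";"),
      direction = aggregate_direction(.data$direction),
      species = paste(sort(unique(.data$species)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::select("human_symbol", "species", "n_species", "n_experiments",
                  "direction", "directions", "provenance") |>
    dplyr::filter(.data$n_species >= min_species) |>
    dplyr::arrange(dplyr::desc(.data$n_species),
                   dplyr::desc(.data$n_experiments), .data$human_symbol)
}

empty_consensus <- function() {
  tibble::tibble(human_symbol = character(), species = character(),
                 n_species = integer(), n_experiments = integer(),
                 direction = character(), directions = character(),
                 provenance = character())
}

# unanimity across determined directions, else "mixed"
aggregate_direction <- function(dirs) {
  d <- unique(dirs[dirs %in% c("positive", "negative")])
  if (length(d) == 1) d else if (length(d) > 1) "mixed" else "undetermined"
}

#' Experiment-wide adjacency threshold
#'
#' The interaction-export threshold of an experiment: the `q` quantile
#' (default 95%) of all off-diagonal adjacency values, each unordered gene
#' pair counted once, using linear interpolation between order statistics.
#'
#' @param adjacency Adjacency matrix or a numeric vector of adjacency values.
#' @param q Quantile probability; default 0.95.
#' @return Scalar threshold.
#' @export
adjacency_threshold <- function(adjacency, q = 0.95) {
  values <- if (is.matrix(adjacency)) upper_values(adjacency) else adjacency
  if (length(values) == 0) stop("no adjacency values", call. = FALSE)
  unname(quantile(values, probs = q, type = 7))
}

#' Export above-threshold interactions among hub genes
#'
#' Keeps, among the pairs of a module's hub genes, those whose adjacency
#' strictly exceeds the experiment-wide threshold, maps both endpoints to
#' human symbols, and drops self-interactions (pairs of probesets or gene
#' copies collapsing to the same human symbol).
#'
#' @param hub_genes Character vector of hub gene IDs (native namespace).
#' @param adjacency The experiment's full adjacency matrix.
#' @param threshold Scalar from [adjacency_threshold()] for the same
#'   experiment.
#' @param species,orthologs Passed to [map_to_human()]; `NULL` keeps native
#'   IDs (identity mapping, e.g. a human experiment).
#' @param experiment,module Provenance labels attached to each edge.
#' @return Tibble `gene_a`, `gene_b` (human symbols, `gene_a < gene_b`),
#'   `adjacency`, `experiment`, `module`.
#' @export
export_interactions <- function(hub_genes, adjacency, threshold,
                                species = NULL, orthologs = NULL,
                                experiment = NA_character_, module = NA) {
  hub_genes <- intersect(hub_genes, rownames(adjacency))
  if (length(hub_genes) < 2) return(empty_edges(experiment, module))
  sub <- adjacency[hub_genes, hub_genes, drop = FALSE]
  idx <- which(upper.tri(sub) & sub > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_edges(experiment, module))
  edges <- tibble::tibble(
    gene_a = hub_genes[idx[, 1]],
    gene_b = hub_genes[idx[, 2]],
    adjacency = sub[cbind(idx[, 1], idx[, 2])]
  )
  if (!is.null(orthologs)) {
    mapping <- map_to_human(hub_genes, species, orthologs)$mapped
    edges <- edges |>
      dplyr::inner_join(mapping, by = c(gene_a = "gene"),
                        relationship = "many-to-many") |>
      dplyr::rename(symbol_a = "human_symbol") |>
      dplyr::inner_join(mapping, by = c(gene_b = "gene"),
                        relationship = "many-to-many") |>
      dplyr::rename(symbol_b = "human_symbol") |>
      dplyr::transmute(gene_a = .data$symbol_a, gene_b = .data$symbol_b,
                       adjacency = .data$adjacency)
  }
  edges |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>  # self-interactions removed
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b),
      gene_a = .data$lo, gene_b = .data$hi
    ) |>
    dplyr::select(-"lo", -"hi") |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(adjacency = max(.data$adjacency), .groups = "drop") |>
    dplyr::mutate(experiment = experiment, module = module) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

empty_edges <- function(experiment = character(), module = integer()) {
  tibble::tibble(gene_a = character(), gene_b = character(),
                 adjacency = numeric(),
                 experiment = rep(experiment, 0), module = rep(module, 0))
}

#' Read / write an ortholog map TSV
#'
#' Columns: `species`, `gene` (native ID), `human_symbol`.
#'
#' @param path File path.
#' @export
read_ortholog_tsv <- function(path) {
  check_ortholog_map(readr::read_tsv(path, show_col_types = FALSE))
}

#' @rdname read_ortholog_tsv
#' @param orthologs Ortholog tibble.
#' @export
write_ortholog_tsv <- function(orthologs, path) {
  readr::write_tsv(check_ortholog_map(orthologs), path)
  invisible(path)
}
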