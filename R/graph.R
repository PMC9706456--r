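#' Assemble the cross-species consensus graph
#'
#' From threshold-filtered interaction edges and the consensus hub set,
#' builds the hub-and-connector graph: hub-hub edges are kept, and a
#' non-hub gene is retained (as a connector) only when it is adjacent to at
#' least two distinct hub genes. Parallel edges contributed by different
#' experiments are merged keeping the maximum adjacency, with the union of
#' experiments as provenance.
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `adjacency` and optionally
#'   `experiment` (already threshold-filtered, human symbols).
#' @param hubs Character vector of consensus hub symbols.
#' @return A list of class `consensus_graph` with `nodes` (tibble `name`,
#'   `role`) and `edges` (tibble `gene_a`, `gene_b`, `weight`,
#'   `experiments`).
#' @export
build_consensus_graph <- function(edges, hubs) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("gene_a", "gene_b", "adjacency") %in% names(edges)))
  if (!"experiment" %in% names(edges)) edges$experiment <- NA_character_
  merged <- edges |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::filter(.data$lo != .data$hi) |>
    dplyr::group_by(gene_a = .data$lo, gene_b = .data$hi) |>
    dplyr::summarise(
      weight = max(.data$adjacency),
      experiments = paste(sort(unique(.data$experiment)), collapse = ";"),
      .groups = "drop"
    )
  is_hub_a <- merged$gene_a %in% hubs
  is_hub_b <- merged$gene_b %in% hubs
  touching <- merged[is_hub_a | is_hub_b, , drop = FALSE]
  non_hub_partner <- c(touching$gene_a[!touching$gene_a %in% hubs],
                       touching$gene_b[!touching$gene_b %in% hubs])
  hub_partner_count <- touching |>
    dplyr::mutate(connector = ifelse(.data$gene_a %in% hubs,
                                     .data$gene_b, .data$gene_a),
                  hub = ifelse(.data$gene_a %in% hubs,
                               .data$gene_a, .data$gene_b)) |>
    dplyr::filter(!.data$connector %in% hubs) |>
    dplyr::group_by(.data$connector) |>
    dplyr::summarise(n_hubs = dplyr::n_distinct(.data$hub), .groups = "drop")
  connectors <- hub_partner_count$connector[hub_partner_count$n_hubs >= 2]
  keep_nodes <- union(intersect(hubs, c(merged$gene_a, merged$gene_b, hubs)),
                      connectors)
  kept <- merged |>
    dplyr::filter(
      (.data$gene_a %in% hubs & .data$gene_b %in% hubs) |
        (.data$gene_a %in% hubs & .data$gene_b %in% connectors) |
        (.data$gene_b %in% hubs & .data$gene_a %in% connectors)
    ) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  nodes <- tibble::tibble(
    name = sort(unique(c(hubs, connectors))),
    role = ifelse(sort(unique(c(hubs, connectors))) %in% hubs,
                  "hub", "connector")
  )
  structure(list(nodes = nodes, edges = kept), class = "consensus_graph")
}

#' @export
print.consensus_graph <- function(x, ...) {
  cat("<consensus_graph>", sum(x$nodes$role == "hub"), "hubs,",
      sum(x$nodes$role == "connector"), "connectors,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Convert a consensus graph to igraph
#'
#' @param graph A `consensus_graph`.
#' @return An undirected weighted [igraph::igraph] object with `role` and
#'   `experiments` attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "consensus_graph"))
  g <- igraph::graph_from_data_frame(
    d = graph$edges[, c("gene_a", "gene_b", "weight", "experiments")],
    directed = FALSE,
    vertices = graph$nodes
  )
  g
}

#' k-hop neighborhood of seed genes
#'
#' Breadth-first expansion from the seeds to all genes at most `k`
#' transitions away, returning the induced subgraph (all edges among reached
#' genes are kept). With `k = 2` this is the two-hop neighborhood used for
#' per-species network views.
#'
#' @param edges Tibble with `gene_a`, `gene_b` and any extra columns.
#' @param seeds Seed gene names; seeds absent from the edge set are kept as
#'   isolated nodes with a warning.
#' @param k Maximum number of transitions; default 2.
#' @return List with `nodes` (character, includes distances as names-free
#'   tibble `name`, `distance`) and `edges` (induced subset of the input).
#' @export
k_hop_neighborhood <- function(edges, seeds, k = 2) {
  stopifnot(k >= 0)
  edges <- tibble::as_tibble(edges)
  vertices <- unique(c(edges$gene_a, edges$gene_b))
  absent <- setdiff(seeds, vertices)
  if (length(absent) > 0) {
    warning("seed(s) absent from the graph kept isolated: ",
            paste(head(absent, 5), collapse = ", "), call. = FALSE)
  }
  dist <- setNames(rep(Inf, length(vertices)), vertices)
  frontier <- intersect(seeds, vertices)
  dist[frontier] <- 0
  d <- 0
  while (d < k && length(frontier) > 0) {
    nb <- unique(c(edges$gene_b[edges$gene_a %in% frontier],
                   edges$gene_a[edges$gene_b %in% frontier]))
    frontier <- nb[is.infinite(dist[nb])]
    dist[frontier] <- d + 1
    d <- d + 1
  }
  reached <- names(dist)[is.finite(dist)]
  nodes <- tibble::tibble(
    name = c(reached, absent),
    distance = c(unname(dist[reached]), rep(NA_real_, length(absent)))
  ) |>
    dplyr::arrange(.data$distance, .data$name)
  induced <- edges[edges$gene_a %in% reached & edges$gene_b %in% reached, ]
  list(nodes = nodes, edges = induced)
}

#' Spanning-tree simplification of a weighted graph
#'
#' Per connected component, keeps the maximum-weight spanning tree of the
#' adjacency-weighted graph — connectivity is maintained while redundant
#' paths are removed, always retaining the stronger of two alternative
#' paths. Weight ties are broken lexicographically by edge name for
#' determinism. Equivalent to the minimum spanning tree on 1 - weight.
#'
#' @param edges Tibble with `gene_a`, `gene_b`, and a weight column named
#'   `weight` or `adjacency`.
#' @return The retained edges (same columns, `gene_a < gene_b`), a forest
#'   with (nodes - components) edges.
#' @export
spanning_tree_simplify <- function(edges) {
  edges <- tibble::as_tibble(edges)
  wcol <- if ("weight" %in% names(edges)) "weight" else "adjacency"
  stopifnot(wcol %in% names(edges))
  if (nrow(edges) == 0) return(edges)
  canon <- edges |>
    dplyr::mutate(
      lo = pmin(.data$gene_a, .data$gene_b),
      hi = pmax(.data$gene_a, .data$gene_b),
      gene_a = .data$lo, gene_b = .data$hi
    ) |>
    dplyr::select(-"lo", -"hi") |>
    dplyr::filter(.data$gene_a != .data$gene_b) |>
    dplyr::arrange(dplyr::desc(.data[[wcol]]), .data$gene_a, .data$gene_b)
  vertices <- unique(c(canon$gene_a, canon$gene_b))
  parent <- setNames(seq_along(vertices), vertices)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  keep <- logical(nrow(canon))
  for (e in seq_len(nrow(canon))) {
    ra <- find(match(canon$gene_a[e], vertices))
    rb <- find(match(canon$gene_b[e], vertices))
    if (ra != rb) {
      parent[ra] <- rb
      keep[e] <- TRUE
    }
  }
  canon[keep, , drop = FALSE] |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
}

#' Write a consensus graph to GraphML and edge-list TSV
#'
#' @param graph A `consensus_graph`.
#' @param graphml_path,edges_path Output paths (`NULL` skips that format).
#' @return Invisibly, the paths written.
#' @export
write_consensus_graph <- function(graph, graphml_path = NULL,
                                  edges_path = NULL) {
  stopifnot(inherits(graph, "consensus_graph"))
  written <- character()
  if (!is.null(graphml_path)) {
    igraph::write_graph(as_igraph(graph), graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  if (!is.null(edges_path)) {
    readr::write_tsv(graph$edges, edges_path)
    written <- c(written, edges_path)
  }
  invisible(written)
}

#' Plot a consensus graph
#'
#' Deterministic circular layout with hubs and connectors distinguished by
#' shape/colour; a quick visual of the consensus network, not a publication
#' layout.
#'
#' @param x A `consensus_graph`.
#' @param ... Unused.
#' @export
plot_consensus_graph <- function(x, ...) {
  stopifnot(inherits(x, "consensus_graph"))
  n <- nrow(x$nodes)
  theta <- 2 * pi * (seq_len(n) - 1) / max(n, 1)
  layout <- tibble::tibble(name = x$nodes$name, role = x$nodes$role,
                           x = cos(theta), y = sin(theta))
  seg <- x$edges |>
    dplyr::left_join(layout, by = c(gene_a = "name")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::select(-"role") |>
    dplyr::left_join(layout, by = c(gene_b = "name")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, linewidth = .data$weight),
      colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$role), size = 3
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(x = .data$x * 1.12, y = .data$y * 1.12, label = .data$name),
      size = 2.6
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.2), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
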