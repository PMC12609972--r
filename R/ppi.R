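#' Confidence-filter a scored interaction edge list
#'
#' Keeps edges whose confidence score is at least `min_score` (inclusive;
#' the conventional high-confidence cutoff is 0.700). Nodes supplied in
#' `nodes` are retained even if they end up isolated, so degree-0 genes
#' stay visible in the hub report.
#'
#' @param edges A tibble `node1`, `node2`, `score` (see [read_edge_list()]).
#' @param min_score Minimum confidence score, inclusive.
#' @param nodes Optional character vector of all node symbols.
#' @return A list of class `"ppi_graph"` with `edges` (filtered tibble) and
#'   `nodes` (character vector).
#' @export
filter_edges <- function(edges, min_score = 0.700, nodes = NULL) {
  stopifnot(all(c("node1", "node2", "score") %in% names(edges)))
  if (any(edges$node1 == edges$node2)) {
    abort("self-loops are not allowed in a PPI graph")
  }
  all_nodes <- unique(c(edges$node1, edges$node2, nodes))
  kept <- edges[edges$score >= min_score, , drop = FALSE]
  structure(
    list(edges = tibble::as_tibble(kept), nodes = all_nodes,
         min_score = min_score),
    class = "ppi_graph"
  )
}

#' Hub detection on a filtered interaction graph
#'
#' Computes node degrees on the confidence-filtered graph and flags hubs:
#' nodes with degree at or above `min_degree` (default 10). Also reports
#' the connected-component size distribution (isolated retained nodes
#' count as size-1 components).
#'
#' @param graph A `"ppi_graph"` from [filter_edges()], or a raw edge tibble
#'   (then filtered at 0.700 first).
#' @param min_degree Minimum degree for the hub flag, inclusive.
#' @return A list of class `"hub_report"`: `degrees` (tibble `gene`,
#'   `degree`, `is_hub`), `hubs` (character vector), and `components`
#'   (tibble `component`, `size`).
#' @export
find_hubs <- function(graph, min_degree = 10) {
  if (!inherits(graph, "ppi_graph")) graph <- filter_edges(graph)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("node1", "node2")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes)
  )
  deg <- igraph::degree(g)
  comp <- igraph::components(g)
  degrees <- tibble::tibble(
    gene = names(deg),
    degree = as.integer(deg),
    is_hub = as.integer(deg) >= min_degree
  ) %>%
    dplyr::arrange(dplyr::desc(.data$degree), .data$gene)
  structure(
    list(
      degrees = degrees,
      hubs = degrees$gene[degrees$is_hub],
      components = tibble::tibble(
        component = seq_along(comp$csize),
        size = as.integer(comp$csize)
      ),
      min_degree = min_degree
    ),
    class = "hub_report"
  )
}

#' @export
tidy.hub_report <- function(x, ...) x$degrees

#' @export
glance.hub_report <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$degrees),
    n_edges = sum(x$degrees$degree) / 2,
    n_hubs = length(x$hubs),
    n_components = nrow(x$components),
    largest_component = max(x$components$size)
  )
}

#' @export
print.hub_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("PPI hub report: %d nodes, %d edges, %d hub(s) at degree >= %d\n",
              g$n_nodes, g$n_edges, g$n_hubs, x$min_degree))
  if (length(x$hubs) > 0) cat("Hubs:", paste(x$hubs, collapse = ", "), "\n")
  invisible(x)
}

#' @export
autoplot.hub_report <- function(object, ...) {
  ggplot2::ggplot(object$degrees, ggplot2::aes(x = .data$degree)) +
    ggplot2::geom_histogram(binwidth = 1, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = object$min_degree, linetype = "dashed") +
    ggplot2::labs(x = "node degree (filtered graph)", y = "genes") +
    ggplot2::theme_minimal()
}
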