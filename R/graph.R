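#' Build the bipartite expression-methylation correlation graph
#'
#' Nodes are expression and methylation probes; edges are significant probe
#' pairs with `|r| >= r_cut` (the pairs are assumed already
#' significance-filtered, e.g. Bonferroni-passing). Connected components of
#' this graph are the confounding diagnostic: when cell composition drives
#' the correlation structure, most nodes collapse into one giant component.
#'
#' @param pairs Tibble with `expr_probe`, `meth_probe`, `r` (and optionally
#'   `same_chromosome`). Duplicate pair records are dropped with a warning
#'   (first kept).
#' @param r_cut Absolute-correlation edge threshold (default 0.5).
#' @return A `correlation_graph`: list with `nodes` (tibble: `node`, `type`,
#'   `component`; component 1 is the largest, ties broken by smallest node
#'   id), `edges` (retained pairs) and `graph` (the underlying igraph object).
#' @export
build_correlation_graph <- function(pairs, r_cut = 0.5) {
  dup <- duplicated(pairs[, c("expr_probe", "meth_probe")])
  if (any(dup)) {
    warning(sum(dup), " duplicate pair record(s) dropped (first kept)")
    pairs <- pairs[!dup, ]
  }
  edges <- filter(pairs, abs(.data$r) >= r_cut)
  both <- intersect(unique(edges$expr_probe), unique(edges$meth_probe))
  abort_if(length(both) > 0,
           "probe id(s) appear as both expression and methylation nodes")
  g <- igraph::graph_from_data_frame(
    edges[, c("expr_probe", "meth_probe")], directed = FALSE
  )
  type <- ifelse(igraph::V(g)$name %in% edges$expr_probe,
                 "expression", "methylation")
  comp <- igraph::components(g)
  # deterministic ids: order by size descending, ties by smallest member id
  min_node <- tapply(igraph::V(g)$name, comp$membership, min)
  ord <- order(-comp$csize, min_node)
  relabel <- match(seq_along(comp$csize), ord)
  nodes <- tibble(
    node = igraph::V(g)$name, type = type,
    component = relabel[comp$membership]
  ) %>% arrange(.data$component, .data$node)
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "correlation_graph")
}

#' @export
print.correlation_graph <- function(x, ...) {
  cat("<correlation_graph> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges, ", max(c(0, x$nodes$component)), " components\n", sep = "")
  invisible(x)
}

#' Summarise connected components of a correlation graph
#'
#' @param graph A `correlation_graph` from [build_correlation_graph()].
#' @return A list with `n_components`, `largest_size`, `median_rest` (median
#'   size of all but the largest component; `NA` when there is only one) and
#'   `components`, a tibble (`component`, `size`, `n_expression`,
#'   `n_methylation`, and — when the edge table carries a `same_chromosome`
#'   flag — `edges_same_chrom` / `edges_diff_chrom` tallies), ordered by
#'   size descending.
#' @export
component_summary <- function(graph) {
  nodes <- graph$nodes
  if (nrow(nodes) == 0) {
    return(list(n_components = 0L, largest_size = 0L, median_rest = NA_real_,
                components = tibble(component = integer(), size = integer(),
                                    n_expression = integer(),
                                    n_methylation = integer())))
  }
  comp <- nodes %>%
    group_by(.data$component) %>%
    summarise(size = n(),
              n_expression = sum(.data$type == "expression"),
              n_methylation = sum(.data$type == "methylation"),
              .groups = "drop") %>%
    arrange(desc(.data$size), .data$component)
  if ("same_chromosome" %in% names(graph$edges)) {
    ec <- graph$edges %>%
      mutate(component = nodes$component[match(.data$expr_probe, nodes$node)]) %>%
      group_by(.data$component) %>%
      summarise(edges_same_chrom = sum(.data$same_chromosome, na.rm = TRUE),
                edges_diff_chrom = sum(!.data$same_chromosome, na.rm = TRUE),
                .groups = "drop")
    comp <- left_join(comp, ec, by = "component")
  }
  sizes <- comp$size
  list(
    n_components = nrow(comp),
    largest_size = sizes[1],
    median_rest = if (length(sizes) > 1) median(sizes[-1]) else NA_real_,
    components = comp
  )
}

#' Cell-type specificity score of a probe set
#'
#' Operationalizes the "purified samples cluster by cell identity" check:
#' reference samples of purified blood cell types are clustered
#' (average-linkage hierarchical clustering on Euclidean distance) using only
#' the supplied probes, the dendrogram is cut at the number of cell types,
#' and the agreement between the resulting grouping and the true cell
#' identities is returned as the adjusted Rand index (1 = perfect recovery,
#' ~0 = no relation to cell identity).
#'
#' @param probes Character vector of probe ids (e.g. members of a graph
#'   component).
#' @param reference Probes x reference-samples matrix of methylation beta (or
#'   expression) values with probe rownames.
#' @param cell_types Character vector of true cell identities, one per
#'   reference sample.
#' @param n_perm Optional number of label permutations used to build a null
#'   distribution of the score (default 0: none).
#' @return List with `score` (ARI in \[-1, 1\], `NA` when fewer than 2 probes
#'   usable), `n_probes` used, and `null` (permutation scores or `NULL`).
#' @export
celltype_specificity_score <- function(probes, reference, cell_types,
                                       n_perm = 0) {
  use <- intersect(probes, rownames(reference))
  if (length(use) < 2) {
    warning("fewer than 2 usable probes; score undefined")
    return(list(score = NA_real_, n_probes = length(use), null = NULL))
  }
  k <- length(unique(cell_types))
  hc <- hclust(dist(t(reference[use, , drop = FALSE])), method = "average")
  grp <- cutree(hc, k = k)
  score <- mclust::adjustedRandIndex(grp, cell_types)
  null <- NULL
  if (n_perm > 0) {
    null <- vapply(seq_len(n_perm), function(i)
      mclust::adjustedRandIndex(grp, sample(cell_types)), numeric(1))
  }
  list(score = score, n_probes = length(use), null = null)
}

#' Overlap of a probe set with a marker list
#'
#' Intersection size between e.g. the largest graph component and a list of
#' hematopoietic cell-type-specific marker probes.
#'
#' @param probes Character vector of probe ids.
#' @param markers Character vector of marker probe ids.
#' @return Integer intersection size.
#' @export
marker_overlap <- function(probes, markers) {
  length(intersect(unique(probes), unique(markers)))
}
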