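# Simple undirected PPI graph and per-protein integration statistics.
#
# The vertex set is always exactly the genes with at least one retained
# interaction: proteins with no interaction data are not part of the
# analyzed graph (their prevalence is summarized separately as the
# per-group "fraction with interactions").

#' Construct a PPI network
#'
#' @param edges Canonical edge data frame (`gene_a`, `gene_b`, `source`),
#'   e.g. from [read_edge_table()] or [canonicalize_edges()].
#' @param restrict_to Optional character vector of gene ids; only edges
#'   with both endpoints inside it are kept (used by the
#'   exclude-essential / exclude-subtelomeric robustness controls).
#' @param source_filter Optional subset of
#'   `c("small_scale", "high_throughput", "unknown")`; only matching
#'   edges are kept (the high-throughput-only control).
#' @return A `ppi_network`: list with `edges` (canonical data frame) and
#'   `vertices` (sorted ids of all edge endpoints).
#' @export
build_network <- function(edges, restrict_to = NULL, source_filter = NULL) {
  edges <- canonicalize_edges(edges)
  if (!is.null(restrict_to)) {
    keep <- edges$gene_a %in% restrict_to & edges$gene_b %in% restrict_to
    edges <- edges[keep, , drop = FALSE]
  }
  if (!is.null(source_filter)) {
    stopifnot(all(source_filter %in% EDGE_SOURCES))
    edges <- edges[edges$source %in% source_filter, , drop = FALSE]
  }
  rownames(edges) <- NULL
  if (nrow(edges) == 0) {
    warning("network has no edges after filtering", call. = FALSE)
  }
  structure(list(edges = edges,
                 vertices = sort(unique(c(edges$gene_a, edges$gene_b)))),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d vertices, %d edges\n",
              length(x$vertices), nrow(x$edges)))
  invisible(x)
}

#' Convert a ppi_network to an igraph graph
#' @param net A `ppi_network`.
#' @return An undirected simple `igraph` graph.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("gene_a", "gene_b")],
                                directed = FALSE, vertices = net$vertices)
}

#' Iteratively remove sticky proteins
#'
#' Promiscuous ("sticky") proteins with more than `threshold` interactions
#' are removed as presumed experimental artifacts.  Removal is iterative:
#' each round deletes all vertices of the current maximum degree among
#' those exceeding the threshold, then recomputes degrees, so a vertex
#' whose degree falls to `threshold` or below once a bigger hub is gone
#' survives.  This makes the procedure deterministic and independent of
#' vertex order while giving the iteration real work to do.
#'
#' @param net A `ppi_network`.
#' @param threshold Maximum allowed degree (default 50).
#' @return The filtered `ppi_network` (vertices with no remaining edges
#'   are dropped) with attribute `removal_log`: list of per-round removed
#'   id vectors.
#' @export
filter_sticky <- function(net, threshold = 50) {
  edges <- net$edges
  rounds <- list()
  repeat {
    if (nrow(edges) == 0) break
    deg <- table(c(edges$gene_a, edges$gene_b))
    over <- names(deg)[deg > threshold]
    if (length(over) == 0) break
    worst <- names(deg)[deg == max(deg)]
    worst <- intersect(worst, over)
    rounds[[length(rounds) + 1]] <- sort(worst)
    keep <- !(edges$gene_a %in% worst | edges$gene_b %in% worst)
    edges <- edges[keep, , drop = FALSE]
  }
  rownames(edges) <- NULL
  out <- structure(list(edges = edges,
                        vertices = sort(unique(c(edges$gene_a, edges$gene_b)))),
                   class = "ppi_network")
  attr(out, "removal_log") <- rounds
  out
}

#' Degree centrality
#'
#' Number of interaction partners of each protein in the analyzed graph.
#'
#' @param net A `ppi_network`.
#' @return Named integer vector over `net$vertices`.
#' @export
degree_centrality <- function(net) {
  deg <- table(factor(c(net$edges$gene_a, net$edges$gene_b),
                      levels = net$vertices))
  stats::setNames(as.integer(deg), net$vertices)
}

#' Betweenness centrality as a fraction of shortest paths
#'
#' For vertex `v`, the sum over unordered pairs `{s, t}` (both distinct
#' from `v`) of the fraction of shortest s-t paths passing through `v`,
#' divided by the number of such pairs `(n-1)(n-2)/2`.  Disconnected
#' pairs contribute zero; endpoints are excluded from their own paths.
#' Values lie in `[0, 1]`; the star center attains 1.
#'
#' @param net A `ppi_network`.
#' @return Named numeric vector over `net$vertices` (all zero if `n < 3`).
#' @export
betweenness_centrality <- function(net) {
  n <- length(net$vertices)
  if (n < 3) {
    return(stats::setNames(rep(0, n), net$vertices))
  }
  g <- as_igraph(net)
  raw <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  out <- raw[net$vertices] / ((n - 1) * (n - 2) / 2)
  stats::setNames(as.numeric(out), net$vertices)
}

#' Normalize per-gene statistics by protein length
#'
#' A protein's size physically limits how many simultaneous interactions
#' it can maintain, so degree and betweenness are also reported per amino
#' acid.
#'
#' @param values Named numeric vector keyed by gene id.
#' @param catalog A `gene_catalog` supplying `length_aa`.
#' @return `values / length_aa`, same names.
#' @export
normalize_by_length <- function(values, catalog) {
  len <- stats::setNames(catalog$length_aa, catalog$gene_id)[names(values)]
  if (anyNA(len)) {
    stop(sprintf("no length for gene %s", names(values)[which(is.na(len))[1]]),
         call. = FALSE)
  }
  values / len
}

#' Per-group summary of a statistic
#'
#' Mean and standard error of a per-gene statistic within each age/origin
#' group.  Only genes present in both `values` and the classification are
#' used (proteins with no interaction data carry no network statistic).
#'
#' @param values Named numeric vector keyed by gene id.
#' @param classification A `gene_classification`.
#' @return Data frame `age`, `origin`, `group`, `n`, `mean`, `se`, one
#'   row per canonical group; empty groups have `n = 0` and `NA`
#'   mean/se.
#' @export
group_summary <- function(values, classification) {
  groups <- classification_groups(classification)
  common <- intersect(names(values), names(groups))
  g <- factor(groups[common], levels = GROUP_LEVELS)
  v <- values[common]
  n <- as.integer(table(g))
  mu <- as.numeric(tapply(v, g, mean))
  se <- as.numeric(tapply(v, g, function(x) {
    if (length(x) < 2) NA_real_ else stats::sd(x) / sqrt(length(x))
  }))
  parts <- strsplit(GROUP_LEVELS, "/", fixed = TRUE)
  data.frame(age = vapply(parts, `[`, character(1), 1),
             origin = vapply(parts, `[`, character(1), 2),
             group = GROUP_LEVELS, n = n, mean = mu, se = se,
             stringsAsFactors = FALSE)
}

#' Ego subnetwork around a seed set
#'
#' Induced subgraph on the seeds and every vertex within `radius` hops of
#' one, with a connected-component report.  Seeds absent from the network
#' (proteins without interactions) are listed in `missing_seeds` and
#' contribute nothing.
#'
#' @param net A `ppi_network`.
#' @param seeds Character vector of gene ids.
#' @param radius Neighborhood radius (default 1: first-degree neighbors).
#' @param labels Optional named group labels; when given, the component
#'   report counts members per group.
#' @return List with `network` (induced `ppi_network`), `components`
#'   (data frame `component`, `size`, `n_seed`, and per-group counts if
#'   labels were supplied), `missing_seeds`, and `membership` (named
#'   component index per vertex).
#' @export
ego_subnetwork <- function(net, seeds, radius = 1, labels = NULL) {
  present <- intersect(seeds, net$vertices)
  missing <- setdiff(seeds, net$vertices)
  if (length(present) == 0) {
    warning("no seed has interactions; returning empty subnetwork",
            call. = FALSE)
    empty <- suppressWarnings(build_network(net$edges[0, , drop = FALSE]))
    return(list(network = empty,
                components = data.frame(component = integer(0),
                                        size = integer(0),
                                        n_seed = integer(0)),
                missing_seeds = missing, membership = integer(0)))
  }
  g <- as_igraph(net)
  hood <- igraph::ego(g, order = radius, nodes = present)
  verts <- sort(unique(unlist(lapply(hood, function(v) names(v)))))
  keep <- net$edges$gene_a %in% verts & net$edges$gene_b %in% verts
  sub <- build_network(net$edges[keep, , drop = FALSE])
  gs <- as_igraph(sub)
  comp <- igraph::components(gs)
  membership <- comp$membership[sub$vertices]
  by_comp <- split(sub$vertices, membership)
  report <- data.frame(component = as.integer(names(by_comp)),
                       size = vapply(by_comp, length, integer(1)),
                       n_seed = vapply(by_comp, function(v) {
                         sum(v %in% present)
                       }, integer(1)),
                       stringsAsFactors = FALSE)
  if (!is.null(labels)) {
    for (gl in sort(unique(stats::na.omit(labels[sub$vertices])))) {
      report[[gl]] <- vapply(by_comp, function(v) {
        sum(labels[v] == gl, na.rm = TRUE)
      }, integer(1))
    }
  }
  report <- report[order(-report$size), , drop = FALSE]
  rownames(report) <- NULL
  list(network = sub, components = report, missing_seeds = missing,
       membership = membership)
}
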