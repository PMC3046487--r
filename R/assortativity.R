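# Group-pair interaction counts tested against a degree-preserving
# randomized-network null.
#
# The null ensemble is the method: each randomized network keeps every
# vertex's exact degree (stub rewiring with restart on self-loop or
# multi-edge collisions, falling back to a double-edge-swap chain for
# degree sequences where stub matching keeps colliding), so each group's
# degree sum and the global edge total are conserved by construction.

pair_names <- function(groups) {
  G <- length(groups)
  idx <- which(upper.tri(matrix(0, G, G), diag = TRUE), arr.ind = TRUE)
  # order must match the C++ pair index: (0,0),(0,1)...(0,G-1),(1,1),...
  ord <- order(idx[, "row"], idx[, "col"])
  idx <- idx[ord, , drop = FALSE]
  paste(groups[idx[, "row"]], groups[idx[, "col"]], sep = "|")
}

net_to_int <- function(net, labels = NULL) {
  verts <- net$vertices
  ea <- match(net$edges$gene_a, verts) - 1L
  eb <- match(net$edges$gene_b, verts) - 1L
  out <- list(edges = cbind(ea, eb), vertices = verts)
  if (!is.null(labels)) {
    lab <- labels[verts]
    if (anyNA(lab)) {
      stop(sprintf("vertex %s has no group label", verts[which(is.na(lab))[1]]),
           call. = FALSE)
    }
    groups <- sort(unique(lab))
    out$group_codes <- match(lab, groups) - 1L
    out$groups <- groups
  }
  out
}

#' Count interactions within and between groups
#'
#' Each edge increments exactly one unordered group-pair cell; the sum
#' over cells (diagonal counted once) equals the edge total.
#'
#' @param net A `ppi_network`.
#' @param labels Named character vector gene_id -> group label.
#' @param unlabeled `"error"` (default) aborts if a vertex lacks a label;
#'   `"drop"` removes edges touching unlabeled vertices first.
#' @return A symmetric `group_interaction_matrix` (groups x groups; the
#'   diagonal holds within-group counts) with attribute `total`.
#' @export
count_group_interactions <- function(net, labels,
                                     unlabeled = c("error", "drop")) {
  unlabeled <- match.arg(unlabeled)
  if (unlabeled == "drop") {
    ok <- net$vertices[!is.na(labels[net$vertices])]
    keep <- net$edges$gene_a %in% ok & net$edges$gene_b %in% ok
    net <- structure(list(edges = net$edges[keep, , drop = FALSE],
                          vertices = ok), class = "ppi_network")
  }
  z <- net_to_int(net, labels)
  groups <- z$groups
  G <- length(groups)
  M <- matrix(0L, G, G, dimnames = list(groups, groups))
  if (nrow(net$edges) > 0) {
    ga <- z$group_codes[z$edges[, 1] + 1L] + 1L
    gb <- z$group_codes[z$edges[, 2] + 1L] + 1L
    lo <- pmin(ga, gb); hi <- pmax(ga, gb)
    tab <- table(factor(lo + (hi - 1L) * G, levels = seq_len(G * G)))
    M[] <- as.integer(tab)
    M <- M + t(M) - diag(diag(M), G)
  }
  structure(M, class = c("group_interaction_matrix", class(M)),
            total = nrow(net$edges))
}

#' One degree-preserving randomization of a network
#'
#' Every vertex keeps its exact observed degree; edges are randomized by
#' stub rewiring (restarting on collisions), with a double-edge-swap
#' fallback for stubborn degree sequences.  Edge source tags are not
#' meaningful after rewiring and are set to `"unknown"`.
#'
#' @param net A `ppi_network`.
#' @param seed Optional integer seed.
#' @return A `ppi_network` on the same vertices with attribute `method`
#'   (`"stub"`, `"swap"`, or `"swap_incomplete"`).
#' @export
rewire_network <- function(net, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  z <- net_to_int(net)
  res <- .cpp_rewire(z$edges, length(z$vertices))
  em <- res$edges
  edges <- data.frame(gene_a = z$vertices[em[, 1] + 1L],
                      gene_b = z$vertices[em[, 2] + 1L],
                      source = rep("unknown", nrow(em)),
                      stringsAsFactors = FALSE)
  if (identical(res$method, "swap_incomplete")) {
    warning("double-edge-swap fallback did not reach its target swap count; degree sequence may admit few realizations",
            call. = FALSE)
  }
  out <- structure(list(edges = canonicalize_edges(edges),
                        vertices = z$vertices), class = "ppi_network")
  attr(out, "method") <- res$method
  out
}

#' Null ensemble of group-pair interaction counts
#'
#' Draws `n_random` independent degree-preserving randomizations and
#' tallies each by group pair.
#'
#' @param net A `ppi_network`.
#' @param labels Named group labels covering all vertices.
#' @param n_random Number of randomized networks (default 1000).
#' @param seed Optional integer seed; the ensemble is reproducible given
#'   the seed.
#' @return Integer matrix with one row per unordered group pair (rownames
#'   `"a|b"`) and one column per null sample; attribute `methods` records
#'   the rewiring scheme used for each sample.
#' @export
null_ensemble <- function(net, labels, n_random = 1000, seed = NULL) {
  if (n_random < 1) stop("n_random must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  z <- net_to_int(net, labels)
  res <- .cpp_null_group_counts(z$edges, z$group_codes,
                                length(z$vertices), length(z$groups),
                                as.integer(n_random))
  counts <- res$counts
  rownames(counts) <- pair_names(z$groups)
  attr(counts, "methods") <- as.character(res$methods)
  counts
}

#' Empirical p-value from a null ensemble
#'
#' Plain proportion of null samples at least (`tail = "ge"`) or at most
#' (`tail = "le"`) as extreme as the observed count; ties count as
#' extreme.  Can be exactly 0; report alongside the ensemble size if a
#' pseudo-count is wanted.
#'
#' @param observed Observed count.
#' @param null_counts Numeric vector of null counts.
#' @param tail `"ge"` (enrichment) or `"le"` (depletion).
#' @return A probability in `[0, 1]`.
#' @export
empirical_p <- function(observed, null_counts, tail = c("ge", "le")) {
  tail <- match.arg(tail)
  if (length(null_counts) == 0) stop("empty null ensemble", call. = FALSE)
  if (tail == "ge") mean(null_counts >= observed) else mean(null_counts <= observed)
}

#' Glass's Delta effect size against a null ensemble
#'
#' `(observed - mean(nulls)) / sd(nulls)` with the sample (n-1) standard
#' deviation.  A degenerate ensemble (zero spread) yields `NA` with
#' attribute `undefined = TRUE` rather than a silent infinity.
#'
#' @param observed Observed count.
#' @param null_counts Numeric vector with at least 2 values.
#' @return Numeric effect size (possibly flagged-undefined `NA`).
#' @export
glass_delta <- function(observed, null_counts) {
  if (length(null_counts) < 2) {
    stop("Glass's Delta needs at least 2 null values", call. = FALSE)
  }
  s <- stats::sd(null_counts)
  if (s == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  (observed - mean(null_counts)) / s
}

#' Significance calls from two-tailed empirical p-values
#'
#' `p_enrich < alpha` wins over `p_deplete < alpha` (both below alpha is
#' anomalous — typically a near-degenerate null — and is reported via a
#' warning); otherwise neutral.
#'
#' @param results Data frame with columns `p_enrich`, `p_deplete`.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of `"enriched"`, `"depleted"`, `"neutral"`.
#' @export
call_significance <- function(results, alpha = 0.05) {
  both <- results$p_enrich < alpha & results$p_deplete < alpha
  if (any(both)) {
    warning(sprintf("%d group pair(s) significant in both tails; calling enriched",
                    sum(both)), call. = FALSE)
  }
  ifelse(results$p_enrich < alpha, "enriched",
         ifelse(results$p_deplete < alpha, "depleted", "neutral"))
}

#' Test group interaction preferences against the degree-preserving null
#'
#' For every unordered pair of groups, compares the observed number of
#' interactions to its distribution over `n_random` degree-preserving
#' randomized networks: null mean and SD, Glass's Delta, empirical
#' enrichment and depletion p-values, and a significance call.
#'
#' @param net A `ppi_network`.
#' @param labels Named group labels covering all vertices (e.g. from
#'   [classification_groups()]).
#' @param n_random Ensemble size (default 1000).
#' @param seed Optional integer seed.
#' @param alpha Significance level for calls (default 0.05).
#' @return A `group_interaction_result` data frame with columns
#'   `group_a`, `group_b`, `observed`, `null_mean`, `null_sd`,
#'   `glass_delta`, `p_enrich`, `p_deplete`, `call`; attributes
#'   `n_random` and `alpha`.
#' @export
assortativity_test <- function(net, labels, n_random = 1000, seed = NULL,
                               alpha = 0.05) {
  obs_mat <- count_group_interactions(net, labels)
  groups <- rownames(obs_mat)
  nulls <- null_ensemble(net, labels, n_random = n_random, seed = seed)
  pn <- strsplit(rownames(nulls), "|", fixed = TRUE)
  ga <- vapply(pn, `[`, character(1), 1)
  gb <- vapply(pn, `[`, character(1), 2)
  observed <- mapply(function(a, b) obs_mat[a, b], ga, gb)
  delta <- numeric(nrow(nulls))
  undef <- logical(nrow(nulls))
  for (i in seq_len(nrow(nulls))) {
    d <- glass_delta(observed[i], nulls[i, ])
    delta[i] <- as.numeric(d)
    undef[i] <- isTRUE(attr(d, "undefined"))
  }
  res <- data.frame(group_a = ga, group_b = gb,
                    observed = as.integer(observed),
                    null_mean = rowMeans(nulls),
                    null_sd = apply(nulls, 1, stats::sd),
                    glass_delta = delta,
                    delta_undefined = undef,
                    p_enrich = vapply(seq_len(nrow(nulls)), function(i) {
                      empirical_p(observed[i], nulls[i, ], "ge")
                    }, numeric(1)),
                    p_deplete = vapply(seq_len(nrow(nulls)), function(i) {
                      empirical_p(observed[i], nulls[i, ], "le")
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  res$call <- call_significance(res, alpha)
  rownames(res) <- NULL
  class(res) <- c("group_interaction_result", "data.frame")
  attr(res, "n_random") <- n_random
  attr(res, "alpha") <- alpha
  res
}
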