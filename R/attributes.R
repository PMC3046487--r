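# Per-group functional summaries, Mann-Whitney comparisons, and
# hypergeometric term enrichment.

#' Per-group functional attribute table
#'
#' Summarizes each age/origin group by gene count, fraction essential,
#' fraction with at least one molecular-function annotation, fraction of
#' genes present in the interaction network (i.e. with >= 1 interaction,
#' measured on the unfiltered network), protein length quartiles, and —
#' when a per-gene Pfam coverage column is supplied — mean Pfam coverage
#' (mean of per-gene fractions).
#'
#' @param catalog A `gene_catalog`.
#' @param classification A `gene_classification` covering the non-dubious
#'   catalog genes.
#' @param net Optional `ppi_network` used for the fraction-with-
#'   interactions column.
#' @param pfam Optional per-gene coverage: named numeric vector or data
#'   frame `gene_id`, `pfam_coverage` with fractions in `[0, 1]`.
#' @return Data frame, one row per canonical group: `age`, `origin`,
#'   `group`, `n_genes`, `fraction_essential`, `go_mf_coverage`,
#'   `length_median`, `length_q1`, `length_q3`, plus
#'   `fraction_with_interactions` and/or `pfam_coverage` when available.
#' @export
attribute_table <- function(catalog, classification, net = NULL, pfam = NULL) {
  cat_idx <- match(classification$gene_id, catalog$gene_id)
  if (anyNA(cat_idx)) {
    stop("classification contains genes absent from catalog", call. = FALSE)
  }
  g <- factor(classification_groups(classification)[classification$gene_id],
              levels = GROUP_LEVELS)
  ess <- catalog$essential[cat_idx]
  mf <- lengths(catalog$go_function[cat_idx]) > 0
  len <- catalog$length_aa[cat_idx]
  agg <- function(x, f) as.numeric(tapply(x, g, f))
  parts <- strsplit(GROUP_LEVELS, "/", fixed = TRUE)
  out <- data.frame(age = vapply(parts, `[`, character(1), 1),
                    origin = vapply(parts, `[`, character(1), 2),
                    group = GROUP_LEVELS,
                    n_genes = as.integer(table(g)),
                    fraction_essential = agg(ess, mean),
                    go_mf_coverage = agg(mf, mean),
                    length_median = agg(len, stats::median),
                    length_q1 = agg(len, function(x) unname(stats::quantile(x, 0.25))),
                    length_q3 = agg(len, function(x) unname(stats::quantile(x, 0.75))),
                    stringsAsFactors = FALSE)
  if (!is.null(net)) {
    out$fraction_with_interactions <-
      agg(classification$gene_id %in% net$vertices, mean)
  }
  if (!is.null(pfam)) {
    if (is.data.frame(pfam)) {
      pfam <- stats::setNames(pfam$pfam_coverage, pfam$gene_id)
    }
    stopifnot(all(pfam >= 0 & pfam <= 1, na.rm = TRUE))
    out$pfam_coverage <- agg(as.numeric(pfam[classification$gene_id]), function(x) {
      mean(x, na.rm = TRUE)
    })
  }
  out
}

#' Mann-Whitney U test between two samples
#'
#' Rank-sum test for a location difference.  Uses the exact null
#' distribution when the smaller sample has at most 8 observations and
#' there are no ties, and the tie-corrected normal approximation (with
#' continuity correction) otherwise.
#'
#' @param a,b Numeric vectors (non-empty).
#' @return List with `U` (the U statistic of sample `a`), `p_value`
#'   (two-sided), and `method` (`"exact"` or `"normal_approx"`).
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- min(length(a), length(b)) <= 8 && !ties
  r <- rank(c(a, b))
  U <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                       alternative = "two.sided"))
  list(U = unname(U), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Hypergeometric term enrichment in a gene subset
#'
#' For each annotation term observed in the subset, the upper-tail
#' hypergeometric probability of drawing at least the observed number of
#' term-annotated genes when sampling the subset from the background
#' without replacement.  By default the background is restricted to
#' annotated genes (those with at least one term in the chosen aspect),
#' mirroring enrichment tools that condition on annotation.
#'
#' @param subset Character vector of gene ids.
#' @param catalog A `gene_catalog`.
#' @param aspect One of `"function"`, `"process"`, `"component"`.
#' @param alpha Significance level applied to adjusted p-values
#'   (default 0.01).
#' @param correction `"bonferroni"` (default; over the terms tested) or
#'   `"none"`.
#' @param include_unannotated If `TRUE`, unannotated genes stay in the
#'   background.
#' @param exclude Optional gene ids to drop from both subset and
#'   background (e.g. subtelomeric genes for the robustness control).
#' @return Data frame sorted by ascending `p_raw` with columns `term`,
#'   `k_subset`, `n_subset`, `K_background`, `N_background`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
term_enrichment <- function(subset, catalog,
                            aspect = c("function", "process", "component"),
                            alpha = 0.01,
                            correction = c("bonferroni", "none"),
                            include_unannotated = FALSE,
                            exclude = NULL) {
  aspect <- match.arg(aspect)
  correction <- match.arg(correction)
  col <- paste0("go_", aspect)
  terms_by_gene <- stats::setNames(catalog[[col]], catalog$gene_id)
  genes <- catalog$gene_id[!catalog$dubious]
  if (!is.null(exclude)) genes <- setdiff(genes, exclude)
  if (!include_unannotated) {
    genes <- genes[lengths(terms_by_gene[genes]) > 0]
  }
  subset <- intersect(subset, genes)
  if (length(subset) == 0) {
    return(data.frame(term = character(0), k_subset = integer(0),
                      n_subset = integer(0), K_background = integer(0),
                      N_background = integer(0), p_raw = numeric(0),
                      p_adjusted = numeric(0), significant = logical(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(genes)
  n <- length(subset)
  bg_terms <- table(unlist(terms_by_gene[genes]))
  sub_terms <- table(unlist(terms_by_gene[subset]))
  tested <- names(sub_terms)
  k <- as.integer(sub_terms)
  K <- as.integer(bg_terms[tested])
  p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_adj <- if (correction == "bonferroni") pmin(1, p_raw * length(tested)) else p_raw
  out <- data.frame(term = tested, k_subset = k, n_subset = n,
                    K_background = K, N_background = N,
                    p_raw = p_raw, p_adjusted = p_adj,
                    significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
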