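# Shared fixture builders.  All fixtures are built in code; tests that
# need files write them to tempdir().

GRP5 <- c("pre_wgd/duplicate", "pre_wgd/novel", "wgd/duplicate",
          "post_wgd/duplicate", "post_wgd/novel")

make_catalog <- function(gene_id, length_aa = 100, essential = FALSE,
                         dubious = FALSE, subtelomeric = FALSE,
                         go_function = NULL) {
  n <- length(gene_id)
  df <- data.frame(gene_id = gene_id,
                   length_aa = as.integer(rep_len(length_aa, n)),
                   stringsAsFactors = FALSE)
  df$essential <- rep_len(essential, n)
  df$dubious <- rep_len(dubious, n)
  df$subtelomeric <- rep_len(subtelomeric, n)
  df$go_process <- rep(list(character(0)), n)
  df$go_function <- if (is.null(go_function)) {
    rep(list(character(0)), n)
  } else {
    go_function
  }
  df$go_component <- rep(list(character(0)), n)
  class(df) <- c("gene_catalog", "data.frame")
  df
}

make_edges <- function(...) {
  pairs <- list(...)
  data.frame(gene_a = vapply(pairs, `[`, character(1), 1),
             gene_b = vapply(pairs, `[`, character(1), 2),
             source = "unknown", stringsAsFactors = FALSE)
}

make_net <- function(...) build_network(make_edges(...))

# G(n, p) random graph as a ppi_network over vertices v01..vnn
random_gnp_network <- function(n, p, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("v%03d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  hit <- runif(nrow(idx)) < p
  edges <- data.frame(gene_a = ids[idx[hit, "row"]],
                      gene_b = ids[idx[hit, "col"]],
                      source = rep("unknown", sum(hit)),
                      stringsAsFactors = FALSE)
  suppressWarnings(build_network(edges))
}

# small all-module synthetic configuration
small_config <- function(seed = 1, ...) {
  synthetic_config(group_sizes = c("pre_wgd/duplicate" = 40,
                                   "pre_wgd/novel" = 60,
                                   "wgd/duplicate" = 30,
                                   "post_wgd/duplicate" = 24,
                                   "post_wgd/novel" = 20),
                   n_dubious = 8, seed = seed, ...)
}

# 5 groups x 100 network vertices, mean degree 6, optional planted
# within-group preference
block_config <- function(seed, within = 1) {
  omega <- matrix(1, 5, 5, dimnames = list(GRP5, GRP5))
  diag(omega) <- within
  synthetic_config(group_sizes = stats::setNames(rep(100, 5), GRP5),
                   interaction_prob = stats::setNames(rep(1, 5), GRP5),
                   mean_degree = 6, mixing = omega, seed = seed)
}
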