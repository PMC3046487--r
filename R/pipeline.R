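# End-to-end orchestration: (simulate | parse) -> classify -> network ->
# assortativity -> attributes, with one root seed feeding named
# per-stage substreams so toggling one stage never perturbs another's
# draws.  Outputs are plain TSVs; a run is byte-identical given the same
# config and seed.

stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, classify = 211L, nulls = 307L)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Build a validated pipeline run configuration
#'
#' Exactly one of `inputs` (paths to existing tables) or `simulate` (a
#' [synthetic_config()]) must be supplied.
#'
#' @param inputs Named list of paths: `catalog`, `edges`, `families`,
#'   `reconstruction`, `orthologs`, optionally `species_ranks`, `pfam`.
#' @param simulate A `synthetic_config`.
#' @param sticky_threshold Degree cutoff for the sticky-protein filter
#'   (default 50).
#' @param n_random Null-ensemble size (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Root seed (default 1).
#' @param exclude_essential,exclude_subtelomeric Robustness controls:
#'   drop the flagged genes before building the network.
#' @param source_filter Optional edge-source filter, e.g.
#'   `"high_throughput"`.
#' @param progenitor_variant Use the progenitor origin relabeling.
#' @return A `run_config` list.
#' @export
run_config <- function(inputs = NULL, simulate = NULL, sticky_threshold = 50,
                       n_random = 1000, alpha = 0.05, seed = 1,
                       exclude_essential = FALSE,
                       exclude_subtelomeric = FALSE, source_filter = NULL,
                       progenitor_variant = FALSE) {
  if (is.null(inputs) == is.null(simulate)) {
    stop("exactly one of 'inputs' and 'simulate' must be given", call. = FALSE)
  }
  if (!is.null(inputs)) {
    need <- c("catalog", "edges", "families", "reconstruction", "orthologs")
    missing <- setdiff(need, names(inputs))
    if (length(missing) > 0) {
      stop(sprintf("inputs is missing: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
  }
  structure(list(inputs = inputs, simulate = simulate,
                 sticky_threshold = sticky_threshold, n_random = n_random,
                 alpha = alpha, seed = seed,
                 exclude_essential = exclude_essential,
                 exclude_subtelomeric = exclude_subtelomeric,
                 source_filter = source_filter,
                 progenitor_variant = progenitor_variant),
            class = "run_config")
}

#' Read a pipeline configuration from a JSON file
#'
#' The JSON mirrors the arguments of [run_config()]; a `simulate` block
#' is passed to [synthetic_config()].
#'
#' @param path Path to a JSON config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(raw$simulate)) {
    args <- raw$simulate
    for (nm in intersect(names(args),
                         c("group_sizes", "length_median", "essential_prob",
                           "annotation_prob", "interaction_prob", "pfam_mean",
                           "subtelomeric_prob"))) {
      args[[nm]] <- unlist(args[[nm]])
    }
    if (!is.null(args$mixing)) args$mixing <- as.matrix(args$mixing)
    sim <- do.call(synthetic_config, args)
  }
  keep <- intersect(names(raw),
                    c("sticky_threshold", "n_random", "alpha", "seed",
                      "exclude_essential", "exclude_subtelomeric",
                      "source_filter", "progenitor_variant"))
  do.call(run_config, c(list(inputs = raw$inputs, simulate = sim), raw[keep]))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
}

#' Run the full analysis pipeline
#'
#' Acquires data (from files or the synthetic generator), classifies
#' genes, builds and filters the interaction network, computes centrality
#' and group summaries, tests group interaction preferences against the
#' degree-preserving null, tabulates per-group attributes, and extracts
#' the young-novel ego subnetwork.  Writes seven artifacts to `outdir`:
#' `classification.tsv`, `centrality.tsv`, `group_summary.tsv`,
#' `assort.tsv`, `table1.tsv`, `young_novel_subnet.tsv` (component
#' report as `#` comment lines above the edge list) and `run_log.txt`.
#'
#' @param config A `run_config`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(sprintf("genesisnet %s", utils::packageVersion("genesisnet")),
                 sprintf("seed: %d", config$seed),
                 sprintf("n_random: %d  alpha: %g  sticky_threshold: %d",
                         config$n_random, config$alpha,
                         config$sticky_threshold))
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # -- acquire ---------------------------------------------------------
  dat <- stage("acquire", {
    if (!is.null(config$simulate)) {
      sim <- config$simulate
      sim$seed <- stage_seed(config$seed, "simulate")
      generate_dataset(sim)
    } else {
      p <- config$inputs
      catalog <- read_gene_catalog(p$catalog)
      evidence <- read_evolution_evidence(p$families, p$reconstruction,
                                          p$orthologs, catalog)
      edges <- read_edge_table(p$edges, catalog)
      sp <- if (!is.null(p$species_ranks)) {
        utils::read.delim(p$species_ranks, stringsAsFactors = FALSE)
      }
      pf <- if (!is.null(p$pfam)) {
        x <- utils::read.delim(p$pfam, stringsAsFactors = FALSE)
        stats::setNames(x$pfam_coverage, x$gene_id)
      }
      list(catalog = catalog, evidence = evidence,
           network = build_network(edges), species_ranks = sp, pfam = pf)
    }
  })
  log_lines <- c(log_lines,
                 sprintf("catalog: %d genes (%d dubious)",
                         nrow(dat$catalog), sum(dat$catalog$dubious)),
                 sprintf("edges: %d", nrow(dat$network$edges)))

  # -- classify --------------------------------------------------------
  classification <- stage("classify", {
    classify_genes(dat$catalog, dat$evidence,
                   progenitor_variant = config$progenitor_variant,
                   species_ranks = dat$species_ranks,
                   seed = stage_seed(config$seed, "classify"))
  })
  write_tsv(as.data.frame(classification),
            file.path(outdir, "classification.tsv"))

  # -- network ---------------------------------------------------------
  net <- stage("network", {
    keep <- dat$catalog$gene_id[!dat$catalog$dubious]
    if (config$exclude_essential) {
      keep <- setdiff(keep, dat$catalog$gene_id[dat$catalog$essential])
    }
    if (config$exclude_subtelomeric) {
      keep <- setdiff(keep, dat$catalog$gene_id[dat$catalog$subtelomeric])
    }
    raw <- build_network(dat$network$edges, restrict_to = keep,
                         source_filter = config$source_filter)
    filter_sticky(raw, threshold = config$sticky_threshold)
  })
  removed <- unlist(attr(net, "removal_log"))
  log_lines <- c(log_lines,
                 sprintf("sticky filter removed %d vertex(es) in %d round(s)",
                         length(removed), length(attr(net, "removal_log"))),
                 sprintf("analyzed network: %d vertices, %d edges",
                         length(net$vertices), nrow(net$edges)))

  # -- centrality ------------------------------------------------------
  cent <- stage("centrality", {
    deg <- degree_centrality(net)
    btw <- betweenness_centrality(net)
    data.frame(gene_id = net$vertices,
               degree = deg[net$vertices],
               betweenness = btw[net$vertices],
               degree_per_aa = normalize_by_length(deg, dat$catalog)[net$vertices],
               betweenness_per_aa = normalize_by_length(btw, dat$catalog)[net$vertices],
               stringsAsFactors = FALSE)
  })
  write_tsv(cent, file.path(outdir, "centrality.tsv"))

  gsum <- stage("group_summary", {
    out <- NULL
    for (stat in c("degree", "betweenness", "degree_per_aa",
                   "betweenness_per_aa")) {
      s <- group_summary(stats::setNames(cent[[stat]], cent$gene_id),
                         classification)
      s$statistic <- stat
      out <- rbind(out, s)
    }
    out[, c("statistic", "age", "origin", "group", "n", "mean", "se")]
  })
  write_tsv(gsum, file.path(outdir, "group_summary.tsv"))

  # -- assortativity ---------------------------------------------------
  assort <- stage("assortativity", {
    labels <- classification_groups(classification)
    assortativity_test(net, labels[net$vertices],
                       n_random = config$n_random,
                       seed = stage_seed(config$seed, "nulls"),
                       alpha = config$alpha)
  })
  write_tsv(as.data.frame(assort), file.path(outdir, "assort.tsv"))

  # -- attributes ------------------------------------------------------
  tab1 <- stage("attributes", {
    attribute_table(dat$catalog, classification, net = dat$network,
                    pfam = dat$pfam)
  })
  write_tsv(tab1, file.path(outdir, "table1.tsv"))

  # -- young-novel ego subnetwork --------------------------------------
  ego <- stage("ego", {
    seeds <- classification$gene_id[classification$age == "post_wgd" &
                                      classification$origin == "novel"]
    labels <- classification_groups(classification)
    suppressWarnings(ego_subnetwork(net, seeds, radius = 1, labels = labels))
  })
  ego_path <- file.path(outdir, "young_novel_subnet.tsv")
  con <- file(ego_path, open = "wt", encoding = "UTF-8")
  writeLines(sprintf("# young novel seeds with interactions: %d of %d",
                     sum(classification$age == "post_wgd" &
                           classification$origin == "novel" &
                           classification$gene_id %in% net$vertices),
                     sum(classification$age == "post_wgd" &
                           classification$origin == "novel")), con)
  if (nrow(ego$components) > 0) {
    writeLines(sprintf("# component %d: size %d, %d seed(s)",
                       ego$components$component, ego$components$size,
                       ego$components$n_seed), con)
  }
  close(con)
  suppressWarnings(
    utils::write.table(ego$network$edges, ego_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, append = TRUE,
                       fileEncoding = "UTF-8"))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))
  invisible(list(data = dat, classification = classification, network = net,
                 centrality = cent, group_summary = gsum, assortativity = assort,
                 attribute_table = tab1, ego = ego))
}
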