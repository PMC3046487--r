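# Ground-truthed synthetic datasets: a gene catalog with group-specific
# attribute distributions, evolution-evidence fixtures that the
# classifier recovers exactly, and a degree-corrected block-model PPI
# network with a planted group-mixing matrix.
#
# Default parameters echo the magnitudes of the yeast study the package
# emulates (five age/origin groups of 1434/2696/1087/314/239 genes,
# median protein lengths 180-450 aa, 25-81% interaction participation)
# without claiming to fit any real dataset.

GROUP_DEFAULT_SIZES <- c("pre_wgd/duplicate" = 1434, "pre_wgd/novel" = 2696,
                         "wgd/duplicate" = 1087, "post_wgd/duplicate" = 314,
                         "post_wgd/novel" = 239)

group_vec <- function(x, default, what) {
  out <- default
  if (!is.null(x)) {
    bad <- setdiff(names(x), GROUP_LEVELS)
    if (length(bad) > 0) {
      stop(sprintf("%s: unknown group '%s'", what, bad[1]), call. = FALSE)
    }
    out[names(x)] <- x
  }
  out
}

#' Configuration for the synthetic-data generator
#'
#' All per-group parameters are named by `"age/origin"` group; partial
#' named vectors override the defaults listed below.
#'
#' @param group_sizes Genes per group.  Defaults to the five-group sizes
#'   1434/2696/1087/314/239; the WGD group is rounded down to an even
#'   count (its members come in pairs).
#' @param length_median,length_sdlog Per-group lognormal protein-length
#'   model (median in amino acids; log-scale SD, default 0.55).
#' @param essential_prob,annotation_prob,interaction_prob Per-group
#'   Bernoulli probabilities for essentiality, molecular-function
#'   annotation, and participation in the interaction network.
#' @param pfam_mean Per-group mean Pfam coverage fraction (Beta model).
#' @param subtelomeric_prob Per-group probability of the subtelomeric
#'   flag; forced to 0 for the WGD group because subtelomeres are
#'   excluded from synteny-based reconstruction.
#' @param n_dubious Extra dubious ORFs appended to the catalog (excluded
#'   from truth labels and from all evidence).
#' @param degree_exponent,degree_min,degree_max Truncated discrete
#'   power-law model for vertex degree propensities.
#' @param mean_degree Target mean degree of the generated network.
#' @param mixing Symmetric 5x5 group-pair weight matrix `omega` with
#'   non-negative entries (default all 1 = neutral mixing); row/column
#'   order follows `group_sizes`.
#' @param n_species,n_pre_wgd_species Ortholog species panel: species
#'   ranked 1..n by divergence depth, the deepest `n_pre_wgd_species` of
#'   which diverged before the WGD.
#' @param seed Root seed for all generator randomness.
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(group_sizes = NULL,
                             length_median = NULL, length_sdlog = 0.55,
                             essential_prob = NULL, annotation_prob = NULL,
                             interaction_prob = NULL, pfam_mean = NULL,
                             subtelomeric_prob = NULL, n_dubious = 0,
                             degree_exponent = 2.5, degree_min = 1,
                             degree_max = 50, mean_degree = 6,
                             mixing = NULL, n_species = 8,
                             n_pre_wgd_species = 4, seed = 1) {
  sizes <- group_vec(group_sizes, GROUP_DEFAULT_SIZES, "group_sizes")
  if (sizes[["wgd/duplicate"]] %% 2 == 1) {
    sizes[["wgd/duplicate"]] <- sizes[["wgd/duplicate"]] - 1
    warning("wgd/duplicate size rounded down to an even pair count",
            call. = FALSE)
  }
  cfg <- list(
    group_sizes = sizes,
    length_median = group_vec(length_median,
                              c("pre_wgd/duplicate" = 450, "pre_wgd/novel" = 398,
                                "wgd/duplicate" = 430, "post_wgd/duplicate" = 400,
                                "post_wgd/novel" = 180), "length_median"),
    length_sdlog = length_sdlog,
    essential_prob = group_vec(essential_prob,
                               c("pre_wgd/duplicate" = 0.30, "pre_wgd/novel" = 0.30,
                                 "wgd/duplicate" = 0.08, "post_wgd/duplicate" = 0.02,
                                 "post_wgd/novel" = 0.00), "essential_prob"),
    annotation_prob = group_vec(annotation_prob,
                                c("pre_wgd/duplicate" = 0.88, "pre_wgd/novel" = 0.67,
                                  "wgd/duplicate" = 0.76, "post_wgd/duplicate" = 0.60,
                                  "post_wgd/novel" = 0.22), "annotation_prob"),
    interaction_prob = group_vec(interaction_prob,
                                 c("pre_wgd/duplicate" = 0.81, "pre_wgd/novel" = 0.77,
                                   "wgd/duplicate" = 0.72, "post_wgd/duplicate" = 0.55,
                                   "post_wgd/novel" = 0.25), "interaction_prob"),
    pfam_mean = group_vec(pfam_mean,
                          c("pre_wgd/duplicate" = 0.57, "pre_wgd/novel" = 0.36,
                            "wgd/duplicate" = 0.45, "post_wgd/duplicate" = 0.53,
                            "post_wgd/novel" = 0.12), "pfam_mean"),
    subtelomeric_prob = group_vec(subtelomeric_prob,
                                  c("pre_wgd/duplicate" = 0.02, "pre_wgd/novel" = 0.02,
                                    "wgd/duplicate" = 0, "post_wgd/duplicate" = 0.35,
                                    "post_wgd/novel" = 0.35), "subtelomeric_prob"),
    n_dubious = n_dubious,
    degree_exponent = degree_exponent, degree_min = degree_min,
    degree_max = degree_max, mean_degree = mean_degree,
    n_species = n_species, n_pre_wgd_species = n_pre_wgd_species,
    seed = seed)
  cfg$subtelomeric_prob[["wgd/duplicate"]] <- 0
  if (is.null(mixing)) {
    mixing <- matrix(1, 5, 5, dimnames = list(GROUP_LEVELS, GROUP_LEVELS))
  }
  if (is.null(dimnames(mixing))) {
    dimnames(mixing) <- list(GROUP_LEVELS, GROUP_LEVELS)
  }
  if (!isTRUE(all.equal(mixing, t(mixing)))) {
    stop("mixing matrix must be symmetric", call. = FALSE)
  }
  if (any(mixing < 0)) stop("mixing weights must be >= 0", call. = FALSE)
  cfg$mixing <- mixing[GROUP_LEVELS, GROUP_LEVELS]
  for (p in c("essential_prob", "annotation_prob", "interaction_prob",
              "pfam_mean", "subtelomeric_prob")) {
    if (any(cfg[[p]] < 0 | cfg[[p]] > 1)) {
      stop(sprintf("%s entries must lie in [0, 1]", p), call. = FALSE)
    }
  }
  if (degree_min < 1 || degree_max < degree_min) {
    stop("need 1 <= degree_min <= degree_max", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' Species table of the synthetic ortholog panel
#'
#' @param config A `synthetic_config`.
#' @return Data frame `species_id`, `depth_rank`, `diverged_pre_wgd`:
#'   ranks run 1 (closest relative) to `n_species` (most distant); the
#'   deepest `n_pre_wgd_species` species diverged before the WGD.
#' @export
synthetic_species_ranks <- function(config) {
  n <- config$n_species
  data.frame(species_id = sprintf("sp%02d", seq_len(n)),
             depth_rank = seq_len(n),
             diverged_pre_wgd = seq_len(n) > n - config$n_pre_wgd_species,
             stringsAsFactors = FALSE)
}

sample_terms <- function(n_genes, pool, weights, n_range = 1:3) {
  lapply(seq_len(n_genes), function(i) {
    k <- sample(n_range, 1)
    sort(sample(pool, k, prob = weights))
  })
}

#' Generate a synthetic gene catalog with known group labels
#'
#' One gene per configured slot; protein lengths lognormal per group,
#' essentiality / annotation / subtelomeric flags Bernoulli per group.
#' Annotated genes draw 1-3 molecular-function terms from a 40-term pool
#' in which each group has a 10x up-weighted signature term, so term
#' enrichment has planted signal.  Deterministic given `config$seed`.
#'
#' @param config A `synthetic_config`.
#' @return List with `catalog` (a `gene_catalog`), `pfam` (named per-gene
#'   coverage fractions), and `truth` (a `synthetic_truth` list holding
#'   `labels` — data frame `gene_id`, `age`, `origin`, `group` — and the
#'   config).
#' @export
generate_catalog <- function(config) {
  set.seed(config$seed + 11L)
  sizes <- config$group_sizes
  n <- sum(sizes)
  group <- rep(names(sizes), times = sizes)
  ids <- sprintf("g%05d", seq_len(n))
  len <- integer(n)
  ess <- logical(n)
  ann <- logical(n)
  sub <- logical(n)
  pfam <- numeric(n)
  term_pool <- sprintf("T%04d", seq_len(40))
  signature <- stats::setNames(term_pool[seq_along(GROUP_LEVELS)], GROUP_LEVELS)
  go_fun <- vector("list", n)
  for (g in names(sizes)) {
    i <- which(group == g)
    len[i] <- pmax(1L, as.integer(round(
      stats::rlnorm(length(i), meanlog = log(config$length_median[[g]]),
                    sdlog = config$length_sdlog))))
    ess[i] <- stats::runif(length(i)) < config$essential_prob[[g]]
    ann[i] <- stats::runif(length(i)) < config$annotation_prob[[g]]
    sub[i] <- stats::runif(length(i)) < config$subtelomeric_prob[[g]]
    m <- config$pfam_mean[[g]]
    conc <- 10
    pfam[i] <- stats::rbeta(length(i), shape1 = m * conc + 1e-6,
                            shape2 = (1 - m) * conc + 1e-6)
    w <- rep(1, length(term_pool))
    w[match(signature[[g]], term_pool)] <- 10
    annotated <- i[ann[i]]
    go_fun[annotated] <- sample_terms(length(annotated), term_pool, w)
  }
  go_fun[vapply(go_fun, is.null, logical(1))] <- list(character(0))
  dub_n <- config$n_dubious
  catalog <- data.frame(gene_id = c(ids, if (dub_n > 0) sprintf("dub%04d", seq_len(dub_n))),
                        length_aa = c(len, if (dub_n > 0) pmax(1L, as.integer(round(
                          stats::rlnorm(dub_n, log(120), 0.5))))),
                        stringsAsFactors = FALSE)
  catalog$essential <- c(ess, rep(FALSE, dub_n))
  catalog$dubious <- c(rep(FALSE, n), rep(TRUE, dub_n))
  catalog$subtelomeric <- c(sub, rep(FALSE, dub_n))
  catalog$go_process <- c(go_fun, rep(list(character(0)), dub_n))
  catalog$go_function <- c(go_fun, rep(list(character(0)), dub_n))
  catalog$go_component <- rep(list(character(0)), n + dub_n)
  class(catalog) <- c("gene_catalog", "data.frame")
  attr(catalog, "n_dubious") <- dub_n
  parts <- strsplit(group, "/", fixed = TRUE)
  truth <- structure(list(
    labels = data.frame(gene_id = ids,
                        age = vapply(parts, `[`, character(1), 1),
                        origin = vapply(parts, `[`, character(1), 2),
                        group = group, stringsAsFactors = FALSE),
    config = config), class = "synthetic_truth")
  list(catalog = catalog,
       pfam = stats::setNames(c(pfam, rep(NA_real_, dub_n)), catalog$gene_id),
       truth = truth)
}

#' Generate evolution-evidence fixtures consistent with the truth labels
#'
#' Emits a family map, ancestral reconstruction, and ortholog profiles
#' such that [classify_genes()] recovers the true labels exactly:
#'
#' * non-subtelomeric pre-WGD genes occupy single-track ancestral loci;
#' * WGD genes come in pairs on the A/B tracks of shared loci (half the
#'   pairs are emitted as a single 2-member family, half as two
#'   singleton families that only family merging reunites);
#' * other duplicate genes are partitioned into families of 2-4 within
#'   their group; novel genes are singletons (half omitted from the
#'   family file to exercise the implicit-singleton rule);
#' * subtelomeric genes are absent from the reconstruction and carry
#'   ortholog rows whose deepest species is pre-WGD-diverging exactly
#'   when the gene is truly pre-WGD;
#' * within every multi-member family a unique deepest-ortholog gene is
#'   planted (the designated progenitor), so the progenitor variant
#'   relabels a known gene set, recorded in `truth$progenitor_genes`.
#'
#' @param truth A `synthetic_truth` from [generate_catalog()].
#' @param catalog The matching `gene_catalog` (supplies the subtelomeric
#'   flags).
#' @return List with `evidence` (an `evolution_evidence`),
#'   `species_ranks`, and the augmented `truth` (adds
#'   `progenitor_genes` and `wgd_pairs`).
#' @export
generate_evolution_fixtures <- function(truth, catalog) {
  config <- truth$config
  set.seed(config$seed + 23L)
  lab <- truth$labels
  subtel <- stats::setNames(catalog$subtelomeric, catalog$gene_id)
  species <- synthetic_species_ranks(config)
  deep_rank_max <- config$n_species          # deepest pre-WGD diverger
  deep_rank_min <- config$n_species - config$n_pre_wgd_species + 1
  shallow_rank_max <- deep_rank_min - 1      # post-WGD divergers

  gene_of <- function(g) lab$gene_id[lab$group == g]

  # --- WGD pairs on shared loci --------------------------------------
  wgd <- gene_of("wgd/duplicate")
  n_pair <- length(wgd) %/% 2
  pair_a <- wgd[seq_len(n_pair) * 2 - 1]
  pair_b <- wgd[seq_len(n_pair) * 2]
  pre <- lab$gene_id[lab$age == "pre_wgd"]
  pre_rec <- pre[!subtel[pre]]
  loci <- sprintf("anc%05d", seq_len(length(pre_rec) + n_pair))
  reconstruction <- rbind(
    data.frame(ancestor_locus = loci[seq_along(pre_rec)], track = "A",
               gene_id = pre_rec, stringsAsFactors = FALSE),
    data.frame(ancestor_locus = rep(loci[length(pre_rec) + seq_len(n_pair)], 2),
               track = rep(c("A", "B"), each = n_pair),
               gene_id = c(pair_a, pair_b), stringsAsFactors = FALSE))

  # --- families -------------------------------------------------------
  fam_rows <- list()
  fam_counter <- 0L
  new_fam <- function() {
    fam_counter <<- fam_counter + 1L
    sprintf("fam%05d", fam_counter)
  }
  split_pair <- stats::runif(n_pair) < 0.5
  for (i in seq_len(n_pair)) {
    if (split_pair[i]) {
      fam_rows[[length(fam_rows) + 1]] <-
        data.frame(gene_id = c(pair_a[i], pair_b[i]),
                   family_id = c(new_fam(), new_fam()),
                   stringsAsFactors = FALSE)
    } else {
      fam_rows[[length(fam_rows) + 1]] <-
        data.frame(gene_id = c(pair_a[i], pair_b[i]),
                   family_id = rep(new_fam(), 2), stringsAsFactors = FALSE)
    }
  }
  # effective families after merging, for progenitor planting
  eff_families <- lapply(seq_len(n_pair), function(i) c(pair_a[i], pair_b[i]))
  for (g in c("pre_wgd/duplicate", "post_wgd/duplicate")) {
    genes <- sample(gene_of(g))
    while (length(genes) > 0) {
      k <- min(length(genes), sample(2:4, 1))
      if (length(genes) - k == 1) k <- k + 1  # avoid stranding a singleton
      members <- genes[seq_len(k)]
      genes <- genes[-seq_len(k)]
      fam_rows[[length(fam_rows) + 1]] <-
        data.frame(gene_id = members, family_id = rep(new_fam(), k),
                   stringsAsFactors = FALSE)
      eff_families[[length(eff_families) + 1]] <- members
    }
  }
  novels <- lab$gene_id[lab$origin == "novel"]
  listed <- novels[stats::runif(length(novels)) < 0.5]
  if (length(listed) > 0) {
    fam_rows[[length(fam_rows) + 1]] <-
      data.frame(gene_id = listed,
                 family_id = vapply(listed, function(x) new_fam(), character(1)),
                 stringsAsFactors = FALSE)
  }
  family_map <- do.call(rbind, fam_rows)

  # --- ortholog depths (drive the subtelomeric rule and progenitors) --
  age_of <- stats::setNames(lab$age, lab$gene_id)
  depth <- stats::setNames(rep(NA_integer_, nrow(lab)), lab$gene_id)
  progenitors <- character(0)
  for (members in eff_families) {
    ages <- age_of[members]
    prog <- members[order(match(ages, AGE_LEVELS))][1]
    progenitors <- c(progenitors, prog)
    for (m in members) {
      if (m == prog) {
        depth[m] <- if (age_of[m] == "post_wgd") shallow_rank_max else deep_rank_max
      } else {
        depth[m] <- if (age_of[m] == "post_wgd") {
          sample(seq_len(shallow_rank_max - 1), 1)
        } else {
          sample(seq(deep_rank_min, deep_rank_max - 1), 1)
        }
      }
    }
  }
  # singletons: depth consistent with age (needed for the subtelomeric rule)
  singles <- lab$gene_id[is.na(depth[lab$gene_id])]
  for (m in singles) {
    depth[m] <- if (age_of[m] == "post_wgd") {
      sample(seq_len(shallow_rank_max), 1)
    } else {
      sample(seq(deep_rank_min, deep_rank_max), 1)
    }
  }
  sp_of_rank <- stats::setNames(species$species_id, species$depth_rank)
  ort <- data.frame(gene_id = lab$gene_id,
                    species_id = sp_of_rank[as.character(depth[lab$gene_id])],
                    stringsAsFactors = FALSE)
  # extra shallower rows (never deeper than the planted maximum)
  extra_idx <- which(depth[lab$gene_id] > 1 & stats::runif(nrow(lab)) < 0.4)
  if (length(extra_idx) > 0) {
    extra_depth <- vapply(extra_idx, function(i) {
      sample(seq_len(depth[lab$gene_id[i]] - 1), 1)
    }, integer(1))
    ort <- rbind(ort, data.frame(gene_id = lab$gene_id[extra_idx],
                                 species_id = sp_of_rank[as.character(extra_depth)],
                                 stringsAsFactors = FALSE))
  }
  rank_of_sp <- stats::setNames(species$depth_rank, species$species_id)
  ort$diverged_pre_wgd <- rank_of_sp[ort$species_id] >= deep_rank_min
  ort <- ort[order(ort$gene_id, ort$species_id), , drop = FALSE]
  rownames(ort) <- NULL

  evidence <- evolution_evidence(family_map, reconstruction, ort, catalog)
  truth$progenitor_genes <- sort(progenitors)
  truth$wgd_pairs <- data.frame(gene_a = pmin(pair_a, pair_b),
                                gene_b = pmax(pair_a, pair_b),
                                stringsAsFactors = FALSE)
  list(evidence = evidence, species_ranks = species, truth = truth)
}

#' Generate a PPI network with a planted group-mixing structure
#'
#' Degree-corrected block model: each participating gene (Bernoulli
#' `interaction_prob` by group) receives a degree propensity drawn from a
#' truncated discrete power law; edge \eqn{(i, j)} is included
#' independently with probability
#' \eqn{\min(1, \theta_i \theta_j \omega_{g(i) g(j)} / C)} where `C`
#' normalizes the expected edge count to `mean_degree * n / 2`.
#'
#' @param config A `synthetic_config`.
#' @param truth A `synthetic_truth` supplying the group labels.
#' @return A `ppi_network` with attributes `expected_group_counts` (the
#'   analytic expectation of every group-pair count given the drawn
#'   propensities) and `expected_group_vars` (the matching binomial
#'   variances), plus `theta` and `participants` for diagnostics.
#' @export
generate_network <- function(config, truth) {
  set.seed(config$seed + 37L)
  lab <- truth$labels
  part <- lab$gene_id[stats::runif(nrow(lab)) <
                        config$interaction_prob[lab$group]]
  n <- length(part)
  if (n < 2) stop("too few participating genes to build a network",
                  call. = FALSE)
  if (config$mean_degree >= n) {
    stop("mean_degree is infeasible for the number of participating genes",
         call. = FALSE)
  }
  dvals <- config$degree_min:config$degree_max
  theta <- sample(dvals, n, replace = TRUE,
                  prob = dvals^(-config$degree_exponent))
  g <- stats::setNames(lab$group, lab$gene_id)[part]
  gi <- match(g, GROUP_LEVELS)
  omega <- config$mixing
  # normalizing constant from group aggregates
  Tg <- tapply(theta, factor(gi, 1:5), sum)
  Qg <- tapply(theta^2, factor(gi, 1:5), sum)
  Tg[is.na(Tg)] <- 0; Qg[is.na(Qg)] <- 0
  S <- (sum(omega * outer(Tg, Tg)) - sum(diag(omega) * Qg)) / 2
  target_edges <- config$mean_degree * n / 2
  C <- S / target_edges
  exp_counts <- matrix(0, 5, 5, dimnames = list(GROUP_LEVELS, GROUP_LEVELS))
  exp_vars <- exp_counts
  ea <- integer(0); eb <- integer(0)
  n_clipped <- 0
  for (i in seq_len(n - 1)) {
    j <- (i + 1):n
    p <- theta[i] * theta[j] * omega[cbind(gi[i], gi[j])] / C
    n_clipped <- n_clipped + sum(p > 1)
    p <- pmin(1, p)
    hit <- stats::runif(length(j)) < p
    ea <- c(ea, rep(i, sum(hit))); eb <- c(eb, j[hit])
    for (h in unique(gi[j])) {
      sel <- gi[j] == h
      a <- min(gi[i], h); b <- max(gi[i], h)
      exp_counts[a, b] <- exp_counts[a, b] + sum(p[sel])
      exp_vars[a, b] <- exp_vars[a, b] + sum(p[sel] * (1 - p[sel]))
    }
  }
  if (n_clipped > 0.01 * n * (n - 1) / 2) {
    warning(sprintf("%d edge probabilities clipped at 1; mean degree may undershoot",
                    n_clipped), call. = FALSE)
  }
  edges <- data.frame(gene_a = part[ea], gene_b = part[eb],
                      source = sample(c("high_throughput", "small_scale"),
                                      length(ea), replace = TRUE,
                                      prob = c(0.7, 0.3)),
                      stringsAsFactors = FALSE)
  net <- build_network(edges)
  attr(net, "expected_group_counts") <- exp_counts
  attr(net, "expected_group_vars") <- exp_vars
  attr(net, "theta") <- stats::setNames(theta, part)
  attr(net, "participants") <- part
  net
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper chaining [generate_catalog()],
#' [generate_evolution_fixtures()] and [generate_network()].
#'
#' @param config A `synthetic_config`.
#' @return List with `catalog`, `pfam`, `evidence`, `species_ranks`,
#'   `network`, `truth`.
#' @export
generate_dataset <- function(config) {
  cat_out <- generate_catalog(config)
  evo <- generate_evolution_fixtures(cat_out$truth, cat_out$catalog)
  net <- generate_network(config, evo$truth)
  list(catalog = cat_out$catalog, pfam = cat_out$pfam,
       evidence = evo$evidence, species_ranks = evo$species_ranks,
       network = net, truth = evo$truth)
}

#' Write a synthetic dataset to a directory of TSV files
#'
#' Emits `catalog.tsv`, `families.tsv`, `reconstruction.tsv`,
#' `orthologs.tsv`, `edges.tsv`, `species_ranks.tsv`, `pfam.tsv` and
#' `truth.json`.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_gene_catalog(dataset$catalog, p("catalog.tsv"))
  write_evolution_evidence(dataset$evidence, p("families.tsv"),
                           p("reconstruction.tsv"), p("orthologs.tsv"))
  write_edge_table(dataset$network$edges, p("edges.tsv"))
  sp <- dataset$species_ranks
  sp$diverged_pre_wgd <- as.integer(sp$diverged_pre_wgd)
  utils::write.table(sp, p("species_ranks.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(dataset$pfam),
                                pfam_coverage = round(unname(dataset$pfam), 6)),
                     p("pfam.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- dataset$truth
  jsonlite::write_json(list(labels = truth$labels,
                            progenitor_genes = truth$progenitor_genes,
                            wgd_pairs = truth$wgd_pairs,
                            group_sizes = as.list(truth$config$group_sizes),
                            seed = truth$config$seed),
                       p("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
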