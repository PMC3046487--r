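#' @useDynLib genesisnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median phyper quantile rbinom rlnorm sd wilcox.test runif
#' @importFrom utils read.delim write.table packageVersion
#' @keywords internal
"_PACKAGE"

# Canonical age/origin vocabulary.  The WGD event defines the age boundary;
# (wgd, novel) is structurally empty because the duplication itself creates
# a paralog for every gene it retains in two copies.
AGE_LEVELS <- c("pre_wgd", "wgd", "post_wgd")
ORIGIN_LEVELS <- c("duplicate", "novel")
GROUP_LEVELS <- c("pre_wgd/duplicate", "pre_wgd/novel", "wgd/duplicate",
                  "post_wgd/duplicate", "post_wgd/novel")
EDGE_SOURCES <- c("small_scale", "high_throughput", "unknown")

read_tsv_table <- function(path, required, what) {
  if (!file.exists(path)) {
    stop(sprintf("%s file not found: %s", what, path), call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          check.names = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

parse_flag <- function(x, col, what) {
  ok <- x %in% c("0", "1")
  if (!all(ok)) {
    stop(sprintf("%s: column '%s' must be 0/1 (offending row %d: '%s')",
                 what, col, which(!ok)[1], x[which(!ok)[1]]), call. = FALSE)
  }
  x == "1"
}

split_terms <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character(0) else strsplit(s, "|", fixed = TRUE)[[1]]
  })
}

join_terms <- function(x) {
  vapply(x, function(t) paste(t, collapse = "|"), character(1))
}

#' Read a gene catalog table
#'
#' The catalog is a tab-separated file with a header and the columns
#' `gene_id`, `length_aa`, `essential`, `dubious`, `subtelomeric` (0/1
#' flags) and pipe-separated annotation-term lists `go_process`,
#' `go_function`, `go_component` (empty allowed).  Lines starting with `#`
#' are comments.  Gene identifiers are case-sensitive and must be unique.
#'
#' @param path Path to the TSV file.
#' @return A `gene_catalog` data frame, one row per gene, preserving input
#'   order.  Term columns are list columns of character vectors.  The
#'   number of dubious genes is attached as attribute `n_dubious`.
#' @export
read_gene_catalog <- function(path) {
  req <- c("gene_id", "length_aa", "essential", "dubious", "subtelomeric",
           "go_process", "go_function", "go_component")
  df <- read_tsv_table(path, req, "gene catalog")
  dup <- duplicated(df$gene_id)
  if (any(dup)) {
    stop(sprintf("duplicate gene_id in catalog: %s",
                 paste(unique(df$gene_id[dup]), collapse = ", ")),
         call. = FALSE)
  }
  len <- suppressWarnings(as.numeric(df$length_aa))
  bad <- is.na(len) | len != floor(len) | len < 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("catalog row %d (gene %s): length_aa '%s' is not a positive integer",
                 i, df$gene_id[i], df$length_aa[i]), call. = FALSE)
  }
  out <- data.frame(gene_id = df$gene_id, length_aa = as.integer(len),
                    stringsAsFactors = FALSE)
  out$essential <- parse_flag(df$essential, "essential", "catalog")
  out$dubious <- parse_flag(df$dubious, "dubious", "catalog")
  out$subtelomeric <- parse_flag(df$subtelomeric, "subtelomeric", "catalog")
  out$go_process <- split_terms(df$go_process)
  out$go_function <- split_terms(df$go_function)
  out$go_component <- split_terms(df$go_component)
  class(out) <- c("gene_catalog", "data.frame")
  attr(out, "n_dubious") <- sum(out$dubious)
  out
}

#' Write a gene catalog table
#'
#' Inverse of [read_gene_catalog()]; `read(write(x))` reproduces `x`.
#'
#' @param catalog A `gene_catalog` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_catalog <- function(catalog, path) {
  df <- data.frame(gene_id = catalog$gene_id,
                   length_aa = catalog$length_aa,
                   essential = as.integer(catalog$essential),
                   dubious = as.integer(catalog$dubious),
                   subtelomeric = as.integer(catalog$subtelomeric),
                   go_process = join_terms(catalog$go_process),
                   go_function = join_terms(catalog$go_function),
                   go_component = join_terms(catalog$go_component),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Canonicalize an edge table
#'
#' Orders each pair lexicographically, drops self-pairs, and collapses
#' duplicate pairs (keeping the first row's source tag).  Used both by the
#' parser and by the synthetic generator so that every edge table in the
#' package satisfies the same invariants.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `source`.
#' @return Canonical edge data frame with attribute `log`, a list with
#'   counts `n_self_dropped` and `n_duplicates_collapsed`.
#' @export
canonicalize_edges <- function(edges) {
  if (!all(c("gene_a", "gene_b") %in% names(edges))) {
    stop("edge table needs columns gene_a and gene_b", call. = FALSE)
  }
  if (is.null(edges$source)) edges$source <- rep("unknown", nrow(edges))
  a <- pmin(edges$gene_a, edges$gene_b)
  b <- pmax(edges$gene_a, edges$gene_b)
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; src <- edges$source[!self]
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  n_dup <- sum(dup)
  out <- data.frame(gene_a = a[!dup], gene_b = b[!dup], source = src[!dup],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "log") <- list(n_self_dropped = n_self,
                           n_duplicates_collapsed = n_dup)
  out
}

#' Read a protein-protein interaction edge list
#'
#' Two- or three-column TSV (`gene_a`, `gene_b`, optional `source` with
#' values `small_scale`, `high_throughput` or `unknown`).  Pairs are
#' canonicalized, self-pairs dropped, and duplicates collapsed; all three
#' events are counted in the attached `log` attribute.  Interactions are
#' treated as an undirected simple graph: homodimer self-interactions are
#' excluded because the downstream centrality definitions assume a simple
#' graph.
#'
#' @param path Path to the TSV file.
#' @param catalog Optional `gene_catalog`; when supplied, edges touching
#'   ids absent from the catalog are handled per `unknown_ids`.
#' @param unknown_ids `"drop"` (default) drops such edges with a warning
#'   and a count in the log; `"error"` aborts naming the first unknown id.
#' @return Canonical edge data frame (`gene_a`, `gene_b`, `source`) with a
#'   `log` attribute.
#' @export
read_edge_table <- function(path, catalog = NULL,
                            unknown_ids = c("drop", "error")) {
  unknown_ids <- match.arg(unknown_ids)
  df <- read_tsv_table(path, c("gene_a", "gene_b"), "edge list")
  if (is.null(df$source)) {
    df$source <- rep("unknown", nrow(df))
  }
  bad_src <- !(df$source %in% EDGE_SOURCES)
  if (any(bad_src)) {
    stop(sprintf("edge list row %d: unknown source '%s'",
                 which(bad_src)[1], df$source[which(bad_src)[1]]),
         call. = FALSE)
  }
  n_unknown <- 0L
  if (!is.null(catalog)) {
    known <- df$gene_a %in% catalog$gene_id & df$gene_b %in% catalog$gene_id
    n_unknown <- sum(!known)
    if (n_unknown > 0) {
      if (unknown_ids == "error") {
        off <- setdiff(unique(c(df$gene_a, df$gene_b)), catalog$gene_id)
        stop(sprintf("edge list references %d id(s) absent from catalog (e.g. %s)",
                     length(off), off[1]), call. = FALSE)
      }
      warning(sprintf("dropped %d edge(s) with ids absent from catalog",
                      n_unknown), call. = FALSE)
      df <- df[known, , drop = FALSE]
    }
  }
  out <- canonicalize_edges(df)
  lg <- attr(out, "log")
  lg$n_unknown_dropped <- n_unknown
  attr(out, "log") <- lg
  out
}

#' Write an edge table
#' @param edges Canonical edge data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(edges, path) {
  utils::write.table(edges[, c("gene_a", "gene_b", "source")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read evolutionary-evidence tables
#'
#' Loads and cross-validates the three evidence inputs used by the
#' classifier:
#'
#' * `families.tsv` (`gene_id`, `family_id`) — homologous family map.
#'   Catalog genes with no row become singleton families.
#' * `reconstruction.tsv` (`ancestor_locus`, `track`, `gene_id`) — the
#'   ancestral gene-order reconstruction with descendant tracks `A`/`B`;
#'   each (locus, track) maps to at most one gene.
#' * `orthologs.tsv` (`gene_id`, `species_id`, `diverged_pre_wgd` 0/1) —
#'   ortholog phylogenetic profile used to age subtelomeric genes.
#'
#' @param family_path,reconstruction_path,ortholog_path TSV paths.
#' @param catalog A `gene_catalog`; rows referencing genes absent from it
#'   are dropped with a warning (they are reported as unknown).
#' @return An `evolution_evidence` list with elements `family_map`
#'   (data frame `gene_id`, `family_id`), `reconstruction` and
#'   `ortholog_profile` data frames.
#' @export
read_evolution_evidence <- function(family_path, reconstruction_path,
                                    ortholog_path, catalog) {
  fam <- read_tsv_table(family_path, c("gene_id", "family_id"), "family map")
  if (anyDuplicated(fam$gene_id)) {
    stop(sprintf("family map lists gene %s more than once",
                 fam$gene_id[duplicated(fam$gene_id)][1]), call. = FALSE)
  }
  rec <- read_tsv_table(reconstruction_path,
                        c("ancestor_locus", "track", "gene_id"),
                        "reconstruction")
  bad_track <- !(rec$track %in% c("A", "B"))
  if (any(bad_track)) {
    stop(sprintf("reconstruction row %d: track '%s' is not A or B",
                 which(bad_track)[1], rec$track[which(bad_track)[1]]),
         call. = FALSE)
  }
  lt <- paste(rec$ancestor_locus, rec$track, sep = "\r")
  if (anyDuplicated(lt)) {
    i <- which(duplicated(lt))[1]
    stop(sprintf("reconstruction locus %s track %s maps to more than one gene",
                 rec$ancestor_locus[i], rec$track[i]), call. = FALSE)
  }
  ort <- read_tsv_table(ortholog_path,
                        c("gene_id", "species_id", "diverged_pre_wgd"),
                        "ortholog profile")
  gs <- paste(ort$gene_id, ort$species_id, sep = "\r")
  if (anyDuplicated(gs)) {
    i <- which(duplicated(gs))[1]
    stop(sprintf("duplicate ortholog row for gene %s, species %s",
                 ort$gene_id[i], ort$species_id[i]), call. = FALSE)
  }
  ort$diverged_pre_wgd <- parse_flag(ort$diverged_pre_wgd,
                                     "diverged_pre_wgd", "ortholog profile")
  evolution_evidence(fam, rec, ort, catalog)
}

#' Assemble an evolution-evidence object from in-memory tables
#'
#' @param family_map Data frame `gene_id`, `family_id`.
#' @param reconstruction Data frame `ancestor_locus`, `track`, `gene_id`.
#' @param ortholog_profile Data frame `gene_id`, `species_id`,
#'   `diverged_pre_wgd` (logical).
#' @param catalog A `gene_catalog` used to complete singleton families and
#'   flag unknown genes.
#' @return An `evolution_evidence` list.
#' @export
evolution_evidence <- function(family_map, reconstruction, ortholog_profile,
                               catalog) {
  all_ref <- unique(c(family_map$gene_id, reconstruction$gene_id,
                      ortholog_profile$gene_id))
  unknown <- setdiff(all_ref, catalog$gene_id)
  if (length(unknown) > 0) {
    warning(sprintf("evidence references %d gene id(s) absent from catalog (e.g. %s); rows dropped",
                    length(unknown), unknown[1]), call. = FALSE)
    family_map <- family_map[family_map$gene_id %in% catalog$gene_id, , drop = FALSE]
    reconstruction <- reconstruction[reconstruction$gene_id %in% catalog$gene_id, , drop = FALSE]
    ortholog_profile <- ortholog_profile[ortholog_profile$gene_id %in% catalog$gene_id, , drop = FALSE]
  }
  missing <- setdiff(catalog$gene_id, family_map$gene_id)
  if (length(missing) > 0) {
    family_map <- rbind(family_map,
                        data.frame(gene_id = missing,
                                   family_id = paste0("singleton:", missing),
                                   stringsAsFactors = FALSE))
  }
  rownames(family_map) <- NULL
  rownames(reconstruction) <- NULL
  rownames(ortholog_profile) <- NULL
  structure(list(family_map = family_map,
                 reconstruction = reconstruction,
                 ortholog_profile = ortholog_profile),
            class = "evolution_evidence")
}

#' Write evolution-evidence tables
#' @param evidence An `evolution_evidence` object.
#' @param family_path,reconstruction_path,ortholog_path Output paths.
#' @return Invisibly, the three paths.
#' @export
write_evolution_evidence <- function(evidence, family_path,
                                     reconstruction_path, ortholog_path) {
  fam <- evidence$family_map
  fam <- fam[!startsWith(fam$family_id, "singleton:"), , drop = FALSE]
  utils::write.table(fam, family_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(evidence$reconstruction, reconstruction_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  ort <- evidence$ortholog_profile
  ort$diverged_pre_wgd <- as.integer(ort$diverged_pre_wgd)
  utils::write.table(ort, ortholog_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(c(family_path, reconstruction_path, ortholog_path))
}

#' Read / write a gene classification table
#'
#' The classification table has columns `gene_id`, `age`, `origin` and
#' optionally `family_id` and `evidence`.
#'
#' @param path TSV path.
#' @return A `gene_classification` data frame.
#' @export
read_classification <- function(path) {
  df <- read_tsv_table(path, c("gene_id", "age", "origin"), "classification")
  bad <- !(df$age %in% AGE_LEVELS)
  if (any(bad)) {
    stop(sprintf("classification row %d: unknown age '%s'",
                 which(bad)[1], df$age[which(bad)[1]]), call. = FALSE)
  }
  bad <- !(df$origin %in% ORIGIN_LEVELS)
  if (any(bad)) {
    stop(sprintf("classification row %d: unknown origin '%s'",
                 which(bad)[1], df$origin[which(bad)[1]]), call. = FALSE)
  }
  class(df) <- c("gene_classification", "data.frame")
  df
}

#' @rdname read_classification
#' @param classification A `gene_classification` data frame.
#' @export
write_classification <- function(classification, path) {
  utils::write.table(as.data.frame(classification), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
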