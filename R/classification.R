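# Age/origin classification.
#
# Age precedence (the rules are applied in this order; the first that
# fires wins):
#   1. membership in a WGD pair            -> wgd
#   2. presence in the ancestral reconstruction -> pre_wgd
#   3. subtelomeric genes: ortholog profile rule -> pre_wgd / post_wgd
#   4. everything else                     -> post_wgd
# Origin: family size >= 2 (counting only non-dubious catalog genes)
# -> duplicate, else novel.  WGD pair members are duplicate by
# construction.  Dubious ORFs are excluded before anything else.

#' Detect duplicate pairs retained from the whole-genome duplication
#'
#' A WGD pair ("ohnolog" pair) is recognized by its synteny signature: a
#' single ancestral locus with descendants on both post-duplication tracks
#' (A and B).  Loci with descendants on only one track yield no pair.
#'
#' @param evidence An `evolution_evidence` object.
#' @return Data frame `ancestor_locus`, `gene_a`, `gene_b` (pair members,
#'   lexicographically ordered).  A gene appears in at most one pair.
#' @export
detect_wgd_pairs <- function(evidence) {
  rec <- evidence$reconstruction
  empty <- data.frame(ancestor_locus = character(0), gene_a = character(0),
                      gene_b = character(0), stringsAsFactors = FALSE)
  if (nrow(rec) == 0) return(empty)
  lt <- paste(rec$ancestor_locus, rec$track, sep = "\r")
  if (anyDuplicated(lt)) {
    i <- which(duplicated(lt))[1]
    stop(sprintf("reconstruction locus %s has more than one gene on track %s",
                 rec$ancestor_locus[i], rec$track[i]), call. = FALSE)
  }
  a_side <- rec[rec$track == "A", c("ancestor_locus", "gene_id")]
  b_side <- rec[rec$track == "B", c("ancestor_locus", "gene_id")]
  both <- merge(a_side, b_side, by = "ancestor_locus",
                suffixes = c("_a", "_b"))
  if (nrow(both) == 0) return(empty)
  out <- data.frame(ancestor_locus = both$ancestor_locus,
                    gene_a = pmin(both$gene_id_a, both$gene_id_b),
                    gene_b = pmax(both$gene_id_a, both$gene_id_b),
                    stringsAsFactors = FALSE)
  members <- c(out$gene_a, out$gene_b)
  if (anyDuplicated(members)) {
    stop(sprintf("gene %s appears in more than one WGD pair",
                 members[duplicated(members)][1]), call. = FALSE)
  }
  out[order(out$ancestor_locus), , drop = FALSE]
}

#' Merge homologous families joined by WGD pairs
#'
#' Family inference and the ancestral reconstruction are independent
#' evidence sources, so the two members of a WGD pair sometimes land in
#' different families.  Families containing members of the same WGD pair
#' are unioned (transitively, via union-find), producing a coarser valid
#' partition.
#'
#' @param family_map Data frame `gene_id`, `family_id`.
#' @param pairs WGD pair table from [detect_wgd_pairs()].
#' @return A family map with the same genes; merged families keep the
#'   lexicographically smallest of the merged ids.
#' @export
merge_wgd_families <- function(family_map, pairs) {
  fam_of <- stats::setNames(family_map$family_id, family_map$gene_id)
  ids <- sort(unique(family_map$family_id))
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      fa <- fam_of[[pairs$gene_a[i]]]
      fb <- fam_of[[pairs$gene_b[i]]]
      if (is.null(fa) || is.null(fb)) next
      ra <- find(fa); rb <- find(fb)
      if (ra != rb) {
        keep <- min(ra, rb); drop <- max(ra, rb)
        parent[[drop]] <- keep
      }
    }
  }
  family_map$family_id <- vapply(family_map$family_id, find, character(1),
                                 USE.NAMES = FALSE)
  family_map
}

#' Assign mechanism of origin from family sizes
#'
#' Genes in a homologous family with at least one other (non-dubious)
#' member in the focal genome have a paralog and are `duplicate`; genes
#' alone in their family are `novel`.  Dubious ORFs are excluded and do
#' not count towards family size.
#'
#' @param catalog A `gene_catalog`.
#' @param family_map Data frame `gene_id`, `family_id` (typically after
#'   [merge_wgd_families()]).
#' @return Named character vector gene_id -> origin over non-dubious genes.
#' @export
assign_origin <- function(catalog, family_map) {
  keep <- catalog$gene_id[!catalog$dubious]
  fm <- family_map[family_map$gene_id %in% keep, , drop = FALSE]
  sizes <- table(fm$family_id)
  fam_of <- stats::setNames(fm$family_id, fm$gene_id)
  origin <- ifelse(sizes[fam_of[keep]] >= 2, "duplicate", "novel")
  # genes missing from the family map are implicit singletons
  origin[is.na(origin)] <- "novel"
  stats::setNames(as.character(origin), keep)
}

#' Assign gene age from reconstruction and ortholog evidence
#'
#' @param catalog A `gene_catalog`.
#' @param evidence An `evolution_evidence` object.
#' @param pairs WGD pair table from [detect_wgd_pairs()].
#' @return List with `age` (named character vector over non-dubious
#'   genes) and `evidence` (named character vector naming the rule that
#'   fired: `wgd_pair`, `ancestral_locus`, `subtelomeric_ortholog`,
#'   `default_post_wgd`).
#' @export
assign_age <- function(catalog, evidence, pairs) {
  keep <- catalog$gene_id[!catalog$dubious]
  subtel <- stats::setNames(catalog$subtelomeric, catalog$gene_id)[keep]
  age <- stats::setNames(rep(NA_character_, length(keep)), keep)
  rule <- stats::setNames(rep(NA_character_, length(keep)), keep)

  pair_members <- intersect(c(pairs$gene_a, pairs$gene_b), keep)
  age[pair_members] <- "wgd"
  rule[pair_members] <- "wgd_pair"

  in_rec <- intersect(unique(evidence$reconstruction$gene_id), keep)
  anc <- setdiff(in_rec, pair_members)
  age[anc] <- "pre_wgd"
  rule[anc] <- "ancestral_locus"

  conflict <- anc[subtel[anc]]
  if (length(conflict) > 0) {
    message(sprintf("%d subtelomeric gene(s) also present in reconstruction; reconstruction wins (e.g. %s)",
                    length(conflict), conflict[1]))
  }

  rest <- keep[is.na(age)]
  ort <- evidence$ortholog_profile
  deep <- unique(ort$gene_id[ort$diverged_pre_wgd])
  sub_rest <- rest[subtel[rest]]
  age[sub_rest] <- ifelse(sub_rest %in% deep, "pre_wgd", "post_wgd")
  rule[sub_rest] <- "subtelomeric_ortholog"

  rest <- keep[is.na(age)]
  age[rest] <- "post_wgd"
  rule[rest] <- "default_post_wgd"
  list(age = age, evidence = rule)
}

#' Classify genes by age and mechanism of origin
#'
#' Runs the full classification: WGD pair detection, family merging,
#' origin assignment from family sizes, and age assignment with the
#' precedence WGD pair > ancestral presence > subtelomeric ortholog rule >
#' post-WGD default.  WGD pair members are always `duplicate` (they have
#' a paralog by construction), so the (wgd, novel) group is empty.
#'
#' @param catalog A `gene_catalog`.
#' @param evidence An `evolution_evidence` object.
#' @param progenitor_variant If `TRUE`, additionally relabel the oldest
#'   gene of each multi-member family as `novel` (see
#'   [apply_progenitor_variant()]); requires `species_ranks`.
#' @param species_ranks Data frame `species_id`, `depth_rank` giving each
#'   species an integer divergence depth (larger = more distant).
#' @param seed Optional integer seed for progenitor tie-breaking.
#' @return A `gene_classification` data frame with columns `gene_id`,
#'   `age`, `origin`, `family_id`, `evidence`, covering exactly the
#'   non-dubious catalog genes.
#' @export
classify_genes <- function(catalog, evidence, progenitor_variant = FALSE,
                           species_ranks = NULL, seed = NULL) {
  pairs <- detect_wgd_pairs(evidence)
  fam <- merge_wgd_families(evidence$family_map, pairs)
  origin <- assign_origin(catalog, fam)
  aged <- assign_age(catalog, evidence, pairs)
  keep <- names(aged$age)
  fam_of <- stats::setNames(fam$family_id, fam$gene_id)
  cls <- data.frame(gene_id = keep,
                    age = unname(aged$age[keep]),
                    origin = unname(origin[keep]),
                    family_id = unname(fam_of[keep]),
                    evidence = unname(aged$evidence[keep]),
                    stringsAsFactors = FALSE)
  # pair members have a paralog by construction
  stopifnot(all(cls$origin[cls$age == "wgd"] == "duplicate"))
  class(cls) <- c("gene_classification", "data.frame")
  if (progenitor_variant) {
    cls <- apply_progenitor_variant(cls, evidence, species_ranks, seed = seed)
  }
  cls
}

#' Relabel each family's progenitor as novel
#'
#' Alternative origin labeling: within every multi-member family exactly
#' one gene — the one with the most distant ortholog (largest
#' `depth_rank`; ties broken uniformly at random) — is taken to be the
#' progenitor of the family and relabeled `novel`.  Families with no
#' ortholog data at all get a uniformly random progenitor (logged).
#'
#' @param classification A `gene_classification`.
#' @param evidence An `evolution_evidence` object supplying ortholog
#'   profiles.
#' @param species_ranks Data frame `species_id`, `depth_rank`.
#' @param seed Optional integer seed for reproducible tie-breaking.
#' @return The modified classification; relabeled rows get evidence
#'   `"progenitor"`.
#' @export
apply_progenitor_variant <- function(classification, evidence, species_ranks,
                                     seed = NULL) {
  if (is.null(species_ranks)) {
    stop("progenitor variant requires a species_ranks table", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  rank_of <- stats::setNames(as.numeric(species_ranks$depth_rank),
                             species_ranks$species_id)
  ort <- evidence$ortholog_profile
  ort <- ort[ort$gene_id %in% classification$gene_id, , drop = FALSE]
  depth <- tapply(rank_of[ort$species_id], ort$gene_id, max)
  fam_sizes <- table(classification$family_id)
  multi <- names(fam_sizes)[fam_sizes >= 2]
  n_nodata <- 0L
  for (f in multi) {
    members <- classification$gene_id[classification$family_id == f]
    d <- depth[members]
    if (all(is.na(d))) {
      n_nodata <- n_nodata + 1L
      cand <- members
    } else {
      d[is.na(d)] <- -Inf
      cand <- members[d == max(d)]
    }
    pick <- if (length(cand) == 1) cand else cand[sample.int(length(cand), 1)]
    i <- classification$gene_id == pick
    classification$origin[i] <- "novel"
    classification$evidence[i] <- "progenitor"
  }
  if (n_nodata > 0) {
    message(sprintf("%d famil(y/ies) had no ortholog data; progenitor chosen uniformly at random",
                    n_nodata))
  }
  classification
}

#' Compare two classifications
#'
#' Computes fractional agreement on the gene universe shared by both
#' inputs, separately for age and origin labels, with full
#' cross-tabulations.
#'
#' @param a,b `gene_classification` data frames.
#' @return List with `n_common`, `origin_agreement`, `age_agreement`,
#'   `origin_table`, `age_table`.
#' @export
compare_classifications <- function(a, b) {
  common <- intersect(a$gene_id, b$gene_id)
  if (length(common) == 0) {
    stop("the two classifications share no genes", call. = FALSE)
  }
  ai <- match(common, a$gene_id)
  bi <- match(common, b$gene_id)
  list(n_common = length(common),
       origin_agreement = mean(a$origin[ai] == b$origin[bi]),
       age_agreement = mean(a$age[ai] == b$age[bi]),
       origin_table = table(a = factor(a$origin[ai], ORIGIN_LEVELS),
                            b = factor(b$origin[bi], ORIGIN_LEVELS)),
       age_table = table(a = factor(a$age[ai], AGE_LEVELS),
                         b = factor(b$age[bi], AGE_LEVELS)))
}

#' Combined age/origin group labels
#'
#' @param classification A `gene_classification`.
#' @return Named character vector gene_id -> `"age/origin"` label.
#' @export
classification_groups <- function(classification) {
  stats::setNames(paste(classification$age, classification$origin, sep = "/"),
                  classification$gene_id)
}
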