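#' Venn partition of 2-3 feature sets
#'
#' Computes all `2^n - 1` disjoint regions of the sets (e.g. expressed
#' circRNAs, RNase R-enriched circRNAs, worse-prognosis circRNAs). Region
#' labels join set labels with `&`; counts sum to the size of the union and
#' each id falls in exactly one region.
#'
#' @param sets Named list of 2 or 3 character vectors of feature ids
#'   (duplicates within a set are dropped).
#' @return List with `counts` (named integer vector over regions) and
#'   `members` (named list of ids per region).
#' @export
venn_partition <- function(sets) {
  stopifnot(is.list(sets), length(sets) %in% 2:3, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  labels <- names(sets)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  counts <- integer(nrow(combos)); members <- vector("list", nrow(combos))
  region <- character(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    inn <- as.logical(combos[r, ])
    sel <- rep(TRUE, length(universe))
    for (j in seq_along(sets))
      sel <- sel & (member[, j] == inn[j])
    region[r] <- paste(labels[inn], collapse = "&")
    counts[r] <- sum(sel)
    members[[r]] <- universe[sel]
  }
  names(counts) <- region; names(members) <- region
  list(counts = counts, members = members)
}

# miRNA id normalization: case-insensitive, "hsa-" prefix stripped
normalize_mirna_id <- function(x) tolower(sub("^hsa-", "", x, ignore.case = TRUE))

#' Intersect circRNA-miRNA predictions from two algorithms
#'
#' A circRNA-miRNA pair is retained only when predicted by both sources
#' (e.g. miRanda and RNA22); single-algorithm predictions are dropped.
#' miRNA ids are matched case-insensitively with any `hsa-` prefix
#' stripped; the retained spelling is the first occurrence in the table.
#'
#' @param pred Data.frame with columns `circ_id`, `mirna_id`, `source`
#'   (exactly two distinct source labels expected) and optionally `score`.
#' @return Data.frame (`circ_id`, `mirna_id`) sorted by circRNA then miRNA,
#'   one row per retained pair.
#' @export
intersect_predictions <- function(pred) {
  stopifnot(all(c("circ_id", "mirna_id", "source") %in% names(pred)))
  empty <- data.frame(circ_id = character(0), mirna_id = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pred) == 0L) return(empty)
  srcs <- unique(pred$source)
  if (length(srcs) < 2L) {
    warning("prediction table has a single source (", srcs,
            "); intersection is empty")
    return(empty)
  }
  norm <- normalize_mirna_id(pred$mirna_id)
  key <- paste(pred$circ_id, norm, sep = "\r")
  n_src <- vapply(split(pred$source, key),
                  function(s) length(unique(s)), integer(1))
  keep_keys <- names(n_src)[n_src >= 2L]
  first <- !duplicated(key)
  out <- data.frame(circ_id = pred$circ_id[first],
                    mirna_id = sub("^hsa-", "", pred$mirna_id[first],
                                   ignore.case = TRUE),
                    key = key[first], stringsAsFactors = FALSE)
  out <- out[out$key %in% keep_keys, c("circ_id", "mirna_id")]
  out <- out[order(out$circ_id, tolower(out$mirna_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the circRNA-miRNA-mRNA (ceRNA) network
#'
#' A triplet `(circ, miRNA, gene)` is emitted iff the miRNA is an
#' intersected prediction for the circRNA, the miRNA is in the upregulated
#' set (up on circRNA knockdown, consistent with sponge release), the
#' miRNA-gene pair is in the target table, and the gene is in the
#' downregulated mRNA set. Passing `NULL` for `upreg_mirnas` or
#' `downreg_mrnas` skips that filter (the triplet list can only grow).
#' Optionally builds the circRNA-RBP edge list and reports RBPs shared by
#' every circRNA present.
#'
#' @param pred Intersected predictions ([intersect_predictions()] output or
#'   any data.frame with `circ_id`, `mirna_id`).
#' @param upreg_mirnas Character vector of upregulated miRNA ids, or `NULL`.
#' @param downreg_mrnas Character vector of downregulated gene ids, or `NULL`.
#' @param targets Data.frame with `mirna_id`, `target_gene` and optionally
#'   `evidence` (stands in for a miRNA target-filter export).
#' @param rbp_table Optional data.frame with `circ_id`, `rbp`.
#' @return List with `triplets` (data.frame `circ_id`, `mirna_id`,
#'   `target_gene`, `evidence`, deduplicated, alluvial-ready), `rbp_edges`
#'   (circos-ready data.frame or `NULL`) and `shared_rbps` (character).
#' @export
build_network <- function(pred, upreg_mirnas = NULL, downreg_mrnas = NULL,
                          targets, rbp_table = NULL) {
  stopifnot(all(c("circ_id", "mirna_id") %in% names(pred)),
            all(c("mirna_id", "target_gene") %in% names(targets)))
  pm <- normalize_mirna_id(pred$mirna_id)
  tm <- normalize_mirna_id(targets$mirna_id)
  keep_p <- rep(TRUE, nrow(pred))
  if (!is.null(upreg_mirnas))
    keep_p <- pm %in% normalize_mirna_id(upreg_mirnas)
  ev <- if ("evidence" %in% names(targets)) targets$evidence
        else rep("target_filter", nrow(targets))
  hits <- merge(
    data.frame(circ_id = pred$circ_id[keep_p], mirna_id = pred$mirna_id[keep_p],
               .m = pm[keep_p], stringsAsFactors = FALSE),
    data.frame(.m = tm, target_gene = targets$target_gene, evidence = ev,
               stringsAsFactors = FALSE),
    by = ".m")
  if (!is.null(downreg_mrnas))
    hits <- hits[hits$target_gene %in% downreg_mrnas, , drop = FALSE]
  trip <- unique(hits[, c("circ_id", "mirna_id", "target_gene", "evidence")])
  trip <- trip[order(trip$circ_id, tolower(trip$mirna_id), trip$target_gene), ,
               drop = FALSE]
  rownames(trip) <- NULL

  rbp_edges <- NULL; shared <- character(0)
  if (!is.null(rbp_table)) {
    stopifnot(all(c("circ_id", "rbp") %in% names(rbp_table)))
    rbp_edges <- unique(rbp_table[, c("circ_id", "rbp")])
    rbp_edges <- rbp_edges[order(rbp_edges$circ_id, rbp_edges$rbp), ,
                           drop = FALSE]
    rownames(rbp_edges) <- NULL
    by_circ <- split(rbp_edges$rbp, rbp_edges$circ_id)
    shared <- sort(Reduce(intersect, by_circ))
  }
  list(triplets = trip, rbp_edges = rbp_edges, shared_rbps = shared)
}
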