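#' Ranked gene list for one compound
#'
#' A prototype ranked list (PRL) is a total order over the genome by a
#' compound's transcriptional effect: rank 1 is the gene most upregulated by
#' the compound, the last rank the most downregulated.
#'
#' @param compound_id Compound identifier.
#' @param genes Character vector: the genome in ranked order, each gene
#'   exactly once.
#' @return Object of class `ranked_list`.
#' @export
ranked_list <- function(compound_id, genes) {
  genes <- as.character(genes)
  if (length(genes) < 1L) stopf("ranked list is empty")
  if (anyDuplicated(genes)) {
    stopf("ranked list for '%s' is not a permutation: duplicated gene(s)", compound_id)
  }
  structure(list(compound_id = as.character(compound_id), genes = genes,
                 n_genes = length(genes)),
            class = "ranked_list")
}

#' Extract a compound's up/down signature from the tails of its ranked list
#'
#' The top `tail_size` genes form the compound's upregulated set, the bottom
#' `tail_size` its downregulated set.
#'
#' @param rl A [ranked_list()].
#' @param tail_size Genes per tail; `2 * tail_size` must not exceed the
#'   genome size.
#' @return Object of class `compound_signature`: list with `compound_id`,
#'   `up_set`, `down_set`, `tail_size`.
#' @export
tails_to_signature <- function(rl, tail_size = 250) {
  if (!inherits(rl, "ranked_list")) stopf("'rl' must be a ranked_list")
  tail_size <- assert_count(tail_size, "tail_size", lower = 1)
  if (2L * tail_size > rl$n_genes) {
    stopf("tail_size %d too large for a %d-gene list", tail_size, rl$n_genes)
  }
  compound_signature(rl$compound_id,
                     up_set = utils::head(rl$genes, tail_size),
                     down_set = utils::tail(rl$genes, tail_size),
                     tail_size = tail_size)
}

#' Build a compound signature from explicit up/down gene sets
#'
#' Used when per-compound up/down gene-list files are supplied directly
#' instead of full ranked lists.
#'
#' @param compound_id Compound identifier.
#' @param up_set,down_set Disjoint character vectors of genes the compound
#'   up-/downregulates.
#' @param tail_size Optional record of the tail size the sets came from.
#' @return Object of class `compound_signature`.
#' @export
compound_signature <- function(compound_id, up_set, down_set, tail_size = NA_integer_) {
  up_set <- unique(as.character(up_set))
  down_set <- unique(as.character(down_set))
  if (length(intersect(up_set, down_set))) {
    stopf("up and down sets of '%s' overlap", compound_id)
  }
  structure(list(compound_id = as.character(compound_id), up_set = up_set,
                 down_set = down_set, tail_size = tail_size),
            class = "compound_signature")
}

#' Aggregate several ranked lists into a consensus ranking
#'
#' Mean-rank (Borda) aggregation over lists that are permutations of one
#' genome; output is ordered by ascending mean rank with ties broken
#' lexicographically by gene id.
#'
#' @param lists List of [ranked_list()] objects over the same genome.
#' @param compound_id Identifier for the aggregate list (default
#'   `"aggregate"`).
#' @return A [ranked_list()].
#' @export
aggregate_ranked_lists <- function(lists, compound_id = "aggregate") {
  if (!length(lists)) stopf("no ranked lists supplied")
  if (!all(vapply(lists, inherits, logical(1), "ranked_list"))) {
    stopf("'lists' must contain ranked_list objects")
  }
  genome <- sort(lists[[1]]$genes)
  for (rl in lists[-1]) {
    if (!identical(sort(rl$genes), genome)) {
      stopf("ranked lists are not permutations of the same genome ('%s' differs)",
            rl$compound_id)
    }
  }
  ranks <- vapply(lists, function(rl) match(genome, rl$genes), numeric(length(genome)))
  mean_rank <- if (is.matrix(ranks)) rowMeans(ranks) else ranks
  ord <- order(mean_rank, genome)
  ranked_list(compound_id, genome[ord])
}

#' Opposite-direction k-of-n voting between disease and compound signatures
#'
#' A disease-upregulated gene is selected when at least `k` compound
#' signatures downregulate it (contain it in their `down_set`); a
#' disease-downregulated gene when at least `k` signatures upregulate it.
#' Genes labelled `ns` in the DEG table are never selected, and same-direction
#' support never counts.
#'
#' @param deg Labelled DEG table (needs `gene` and `direction` columns, see
#'   [label_degs()]).
#' @param signatures List of [compound_signature()] objects.
#' @param k Minimum number of opposing compounds (default 4).
#' @return Data frame of reversal candidates: `gene`, `disease_direction`,
#'   `supporting_compounds` (count), `compounds` (comma-separated ids),
#'   ordered by direction, then decreasing support, then gene. The attribute
#'   `"counts"` holds `disease_up_reversed` and `disease_down_reversed`.
#' @export
vote_reversal <- function(deg, signatures, k = 4) {
  k <- assert_count(k, "k", lower = 1)
  if (!length(signatures)) stopf("no compound signatures supplied")
  if (!all(vapply(signatures, inherits, logical(1), "compound_signature"))) {
    stopf("'signatures' must contain compound_signature objects")
  }
  if (k > length(signatures)) {
    stopf("k = %d exceeds the number of signatures (%d)", k, length(signatures))
  }
  if (!all(c("gene", "direction") %in% names(deg))) {
    stopf("DEG table needs 'gene' and 'direction' columns")
  }
  ids <- vapply(signatures, `[[`, character(1), "compound_id")
  if (anyDuplicated(ids)) stopf("duplicate compound ids among signatures")

  select_side <- function(disease_genes, side, direction_label) {
    if (!length(disease_genes)) {
      return(data.frame(gene = character(), disease_direction = character(),
                        supporting_compounds = integer(), compounds = character(),
                        stringsAsFactors = FALSE))
    }
    # membership matrix: genes x signatures
    member <- vapply(signatures, function(sg) disease_genes %in% sg[[side]],
                     logical(length(disease_genes)))
    member <- matrix(member, nrow = length(disease_genes))
    support <- rowSums(member)
    sel <- which(support >= k)
    data.frame(
      gene = disease_genes[sel],
      disease_direction = rep(direction_label, length(sel)),
      supporting_compounds = as.integer(support[sel]),
      compounds = vapply(sel, function(i) {
        paste(sort(ids[member[i, ]]), collapse = ",")
      }, character(1)),
      stringsAsFactors = FALSE
    )
  }

  up_candidates <- select_side(deg$gene[deg$direction == "up"], "down_set", "up")
  down_candidates <- select_side(deg$gene[deg$direction == "down"], "up_set", "down")
  out <- rbind(down_candidates, up_candidates)
  out <- out[order(out$disease_direction, -out$supporting_compounds, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- list(
    disease_up_reversed = nrow(up_candidates),
    disease_down_reversed = nrow(down_candidates)
  )
  out
}
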