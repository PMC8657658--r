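#' Gene-set collection against a universe
#'
#' Harmonizes a list of annotated gene sets to a background universe: genes
#' outside the universe are dropped (with a message reporting how many), and
#' sets left empty are removed.
#'
#' @param sets List of sets, each a list with `id`, `name`, `genes` (as read
#'   by [read_gmt()]), or a named list of character vectors.
#' @param universe Character vector: the background gene universe.
#' @return Object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stopf("empty universe")
  if (!is.null(names(sets)) && all(vapply(sets, is.character, logical(1)))) {
    sets <- lapply(names(sets), function(id) list(id = id, name = id, genes = sets[[id]]))
  }
  dropped <- 0L
  harmonized <- lapply(sets, function(s) {
    genes <- unique(as.character(s$genes))
    keep <- genes %in% universe
    dropped <<- dropped + sum(!keep)
    list(id = s$id, name = s$name %||% s$id, genes = genes[keep])
  })
  empty <- vapply(harmonized, function(s) length(s$genes) == 0L, logical(1))
  if (dropped > 0L || any(empty)) {
    message(sprintf("gene_set_collection: dropped %d gene(s) outside the universe, %d empty set(s)",
                    dropped, sum(empty)))
  }
  harmonized <- harmonized[!empty]
  if (!length(harmonized)) stopf("no gene set survives harmonization to the universe")
  names(harmonized) <- vapply(harmonized, `[[`, character(1), "id")
  structure(list(sets = harmonized, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each annotated set, the upper-tail hypergeometric probability
#' `P(X >= x)` of drawing `x` or more of the set's `K` genes when sampling
#' the query's `n` genes from the `M`-gene universe (one-sided Fisher test).
#' Query genes outside the universe are dropped and counted. FDR by
#' Benjamini-Hochberg over all tested sets; results sorted by p.
#'
#' @param query Character vector of query genes (e.g. reversal candidates).
#' @param collection A [gene_set_collection()].
#' @return Data frame with `set_id`, `name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p`, `fdr`, sorted by ascending `p`.
#'   Attribute `"dropped_query_genes"` counts query genes outside the
#'   universe.
#' @export
hypergeom_enrich <- function(query, collection) {
  if (!inherits(collection, "gene_set_collection")) {
    stopf("'collection' must be a gene_set_collection")
  }
  query <- unique(as.character(query))
  in_universe <- query %in% collection$universe
  dropped <- sum(!in_universe)
  if (dropped > 0L) {
    message(sprintf("hypergeom_enrich: dropped %d query gene(s) outside the universe", dropped))
  }
  query <- query[in_universe]
  if (!length(query)) stopf("query is empty after harmonization to the universe")

  M <- length(collection$universe)
  n <- length(query)
  rows <- lapply(collection$sets, function(s) {
    K <- length(s$genes)
    x <- sum(query %in% s$genes)
    p <- stats::phyper(x - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set_id = s$id, name = s$name, overlap = x, set_size = K,
               query_size = n, universe_size = M, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out <- out[order(out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_query_genes") <- dropped
  out
}

#' Group redundant enriched sets by gene-membership overlap
#'
#' Greedy clustering of the significant results: sets are taken in order of
#' ascending p; each joins the first existing cluster whose representative
#' (its lowest-p member) has Jaccard similarity of member genes at or above
#' `similarity_cut`, otherwise it founds a new cluster. Deterministic given
#' the p-ordering.
#'
#' @param results Output of [hypergeom_enrich()].
#' @param collection The [gene_set_collection()] the results came from
#'   (supplies member genes).
#' @param similarity_cut Jaccard threshold in \[0, 1\] (default 0.3).
#' @param alpha FDR cut defining which sets are clustered (default 0.05).
#' @return Data frame with `cluster`, `set_id`, `name`, `p`, `fdr`,
#'   `representative` (logical); empty (zero rows) when nothing is
#'   significant.
#' @export
summarize_clusters <- function(results, collection, similarity_cut = 0.3,
                               alpha = 0.05) {
  if (!nrow(results)) stopf("'results' is empty")
  assert_number(similarity_cut, "similarity_cut", lower = 0, upper = 1)
  sig <- results[results$fdr < alpha, , drop = FALSE]
  empty <- data.frame(cluster = integer(), set_id = character(),
                      name = character(), p = numeric(), fdr = numeric(),
                      representative = logical(), stringsAsFactors = FALSE)
  if (!nrow(sig)) return(empty)
  sig <- sig[order(sig$p, sig$set_id), , drop = FALSE]

  genes_of <- function(id) collection$sets[[id]]$genes
  jaccard <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) return(0)
    length(intersect(a, b)) / u
  }
  cluster <- integer(nrow(sig))
  reps <- list()  # representative gene sets per cluster
  for (i in seq_len(nrow(sig))) {
    g <- genes_of(sig$set_id[i])
    assigned <- 0L
    for (cl in seq_along(reps)) {
      if (jaccard(reps[[cl]], g) >= similarity_cut) { assigned <- cl; break }
    }
    if (assigned == 0L) {
      reps[[length(reps) + 1L]] <- g
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  out <- data.frame(cluster = cluster, set_id = sig$set_id, name = sig$name,
                    p = sig$p, fdr = sig$fdr,
                    representative = !duplicated(cluster),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
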