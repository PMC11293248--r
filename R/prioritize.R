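#' DEG fraction among a gene's network neighbors
#'
#' First prioritization criterion: the share of a gene's adjacent genes
#' that are differentially expressed. An isolated gene scores 0 (so the
#' ranking stays total).
#'
#' @param network a `gene_network`.
#' @param deg_set character vector of DEG ids.
#' @param gene gene id (must be a network node).
#' @return ratio in `[0, 1]`.
#' @export
deg_neighbor_ratio <- function(network, deg_set, gene) {
  nb <- neighbors_of(network, gene)
  if (!length(nb)) return(0)
  length(intersect(nb, deg_set)) / length(nb)
}

#' Pathway membership count of a gene
#'
#' Second prioritization criterion: in how many annotated pathways the
#' gene participates.
#'
#' @param pathways a `pathway_map`.
#' @param gene gene id.
#' @return non-negative integer.
#' @export
pathway_count <- function(pathways, gene) {
  if (!length(pathways$sets)) return(0L)
  sum(vapply(pathways$sets, function(s) gene %in% s, TRUE))
}

#' Assemble the four-criteria priority table for DNB genes
#'
#' Per DNB gene: (1) DEG share among network neighbors, (2) pathway
#' membership count, (3) whether the gene is itself a DEG (0/1), (4)
#' whether it belongs to one of the temporal expression clusters (0/1,
#' with the cluster id reported when it does). Genes absent from the
#' network or annotation score 0 on the respective criterion, with a
#' warning.
#'
#' @param dnb_genes character vector of DNB gene ids (non-empty).
#' @param network a `gene_network`.
#' @param deg_result data.frame from [test_deg_across_time()] (columns
#'   `gene_id`, `is_deg`).
#' @param clusters optional named integer vector mapping clustered gene ids
#'   to cluster labels (e.g. hard labels of [fuzzy_cmeans()] named by
#'   gene); `NULL` for no cluster information.
#' @param pathways a `pathway_map`.
#' @return data.frame (one row per DNB gene) with columns `gene_id`,
#'   `criterion1` .. `criterion4`, `cluster_id`.
#' @export
build_priority_table <- function(dnb_genes, network, deg_result,
                                 clusters = NULL, pathways = pathway_map()) {
  if (!length(dnb_genes)) stop("empty DNB gene set")
  deg_set <- deg_result$gene_id[deg_result$is_deg]
  rows <- lapply(dnb_genes, function(g) {
    c1 <- if (g %in% network$nodes) deg_neighbor_ratio(network, deg_set, g)
    else {
      warning("gene absent from network, criterion 1 = 0: ", g)
      0
    }
    c2 <- pathway_count(pathways, g)
    c3 <- as.integer(g %in% deg_set)
    cl <- if (!is.null(clusters) && g %in% names(clusters))
      clusters[[g]] else NA_integer_
    data.frame(gene_id = g, criterion1 = c1, criterion2 = c2,
               criterion3 = c3, criterion4 = as.integer(!is.na(cl)),
               cluster_id = cl, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Rank DNB genes by the four prioritization criteria
#'
#' `"lexicographic"` (default) reads the criteria as strict priorities:
#' sort descending by criterion 1, then 2, 3, 4, with ties broken by
#' ascending gene id. `"ranksum"` averages the per-criterion descending
#' ranks (lower is better), same final tie-break.
#'
#' @param records data.frame from [build_priority_table()].
#' @param mode `"lexicographic"` or `"ranksum"`.
#' @return `records` reordered with a `rank` column (1 = top candidate).
#' @export
rank_dnb_genes <- function(records, mode = c("lexicographic", "ranksum")) {
  mode <- match.arg(mode)
  stopifnot(nrow(records) >= 1)
  if (mode == "lexicographic") {
    ord <- order(-records$criterion1, -records$criterion2,
                 -records$criterion3, -records$criterion4, records$gene_id)
  } else {
    per_rank <- function(v) rank(-v, ties.method = "average")
    score <- (per_rank(records$criterion1) + per_rank(records$criterion2) +
              per_rank(records$criterion3) + per_rank(records$criterion4)) / 4
    ord <- order(score, records$gene_id)
  }
  out <- records[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$mode <- mode
  rownames(out) <- NULL
  out
}
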