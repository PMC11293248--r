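#' Absolute correlations between a focal gene and all others at one time
#'
#' |Pearson r| between the focal gene and every other gene, computed over
#' the replicates of time `t`. Pairs involving a zero-variance gene are
#' recorded as 0.
#'
#' @param series an `expression_series`.
#' @param focal focal gene id.
#' @param t time index.
#' @return named numeric vector over the non-focal genes.
#' @export
focal_correlations <- function(series, focal, t) {
  if (!focal %in% series$gene_ids) stop("focal gene absent: ", focal)
  R <- pearson_matrix(series, t)
  v <- abs(R[focal, ])
  v[setdiff(names(v), focal)]
}

#' Aggregate per-month focal-gene correlation rankings
#'
#' Within each month genes are ranked by descending |r| (competition
#' ranking: ties share the smaller rank); the overall score is the mean
#' rank across months and the top `k` genes by ascending score are
#' returned (ties broken by gene id).
#'
#' @param cor_list list of named |r| vectors (one per month), identical
#'   gene sets.
#' @param k size of the reported top list (default 20).
#' @return data.frame with `gene_id`, per-month ranks, `score`, ordered by
#'   the overall ranking, truncated to `k` rows.
#' @export
aggregate_ranking <- function(cor_list, k = 20) {
  if (k < 1) stop("k must be >= 1")
  if (!length(cor_list)) stop("need >= 1 month of correlations")
  genes <- names(cor_list[[1]])
  ranks <- sapply(cor_list, function(v) {
    stopifnot(setequal(names(v), genes))
    rank(-v[genes], ties.method = "min")
  })
  ranks <- matrix(ranks, nrow = length(genes),
                  dimnames = list(genes, names(cor_list)))
  score <- rowMeans(ranks)
  ord <- order(score, genes)
  out <- data.frame(gene_id = genes[ord], ranks[ord, , drop = FALSE],
                    score = score[ord], row.names = NULL,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Correlation-weight proportions around the tipping point
#'
#' For each gene of `gene_set`, its share of the total correlation weight
#' to the focal gene: share_i = mean_months |r(focal, i)| normalized over
#' the evaluated set. The default months are the tipping month and the one
#' before it. When every weight is 0 the shares are uniform (flagged by a
#' warning).
#'
#' @param series an `expression_series`.
#' @param focal focal gene id.
#' @param gene_set non-empty character vector of evaluated genes.
#' @param months non-empty vector of time indices (default `c(t* - 1, t*)`
#'   cannot be derived here, so it must be supplied).
#' @return object of class `weight_proportion`: list with `shares` (named,
#'   summing to 1), `mean_weights`, `months`.
#' @export
weight_proportions <- function(series, focal, gene_set, months) {
  if (!length(gene_set)) stop("empty gene set")
  if (!length(months)) stop("no months given")
  W <- sapply(months, function(t) focal_correlations(series, focal, t)[gene_set])
  W <- matrix(W, nrow = length(gene_set),
              dimnames = list(gene_set, paste0("T", months)))
  mw <- rowMeans(W)
  tot <- sum(mw)
  shares <- if (tot == 0) {
    warning("all correlation weights are zero; uniform shares")
    stats::setNames(rep(1 / length(mw), length(mw)), names(mw))
  } else mw / tot
  structure(list(shares = shares, mean_weights = mw, months = months),
            class = "weight_proportion")
}

#' Focal-gene subnet summary across the time course
#'
#' Convenience wrapper reproducing the tipping-point subnet analysis: the
#' per-month |r| vectors for the focal gene, the aggregated overall top-k
#' ranking, and the correlation-weight shares of the top genes around the
#' tipping months.
#'
#' @param series an `expression_series`.
#' @param focal focal gene id.
#' @param tipping tipping time index (e.g. from [scan_time_points()]).
#' @param k aggregated top-list size (default 20).
#' @param n_weights how many top genes enter the weight-share panel
#'   (default 10).
#' @return list with `ranking` (data.frame), `weights`
#'   (`weight_proportion`), `months_used`.
#' @export
subnet_dynamics <- function(series, focal, tipping, k = 20, n_weights = 10) {
  times <- sort(unique(series$time))
  cor_list <- lapply(times, function(t) focal_correlations(series, focal, t))
  names(cor_list) <- paste0("T", times)
  ranking <- aggregate_ranking(cor_list, k = k)
  months <- intersect(c(tipping - 1L, tipping), times)
  top <- utils::head(ranking$gene_id, n_weights)
  list(ranking = ranking,
       weights = weight_proportions(series, focal, top, months),
       months_used = months)
}
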