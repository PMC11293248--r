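#' Dominant-group search configuration
#'
#' Knobs of the per-time dominant-group search behind [scan_time_points()].
#'
#' Two candidate-group sources are scored (their union) at every time point:
#'
#' * the classic recipe: genes whose SD at time t exceeds `sd_fold` times
#'   their baseline SD are clustered by average linkage on the distance
#'   1 - |r| computed from that time point's replicates, cut at
#'   `cut_height`;
#' * time-course modules: average-linkage clusters of the within-time-
#'   centred correlation matrix pooled over all samples, cut at
#'   `pooled_cut`. With few replicates the per-time correlation of
#'   unrelated genes is badly dispersed (at r = 4 the null |r| is uniform
#'   on \[0, 1\]), while the pooled estimate has many more degrees of
#'   freedom; scoring both sources makes the scan robust to either failure
#'   mode.
#'
#' `moderated` applies empirical-Bayes shrinkage (limma's `squeezeVar`) to
#' the per-gene baseline variances before the fold filter: with r - 1
#' degrees of freedom raw per-gene SDs produce an unacceptable
#' false-candidate rate.
#'
#' @param min_size smallest group reported (default 5).
#' @param sd_fold candidate SD-fold threshold vs baseline (default 2).
#' @param cut_height cut on the per-time 1 - |r| dendrogram (default 0.5).
#' @param pooled_cut cut on the pooled 1 - |r| dendrogram (default 0.65).
#' @param epsilon additive guard on the PCC_o denominator (default 1e-3).
#' @param baseline baseline time index (default 1).
#' @param use_pooled_modules logical; score pooled time-course modules in
#'   addition to the per-time clusters (default TRUE).
#' @param moderated logical; moderate baseline variances (default TRUE).
#' @return a `dominant_group_config` list.
#' @export
dominant_group_config <- function(min_size = 5, sd_fold = 2, cut_height = 0.5,
                                  pooled_cut = 0.65, epsilon = 1e-3,
                                  baseline = 1, use_pooled_modules = TRUE,
                                  moderated = TRUE) {
  stopifnot(min_size >= 2, sd_fold > 0, cut_height > 0, epsilon > 0)
  structure(as.list(environment()), class = "dominant_group_config")
}

#' Per-gene sample SD at one time point
#'
#' @param series an `expression_series`.
#' @param t time index with >= 2 replicates.
#' @return named numeric vector of sample SDs (denominator r - 1).
#' @export
per_time_sd <- function(series, t) {
  cols <- samples_at(series, t)
  if (length(cols) < 2) stop("time point ", t, " has < 2 replicates")
  stats::setNames(.row_sds(series$values[, cols, drop = FALSE]),
                  series$gene_ids)
}

# vectorized row-wise sample SD
.row_sds <- function(X) {
  sqrt(rowSums((X - rowMeans(X))^2) / (ncol(X) - 1L))
}

#' Pairwise Pearson correlation at one time point
#'
#' Correlations over the replicates of time `t`. Any pair involving a
#' zero-variance gene is recorded as 0 (those genes carry no correlation
#' information at that time point); the diagonal stays 1.
#'
#' @param series an `expression_series`.
#' @param t time index.
#' @param genes gene ids (default: all genes).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(series, t, genes = series$gene_ids) {
  cols <- samples_at(series, t)
  if (length(cols) < 2) stop("time point ", t, " has < 2 replicates")
  missing <- setdiff(genes, series$gene_ids)
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  X <- series$values[genes, cols, drop = FALSE]
  sds <- .row_sds(X)
  R <- suppressWarnings(stats::cor(t(X)))
  zero <- sds < .Machine$double.eps * 100
  if (any(zero)) {
    R[zero, ] <- 0
    R[, zero] <- 0
  }
  diag(R) <- 1
  R[!is.finite(R)] <- 0
  R
}

# |r| matrix from within-time-centred data pooled over the full course
pooled_pearson_matrix <- function(series, genes = series$gene_ids) {
  X <- series$values[genes, , drop = FALSE]
  for (t in unique(series$time)) {
    cols <- which(series$time == t)
    X[, cols] <- X[, cols, drop = FALSE] -
      rowMeans(X[, cols, drop = FALSE])
  }
  R <- suppressWarnings(stats::cor(t(X)))
  R[!is.finite(R)] <- 0
  diag(R) <- 1
  R
}

#' SD-fold candidate genes at one time point
#'
#' Genes whose SD at time `t` is at least `sd_fold` times their baseline
#' SD. With `moderated = TRUE` the baseline variances are shrunk toward a
#' common prior (limma empirical Bayes) before forming the denominator;
#' genes with an exactly zero baseline SD fall back to the global median
#' baseline SD.
#'
#' @param series an `expression_series`.
#' @param t time index (must differ from `baseline`).
#' @param baseline baseline time index.
#' @param sd_fold fold threshold (default 2).
#' @param moderated moderate the baseline variances (default TRUE).
#' @return character vector of candidate gene ids.
#' @export
candidate_genes <- function(series, t, baseline = 1, sd_fold = 2,
                            moderated = TRUE) {
  if (t == baseline) stop("candidate time must differ from baseline")
  den <- .baseline_sd_denominator(series, baseline, moderated)
  series$gene_ids[per_time_sd(series, t) / den >= sd_fold]
}

.baseline_sd_denominator <- function(series, baseline, moderated) {
  sd_b <- per_time_sd(series, baseline)
  if (moderated) {
    df <- length(samples_at(series, baseline)) - 1L
    den <- sqrt(limma::squeezeVar(sd_b^2, df)$var.post)
  } else den <- sd_b
  zero <- den < .Machine$double.eps * 100
  if (any(zero)) den[zero] <- stats::median(sd_b[!zero])
  den
}

#' Correlation clustering of candidate genes
#'
#' Average-linkage hierarchical clustering on the distance 1 - |r|, cut at
#' `cut_height`; groups smaller than `min_size` are discarded. Candidates
#' are ordered lexicographically before clustering so linkage ties resolve
#' deterministically.
#'
#' @param pcc_matrix correlation matrix covering at least the candidates
#'   (signed or absolute; absolute values are taken).
#' @param candidates character vector of candidate gene ids.
#' @param cut_height dendrogram cut on 1 - |r| (default 0.5).
#' @param min_size smallest group retained (default 5).
#' @return list of character vectors (possibly empty).
#' @export
cluster_candidates <- function(pcc_matrix, candidates, cut_height = 0.5,
                               min_size = 5) {
  candidates <- sort(unique(candidates))
  if (length(candidates) < min_size) return(list())
  D <- stats::as.dist(1 - abs(pcc_matrix[candidates, candidates]))
  lab <- stats::cutree(stats::hclust(D, method = "average"), h = cut_height)
  unname(Filter(function(g) length(g) >= min_size,
                split(candidates, lab)))
}

#' Criticality-index components of one gene group
#'
#' SD_i is the mean per-gene SD within the group, PCC_i the mean absolute
#' pairwise correlation within the group, PCC_o the mean absolute
#' correlation between group members and all non-members, and
#' CI = SD_i * PCC_i / (PCC_o + epsilon). A rising CI flags the critical
#' state ahead of a qualitative transition: member fluctuations and
#' mutual coupling grow while coupling to the rest of the system decays.
#'
#' @param sd_vector named per-gene SD vector covering all genes.
#' @param pcc_matrix correlation matrix over all genes (named dims).
#' @param group character vector of member gene ids (>= 2, and at least one
#'   non-member must exist).
#' @param epsilon additive guard on the denominator (default 1e-3).
#' @return object of class `ci_components`: list with `members`, `n`,
#'   `sd_in`, `pcc_in`, `pcc_out`, `ci`, `epsilon_guard` (TRUE when PCC_o
#'   underflowed to ~0 and the guard dominated).
#' @export
compute_ci <- function(sd_vector, pcc_matrix, group, epsilon = 1e-3) {
  group <- as.character(group)
  if (length(group) < 2) stop("group must have >= 2 members")
  all_genes <- names(sd_vector)
  outside <- setdiff(all_genes, group)
  if (!length(outside)) stop("PCC_o undefined: no non-member genes")
  A <- abs(pcc_matrix[group, group])
  sd_in <- mean(sd_vector[group])
  pcc_in <- mean(A[upper.tri(A)])
  pcc_out <- mean(abs(pcc_matrix[group, outside]))
  structure(list(members = group, n = length(group), sd_in = sd_in,
                 pcc_in = pcc_in, pcc_out = pcc_out,
                 ci = sd_in * pcc_in / (pcc_out + epsilon),
                 epsilon_guard = pcc_out < epsilon),
            class = "ci_components")
}

#' Scan all time points for the dominant group and the tipping point
#'
#' For every non-baseline time point the candidate groups (per-time SD-fold
#' clusters, plus pooled time-course modules when enabled; see
#' [dominant_group_config()]) are scored with [compute_ci()] on that time
#' point's replicate statistics, and the maximum-CI group is kept. The
#' baseline CI is defined as 0 with an empty group. The tipping point is
#' the argmax of the CI series (ties -> earliest time, flagged).
#'
#' @param series an `expression_series` with >= 3 time points.
#' @param config a `dominant_group_config`.
#' @return object of class `dnb_result`: list with `ci_table` (data.frame
#'   t, n, sd_in, pcc_in, pcc_out, ci), `groups` (per-time member vectors),
#'   `ci` (named CI series), `tipping` (time index or NA), `config`.
#' @export
scan_time_points <- function(series, config = dominant_group_config()) {
  validate_series(series)
  times <- sort(unique(series$time))
  if (length(times) < 3) stop("need >= 3 time points")
  baseline <- config$baseline
  pooled_mods <- list()
  if (isTRUE(config$use_pooled_modules)) {
    Rp <- pooled_pearson_matrix(series)
    pooled_mods <- cluster_candidates(Rp, series$gene_ids,
                                      cut_height = config$pooled_cut,
                                      min_size = config$min_size)
  }
  ci <- stats::setNames(numeric(length(times)), times)
  groups <- stats::setNames(vector("list", length(times)), times)
  comp_rows <- list()
  den <- .baseline_sd_denominator(series, baseline, config$moderated)
  for (t in setdiff(times, baseline)) {
    R <- pearson_matrix(series, t)
    sds <- per_time_sd(series, t)
    cand <- series$gene_ids[sds / den >= config$sd_fold]
    mods <- c(cluster_candidates(R, cand, cut_height = config$cut_height,
                                 min_size = config$min_size),
              pooled_mods)
    best <- NULL
    for (grp in mods) {
      cc <- compute_ci(sds, R, grp, epsilon = config$epsilon)
      if (is.null(best) || cc$ci > best$ci) best <- cc
    }
    if (!is.null(best)) {
      ci[as.character(t)] <- best$ci
      groups[[as.character(t)]] <- best$members
      comp_rows[[as.character(t)]] <-
        data.frame(t = t, n = best$n, sd_in = best$sd_in,
                   pcc_in = best$pcc_in, pcc_out = best$pcc_out, ci = best$ci)
    } else {
      comp_rows[[as.character(t)]] <-
        data.frame(t = t, n = 0L, sd_in = NA_real_, pcc_in = NA_real_,
                   pcc_out = NA_real_, ci = 0)
    }
  }
  comp_rows[[as.character(baseline)]] <-
    data.frame(t = baseline, n = 0L, sd_in = NA_real_, pcc_in = NA_real_,
               pcc_out = NA_real_, ci = 0)
  ci_table <- do.call(rbind, comp_rows)
  ci_table <- ci_table[order(ci_table$t), ]
  rownames(ci_table) <- NULL
  structure(list(ci_table = ci_table, groups = groups, ci = ci,
                 tipping = detect_tipping(ci), config = config),
            class = "dnb_result")
}

#' @export
print.dnb_result <- function(x, ...) {
  cat("dnb_result: CI series over", length(x$ci), "time points\n")
  print(round(x$ci, 3))
  cat("tipping point:",
      if (is.na(x$tipping)) "none detected" else x$tipping, "\n")
  invisible(x)
}

#' Tipping point of a CI series
#'
#' Index (time label) of the maximum CI; `NA` when every value is 0 (no
#' transition detected). Ties resolve to the earliest time, with a warning.
#'
#' @param ci_series numeric CI values; names, if present, are time labels.
#' @return integer time index or `NA`.
#' @export
detect_tipping <- function(ci_series) {
  if (!length(ci_series)) stop("empty CI series")
  if (all(ci_series == 0)) return(NA_integer_)
  labs <- if (!is.null(names(ci_series))) as.integer(names(ci_series))
          else seq_along(ci_series)
  hits <- which(ci_series == max(ci_series))
  if (length(hits) > 1) warning("CI tie; earliest time reported")
  labs[hits[1]]
}

#' Permutation significance of the observed CI peak
#'
#' Null distribution built by shuffling the sample-to-time assignment
#' (replicates reallocated across all samples) and re-running the full
#' scan; p = (1 + #(null peak >= observed peak)) / (n_perm + 1).
#'
#' The permutation null is "time plays no role at all": it is exact under
#' exchangeability of samples across time points. Note that strong mean
#' shifts between time points (ordinary differential expression) violate
#' that null by themselves — permutation then converts mean differences
#' into inflated within-group variances, which raises the null peaks and
#' makes the test conservative against a criticality signal riding on top
#' of widespread DE. Residualizing the means before permuting is not a
#' remedy at small r (within-time centring deflates mixed-group variances
#' by 1 - 1/r and the test becomes anticonservative), so the exact scheme
#' is kept and the limitation documented.
#'
#' @param series an `expression_series`.
#' @param config a `dominant_group_config`.
#' @param n_perm number of permutations (>= 19; default 99).
#' @param seed integer seed.
#' @return list with `p_value`, `observed_peak`, `null_peaks`.
#' @export
permutation_test <- function(series, config = dominant_group_config(),
                             n_perm = 99, seed = 1) {
  stopifnot(n_perm >= 19)
  observed <- max(scan_time_points(series, config)$ci)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  null_peaks <- vapply(seq_len(n_perm), function(i) {
    perm <- series
    perm$time <- sample(series$time)
    max(scan_time_points(perm, config)$ci)
  }, 0)
  list(p_value = (1 + sum(null_peaks >= observed)) / (n_perm + 1),
       observed_peak = observed, null_peaks = null_peaks)
}
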