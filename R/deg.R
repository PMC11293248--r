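#' Screen for differential expression across the time course
#'
#' Per-gene one-way ANOVA of expression against the time factor, with
#' Benjamini-Hochberg control of the false discovery rate. The F statistics
#' are computed row-wise from the group sums of squares (identical to
#' `anova(lm(...))` per gene, but vectorized over the matrix).
#'
#' With `moderated = TRUE` (default) the residual variances are shrunk
#' toward a common prior (limma's empirical Bayes, adding its prior
#' degrees of freedom to the denominator df) before forming F — at a
#' handful of replicates per time point the raw per-gene variance is too
#' unstable for a usable FDR cut. `moderated = FALSE` gives the plain
#' per-gene ANOVA.
#'
#' @param series an `expression_series` with >= 2 time points and >= 2
#'   replicates per time point.
#' @param fdr_threshold FDR cut for the `is_deg` flag (default 0.05).
#' @param moderated shrink residual variances before testing (default TRUE).
#' @return data.frame with columns `gene_id`, `statistic` (F), `p_value`,
#'   `q_value`, `is_deg`, `zero_variance`. Genes with zero total variance
#'   get p = 1 and are flagged.
#' @export
test_deg_across_time <- function(series, fdr_threshold = 0.05,
                                 moderated = TRUE) {
  validate_series(series)
  time <- series$time
  if (length(unique(time)) < 2) stop("need >= 2 time points")
  X <- series$values
  n <- ncol(X)
  k <- length(unique(time))
  grand <- rowMeans(X)
  ss_tot <- rowSums((X - grand)^2)
  ss_between <- numeric(nrow(X))
  for (t in unique(time)) {
    cols <- which(time == t)
    ss_between <- ss_between + length(cols) * (rowMeans(X[, cols, drop = FALSE]) - grand)^2
  }
  ss_within <- ss_tot - ss_between
  df1 <- k - 1L
  df2 <- n - k
  s2 <- ss_within / df2
  if (moderated) {
    sq <- limma::squeezeVar(s2, df2)
    Fstat <- (ss_between / df1) / sq$var.post
    df_den <- min(df2 + sq$df.prior, 1e6)
  } else {
    Fstat <- (ss_between / df1) / s2
    df_den <- df2
  }
  p <- stats::pf(Fstat, df1, df_den, lower.tail = FALSE)
  zero <- ss_tot < .Machine$double.eps * n
  # zero within-group variance but real between-group differences -> p ~ 0
  degenerate_within <- !zero & ss_within < .Machine$double.eps * n
  p[degenerate_within] <- 0
  Fstat[zero] <- 0
  p[zero] <- 1
  q <- bh_adjust(p)
  data.frame(gene_id = series$gene_ids, statistic = Fstat, p_value = p,
             q_value = q, is_deg = q < fdr_threshold, zero_variance = zero,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: q_(i) = min_{j >= i} m p_(j) / j, capped at 1,
#' returned in the input order. Delegates to `stats::p.adjust(method="BH")`.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-month DEG sets against a baseline month, with intersections
#'
#' For every non-baseline time point, a per-gene two-sided t-test of that
#' month's replicates against the baseline month, with BH adjustment
#' within each comparison; the DEG set is `q < fdr_threshold`. With
#' `moderated = TRUE` (default) a pooled-variance t with empirical-Bayes
#' variance shrinkage is used (the workable choice at a handful of
#' replicates); `moderated = FALSE` gives the plain Welch test with
#' Satterthwaite degrees of freedom. All pairwise
#' intersection sizes are tabulated (the UpSet-style summary) and the
#' comparison least similar to the others (smallest mean Jaccard; ties
#' broken toward the later month) is identified.
#'
#' @param series an `expression_series`.
#' @param baseline baseline time index (default 1).
#' @param fdr_threshold FDR cut (default 0.05).
#' @param moderated shrink variances before testing (default TRUE).
#' @return object of class `deg_set_comparison`: list with `sets` (named
#'   list of gene-id vectors), `set_sizes`, `intersections` (symmetric
#'   matrix of pairwise intersection sizes), `smallest_overlap` (comparison
#'   label) and `tests` (per-comparison statistics).
#' @export
deg_sets_vs_baseline <- function(series, baseline = 1, fdr_threshold = 0.05,
                                 moderated = TRUE) {
  validate_series(series)
  if (!baseline %in% series$time) stop("baseline time index not present")
  times <- setdiff(sort(unique(series$time)), baseline)
  X <- series$values
  base_cols <- samples_at(series, baseline)
  two_sample <- function(cols_a, cols_b) {
    a <- X[, cols_a, drop = FALSE]; b <- X[, cols_b, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    va <- rowSums((a - rowMeans(a))^2) / (na - 1)
    vb <- rowSums((b - rowMeans(b))^2) / (nb - 1)
    if (moderated) {
      pooled <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      sq <- limma::squeezeVar(pooled, na + nb - 2)
      tt <- (rowMeans(a) - rowMeans(b)) /
        sqrt(sq$var.post * (1 / na + 1 / nb))
      df <- rep(min(na + nb - 2 + sq$df.prior, 1e6), length(tt))
    } else {
      sa <- va / na; sb <- vb / nb
      tt <- (rowMeans(a) - rowMeans(b)) / sqrt(sa + sb)
      df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
    }
    p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    p[!is.finite(p)] <- 1        # zero variance in both groups
    list(t = tt, df = df, p = p)
  }
  sets <- list(); tests <- list()
  for (t in times) {
    w <- two_sample(samples_at(series, t), base_cols)
    q <- bh_adjust(w$p)
    lab <- sprintf("T%d vs T%d", t, baseline)
    sets[[lab]] <- series$gene_ids[q < fdr_threshold]
    tests[[lab]] <- data.frame(gene_id = series$gene_ids, statistic = w$t,
                               df = w$df, p_value = w$p, q_value = q,
                               stringsAsFactors = FALSE)
  }
  labs <- names(sets)
  m <- length(labs)
  inter <- matrix(0L, m, m, dimnames = list(labs, labs))
  for (i in seq_len(m)) for (j in seq_len(m))
    inter[i, j] <- length(intersect(sets[[i]], sets[[j]]))
  jac <- function(a, b) {
    u <- length(union(a, b))
    if (u == 0) 0 else length(intersect(a, b)) / u
  }
  score <- vapply(seq_len(m), function(i)
    mean(vapply(setdiff(seq_len(m), i), function(j)
      jac(sets[[i]], sets[[j]]), 0)), 0)
  if (m >= 2) {
    best <- which(score == min(score))
    smallest <- labs[best[length(best)]]   # tie -> later month
  } else smallest <- if (m == 1) labs else NA_character_
  structure(list(sets = sets, set_sizes = lengths(sets), intersections = inter,
                 overlap_score = stats::setNames(score, labs),
                 smallest_overlap = smallest, tests = tests),
            class = "deg_set_comparison")
}

#' Standardized temporal profiles
#'
#' Per gene: the mean expression within each time point, then centred and
#' scaled to mean 0 / SD 1 across time points (the usual soft-clustering
#' preprocessing). Genes whose time-mean profile has zero variance are
#' dropped with a warning.
#'
#' @param series an `expression_series`.
#' @param genes gene ids to profile (default: all).
#' @return numeric matrix genes x T of standardized profiles.
#' @export
standardize_profiles <- function(series, genes = series$gene_ids) {
  missing <- setdiff(genes, series$gene_ids)
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  times <- sort(unique(series$time))
  M <- sapply(times, function(t)
    rowMeans(series$values[genes, samples_at(series, t), drop = FALSE]))
  M <- matrix(M, nrow = length(genes),
              dimnames = list(genes, paste0("T", times)))
  sds <- apply(M, 1, stats::sd)
  drop <- sds < .Machine$double.eps * 100
  if (any(drop)) {
    warning(sum(drop), " constant profile(s) dropped")
    M <- M[!drop, , drop = FALSE]; sds <- sds[!drop]
  }
  (M - rowMeans(M)) / sds
}

#' Fuzzy c-means clustering of temporal profiles
#'
#' Standard fuzzy c-means on Euclidean distance: memberships
#' u_ik proportional to (1/d_ik^2)^(1/(m-1)), centroids as membership^m
#' weighted means, alternated until the objective improves by less than
#' `tol`. A profile falling exactly on a centroid takes membership 1 there.
#' Initialization draws `c` distinct profiles as starting centroids
#' (deterministic given `seed`).
#'
#' @param profiles numeric matrix (observations x dimensions), e.g. from
#'   [standardize_profiles()].
#' @param c number of clusters (default 9, the number of temporal patterns
#'   the pipeline reports).
#' @param m fuzzifier > 1 (default 2).
#' @param tol convergence tolerance on the objective (default 1e-8).
#' @param max_iter iteration cap (default 200).
#' @param seed integer seed for the centroid initialization.
#' @return object of class `cluster_assignment`: list with `membership`
#'   (rows sum to 1), `centers`, `cluster` (hard labels = argmax row),
#'   `iterations`, `objective` (final value) and `objective_trace`.
#' @export
fuzzy_cmeans <- function(profiles, c = 9, m = 2, tol = 1e-8,
                         max_iter = 200, seed = 1) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (c > n) stop("more clusters than profiles")
  stopifnot(c >= 1, m > 1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  centers <- profiles[sample.int(n, c), , drop = FALSE]
  obj_trace <- numeric(0)
  U <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(profiles^2), rep(1, c)) +
      outer(rep(1, n), rowSums(centers^2)) -
      2 * profiles %*% t(centers)
    d2[d2 < 0] <- 0
    U <- matrix(0, n, c)
    zero <- d2 < .Machine$double.eps
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      for (i in which(hit)) U[i, which(zero[i, ])[1]] <- 1
    }
    if (any(!hit)) {
      W <- (1 / d2[!hit, , drop = FALSE])^(1 / (m - 1))
      U[!hit, ] <- W / rowSums(W)
    }
    obj <- sum(U^m * d2)
    obj_trace <- c(obj_trace, obj)
    if (it > 1 && abs(obj_trace[it - 1] - obj) < tol) break
    Um <- U^m
    centers <- (t(Um) %*% profiles) / colSums(Um)
  }
  structure(list(membership = U, centers = centers,
                 cluster = max.col(U, ties.method = "first"),
                 iterations = length(obj_trace),
                 objective = obj_trace[length(obj_trace)],
                 objective_trace = obj_trace,
                 c = c, m = m), class = "cluster_assignment")
}
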