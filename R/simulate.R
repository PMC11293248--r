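#' Configuration for the synthetic critical-transition generator
#'
#' The generator emulates the study design the pipeline targets: T monthly
#' time points with r biological replicates each, a planted dynamic-network-
#' biomarker (DNB) module whose per-gene SD inflates and whose intra-module
#' correlation rises at a tipping time while its coupling to the background
#' drops, plus background differentially expressed genes (DEGs) whose mean
#' shifts are concentrated early (down) and at the tipping month (up).
#'
#' The three module effects map onto the three DNB criteria: `sd_fold`
#' (increased SD), `rho_in` (increased within-module correlation) and
#' `rho_out` (decreased module-to-background correlation). Off-tipping /
#' at-tipping values are given as length-2 vectors.
#'
#' `n_coupled` bounds how many background genes carry the `rho_out` coupling:
#' a module cannot correlate with an unlimited number of mutually independent
#' genes and stay positive semidefinite, so the coupling is placed on a small
#' background subset.
#'
#' @param n_genes total genes (default 500).
#' @param n_dnb planted module size (default 10).
#' @param n_time,n_rep time points and replicates per time point (8 x 4).
#' @param t_star tipping time index (default 6).
#' @param sigma0 baseline per-gene SD in log2 units (default 1).
#' @param sd_fold module SD inflation factor at `t_star` (default 3).
#' @param rho_in intra-module correlation off/at tipping (0.2 / 0.8).
#' @param rho_out module-to-coupled-background correlation off/at tipping
#'   (0.2 / 0.02).
#' @param n_coupled background genes carrying the `rho_out` coupling (5).
#' @param n_deg background DEGs (default 100) and `deg_shift` their mean
#'   shift in log2 units (default 2); half shift down at `deg_down_time`
#'   (default 2), half up at `deg_up_time` (default `t_star`).
#' @param deg_down_time,deg_up_time time indices carrying the DEG shifts.
#' @param er_prob background Erdos-Renyi edge probability (0.02).
#' @param k_top degree given to the planted top-priority gene (12).
#' @param enrich_top,enrich_other probability that a neighbor of the planted
#'   top gene / of another module gene is a DEG (0.9 / 0.2; the top gene's
#'   enrichment must exceed the others').
#' @param n_pathways,pathway_size pathway count and size range for the
#'   synthetic annotation.
#' @param extra_top_pathways additional pathway memberships granted to the
#'   planted top gene (it always ends strictly ahead of other module genes).
#' @param transition logical; `FALSE` produces a null series (no SD or
#'   correlation change at `t_star`) for calibration runs.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 500, n_dnb = 10, n_time = 8, n_rep = 4,
                              t_star = 6, sigma0 = 1, sd_fold = 3,
                              rho_in = c(0.2, 0.8), rho_out = c(0.2, 0.02),
                              n_coupled = 5, n_deg = 100, deg_shift = 2,
                              deg_down_time = 2, deg_up_time = t_star,
                              er_prob = 0.02, k_top = 12,
                              enrich_top = 0.9, enrich_other = 0.2,
                              n_pathways = 20, pathway_size = c(10, 50),
                              extra_top_pathways = 3, transition = TRUE) {
  cfg <- as.list(environment())
  stopifnot(n_dnb >= 2, n_dnb < n_genes, t_star >= 1, t_star <= n_time,
            sd_fold >= 1, all(abs(c(rho_in, rho_out)) < 1), n_rep >= 2,
            n_coupled >= 0, n_coupled <= n_genes - n_dnb,
            enrich_top > enrich_other)
  class(cfg) <- "simulation_config"
  cfg
}

#' Per-time covariance of the synthetic model
#'
#' Block covariance over genes at time `t`: the module block has diagonal
#' sigma(t)^2 and off-diagonal rho_in(t) sigma(t)^2; module genes correlate
#' rho_out(t) with the first `n_coupled` background genes; the remaining
#' background is independent with variance sigma0^2. sigma(t) = sigma0 *
#' sd_fold and the tipping correlation values apply iff `t == t_star` (and
#' the transition is enabled). Gene order here is canonical: module genes
#' first; [simulate_series()] maps blocks onto shuffled positions.
#'
#' @param config a `simulation_config`.
#' @param t time index.
#' @return symmetric positive-semidefinite covariance matrix
#'   (`n_genes` x `n_genes`). If the parameter combination is not PSD, a
#'   nearest-PSD repair is attempted via `Matrix::nearPD` (with a warning);
#'   an irreparable configuration is an error.
#' @export
build_covariance <- function(config, t) {
  at_tip <- config$transition && t == config$t_star
  s0 <- config$sigma0
  st <- if (at_tip) s0 * config$sd_fold else s0
  rin <- if (at_tip) config$rho_in[2] else config$rho_in[1]
  rout <- if (at_tip) config$rho_out[2] else config$rho_out[1]
  n <- config$n_genes
  k <- config$n_dnb
  S <- diag(rep(s0^2, n))
  S[1:k, 1:k] <- rin * st^2
  diag(S)[1:k] <- st^2
  if (config$n_coupled > 0) {
    cb <- k + seq_len(config$n_coupled)
    S[1:k, cb] <- rout * st * s0
    S[cb, 1:k] <- t(S[1:k, cb, drop = FALSE])
  }
  ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8) {
    warning("covariance not PSD (min eigenvalue ", signif(ev, 3),
            "); applying nearest-PSD repair")
    rep_ <- try(Matrix::nearPD(S, corr = FALSE, keepDiag = TRUE), silent = TRUE)
    if (inherits(rep_, "try-error"))
      stop("covariance configuration is not PSD-repairable")
    S <- as.matrix(rep_$mat)
  }
  S
}

# mean template per (gene position in canonical order) x time
.mean_templates <- function(config) {
  n <- config$n_genes; Tn <- config$n_time; k <- config$n_dnb
  mu <- matrix(0, n, Tn)
  if (config$n_deg > 0) {
    deg <- k + config$n_coupled + seq_len(config$n_deg)
    half <- ceiling(config$n_deg / 2)
    mu[deg[seq_len(half)], config$deg_down_time] <- -config$deg_shift
    if (config$n_deg > half)
      mu[deg[(half + 1):config$n_deg], config$deg_up_time] <- config$deg_shift
  }
  mu
}

#' Simulate a time-course expression series with a planted transition
#'
#' For each time point, `n_rep` samples are drawn from a multivariate normal
#' with the block covariance of [build_covariance()] and mean templates that
#' place the DEG shifts. Gene positions are shuffled (deterministically per
#' seed) so downstream order-invariance is exercised.
#'
#' @param config a `simulation_config`.
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `series` (an `expression_series`) and `truth` (class
#'   `simulation_truth`): planted module ids (`dnb_genes`), the planted
#'   top-priority gene (`top_gene`), `t_star`, DEG ids with template labels,
#'   and the covariance parameters used.
#' @export
simulate_series <- function(config, seed = 1) {
  stopifnot(inherits(config, "simulation_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  n <- config$n_genes; Tn <- config$n_time; r <- config$n_rep
  gene_ids <- sprintf("G%04d", seq_len(n))
  pos <- sample.int(n)              # canonical slot -> matrix row
  mu <- .mean_templates(config)
  safe_chol <- function(S) if (all(S == 0)) S else chol(S)
  ch_off <- safe_chol(build_covariance(config, if (config$t_star == 1) 2 else 1))
  ch_tip <- if (config$transition)
    safe_chol(build_covariance(config, config$t_star)) else ch_off
  X <- matrix(0, n, Tn * r)
  for (t in seq_len(Tn)) {
    ch <- if (config$transition && t == config$t_star) ch_tip else ch_off
    Z <- matrix(stats::rnorm(n * r), r, n)
    draws <- t(Z %*% ch) + mu[, t]   # canonical order
    X[pos, (t - 1L) * r + seq_len(r)] <- draws
  }
  rownames(X) <- gene_ids
  series <- expression_series(X, time = rep(seq_len(Tn), each = r),
                              sample_labels = sprintf("M%d_R%d",
                                rep(seq_len(Tn), each = r),
                                rep(seq_len(r), Tn)))
  k <- config$n_dnb
  dnb_genes <- gene_ids[pos[seq_len(k)]]
  half <- ceiling(config$n_deg / 2)
  deg_slots <- k + config$n_coupled + seq_len(config$n_deg)
  deg_genes <- gene_ids[pos[deg_slots]]
  truth <- structure(list(
    dnb_genes = dnb_genes,
    top_gene = dnb_genes[1],
    t_star = config$t_star,
    deg_genes = deg_genes,
    deg_pattern = stats::setNames(
      rep(c("down_early", "up_at_tipping"),
          c(half, config$n_deg - half))[seq_along(deg_genes)], deg_genes),
    coupled_genes = gene_ids[pos[k + seq_len(config$n_coupled)]],
    config = config), class = "simulation_truth")
  list(series = series, truth = truth)
}

#' Simulate a gene network consistent with a planted truth
#'
#' Erdos-Renyi background wiring; every planted module gene gets its
#' neighborhood redrawn so that each neighbor is a DEG with the configured
#' enrichment probability (`enrich_top` for the planted top gene, which gets
#' `k_top` neighbors; `enrich_other` for the rest). The top gene's DEG
#' enrichment is strictly higher by construction of the config.
#'
#' @param truth a `simulation_truth` from [simulate_series()].
#' @param config the same `simulation_config`.
#' @param seed integer seed.
#' @return a `gene_network` over all simulated genes.
#' @export
simulate_network <- function(truth, config, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  genes <- sort(c(truth$dnb_genes, truth$deg_genes, truth$coupled_genes,
                  sprintf("G%04d", seq_len(config$n_genes))))
  genes <- unique(genes)
  n <- length(genes)
  bg <- setdiff(genes, truth$dnb_genes)
  # background ER edges among non-module genes
  idx <- which(upper.tri(matrix(0, length(bg), length(bg))), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < config$er_prob
  edges <- cbind(bg[idx[keep, 1]], bg[idx[keep, 2]])
  # module neighborhoods with controlled DEG enrichment
  deg_pool <- setdiff(truth$deg_genes, truth$dnb_genes)
  nondeg_pool <- setdiff(bg, deg_pool)
  for (g in truth$dnb_genes) {
    k <- if (g == truth$top_gene) config$k_top
         else stats::rbinom(1, n - 1L, config$er_prob)
    if (k == 0) next
    p <- if (g == truth$top_gene) config$enrich_top else config$enrich_other
    n_deg_nb <- stats::rbinom(1, k, p)
    nb <- c(sample(deg_pool, min(n_deg_nb, length(deg_pool))),
            sample(nondeg_pool, min(k - n_deg_nb, length(nondeg_pool))))
    edges <- rbind(edges, cbind(g, nb))
  }
  gene_network(edges, nodes = genes)
}

#' Simulate pathway annotation consistent with a planted truth
#'
#' Random pathways of the configured sizes; the planted top gene is then
#' added to extra pathways until its membership count strictly exceeds that
#' of every other module gene (enforced postcondition).
#'
#' @param truth a `simulation_truth`.
#' @param config the same `simulation_config`.
#' @param seed integer seed.
#' @return a `pathway_map`.
#' @export
simulate_pathways <- function(truth, config, seed = 1) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  if (config$n_pathways == 0) return(pathway_map())
  genes <- sprintf("G%04d", seq_len(config$n_genes))
  size_range <- config$pathway_size[1]:config$pathway_size[2]
  sizes <- size_range[sample.int(length(size_range), config$n_pathways,
                                 replace = TRUE)]
  sets <- lapply(sizes, function(s) sample(genes, s))
  names(sets) <- sprintf("PW%03d", seq_along(sets))
  count_of <- function(g) sum(vapply(sets, function(s) g %in% s, TRUE))
  top <- truth$top_gene
  if (config$extra_top_pathways > 0) {
    # seed extra memberships, then enforce the strict maximum
    absent <- names(sets)[!vapply(sets, function(s) top %in% s, TRUE)]
    boost <- utils::head(absent, config$extra_top_pathways)
    for (p in boost) sets[[p]] <- c(sets[[p]], top)
    others <- setdiff(truth$dnb_genes, top)
    max_other <- if (length(others)) max(vapply(others, count_of, 1)) else 0
    absent <- names(sets)[!vapply(sets, function(s) top %in% s, TRUE)]
    i <- 1L
    while (count_of(top) <= max_other && i <= length(absent)) {
      sets[[absent[i]]] <- c(sets[[absent[i]]], top)
      i <- i + 1L
    }
    if (count_of(top) <= max_other)
      stop("cannot enforce top-gene pathway maximum: too few pathways")
  }
  pathway_map(sets, stats::setNames(rep("synthetic pathway", length(sets)),
                                    names(sets)))
}

#' Simulate a complete dataset (series, truth, network, pathways)
#'
#' @param config a `simulation_config`.
#' @param seed integer seed; stage seeds are derived deterministically.
#' @return list with `series`, `truth`, `network`, `pathways`.
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1) {
  sim <- simulate_series(config, seed = seed)
  list(series = sim$series, truth = sim$truth,
       network = simulate_network(sim$truth, config, seed = seed + 1L),
       pathways = simulate_pathways(sim$truth, config, seed = seed + 2L))
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
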