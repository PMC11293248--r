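# in-code fixtures shared across the suite

# tiny deterministic series: values chosen so SDs/correlations are exact
toy_series <- function() {
  vals <- rbind(
    g1 = c(1, 2, 3, 4),
    g2 = c(2, 4, 6, 8),       # 2 * g1 -> r = 1
    g3 = c(1, 1, 2, 2))       # r(g1, g3) = 2 / sqrt(5)
  expression_series(vals, time = rep(1L, 4))
}

# two well-separated correlated blocks at one time point
block_series <- function(n_rep = 8, seed = 42) {
  withr::with_seed(seed, {
    f1 <- rnorm(n_rep); f2 <- rnorm(n_rep)
    vals <- rbind(
      a1 = f1, a2 = f1 + rnorm(n_rep, sd = 1e-3), a3 = -f1 + rnorm(n_rep, sd = 1e-3),
      b1 = f2, b2 = f2 + rnorm(n_rep, sd = 1e-3), b3 = f2 + rnorm(n_rep, sd = 1e-3))
    expression_series(vals, time = rep(1L, n_rep))
  })
}

# random small series for property checks
random_series <- function(n_genes, n_time, n_rep, seed) {
  withr::with_seed(seed, {
    vals <- matrix(rnorm(n_genes * n_time * n_rep), n_genes)
    rownames(vals) <- sprintf("g%02d", seq_len(n_genes))
    colnames(vals) <- sprintf("M%d_R%d", rep(seq_len(n_time), each = n_rep),
                              rep(seq_len(n_rep), n_time))
    expression_series(vals, time = rep(seq_len(n_time), each = n_rep))
  })
}

small_sim_config <- function(...) {
  defaults <- list(n_genes = 80, n_dnb = 8, n_deg = 20, n_coupled = 3,
                   n_pathways = 8, pathway_size = c(5, 15))
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}

# independent adjusted Rand index (contingency-table formula)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}
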