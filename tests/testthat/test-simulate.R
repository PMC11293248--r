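test_that("covariance blocks carry the configured values and stay PSD", {
  cfg <- simulation_config()
  S_off <- build_covariance(cfg, 2)
  expect_equal(unname(diag(S_off)[1:10]), rep(1, 10))
  expect_equal(S_off[1, 2], 0.2)
  expect_equal(S_off[1, 11], 0.2)      # coupled background gene
  expect_equal(S_off[11, 12], 0)       # background independent
  S_tip <- build_covariance(cfg, cfg$t_star)
  expect_equal(unname(diag(S_tip)[1:10]), rep(9, 10))
  expect_equal(S_tip[1, 2], 0.8 * 9)
  for (t in c(1, 2, cfg$t_star, cfg$n_time)) {
    ev <- eigen(build_covariance(cfg, t), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
})

test_that("simulation is deterministic given the seed", {
  cfg <- small_sim_config()
  a <- simulate_dataset(cfg, seed = 3)
  b <- simulate_dataset(cfg, seed = 3)
  expect_identical(a$series$values, b$series$values)
  expect_identical(a$truth$dnb_genes, b$truth$dnb_genes)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$pathways$sets, b$pathways$sets)
  c <- simulate_series(cfg, seed = 4)
  expect_false(identical(a$series$values, c$series$values))
})

test_that("zero-noise simulation reproduces the mean templates exactly", {
  cfg <- small_sim_config(sigma0 = 0, rho_in = c(0, 0), rho_out = c(0, 0))
  sim <- simulate_series(cfg, seed = 1)
  down <- names(sim$truth$deg_pattern)[sim$truth$deg_pattern == "down_early"]
  up <- names(sim$truth$deg_pattern)[sim$truth$deg_pattern == "up_at_tipping"]
  expect_true(all(sim$series$values[down, samples_at(sim$series, 2)] == -2))
  expect_true(all(sim$series$values[up, samples_at(sim$series, 6)] == 2))
  other <- setdiff(sim$series$gene_ids, c(down, up))
  expect_true(all(sim$series$values[other, ] == 0))
})

test_that("empirical moments match the planted covariance", {
  # moments are independent of the background size; a small gene count keeps
  # the 200-seed Monte-Carlo average fast
  cfg <- simulation_config(n_genes = 60, n_dnb = 10, n_deg = 10)
  sds <- c(); cors <- c()
  for (s in 1:200) {
    sim <- simulate_series(cfg, seed = s)
    cols <- samples_at(sim$series, cfg$t_star)
    X <- sim$series$values[sim$truth$dnb_genes, cols]
    sds <- c(sds, apply(X, 1, sd))
    R <- cor(t(X))
    cors <- c(cors, mean(R[upper.tri(R)]))
  }
  pooled_sd <- sqrt(mean(sds^2))
  expect_lt(abs(pooled_sd - 3) / 3, 0.15)
  expect_lt(abs(mean(cors) - 0.8), 0.1)
})

test_that("truth ids are consistent across series, network and pathways", {
  ds <- simulate_dataset(small_sim_config(), seed = 9)
  expect_true(all(ds$truth$dnb_genes %in% ds$series$gene_ids))
  expect_true(ds$truth$top_gene %in% ds$truth$dnb_genes)
  expect_true(all(ds$truth$deg_genes %in% ds$series$gene_ids))
  expect_true(all(ds$network$nodes %in% ds$series$gene_ids))
  expect_true(all(unlist(ds$pathways$sets) %in% ds$series$gene_ids))
})

test_that("network enrichment singles out the planted top gene", {
  cfg <- small_sim_config(enrich_top = 1.0)
  sim <- simulate_series(cfg, seed = 5)
  net <- simulate_network(sim$truth, cfg, seed = 6)
  nb <- neighbors_of(net, sim$truth$top_gene)
  expect_true(all(nb %in% sim$truth$deg_genes))      # enrichment 1.0
  # default config: top gene's DEG-neighbor ratio beats the other module
  # genes' median ratio in nearly every draw
  cfg <- small_sim_config()
  wins <- 0
  for (s in 1:20) {
    sim <- simulate_series(cfg, seed = 100 + s)
    net <- simulate_network(sim$truth, cfg, seed = 200 + s)
    ratio <- function(g) deg_neighbor_ratio(net, sim$truth$deg_genes, g)
    top <- ratio(sim$truth$top_gene)
    rest <- vapply(setdiff(sim$truth$dnb_genes, sim$truth$top_gene), ratio, 0)
    if (top > median(rest)) wins <- wins + 1
  }
  expect_gte(wins, 18)
})

test_that("pathway annotation gives the top gene a strict maximum", {
  cfg <- small_sim_config()
  sim <- simulate_series(cfg, seed = 7)
  pm <- simulate_pathways(sim$truth, cfg, seed = 8)
  counts <- vapply(sim$truth$dnb_genes, function(g) pathway_count(pm, g), 0L)
  top <- counts[[sim$truth$top_gene]]
  expect_gt(top, max(counts[names(counts) != sim$truth$top_gene]))
  # degenerate configs
  cfg0 <- small_sim_config(n_pathways = 0)
  expect_length(simulate_pathways(sim$truth, cfg0, seed = 1)$sets, 0)
  cfg1 <- simulation_config(n_genes = 30, n_dnb = 5, n_deg = 5, n_coupled = 2,
                            n_pathways = 1, pathway_size = c(30, 30),
                            extra_top_pathways = 0)
  sim1 <- simulate_series(cfg1, seed = 2)
  pm1 <- simulate_pathways(sim1$truth, cfg1, seed = 3)
  counts <- vapply(sim1$series$gene_ids, function(g) pathway_count(pm1, g), 0L)
  expect_true(all(counts == 1L))
})
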