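test_that("per-time SDs follow the sample formula and scale homogeneously", {
  s <- toy_series()
  sds <- per_time_sd(s, 1)
  expect_equal(unname(sds["g1"]), sqrt(sum((1:4 - 2.5)^2) / 3))
  expect_equal(unname(sds["g1"]), 1.2909944, tolerance = 1e-7)
  s2 <- s; s2$values <- 2 * s$values
  expect_equal(per_time_sd(s2, 1), 2 * sds)
  sc <- expression_series(rbind(k = rep(3, 4)), rep(1, 4))
  expect_equal(unname(per_time_sd(sc, 1)), 0)
})

test_that("pearson matrix handles perfect, anti- and degenerate correlation", {
  s <- toy_series()
  R <- pearson_matrix(s, 1)
  expect_equal(R["g1", "g2"], 1)
  expect_equal(R["g1", "g3"], 2 / sqrt(5))
  expect_equal(R["g1", "g3"], 0.894427, tolerance = 1e-6)
  expect_equal(R, t(R))
  expect_true(all(diag(R) == 1))
  expect_true(all(R >= -1 & R <= 1))
  neg <- expression_series(rbind(a = c(1, 2, 3, 4), b = -c(1, 2, 3, 4) + 7),
                           rep(1, 4))
  expect_equal(pearson_matrix(neg, 1)["a", "b"], -1)
  dg <- expression_series(rbind(a = c(1, 2, 3, 4), z = rep(2, 4)), rep(1, 4))
  expect_equal(pearson_matrix(dg, 1)["a", "z"], 0)
})

test_that("SD-fold candidate selection includes and excludes as specified", {
  vals <- rbind(up = c(1, 2, 3, 4, 1, 4, 7, 10),   # SD triples at t = 2
                flat = c(1, 2, 3, 4, 1, 2, 3, 4))  # SD unchanged
  s <- expression_series(vals, time = rep(1:2, each = 4))
  cand <- candidate_genes(s, 2, baseline = 1, sd_fold = 2, moderated = FALSE)
  expect_true("up" %in% cand)
  expect_false("flat" %in% cand)
})

test_that("correlation clustering recovers blocks and respects min size", {
  s <- block_series()
  R <- pearson_matrix(s, 1)
  groups <- cluster_candidates(R, rownames(s$values), cut_height = 0.5,
                               min_size = 2)
  expect_equal(length(groups), 2L)
  expect_setequal(groups[[which(vapply(groups, function(g) "a1" %in% g, TRUE))]],
                  c("a1", "a2", "a3"))
  # all mutually perfect -> one group
  ident <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_equal(length(cluster_candidates(ident, letters[1:4], min_size = 2)), 1L)
  expect_equal(cluster_candidates(R, c("a1", "a2"), min_size = 5), list())
})

test_that("the worked criticality-index example evaluates exactly", {
  s <- toy_series()
  sds <- per_time_sd(s, 1)
  R <- pearson_matrix(s, 1)
  cc <- compute_ci(sds, R, c("g1", "g2"), epsilon = 1e-3)
  expect_equal(cc$sd_in, (1.2909944 + 2.5819889) / 2, tolerance = 1e-6)
  expect_equal(cc$pcc_in, 1)
  expect_equal(cc$pcc_out, 0.894427, tolerance = 1e-6)
  expect_equal(cc$ci, cc$sd_in * 1 / (cc$pcc_out + 1e-3))
  expect_equal(cc$ci, 2.16268, tolerance = 1e-4)
  # doubling the data doubles CI (correlations unchanged)
  s2 <- s; s2$values <- 2 * s$values
  cc2 <- compute_ci(per_time_sd(s2, 1), pearson_matrix(s2, 1), c("g1", "g2"))
  expect_equal(cc2$ci, 2 * cc$ci, tolerance = 1e-12)
  expect_error(compute_ci(sds, R, "g1"), ">= 2")
  expect_error(compute_ci(sds, R, c("g1", "g2", "g3")), "no non-member")
})

test_that("the epsilon guard takes over when outside correlation vanishes", {
  dg <- expression_series(rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8),
                                z = rep(1, 4)), rep(1, 4))
  cc <- compute_ci(per_time_sd(dg, 1), pearson_matrix(dg, 1), c("a", "b"),
                   epsilon = 1e-3)
  expect_true(cc$epsilon_guard)
  expect_equal(cc$ci, cc$sd_in * cc$pcc_in / 1e-3)
})

test_that("CI is monotone in within-group and out-group correlation", {
  sds <- setNames(rep(1, 6), letters[1:6])
  make_R <- function(rin, rout) {
    R <- diag(6)
    R[1:3, 1:3] <- rin; diag(R) <- 1
    R[1:3, 4:6] <- rout; R[4:6, 1:3] <- rout
    dimnames(R) <- list(letters[1:6], letters[1:6])
    R
  }
  ci_at <- function(rin, rout)
    compute_ci(sds, make_R(rin, rout), c("a", "b", "c"))$ci
  rins <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(vapply(rins, ci_at, 0, rout = 0.3)) >= 0))
  routs <- seq(0.05, 0.9, by = 0.05)
  expect_true(all(diff(vapply(routs, function(ro) ci_at(0.5, ro), 0)) <= 0))
})

test_that("tipping detection is the argmax with documented edge cases", {
  expect_equal(detect_tipping(c(0, 0.5, 0.4, 3.1, 0.2, 8.9, 1.0, 0.7)), 6L)
  expect_true(is.na(detect_tipping(rep(0, 5))))
  expect_warning(tie <- detect_tipping(c(1, 3, 3)), "tie")
  expect_equal(tie, 2L)
  named <- setNames(c(0, 2, 5), c(2, 4, 6))
  expect_equal(detect_tipping(named), 6L)
})

test_that("the scan finds the planted tipping point and is order-invariant", {
  cfg <- simulation_config(n_genes = 150, n_dnb = 10, n_deg = 30)
  sim <- simulate_series(cfg, seed = 2)
  res <- scan_time_points(sim$series)
  expect_equal(res$tipping, cfg$t_star)
  expect_equal(unname(res$ci[as.character(res$tipping)]), max(res$ci))
  expect_equal(res$ci_table$ci[res$ci_table$t == 1], 0)
  # permute genes and samples: identical CI series
  perm <- sim$series
  gp <- withr::with_seed(5, sample(nrow(perm$values)))
  sp <- withr::with_seed(6, sample(ncol(perm$values)))
  perm <- expression_series(perm$values[gp, sp], time = perm$time[sp],
                            replicate = perm$replicate[sp])
  res2 <- scan_time_points(perm)
  expect_equal(res2$ci, res$ci, tolerance = 1e-12)
  expect_setequal(res2$groups[[as.character(res2$tipping)]],
                  res$groups[[as.character(res$tipping)]])
})

test_that("a featureless series reports no transition", {
  s <- random_series(30, 4, 3, seed = 77)
  res <- scan_time_points(s, dominant_group_config(min_size = 25))
  expect_true(all(res$ci == 0))
  expect_true(is.na(res$tipping))
})

test_that("permutation p-values are deterministic, bounded and well-formed", {
  cfg <- simulation_config(n_genes = 60, n_dnb = 8, n_deg = 10, n_coupled = 3)
  sim <- simulate_series(cfg, seed = 3)
  p1 <- permutation_test(sim$series, n_perm = 19, seed = 11)
  p2 <- permutation_test(sim$series, n_perm = 19, seed = 11)
  expect_identical(p1, p2)
  expect_gte(p1$p_value, 1 / 20)
  expect_lte(p1$p_value, 1)
  expect_equal(p1$p_value,
               (1 + sum(p1$null_peaks >= p1$observed_peak)) / 20)
  expect_error(permutation_test(sim$series, n_perm = 5), "19")
})
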