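test_that("degenerate genes get p = 1 and identical group means give F = 0", {
  vals <- rbind(const = rep(5, 6), flat = c(1, 2, 3, 1, 2, 3))
  s <- expression_series(vals, time = rep(1:2, each = 3))
  res <- test_deg_across_time(s, moderated = FALSE)
  expect_equal(res$p_value[res$gene_id == "const"], 1)
  expect_false(res$is_deg[res$gene_id == "const"])
  expect_true(res$zero_variance[res$gene_id == "const"])
  expect_equal(res$statistic[res$gene_id == "flat"], 0)
  expect_equal(res$p_value[res$gene_id == "flat"], 1)
})

test_that("row-wise ANOVA matches per-gene lm/anova to 1e-10", {
  s <- random_series(20, 3, 4, seed = 21)
  res <- test_deg_across_time(s, moderated = FALSE)
  grp <- factor(s$time)
  for (i in seq_len(20)) {
    a <- anova(lm(s$values[i, ] ~ grp))
    expect_equal(res$statistic[i], a[["F value"]][1], tolerance = 1e-10)
    expect_equal(res$p_value[i], a[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("BH adjustment reproduces the step-up definition", {
  expect_equal(bh_adjust(rep(0.01, 10)), rep(0.01, 10))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # brute-force step-up oracle on random vectors
  brute_bh <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- numeric(m)
    for (i in seq_len(m))
      q[o[i]] <- min(1, min(m * p[o][i:m] / (i:m)))
    q
  }
  withr::with_seed(99, {
    for (rep in 1:200) {
      p <- runif(sample(1:30, 1))
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
      q <- bh_adjust(p)
      expect_true(all(q >= p - 1e-15))
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
    }
  })
})

test_that("per-month DEG sets recover the planted directional shifts", {
  ds <- simulate_dataset(simulation_config(), seed = 12)
  sets <- deg_sets_vs_baseline(ds$series)
  down <- names(ds$truth$deg_pattern)[ds$truth$deg_pattern == "down_early"]
  up <- names(ds$truth$deg_pattern)[ds$truth$deg_pattern == "up_at_tipping"]
  s2 <- sets$sets[["T2 vs T1"]]
  s6 <- sets$sets[["T6 vs T1"]]
  expect_gt(mean(down %in% s2), 0.2)          # real power at r = 4
  expect_gt(mean(up %in% s6), 0.2)
  fp <- setdiff(s2, down)
  expect_lt(length(fp) / max(1, length(s2)), 0.35)
  # intersection bookkeeping
  expect_true(all(sets$intersections <= outer(sets$set_sizes, sets$set_sizes,
                                              pmin)))
  expect_equal(unname(diag(sets$intersections)), unname(sets$set_sizes))
})

test_that("identical and disjoint DEG sets give the expected intersections", {
  # big shifts so sets are exact: genes d1,d2 move at t=2 and t=3 alike
  vals <- rbind(d1 = c(0, 0, 0, 9, 9, 9, 9, 9, 9),
                d2 = c(0, 0, 0, 9, 9, 9, 9, 9, 9),
                n1 = rep(c(0.1, -0.1, 0), 3))
  s <- expression_series(vals + matrix(rnorm(27, sd = 0.01), 3), rep(1:3, each = 3))
  sets <- deg_sets_vs_baseline(s, fdr_threshold = 0.2)
  expect_setequal(sets$sets[["T2 vs T1"]], c("d1", "d2"))
  expect_equal(sets$intersections["T2 vs T1", "T3 vs T1"],
               length(intersect(sets$sets[[1]], sets$sets[[2]])))
})

test_that("standardized profiles have zero mean and unit SD per gene", {
  s <- random_series(10, 8, 3, seed = 31)
  prof <- standardize_profiles(s)
  expect_equal(ncol(prof), 8)
  expect_true(all(abs(rowMeans(prof)) < 1e-12))
  expect_true(all(abs(apply(prof, 1, sd) - 1) < 1e-12))
  vals <- rbind(lin = rep(1:4, each = 2), const = rep(3, 8))
  s2 <- expression_series(vals, time = rep(1:4, each = 2))
  expect_warning(p2 <- standardize_profiles(s2), "constant")
  expect_equal(rownames(p2), "lin")
})

test_that("fuzzy c-means satisfies its contracts and recovers separation", {
  prof <- random_series(30, 5, 2, seed = 41)
  P <- standardize_profiles(prof)
  fit1 <- fuzzy_cmeans(P, c = 1)
  expect_true(all(fit1$membership == 1))
  expect_equal(drop(fit1$centers), colMeans(P), tolerance = 1e-12)
  # two far-separated groups -> exact recovery
  withr::with_seed(7, {
    X <- rbind(matrix(rnorm(20 * 4, mean = 0, sd = 0.05), 20),
               matrix(rnorm(20 * 4, mean = 5, sd = 0.05), 20))
  })
  truthlab <- rep(1:2, each = 20)
  fit2 <- fuzzy_cmeans(X, c = 2, seed = 3)
  expect_equal(ari(fit2$cluster, truthlab), 1)
  # invariants on arbitrary inputs
  for (sd_ in 1:3) {
    Y <- matrix(rnorm(40 * 6, sd = sd_), 40)
    fit <- fuzzy_cmeans(Y, c = 4, seed = sd_)
    expect_true(all(abs(rowSums(fit$membership) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    expect_true(all(fit$cluster %in% 1:4))
  }
  expect_error(fuzzy_cmeans(X, c = 100), "more clusters")
  # a profile sitting exactly on a centroid takes membership 1
  Z <- rbind(c(0, 0), c(0, 0), c(3, 3), c(3.5, 3))
  fit <- fuzzy_cmeans(Z, c = 2, seed = 1, max_iter = 50)
  on_center <- apply(fit$membership, 1, max)
  expect_true(any(on_center > 1 - 1e-9))
})

test_that("fuzzy c-means agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  withr::with_seed(17, {
    X <- rbind(matrix(rnorm(25 * 3, 0, 0.3), 25),
               matrix(rnorm(25 * 3, 4, 0.3), 25))
  })
  ours <- fuzzy_cmeans(X, c = 2, m = 2, seed = 2)
  ref <- e1071::cmeans(X, centers = 2, m = 2)
  expect_equal(ari(ours$cluster, ref$cluster), 1)
  expect_equal(unname(sort(rowMeans(ours$centers))),
               unname(sort(rowMeans(ref$centers))), tolerance = 0.05)
})
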