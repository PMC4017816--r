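test_that("fisher_z behaves like atanh with domain checks", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493061, tolerance = 1e-6)
  rs <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-rs), -fisher_z(rs))
  # round trip with the inverse to 1e-12
  rr <- seq(-0.999, 0.999, length.out = 201)
  expect_equal(fisher_z_inv(fisher_z(rr)), rr, tolerance = 1e-12)
  expect_error(fisher_z(1), "< 1")
  expect_error(fisher_z(-1.2), "< 1")
})

test_that("one_sample_t matches the reference implementation", {
  r <- one_sample_t(c(1, 2, 3))
  expect_equal(r$t, 3.4641016, tolerance = 1e-6)
  expect_identical(r$df, 2L)
  set.seed(51)
  for (i in 1:100) {
    v <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    mine <- one_sample_t(v)
    ref <- t.test(v)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
  # sign flip negates t, preserves p
  v <- rnorm(10)
  expect_equal(one_sample_t(-v)$t, -one_sample_t(v)$t)
  expect_equal(one_sample_t(-v)$p, one_sample_t(v)$p)
  expect_error(one_sample_t(rep(2, 5), mu0 = 2), "zero")
  expect_error(one_sample_t(1), "at least 2")
})

test_that("bonferroni_threshold is alpha/m", {
  expect_equal(bonferroni_threshold(0.05, 60), 0.05 / 60)
  expect_equal(signif(bonferroni_threshold(0.05, 60), 3), 8.33e-4)
  expect_equal(signif(bonferroni_threshold(0.05, 15), 2), 0.0033)
  expect_identical(bonferroni_threshold(0.17, 1), 0.17)
  expect_error(bonferroni_threshold(0, 5), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "m must")
})

test_that("correlation_table recovers induced inter-network correlation", {
  set.seed(52)
  n_sub <- 24; n <- 228
  make_cohort <- function(rho) {
    lapply(seq_len(n_sub), function(s) {
      base <- rnorm(n)
      m <- sapply(1:6, function(j)
        if (j <= 2) sqrt(rho) * base + sqrt(1 - rho) * rnorm(n) else rnorm(n))
      colnames(m) <- c("aDMN", "pDMN", "SAL", "DAN", "LECN", "RECN")
      m
    })
  }
  tab <- correlation_table(make_cohort(0.3))
  expect_identical(nrow(tab), 15L)
  expect_identical(anyDuplicated(tab$pair), 0L)
  expect_equal(tab$p_threshold[1], 0.05 / 15)
  # the aDMN-pDMN pair carries correlation rho = 0.3; Monte-Carlo CI around
  # atanh(0.3) with sd ~ 1/sqrt(n-3) / sqrt(n_sub)
  row <- tab[tab$pair == "aDMNxpDMN", ]
  se <- 1 / sqrt(n - 3) / sqrt(n_sub)
  expect_lt(abs(row$mean_z - atanh(0.3)), 4 * se)
  expect_true(row$significant)
  # independent pairs: small mean z, mostly non-significant
  null_rows <- tab[tab$n1 != "aDMN" | tab$n2 != "pDMN", ]
  expect_lt(max(abs(null_rows$mean_z)), 4 / sqrt(n - 3))

  cohort_bad <- make_cohort(0)
  cohort_bad[[3]][, 2] <- 5
  expect_error(correlation_table(cohort_bad), "constant")
})

test_that("group_t_map computes voxel-wise one-sample t across subjects", {
  d <- c(8, 8, 4)
  zeros <- lapply(1:5, function(i) array(0, d))
  g0 <- group_t_map(zeros)
  expect_true(all(g0$t == 0))
  set.seed(53)
  maps <- lapply(1:8, function(i) array(rnorm(prod(d)), d) +
                   array(rep(c(2, 0), c(20, prod(d) - 20)), d))
  gp <- group_t_map(maps, 1)
  gm <- group_t_map(maps, -1)
  expect_equal(gm$t, -gp$t)
  expect_identical(gp$df, 7L)
  # oracle at one voxel
  v <- sapply(maps, function(m) m[3, 1, 1])
  expect_equal(gp$t[3, 1, 1], unname(t.test(v)$statistic), tolerance = 1e-10)
  expect_error(group_t_map(maps[1:2]), "at least 3")
  expect_error(group_t_map(c(maps, list(array(0, c(2, 2, 2))))), "mismatch")
})

test_that("label_components agrees with the igraph flood-fill oracle", {
  skip_if_not_installed("igraph")
  set.seed(54)
  for (conn in c(6, 18, 26)) {
    for (i in 1:4) {
      vol <- array(runif(1000) < 0.35, c(10, 10, 10))
      mine <- canonical_labels(label_components(vol, conn))
      oracle <- canonical_labels(flood_fill_components(vol, conn))
      expect_identical(mine, oracle)
    }
  }
  # empty volume
  expect_true(all(label_components(array(FALSE, c(5, 5, 5))) == 0L))
})

test_that("estimate_smoothness recovers applied smoothing", {
  set.seed(55)
  d <- c(40, 40, 40); vox <- c(3, 3, 3)
  mask <- array(TRUE, d)
  # white noise smoothed to 8 mm FWHM = 8/3 voxels
  frames <- lapply(1:4, function(i)
    gaussian_smooth_3d(array(rnorm(prod(d)), d), 8 / 3))
  fw <- estimate_smoothness(frames, vox, mask)
  expect_true(all(abs(fw - 8) / 8 < 0.2))

  # unsmoothed noise: close to voxel size, below 1.5 voxels
  raw <- lapply(1:4, function(i) array(rnorm(prod(d)), d))
  fw0 <- estimate_smoothness(raw, vox, mask)
  expect_true(all(fw0 < 1.5 * 3))

  # identical maps across subjects -> zero residual variance is degenerate
  same <- lapply(1:3, function(i) array(0, c(4, 4, 4)))
  expect_error(estimate_smoothness(same, vox, array(TRUE, c(4, 4, 4))),
               "unreliable|zero variance")
  expect_error(estimate_smoothness(raw, vox, array(FALSE, d)), "27")
})

test_that("cluster_inference thresholds, labels, and orders p by extent", {
  set.seed(56)
  d <- c(20, 20, 12)
  mask <- array(TRUE, d)
  tmap <- array(rnorm(prod(d), 0, 0.5), d)
  # two planted clusters of different extents
  tmap[3:5, 3:5, 3:5] <- 8
  tmap[14:19, 14:19, 5:10] <- 8
  cl <- cluster_inference(tmap, df = 20, height_p = 0.001,
                          fwhm_mm = c(6, 6, 6), mask = mask,
                          voxel_mm = c(3, 3, 3))
  expect_identical(nrow(cl), 2L)
  expect_identical(sort(cl$extent), c(27L, 216L))
  # p_cluster strictly decreasing in extent
  expect_lt(cl$p_cluster[cl$extent == 216], cl$p_cluster[cl$extent == 27])
  # peaks reported as 0-based indices inside the planted blocks
  big <- cl[cl$extent == 216, ]
  expect_true(big$peak_i >= 13 && big$peak_i <= 18)

  # threshold above max(t): empty, not an error
  empty <- cluster_inference(array(0, d), 20, 0.001, c(6, 6, 6), mask)
  expect_identical(nrow(empty), 0L)

  # monotonicity of the extent p-value over a range of sizes
  ps <- vapply(c(5, 20, 80, 320), function(k) {
    tm <- array(0, d); tm[seq_len(k)] <- 8
    # isolate a single straight run of voxels along x columns
    cluster_inference(tm, 20, 0.001, c(6, 6, 6), mask)$p_cluster[1]
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(cluster_inference(tmap, 20, 0.2, c(6, 6, 6), mask), "height_p")
})

test_that("group_networkwise aggregates per-subject effect tables", {
  k <- tiny_hrf()
  cfg <- synthetic_config(n_subjects = 4, n_volumes = 96, seed = 57)
  coh <- simulate_cohort(cfg, k)
  tabs <- lapply(coh, function(su)
    run_networkwise_all(clean_network_series(su$bold, su$nuisance, 0.01), k))
  g <- group_networkwise(tabs)
  expect_identical(nrow(g), 60L)
  expect_equal(g$p_threshold[1], 0.05 / 60)
  expect_identical(g$df[1], 3L)
  # a row's t matches a direct one-sample t on the collected betas
  b <- sapply(tabs, function(tb) tb$beta[5])
  expect_equal(g$t[5], one_sample_t(b)$t, tolerance = 1e-10)
})
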