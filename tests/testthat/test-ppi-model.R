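make_bold_pair <- function(n = 228, tr = 2, seed = 1, k = tiny_hrf()) {
  set.seed(seed)
  n1 <- band_limited_signal(n, tr, runif(3, 0.005, 0.045))
  n2 <- band_limited_signal(n, tr, runif(3, 0.005, 0.045))
  list(n1 = time_series(n1, tr, "neural", "A"),
       n2 = time_series(n2, tr, "neural", "B"),
       s1 = convolve_bold(time_series(n1, tr, "neural", "A"), k),
       s2 = convolve_bold(time_series(n2, tr, "neural", "B"), k))
}

test_that("build_ppi_regressor follows deconvolve-detrend-multiply-reconvolve", {
  k <- tiny_hrf()
  p <- make_bold_pair(seed = 31)
  reg <- build_ppi_regressor(p$s1, p$s2, k)
  expect_identical(reg$level, "bold")
  expect_length(reg$values, 228L)

  # ground truth built forward from the known neural series
  truth <- convolve_bold(
    time_series(detrend_linear(p$n1$values) * detrend_linear(p$n2$values),
                2, "neural"), k)
  expect_gt(cor(reg$values, truth$values), 0.9)

  # symmetry of the product
  reg_swap <- build_ppi_regressor(p$s2, p$s1, k)
  expect_equal(reg$values, reg_swap$values, tolerance = 1e-10)

  # zero input propagates
  z <- time_series(rep(0, 228), 2, "bold", "Z")
  expect_true(all(abs(build_ppi_regressor(p$s1, z, k)$values) < 1e-10))
})

test_that("fit_glm matches hand computation and the normal-equations oracle", {
  # intercept-only, y = 1,2,3: beta 2, t = 2/(1/sqrt(3)) = 3.464, df = 2
  f <- fit_glm(matrix(1, 3, 1), c(1, 2, 3))
  expect_equal(unname(f$beta), 2)
  expect_equal(unname(f$t), 3.4641016, tolerance = 1e-6)
  expect_identical(f$df, 2L)

  set.seed(32)
  for (i in 1:20) {
    n <- sample(20:60, 1); pcol <- sample(2:6, 1)
    X <- cbind(1, matrix(rnorm(n * (pcol - 1)), n))
    y <- rnorm(n)
    fit <- fit_glm(X, y)
    oracle <- normal_equations_fit(X, y)
    expect_equal(unname(fit$beta), oracle$beta, tolerance = 1e-8)
    expect_equal(unname(fit$se), oracle$se, tolerance = 1e-8)
    expect_equal(unname(fit$t), oracle$t, tolerance = 1e-8)
    expect_identical(fit$df, as.integer(oracle$df))
    # invariants: df = n - rank, t = beta/se
    expect_identical(fit$df, n - ncol(X))
    expect_equal(unname(fit$t), unname(fit$beta / fit$se), tolerance = 1e-12)
  }

  # noiseless recovery to machine precision
  X <- cbind(1, rnorm(30), rnorm(30))
  b <- c(2, -1, 0.5)
  fit <- fit_glm(X, drop(X %*% b))
  expect_equal(unname(fit$beta), b, tolerance = 1e-10)

  # duplicated column errors with names
  Xd <- cbind(a = rnorm(10), b = 1:10, dup = 1:10)
  expect_error(fit_glm(Xd, rnorm(10)), "rank deficient")
})

test_that("networkwise_ppi recovers planted couplings and respects symmetry", {
  k <- tiny_hrf()
  cpl <- data.frame(source_a = "SAL", source_b = "RECN", target = "aDMN",
                    c = 0.5)
  cfg <- synthetic_config(n_subjects = 1, couplings = cpl, seed = 33)
  su <- simulate_subject_bold(simulate_neural_networks(cfg, 1), cfg, k, 1)
  cl <- clean_network_series(su$bold, su$nuisance, 0.01)
  fit <- networkwise_ppi(cl$aDMN, cl$SAL, cl$RECN, k)
  expect_gt(fit$t["ppi"], 2)
  # source order does not matter
  fit_sw <- networkwise_ppi(cl$aDMN, cl$RECN, cl$SAL, k)
  expect_equal(unname(fit$beta["ppi"]), unname(fit_sw$beta["ppi"]),
               tolerance = 1e-8)
  # target must differ from predictors
  expect_error(networkwise_ppi(cl$SAL, cl$SAL, cl$RECN, k), "identical")
})

test_that("white-noise targets give calibrated subject-level p values", {
  k <- tiny_hrf()
  p <- make_bold_pair(seed = 34)
  set.seed(34)
  nrep <- 400
  pvals <- numeric(nrep)
  betas <- numeric(nrep)
  for (i in seq_len(nrep)) {
    y <- time_series(rnorm(228), 2, "bold", "null")
    fit <- networkwise_ppi(y, p$s1, p$s2, k)
    pvals[i] <- fit$p["ppi"]; betas[i] <- fit$beta["ppi"]
  }
  expect_lt(abs(mean(betas)), 0.02)
  rate <- mean(pvals < 0.05)
  ci <- qbinom(c(0.005, 0.995), nrep, 0.05) / nrep
  expect_gte(rate, ci[1]); expect_lte(rate, ci[2])
})

test_that("PPI is not fooled by purely additive dependence", {
  # y depends additively on both sources: main effects fire, the
  # interaction does not (the contrast with partial correlation)
  k <- tiny_hrf()
  set.seed(35)
  nrep <- 40
  t_ppi <- numeric(nrep); t_main <- numeric(nrep)
  for (i in seq_len(nrep)) {
    p <- make_bold_pair(seed = 3500 + i)
    y <- time_series(p$s1$values + p$s2$values + rnorm(228, 0, 0.5),
                     2, "bold", "add")
    fit <- networkwise_ppi(y, p$s1, p$s2, k)
    t_ppi[i] <- fit$t["ppi"]; t_main[i] <- fit$t["n1"]
  }
  # main effects are overwhelmingly significant, interaction is null-like
  expect_gt(mean(abs(t_main) > 5), 0.9)
  expect_lt(mean(abs(t_ppi) > qt(0.975, 224)), 0.2)
  expect_lt(abs(mean(t_ppi)), 1)
})

test_that("run_networkwise_all enumerates pairs x targets", {
  k <- tiny_hrf()
  cfg <- synthetic_config(n_subjects = 1, seed = 36)
  su <- simulate_subject_bold(simulate_neural_networks(cfg, 1), cfg, k, 1)
  cl <- clean_network_series(su$bold, su$nuisance, 0.01)
  tab <- run_networkwise_all(cl, k)
  expect_identical(nrow(tab), 60L)
  expect_identical(length(unique(tab$pair)), 15L)
  expect_true(all(table(tab$pair) == 4L))
  # a network never appears as target of its own pair
  expect_false(any(tab$target == tab$n1 | tab$target == tab$n2))
  # effect rows distinguish targets: A vs BxC and C vs AxB are distinct
  expect_identical(anyDuplicated(paste(tab$pair, tab$target)), 0L)

  tab5 <- run_networkwise_all(cl[1:5], k)
  expect_identical(nrow(tab5), 30L)  # C(5,2) * 3

  dup <- cl; names(dup)[2] <- names(dup)[1]
  expect_error(run_networkwise_all(dup, k), "duplicate")
})

test_that("voxelwise_ppi localizes a planted interaction region", {
  k <- tiny_hrf()
  cpl <- data.frame(source_a = "SAL", source_b = "RECN", target = "aDMN",
                    c = 0)
  cfg <- synthetic_config(n_subjects = 1, n_volumes = 120, seed = 37,
                          couplings = cpl)
  sc <- simulate_volume_scene(cfg, 1, grid = c(24, 24, 20),
                              interaction_c = 2, voxel_noise_sd = 0.5, k = k)
  su <- sc$subject
  cl <- clean_network_series(su$bold[sc$pair], su$nuisance, 0.01)
  fit <- voxelwise_ppi(sc$img, cl[[1]], cl[[2]], k, su$nuisance,
                       mask = sc$mask)
  expect_identical(dim(fit$beta_ppi), dim(sc$mask))
  peak <- which.max(abs(ifelse(is.na(fit$beta_ppi), 0, fit$beta_ppi)))
  expect_true(sc$interaction_mask[peak])

  # all-zero image -> all-zero betas (mask must be supplied: mean is zero)
  z <- array(0, dim = dim(sc$img))
  fz <- voxelwise_ppi(z, cl[[1]], cl[[2]], k, su$nuisance, mask = sc$mask)
  expect_true(all(abs(fz$beta_ppi[sc$mask]) < 1e-10))

  # every voxel equal to s1: no interaction anywhere
  n <- length(cl[[1]]$values)
  one <- array(rep(cl[[1]]$values, each = prod(dim(sc$mask))),
               dim = c(dim(sc$mask), n))
  f1 <- voxelwise_ppi(one, cl[[1]], cl[[2]], k, su$nuisance, mask = sc$mask)
  expect_lt(max(abs(f1$beta_ppi[sc$mask])), 1e-6)
})
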