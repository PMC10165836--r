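test_that("simulation is a deterministic function of the seed", {
  cfg <- simulation_config(n_patients = 8, n_signatures = 3,
                           noise = "negbin_patient", seed = 77)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$true_alphas, s2$true_alphas)
  cfg2 <- simulation_config(n_patients = 8, n_signatures = 3,
                            noise = "negbin_patient", seed = 78)
  s3 <- simulate_dataset(cfg2)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("exposure draws hit the configured NB mean and variance", {
  cfg <- simulation_config(n_patients = 10000, n_signatures = 1, seed = 5)
  set.seed(5)
  W <- draw_exposures(cfg)
  se <- sqrt(6000 * (1 + 6000 / 1.5) / 1e4)
  expect_lt(abs(mean(W) - 6000), 3 * se)
  expect_lt(abs(var(as.numeric(W)) / (6000 * (1 + 6000 / 1.5)) - 1), 0.1)
  # huge dispersion approaches the Poisson limit Var = mean
  cfgp <- simulation_config(n_patients = 10000, n_signatures = 1,
                            exposure_mean = 100, exposure_dispersion = 1e9,
                            seed = 6)
  set.seed(6)
  Wp <- draw_exposures(cfgp)
  expect_lt(abs(var(as.numeric(Wp)) / mean(Wp) - 1), 0.1)
})

test_that("noise models reproduce their mean-variance laws", {
  mu <- matrix(100, 100, 100)
  set.seed(8)
  po <- apply_noise(mu, simulation_config(noise = "poisson"))
  expect_null(po$alphas)
  idx <- var(as.numeric(po$counts)) / mean(po$counts)
  expect_gt(idx, 0.95); expect_lt(idx, 1.05)

  nb <- apply_noise(mu, simulation_config(noise = "negbin_fixed", alpha = 10))
  expect_equal(nb$alphas, rep(10, 100), ignore_attr = TRUE)
  expect_lt(abs(var(as.numeric(nb$counts)) / 1100 - 1), 0.1)

  pp <- apply_noise(mu, simulation_config(noise = "negbin_patient",
                                          alpha_range = c(10, 500)))
  expect_length(pp$alphas, 100)
  expect_true(all(pp$alphas >= 10 & pp$alphas <= 500))
  # patient rows with smaller alpha are more dispersed
  rv <- apply(pp$counts, 1, var)
  expect_lt(cor(pp$alphas, rv, method = "spearman"), 0)

  none <- apply_noise(mu + 0.4, simulation_config(noise = "none"))
  expect_true(all(none$counts == 100))
})

test_that("counts are centered on the true signal under every noise model", {
  fx <- exact_factor_fixture(N = 4, M = 6, K = 2, seed = 19)
  mu <- fx$W %*% fx$H
  for (noise in c("poisson", "negbin_fixed")) {
    cfg <- simulation_config(noise = noise, alpha = 20)
    set.seed(33)
    acc <- matrix(0, 4, 6)
    for (r in 1:200) acc <- acc + apply_noise(mu, cfg)$counts
    rel <- abs(acc / 200 - mu) / mu
    expect_lt(max(rel), 0.05)
  }
})

test_that("catalog-mode signatures always include the forced pair", {
  catalog <- synthetic_catalog()
  cfg <- simulation_config(n_signatures = 5, seed = 3)
  for (i in 1:5) {
    H <- draw_signatures(cfg, catalog)
    expect_true(all(c("SBS1", "SBS5") %in% rownames(H)))
    expect_equal(nrow(H), 5L)
    expect_false(anyDuplicated(rownames(H)) > 0)
  }
  expect_error(draw_signatures(simulation_config(n_signatures = 99, seed = 1),
                               catalog), "exceeds catalog size")
  bad <- simulation_config(n_signatures = 3,
                           forced_signatures = c("SBS1", "SBSX"), seed = 1)
  expect_error(draw_signatures(bad, catalog), "not in catalog")
})

test_that("Dirichlet-mode signatures are row-stochastic", {
  cfg <- simulation_config(n_signatures = 4,
                           signature_source = "dirichlet_random", seed = 9)
  set.seed(9)
  H <- draw_signatures(cfg)
  expect_equal(dim(H), c(4L, 96L))
  expect_equal(rowSums(H), rep(1, 4), ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("simulated datasets round-trip through a directory", {
  cfg <- simulation_config(n_patients = 4, n_signatures = 2,
                           noise = "negbin_fixed", alpha = 50, seed = 44)
  sim <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_simulated_dataset(sim, dir)
  expect_equal(read_count_matrix(file.path(dir, "counts.tsv")), sim$counts)
  expect_true(file.exists(file.path(dir, "true_alpha.tsv")))
  man <- readLines(file.path(dir, "manifest.txt"))
  expect_true(any(grepl("Mersenne-Twister", man)))
})
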