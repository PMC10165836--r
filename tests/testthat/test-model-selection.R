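test_that("signature matching recovers identity and known permutations", {
  H <- synthetic_catalog()[1:5, ]
  m <- match_signatures(H, H)
  expect_identical(m$permutation, 1:5)
  expect_equal(m$similarity, rep(1, 5), tolerance = 1e-12)

  sigma <- c(3, 1, 5, 2, 4)
  m2 <- match_signatures(H, H[sigma, ])
  # H[sigma, ][perm, ] must equal H => perm is the inverse of sigma
  expect_identical(m2$permutation, order(sigma))
  expect_equal(m2$similarity, rep(1, 5), tolerance = 1e-12)
})

test_that("assignment equals the exhaustive-permutation optimum", {
  set.seed(14)
  for (rep in 1:5) {
    A <- matrix(rgamma(4 * 96, 0.5), 4, 96); A <- A / rowSums(A)
    B <- matrix(rgamma(4 * 96, 0.5), 4, 96); B <- B / rowSums(B)
    m <- match_signatures(A, B)
    S <- nbsig:::cosine_matrix(A, B)
    perms <- expand.grid(rep(list(1:4), 4))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    best <- max(apply(perms, 1, function(p) sum(S[cbind(1:4, unlist(p))])))
    expect_equal(m$total, best, tolerance = 1e-12)
  }
})

test_that("matching composed with its inverse is the identity", {
  set.seed(15)
  A <- matrix(rgamma(5 * 20, 1), 5, 20)
  B <- matrix(rgamma(5 * 20, 1), 5, 20)
  mf <- match_signatures(A, B)
  mb <- match_signatures(B, A)
  expect_identical(mb$permutation[mf$permutation], 1:5)
})

test_that("information criteria satisfy their formulas and conventions", {
  fx <- exact_factor_fixture(N = 10, M = 8, K = 2, seed = 12)
  V <- fx$V
  pofit <- poisson_nmf(V, K = 2, n_inits = 2, seed = 1, max_iter = 1000)
  ic <- information_criteria(pofit, V)
  expect_equal(ic$n_obs, 10L)
  expect_equal(ic$n_prm, 2 * (10 + 8))
  expect_equal(ic$aic, -2 * ic$loglik + 2 * ic$n_prm)
  expect_equal(ic$bic, -2 * ic$loglik + log(10) * ic$n_prm)

  nbfit <- nb_nmf(V, K = 2, n_inits = 2, seed = 1, max_iter = 1000)
  icn <- information_criteria(nbfit, V)
  expect_equal(icn$n_prm, 2 * (10 + 8) + 10)   # + N patient dispersions
  nbs <- nb_nmf(V, K = 2, mode = "shared", n_inits = 2, seed = 1,
                max_iter = 1000)
  ics <- information_criteria(nbs, V)
  expect_equal(ics$n_prm, 2 * (10 + 8) + 1)    # + 1 shared dispersion
  # AIC = BIC exactly when ln(n_obs) = 2
  expect_equal(ic$aic - ic$bic, (2 - log(10)) * ic$n_prm)
})

test_that("single-candidate grids are returned unconditionally", {
  fx <- exact_factor_fixture(N = 12, M = 10, K = 2, seed = 9)
  res <- sigmos(fx$V, "poisson", k_grid = 4, J = 3, seed = 2, n_inits = 2,
                max_iter = 1000)
  expect_identical(res$chosen_k, 4L)
  ic <- select_rank_ic(fx$V, "poisson", k_grid = 2, criterion = "bic",
                       seed = 2, n_inits = 2, max_iter = 1000)
  expect_identical(ic$chosen_k, 2L)
})

test_that("the split-cost procedure is reproducible and order-invariant", {
  fx <- exact_factor_fixture(N = 20, M = 12, K = 2, seed = 10)
  r1 <- sigmos(fx$V, "poisson", k_grid = 2:3, J = 4, seed = 99, n_inits = 2,
               max_iter = 1000)
  r2 <- sigmos(fx$V, "poisson", k_grid = 2:3, J = 4, seed = 99, n_inits = 2,
               max_iter = 1000)
  expect_identical(r1$per_split_costs, r2$per_split_costs)
  r3 <- sigmos(fx$V, "poisson", k_grid = c(3, 2), J = 4, seed = 99,
               n_inits = 2, max_iter = 1000)
  expect_equal(r1$median_costs, r3$median_costs)
  expect_equal(length(r1$per_split_costs[["2"]]), 4L)
  expect_true(all(unlist(r1$per_split_costs) >= 0))
})

test_that("held-out cost selects the true rank on clean simulated data", {
  cfg <- simulation_config(n_patients = 50, n_signatures = 3,
                           noise = "poisson", seed = 31)
  sim <- simulate_dataset(cfg)
  res <- sigmos(sim$counts, "poisson", k_grid = 2:5, J = 5, seed = 31,
                n_inits = 3)
  expect_identical(res$chosen_k, 3L)
})

test_that("alternative costs run and never go negative", {
  fx <- exact_factor_fixture(N = 15, M = 10, K = 2, seed = 17)
  for (cost in c("frobenius", "itakura_saito")) {
    r <- sigmos(fx$V, "poisson", k_grid = 2, J = 3, seed = 5, n_inits = 2,
                cost = cost, max_iter = 500)
    expect_true(all(unlist(r$per_split_costs) >= 0))
  }
})
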