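test_that("NB updates fix points where V equals WH", {
  fx <- exact_factor_fixture()
  a <- runif(nrow(fx$V), 1, 100)
  H2 <- nb_update_H(fx$V, fx$W, fx$H, a)
  W2 <- nb_update_W(fx$V, fx$W, fx$H, a)
  expect_equal(H2, fx$H, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(W2, fx$W, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("NB updates reduce to the Poisson KL updates as alpha grows", {
  set.seed(13)
  inst <- random_nb_instance(N = 4, M = 6, K = 2)
  a_big <- rep(1e9, 4)
  expect_equal(nb_update_H(inst$V, inst$W, inst$H, a_big),
               kl_update_H(inst$V, inst$W, inst$H), tolerance = 1e-6)
  expect_equal(nb_update_W(inst$V, inst$W, inst$H, a_big),
               kl_update_W(inst$V, inst$W, inst$H), tolerance = 1e-6)
})

test_that("each NB update monotonically decreases the divergence", {
  set.seed(77)
  worst <- 0
  for (i in 1:100) {
    inst <- random_nb_instance(N = sample(2:6, 1), M = sample(3:8, 1),
                               K = sample(2:3, 1))
    d0 <- nb_divergence(inst$V, inst$W %*% inst$H, inst$a)
    H1 <- nb_update_H(inst$V, inst$W, inst$H, inst$a)
    d1 <- nb_divergence(inst$V, inst$W %*% H1, inst$a)
    W1 <- nb_update_W(inst$V, inst$W, H1, inst$a)
    d2 <- nb_divergence(inst$V, W1 %*% H1, inst$a)
    worst <- max(worst, d1 - d0, d2 - d1)
  }
  expect_lte(worst, 1e-9)
})

test_that("the compiled iteration equals one R-level H and W update", {
  set.seed(31)
  inst <- random_nb_instance(N = 5, M = 7, K = 2)
  res <- nbsig:::.nmf_mm_cpp(inst$V, inst$W, inst$H, inst$a,
                             tol = 0, max_iter = 1)
  H1 <- nb_update_H(inst$V, inst$W, inst$H, inst$a)
  W1 <- nb_update_W(inst$V, inst$W, H1, inst$a)
  expect_equal(res$H, H1, tolerance = 1e-12)
  expect_equal(res$W, W1, tolerance = 1e-12)
  expect_equal(res$trace[1], nb_divergence(inst$V, W1 %*% H1, inst$a),
               tolerance = 1e-8)
})

test_that("Poisson NMF recovers an exact factorization to ~zero divergence", {
  fx <- exact_factor_fixture()
  fit <- poisson_nmf(fx$V, K = 3, seed = 2)
  expect_lte(fit$divergence, 1e-6 * sum(fx$V))
  expect_equal(rowSums(fit$H), rep(1, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  tr <- fit$divergence_trace
  expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(utils::head(tr, -1)))))
})

test_that("rank-1 Poisson NMF attains the closed-form margin product", {
  # for K = 1 the gKL-optimal means are rowSums %o% colSums / total
  set.seed(4)
  V <- matrix(rpois(12, 30), 3, 4,
              dimnames = list(paste0("p", 1:3), paste0("t", 1:4)))
  fit <- poisson_nmf(V, K = 1, seed = 6)
  d_opt <- gkl_divergence(V, outer(rowSums(V), colSums(V)) / sum(V))
  expect_equal(fit$divergence, d_opt, tolerance = 1e-6)
})

test_that("fits are deterministic given the seed", {
  fx <- exact_factor_fixture()
  f1 <- poisson_nmf(fx$V, K = 2, n_inits = 3, seed = 123, max_iter = 300)
  f2 <- poisson_nmf(fx$V, K = 2, n_inits = 3, seed = 123, max_iter = 300)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  n1 <- nb_nmf(fx$V, K = 2, n_inits = 2, seed = 123, max_iter = 300)
  n2 <- nb_nmf(fx$V, K = 2, n_inits = 2, seed = 123, max_iter = 300)
  expect_identical(n1$W, n2$W)
  expect_identical(unname(as.numeric(n1$alphas)),
                   unname(as.numeric(n2$alphas)))
})

test_that("NB NMF recovers noise-free structure and the Poisson limit", {
  fx <- exact_factor_fixture()
  fit <- nb_nmf(fx$V, K = 3, seed = 2)
  expect_lte(fit$divergence, 1e-6 * sum(fx$V))
  # noise-free data push the dispersion to the ceiling => Poisson-like fit
  expect_true(all(as.numeric(fit$alphas) == 1e5))
  pofit <- poisson_nmf(fx$V, K = 3, seed = 2)
  expect_equal(gkl_divergence(fx$V, fitted(fit)),
               gkl_divergence(fx$V, fitted(pofit)),
               tolerance = 1e-3)

  # signature recovery on noise-free catalog-style data (96 contexts make
  # the factors identifiable, unlike an arbitrary low-dimensional factor pair)
  sim <- simulate_dataset(simulation_config(
    n_patients = 30, n_signatures = 3, noise = "none", seed = 14))
  nfit <- nb_nmf(sim$counts, K = 3, seed = 3)
  m <- match_signatures(sim$true_H, nfit$H)
  expect_true(all(m$similarity > 0.99))
})

test_that("degenerate inputs are rejected", {
  fx <- exact_factor_fixture()
  expect_error(poisson_nmf(fx$V, K = 0), "K must be")
  expect_error(poisson_nmf(fx$V, K = 100), "K must be")
  Vz <- fx$V; Vz[2, ] <- 0
  expect_error(poisson_nmf(Vz, K = 2), "all-zero patient")
  Vc <- fx$V; Vc[, 3] <- 0
  expect_error(poisson_nmf(Vc, K = 2), "all-zero mutation")
})

test_that("permuting patients permutes exposures but not the fit quality", {
  fx <- exact_factor_fixture(N = 12, M = 10, K = 2, seed = 3)
  perm <- sample(nrow(fx$V))
  f1 <- nb_nmf(fx$V, K = 2, n_inits = 3, seed = 8, max_iter = 2000)
  f2 <- nb_nmf(fx$V[perm, ], K = 2, n_inits = 3, seed = 8, max_iter = 2000)
  expect_equal(f2$divergence, f1$divergence, tolerance = 1e-4)
})
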