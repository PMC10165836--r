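# Shared fixtures built in code at test time.

# Small count matrix with an exact rank-K factorization: H rows are
# integer weight vectors divided by their sums, and each column of W is an
# integer multiple of the corresponding weight sum, so V = W %*% H is
# exactly integer with no zero rows or columns.
exact_factor_fixture <- function(N = 24, M = 16, K = 3, seed = 7) {
  set.seed(seed)
  Wt <- matrix(sample(c(0, 0, 1, 2, 4, 8), K * M, replace = TRUE), K, M)
  for (j in which(colSums(Wt) == 0)) Wt[sample(K, 1), j] <- 1
  for (k in which(rowSums(Wt) == 0)) Wt[k, sample(M, 1)] <- 8
  s <- rowSums(Wt)
  H <- Wt / s
  W <- vapply(seq_len(K), function(k) s[k] * sample(5:60, N, replace = TRUE),
              numeric(N))
  V <- W %*% H
  stopifnot(max(abs(V - round(V))) < 1e-9, all(colSums(V) > 0))
  dimnames(V) <- list(sprintf("P%02d", 1:N), sprintf("T%02d", 1:M))
  list(V = V, W = W, H = H)
}

# Random strictly positive factors and counts for property checks.
random_nb_instance <- function(N = 4, M = 6, K = 2) {
  V <- matrix(rpois(N * M, lambda = 40), N, M)
  W <- matrix(runif(N * K, 0.5, 5), N, K)
  H <- matrix(runif(K * M, 0.5, 5), K, M)
  a <- runif(N, 1, 50)
  list(V = V, W = W, H = H, a = a)
}

# Classical Poisson KL multiplicative updates (oracle for the NB limit).
kl_update_H <- function(V, W, H) {
  L <- pmax(W %*% H, 1e-10)
  H * crossprod(W, V / L) / pmax(matrix(colSums(W), nrow(H), ncol(H)), 1e-10)
}
kl_update_W <- function(V, W, H) {
  L <- pmax(W %*% H, 1e-10)
  W * ((V / L) %*% t(H)) / pmax(matrix(rowSums(H), nrow(W), ncol(W),
                                       byrow = TRUE), 1e-10)
}

# Paper-design simulation scenario at desk scale.
scenario_dataset <- function(alpha, seed, n_patients = 100, k_true = 5) {
  cfg <- simulation_config(n_patients = n_patients, n_signatures = k_true,
                           noise = "negbin_fixed", alpha = alpha, seed = seed)
  simulate_dataset(cfg)
}
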