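#' Optimally match two sets of signatures by cosine similarity
#'
#' Finds the one-to-one assignment between the rows of `H_query` and the
#' rows of `H_ref` that maximizes the total cosine similarity (exact linear
#' assignment, not greedy).  Used inside [sigmos()] to align training-set
#' signatures with the full-data signatures before predicting held-out
#' patients.
#'
#' @param H_ref Reference signature matrix (K x M).
#' @param H_query Query signature matrix with the same dimensions.
#' @return A list with `permutation` (integer vector; `permutation[i]` is
#'   the row of `H_query` assigned to row `i` of `H_ref`, so
#'   `H_query[permutation, ]` is aligned with `H_ref`), `similarity`
#'   (per-pair cosine similarities in reference order) and `total`.
#' @export
match_signatures <- function(H_ref, H_query) {
  if (!all(dim(H_ref) == dim(H_query))) {
    stop("signature matrices must have identical dimensions")
  }
  if (any(rowSums(H_ref^2) == 0) || any(rowSums(H_query^2) == 0)) {
    stop("zero signature row: cosine similarity undefined")
  }
  S <- cosine_matrix(H_ref, H_query)
  perm <- .assign_max_cpp(S)
  sim <- S[cbind(seq_len(nrow(S)), perm)]
  list(permutation = as.integer(perm), similarity = sim, total = sum(sim))
}

#' Rank selection by repeated patient splitting (SigMoS)
#'
#' For each candidate number of signatures K the procedure (i) factorizes
#' the full matrix to obtain exposures `W` and signatures `H`; (ii) for each
#' of `J` random splits fits the same NMF on the training patients (a
#' fraction `split_fraction`, default 90%), aligns the training signatures
#' with the full-data ones by [match_signatures()], and predicts the
#' held-out patients as `W_test %*% H_train` using the full-data exposures
#' of the test patients; (iii) records the cost between held-out counts and
#' their prediction, and takes the median over the `J` splits.  The chosen K
#' minimizes the median cost (ties go to the smaller K).  Test-set
#' exposures are deliberately *not* re-estimated from the training
#' signatures, which would overfit the held-out patients.
#'
#' The default cost is the generalized KL divergence; Frobenius and
#' Itakura-Saito are available.  Costs are comparable across K for one
#' model, never across models.
#'
#' @param V Count matrix, patients as rows.
#' @param nmf_method `"poisson"`, `"negbin_patient"` or `"negbin_shared"`.
#' @param k_grid Candidate ranks (positive integers).
#' @param J Number of random training/test splits per K (default 10).
#' @param split_fraction Fraction of patients in the training set.
#' @param cost `"gkl"`, `"frobenius"` or `"itakura_saito"`.
#' @param seed Integer master seed; the J splits are drawn once from it and
#'   shared across all K so that candidate ranks face identical splits.
#' @param n_inits,tol,max_iter Passed to the NMF fits.  The default solver
#'   tolerance here is looser (`1e-5`) than the fitting default: rank
#'   comparison depends on held-out cost differences orders of magnitude
#'   larger than the final convergence refinement.
#' @return A `sigmos_result`: list with `chosen_k`, `k_grid`,
#'   `median_costs`, `per_split_costs` (list of length-J vectors per K),
#'   `method`, `cost_name`, `J`, `split_fraction`, `seed`.
#' @export
sigmos <- function(V, nmf_method = c("poisson", "negbin_patient",
                                     "negbin_shared"),
                   k_grid = 2:8, J = 10L, split_fraction = 0.9,
                   cost = c("gkl", "frobenius", "itakura_saito"),
                   seed = NULL, n_inits = 5L, tol = 1e-5, max_iter = 10000L) {
  nmf_method <- match.arg(nmf_method)
  cost <- match.arg(cost)
  validate_count_matrix(V)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (any(k_grid < 1)) stop("k_grid must contain positive ranks")
  N <- nrow(V)
  n_test <- ceiling((1 - split_fraction) * N)
  if (n_test < 1 || n_test >= N) {
    stop("split_fraction leaves an empty training or test set")
  }

  if (!is.null(seed)) set.seed(seed)
  splits <- lapply(seq_len(J), function(j) sort(sample.int(N, n_test)))

  cost_fun <- switch(cost,
    gkl = gkl_divergence,
    frobenius = function(V, P) sum((V - P)^2),
    itakura_saito = function(V, P) {
      v <- pmax(V, 1e-10); p <- pmax(P, 1e-10)
      sum(v / p - log(v / p) - 1)
    })

  fit_one <- function(Vsub, K, s) {
    switch(nmf_method,
      poisson = poisson_nmf(Vsub, K, n_inits = n_inits, tol = tol,
                            max_iter = max_iter, seed = s),
      negbin_patient = nb_nmf(Vsub, K, mode = "patient", n_inits = n_inits,
                              tol = tol, max_iter = max_iter, seed = s),
      negbin_shared = nb_nmf(Vsub, K, mode = "shared", n_inits = n_inits,
                             tol = tol, max_iter = max_iter, seed = s))
  }

  per_split <- list()
  medians <- rep(NA_real_, length(k_grid))
  names(medians) <- as.character(k_grid)
  for (ki in seq_along(k_grid)) {
    K <- k_grid[ki]
    if (K > min(N - n_test, ncol(V))) {
      warning("skipping K = ", K, ": exceeds training dimensions")
      next
    }
    seed_k <- if (is.null(seed)) NULL else seed + 1000L * ki
    full <- fit_one(V, K, seed_k)
    costs <- vapply(seq_len(J), function(j) {
      test <- splits[[j]]
      fit_tr <- fit_one(V[-test, , drop = FALSE], K,
                        if (is.null(seed_k)) NULL else seed_k + 17L * j)
      m <- match_signatures(full$H, fit_tr$H)
      H_tr <- fit_tr$H[m$permutation, , drop = FALSE]
      V_pred <- full$W[test, , drop = FALSE] %*% H_tr
      cost_fun(V[test, , drop = FALSE], V_pred)
    }, numeric(1))
    per_split[[as.character(K)]] <- costs
    medians[ki] <- stats::median(costs)
  }
  if (all(is.na(medians))) stop("no candidate rank could be evaluated")
  chosen <- k_grid[which.min(medians)]   # which.min: first (smallest K) on ties

  structure(list(
    chosen_k = chosen, k_grid = k_grid, median_costs = medians,
    per_split_costs = per_split, method = nmf_method, cost_name = cost,
    J = J, split_fraction = split_fraction, seed = seed
  ), class = "sigmos_result")
}

#' @export
print.sigmos_result <- function(x, ...) {
  cat("SigMoS rank selection (", x$method, ", cost = ", x$cost_name, ", J = ",
      x$J, ")\n", sep = "")
  tab <- data.frame(K = x$k_grid, median_cost = unname(x$median_costs))
  print(tab, row.names = FALSE)
  cat("chosen K:", x$chosen_k, "\n")
  invisible(x)
}

#' AIC and BIC of a factorization fit
#'
#' Computes \eqn{\mathrm{AIC} = -2\ln L + 2 n_{prm}} and
#' \eqn{\mathrm{BIC} = -2\ln L + \ln(n_{obs})\, n_{prm}} with the number of
#' observations taken as the number of patients N.  The parameter count is
#' \eqn{K(N+M)} for the Poisson model, plus N dispersions for
#' patient-specific Negative Binomial fits or 1 for a shared dispersion.
#'
#' @param fit A `signature_fit`.
#' @param V The count matrix the fit was computed from.
#' @return List with `loglik`, `n_obs`, `n_prm`, `aic`, `bic`.
#' @export
information_criteria <- function(fit, V) {
  stopifnot(inherits(fit, "signature_fit"))
  check_same_shape(V, fit$W %*% fit$H)
  N <- nrow(V); M <- ncol(V); K <- fit$rank
  Lam <- fit$W %*% fit$H
  ll <- switch(fit$model,
    poisson = poisson_loglik(V, Lam),
    negbin_patient = nb_loglik(V, Lam, fit$alphas),
    negbin_shared = nb_loglik(V, Lam, fit$alphas),
    stop("unknown model tag ", fit$model))
  n_prm <- K * (N + M) + switch(fit$model, poisson = 0L,
                                negbin_patient = N, negbin_shared = 1L)
  list(loglik = ll, n_obs = N, n_prm = n_prm,
       aic = -2 * ll + 2 * n_prm,
       bic = -2 * ll + log(N) * n_prm)
}

#' Rank selection by information criterion
#'
#' Fits each candidate rank with the requested model and returns the rank
#' minimizing AIC or BIC (ties go to the smaller K).
#'
#' @inheritParams sigmos
#' @param criterion `"aic"` or `"bic"`.
#' @return A list with `chosen_k`, `k_grid`, `criterion`, `values` (the
#'   criterion per rank) and `fits` omitted for size.
#' @export
select_rank_ic <- function(V, nmf_method = c("poisson", "negbin_patient",
                                             "negbin_shared"),
                           k_grid = 2:8, criterion = c("aic", "bic"),
                           seed = NULL, n_inits = 5L, tol = 1e-5,
                           max_iter = 10000L) {
  nmf_method <- match.arg(nmf_method)
  criterion <- match.arg(criterion)
  k_grid <- sort(unique(as.integer(k_grid)))
  vals <- vapply(seq_along(k_grid), function(ki) {
    K <- k_grid[ki]
    s <- if (is.null(seed)) NULL else seed + 1000L * ki
    fit <- switch(nmf_method,
      poisson = poisson_nmf(V, K, n_inits = n_inits, tol = tol,
                            max_iter = max_iter, seed = s),
      negbin_patient = nb_nmf(V, K, mode = "patient", n_inits = n_inits,
                              tol = tol, max_iter = max_iter, seed = s),
      negbin_shared = nb_nmf(V, K, mode = "shared", n_inits = n_inits,
                             tol = tol, max_iter = max_iter, seed = s))
    ic <- information_criteria(fit, V)
    ic[[criterion]]
  }, numeric(1))
  names(vals) <- as.character(k_grid)
  list(chosen_k = k_grid[which.min(vals)], k_grid = k_grid,
       criterion = criterion, values = vals)
}

# ---- internal ---------------------------------------------------------------

cosine_matrix <- function(A, B) {
  An <- A / sqrt(rowSums(A^2))
  Bn <- B / sqrt(rowSums(B^2))
  tcrossprod(An, Bn)
}
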