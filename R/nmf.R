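#' Poisson NMF by Kullback-Leibler multiplicative updates
#'
#' Factorizes a count matrix \eqn{V \approx WH} by minimizing the
#' generalized KL divergence with the classical multiplicative updates,
#' which are maximum likelihood under a Poisson model
#' \eqn{V_{nm} \sim \mathrm{Po}((WH)_{nm})}.  The best of `n_inits` random
#' initializations (by final divergence) is returned; the divergence trace
#' of the winning run is non-increasing by the MM descent guarantee.
#'
#' At output the signature matrix `H` is normalized so each row is a
#' probability vector over mutation types, with `W` rescaled so `W %*% H`
#' is unchanged.
#'
#' @param V Count matrix, patients as rows; every row and column must have
#'   at least one positive entry.
#' @param K Number of signatures, `1 <= K <= min(dim(V))`.
#' @param n_inits Number of random initializations (default 5).
#' @param tol Relative divergence-change convergence tolerance.
#' @param max_iter Maximum outer iterations per initialization.
#' @param seed Integer master seed; initialization `i` uses `seed + i`.
#' @return A `signature_fit` object: list with `W`, `H`, `alphas` (`NULL`
#'   here), `model`, `rank`, `divergence`, `divergence_trace`, `loglik`,
#'   `iterations`, `converged`, `n_inits`, `best_init`, `seed`.
#' @export
poisson_nmf <- function(V, K, n_inits = 5L, tol = 1e-8, max_iter = 10000L,
                        seed = NULL) {
  check_nmf_inputs(V, K)
  runs <- run_inits(V, K, alphas = NULL, n_inits = n_inits, tol = tol,
                    max_iter = max_iter, seed = seed)
  finish_fit(runs, V, model = "poisson", alphas = NULL, K = K,
             n_inits = n_inits, seed = seed)
}

#' Negative Binomial NMF with patient-specific dispersion
#'
#' Fits \eqn{V \approx WH} under the Negative Binomial model
#' \eqn{V_{nm} \sim \mathrm{NB}(\mathrm{mean} = (WH)_{nm}, \mathrm{Var} =
#' (WH)_{nm}(1 + (WH)_{nm}/\alpha_n))} in three stages: (i) a Poisson NMF
#' fit supplies initial fitted means; (ii) the dispersions
#' \eqn{\alpha_1,\dots,\alpha_N} are estimated by maximum likelihood from
#' those means ([estimate_dispersion()]); (iii) with the dispersions held
#' fixed, `W` and `H` are re-estimated by the Negative Binomial
#' majorization-minimization updates ([nb_update_H()], [nb_update_W()]),
#' taking the best of `n_inits` random initializations by final divergence.
#' `mode = "shared"` constrains \eqn{\alpha_1 = \dots = \alpha_N} to one
#' pooled estimate.
#'
#' @inheritParams poisson_nmf
#' @param mode `"patient"` for per-patient dispersion, `"shared"` for a
#'   single dispersion.
#' @param refit_dispersion If `TRUE`, re-estimate the dispersions once from
#'   the final NB fitted means for reporting (the fit itself always uses
#'   the Poisson-stage estimates, which stay in `alphas_poisson_stage`).
#' @return A `signature_fit` object; `alphas` holds the dispersions used by
#'   the updates (or the refit ones when `refit_dispersion = TRUE`).
#' @export
nb_nmf <- function(V, K, mode = c("patient", "shared"), n_inits = 5L,
                   tol = 1e-8, max_iter = 10000L, seed = NULL,
                   refit_dispersion = FALSE) {
  mode <- match.arg(mode)
  check_nmf_inputs(V, K)
  pofit <- poisson_nmf(V, K, n_inits = n_inits, tol = tol,
                       max_iter = max_iter, seed = seed)
  alphas <- estimate_dispersion(V, pofit$W %*% pofit$H, mode = mode)
  runs <- run_inits(V, K, alphas = as.numeric(alphas), n_inits = n_inits,
                    tol = tol, max_iter = max_iter, seed = seed)
  fit <- finish_fit(runs, V, model = paste0("negbin_", mode), alphas = alphas,
                    K = K, n_inits = n_inits, seed = seed)
  if (refit_dispersion) {
    fit$alphas_poisson_stage <- alphas
    fit$alphas <- estimate_dispersion(V, fit$W %*% fit$H, mode = mode)
    fit$loglik <- nb_loglik(V, fit$W %*% fit$H, fit$alphas)
  }
  fit
}

#' One Negative Binomial multiplicative update of the signature matrix
#'
#' The majorization-minimization update
#' \deqn{H_{km} \leftarrow H_{km}\,
#'  \frac{\sum_n W_{nk} V_{nm}/(WH)_{nm}}
#'       {\sum_n W_{nk} (V_{nm}+\alpha_n)/((WH)_{nm}+\alpha_n)},}
#' which never increases the divergence [nb_divergence()].  With all
#' \eqn{\alpha_n \to \infty} the denominator tends to \eqn{\sum_n W_{nk}}
#' and the classical Poisson KL update is recovered.
#'
#' @param V Count matrix.
#' @param W Current exposure matrix (N x K).
#' @param H Current signature matrix (K x M).
#' @param alphas Positive dispersions, one per patient or a scalar.
#' @return Updated `H` of the same shape.
#' @export
nb_update_H <- function(V, W, H, alphas) {
  a <- check_alphas(alphas, nrow(V))
  L <- pmax(W %*% H, 1e-10)
  num <- crossprod(W, V / L)
  den <- crossprod(W, (V + a) / (L + a))   # a recycles down columns
  H * num / pmax(den, 1e-10)
}

#' One Negative Binomial multiplicative update of the exposure matrix
#'
#' Companion of [nb_update_H()]:
#' \deqn{W_{nk} \leftarrow W_{nk}\,
#'  \frac{\sum_m H_{km} V_{nm}/(WH)_{nm}}
#'       {\sum_m H_{km} (V_{nm}+\alpha_n)/((WH)_{nm}+\alpha_n)}.}
#'
#' @inheritParams nb_update_H
#' @return Updated `W` of the same shape.
#' @export
nb_update_W <- function(V, W, H, alphas) {
  a <- check_alphas(alphas, nrow(V))
  L <- pmax(W %*% H, 1e-10)
  num <- (V / L) %*% t(H)
  den <- ((V + a) / (L + a)) %*% t(H)
  W * num / pmax(den, 1e-10)
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("Signature factorization fit\n")
  cat("  model      :", x$model, "\n")
  cat("  rank K     :", x$rank, "\n")
  cat("  patients   :", nrow(x$W), " mutation types:", ncol(x$H), "\n")
  cat("  divergence :", format(x$divergence, digits = 8),
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  cat("  loglik     :", format(x$loglik, digits = 8), "\n")
  if (!is.null(x$alphas)) {
    cat("  dispersion :",
        if (isTRUE(attr(x$alphas, "shared"))) {
          paste("shared alpha =", format(x$alphas[1], digits = 6))
        } else {
          paste0("per patient, median ",
                 format(stats::median(x$alphas), digits = 6))
        }, "\n")
  }
  invisible(x)
}

#' Fitted mean matrix of a factorization fit
#'
#' @param object A `signature_fit`.
#' @param ... Unused.
#' @return The matrix `W %*% H` of fitted means.
#' @export
fitted.signature_fit <- function(object, ...) {
  object$W %*% object$H
}

# ---- internal ---------------------------------------------------------------

check_nmf_inputs <- function(V, K) {
  validate_count_matrix(V)
  if (K < 1 || K > min(dim(V))) {
    stop("K must be in [1, ", min(dim(V)), "]")
  }
  if (any(rowSums(V) == 0)) {
    stop("all-zero patient row(s): ",
         paste(utils::head(rownames(V)[rowSums(V) == 0], 3), collapse = ", "))
  }
  if (any(colSums(V) == 0)) {
    stop("all-zero mutation-type column(s): ",
         paste(utils::head(colnames(V)[colSums(V) == 0], 3), collapse = ", "))
  }
  invisible(TRUE)
}

# Random init: entries uniform on (0, 1], scaled so mean(WH) = mean(V).
random_init <- function(N, M, K, V, seed_i) {
  if (!is.null(seed_i)) set.seed(seed_i)
  W <- matrix(runif(N * K, min = .Machine$double.eps, max = 1), N, K)
  H <- matrix(runif(K * M, min = .Machine$double.eps, max = 1), K, M)
  W <- W * mean(V) / mean(W %*% H)
  list(W = W, H = H)
}

# Multi-start race: every initialization runs to a screening tolerance
# (max(tol, 1e-5)); only the winner is refined to the requested tolerance.
# Local optima are separated by divergence gaps orders of magnitude larger
# than the screening refinement, so the winner is the same as under full
# runs at a fraction of the iterations.  The returned trace concatenates
# the winner's screening and refinement phases (still non-increasing).
run_inits <- function(V, K, alphas, n_inits, tol, max_iter, seed) {
  N <- nrow(V); M <- ncol(V)
  avec <- if (is.null(alphas)) numeric(0) else alphas
  screen_tol <- max(tol, 1e-5)
  best <- NULL
  for (i in seq_len(n_inits)) {
    init <- random_init(N, M, K, V, if (is.null(seed)) NULL else seed + i)
    res <- .nmf_mm_cpp(V, init$W, init$H, avec, screen_tol, max_iter)
    d <- res$trace[length(res$trace)]
    if (is.null(best) || d < best$divergence) {   # ties keep the lowest init
      best <- res
      best$divergence <- d
      best$best_init <- i
    }
  }
  if (tol < screen_tol && best$iterations < max_iter) {
    more <- .nmf_mm_cpp(V, best$W, best$H, avec, tol,
                        max_iter - best$iterations)
    best$W <- more$W
    best$H <- more$H
    best$trace <- c(best$trace, more$trace)
    best$iterations <- best$iterations + more$iterations
    best$converged <- more$converged
    best$divergence <- more$trace[length(more$trace)]
  }
  best
}

finish_fit <- function(runs, V, model, alphas, K, n_inits, seed) {
  W <- runs$W; H <- runs$H
  # row-stochastic H, W rescaled so WH is unchanged
  r <- rowSums(H)
  H <- H / r
  W <- sweep(W, 2, r, `*`)
  sig_ids <- paste0("S", seq_len(K))
  dimnames(W) <- list(rownames(V), sig_ids)
  dimnames(H) <- list(sig_ids, colnames(V))
  Lam <- W %*% H
  ll <- if (model == "poisson") poisson_loglik(V, Lam) else
    nb_loglik(V, Lam, alphas)
  structure(list(
    W = W, H = H, alphas = alphas, model = model, rank = K,
    divergence = runs$divergence,
    divergence_trace = as.numeric(runs$trace),
    loglik = ll,
    iterations = runs$iterations,
    converged = isTRUE(runs$converged),
    n_inits = n_inits, best_init = runs$best_init, seed = seed
  ), class = "signature_fit")
}
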