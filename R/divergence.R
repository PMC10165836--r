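#' Generalized Kullback-Leibler divergence
#'
#' \eqn{D(V \| \Lambda) = \sum_{nm} V_{nm}\log(V_{nm}/\Lambda_{nm}) - V_{nm}
#' + \Lambda_{nm}} with the convention \eqn{0 \log 0 = 0}.  This is the cost
#' minimized by Poisson NMF: up to a term not involving \eqn{\Lambda} it is
#' the negative Poisson log-likelihood of the counts.
#'
#' @param V Nonnegative count matrix.
#' @param Lambda Positive matrix of fitted means, same shape as `V`; entries
#'   below `1e-10` are clamped.
#' @return Nonnegative scalar, 0 iff `V == Lambda`.
#' @export
gkl_divergence <- function(V, Lambda) {
  check_same_shape(V, Lambda)
  L <- pmax(Lambda, 1e-10)
  term <- ifelse(V > 0, V * log(V / L), 0)
  d <- sum(term - V + L)
  zero_snap(d)
}

#' Negative Binomial divergence with patient-specific dispersion
#'
#' The divergence whose minimization in \eqn{\Lambda = WH} is equivalent to
#' maximizing the Negative Binomial log-likelihood at fixed dispersions:
#' \deqn{d_N(V\|\Lambda) = \sum_{nm} V_{nm}\log\frac{V_{nm}}{\Lambda_{nm}}
#'   - (\alpha_n + V_{nm})\log\frac{\alpha_n + V_{nm}}{\alpha_n +
#'   \Lambda_{nm}}.}
#' It is nonnegative and zero iff `V == Lambda`.  As all \eqn{\alpha_n \to
#' \infty} it converges to [gkl_divergence()].
#'
#' @inheritParams gkl_divergence
#' @param alphas Positive dispersion parameters, one per patient (row of
#'   `V`), or a single shared value.
#' @return Nonnegative scalar.
#' @export
nb_divergence <- function(V, Lambda, alphas) {
  check_same_shape(V, Lambda)
  a <- check_alphas(alphas, nrow(V))
  L <- pmax(Lambda, 1e-10)
  A <- matrix(a, nrow(V), ncol(V))
  t1 <- ifelse(V > 0, V * log(V / L), 0)
  AV <- A + V
  t2 <- AV * log(AV / (A + L))
  zero_snap(sum(t1 - t2))
}

#' Negative Binomial log-likelihood with patient-specific dispersion
#'
#' \deqn{\ell = \sum_{nm} \log\binom{\alpha_n + V_{nm} - 1}{V_{nm}}
#'  + V_{nm}\log\frac{\Lambda_{nm}}{\alpha_n+\Lambda_{nm}}
#'  + \alpha_n\log\frac{\alpha_n}{\alpha_n+\Lambda_{nm}}}
#' with the binomial coefficient evaluated through log-gamma so that
#' non-integer dispersions are supported.  Up to a constant in \eqn{\Lambda},
#' \eqn{-\ell} equals [nb_divergence()].
#'
#' @inheritParams nb_divergence
#' @return Finite scalar log-likelihood.
#' @export
nb_loglik <- function(V, Lambda, alphas) {
  check_same_shape(V, Lambda)
  a <- check_alphas(alphas, nrow(V))
  L <- pmax(Lambda, 1e-10)
  A <- matrix(a, nrow(V), ncol(V))
  lchoose_term <- lgamma(A + V) - lgamma(A) - lgamma(V + 1)
  sum(lchoose_term + V * log(L / (A + L)) + A * log(A / (A + L)))
}

#' Poisson log-likelihood of a count matrix given fitted means
#'
#' @inheritParams gkl_divergence
#' @return Scalar log-likelihood \eqn{\sum V\log\Lambda - \Lambda - \log V!}.
#' @export
poisson_loglik <- function(V, Lambda) {
  check_same_shape(V, Lambda)
  L <- pmax(Lambda, 1e-10)
  sum(V * log(L) - L - lgamma(V + 1))
}

# ---- internal ---------------------------------------------------------------

check_same_shape <- function(V, Lambda) {
  if (!all(dim(V) == dim(Lambda))) {
    stop("shape mismatch: V is ", nrow(V), "x", ncol(V), ", Lambda is ",
         nrow(Lambda), "x", ncol(Lambda))
  }
  invisible(TRUE)
}

check_alphas <- function(alphas, n) {
  a <- as.numeric(alphas)
  if (length(a) == 1) a <- rep(a, n)
  if (length(a) != n) {
    stop("need one dispersion per patient (", n, "), got ", length(a))
  }
  if (any(!is.finite(a)) || any(a <= 0)) stop("dispersions must be positive")
  a
}

# Snap tiny negative rounding residue of a theoretically nonnegative sum.
zero_snap <- function(d, tol = 1e-8) {
  if (d < 0 && d > -tol) 0 else d
}
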