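#' Maximum likelihood estimation of Negative Binomial dispersion
#'
#' Estimates the dispersion \eqn{\alpha} of the Negative Binomial model
#' \eqn{V_{nm} \sim \mathrm{NB}(\mathrm{mean} = \Lambda_{nm},
#' \mathrm{Var} = \Lambda_{nm}(1 + \Lambda_{nm}/\alpha_n))} by maximizing the
#' profile log-likelihood in \eqn{\alpha} at fixed means, typically the
#' fitted means \eqn{\widehat{WH}} of a Poisson NMF fit.  `mode = "patient"`
#' estimates one \eqn{\alpha_n} per patient from that patient's row;
#' `mode = "shared"` pools all cells into a single estimate.
#'
#' Newton-Raphson is run on \eqn{\theta = \log\alpha} (which keeps
#' \eqn{\alpha} positive), initialized at the method-of-moments estimate
#' \eqn{\hat\alpha = \sum \Lambda^2 / \sum[(V-\Lambda)^2 - \Lambda]}.  When
#' the Newton step is unstable the estimate falls back to golden-section
#' search on \eqn{\log\alpha}.  Data showing no overdispersion (score still
#' positive at the ceiling) return `alpha_cap`, signalling an effectively
#' Poisson patient.
#'
#' @param V Count matrix (patients x mutation types).
#' @param Lambda Positive matrix of fitted means, same shape.
#' @param mode `"patient"` (one dispersion per row) or `"shared"`.
#' @param alpha_cap Ceiling for the estimate; default `1e5`.
#' @param tol Convergence tolerance on the score (gradient in
#'   \eqn{\log\alpha}); default `1e-8`.
#' @param max_steps Maximum Newton iterations per estimate.
#' @return Numeric vector of length `nrow(V)` with attribute `shared`
#'   (`TRUE` when all entries are one pooled estimate).
#' @export
estimate_dispersion <- function(V, Lambda, mode = c("patient", "shared"),
                                alpha_cap = 1e5, tol = 1e-8, max_steps = 100L) {
  mode <- match.arg(mode)
  check_same_shape(V, Lambda)
  if (any(Lambda <= 0)) Lambda <- pmax(Lambda, 1e-10)
  if (mode == "shared") {
    a <- alpha_mle_one(as.numeric(V), as.numeric(Lambda), alpha_cap, tol,
                       max_steps)
    out <- rep(a, nrow(V))
    attr(out, "shared") <- TRUE
  } else {
    out <- vapply(seq_len(nrow(V)), function(n) {
      alpha_mle_one(V[n, ], Lambda[n, ], alpha_cap, tol, max_steps)
    }, numeric(1))
    attr(out, "shared") <- FALSE
  }
  names(out) <- rownames(V)
  out
}

# ---- internal ---------------------------------------------------------------

# NB profile log-likelihood in alpha at fixed means (constants in alpha kept;
# terms constant in both alpha and mu dropped).
alpha_profile_ll <- function(a, v, mu) {
  sum(lgamma(a + v) - lgamma(a) + a * log(a) - (a + v) * log(a + mu) +
        v * log(mu))
}

# Score d ell / d alpha.
alpha_score <- function(a, v, mu) {
  sum(digamma(a + v) - digamma(a) + log(a / (a + mu)) + 1 - (a + v) / (a + mu))
}

# Derivative of the score in alpha.
alpha_score_deriv <- function(a, v, mu) {
  sum(trigamma(a + v) - trigamma(a) + 1 / a - 1 / (a + mu) +
        (v - mu) / (a + mu)^2)
}

alpha_mle_one <- function(v, mu, alpha_cap, tol, max_steps) {
  # no overdispersion at the ceiling => effectively Poisson
  if (alpha_score(alpha_cap, v, mu) > 0) return(alpha_cap)

  # method-of-moments start: Var = mu (1 + mu / alpha)
  denom <- sum((v - mu)^2 - mu)
  a0 <- if (denom > 0) sum(mu^2) / denom else alpha_cap / 2
  a0 <- min(max(a0, 1e-3), alpha_cap)

  theta <- log(a0)
  lo <- log(1e-3); hi <- log(alpha_cap)
  ok <- FALSE
  for (i in seq_len(max_steps)) {
    a <- exp(theta)
    s <- alpha_score(a, v, mu)
    g <- a * s                                   # d ell / d theta
    if (abs(g) < tol) { ok <- TRUE; break }
    h <- a * s + a^2 * alpha_score_deriv(a, v, mu)
    if (!is.finite(h) || h >= 0) break           # not locally concave: bail
    step <- g / h
    if (!is.finite(step) || abs(step) > 5) break
    theta <- theta - step
    if (theta < lo || theta > hi) break
  }
  if (ok) return(exp(theta))

  # bracketed fallback (golden-section/Brent) on log alpha
  opt <- stats::optimize(function(th) alpha_profile_ll(exp(th), v, mu),
                         interval = c(lo, hi), maximum = TRUE, tol = 1e-10)
  a <- exp(opt$maximum)
  if (a > 0.999 * alpha_cap) alpha_cap else a
}
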