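#' Residual-based goodness-of-fit report
#'
#' Computes raw residuals \eqn{R_{nm} = V_{nm} - (WH)_{nm}}, the model
#' standard deviation of each cell (\eqn{\sigma^2 = \mu} for Poisson,
#' \eqn{\sigma^2 = \mu(1 + \mu/\alpha_n)} for Negative Binomial), Pearson
#' normalized residuals \eqn{R/\sigma}, and the fraction of cells inside
#' the \eqn{\pm b\sigma} band (default \eqn{b = 2}).  Under a correctly
#' specified model with moderate counts the normalized residuals are
#' approximately standard normal, so coverage at \eqn{\pm 2\sigma} should
#' be near 95%; a Poisson fit to overdispersed data shows clearly lower
#' coverage.  For Negative Binomial fits the report also tabulates the
#' \eqn{\sigma(\mu)} band curves of the median, least and most dispersed
#' patients over a grid of fitted means.
#'
#' @param V Count matrix.
#' @param fit A `signature_fit` conforming to `V`.
#' @param probs Quantile probabilities for the quantile comparison
#'   (default `c(0.025, 0.975)`).
#' @param band_multiplier Width of the residual band in standard
#'   deviations.
#' @return A `residual_report`: list with `fitted_means`, `raw_residuals`,
#'   `model_sd`, `normalized_residuals`, `band_multiplier`,
#'   `coverage_fraction`, `qq` (from [qq_data()]) and, for NB fits,
#'   `sigma_curves`.
#' @export
residual_report <- function(V, fit, probs = c(0.025, 0.975),
                            band_multiplier = 2) {
  stopifnot(inherits(fit, "signature_fit"))
  Lam <- fit$W %*% fit$H
  check_same_shape(V, Lam)
  raw <- V - Lam
  if (fit$model == "poisson") {
    vr <- Lam
  } else {
    a <- check_alphas(fit$alphas, nrow(V))
    vr <- Lam * (1 + Lam / a)       # alpha recycles down columns (per patient)
  }
  sd_ <- sqrt(pmax(vr, 1e-10))
  norm <- raw / sd_
  cov <- mean(abs(raw) <= band_multiplier * sd_)

  out <- list(
    fitted_means = Lam, raw_residuals = raw, model_sd = sd_,
    normalized_residuals = norm, band_multiplier = band_multiplier,
    coverage_fraction = cov,
    qq = qq_data(norm, probs = probs)
  )
  if (fit$model != "poisson") {
    a <- check_alphas(fit$alphas, nrow(V))
    mu_grid <- seq(min(Lam), max(Lam), length.out = 50)
    sig <- function(alpha) sqrt(mu_grid * (1 + mu_grid / alpha))
    out$sigma_curves <- data.frame(
      mean = mu_grid,
      sigma_median = sig(stats::median(a)),
      sigma_min = sig(max(a)),       # largest alpha = least dispersed
      sigma_max = sig(min(a))
    )
  }
  class(out) <- "residual_report"
  out
}

#' @export
print.residual_report <- function(x, ...) {
  cat("Residual report\n")
  cat("  cells               :", length(x$raw_residuals), "\n")
  cat(sprintf("  coverage (+/- %g sd) : %.3f\n", x$band_multiplier,
              x$coverage_fraction))
  cat("  quantiles (empirical vs theoretical):\n")
  print(x$qq, row.names = FALSE)
  invisible(x)
}

#' Empirical vs theoretical quantiles of normalized residuals
#'
#' @param normalized_residuals Numeric vector or matrix of Pearson
#'   residuals.
#' @param probs Probabilities at which to compare quantiles.
#' @param reference Reference distribution; only `"std_normal"`.
#' @return Data frame with columns `prob`, `empirical`, `theoretical`.
#' @export
qq_data <- function(normalized_residuals, probs = c(0.025, 0.975),
                    reference = c("std_normal")) {
  reference <- match.arg(reference)
  r <- as.numeric(normalized_residuals)
  if (length(r) == 0) stop("empty residuals")
  data.frame(
    prob = probs,
    empirical = as.numeric(quantile(r, probs, names = FALSE)),
    theoretical = qnorm(probs)
  )
}

#' Best catalog match per estimated signature
#'
#' For every estimated signature, finds the catalog signature with the
#' highest cosine similarity (many-to-one matches allowed, unlike
#' [match_signatures()]).  Similarities at or above `threshold` (default
#' 0.8, a conventional cutoff for grouping similar signatures) are flagged.
#'
#' @param H Estimated signature matrix (rows = signatures).
#' @param catalog Reference catalog as from [read_signature_catalog()],
#'   with the same mutation-type order.
#' @param threshold Flagging threshold for the cosine similarity.
#' @return Data frame with columns `signature`, `best_match`, `cosine`,
#'   `flagged`.
#' @export
catalog_similarity <- function(H, catalog, threshold = 0.8) {
  if (ncol(H) != ncol(catalog)) {
    stop("H and catalog must share the mutation-type dimension")
  }
  if (any(rowSums(H^2) == 0) || any(rowSums(catalog^2) == 0)) {
    stop("zero signature row: cosine similarity undefined")
  }
  S <- cosine_matrix(H, catalog)
  best <- apply(S, 1, which.max)
  sim <- S[cbind(seq_len(nrow(S)), best)]
  data.frame(
    signature = if (is.null(rownames(H))) paste0("S", seq_len(nrow(H)))
                else rownames(H),
    best_match = colnames(S)[best],
    cosine = sim,
    flagged = sim >= threshold,
    row.names = NULL
  )
}

#' Residual diagnostic plot
#'
#' Base-graphics rendering of a [residual_report()]: raw residuals against
#' fitted means with the \eqn{\pm b\sigma} band, and a second panel of
#' normalized residuals with the reference quantiles.
#'
#' @param x A `residual_report`.
#' @param ... Passed to `plot`.
#' @return Invisibly, `x`.
#' @export
plot.residual_report <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  mu <- as.numeric(x$fitted_means)
  graphics::plot(mu, as.numeric(x$raw_residuals), pch = 16, cex = 0.4,
                 xlab = "fitted mean", ylab = "raw residual",
                 main = "raw residuals", ...)
  o <- order(mu)
  graphics::lines(mu[o], x$band_multiplier * as.numeric(x$model_sd)[o],
                  col = "red")
  graphics::lines(mu[o], -x$band_multiplier * as.numeric(x$model_sd)[o],
                  col = "red")
  graphics::plot(mu, as.numeric(x$normalized_residuals), pch = 16, cex = 0.4,
                 xlab = "fitted mean", ylab = "normalized residual",
                 main = "normalized residuals")
  graphics::abline(h = x$qq$theoretical, col = "blue", lty = 2)
  graphics::abline(h = x$qq$empirical, col = "gray40")
  invisible(x)
}
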