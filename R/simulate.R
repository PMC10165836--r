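#' Configuration for the mutational-count simulator
#'
#' Collects and validates the parameters of the benchmark generator: counts
#' are built as `W %*% H` from Negative Binomial exposures and catalog (or
#' Dirichlet) signatures, then each cell is resampled from the configured
#' noise distribution with that mean.  Defaults follow the benchmark design
#' this generator emulates: exposures with mean 6000 and dispersion 1.5,
#' and Negative Binomial noise with dispersion 10 or 200 (or per-patient
#' dispersions uniform on \[10, 500\]).
#'
#' @param n_patients Number of patients N.
#' @param n_signatures Number of signatures K.
#' @param exposure_mean,exposure_dispersion Mean and NB dispersion of the
#'   i.i.d. exposure draws (variance `mu * (1 + mu/dispersion)`).
#' @param noise One of `"none"`, `"poisson"`, `"negbin_fixed"`,
#'   `"negbin_patient"`.
#' @param alpha Shared noise dispersion for `"negbin_fixed"`.
#' @param alpha_range Ordered positive pair for `"negbin_patient"`;
#'   per-patient dispersions are drawn uniformly from it.
#' @param signature_source `"catalog_file"` (sample signatures from a
#'   catalog, always including `forced_signatures`) or `"dirichlet_random"`.
#' @param forced_signatures Catalog labels always included in catalog mode;
#'   default `c("SBS1", "SBS5")`, the signatures shared across cancer
#'   types.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it (Mersenne-Twister RNG).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 100L, n_signatures = 5L,
                              exposure_mean = 6000, exposure_dispersion = 1.5,
                              noise = c("poisson", "none", "negbin_fixed",
                                        "negbin_patient"),
                              alpha = 200, alpha_range = c(10, 500),
                              signature_source = c("catalog_file",
                                                   "dirichlet_random"),
                              forced_signatures = c("SBS1", "SBS5"),
                              seed = NULL) {
  noise <- match.arg(noise)
  signature_source <- match.arg(signature_source)
  stopifnot(n_patients >= 1, n_signatures >= 1,
            exposure_mean > 0, exposure_dispersion > 0)
  if (noise == "negbin_fixed" && (!is.numeric(alpha) || alpha <= 0)) {
    stop("negbin_fixed noise needs a positive alpha")
  }
  if (noise == "negbin_patient") {
    if (length(alpha_range) != 2 || any(alpha_range <= 0) ||
        alpha_range[1] > alpha_range[2]) {
      stop("alpha_range must be an ordered positive pair")
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_signatures = as.integer(n_signatures),
    exposure_mean = exposure_mean,
    exposure_dispersion = exposure_dispersion,
    noise = noise, alpha = alpha, alpha_range = alpha_range,
    signature_source = signature_source,
    forced_signatures = forced_signatures, seed = seed
  ), class = "simulation_config")
}

#' Draw the true signature matrix for a simulation
#'
#' In catalog mode the forced signatures are always included and the
#' remaining `K - length(forced)` are sampled without replacement from the
#' rest of the catalog.  In Dirichlet mode each signature is an independent
#' symmetric Dirichlet draw (concentration 0.5, giving the peaky profiles
#' typical of real signatures).
#'
#' @param config A [simulation_config()].
#' @param catalog Optional catalog matrix (signatures as rows); defaults to
#'   the synthetic catalog shipped with the package.
#' @return Row-stochastic K x 96 signature matrix.
#' @export
draw_signatures <- function(config, catalog = NULL) {
  K <- config$n_signatures
  if (config$signature_source == "dirichlet_random") {
    M <- 96L
    H <- matrix(rgamma(K * M, shape = 0.5), K, M)
    H <- H / rowSums(H)
    dimnames(H) <- list(paste0("Sig", seq_len(K)), sbs96_types())
    return(H)
  }
  if (is.null(catalog)) catalog <- synthetic_catalog()
  forced <- config$forced_signatures
  missing_lab <- setdiff(forced, rownames(catalog))
  if (length(missing_lab) > 0) {
    stop("forced signature(s) not in catalog: ",
         paste(missing_lab, collapse = ", "))
  }
  if (K > nrow(catalog)) {
    stop("K = ", K, " exceeds catalog size ", nrow(catalog))
  }
  pool <- setdiff(rownames(catalog), forced)
  n_extra <- K - length(forced)
  if (n_extra < 0) stop("more forced signatures than K")
  extra <- if (n_extra > 0) sample(pool, n_extra) else character(0)
  catalog[c(forced, extra), , drop = FALSE]
}

#' Draw the true exposure matrix for a simulation
#'
#' N x K i.i.d. Negative Binomial draws with the configured mean and
#' dispersion (`rnbinom(mu = mean, size = dispersion)`, so the variance is
#' `mu * (1 + mu/dispersion)`).
#'
#' @param config A [simulation_config()].
#' @return Nonnegative integer N x K matrix.
#' @export
draw_exposures <- function(config) {
  N <- config$n_patients; K <- config$n_signatures
  W <- matrix(rnbinom(N * K, size = config$exposure_dispersion,
                      mu = config$exposure_mean), N, K)
  rownames(W) <- sprintf("P%03d", seq_len(N))
  W
}

#' Resample counts around a mean matrix under the configured noise model
#'
#' Each cell is drawn independently with expectation equal to the given
#' mean: Poisson, Negative Binomial with shared dispersion, or Negative
#' Binomial with per-patient dispersions drawn uniformly from
#' `alpha_range`.  `noise = "none"` rounds the means.  (Resampling rather
#' than adding noise keeps the mean structure `E[V] = WH` exact.)
#'
#' @param mean_matrix Nonnegative matrix of target means.
#' @param config A [simulation_config()].
#' @return List with `counts` (integer matrix, same dimnames) and `alphas`
#'   (per-patient dispersions, or `NULL` when the noise model has none).
#' @export
apply_noise <- function(mean_matrix, config) {
  if (any(mean_matrix < 0)) stop("mean matrix must be nonnegative")
  N <- nrow(mean_matrix); M <- ncol(mean_matrix)
  mu <- as.numeric(mean_matrix)
  alphas <- NULL
  counts <- switch(config$noise,
    none = round(mu),
    poisson = rpois(N * M, mu),
    negbin_fixed = {
      alphas <- rep(config$alpha, N)
      rnbinom(N * M, size = config$alpha, mu = mu)
    },
    negbin_patient = {
      alphas <- runif(N, config$alpha_range[1], config$alpha_range[2])
      # size recycles over the column-major layout: one alpha per row
      rnbinom(N * M, size = rep(alphas, times = M), mu = mu)
    })
  counts <- matrix(as.numeric(counts), N, M, dimnames = dimnames(mean_matrix))
  if (!is.null(alphas)) names(alphas) <- rownames(mean_matrix)
  list(counts = counts, alphas = alphas)
}

#' Simulate a benchmark mutational count dataset
#'
#' Composition of [draw_signatures()], [draw_exposures()], the product
#' `W %*% H`, and [apply_noise()]; fully determined by `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param catalog Optional catalog for [draw_signatures()].
#' @return A `simulated_dataset`: list with `counts`, `true_W`, `true_H`,
#'   `true_alphas` (or `NULL`) and `config`.
#' @export
simulate_dataset <- function(config, catalog = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  H <- draw_signatures(config, catalog)
  W <- draw_exposures(config)
  mean_matrix <- W %*% H
  noise <- apply_noise(mean_matrix, config)
  structure(list(
    counts = noise$counts, true_W = W, true_H = H,
    true_alphas = noise$alphas, config = config
  ), class = "simulated_dataset")
}

#' The synthetic signature catalog shipped with the package
#'
#' Ten synthetic row-stochastic SBS96 signatures labelled SBS1...SBS10 so
#' that catalog-mode simulation works offline.  They are Dirichlet-style
#' stand-ins with realistic sparsity, not estimates of the published
#' consensus signatures of the same names.
#'
#' @return 10 x 96 row-stochastic matrix.
#' @export
synthetic_catalog <- function() {
  path <- system.file("extdata", "synthetic_sbs96_catalog.tsv",
                      package = "nbsig")
  if (path == "") stop("bundled synthetic catalog not found")
  read_signature_catalog(path)
}

#' Write a simulated dataset to a directory
#'
#' Emits `counts.tsv`, `true_W.tsv`, `true_H.tsv`, `true_alpha.tsv` (when
#' the noise model has dispersions) and a `manifest.txt` with the full
#' configuration and the RNG algorithm.
#'
#' @param sim A `simulated_dataset`.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_simulated_dataset <- function(sim, out_dir) {
  stopifnot(inherits(sim, "simulated_dataset"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_count_matrix(sim$counts, file.path(out_dir, "counts.tsv"))
  write_labelled_tsv(sim$true_W, file.path(out_dir, "true_W.tsv"),
                     corner = "Patient")
  write_labelled_tsv(t(sim$true_H), file.path(out_dir, "true_H.tsv"),
                     corner = "Type")
  if (!is.null(sim$true_alphas)) {
    a <- matrix(sim$true_alphas, ncol = 1,
                dimnames = list(rownames(sim$counts), "alpha"))
    write_labelled_tsv(a, file.path(out_dir, "true_alpha.tsv"),
                       corner = "Patient")
  }
  cfg <- sim$config
  lines <- c(
    paste0("n_patients\t", cfg$n_patients),
    paste0("n_signatures\t", cfg$n_signatures),
    paste0("exposure_mean\t", cfg$exposure_mean),
    paste0("exposure_dispersion\t", cfg$exposure_dispersion),
    paste0("noise\t", cfg$noise),
    paste0("alpha\t", cfg$alpha),
    paste0("alpha_range\t", paste(cfg$alpha_range, collapse = ",")),
    paste0("signature_source\t", cfg$signature_source),
    paste0("forced_signatures\t", paste(cfg$forced_signatures,
                                        collapse = ",")),
    paste0("seed\t", if (is.null(cfg$seed)) "NA" else cfg$seed),
    "rng\tMersenne-Twister"
  )
  writeLines(lines, file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}
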