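#' Read a mutational count matrix from a tab-separated file
#'
#' The file must have a header row and a first column of labels; the body is
#' numeric.  With `orientation = "patients_as_rows"` rows are patients and
#' columns mutation types; with `"patients_as_columns"` the file stores the
#' transpose (mutation types as rows) and is transposed on reading.  The
#' returned matrix always has patients as rows.  Orientation is never
#' guessed: a 96 x 96 file would be ambiguous.
#'
#' @param path Path to a TSV file.
#' @param orientation Either `"patients_as_rows"` (default) or
#'   `"patients_as_columns"`.
#' @return Numeric matrix of nonnegative integer counts with patient ids as
#'   row names and mutation types as column names.
#' @export
read_count_matrix <- function(path,
                              orientation = c("patients_as_rows",
                                              "patients_as_columns")) {
  orientation <- match.arg(orientation)
  V <- read_labelled_tsv(path)
  if (orientation == "patients_as_columns") V <- t(V)
  validate_count_matrix(V)
  V
}

#' Write a mutational count matrix as TSV
#'
#' Inverse of [read_count_matrix()] with `orientation = "patients_as_rows"`:
#' header = mutation types, first column = patient id.
#'
#' @param V Count matrix, patients as rows.
#' @param path Output file path.
#' @export
write_count_matrix <- function(V, path) {
  validate_count_matrix(V)
  write_labelled_tsv(V, path, corner = "Patient", integer = TRUE)
  invisible(path)
}

#' Read a signature catalog (COSMIC-style TSV)
#'
#' The file stores mutation types as rows (first column, `"A[C>A]A"`
#' notation) and signatures as columns.  Rows are reordered to the canonical
#' SBS96 order of [sbs96_types()] and the result is returned with signatures
#' as rows.  Signature probability vectors whose sum deviates from 1 by more
#' than `1e-6` are renormalized with a warning (published catalogs carry
#' rounding error).
#'
#' @param path Path to a TSV catalog.
#' @return Numeric matrix, signatures as rows (row names = signature ids),
#'   96 columns in canonical SBS96 order, each row summing to 1.
#' @export
read_signature_catalog <- function(path) {
  M <- read_labelled_tsv(path)
  if (nrow(M) != 96) {
    stop("expected 96 mutation types, got ", nrow(M), " rows in ", path)
  }
  if (any(M < 0)) {
    bad <- which(M < 0, arr.ind = TRUE)[1, ]
    stop("negative entry at mutation type '", rownames(M)[bad[1]],
         "', signature '", colnames(M)[bad[2]], "'")
  }
  if (any(colSums(M) <= 0)) {
    stop("signature column(s) with nonpositive sum: ",
         paste(colnames(M)[colSums(M) <= 0], collapse = ", "))
  }
  M <- M[sbs96_order(rownames(M)), , drop = FALSE]
  H <- t(M)
  s <- rowSums(H)
  off <- abs(s - 1) > 1e-6
  if (any(off)) {
    warning("renormalizing ", sum(off), " signature(s) whose probabilities ",
            "did not sum to 1 (max deviation ", signif(max(abs(s - 1)), 3), ")")
  }
  H / s
}

#' Write a signature matrix as a COSMIC-style catalog TSV
#'
#' @param H Signature matrix, signatures as rows, mutation types as columns.
#' @param path Output file path.
#' @export
write_signature_catalog <- function(H, path) {
  validate_signature_matrix(H)
  write_labelled_tsv(t(H), path, corner = "Type", integer = FALSE)
  invisible(path)
}

#' Read an exposure matrix (patients x signatures) from TSV
#'
#' @param path Path to a TSV file with patients as rows.
#' @return Numeric matrix of nonnegative exposures.
#' @export
read_exposure_matrix <- function(path) {
  W <- read_labelled_tsv(path)
  if (any(W < 0)) stop("negative exposure entries in ", path)
  W
}

#' Write a factorization fit to a directory
#'
#' Emits `W.tsv` (patients x signatures), `H.tsv` (catalog orientation:
#' mutation types x signatures), `alpha.tsv` (per-patient dispersion, only
#' for Negative Binomial fits) and a plain-text `manifest.txt` recording the
#' model tag, rank, seed, iteration count and final divergence.
#'
#' @param fit A `signature_fit` object from [poisson_nmf()] or [nb_nmf()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_fit <- function(fit, out_dir) {
  stopifnot(inherits(fit, "signature_fit"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory ", out_dir)
  }
  write_labelled_tsv(fit$W, file.path(out_dir, "W.tsv"),
                     corner = "Patient", integer = FALSE)
  write_labelled_tsv(t(fit$H), file.path(out_dir, "H.tsv"),
                     corner = "Type", integer = FALSE)
  if (!is.null(fit$alphas)) {
    a <- matrix(as.numeric(fit$alphas), ncol = 1,
                dimnames = list(rownames(fit$W), "alpha"))
    write_labelled_tsv(a, file.path(out_dir, "alpha.tsv"),
                       corner = "Patient", integer = FALSE)
  }
  manifest <- c(
    model       = fit$model,
    rank        = fit$rank,
    n_inits     = fit$n_inits,
    seed        = if (is.null(fit$seed)) NA else fit$seed,
    best_init   = fit$best_init,
    iterations  = fit$iterations,
    converged   = fit$converged,
    divergence  = formatC(fit$divergence, digits = 15, format = "g"),
    loglik      = formatC(fit$loglik, digits = 15, format = "g"),
    rng_kind    = "Mersenne-Twister",
    package     = as.character(utils::packageVersion("nbsig"))
  )
  writeLines(paste(names(manifest), manifest, sep = "\t"),
             file.path(out_dir, "manifest.txt"))
  invisible(out_dir)
}

# ---- internal helpers -------------------------------------------------------

# Read a TSV with a header row and a label column; returns a numeric matrix.
read_labelled_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) stop("empty or label-only matrix in ", path)
  labels <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    if (!is.numeric(body[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(body[[j]]))))[1]
      stop("non-numeric cell at row '", labels[bad], "', column '",
           colnames(body)[j], "' in ", path)
    }
  }
  if (anyDuplicated(labels)) stop("duplicate row labels in ", path)
  if (anyDuplicated(colnames(body))) stop("duplicate column labels in ", path)
  M <- as.matrix(body)
  rownames(M) <- labels
  M
}

write_labelled_tsv <- function(M, path, corner = "id", integer = FALSE) {
  fmt <- if (integer) {
    format(M, scientific = FALSE, trim = TRUE)
  } else {
    formatC(M, digits = 15, format = "g")
  }
  fmt <- matrix(fmt, nrow = nrow(M), dimnames = dimnames(M))
  lines <- c(
    paste(c(corner, colnames(M)), collapse = "\t"),
    vapply(seq_len(nrow(M)), function(i) {
      paste(c(rownames(M)[i], fmt[i, ]), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
}

validate_count_matrix <- function(V) {
  if (!is.matrix(V) || !is.numeric(V)) stop("count matrix must be numeric")
  if (nrow(V) == 0 || ncol(V) == 0) stop("empty count matrix")
  if (any(V < 0)) {
    bad <- which(V < 0, arr.ind = TRUE)[1, ]
    stop("negative count at patient '", rownames(V)[bad[1]],
         "', mutation type '", colnames(V)[bad[2]], "'")
  }
  if (any(abs(V - round(V)) > 1e-8)) {
    bad <- which(abs(V - round(V)) > 1e-8, arr.ind = TRUE)[1, ]
    stop("non-integer count at patient '", rownames(V)[bad[1]],
         "', mutation type '", colnames(V)[bad[2]], "'")
  }
  if (anyDuplicated(rownames(V))) stop("duplicate patient ids")
  if (anyDuplicated(colnames(V))) stop("duplicate mutation types")
  if (ncol(V) != 96) {
    message("note: count matrix has ", ncol(V),
            " mutation types (SBS96 data have 96)")
  }
  invisible(TRUE)
}

validate_signature_matrix <- function(H, tol = 1e-8) {
  if (!is.matrix(H) || !is.numeric(H)) stop("signature matrix must be numeric")
  if (any(H < 0)) stop("negative signature entries")
  s <- rowSums(H)
  if (any(abs(s - 1) > tol)) {
    stop("signature row(s) do not sum to 1 (max deviation ",
         signif(max(abs(s - 1)), 3), ")")
  }
  invisible(TRUE)
}
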