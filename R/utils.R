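#' Rank-based inverse-normal transform
#'
#' Maps values to standard-normal quantiles via the Blom-type offset
#' (rank - 0.5)/n, the transform applied to model-training expression
#' residuals and to trait residuals before association testing.
#'
#' @param x Numeric vector; `NA`s are preserved.
#' @return Numeric vector of the same length with standard-normal margins.
#' @export
inverse_normal_transform <- function(x) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0L) return(out)
  out[ok] <- stats::qnorm((rank(x[ok], ties.method = "average") - 0.5) / n)
  out
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Column-standardize a dosage matrix; zero-variance columns become all-zero.
#' @keywords internal
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[sdv == 0] <- Inf
  sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
}

# Derive a reproducible 32-bit sub-seed from a base seed and an index.
#' @keywords internal
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(index) * 12289L) %% 2147483647)
}

#' @keywords internal
stop_if <- function(cond, msg) if (isTRUE(cond)) stop(msg, call. = FALSE)

#' Empirical minor allele frequency of dosage columns
#' @param dosage samples x variants numeric matrix of alt-allele dosages in [0, 2].
#' @return numeric vector of per-variant minor allele frequencies.
#' @export
empirical_maf <- function(dosage) {
  f <- colMeans(dosage) / 2
  pmin(f, 1 - f)
}
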