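#' Specify a Gaussian-process covariance kernel
#'
#' Two stationary families are used throughout the package: the squared
#' exponential (for smooth mean functions such as the population trajectory
#' `w(t)` and the coefficient curves `alpha(t)`, `beta(t)`) and the exponential
#' (Ornstein--Uhlenbeck) kernel, whose rough, mean-reverting sample paths
#' describe daily weather residuals.
#'
#' @param family `"squared_exponential"` or `"exponential"`.
#' @param variance Marginal variance (units of the modelled quantity, squared).
#' @param length_scale Correlation length in days.  For the exponential family
#'   this is the range parameter (e-folding distance).
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- kernel_spec("squared_exponential", variance = 2, length_scale = 5)
#' build_kernel_matrix(k, grid = -2:2)
#' @export
kernel_spec <- function(family = c("squared_exponential", "exponential"),
                        variance, length_scale) {
  family <- match.arg(family)
  if (!is.numeric(variance) || length(variance) != 1L || !is.finite(variance) ||
      variance < 0)
    stop("`variance` must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(length_scale) || length(length_scale) != 1L ||
      !is.finite(length_scale) || length_scale <= 0)
    stop("`length_scale` must be a single positive number", call. = FALSE)
  structure(list(family = family, variance = variance,
                 length_scale = length_scale),
            class = "kernel_spec")
}

#' Build a covariance matrix from a kernel specification
#'
#' @param spec A [kernel_spec()].
#' @param grid Numeric vector of (distinct, finite) input locations, in days.
#' @return A symmetric positive semi-definite matrix with `spec$variance` on
#'   the diagonal.
#' @export
build_kernel_matrix <- function(spec, grid) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.numeric(grid) || !all(is.finite(grid)))
    stop("`grid` must be a finite numeric vector", call. = FALSE)
  d <- abs(outer(grid, grid, "-"))
  K <- switch(spec$family,
    squared_exponential = spec$variance * exp(-d^2 / (2 * spec$length_scale^2)),
    exponential         = spec$variance * exp(-d / spec$length_scale)
  )
  (K + t(K)) / 2
}

se_kernel  <- function(grid, variance, length_scale)
  build_kernel_matrix(kernel_spec("squared_exponential", variance, length_scale), grid)
ou_kernel  <- function(grid, variance, range)
  build_kernel_matrix(kernel_spec("exponential", variance, range), grid)

## Cholesky with escalating diagonal jitter.  Jitter is only added when the
## plain factorization fails; the amount actually used is attached as an
## attribute so callers can log it.
chol_psd <- function(S, max_tries = 8L) {
  jit <- 0
  base <- mean(diag(S))
  if (!is.finite(base) || base <= 0) base <- 1
  for (i in 0:max_tries) {
    R <- tryCatch(chol(S + diag(jit, nrow(S))), error = function(e) NULL)
    if (!is.null(R)) {
      attr(R, "jitter") <- jit
      return(R)
    }
    jit <- if (jit == 0) base * 1e-10 else jit * 100
  }
  stop("covariance matrix could not be factorized even with jitter", call. = FALSE)
}

## log N(y; mu, S) via Cholesky; R optionally precomputed
mvn_logpdf <- function(y, mu, S = NULL, R = NULL) {
  if (is.null(R)) R <- chol_psd(S)
  z <- backsolve(R, y - mu, transpose = TRUE)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

## one draw from N(mu, S)
mvn_draw <- function(mu, S = NULL, R = NULL) {
  if (is.null(R)) R <- chol_psd(S)
  drop(mu + t(R) %*% rnorm(length(mu)))
}

## draw a GP sample path on `grid`
gp_draw <- function(grid, variance, length_scale,
                    family = "squared_exponential", mean = 0) {
  if (variance == 0) return(rep(mean, length(grid)) + numeric(length(grid)))
  K <- build_kernel_matrix(kernel_spec(family, variance, length_scale), grid)
  mvn_draw(rep(mean, length(grid)), K)
}
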