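#' Lognormal parameter container
#'
#' Log-scale location and spread of a lognormal distribution, together with
#' the fitting route that produced them. `sdlog = 0` is accepted as the
#' degenerate point-mass limit and flagged.
#'
#' @param meanlog log-scale location.
#' @param sdlog log-scale spread, >= 0.
#' @param provenance one of `"mle"`, `"moment_match"`, `"quantile_match"`,
#'   `"manual"`.
#' @return An object of class `lognormal_params`.
#' @export
lognormal_params <- function(meanlog, sdlog, provenance = "manual") {
  stopifnot_scalar_num(meanlog, "meanlog")
  stopifnot_scalar_num(sdlog, "sdlog", nonneg = TRUE)
  if (!is.finite(exp(meanlog + sdlog^2 / 2))) {
    stop("implied mean exp(meanlog + sdlog^2/2) is not finite")
  }
  structure(
    list(meanlog = meanlog, sdlog = sdlog, provenance = provenance,
         degenerate = sdlog == 0),
    class = "lognormal_params"
  )
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf(
    "lognormal (%s): meanlog = %.4f, sdlog = %.4f [mean %.4g, sd %.4g]%s\n",
    x$provenance, x$meanlog, x$sdlog,
    lognormal_mean(x), lognormal_sd(x),
    if (x$degenerate) " (degenerate)" else ""
  ))
  invisible(x)
}

#' @export
coef.lognormal_params <- function(object, ...) {
  c(meanlog = object$meanlog, sdlog = object$sdlog)
}

#' Implied arithmetic mean and SD of lognormal parameters
#' @param p a `lognormal_params` object.
#' @return A single number.
#' @export
lognormal_mean <- function(p) exp(p$meanlog + p$sdlog^2 / 2)

#' @rdname lognormal_mean
#' @export
lognormal_sd <- function(p) lognormal_mean(p) * sqrt(exp(p$sdlog^2) - 1)

#' Moment-matched lognormal parameters
#'
#' Closed-form match of a lognormal to a target arithmetic mean and SD:
#' `sdlog^2 = log(1 + (sd/mean)^2)`, `meanlog = log(mean) - sdlog^2/2`.
#' The implied moments round-trip the inputs exactly (to floating point).
#'
#' @param mean target arithmetic mean, > 0.
#' @param sd target arithmetic SD, >= 0 (0 gives the degenerate point mass).
#' @return A `lognormal_params` with provenance `"moment_match"`.
#' @examples
#' fit_lognormal_moments(0.78, 0.55)  # meanlog -0.4503, sdlog 0.6353
#' @export
fit_lognormal_moments <- function(mean, sd) {
  stopifnot_scalar_num(mean, "mean", positive = TRUE)
  stopifnot_scalar_num(sd, "sd", nonneg = TRUE)
  s2 <- log(1 + (sd / mean)^2)
  lognormal_params(log(mean) - s2 / 2, sqrt(s2), "moment_match")
}

#' Lognormal parameters from a mean and a 95th percentile
#'
#' Solves `meanlog + sdlog^2/2 = log(mean)` together with
#' `meanlog + z95 * sdlog = log(p95)` (z95 = 1.6449). The quadratic in
#' `sdlog` has two positive roots when solvable; the smaller is taken, the
#' larger corresponding to an implausibly extreme skew for consumption-type
#' data. Both target quantities round-trip exactly.
#'
#' @param mean target arithmetic mean, > 0.
#' @param p95 target 95th percentile, > mean.
#' @return A `lognormal_params` with provenance `"quantile_match"`.
#' @examples
#' fit_lognormal_mean_p95(234.15, 557.89)  # sdlog 0.6604
#' @export
fit_lognormal_mean_p95 <- function(mean, p95) {
  stopifnot_scalar_num(mean, "mean", positive = TRUE)
  stopifnot_scalar_num(p95, "p95", positive = TRUE)
  if (p95 <= mean) stop("p95 must exceed the mean for a lognormal")
  z95 <- stats::qnorm(0.95)
  # sdlog^2/2 - z95 sdlog + log(p95/mean) = 0
  disc <- z95^2 - 2 * log(p95 / mean)
  if (disc <= 0) {
    stop("no positive real root: p95/mean ratio too large for a lognormal ",
         "matched through its mean and 95th percentile")
  }
  s <- z95 - sqrt(disc)  # smaller root
  lognormal_params(log(mean) - s^2 / 2, s, "quantile_match")
}

#' Fit a lognormal to positive data
#'
#' Estimates `meanlog` and `sdlog` as the mean and SD of the log data
#' (SD with the n-1 divisor; the estimator convention for `sdlog`
#' throughout this package). Data containing zeros — as lower-bound
#' censored series do — cannot feed a lognormal directly; zeros are
#' replaced by half the smallest positive value and the substitution is
#' recorded in the result.
#'
#' @param x numeric vector, n >= 2, all values >= 0 with at least one
#'   positive.
#' @param zero_policy `"half_min_positive"` (default) or `"error"`.
#' @return A `lognormal_params` with provenance `"mle"` and extra fields
#'   `n`, `n_zero_substituted`; all-equal data yield `sdlog = 0`, flagged
#'   degenerate.
#' @export
fit_lognormal_mle <- function(x, zero_policy = c("half_min_positive", "error")) {
  zero_policy <- match.arg(zero_policy)
  x <- as.numeric(x)
  if (length(x) < 2) stop("need at least 2 observations")
  if (any(!is.finite(x)) || any(x < 0)) stop("data must be finite and >= 0")
  nz <- sum(x == 0)
  if (nz > 0) {
    if (zero_policy == "error") stop("data contain zeros")
    pos <- x[x > 0]
    if (!length(pos)) stop("all observations are zero; lognormal fit impossible")
    x[x == 0] <- min(pos) / 2
  }
  lx <- log(x)
  p <- lognormal_params(mean(lx), stats::sd(lx), "mle")
  p$n <- length(x)
  p$n_zero_substituted <- nz
  p
}

#' Kolmogorov-Smirnov goodness of fit for a lognormal
#'
#' `D` is the supremum distance between the empirical CDF and the fitted
#' lognormal CDF, evaluated at both sides of every jump (the 2n comparison
#' points). When `params` is omitted the lognormal is fitted to the data
#' first, which invalidates the classical KS null distribution; the p-value
#' is then obtained by parametric bootstrap with refitting on every
#' replicate (the Lilliefors construction). With fixed `params` the
#' bootstrap draws from them without refitting.
#'
#' @param x positive data, n >= 5.
#' @param params optional fixed `lognormal_params` to test against.
#' @param n_boot bootstrap replicates; below 100 a warning is recorded in
#'   the result (the p-value resolution gets too coarse to act on).
#' @param seed optional integer seed for the bootstrap.
#' @return A list of class `ks_gof`: `statistic` (D), `p_value`, `params`,
#'   `fitted` (logical), `n`, `n_boot`, `warning` (character or `NULL`).
#' @export
ks_gof <- function(x, params = NULL, n_boot = 1000, seed = NULL) {
  x <- as.numeric(x)
  if (length(x) < 5) stop("need at least 5 observations")
  if (any(x <= 0)) stop("data must be positive (substitute censored zeros first)")
  warn <- NULL
  if (n_boot < 100) warn <- "n_boot < 100: bootstrap p-value is unreliable"

  fitted <- is.null(params)
  if (fitted) params <- fit_lognormal_mle(x)
  n <- length(x)
  D0 <- ks_stat(x, params)

  p_value <- with_seed(seed, {
    exceed <- 0L
    for (b in seq_len(n_boot)) {
      xb <- stats::rlnorm(n, params$meanlog, params$sdlog)
      pb <- if (fitted) fit_lognormal_mle(xb) else params
      if (ks_stat(xb, pb) >= D0) exceed <- exceed + 1L
    }
    (1 + exceed) / (n_boot + 1)
  })

  structure(
    list(statistic = D0, p_value = p_value, params = params,
         fitted = fitted, n = n, n_boot = n_boot, warning = warn),
    class = "ks_gof"
  )
}

# sup |ECDF - F| over the 2n comparison points
ks_stat <- function(x, params) {
  n <- length(x)
  Fx <- stats::plnorm(sort(x), params$meanlog, params$sdlog)
  max(pmax(seq_len(n) / n - Fx, Fx - (seq_len(n) - 1) / n))
}

#' @export
print.ks_gof <- function(x, ...) {
  cat(sprintf(
    "KS lognormal goodness of fit (%s): D = %.4f, bootstrap p = %.4f (n = %d, B = %d)\n",
    if (x$fitted) "parameters refit per replicate" else "fixed parameters",
    x$statistic, x$p_value, x$n, x$n_boot
  ))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}
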