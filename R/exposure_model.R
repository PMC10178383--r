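#' Probabilistic exposure model
#'
#' The second-tier exposure model: milk-fat contamination `C` (pg TEQ/g fat)
#' and weekly milk consumption `M` (g/kg bw/week) are independent lognormal
#' random variables, the milk fat content `F` is fixed per milk type, and
#' the estimated weekly intake per draw is `EWI = C * M * F / 100`
#' (pg TEQ/kg bw/week).
#'
#' Because the product of independent lognormals is lognormal, the model's
#' EWI distribution is available in closed form with
#' `meanlog = meanlog_C + meanlog_M + log(F/100)` and
#' `sdlog = sqrt(sdlog_C^2 + sdlog_M^2)`; [quantile.exposure_model()],
#' [exceedance_prob()] and [summary.exposure_model()] use it, and
#' [simulate.exposure_model()] provides the seeded Monte Carlo counterpart.
#'
#' @param contamination `lognormal_params` for C.
#' @param consumption `lognormal_params` for M.
#' @param fat_content fixed F, g fat/100 g, > 0.
#' @param twi tolerable weekly intake, pg TEQ/kg bw/week.
#' @param label optional cell label (e.g. "infants/whole/MB") carried into
#'   reports.
#' @return An object of class `exposure_model`.
#' @examples
#' m <- exposure_model(
#'   fit_lognormal_moments(0.78, 0.55),
#'   fit_lognormal_mean_p95(234.15, 557.89),
#'   fat_content = 3.5
#' )
#' exceedance_prob(m)  # 0.791
#' @export
exposure_model <- function(contamination, consumption, fat_content,
                           twi = 2, label = NULL) {
  stopifnot(inherits(contamination, "lognormal_params"),
            inherits(consumption, "lognormal_params"))
  stopifnot_scalar_num(fat_content, "fat_content", positive = TRUE)
  stopifnot_scalar_num(twi, "twi", positive = TRUE)
  structure(
    list(
      contamination = contamination,
      consumption = consumption,
      fat_content = fat_content,
      twi = twi,
      label = label,
      meanlog = contamination$meanlog + consumption$meanlog + log(fat_content / 100),
      sdlog = sqrt(contamination$sdlog^2 + consumption$sdlog^2)
    ),
    class = "exposure_model"
  )
}

#' Closed-form EWI quantiles of an exposure model
#'
#' @param x an [exposure_model()].
#' @param probs probabilities in (0, 1).
#' @param ... unused.
#' @return Named vector of EWI quantiles, pg TEQ/kg bw/week.
#' @export
quantile.exposure_model <- function(x, probs = seq(0.1, 0.9, by = 0.1), ...) {
  stopifnot(all(probs > 0 & probs < 1))
  q <- exp(x$meanlog + stats::qnorm(probs) * x$sdlog)
  names(q) <- paste0(format(100 * probs, trim = TRUE), "%")
  q
}

#' Closed-form probability that the EWI exceeds the TWI
#'
#' `P(EWI > twi) = Phi((meanlog_total - log(twi)) / sdlog_total)`; in the
#' degenerate (sdlog 0) limit the indicator of the deterministic EWI
#' exceeding the TWI.
#'
#' @param model an [exposure_model()].
#' @param twi override of the model's TWI.
#' @return Probability in `[0, 1]`.
#' @export
exceedance_prob <- function(model, twi = model$twi) {
  stopifnot(inherits(model, "exposure_model"))
  stopifnot_scalar_num(twi, "twi", positive = TRUE)
  if (model$sdlog == 0) return(as.numeric(exp(model$meanlog) > twi))
  stats::pnorm((model$meanlog - log(twi)) / model$sdlog)
}

#' @export
print.exposure_model <- function(x, ...) {
  cat("Lognormal-product exposure model",
      if (!is.null(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  contamination: meanlog %.4f, sdlog %.4f (%s)\n",
              x$contamination$meanlog, x$contamination$sdlog,
              x$contamination$provenance))
  cat(sprintf("  consumption:   meanlog %.4f, sdlog %.4f (%s)\n",
              x$consumption$meanlog, x$consumption$sdlog,
              x$consumption$provenance))
  cat(sprintf("  fat %.1f g/100 g, TWI %g pg TEQ/kg bw/week\n",
              x$fat_content, x$twi))
  cat(sprintf("  P(EWI > TWI) = %.4f (closed form)\n", exceedance_prob(x)))
  invisible(x)
}

#' @export
summary.exposure_model <- function(object, probs = seq(0.1, 0.9, by = 0.1), ...) {
  ml <- object$meanlog; sl <- object$sdlog
  out <- list(
    model = object,
    ewi_mean = exp(ml + sl^2 / 2),
    ewi_sd = exp(ml + sl^2 / 2) * sqrt(exp(sl^2) - 1),
    ewi_median = exp(ml),
    ewi_percentiles = quantile(object, probs),
    pct_twi_percentiles = 100 * quantile(object, probs) / object$twi,
    exceedance_prob = exceedance_prob(object)
  )
  class(out) <- "summary.exposure_model"
  out
}

#' @export
print.summary.exposure_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("  EWI mean %.3f, sd %.3f, median %.3f pg TEQ/kg bw/week\n",
              x$ewi_mean, x$ewi_sd, x$ewi_median))
  cat("  percentiles (pg TEQ/kg bw/week):\n")
  print(round(x$ewi_percentiles, 3))
  invisible(x)
}

#' Monte Carlo simulation of an exposure model
#'
#' Draws `nsim` independent (C, M) pairs, forms the per-draw EWI, and
#' summarises the simulated distribution: mean, SD, percentile grid (for
#' both EWI and %TWI), and the fraction of draws exceeding the TWI. The
#' same `seed` and `nsim` always give a bit-identical result; the caller's
#' RNG state is left untouched.
#'
#' Percentile estimates use the default quantile estimator (linear
#' interpolation of the empirical CDF, [stats::quantile()] type 7).
#' Percentiles beyond the 90th are computable through `percentiles` but are
#' flagged low-support in the result: the right tail of a 50,000-draw
#' simulation of a skewed product carries few observations.
#'
#' @param object an [exposure_model()].
#' @param nsim number of iterations, >= 1000 (convention: 50,000).
#' @param seed integer seed.
#' @param percentiles percentile grid (percent units, strictly increasing
#'   in (0, 100)), default 10th-90th by 10.
#' @param ... unused.
#' @return An object of class `mc_exposure`: fields `ewi_mean`, `ewi_sd`,
#'   `ewi_percentiles`, `pct_twi_percentiles`, `exceedance_prob`, `n_iter`,
#'   `seed`, `label`, `low_support` (logical per percentile), and `draws`
#'   (the simulated EWIs, for plotting).
#' @examples
#' m <- exposure_model(fit_lognormal_moments(0.78, 0.55),
#'                     fit_lognormal_mean_p95(234.15, 557.89), 3.5)
#' sim <- simulate(m, nsim = 5000, seed = 7)
#' sim$exceedance_prob
#' @export
simulate.exposure_model <- function(object, nsim = 50000, seed = NULL,
                                    percentiles = seq(10, 90, by = 10), ...) {
  if (nsim < 1000) stop("nsim must be at least 1000")
  if (any(percentiles <= 0 | percentiles >= 100) ||
      any(diff(percentiles) <= 0)) {
    stop("percentiles must be strictly increasing within (0, 100)")
  }
  draws <- with_seed(seed, {
    C <- stats::rlnorm(nsim, object$contamination$meanlog, object$contamination$sdlog)
    M <- stats::rlnorm(nsim, object$consumption$meanlog, object$consumption$sdlog)
    ewi(C, M, object$fat_content)
  })
  qs <- stats::quantile(draws, percentiles / 100, names = FALSE, type = 7)
  names(qs) <- paste0(percentiles, "%")
  structure(
    list(
      ewi_mean = mean(draws),
      ewi_sd = stats::sd(draws),
      ewi_percentiles = qs,
      pct_twi_percentiles = 100 * qs / object$twi,
      exceedance_prob = mean(draws > object$twi),
      n_iter = nsim,
      seed = seed,
      label = object$label,
      low_support = percentiles > 90,
      model = object,
      draws = draws
    ),
    class = "mc_exposure"
  )
}

#' @export
print.mc_exposure <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo exposure simulation%s: %d iterations%s\n",
    if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
    x$n_iter,
    if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")") else ""
  ))
  cat(sprintf("  EWI mean %.3f +/- %.3f pg TEQ/kg bw/week\n", x$ewi_mean, x$ewi_sd))
  cat("  EWI percentiles:\n"); print(round(x$ewi_percentiles, 3))
  cat(sprintf("  P(EWI > TWI) = %.4f\n", x$exceedance_prob))
  if (any(x$low_support)) {
    cat("  note: percentiles beyond the 90th have low tail support\n")
  }
  invisible(x)
}

#' Cumulative risk curve
#'
#' Plots the cumulative probability of the percent contribution to the TWI
#' — the Monte Carlo analogue of a cumulative risk chart — with the TWI
#' (100%) marked.
#'
#' @param x an `mc_exposure` (or an `exposure_model`, plotted from its
#'   closed form).
#' @param xmax right edge of the %TWI axis.
#' @param ... passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.mc_exposure <- function(x, xmax = NULL, ...) {
  pct <- 100 * sort(x$draws) / x$model$twi
  p <- seq_along(pct) / length(pct)
  if (is.null(xmax)) xmax <- stats::quantile(pct, 0.99)
  graphics::plot(pct, p, type = "l", xlim = c(0, xmax),
                 xlab = "% of TWI", ylab = "cumulative probability",
                 main = x$label %||% "Cumulative risk", ...)
  graphics::abline(v = 100, lty = 2)
  invisible(x)
}

#' @export
plot.exposure_model <- function(x, xmax = NULL, ...) {
  probs <- seq(0.001, 0.999, by = 0.001)
  pct <- 100 * quantile(x, probs) / x$twi
  if (is.null(xmax)) xmax <- 100 * quantile(x, 0.99) / x$twi
  graphics::plot(pct, probs, type = "l", xlim = c(0, xmax),
                 xlab = "% of TWI", ylab = "cumulative probability",
                 main = x$label %||% "Cumulative risk (closed form)", ...)
  graphics::abline(v = 100, lty = 2)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decile report across simulated cells
#'
#' Binds the percentile grids of a set of Monte Carlo simulations into the
#' long report shape used for scenario x age group x milk type tables: one
#' row per cell and percentile, with both the EWI and the %TWI value.
#'
#' @param sims a list of `mc_exposure` objects; names (or labels) identify
#'   the cells.
#' @return A data frame of class `risk_table` with columns `cell`,
#'   `percentile`, `ewi`, `pct_twi`.
#' @export
risk_table <- function(sims) {
  if (inherits(sims, "mc_exposure")) sims <- list(sims)
  labels <- names(sims)
  if (is.null(labels)) labels <- vapply(sims, function(s) s$label %||% "", "")
  rows <- Map(function(s, lab) {
    pg <- as.numeric(sub("%", "", names(s$ewi_percentiles)))
    data.frame(cell = lab, percentile = pg,
               ewi = unname(s$ewi_percentiles),
               pct_twi = unname(s$pct_twi_percentiles),
               stringsAsFactors = FALSE)
  }, sims, labels)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("risk_table", "data.frame")
  out
}
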