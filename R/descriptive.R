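#' Survey summary statistics by group
#'
#' Mean, SD and median of the per-sample TEQ and mass sums, overall or split
#' by region or sampling year. The SD convention is the sample SD (n-1
#' divisor) for groups of two or more; a single-sample group reports SD 0.
#'
#' @param survey a [milk_survey()].
#' @param tefs named TEF vector.
#' @param scenario censoring scenario, default `"UB"` (the conventional
#'   basis for descriptive tables of censored occurrence data).
#' @param by `"overall"`, `"region"` or `"year"`.
#' @return A data frame of class `survey_summary`: one row per group x
#'   quantity (`pcddf_teq`, `dlpcb_teq`, `total_teq`, `ndl_sum`,
#'   `pcddf_mass`, `dlpcb_mass`) with columns `n`, `mean`, `sd`, `median`.
#' @export
summarize_survey <- function(survey, tefs = tef_who2005(), scenario = "UB",
                             by = c("overall", "region", "year")) {
  by <- match.arg(by)
  teq <- compute_teq(survey, tefs, scenario)
  g <- switch(by,
    overall = rep("overall", nrow(teq)),
    region = as.character(survey$meta$region),
    year = as.character(survey$meta$year)
  )
  quantities <- c("pcddf_teq", "dlpcb_teq", "total_teq", "ndl_sum",
                  "pcddf_mass", "dlpcb_mass")
  rows <- list()
  for (lev in unique(g)) {
    sel <- g == lev
    if (!any(sel)) next
    for (q in quantities) {
      v <- teq[[q]][sel]
      rows[[length(rows) + 1L]] <- data.frame(
        group = lev, quantity = q, n = sum(sel),
        mean = mean(v),
        sd = if (sum(sel) >= 2) stats::sd(v) else 0,
        median = stats::median(v),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "scenario") <- as_scenario(scenario)$label
  class(out) <- c("survey_summary", "data.frame")
  out
}

#' Inter-survey percent variation
#'
#' Percentage change between a historical mean and a current mean,
#' `100 * (new - old) / old`. Reported values are conventionally rounded to
#' the nearest integer (half away from zero); set `digits = NULL` to return
#' the exact value.
#'
#' @param old_mean historical mean, > 0.
#' @param new_mean current mean, >= 0.
#' @param digits integer digits for report rounding, or `NULL` for exact.
#' @return Percent variation (negative = decline).
#' @examples
#' trend_delta(2513, 764)   # -70
#' trend_delta(10.59, 6.71) # -37
#' @export
trend_delta <- function(old_mean, new_mean, digits = 0) {
  if (any(old_mean <= 0)) stop("old_mean must be > 0")
  if (any(new_mean < 0)) stop("new_mean must be >= 0")
  delta <- 100 * (new_mean - old_mean) / old_mean
  if (is.null(digits)) delta else round_half_up(delta, digits)
}

#' Fat-contamination Spearman correlation per region
#'
#' Correlates, within each region, the total PCDD/F + dl-PCB load in 100 g
#' of milk (per-fat concentration times fat content / 100) with the fat
#' content itself. A coefficient above 0.6 is conventionally read as a
#' positive association, i.e. fat content tracks the contamination level.
#'
#' The per-100 g contamination can be computed on the TEQ basis (default) or
#' on the mass basis. Ties get average ranks; the p-value is exact for small
#' tie-free samples and asymptotic otherwise (the [stats::cor.test()]
#' conventions).
#'
#' @param survey a [milk_survey()].
#' @param tefs named TEF vector.
#' @param scenario censoring scenario, default `"UB"`.
#' @param basis `"teq"` or `"mass"`.
#' @return A data frame of class `fat_correlation`: one row per region with
#'   `n`, `r` (Spearman rho), `p_value`.
#' @export
fat_correlation <- function(survey, tefs = tef_who2005(), scenario = "UB",
                            basis = c("teq", "mass")) {
  basis <- match.arg(basis)
  teq <- compute_teq(survey, tefs, scenario)
  load_per_fat <- if (basis == "teq") teq$total_teq else teq$pcddf_mass + teq$dlpcb_mass
  per100g <- load_per_fat * survey$meta$fat / 100
  regions <- unique(as.character(survey$meta$region))
  rows <- lapply(regions, function(rg) {
    sel <- survey$meta$region == rg
    if (sum(sel) < 3) stop("need at least 3 samples per region (", rg, ")")
    fat <- survey$meta$fat[sel]
    if (length(unique(fat)) == 1L) {
      stop("fat content is constant in region ", rg, "; correlation undefined")
    }
    ct <- suppressWarnings(stats::cor.test(
      per100g[sel], fat,
      method = "spearman",
      exact = sum(sel) < 10 && !anyDuplicated(fat) && !anyDuplicated(per100g[sel])
    ))
    data.frame(region = rg, n = sum(sel),
               r = unname(ct$estimate), p_value = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("fat_correlation", "data.frame")
  out
}

#' Congener profiles: mean mass and percent TEQ contribution
#'
#' For each of the 29 TEQ-relevant congeners: the mean mass concentration
#' (pg/g fat) and the percentage of the mean total PCDD/F + dl-PCB TEQ the
#' congener accounts for, per region (or overall). Contributions across the
#' 29 congeners sum to 100 within rounding.
#'
#' @param survey a [milk_survey()].
#' @param tefs named TEF vector.
#' @param scenario censoring scenario, default `"UB"`.
#' @param by `"region"` or `"overall"`.
#' @return A data frame of class `congener_profile` with columns `group`
#'   (region label), `congener`, `mean_mass`, `pct_teq`.
#' @export
congener_profiles <- function(survey, tefs = tef_who2005(), scenario = "UB",
                              by = c("region", "overall")) {
  by <- match.arg(by)
  stopifnot(inherits(survey, "milk_survey"))
  scenario <- as_scenario(scenario)
  reg <- congener_registry()
  ids <- reg$congener[reg$group != "ndl-PCB"]
  assert_panel(survey, ids)

  sub <- survey$conc
  cens <- !survey$detected
  sub[cens] <- scenario$factor * survey$loq[cens]
  sub <- sub[, ids, drop = FALSE]

  g <- if (by == "region") as.character(survey$meta$region) else rep("overall", nrow(sub))
  rows <- lapply(unique(g), function(lev) {
    m <- sub[g == lev, , drop = FALSE]
    mean_mass <- colMeans(m)
    teq_means <- mean_mass * tefs[ids]
    data.frame(group = lev, congener = ids,
               mean_mass = unname(mean_mass),
               pct_teq = unname(100 * teq_means / sum(teq_means)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("congener_profile", "data.frame")
  out
}

#' Compare contamination between groups of samples
#'
#' Two levels: Welch two-sample t test. Three or more: one-way ANOVA
#' followed by Tukey's HSD at alpha = 0.05. The response defaults to the
#' per-sample total TEQ under the chosen scenario.
#'
#' @param survey a [milk_survey()].
#' @param factor name of the grouping column in the survey metadata
#'   (`"region"` or `"year"`), or a vector with one level per sample.
#' @param quantity which `teq_result` column to compare.
#' @param tefs named TEF vector.
#' @param scenario censoring scenario, default `"UB"`.
#' @param alpha significance level for Tukey decisions.
#' @return A list of class `group_comparison` with fields `method`,
#'   `statistic`, `p_value`, and for ANOVA a `tukey` data frame with
#'   per-pair differences, adjusted p-values and `significant` flags.
#' @export
group_comparison <- function(survey, factor = "region", quantity = "total_teq",
                             tefs = tef_who2005(), scenario = "UB",
                             alpha = 0.05) {
  teq <- compute_teq(survey, tefs, scenario)
  g <- if (length(factor) == 1L && is.character(factor)) {
    survey$meta[[factor]]
  } else factor
  g <- base::factor(g)
  if (any(table(g) < 2)) stop("need at least 2 observations per level")
  y <- teq[[quantity]]
  if (nlevels(g) == 2L) {
    tt <- stats::t.test(y ~ g)
    res <- list(method = "t", statistic = unname(tt$statistic),
                p_value = tt$p.value, tukey = NULL)
  } else {
    fit <- stats::aov(y ~ g)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
    res <- list(
      method = "anova",
      statistic = an[["F value"]][1],
      p_value = an[["Pr(>F)"]][1],
      tukey = data.frame(
        pair = rownames(tk), diff = tk[, "diff"],
        p_adj = tk[, "p adj"], significant = tk[, "p adj"] <= alpha,
        row.names = NULL, stringsAsFactors = FALSE
      )
    )
  }
  res$quantity <- quantity
  res$scenario <- as_scenario(scenario)$label
  class(res) <- "group_comparison"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s on %s (%s scenario): statistic = %.3f, p = %.4g\n",
              if (x$method == "t") "Welch t test" else "one-way ANOVA",
              x$quantity, x$scenario, x$statistic, x$p_value))
  if (!is.null(x$tukey)) {
    cat("Tukey HSD pairs flagged:",
        if (any(x$tukey$significant)) {
          paste(x$tukey$pair[x$tukey$significant], collapse = ", ")
        } else "none", "\n")
  }
  invisible(x)
}
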