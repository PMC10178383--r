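#' Fat content of retail milk types
#'
#' Skimmed, semi-skimmed and whole cow milk are taken to contain 0.3, 1.8
#' and 3.5 g fat per 100 g respectively.
#'
#' @return Named numeric vector (g fat/100 g).
#' @export
milk_fat_contents <- function() {
  c(skimmed = 0.3, `semi-skimmed` = 1.8, whole = 3.5)
}

#' Chronic milk consumption of the Italian population
#'
#' Mean and 95th-percentile chronic weekly consumption of skimmed,
#' semi-skimmed and whole cow milk (consumers only) by six age groups,
#' in g per kg body weight per week, from the national food-consumption
#' survey within the EFSA Comprehensive Food Consumption Database.
#'
#' @return A data frame of class `consumption_table`: `age_group`,
#'   `milk_type`, `mean_weekly`, `p95_weekly` (g/kg bw/week).
#' @export
italian_milk_consumption <- function() {
  path <- system.file("extdata", "consumption_weekly.csv", package = "milkTEQ")
  read_consumption(path)
}

#' Read a consumption table CSV
#'
#' Expected columns: `age_group`, `milk_type`,
#' `mean_g_per_kgbw_week`, `p95_g_per_kgbw_week`.
#'
#' @param path CSV file path.
#' @return A `consumption_table` data frame (see
#'   [italian_milk_consumption()]).
#' @export
read_consumption <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("age_group", "milk_type", "mean_g_per_kgbw_week", "p95_g_per_kgbw_week")
  if (!all(need %in% names(df))) {
    stop("consumption CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    age_group = df$age_group,
    milk_type = df$milk_type,
    mean_weekly = as.numeric(df$mean_g_per_kgbw_week),
    p95_weekly = as.numeric(df$p95_g_per_kgbw_week),
    stringsAsFactors = FALSE
  )
  bad <- !(out$mean_weekly >= 0 & out$p95_weekly >= out$mean_weekly)
  if (any(bad)) {
    stop("invalid consumption rows (need 0 <= mean <= P95): ",
         paste(which(bad), collapse = ", "))
  }
  class(out) <- c("consumption_table", "data.frame")
  out
}

#' Estimated weekly intake
#'
#' `EWI = C * M * F / 100` in pg TEQ per kg body weight per week, where `C`
#' is the contamination of milk fat (pg TEQ/g fat), `M` the weekly milk
#' consumption (g/kg bw/week) and `F` the milk fat content (g fat/100 g).
#' Exact arithmetic; rounding happens only in report tables.
#'
#' @param C contamination, pg TEQ/g fat.
#' @param M weekly consumption, g/kg bw/week.
#' @param F_fat fat content, g fat/100 g.
#' @return EWI in pg TEQ/kg bw/week.
#' @examples
#' ewi(0.78, 234.15, 3.5)  # 6.392295
#' @export
ewi <- function(C, M, F_fat) {
  if (any(C < 0) || any(M < 0) || any(F_fat < 0)) {
    stop("all EWI inputs must be >= 0")
  }
  C * M * F_fat / 100
}

#' Percent contribution to the tolerable weekly intake
#'
#' @param ewi estimated weekly intake, pg TEQ/kg bw/week.
#' @param twi tolerable weekly intake, default 2 pg TEQ/kg bw/week.
#' @return Percentage of the TWI.
#' @examples
#' pct_twi(ewi(0.78, 234.15, 3.5))  # 319.6148
#' @export
pct_twi <- function(ewi, twi = 2) {
  stopifnot_scalar_num(twi, "twi", positive = TRUE)
  100 * ewi / twi
}

#' First-tier deterministic exposure screening
#'
#' Crosses a consumption table with a single point estimate of milk-fat
#' contamination to produce the screening grid: one row per age group x
#' milk type with mean- and P95-based EWIs, their percent contribution to
#' the TWI, and an escalation flag for cells exceeding the TWI at either
#' statistic (the cells worth refining probabilistically).
#'
#' @param consumption a `consumption_table`, default
#'   [italian_milk_consumption()].
#' @param contamination point estimate `C`, pg TEQ/g fat (conventionally
#'   the upper-bound survey mean).
#' @param fat_contents named vector mapping milk types to g fat/100 g.
#' @param twi tolerable weekly intake, pg TEQ/kg bw/week.
#' @param escalate_threshold %TWI above which a cell is flagged for
#'   probabilistic refinement (default 100: the intake estimate itself
#'   exceeds the TWI).
#' @return A data frame of class `screening_table` with full-precision
#'   columns `ewi_mean`, `ewi_p95`, `pct_twi_mean`, `pct_twi_p95` and
#'   logical `escalate`. The print method applies report rounding (EWI to 2
#'   decimals, %TWI to integers).
#' @examples
#' screening_table(contamination = 0.78)
#' @export
screening_table <- function(consumption = italian_milk_consumption(),
                            contamination = 0.78,
                            fat_contents = milk_fat_contents(),
                            twi = 2, escalate_threshold = 100) {
  stopifnot_scalar_num(contamination, "contamination", nonneg = TRUE)
  unknown <- setdiff(unique(consumption$milk_type), names(fat_contents))
  if (length(unknown)) {
    stop("no fat content for milk type(s): ", paste(unknown, collapse = ", "))
  }
  F_fat <- fat_contents[consumption$milk_type]
  out <- data.frame(
    age_group = consumption$age_group,
    milk_type = consumption$milk_type,
    fat_content = unname(F_fat),
    mean_weekly = consumption$mean_weekly,
    p95_weekly = consumption$p95_weekly,
    ewi_mean = ewi(contamination, consumption$mean_weekly, F_fat),
    ewi_p95 = ewi(contamination, consumption$p95_weekly, F_fat),
    stringsAsFactors = FALSE
  )
  out$pct_twi_mean <- pct_twi(out$ewi_mean, twi)
  out$pct_twi_p95 <- pct_twi(out$ewi_p95, twi)
  out$escalate <- out$pct_twi_mean > escalate_threshold |
    out$pct_twi_p95 > escalate_threshold
  attr(out, "contamination") <- contamination
  attr(out, "twi") <- twi
  class(out) <- c("screening_table", "data.frame")
  out
}

#' @export
`[.screening_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.screening_table <- function(x, ...) {
  cat(sprintf(
    "Deterministic EWI screening (C = %.2f pg TEQ/g fat, TWI = %g pg TEQ/kg bw/week)\n",
    attr(x, "contamination"), attr(x, "twi")
  ))
  shown <- data.frame(
    age_group = x$age_group, milk_type = x$milk_type,
    ewi_mean = round_half_up(x$ewi_mean, 2),
    ewi_p95 = round_half_up(x$ewi_p95, 2),
    pct_twi_mean = round_half_up(x$pct_twi_mean),
    pct_twi_p95 = round_half_up(x$pct_twi_p95),
    escalate = x$escalate
  )
  print.data.frame(shown, row.names = FALSE)
  invisible(x)
}
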