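#' Censoring scenarios for non-detects
#'
#' Values below the limit of quantification are substituted with 0 (lower
#' bound, LB), half the LOQ (middle bound, MB) or the LOQ itself (upper
#' bound, UB). The three scenarios bracket the unknown true concentration,
#' so every TEQ sum satisfies LB <= MB <= UB.
#'
#' @param label one of `"LB"`, `"MB"`, `"UB"`.
#' @return A `censoring_scenario` object with fields `label` and `factor`
#'   (the LOQ multiplier: 0, 0.5 or 1).
#' @examples
#' censoring_scenario("MB")$factor  # 0.5
#' @export
censoring_scenario <- function(label = c("UB", "MB", "LB")) {
  label <- match.arg(label)
  structure(
    list(label = label, factor = c(LB = 0, MB = 0.5, UB = 1)[[label]]),
    class = "censoring_scenario"
  )
}

as_scenario <- function(s) {
  if (inherits(s, "censoring_scenario")) s else censoring_scenario(s)
}

#' Substitute non-detects under a censoring scenario
#'
#' Detected values pass through unchanged under every scenario; non-detects
#' are replaced by `factor * loq`.
#'
#' @param value measured concentration(s), >= 0.
#' @param loq limit(s) of quantification, > 0.
#' @param detected logical; `FALSE` marks a non-detect.
#' @param scenario a [censoring_scenario()] or its label.
#' @return Numeric vector of substituted concentrations.
#' @examples
#' apply_censoring(5, 0.1, TRUE, "LB")    # 5: detection bypasses substitution
#' apply_censoring(0, 0.1, FALSE, "MB")   # 0.05
#' @export
apply_censoring <- function(value, loq, detected, scenario) {
  scenario <- as_scenario(scenario)
  if (any(value < 0, na.rm = TRUE)) stop("concentrations must be >= 0")
  if (any(!is.finite(loq)) || any(loq <= 0)) stop("LOQ must be > 0")
  out <- ifelse(detected, value, scenario$factor * loq)
  as.numeric(out)
}

#' Regulatory limits for dioxins and PCBs in milk
#'
#' European maximum levels (MLs, enforcement) and action levels (ALs,
#' investigation triggers) for milk and dairy fat, plus the tolerable weekly
#' intake (TWI) used in risk characterisation.
#'
#' @param ml_pcddf ML for PCDD/Fs, pg TEQ/g fat.
#' @param ml_total ML for PCDD/Fs + dl-PCBs, pg TEQ/g fat.
#' @param ml_ndl ML for the six indicator PCBs, ng/g fat.
#' @param al_pcddf AL for PCDD/Fs, pg TEQ/g fat.
#' @param al_dlpcb AL for dl-PCBs, pg TEQ/g fat.
#' @param twi tolerable weekly intake, pg TEQ/kg bw/week.
#' @return A `regulatory_limits` object (named list).
#' @export
regulatory_limits <- function(ml_pcddf = 2, ml_total = 4, ml_ndl = 40,
                              al_pcddf = 1.75, al_dlpcb = 2, twi = 2) {
  vals <- c(ml_pcddf = ml_pcddf, ml_total = ml_total, ml_ndl = ml_ndl,
            al_pcddf = al_pcddf, al_dlpcb = al_dlpcb, twi = twi)
  if (any(vals <= 0)) stop("all limits must be positive")
  if (al_pcddf >= ml_pcddf) stop("AL for PCDD/Fs must be below its ML")
  structure(as.list(vals), class = "regulatory_limits")
}

#' TEF-weighted TEQ sums per sample
#'
#' Computes, for every sample and one censoring scenario, the toxic
#' equivalent of the PCDD/F group, the dl-PCB group and their total
#' (pg TEQ/g fat), the unweighted sum of the six indicator PCBs (ng/g fat),
#' and the plain mass sums per group.
#'
#' A congener present in the survey but missing from the TEF table (within a
#' TEQ group) is a hard error. A congener missing from the survey is also an
#' error unless `allow_partial = TRUE`, in which case it contributes nothing
#' and the result is flagged `partial` (meaningful for LB only: under MB/UB
#' the absent congener's LOQ contribution is unknowable).
#'
#' @param survey a [milk_survey()].
#' @param tefs named TEF vector, default [tef_who2005()].
#' @param scenario censoring scenario (label or object), default `"UB"`.
#' @param allow_partial accept incomplete congener panels (see Details).
#' @return A data frame of class `teq_result` with columns `sample_id`,
#'   `scenario`, `pcddf_teq`, `dlpcb_teq`, `total_teq`, `ndl_sum`,
#'   `pcddf_mass`, `dlpcb_mass`, `partial`.
#' @examples
#' sv <- generate_survey(survey_config(n_samples = 5), seed = 1)
#' compute_teq(sv, scenario = "MB")
#' @export
compute_teq <- function(survey, tefs = tef_who2005(),
                        scenario = "UB", allow_partial = FALSE) {
  stopifnot(inherits(survey, "milk_survey"))
  scenario <- as_scenario(scenario)
  reg <- congener_registry()
  teq_congeners <- reg$congener[reg$group != "ndl-PCB"]
  ndl_congeners <- reg$congener[reg$group == "ndl-PCB"]

  present_teq <- intersect(teq_congeners, colnames(survey$conc))
  no_tef <- setdiff(present_teq, names(tefs))
  if (length(no_tef)) {
    stop("no TEF for congener(s): ", paste(no_tef, collapse = ", "))
  }
  missing <- c(
    assert_panel(survey, teq_congeners, allow_partial),
    assert_panel(survey, ndl_congeners, allow_partial)
  )

  sub <- survey$conc
  cens <- !survey$detected
  sub[cens] <- scenario$factor * survey$loq[cens]

  group_sum <- function(ids, weights = NULL) {
    ids <- intersect(ids, colnames(sub))
    if (!length(ids)) return(rep(0, nrow(sub)))
    m <- sub[, ids, drop = FALSE]
    if (!is.null(weights)) m <- sweep(m, 2, weights[ids], `*`)
    rowSums(m)
  }

  pcddf_ids <- reg$congener[reg$group == "PCDD/F"]
  dl_ids <- reg$congener[reg$group == "dl-PCB"]
  pcddf_teq <- group_sum(pcddf_ids, tefs)
  dlpcb_teq <- group_sum(dl_ids, tefs)

  out <- data.frame(
    sample_id = survey$meta$sample_id,
    scenario = scenario$label,
    pcddf_teq = pcddf_teq,
    dlpcb_teq = dlpcb_teq,
    total_teq = pcddf_teq + dlpcb_teq,
    ndl_sum = group_sum(ndl_congeners),
    pcddf_mass = group_sum(pcddf_ids),
    dlpcb_mass = group_sum(dl_ids),
    partial = length(missing) > 0,
    stringsAsFactors = FALSE
  )
  class(out) <- c("teq_result", "data.frame")
  out
}

#' Screen TEQ results against EU limits
#'
#' Flags, independently for each maximum and action level, whether a sample
#' exceeds it, and reports the margin (value minus limit; positive means
#' exceedance). Enforcement conventionally uses the most conservative
#' upper-bound scenario; the caller chooses which scenario's results to
#' screen.
#'
#' @param teq a `teq_result` from [compute_teq()].
#' @param limits a [regulatory_limits()] object.
#' @return A data frame of class `compliance_report` with one row per sample:
#'   logical `*_exceeded` flags and numeric `*_margin` columns for the
#'   PCDD/F ML, total ML, ndl ML, PCDD/F AL and dl-PCB AL, plus `compliant`
#'   (no ML exceeded).
#' @export
check_compliance <- function(teq, limits = regulatory_limits()) {
  stopifnot(inherits(teq, "teq_result"), inherits(limits, "regulatory_limits"))
  out <- data.frame(
    sample_id = teq$sample_id,
    scenario = teq$scenario,
    ml_pcddf_exceeded = teq$pcddf_teq > limits$ml_pcddf,
    ml_pcddf_margin = teq$pcddf_teq - limits$ml_pcddf,
    ml_total_exceeded = teq$total_teq > limits$ml_total,
    ml_total_margin = teq$total_teq - limits$ml_total,
    ml_ndl_exceeded = teq$ndl_sum > limits$ml_ndl,
    ml_ndl_margin = teq$ndl_sum - limits$ml_ndl,
    al_pcddf_exceeded = teq$pcddf_teq > limits$al_pcddf,
    al_pcddf_margin = teq$pcddf_teq - limits$al_pcddf,
    al_dlpcb_exceeded = teq$dlpcb_teq > limits$al_dlpcb,
    al_dlpcb_margin = teq$dlpcb_teq - limits$al_dlpcb,
    stringsAsFactors = FALSE
  )
  out$compliant <- !(out$ml_pcddf_exceeded | out$ml_total_exceeded | out$ml_ndl_exceeded)
  class(out) <- c("compliance_report", "data.frame")
  out
}
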