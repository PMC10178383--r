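#' Congener registry
#'
#' The 35 congeners routinely quantified in milk monitoring: the 17
#' toxicologically relevant 2,3,7,8-substituted PCDD/Fs, the 12 dioxin-like
#' PCBs carrying WHO-2005 toxic equivalency factors, and the 6 indicator
#' (non-dioxin-like) PCBs that are summed without TEF weighting.
#'
#' Canonical identifiers drop commas and internal punctuation
#' (`"2378-TCDD"`, `"PCB126"`); [normalize_congener()] maps common spellings
#' found in CSV headers onto them.
#'
#' @return A data frame with columns `congener` (canonical id), `group`
#'   (`"PCDD/F"`, `"dl-PCB"` or `"ndl-PCB"`) and `unit` (`"pg/g fat"` for the
#'   29 TEQ-relevant congeners, `"ng/g fat"` for the indicator PCBs).
#' @examples
#' table(congener_registry()$group)
#' @export
congener_registry <- function() {
  pcddf <- c(
    "2378-TCDD", "12378-PeCDD", "123478-HxCDD", "123678-HxCDD",
    "123789-HxCDD", "1234678-HpCDD", "OCDD",
    "2378-TCDF", "12378-PeCDF", "23478-PeCDF", "123478-HxCDF",
    "123678-HxCDF", "123789-HxCDF", "234678-HxCDF", "1234678-HpCDF",
    "1234789-HpCDF", "OCDF"
  )
  dl <- paste0("PCB", c(77, 81, 105, 114, 118, 123, 126, 156, 157, 167, 169, 189))
  ndl <- paste0("PCB", c(28, 52, 101, 138, 153, 180))
  data.frame(
    congener = c(pcddf, dl, ndl),
    group = rep(c("PCDD/F", "dl-PCB", "ndl-PCB"), c(length(pcddf), length(dl), length(ndl))),
    unit = rep(c("pg/g fat", "pg/g fat", "ng/g fat"), c(length(pcddf), length(dl), length(ndl))),
    stringsAsFactors = FALSE
  )
}

#' WHO-2005 toxic equivalency factors
#'
#' TEFs express the potency of each PCDD/F and dioxin-like PCB congener
#' relative to 2,3,7,8-TCDD (TEF = 1). Indicator PCBs carry no TEF and are
#' deliberately absent from the table; requesting one is an error in TEQ
#' arithmetic, not a zero.
#'
#' @return A named numeric vector keyed by canonical congener id, covering
#'   exactly the 29 TEQ-relevant congeners.
#' @references Van den Berg et al. (2006) The 2005 World Health Organization
#'   reevaluation of human and mammalian toxic equivalency factors for
#'   dioxins and dioxin-like compounds. Toxicol Sci 93(2):223-241.
#' @examples
#' tef_who2005()[["2378-TCDD"]]  # 1
#' tef_who2005()[["PCB126"]]     # 0.1
#' @export
tef_who2005 <- function() {
  c(
    "2378-TCDD"     = 1,
    "12378-PeCDD"   = 1,
    "123478-HxCDD"  = 0.1,
    "123678-HxCDD"  = 0.1,
    "123789-HxCDD"  = 0.1,
    "1234678-HpCDD" = 0.01,
    "OCDD"          = 0.0003,
    "2378-TCDF"     = 0.1,
    "12378-PeCDF"   = 0.03,
    "23478-PeCDF"   = 0.3,
    "123478-HxCDF"  = 0.1,
    "123678-HxCDF"  = 0.1,
    "123789-HxCDF"  = 0.1,
    "234678-HxCDF"  = 0.1,
    "1234678-HpCDF" = 0.01,
    "1234789-HpCDF" = 0.01,
    "OCDF"          = 0.0003,
    "PCB77"  = 0.0001,
    "PCB81"  = 0.0003,
    "PCB105" = 0.00003,
    "PCB114" = 0.00003,
    "PCB118" = 0.00003,
    "PCB123" = 0.00003,
    "PCB126" = 0.1,
    "PCB156" = 0.00003,
    "PCB157" = 0.00003,
    "PCB167" = 0.00003,
    "PCB169" = 0.03,
    "PCB189" = 0.00003
  )
}

#' Normalize congener labels to canonical identifiers
#'
#' Accepts the spellings commonly seen in laboratory exports:
#' `"2,3,7,8-TCDD"`, `"PCB 126"`, `"PCB-126"`, lower case, extra whitespace.
#' Matching strips commas, spaces, hyphens and case before comparing against
#' the registry.
#'
#' @param x character vector of congener labels.
#' @param error_on_unknown error (default) or return `NA` for labels that do
#'   not resolve.
#' @return Character vector of canonical ids.
#' @examples
#' normalize_congener(c("2,3,7,8-TCDD", "pcb 126"))
#' @export
normalize_congener <- function(x, error_on_unknown = TRUE) {
  canon <- congener_registry()$congener
  squash <- function(v) toupper(gsub("[ ,'’._-]", "", v))
  idx <- match(squash(x), squash(canon))
  if (error_on_unknown && anyNA(idx)) {
    stop("unknown congener label(s): ", paste(unique(x[is.na(idx)]), collapse = ", "))
  }
  canon[idx]
}

congener_group <- function(ids) {
  reg <- congener_registry()
  reg$group[match(ids, reg$congener)]
}
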