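#' Milk survey container
#'
#' A `milk_survey` holds congener-level measurements for a set of bulk-tank
#' milk samples: per-sample metadata plus three aligned sample-by-congener
#' matrices (measured concentration, limit of quantification, detection
#' flag). PCDD/F and dl-PCB concentrations are in pg/g fat, indicator
#' (ndl) PCBs in ng/g fat; the two unit families are never mixed or
#' auto-converted.
#'
#' For a non-detect the stored `conc` entry is ignored by all downstream
#' computation: the value entering any sum is determined by the censoring
#' scenario (0, half the LOQ, or the LOQ; see [censoring_scenario()]).
#'
#' @param meta data frame with columns `sample_id`, `region`, `year`,
#'   `fat` (g fat/100 g milk, in (0, 100)).
#' @param conc numeric matrix (samples x congeners) of measured
#'   concentrations; column names must resolve via [normalize_congener()].
#' @param loq numeric matrix of per-congener LOQs, same shape; all entries
#'   must be positive.
#' @param detected logical matrix, same shape; `FALSE` marks a value below
#'   the LOQ.
#' @return An object of class `milk_survey`.
#' @export
milk_survey <- function(meta, conc, loq, detected) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("sample_id", "region", "year", "fat")
  if (!all(need %in% names(meta))) {
    stop("meta must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id")
  if (any(!is.finite(meta$fat)) || any(meta$fat <= 0) || any(meta$fat >= 100)) {
    stop("fat content must lie strictly between 0 and 100 g/100 g")
  }
  conc <- as.matrix(conc); loq <- as.matrix(loq); detected <- as.matrix(detected)
  if (!all(dim(conc) == dim(loq)) || !all(dim(conc) == dim(detected))) {
    stop("conc, loq and detected must have identical dimensions")
  }
  if (nrow(conc) != nrow(meta)) stop("matrix rows must match meta rows")
  ids <- normalize_congener(colnames(conc))
  if (anyDuplicated(ids)) stop("each congener may appear at most once")
  colnames(conc) <- colnames(loq) <- colnames(detected) <- ids
  if (any(conc < 0, na.rm = TRUE)) stop("negative concentrations are invalid")
  if (any(!is.finite(loq)) || any(loq <= 0)) stop("all LOQs must be positive")
  conc[is.na(conc)] <- 0  # non-detect placeholders; never read downstream
  rownames(conc) <- rownames(loq) <- rownames(detected) <- NULL
  structure(
    list(meta = meta, conc = conc, loq = loq, detected = detected),
    class = "milk_survey"
  )
}

#' @export
print.milk_survey <- function(x, ...) {
  cat(sprintf(
    "milk_survey: %d samples, %d congeners\n",
    nrow(x$meta), ncol(x$conc)
  ))
  cat("regions:", paste(sprintf(
    "%s (%d)", names(table(x$meta$region)), table(x$meta$region)
  ), collapse = ", "), "\n")
  cat(sprintf(
    "years %s-%s; fat %.2f-%.2f g/100 g; %.0f%% of entries censored\n",
    min(x$meta$year), max(x$meta$year),
    min(x$meta$fat), max(x$meta$fat),
    100 * mean(!x$detected)
  ))
  invisible(x)
}

#' @export
`[.milk_survey` <- function(x, i, ...) {
  milk_survey(x$meta[i, , drop = FALSE],
              x$conc[i, , drop = FALSE],
              x$loq[i, , drop = FALSE],
              x$detected[i, , drop = FALSE])
}

#' Number of samples in a survey
#' @param x a `milk_survey`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) nrow(x$meta)

# Check the survey carries a full panel for the requested congeners.
assert_panel <- function(survey, congeners, allow_partial = FALSE) {
  missing <- setdiff(congeners, colnames(survey$conc))
  if (length(missing) && !allow_partial) {
    stop(
      "incomplete congener panel (missing: ",
      paste(missing, collapse = ", "),
      "); upper/middle-bound sums are undefined without an LOQ for every ",
      "congener. Pass allow_partial = TRUE to treat them as absent."
    )
  }
  missing
}
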