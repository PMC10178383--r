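# Build a tiny survey directly from matrices; values default to "detected
# at zero" so individual congeners can be set without touching the rest.
make_survey <- function(values = list(), n = 1, loq = 0.1,
                        fat = 4, region = "Lombardy", year = 2020,
                        detected = TRUE) {
  ids <- congener_registry()$congener
  conc <- matrix(0, n, length(ids), dimnames = list(NULL, ids))
  det <- matrix(detected, n, length(ids), dimnames = list(NULL, ids))
  lq <- matrix(loq, n, length(ids), dimnames = list(NULL, ids))
  for (nm in names(values)) {
    v <- values[[nm]]
    conc[, nm] <- v
  }
  milk_survey(
    meta = data.frame(
      sample_id = sprintf("T%02d", seq_len(n)),
      region = rep_len(region, n),
      year = rep_len(year, n),
      fat = rep_len(fat, n),
      stringsAsFactors = FALSE
    ),
    conc = conc, loq = lq, detected = det
  )
}

# Independent brute-force TEQ: explicit loop over (congener, TEF) pairs,
# no matrix algebra shared with the implementation.
brute_force_teq <- function(survey, scenario, tefs = tef_who2005()) {
  reg <- congener_registry()
  fac <- c(LB = 0, MB = 0.5, UB = 1)[[scenario]]
  out <- data.frame(pcddf = numeric(n_samples(survey)),
                    dlpcb = numeric(n_samples(survey)),
                    ndl = numeric(n_samples(survey)))
  for (i in seq_len(n_samples(survey))) {
    for (j in colnames(survey$conc)) {
      v <- if (survey$detected[i, j]) survey$conc[i, j] else fac * survey$loq[i, j]
      grp <- reg$group[reg$congener == j]
      if (grp == "PCDD/F") out$pcddf[i] <- out$pcddf[i] + v * tefs[[j]]
      if (grp == "dl-PCB") out$dlpcb[i] <- out$dlpcb[i] + v * tefs[[j]]
      if (grp == "ndl-PCB") out$ndl[i] <- out$ndl[i] + v
    }
  }
  out
}

# Small calibrated survey config reused across tests (calibration is the
# slow step; do it once per test run).
small_cfg <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- calibrate_survey(survey_config())
    cached
  }
})
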