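test_that("censoring substitution follows the LB/MB/UB convention", {
  # detection bypasses substitution under every scenario
  for (s in c("LB", "MB", "UB")) {
    expect_equal(apply_censoring(5.0, 0.1, TRUE, s), 5.0)
  }
  expect_equal(apply_censoring(0, 0.10, FALSE, "UB"), 0.10)
  expect_equal(apply_censoring(0, 0.10, FALSE, "MB"), 0.05)
  expect_equal(apply_censoring(0, 0.10, FALSE, "LB"), 0.0)
  # vectorized with mixed detection
  expect_equal(
    apply_censoring(c(1, 0), c(0.2, 0.2), c(TRUE, FALSE), "MB"),
    c(1, 0.1)
  )
  expect_error(apply_censoring(-1, 0.1, TRUE, "UB"), ">= 0")
  expect_error(apply_censoring(1, 0, TRUE, "UB"), "> 0")
  expect_error(censoring_scenario("XX"))
})

test_that("TEQ sums reproduce hand-computed TEF arithmetic", {
  # single dl-PCB congener: 5.0 pg/g x TEF 0.1
  sv <- make_survey(list(PCB126 = 5.0))
  r <- compute_teq(sv, scenario = "LB")
  expect_equal(r$dlpcb_teq, 0.5)
  expect_equal(r$pcddf_teq, 0)
  expect_equal(r$total_teq, 0.5)

  # TCDD 0.2 x 1 + OCDD 100 x 0.0003
  sv2 <- make_survey(list(`2378-TCDD` = 0.2, OCDD = 100))
  r2 <- compute_teq(sv2, scenario = "LB")
  expect_equal(r2$pcddf_teq, 0.23)

  # everything detected at zero: empty sums
  r0 <- compute_teq(make_survey(), scenario = "UB")
  for (col in c("pcddf_teq", "dlpcb_teq", "total_teq", "ndl_sum",
                "pcddf_mass", "dlpcb_mass")) {
    expect_equal(r0[[col]], 0)
  }

  # ndl congeners are summed without TEF weighting
  sv3 <- make_survey(list(PCB138 = 2, PCB153 = 3, PCB180 = 1.5))
  expect_equal(compute_teq(sv3, scenario = "LB")$ndl_sum, 6.5)
  expect_equal(compute_teq(sv3, scenario = "LB")$total_teq, 0)
})

test_that("TEQ equals an independent brute-force congener loop", {
  set.seed(11)
  for (rep in 1:3) {
    sv <- generate_survey(
      survey_config(n_samples = 8, n_exceed = 0, calib_nsim = 3000),
      seed = rep
    )
    for (s in c("LB", "MB", "UB")) {
      r <- compute_teq(sv, scenario = s)
      bf <- brute_force_teq(sv, s)
      expect_equal(r$pcddf_teq, bf$pcddf, tolerance = 1e-12)
      expect_equal(r$dlpcb_teq, bf$dlpcb, tolerance = 1e-12)
      expect_equal(r$ndl_sum, bf$ndl, tolerance = 1e-12)
    }
  }
})

test_that("TEQ is monotone, scenario-ordered and linear", {
  sv <- generate_survey(
    survey_config(n_samples = 12, n_exceed = 0, calib_nsim = 3000),
    seed = 5
  )
  lb <- compute_teq(sv, scenario = "LB")
  mb <- compute_teq(sv, scenario = "MB")
  ub <- compute_teq(sv, scenario = "UB")
  for (col in c("pcddf_teq", "dlpcb_teq", "total_teq", "ndl_sum")) {
    expect_true(all(lb[[col]] <= mb[[col]] + 1e-12))
    expect_true(all(mb[[col]] <= ub[[col]] + 1e-12))
  }
  # equality exactly where nothing in the group is censored
  uncensored <- rowSums(!sv$detected) == 0
  expect_equal(lb$total_teq[uncensored], ub$total_teq[uncensored])
  if (any(!uncensored)) {
    reg <- congener_registry()
    teq_ids <- reg$congener[reg$group != "ndl-PCB"]
    cens_teq <- rowSums(!sv$detected[, teq_ids, drop = FALSE]) > 0
    expect_true(all(lb$total_teq[cens_teq] < ub$total_teq[cens_teq]))
  }

  # increasing one congener never decreases any sum
  sv_up <- sv
  sv_up$conc[, "PCB126"] <- sv_up$conc[, "PCB126"] + 1
  up <- compute_teq(sv_up, scenario = "MB")
  expect_true(all(up$total_teq >= mb$total_teq))
  expect_true(all(up$pcddf_teq == mb$pcddf_teq))

  # scaling all concentrations and LOQs by k scales every sum by k
  k <- 3.7
  sv_k <- sv
  sv_k$conc <- sv_k$conc * k
  sv_k$loq <- sv_k$loq * k
  mb_k <- compute_teq(sv_k, scenario = "MB")
  for (col in c("pcddf_teq", "dlpcb_teq", "total_teq", "ndl_sum")) {
    expect_equal(mb_k[[col]], k * mb[[col]], tolerance = 1e-12)
  }
})

test_that("incomplete congener panels are rejected unless allowed", {
  sv <- make_survey(list(PCB126 = 1))
  sv_drop <- sv
  keep <- setdiff(colnames(sv$conc), "2378-TCDD")
  sv_drop$conc <- sv_drop$conc[, keep, drop = FALSE]
  sv_drop$loq <- sv_drop$loq[, keep, drop = FALSE]
  sv_drop$detected <- sv_drop$detected[, keep, drop = FALSE]
  expect_error(compute_teq(sv_drop), "incomplete congener panel")
  r <- compute_teq(sv_drop, allow_partial = TRUE)
  expect_true(r$partial)
  expect_equal(r$dlpcb_teq, 0.1)

  # congener without a TEF entry is a hard error
  tefs <- tef_who2005()
  expect_error(compute_teq(sv, tefs = tefs[names(tefs) != "PCB126"]),
               "no TEF")
})

test_that("compliance screening flags MLs and ALs independently", {
  lim <- regulatory_limits()
  # the single-exceedance pattern: total 6.28 vs ML 4
  sv <- make_survey(list(PCB126 = 62.8))  # dl-PCB TEQ 6.28
  r <- compute_teq(sv, scenario = "UB")
  cc <- check_compliance(r, lim)
  expect_true(cc$ml_total_exceeded)
  expect_equal(cc$ml_total_margin, 2.28)
  expect_false(cc$ml_pcddf_exceeded)
  expect_true(cc$al_dlpcb_exceeded)
  expect_false(cc$compliant)

  # AL exceedance without ML exceedance
  sv2 <- make_survey(list(PCB126 = 21.0))  # dl-PCB TEQ 2.10
  cc2 <- check_compliance(compute_teq(sv2, scenario = "UB"), lim)
  expect_true(cc2$al_dlpcb_exceeded)
  expect_false(cc2$ml_total_exceeded)
  expect_equal(cc2$al_dlpcb_margin, 0.1)
  expect_true(cc2$compliant)

  # all-zero sample is fully compliant
  cc0 <- check_compliance(compute_teq(make_survey(), scenario = "LB"), lim)
  expect_true(cc0$compliant)
  expect_false(any(cc0$al_pcddf_exceeded, cc0$al_dlpcb_exceeded))

  expect_error(regulatory_limits(al_pcddf = 3), "below its ML")
})

test_that("congener registry and aliases resolve laboratory spellings", {
  reg <- congener_registry()
  expect_equal(nrow(reg), 35)
  expect_equal(sum(reg$group == "PCDD/F"), 17)
  expect_equal(sum(reg$group == "dl-PCB"), 12)
  expect_equal(sum(reg$group == "ndl-PCB"), 6)
  tefs <- tef_who2005()
  expect_equal(length(tefs), 29)
  expect_true(all(tefs > 0 & tefs <= 1))
  expect_false(any(reg$congener[reg$group == "ndl-PCB"] %in% names(tefs)))
  expect_equal(
    normalize_congener(c("2,3,7,8-TCDD", "pcb 126", "PCB-153", "1,2,3,7,8-PeCDD")),
    c("2378-TCDD", "PCB126", "PCB153", "12378-PeCDD")
  )
  expect_error(normalize_congener("PCB999"), "unknown congener")
})
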