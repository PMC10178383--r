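test_that("survey summaries follow the documented conventions", {
  sv <- make_survey(list(PCB126 = c(10, 20, 30)), n = 3)  # total TEQ 1,2,3
  s <- summarize_survey(sv, by = "overall")
  tot <- s[s$quantity == "total_teq", ]
  expect_equal(tot$mean, 2)
  expect_equal(tot$median, 2)
  expect_equal(tot$sd, 1)  # sample SD, n-1

  s1 <- summarize_survey(make_survey(list(PCB126 = 10)), by = "overall")
  expect_equal(s1$sd[s1$quantity == "total_teq"], 0)  # singleton convention

  sv2 <- make_survey(list(PCB126 = c(10, 20, 30, 40)), n = 4,
                     region = c("A", "A", "B", "B"))
  s2 <- summarize_survey(sv2, by = "region")
  expect_equal(s2$mean[s2$group == "A" & s2$quantity == "total_teq"], 1.5)
  expect_equal(s2$mean[s2$group == "B" & s2$quantity == "total_teq"], 3.5)
})

test_that("inter-survey trend deltas reproduce the printed report integers", {
  expect_equal(trend_delta(2513, 764), -70)
  expect_equal(trend_delta(10.59, 6.71), -37)
  expect_equal(trend_delta(5, 5), 0)
  # exact value available unrounded
  expect_equal(trend_delta(2513, 764, digits = NULL),
               100 * (764 - 2513) / 2513)
  # sign flips direction; zero only at equality
  expect_true(trend_delta(2, 3, digits = NULL) > 0)
  expect_true(trend_delta(3, 2, digits = NULL) < 0)
  expect_error(trend_delta(0, 1), "old_mean")
})

test_that("half-up rounding matches report conventions", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-69.598), -70)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(319.6148), 320)
})

test_that("fat correlation detects coupling and rejects it under independence", {
  # contamination per g fat constant, fat varying: per-100 g load is a
  # strictly monotone function of fat, so Spearman r = 1
  sv <- make_survey(list(PCB126 = 10), n = 6)
  sv$meta$fat <- c(3.1, 3.5, 3.9, 4.2, 4.6, 5.0)
  fc <- fat_correlation(sv)
  expect_equal(fc$r, 1)

  # contamination independent of fat at large n: |r| small
  set.seed(42)
  n <- 300
  svi <- make_survey(list(PCB126 = rlnorm(n, 1, 0.5)), n = n)
  svi$meta$fat <- runif(n, 3, 5)
  # the x fat factor alone induces a mild positive rank correlation even
  # under independence; it must stay well below the 0.6 decision threshold
  fci <- fat_correlation(svi)
  expect_lt(fci$r, 0.6)
  expect_lt(abs(fci$r), 0.5)

  # degenerate fat is an explicit error
  svc <- make_survey(list(PCB126 = c(1, 2, 3)), n = 3)
  expect_error(fat_correlation(svc), "constant")
})

test_that("Spearman r is invariant under monotone rescaling of either axis", {
  set.seed(7)
  n <- 40
  x <- rlnorm(n, 0, 0.4)
  sv <- make_survey(list(PCB126 = x * 10), n = n)
  sv$meta$fat <- runif(n, 3, 5)
  r0 <- fat_correlation(sv)$r

  # strictly monotone rescaling of contamination preserves the load ranks
  sv2 <- sv
  sv2$conc[, "PCB126"] <- sv2$conc[, "PCB126"] * 17.3
  expect_equal(fat_correlation(sv2)$r, r0)

  # rank ties on the mass basis vs TEQ basis: a single congener makes the
  # two bases proportional, hence identical r
  expect_equal(fat_correlation(sv, basis = "mass")$r, r0)
})

test_that("congener profiles sum to 100 and match brute force", {
  sv <- make_survey(list(PCB126 = 5))
  p <- congener_profiles(sv)
  expect_equal(p$pct_teq[p$congener == "PCB126"], 100)
  expect_equal(sum(p$pct_teq), 100)

  # two congeners engineered to equal TEQ: 50/50
  sv2 <- make_survey(list(`2378-TCDD` = 1, PCB126 = 10))
  p2 <- congener_profiles(sv2)
  expect_equal(p2$pct_teq[p2$congener == "2378-TCDD"], 50)
  expect_equal(p2$pct_teq[p2$congener == "PCB126"], 50)

  # random panel vs hand loop
  sv3 <- generate_survey(
    survey_config(n_samples = 10, n_exceed = 0, calib_nsim = 3000), seed = 9
  )
  p3 <- congener_profiles(sv3, scenario = "MB", by = "overall")
  tefs <- tef_who2005()
  fac <- 0.5
  for (j in sample(p3$congener, 5)) {
    v <- ifelse(sv3$detected[, j], sv3$conc[, j], fac * sv3$loq[, j])
    expect_equal(p3$mean_mass[p3$congener == j], mean(v), tolerance = 1e-12)
  }
  expect_equal(sum(p3$pct_teq), 100, tolerance = 1e-9)
  # each regional profile also closes to 100
  p4 <- congener_profiles(sv3, scenario = "MB", by = "region")
  for (g in unique(p4$group)) {
    expect_equal(sum(p4$pct_teq[p4$group == g]), 100, tolerance = 1e-9)
  }
})

test_that("group comparisons separate shifted groups and spare equal ones", {
  # identical groups: p near 1
  svA <- make_survey(list(PCB126 = rep(c(1, 2, 3, 4), 2) * 10), n = 8,
                     region = rep(c("X", "Y"), each = 4))
  gc <- group_comparison(svA, "region")
  expect_equal(gc$method, "t")
  expect_gt(gc$p_value, 0.9)

  # two groups shifted by ~10 SD: detected with near-certain power
  set.seed(3)
  base <- rlnorm(20, 0, 0.1)
  svB <- make_survey(list(PCB126 = c(base, base * 3) * 10), n = 40,
                     region = rep(c("low", "high"), each = 20))
  gcB <- group_comparison(svB, "region")
  expect_lt(gcB$p_value, 0.001)

  # three equal-mean groups: ANOVA + Tukey flag nothing for this draw
  set.seed(8)
  svC <- make_survey(list(PCB126 = rlnorm(30, 1, 0.2) * 10), n = 30,
                     region = rep(c("a", "b", "c"), each = 10))
  gcC <- group_comparison(svC, "region")
  expect_equal(gcC$method, "anova")
  expect_false(any(gcC$tukey$significant))
  expect_equal(nrow(gcC$tukey), 3)

  expect_error(group_comparison(svA, rep(c("u", "v", "w"), c(6, 1, 1))),
               "at least 2")
})
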