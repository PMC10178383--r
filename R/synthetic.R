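#' Configuration for the synthetic milk survey generator
#'
#' Describes a two-region bulk-tank monitoring campaign with congener-level
#' lognormal contamination, per-congener left-censoring, and region-specific
#' structure: one region ("Emilia-Romagna"-like) with stable background
#' contamination whose per-100 g load tracks the milk fat content, and one
#' ("Lombardy"-like) where a small point-source mixture decouples fat and
#' contamination and pushes a configured number of samples above the total
#' maximum level.
#'
#' Per-sample, per-congener concentrations follow
#' `log X = m_j + region effect + shared factor + fat coupling + point source + noise`:
#' a shared lognormal factor induces the within-sample correlation that
#' gives the survey total its spread; the fat coupling (Emilia only) raises
#' contamination with fat content; the point-source term (a lognormal
#' multiplier hitting a small fraction of Lombardy samples) fattens that
#' region's tail. Censoring is mechanistic: a draw below the congener's LOQ
#' is a non-detect. Per-congener LOQs are placed, during calibration, at
#' the concentration quantile matching the requested non-detect fraction.
#'
#' @param n_samples survey size.
#' @param lombardy_frac fraction of samples from the point-source region.
#' @param region_logeffect named log-scale contamination offsets for the two
#'   regions (mean contamination contrast).
#' @param target_mean,target_sd survey-level targets for the upper-bound
#'   mean and SD of total TEQ (pg TEQ/g fat); calibration hits the mean
#'   analytically and the SD by bisection.
#' @param teq_profile named vector of TEQ-share weights over the 29 TEQ
#'   congeners (normalised internally); the default puts PCB 126 near 60%
#'   and 2,3,4,7,8-PeCDF second, the shape typical of milk.
#' @param censoring named non-detect target fractions for the 29 TEQ
#'   congeners (recycled scalar allowed). `NA` entries use the fixed
#'   `ndl_loq` instead of the quantile rule.
#' @param ndl_censoring targets for the 6 indicator PCBs; default `NA`
#'   (fixed LOQ).
#' @param ndl_loq fixed LOQ for indicator PCBs, ng/g fat.
#' @param idio_sdlog per-congener idiosyncratic log-SD.
#' @param fat_mean,fat_sd,fat_bounds truncated-normal fat distribution
#'   (g fat/100 g).
#' @param emilia_fat_kappa fat-coupling exponent for the Emilia-like region
#'   (contamination per g fat scales with `(fat/fat_mean)^kappa`).
#' @param point_frac,point_meanlog,point_sdlog Lombardy point-source
#'   mixture: fraction of samples hit and the lognormal multiplier.
#' @param n_exceed,exceed_teq number of constructed ML exceedances and the
#'   UB total TEQ they are set to.
#' @param ml_cap total-TEQ maximum level used to cap non-designated samples
#'   so the exceedance count is exact.
#' @param years sampling years to assign.
#' @param calib_nsim,calib_seed size and seed of the internal calibration
#'   simulation (isolated from the generation seed).
#' @return An object of class `survey_config`.
#' @export
survey_config <- function(n_samples = 214,
                          lombardy_frac = 0.5,
                          region_logeffect = c("Lombardy" = 0.17,
                                               "Emilia-Romagna" = -0.17),
                          target_mean = 0.78,
                          target_sd = 0.55,
                          teq_profile = default_teq_profile(),
                          censoring = default_censoring_targets(),
                          ndl_censoring = NA,
                          ndl_loq = 2,
                          idio_sdlog = 0.3,
                          fat_mean = 3.9,
                          fat_sd = 0.45,
                          fat_bounds = c(2.7, 5.3),
                          emilia_fat_kappa = 2.5,
                          point_frac = 0.03,
                          point_meanlog = log(3),
                          point_sdlog = 0.4,
                          n_exceed = 1,
                          exceed_teq = 6.28,
                          ml_cap = 4,
                          years = 2018:2021,
                          calib_nsim = 20000,
                          calib_seed = 20230430) {
  reg <- congener_registry()
  teq_ids <- reg$congener[reg$group != "ndl-PCB"]
  ndl_ids <- reg$congener[reg$group == "ndl-PCB"]

  if (is.null(names(teq_profile))) stop("teq_profile must be named")
  teq_profile <- teq_profile[teq_ids]
  if (anyNA(teq_profile) || any(teq_profile <= 0)) {
    stop("teq_profile must cover all 29 TEQ congeners with positive weights")
  }
  teq_profile <- teq_profile / sum(teq_profile)

  if (length(censoring) == 1L && is.null(names(censoring))) {
    censoring <- stats::setNames(rep(censoring, length(teq_ids)), teq_ids)
  }
  censoring <- censoring[teq_ids]
  if (any(stats::na.omit(censoring) < 0 | stats::na.omit(censoring) >= 1)) {
    stop("censoring targets must lie in [0, 1)")
  }
  if (length(ndl_censoring) == 1L) {
    ndl_censoring <- stats::setNames(rep(ndl_censoring, length(ndl_ids)), ndl_ids)
  }
  ndl_censoring <- ndl_censoring[ndl_ids]

  stopifnot(lombardy_frac >= 0, lombardy_frac <= 1,
            point_frac >= 0, point_frac <= 1,
            target_mean > 0, target_sd > 0,
            idio_sdlog > 0, fat_sd > 0, ndl_loq > 0,
            n_exceed >= 0, exceed_teq > 0)

  structure(
    list(
      n_samples = n_samples, lombardy_frac = lombardy_frac,
      region_logeffect = region_logeffect,
      target_mean = target_mean, target_sd = target_sd,
      teq_profile = teq_profile, censoring = censoring,
      ndl_censoring = ndl_censoring, ndl_loq = ndl_loq,
      ndl_meanlog = c(PCB28 = log(0.15), PCB52 = log(0.2), PCB101 = log(0.3),
                      PCB138 = log(2.2), PCB153 = log(2.4), PCB180 = log(1.3)),
      ndl_idio_sdlog = 0.4,
      idio_sdlog = idio_sdlog,
      fat_mean = fat_mean, fat_sd = fat_sd, fat_bounds = fat_bounds,
      emilia_fat_kappa = emilia_fat_kappa,
      point_frac = point_frac, point_meanlog = point_meanlog,
      point_sdlog = point_sdlog,
      n_exceed = n_exceed, exceed_teq = exceed_teq, ml_cap = ml_cap,
      years = years,
      calib_nsim = calib_nsim, calib_seed = calib_seed,
      calib = NULL
    ),
    class = "survey_config"
  )
}

#' Default TEQ-share profile over the 29 congeners
#'
#' PCB 126 dominates (~60% of total TEQ) with 2,3,4,7,8-PeCDF second, the
#' congener fingerprint typical of background-contaminated cow milk.
#'
#' @return Named weight vector (normalised by [survey_config()]).
#' @export
default_teq_profile <- function() {
  c(
    "2378-TCDD" = 0.03, "12378-PeCDD" = 0.06,
    "123478-HxCDD" = 0.01, "123678-HxCDD" = 0.01, "123789-HxCDD" = 0.01,
    "1234678-HpCDD" = 0.005, "OCDD" = 0.005,
    "2378-TCDF" = 0.01, "12378-PeCDF" = 0.005, "23478-PeCDF" = 0.12,
    "123478-HxCDF" = 0.01, "123678-HxCDF" = 0.01, "123789-HxCDF" = 0.01,
    "234678-HxCDF" = 0.01, "1234678-HpCDF" = 0.004, "1234789-HpCDF" = 0.004,
    "OCDF" = 0.002,
    "PCB77" = 0.005, "PCB81" = 0.005, "PCB105" = 0.01, "PCB114" = 0.005,
    "PCB118" = 0.02, "PCB123" = 0.002, "PCB126" = 0.60, "PCB156" = 0.01,
    "PCB157" = 0.005, "PCB167" = 0.005, "PCB169" = 0.05, "PCB189" = 0.005
  )
}

#' Default non-detect target fractions for the TEQ congeners
#'
#' Dioxin congeners in background-level milk are heavily censored; the
#' TEQ-dominant non-ortho PCBs much less so.
#'
#' @return Named fraction vector.
#' @export
default_censoring_targets <- function() {
  reg <- congener_registry()
  ids <- reg$congener[reg$group != "ndl-PCB"]
  out <- stats::setNames(rep(0.5, length(ids)), ids)
  out[reg$congener[reg$group == "dl-PCB"]] <- 0.15
  out["PCB126"] <- 0.05
  out["PCB169"] <- 0.10
  out["2378-TCDD"] <- 0.70
  out["OCDD"] <- 0.25
  out[ids]
}

# Simulate the per-sample latent structure shared by calibration and
# generation. Returns log-concentration matrices for the TEQ and ndl panels.
.sim_latent <- function(cfg, n, meanlog_teq, shared_sdlog) {
  reg <- congener_registry()
  teq_ids <- names(meanlog_teq)
  ndl_ids <- names(cfg$ndl_meanlog)

  n_lomb <- round(cfg$lombardy_frac * n)
  region <- rep(c("Lombardy", "Emilia-Romagna"), c(n_lomb, n - n_lomb))

  # truncated-normal fat via inverse CDF so draw count is fixed
  lo <- stats::pnorm(cfg$fat_bounds[1], cfg$fat_mean, cfg$fat_sd)
  hi <- stats::pnorm(cfg$fat_bounds[2], cfg$fat_mean, cfg$fat_sd)
  fat <- stats::qnorm(stats::runif(n, lo, hi), cfg$fat_mean, cfg$fat_sd)

  shared <- stats::rnorm(n, 0, shared_sdlog)
  point_hit <- stats::runif(n) < cfg$point_frac & region == "Lombardy"
  point <- ifelse(point_hit,
                  stats::rnorm(n, cfg$point_meanlog, cfg$point_sdlog), 0)
  coupling <- ifelse(region == "Emilia-Romagna",
                     cfg$emilia_fat_kappa * log(fat / cfg$fat_mean), 0)
  sample_eff <- cfg$region_logeffect[region] + shared + point + coupling

  log_teq <- outer(sample_eff, meanlog_teq, `+`) +
    matrix(stats::rnorm(n * length(teq_ids), 0, cfg$idio_sdlog),
           n, length(teq_ids))
  colnames(log_teq) <- teq_ids
  log_ndl <- outer(shared, cfg$ndl_meanlog, `+`) +
    matrix(stats::rnorm(n * length(ndl_ids), 0, cfg$ndl_idio_sdlog),
           n, length(ndl_ids))
  colnames(log_ndl) <- ndl_ids

  list(region = region, fat = fat, point_hit = point_hit,
       log_teq = log_teq, log_ndl = log_ndl)
}

# LOQ per congener: target-fraction quantile of the simulated marginal, or
# the fixed ndl LOQ where the target is NA. Zero targets get an LOQ far
# below the observable range so detection is certain.
.loq_from_targets <- function(draws, targets, fixed_loq = NULL) {
  vapply(colnames(draws), function(j) {
    p <- targets[[j]]
    if (is.na(p)) return(fixed_loq)
    if (p == 0) return(min(draws[, j]) * 1e-6)
    unname(stats::quantile(draws[, j], p, type = 7))
  }, numeric(1))
}

.ub_total_teq <- function(x, loq, tefs) {
  ids <- colnames(x)
  ub <- pmax(x, rep(loq[ids], each = nrow(x)))
  as.numeric(ub %*% tefs[ids])
}

#' Calibrate the generator to survey-level TEQ targets
#'
#' Tunes the generator so the expected upper-bound mean and SD of the total
#' PCDD/F + dl-PCB TEQ match the requested targets. The shared log-SD is
#' found by bisection against a fixed-seed internal simulation; the
#' congener locations are then shifted by a single exact multiplicative
#' factor (the UB total scales linearly with a common concentration scale,
#' because the quantile-placed LOQs scale along with it). When constructed
#' ML exceedances are configured, the background targets are adjusted
#' analytically so the full survey, exceedances included, hits the
#' requested moments.
#'
#' @param cfg a [survey_config()].
#' @param target_mean,target_sd overrides of the config targets.
#' @return The config with a populated `calib` field: per-congener
#'   `meanlog`, `shared_sdlog`, `loq` (all 35 congeners),
#'   `expected_censoring`, `expected_mean`, `expected_sd` (background,
#'   i.e. exceedance samples excluded).
#' @export
calibrate_survey <- function(cfg, target_mean = cfg$target_mean,
                             target_sd = cfg$target_sd) {
  stopifnot(inherits(cfg, "survey_config"))
  stopifnot_scalar_num(target_mean, "target_mean", positive = TRUE)
  stopifnot_scalar_num(target_sd, "target_sd", positive = TRUE)
  tefs <- tef_who2005()
  n <- cfg$n_samples
  k <- cfg$n_exceed

  # background moments implied by the survey-level targets
  if (k > 0) {
    bg_mean <- (n * target_mean - k * cfg$exceed_teq) / (n - k)
    if (bg_mean <= 0) {
      stop("infeasible calibration: exceedance construction already exceeds ",
           "the survey mean target")
    }
    bg_var <- (n * (target_sd^2 + target_mean^2) - k * cfg$exceed_teq^2) /
      (n - k) - bg_mean^2
    if (bg_var <= 0) {
      stop("infeasible calibration: target SD too small to host the ",
           "constructed exceedance sample(s)")
    }
    bg_sd <- sqrt(bg_var)
  } else {
    bg_mean <- target_mean
    bg_sd <- target_sd
  }
  cv_target <- bg_sd / bg_mean

  ids <- names(cfg$teq_profile)
  m0 <- log(cfg$teq_profile * bg_mean / tefs[ids])
  names(m0) <- ids

  sim_cv <- function(b) {
    with_seed(cfg$calib_seed, {
      lat <- .sim_latent(cfg, cfg$calib_nsim, m0, b)
      x <- exp(lat$log_teq)
      loq <- .loq_from_targets(x, cfg$censoring)
      tot <- .ub_total_teq(x, loq, tefs)
      list(cv = stats::sd(tot) / mean(tot), mean = mean(tot), loq = loq,
           x = x, lat = lat)
    })
  }

  lo <- 0.02; hi <- 1.5
  if (sim_cv(lo)$cv > cv_target) {
    stop("infeasible calibration: target SD below the spread already ",
         "induced by the regional and fat-coupling structure")
  }
  if (sim_cv(hi)$cv < cv_target) {
    stop("infeasible calibration: target SD too large")
  }
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (sim_cv(mid)$cv < cv_target) lo <- mid else hi <- mid
    if (hi - lo < 1e-4) break
  }
  b <- (lo + hi) / 2
  sim <- sim_cv(b)
  if (abs(sim$cv - cv_target) / cv_target > 0.10) {
    stop("calibration failed to reach the target SD within 10%")
  }

  shift <- log(bg_mean / sim$mean)  # exact: UB total is scale-linear
  meanlog <- m0 + shift
  loq_teq <- sim$loq * exp(shift)

  ndl_draws <- exp(sim$lat$log_ndl)
  loq_ndl <- .loq_from_targets(ndl_draws, cfg$ndl_censoring, cfg$ndl_loq)
  exp_cens <- c(
    colMeans(sim$x * exp(shift) < rep(loq_teq, each = nrow(sim$x))),
    colMeans(ndl_draws < rep(loq_ndl, each = nrow(ndl_draws)))
  )

  cfg$target_mean <- target_mean
  cfg$target_sd <- target_sd
  cfg$calib <- list(
    meanlog = meanlog,
    shared_sdlog = b,
    loq = c(loq_teq, loq_ndl),
    expected_censoring = exp_cens,
    expected_mean = bg_mean,
    expected_sd = bg_sd,
    achieved_cv = sim$cv
  )
  cfg
}

#' Generate a synthetic milk survey
#'
#' Draws a full congener-level survey from a (calibrated) generator
#' configuration. Deterministic under `seed`: identical config and seed
#' give an identical survey. After the raw draws, the configured number of
#' maximum-level exceedances is constructed by scaling the most
#' contaminated Lombardy sample(s) to the configured upper-bound total TEQ,
#' and any other sample that would exceed the total ML by chance is scaled
#' just below it, so the exceedance count is exact.
#'
#' @param cfg a [survey_config()]; calibrated automatically if needed.
#' @param seed integer seed.
#' @return A [milk_survey()]; the config used (with calibration) is
#'   attached as attribute `"config"`.
#' @examples
#' sv <- generate_survey(survey_config(n_samples = 20), seed = 1)
#' sv
#' @export
generate_survey <- function(cfg = survey_config(), seed = 1) {
  stopifnot(inherits(cfg, "survey_config"))
  if (is.null(cfg$calib)) cfg <- calibrate_survey(cfg)
  tefs <- tef_who2005()
  n <- cfg$n_samples
  loq <- cfg$calib$loq

  lat <- with_seed(seed, {
    l <- .sim_latent(cfg, n, cfg$calib$meanlog, cfg$calib$shared_sdlog)
    l$year <- sample(cfg$years, n, replace = TRUE)
    l
  })
  x_teq <- exp(lat$log_teq)
  x_ndl <- exp(lat$log_ndl)
  teq_ids <- colnames(x_teq)

  # LOQs for the TEQ panel sit at the realized concentration quantile of
  # this survey, so the configured non-detect fractions are honored exactly
  # (a lab's LOQ is set per analytical campaign; here the campaign is the
  # generated survey). Calibration used the population quantile of the same
  # model, so the two agree up to sampling noise in the quantile.
  loq[teq_ids] <- .loq_from_targets(x_teq, cfg$censoring)

  # constructed ML exceedances, then cap chance exceedances elsewhere
  scale_to <- function(row_x, target) {
    det <- row_x >= loq[teq_ids]
    cens_part <- sum(loq[teq_ids][!det] * tefs[teq_ids][!det])
    det_part <- sum(row_x[det] * tefs[teq_ids][det])
    if (det_part <= 0 || target <= cens_part) return(row_x)
    row_x[det] <- row_x[det] * (target - cens_part) / det_part
    row_x
  }
  if (cfg$n_exceed > 0) {
    tot <- .ub_total_teq(x_teq, loq, tefs)
    lomb <- which(lat$region == "Lombardy")
    if (length(lomb) < cfg$n_exceed) {
      stop("not enough Lombardy samples to host the configured exceedances")
    }
    # a median-typical sample hosts the point-source hit: replacing an
    # extreme draw would silently remove the background tail the SD
    # calibration accounts for
    designated <- lomb[order(abs(tot[lomb] - stats::median(tot[lomb])))][seq_len(cfg$n_exceed)]
    for (i in designated) x_teq[i, ] <- scale_to(x_teq[i, ], cfg$exceed_teq)
  } else {
    designated <- integer(0)
  }
  for (pass in 1:3) {
    tot <- .ub_total_teq(x_teq, loq, tefs)
    over <- setdiff(which(tot > cfg$ml_cap), designated)
    if (!length(over)) break
    for (i in over) x_teq[i, ] <- scale_to(x_teq[i, ], 0.95 * cfg$ml_cap)
  }

  conc <- cbind(x_teq, x_ndl)
  loq_m <- matrix(loq[colnames(conc)], n, ncol(conc), byrow = TRUE,
                  dimnames = list(NULL, colnames(conc)))
  detected <- conc >= loq_m

  sv <- milk_survey(
    meta = data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      region = lat$region,
      year = lat$year,
      fat = lat$fat,
      stringsAsFactors = FALSE
    ),
    conc = conc, loq = loq_m, detected = detected
  )
  attr(sv, "config") <- cfg
  attr(sv, "seed") <- seed
  sv
}
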