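#' Configuration for the synthetic CKD cohort generator
#'
#' Defaults emulate a CKD cohort under nephrological care, calibrated to the
#' sub-study the package is designed to analyse: n = 108 with 66 men, age
#' 62.2 (SD 11.9) years truncated to the 19-74 y enrolment window, BMI 29.7
#' (SD 6.2), serum creatinine 1.56 (SD 0.5) mg/dl, collection time 24.2
#' (SD 1) h within 20.8-26.7 h, recorded urine volume averaging 2511 ml in
#' 500-6500 ml, 24h sodium excretion averaging ~183 mmol/d (10.7 g/d salt)
#' in 19-437 mmol/d, 54.6% diuretic use, and Spearman targets of 0.234 (AM)
#' and 0.463 (PM) between spot sodium concentration and daily excretion.
#'
#' @param n Number of participants.
#' @param frac_male Fraction of men; the generated count is
#'   `round(n * frac_male)` exactly.
#' @param age_mean,age_sd,age_range Age distribution, years: a scaled Beta
#'   on `age_range` moment-matched to `age_mean`/`age_sd` (the enrolment
#'   window is tight relative to the SD, which rules out a truncated
#'   normal with these moments).
#' @param bmi_mean,bmi_sd,bmi_range BMI distribution (truncated normal
#'   whose truncated moments equal the configured ones), kg/m2.
#' @param scr_mean,scr_sd,scr_range Serum creatinine, mg/dl.
#' @param dur_mean,dur_sd,dur_range Collection duration, h.
#' @param vol_mean,vol_range Recorded collection volume (truncated
#'   lognormal whose truncated mean equals `vol_mean`), ml.
#' @param vol_sdlog Log-scale SD of the volume distribution.
#' @param na24_mean,na24_range 24h sodium excretion (truncated lognormal),
#'   mmol/d.
#' @param na24_sdlog Log-scale SD of the excretion distribution.
#' @param target_rho_am,target_rho_pm Spearman correlation targets between
#'   the spot sodium concentration (AM/PM) and 24h sodium excretion,
#'   achieved through a Gaussian copula.
#' @param frac_diuretic Probability of diuretic use (Bernoulli).
#' @param k24_mean,k24_sdlog 24h potassium excretion (lognormal), mmol/d.
#' @param spot_na_sdlog Log-scale SD of the spot sodium concentration
#'   marginal; its median is set to `na24_mean / (vol_mean/1000)` so spot
#'   concentrations sit on the excretion-per-volume scale.
#' @param spot_noise_sdlog Multiplicative (lognormal) circadian noise on
#'   spot creatinine and potassium concentrations.
#' @param crea_mg_kg_male,crea_mg_kg_female Daily creatinine excretion per
#'   kg body weight (mg/kg/d), attenuated 2%/year after age 50 (floored at
#'   30%) — standard physiology, isolated here so tests do not depend on it.
#' @param serum_na_mean,serum_na_sd Serum sodium, mmol/l (calibration
#'   constants only; nothing downstream consumes them).
#' @param file Optional YAML or JSON file whose top-level keys override the
#'   defaults above (unknown keys are an error).
#' @return A list of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n = 108,
                          frac_male = 66 / 108,
                          age_mean = 62.2, age_sd = 11.9, age_range = c(19, 74),
                          bmi_mean = 29.7, bmi_sd = 6.2, bmi_range = c(16, 55),
                          scr_mean = 1.56, scr_sd = 0.5, scr_range = c(0.5, 4),
                          dur_mean = 24.2, dur_sd = 1, dur_range = c(20.8, 26.7),
                          vol_mean = 2511, vol_range = c(500, 6500),
                          vol_sdlog = 0.4,
                          na24_mean = 10.7 / (58.443 / 22.98977) / 23 * 1000,
                          na24_range = c(19, 437), na24_sdlog = 0.45,
                          target_rho_am = 0.234, target_rho_pm = 0.463,
                          frac_diuretic = 0.546,
                          k24_mean = 70, k24_sdlog = 0.35,
                          spot_na_sdlog = 0.55, spot_noise_sdlog = 0.3,
                          crea_mg_kg_male = 20, crea_mg_kg_female = 15,
                          serum_na_mean = 145, serum_na_sd = 4.8,
                          file = NULL) {
  config <- as.list(environment())
  config$file <- NULL
  if (!is.null(file)) {
    override <- if (grepl("\\.json$", file, ignore.case = TRUE)) {
      jsonlite::read_json(file, simplifyVector = TRUE)
    } else {
      # YAML 1.1 would read the bare key `n:` as a boolean; keep y/n literal
      yaml::read_yaml(file, handlers = list(
        "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
        "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE
      ))
    }
    unknown <- setdiff(names(override), names(config))
    if (length(unknown)) {
      rlang::abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
    }
    config[names(override)] <- override
  }
  stopifnot(
    config$n >= 1,
    config$frac_male >= 0, config$frac_male <= 1,
    config$frac_diuretic >= 0, config$frac_diuretic <= 1,
    config$age_sd > 0, config$bmi_sd > 0, config$scr_sd > 0, config$dur_sd > 0,
    abs(config$target_rho_am) < 1, abs(config$target_rho_pm) < 1
  )
  structure(config, class = "cohort_config")
}

# Moments of a normal(mu, s) truncated to [a, b].
truncnorm_moments <- function(mu, s, range) {
  al <- (range[[1]] - mu) / s
  be <- (range[[2]] - mu) / s
  z <- stats::pnorm(be) - stats::pnorm(al)
  dd <- (stats::dnorm(be) - stats::dnorm(al)) / z
  m <- mu - s * dd
  v <- s^2 * (1 - (be * stats::dnorm(be) - al * stats::dnorm(al)) / z - dd^2)
  c(mean = m, sd = if (is.finite(v) && v > 0) sqrt(v) else NaN)
}

# Parent (mu, sigma) such that the [a, b]-truncated normal has the requested
# mean and SD. Infeasible combinations (bounds clip too much tail mass for
# the SD to be reachable) are an error: the caller must pick a family whose
# support can carry the requested moments, cf. the Beta used for age.
solve_truncnorm_params <- function(mean, sd, range) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[[1]], exp(p[[2]]), range)
    if (!all(is.finite(mo))) return(1e10)
    sum((mo - c(mean, sd))^2)
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(maxit = 5000, reltol = 1e-14))
  if (fit$value > (1e-6 * sd)^2) {
    rlang::abort(sprintf(
      "No truncated normal on [%g, %g] has mean %g and SD %g.",
      range[[1]], range[[2]], mean, sd
    ))
  }
  c(mu = fit$par[[1]], sigma = exp(fit$par[[2]]))
}

# Truncated-normal sampling by quantile inversion (no rejection, no boundary
# atoms), with the parent parameters solved so the realised truncated
# mean/SD equal the requested ones.
rtruncnorm_mm <- function(n, mean, sd, range) {
  par <- solve_truncnorm_params(mean, sd, range)
  plo <- stats::pnorm(range[[1]], par[["mu"]], par[["sigma"]])
  phi <- stats::pnorm(range[[2]], par[["mu"]], par[["sigma"]])
  stats::qnorm(stats::runif(n, plo, phi), par[["mu"]], par[["sigma"]])
}

# Scaled-Beta sampling on `range`, moment-matched to the requested mean/SD.
# Used where the bounds are tight relative to the SD (age: the enrolment
# window clips a truncated normal's upper tail so hard that no member of
# that family attains the observed SD).
rbeta_mm <- function(n, mean, sd, range) {
  width <- range[[2]] - range[[1]]
  m <- (mean - range[[1]]) / width
  v <- (sd / width)^2
  stopifnot(m > 0, m < 1, v < m * (1 - m))
  conc <- m * (1 - m) / v - 1
  stats::qbeta(stats::runif(n), m * conc, (1 - m) * conc) * width + range[[1]]
}

# Quantile transform of standard-normal latents to a lognormal truncated to
# `range`, with meanlog solved so the *truncated* mean equals target_mean.
qlnorm_trunc <- function(z, target_mean, sdlog, range) {
  meanlog <- solve_trunc_lnorm_meanlog(target_mean, sdlog, range)
  plo <- stats::plnorm(range[[1]], meanlog, sdlog)
  phi <- stats::plnorm(range[[2]], meanlog, sdlog)
  stats::qlnorm(plo + stats::pnorm(z) * (phi - plo), meanlog, sdlog)
}

trunc_lnorm_mean <- function(meanlog, sdlog, range) {
  a <- (log(range[[1]]) - meanlog) / sdlog
  b <- (log(range[[2]]) - meanlog) / sdlog
  num <- stats::pnorm(b - sdlog) - stats::pnorm(a - sdlog)
  den <- stats::pnorm(b) - stats::pnorm(a)
  exp(meanlog + sdlog^2 / 2) * num / den
}

solve_trunc_lnorm_meanlog <- function(target_mean, sdlog, range) {
  stopifnot(target_mean > range[[1]], target_mean < range[[2]])
  stats::uniroot(
    function(m) trunc_lnorm_mean(m, sdlog, range) - target_mean,
    interval = log(c(range[[1]], range[[2]])),
    tol = 1e-10
  )$root
}

#' Simulate a synthetic CKD cohort
#'
#' Generates a cohort in the schema of [read_cohort()], reproducible
#' bit-for-bit given `(config, seed)`. Demographics come from truncated
#' normals; 24h sodium excretion and the recorded collection volume from
#' truncated lognormals whose truncated means match the configured means;
#' AM and PM spot sodium concentrations are tied to 24h excretion through a
#' Gaussian copula whose latent correlation `2 sin(pi * rho_s / 6)` yields
#' the configured Spearman targets; spot creatinine and potassium follow
#' from sex- and age-specific daily excretion divided by urine volume with
#' multiplicative circadian noise. CKD staging inputs (serum creatinine,
#' age, sex) feed [egfr_mdrd()], keeping eGFR internally consistent with
#' the sampled demographics.
#'
#' The recorded volume is the truncated-lognormal draw; the 24h-collection
#' concentrations are defined so that [normalize_collections()] recovers
#' the latent daily excretion exactly. Under the default configuration no
#' generated collection fails [screen_collections()].
#'
#' @param n Number of participants (overrides `config$n`).
#' @param config A [cohort_config()].
#' @param seed Integer seed. The global RNG state is left untouched.
#' @return A tibble in the cohort schema, with attributes `seed` and
#'   `config`.
#' @examples
#' cohort <- simulate_cohort(n = 20, seed = 42)
#' dplyr::count(cohort, sex)
#' @export
simulate_cohort <- function(n = NULL, config = cohort_config(), seed = 1L) {
  if (!inherits(config, "cohort_config")) {
    rlang::abort("`config` must be a cohort_config().")
  }
  if (!is.null(n)) config$n <- n
  n <- config$n

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  n_male <- round(n * config$frac_male)
  sex <- sample(rep(c("male", "female"), c(n_male, n - n_male)))
  age <- rbeta_mm(n, config$age_mean, config$age_sd, config$age_range)
  bmi <- rtruncnorm_mm(n, config$bmi_mean, config$bmi_sd, config$bmi_range)
  height_m <- rtruncnorm_mm(n, 176, 7, c(150, 205))
  height_f <- rtruncnorm_mm(n, 163, 6.5, c(140, 195))
  height <- ifelse(sex == "male", height_m, height_f)
  weight <- bmi * (height / 100)^2
  scr <- rtruncnorm_mm(n, config$scr_mean, config$scr_sd, config$scr_range)
  diuretic <- stats::runif(n) < config$frac_diuretic
  dur <- rtruncnorm_mm(n, config$dur_mean, config$dur_sd, config$dur_range)

  # Latent Gaussian copula: z24 drives daily excretion; the spot latents
  # share rank correlation rho_s with it via pearson = 2 sin(pi rho_s / 6).
  z24 <- stats::rnorm(n)
  rho_am <- 2 * sin(pi * config$target_rho_am / 6)
  rho_pm <- 2 * sin(pi * config$target_rho_pm / 6)
  z_am <- rho_am * z24 + sqrt(1 - rho_am^2) * stats::rnorm(n)
  z_pm <- rho_pm * z24 + sqrt(1 - rho_pm^2) * stats::rnorm(n)

  na24 <- qlnorm_trunc(z24, config$na24_mean, config$na24_sdlog, config$na24_range)
  vol <- qlnorm_trunc(stats::rnorm(n), config$vol_mean, config$vol_sdlog, config$vol_range)
  vol_daily <- vol * 24 / dur

  spot_na_median <- config$na24_mean / (config$vol_mean / 1000)
  spot_na <- function(z) {
    stats::qlnorm(stats::pnorm(z), log(spot_na_median), config$spot_na_sdlog)
  }
  am_una <- spot_na(z_am)
  pm_una <- spot_na(z_pm)

  # Daily creatinine excretion (mg/d): mg/kg/d by sex, attenuated 2%/y
  # after 50, floored at 30% of the adult rate.
  crea_rate <- ifelse(sex == "male", config$crea_mg_kg_male, config$crea_mg_kg_female)
  atten <- pmax(0.3, 1 - 0.02 * pmax(0, age - 50))
  crea24_mg <- weight * crea_rate * atten

  k24 <- stats::rlnorm(n, log(config$k24_mean) - config$k24_sdlog^2 / 2, config$k24_sdlog)

  noise <- function() stats::rlnorm(n, -config$spot_noise_sdlog^2 / 2, config$spot_noise_sdlog)
  # concentrations: excretion / daily volume (creatinine in mg/dl:
  # mg/d / (ml/d / 100 ml per dl))
  am_ucrea <- crea24_mg / (vol_daily / 100) * noise()
  pm_ucrea <- crea24_mg / (vol_daily / 100) * noise()
  am_uk <- k24 / (vol_daily / 1000) * noise()
  pm_uk <- k24 / (vol_daily / 1000) * noise()

  u24_una <- na24 / (vol_daily / 1000)
  u24_uk <- k24 / (vol_daily / 1000)
  u24_ucrea <- crea24_mg / (vol_daily / 100)

  cohort <- tibble::tibble(
    id = sprintf("S%04d", seq_len(n)),
    sex = sex,
    age_y = round(age, 1),
    weight_kg = round(weight, 1),
    height_cm = round(height, 1),
    bmi = round(bmi, 1),
    serum_crea_mg_dl = round(scr, 2),
    diuretic = diuretic,
    egfr_ml_min = round(egfr_mdrd(round(scr, 2), round(age, 1), sex), 1),
    am_una_mmol_l = round(am_una, 1),
    am_uk_mmol_l = round(am_uk, 1),
    am_ucrea_mg_dl = round(am_ucrea, 1),
    pm_una_mmol_l = round(pm_una, 1),
    pm_uk_mmol_l = round(pm_uk, 1),
    pm_ucrea_mg_dl = round(pm_ucrea, 1),
    dur_h = round(dur, 1),
    vol_ml = round(vol),
    u24_una_mmol_l = round(u24_una, 1),
    u24_uk_mmol_l = round(u24_uk, 1),
    u24_ucrea_mg_dl = round(u24_ucrea, 1)
  )
  attr(cohort, "seed") <- as.integer(seed)
  attr(cohort, "config") <- config
  cohort
}

#' MDRD estimated glomerular filtration rate and KDIGO stage
#'
#' Four-variable MDRD equation (175-based):
#' \deqn{175 \times Scr^{-1.154} \times age^{-0.203} \times 0.742^{[female]}}
#' in ml/min/1.73 m2 (the race coefficient is not applied).
#'
#' @param scr Serum creatinine, mg/dl; strictly positive.
#' @param age_y Age in years; strictly positive.
#' @param sex `"male"` or `"female"`.
#' @return Numeric vector of eGFR values.
#' @examples
#' egfr_mdrd(1.56, 62.2, "male") # ~45.3
#' @export
egfr_mdrd <- function(scr, age_y, sex) {
  sex <- check_sex(sex)
  check_positive(scr, "scr")
  check_positive(age_y, "age_y")
  175 * scr^-1.154 * age_y^-0.203 * ifelse(sex == "female", 0.742, 1)
}

#' @rdname egfr_mdrd
#' @param egfr eGFR in ml/min/1.73 m2.
#' @return `ckd_stage()`: a factor with KDIGO G-stage levels
#'   `G1, G2, G3a, G3b, G4, G5` (G3 split at 45; G4 below 30).
#' @examples
#' ckd_stage(c(95, 75, 50, 40, 20, 10))
#' @export
ckd_stage <- function(egfr) {
  cut(egfr,
    breaks = c(-Inf, 15, 30, 45, 60, 90, Inf),
    labels = c("G5", "G4", "G3b", "G3a", "G2", "G1"),
    right = FALSE
  ) |>
    factor(levels = c("G1", "G2", "G3a", "G3b", "G4", "G5"))
}
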