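#' @importFrom rlang .data abort warn %||%
NULL

# Molar factor used by all three published equations to convert mmol Na to mg
# Na. The equations print "23 x", not the exact atomic mass 22.98977, and the
# implementation reproduces them digit-for-digit.
MG_PER_MMOL_NA <- 23

# mg/dl -> mmol/l for creatinine (molar mass 113.12 g/mol):
# mg/dl x 10 = mg/l; / 113.12 = mmol/l.
CREA_MGDL_TO_MMOLL <- 10 / 113.12

#' Kawasaki equation: predicted 24h sodium excretion from a morning spot urine
#'
#' Sex-specific closed form
#' \deqn{23 \times 16.3 \times \sqrt{\frac{U_{Na}}{U_{crea} \times 10} \times B}}
#' where \eqn{U_{Na}} is the spot sodium concentration (mmol/l),
#' \eqn{U_{crea}} the spot creatinine concentration (mg/dl; the printed
#' \eqn{\times 10} converts it to mg/l), and \eqn{B} the sex-specific body
#' term: \eqn{15.12 w + 7.39 h - 12.63 a - 79.9} for men and
#' \eqn{8.58 w + 5.09 h - 4.72 a - 74.5} for women (weight in kg, height in
#' cm, age in years). The equation was derived for second-morning-void
#' samples; evening samples are not an eligible input (see
#' [estimate_sodium()] for how timing eligibility is enforced).
#'
#' @param una Spot urinary sodium concentration, mmol/l. Vectorised.
#' @param ucrea_mg_dl Spot urinary creatinine concentration, mg/dl. Must be
#'   positive.
#' @param sex Character vector, `"male"` or `"female"` (recycled).
#' @param age_y,weight_kg,height_cm Anthropometry: age in years, weight in
#'   kg, height in cm.
#' @return Numeric vector of predicted 24h sodium excretion in mg/d.
#'   Missing inputs propagate as `NA`.
#' @seealso [tanaka_sodium()], [intersalt_sodium()], [estimate_sodium()]
#' @examples
#' kawasaki_sodium(100, 100, "male", 60, 80, 170) # ~4784 mg/d
#' @export
kawasaki_sodium <- function(una, ucrea_mg_dl, sex, age_y, weight_kg, height_cm) {
  sex <- check_sex(sex)
  check_positive(ucrea_mg_dl, "ucrea_mg_dl")
  check_nonnegative(una, "una")
  body <- ifelse(sex == "male",
    15.12 * weight_kg + 7.39 * height_cm - 12.63 * age_y - 79.9,
    8.58 * weight_kg + 5.09 * height_cm - 4.72 * age_y - 74.5
  )
  if (any(body <= 0, na.rm = TRUE)) {
    abort("Kawasaki body-size term is non-positive; anthropometry out of the equation's domain.")
  }
  MG_PER_MMOL_NA * (16.3 * sqrt(una / (ucrea_mg_dl * 10) * body))
}

#' Tanaka equation: predicted 24h sodium excretion from a spot urine
#'
#' Single form for men and women,
#' \deqn{23 \times 21.98 \times \left(\frac{U_{Na}}{U_{crea} \times 10}
#'   \times B\right)^{0.392}}
#' with body term
#' \eqn{B = -2.04 a + 14.89 w + 16.14 h - 2244.45} (age in years, weight in
#' kg, height in cm). Applicable to morning and evening spot samples.
#'
#' @inheritParams kawasaki_sodium
#' @return Numeric vector of predicted 24h sodium excretion in mg/d.
#' @examples
#' tanaka_sodium(100, 100, 60, 80, 170) # ~3667 mg/d
#' @export
tanaka_sodium <- function(una, ucrea_mg_dl, age_y, weight_kg, height_cm) {
  check_positive(ucrea_mg_dl, "ucrea_mg_dl")
  check_nonnegative(una, "una")
  body <- -2.04 * age_y + 14.89 * weight_kg + 16.14 * height_cm - 2244.45
  if (any(body <= 0, na.rm = TRUE)) {
    abort("Tanaka body-size term is non-positive; anthropometry out of the equation's domain.")
  }
  MG_PER_MMOL_NA * (21.98 * (una / (ucrea_mg_dl * 10) * body)^0.392)
}

#' INTERSALT equation: predicted 24h sodium excretion from a spot urine
#'
#' Sex-specific linear predictor in mmol/d, multiplied by 23 to mg/d.
#' Men: \eqn{25.46 + 0.46 U_{Na} - 2.75 U_{crea} - 0.13 U_K + 4.10 BMI +
#' 0.26 a}. Women: \eqn{5.07 + 0.34 U_{Na} - 2.16 U_{crea} - 0.09 U_K +
#' 2.39 BMI + 2.35 a - 0.03 a^2}. Concentrations in mmol/l (note creatinine
#' here is molar — use [convert_creatinine()] for mg/dl values), BMI in
#' kg/m2, age in years. Unlike the power-form equations the predictor can go
#' negative for very dilute urines; negative values are returned as-is so
#' that downstream agreement statistics are not distorted (callers may
#' inspect the sign; [estimate_sodium()] flags them).
#'
#' @inheritParams kawasaki_sodium
#' @param uk Spot urinary potassium concentration, mmol/l. Required.
#' @param ucrea_mmol_l Spot urinary creatinine concentration, mmol/l.
#' @param bmi Body-mass index, kg/m2. Required (it enters the predictor
#'   directly).
#' @return Numeric vector of predicted 24h sodium excretion in mg/d
#'   (possibly negative).
#' @examples
#' intersalt_sodium(100, 50, convert_creatinine(100, "mg/dl", "mmol/l"),
#'   "male", 60, bmi = 29.7) # ~4094 mg/d
#' @export
intersalt_sodium <- function(una, uk, ucrea_mmol_l, sex, age_y, bmi) {
  sex <- check_sex(sex)
  if (missing(uk) || is.null(uk)) {
    abort("INTERSALT requires the spot potassium concentration (`uk`).")
  }
  if (missing(bmi) || is.null(bmi)) {
    abort("INTERSALT requires BMI.")
  }
  check_nonnegative(una, "una")
  mmol_d <- ifelse(sex == "male",
    25.46 + 0.46 * una - 2.75 * ucrea_mmol_l - 0.13 * uk + 4.10 * bmi +
      0.26 * age_y,
    5.07 + 0.34 * una - 2.16 * ucrea_mmol_l - 0.09 * uk + 2.39 * bmi +
      2.35 * age_y - 0.03 * age_y^2
  )
  MG_PER_MMOL_NA * mmol_d
}

#' Estimate 24h sodium excretion for a cohort with one or more equations
#'
#' Data-frame-first wrapper around [kawasaki_sodium()], [tanaka_sodium()] and
#' [intersalt_sodium()]. Expects the cohort schema of [read_cohort()] /
#' [simulate_cohort()] (columns `sex`, `age_y`, `weight_kg`, `height_cm`,
#' `bmi`, and per-timing spot columns `am_una_mmol_l`, `am_uk_mmol_l`,
#' `am_ucrea_mg_dl`, likewise `pm_*`). Returns one row per participant x
#' equation x timing in long format, carrying provenance and quality flags.
#'
#' The Kawasaki equation was derived for morning samples only; its PM cell
#' is skipped unless `allow_kawasaki_pm = TRUE`, in which case the estimate
#' is computed and flagged `ineligible_timing`. Negative INTERSALT estimates
#' are returned flagged (`negative_estimate`), never clamped: clamping would
#' bias Bland-Altman statistics.
#'
#' If `bmi` is missing for a participant it is derived as
#' `weight_kg / (height_cm / 100)^2`; a supplied BMI always wins.
#'
#' @param data Cohort data frame (see [read_cohort()] for the schema).
#' @param formulas Character subset of `c("kawasaki", "tanaka", "intersalt")`.
#' @param timings Character subset of `c("am", "pm")`.
#' @param allow_kawasaki_pm Compute the (ineligible) Kawasaki-PM estimate
#'   anyway? Default `FALSE`: the combination is silently dropped from the
#'   grid.
#' @return A tibble with columns `id`, `formula`, `timing`,
#'   `na_mmol_day`, `na_mg_day` (`na_mg_day = 23 * na_mmol_day` always),
#'   `negative_estimate`, `ineligible_timing`.
#' @examples
#' cohort <- simulate_cohort(n = 6, seed = 1)
#' estimate_sodium(cohort, formulas = "tanaka")
#' @export
estimate_sodium <- function(data,
                            formulas = c("kawasaki", "tanaka", "intersalt"),
                            timings = c("am", "pm"),
                            allow_kawasaki_pm = FALSE) {
  formulas <- match.arg(formulas, several.ok = TRUE)
  timings <- match.arg(timings, several.ok = TRUE)
  data <- tibble::as_tibble(data)
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  bmi <- derive_bmi(data)

  grid <- tidyr::expand_grid(formula = formulas, timing = timings)
  keep <- !(grid$formula == "kawasaki" & grid$timing == "pm") | allow_kawasaki_pm
  if (!any(keep)) {
    abort(paste0(
      "The PM spot sample is not an eligible input to the Kawasaki equation ",
      "(derived for morning urine); set `allow_kawasaki_pm = TRUE` to compute ",
      "it anyway (flagged)."
    ))
  }
  grid <- grid[keep, ]

  purrr::pmap(grid, function(formula, timing) {
    una <- data[[paste0(timing, "_una_mmol_l")]]
    uk <- data[[paste0(timing, "_uk_mmol_l")]]
    ucrea <- data[[paste0(timing, "_ucrea_mg_dl")]]
    ok <- !is.na(una) & !is.na(ucrea) & ucrea > 0
    mg <- rep(NA_real_, nrow(data))
    mg[ok] <- switch(formula,
      kawasaki = kawasaki_sodium(
        una[ok], ucrea[ok], data$sex[ok], data$age_y[ok],
        data$weight_kg[ok], data$height_cm[ok]
      ),
      tanaka = tanaka_sodium(
        una[ok], ucrea[ok], data$age_y[ok],
        data$weight_kg[ok], data$height_cm[ok]
      ),
      intersalt = {
        ok2 <- ok & !is.na(uk)
        out <- rep(NA_real_, sum(ok))
        out[ok2[ok]] <- intersalt_sodium(
          una[ok2], uk[ok2],
          convert_creatinine(ucrea[ok2], "mg/dl", "mmol/l"),
          data$sex[ok2], data$age_y[ok2], bmi[ok2]
        )
        out
      }
    )
    tibble::tibble(
      id = data$id,
      formula = formula,
      timing = timing,
      na_mmol_day = mg / MG_PER_MMOL_NA,
      na_mg_day = mg,
      negative_estimate = !is.na(mg) & mg < 0,
      ineligible_timing = formula == "kawasaki" & timing == "pm"
    )
  }) |>
    purrr::list_rbind()
}

derive_bmi <- function(data) {
  bmi <- if ("bmi" %in% names(data)) data$bmi else rep(NA_real_, nrow(data))
  fill <- is.na(bmi) & !is.na(data$weight_kg) & !is.na(data$height_cm)
  bmi[fill] <- data$weight_kg[fill] / (data$height_cm[fill] / 100)^2
  bmi
}

#' Convert a daily sodium mass to the equivalent salt (NaCl) mass
#'
#' Uses exact molar masses (NaCl 58.443 g/mol, Na 22.98977 g/mol), giving
#' the conventional factor 2.54 g salt per g sodium at three significant
#' figures. Guideline thresholds of 2 g/d and 4 g/d sodium correspond to
#' about 5 g/d and 10 g/d salt.
#'
#' @param na_g Sodium mass, g/d. Non-negative.
#' @return Salt mass, g/d.
#' @examples
#' na_to_salt(1) # 2.542
#' na_to_salt(2) # ~5.08
#' @export
na_to_salt <- function(na_g) {
  check_nonnegative(na_g, "na_g")
  na_g * (58.443 / 22.98977)
}

#' Convert creatinine concentrations between mg/dl and mmol/l
#'
#' The Kawasaki and Tanaka equations take spot creatinine in mg/dl while
#' INTERSALT takes mmol/l; this converter bridges the two using creatinine's
#' molar mass (113.12 g/mol), i.e. mg/dl x 0.0884 = mmol/l.
#'
#' @param value Numeric vector of concentrations.
#' @param from,to Units, each one of `"mg/dl"` or `"mmol/l"`.
#' @return Converted concentrations; the round trip is the identity.
#' @examples
#' convert_creatinine(100, "mg/dl", "mmol/l") # 8.84
#' @export
convert_creatinine <- function(value, from, to) {
  units <- c("mg/dl", "mmol/l")
  from <- match.arg(from, units)
  to <- match.arg(to, units)
  if (from == to) {
    value
  } else if (from == "mg/dl") {
    value * CREA_MGDL_TO_MMOLL
  } else {
    value / CREA_MGDL_TO_MMOLL
  }
}

check_sex <- function(sex) {
  sex <- tolower(as.character(sex))
  bad <- !sex %in% c("male", "female") & !is.na(sex)
  if (any(bad)) {
    abort(paste0("`sex` must be \"male\" or \"female\"; got: ",
                 paste(unique(sex[bad]), collapse = ", ")))
  }
  sex
}

check_positive <- function(x, name) {
  if (any(x <= 0, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be strictly positive."))
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (any(x < 0, na.rm = TRUE)) {
    abort(paste0("`", name, "` must be non-negative."))
  }
  invisible(x)
}
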