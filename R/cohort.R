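# Cohort CSV schema. One row per participant; empty field = missing.
cohort_columns <- function() {
  c(
    "id", "sex", "age_y", "weight_kg", "height_cm", "bmi",
    "serum_crea_mg_dl", "diuretic", "egfr_ml_min",
    "am_una_mmol_l", "am_uk_mmol_l", "am_ucrea_mg_dl",
    "pm_una_mmol_l", "pm_uk_mmol_l", "pm_ucrea_mg_dl",
    "dur_h", "vol_ml",
    "u24_una_mmol_l", "u24_uk_mmol_l", "u24_ucrea_mg_dl"
  )
}

#' Read a cohort file
#'
#' Reads the tabular cohort format used throughout the package: one row per
#' participant with demographics (`sex`, `age_y`, `weight_kg`, `height_cm`,
#' `bmi`, `serum_crea_mg_dl`, `diuretic`, `egfr_ml_min`), AM and PM spot
#' urine concentrations (`*_una_mmol_l`, `*_uk_mmol_l`, `*_ucrea_mg_dl`) and
#' the 24h collection record (`dur_h`, `vol_ml`, `u24_*`). Lines starting
#' with `#` (e.g. the seed comment written by [write_cohort()]) are skipped.
#'
#' @param path Path to a CSV (or TSV) cohort file.
#' @return A tibble with one row per participant.
#' @seealso [write_cohort()], [simulate_cohort()]
#' @export
read_cohort <- function(path) {
  data <- readr::read_csv(
    path,
    comment = "#", show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      diuretic = readr::col_logical(),
      .default = readr::col_double()
    )
  )
  missing_cols <- setdiff(cohort_columns(), names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0(
      "Cohort file is missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  data$sex <- check_sex(data$sex)
  data
}

#' Write a cohort file
#'
#' Writes the cohort CSV schema of [read_cohort()]. If the data carry a
#' `seed` attribute (as cohorts from [simulate_cohort()] do) it is recorded
#' in a leading `# seed: <n>` comment line so a simulated cohort is
#' reproducible from its file alone.
#'
#' @param data Cohort data frame.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_cohort <- function(data, path) {
  seed <- attr(data, "seed", exact = TRUE)
  header <- if (!is.null(seed)) paste0("# seed: ", seed)
  lines <- readr::format_csv(data)
  writeLines(c(header, sub("\n$", "", lines)), path)
  invisible(data)
}

#' Screen 24h urine collections against the study protocol
#'
#' A collection is rejected when its volume, normalised to a daily rate
#' (`vol_ml * 24 / dur_h`), is below 250 ml/d, or when the collection time
#' is below 20 h or above 28 h. Boundary values are accepted (the rules are
#' phrased as strictly below/above). Rejected rows are kept and labelled,
#' never dropped, so callers decide how to handle them.
#'
#' @param data Cohort data frame with `dur_h` and `vol_ml` columns.
#' @return `data` with two added columns: `collection_ok` (logical) and
#'   `reject_reason` (`NA`, `"volume"`, `"duration_short"` or
#'   `"duration_long"`; volume is only assessed for collections with a valid
#'   duration).
#' @examples
#' screen_collections(tibble::tibble(dur_h = c(24, 19.9), vol_ml = c(500, 2000)))
#' @export
screen_collections <- function(data) {
  data <- tibble::as_tibble(data)
  rate <- data$vol_ml * 24 / data$dur_h
  reason <- dplyr::case_when(
    data$dur_h < 20 ~ "duration_short",
    data$dur_h > 28 ~ "duration_long",
    rate < 250 ~ "volume",
    .default = NA_character_
  )
  dplyr::mutate(data,
    collection_ok = is.na(reason) & !is.na(data$dur_h) & !is.na(data$vol_ml),
    reject_reason = reason
  )
}

#' Correct a timed urine collection to 24 hours
#'
#' Converts the measured 24h-collection concentrations into daily excretion
#' totals (`concentration x volume / 1000`) and linearly rescales them by
#' `24 / dur_h` for collections that did not last exactly 24 h, following
#' the timed-collection correction used in population salt surveys. Only
#' totals are rescaled; concentrations are ratios and unaffected.
#'
#' @param data Cohort data frame that has passed [screen_collections()]
#'   (rows failing the screen raise an error; screen first and filter).
#' @return `data` with added columns `na24_mmol_d`, `na24_mg_d`
#'   (`= 23 * na24_mmol_d`), `k24_mmol_d`, `crea24_g_d` and `normalized`
#'   (`TRUE` where `dur_h != 24`).
#' @examples
#' x <- tibble::tibble(
#'   dur_h = 20.8, vol_ml = 2000, u24_una_mmol_l = 100,
#'   u24_uk_mmol_l = 50, u24_ucrea_mg_dl = 80
#' )
#' normalize_collections(x)$na24_mmol_d # 230.77
#' @export
normalize_collections <- function(data) {
  data <- tibble::as_tibble(data)
  screened <- screen_collections(data)
  if (any(!screened$collection_ok, na.rm = TRUE)) {
    rlang::abort(paste0(
      "normalize_collections() requires collections that pass ",
      "screen_collections(); ", sum(!screened$collection_ok),
      " row(s) fail. Screen and filter first."
    ))
  }
  scale <- 24 / data$dur_h
  vol_l <- data$vol_ml / 1000
  dplyr::mutate(data,
    na24_mmol_d = data$u24_una_mmol_l * vol_l * scale,
    na24_mg_d = MG_PER_MMOL_NA * data$u24_una_mmol_l * vol_l * scale,
    k24_mmol_d = data$u24_uk_mmol_l * vol_l * scale,
    # creatinine: mg/dl x 10 = mg/l; x vol_l = mg/d; /1000 = g/d
    crea24_g_d = data$u24_ucrea_mg_dl * 10 * vol_l * scale / 1000,
    normalized = data$dur_h != 24
  )
}

#' Average the AM and PM spot samples component-wise
#'
#' Adds `(AM + PM)/2` columns for sodium, potassium and creatinine. If
#' either sample is missing a component, the average is missing too
#' (pairwise-complete analysis downstream, never imputation).
#'
#' @param data Cohort data frame with `am_*` and `pm_*` spot columns.
#' @return `data` with added `avg_una_mmol_l`, `avg_uk_mmol_l`,
#'   `avg_ucrea_mg_dl`.
#' @export
average_spot <- function(data) {
  data <- tibble::as_tibble(data)
  dplyr::mutate(data,
    avg_una_mmol_l = (data$am_una_mmol_l + data$pm_una_mmol_l) / 2,
    avg_uk_mmol_l = (data$am_uk_mmol_l + data$pm_uk_mmol_l) / 2,
    avg_ucrea_mg_dl = (data$am_ucrea_mg_dl + data$pm_ucrea_mg_dl) / 2
  )
}

#' Creatinine-adjusted spot sodium
#'
#' Expresses a spot sodium concentration per gram of urinary creatinine:
#' `una_mmol_l / (ucrea_mg_dl / 100)` (100 mg/dl = 1 g/l; the litres
#' cancel), in mmol Na per g creatinine. Used to test whether creatinine
#' adjustment improves the correlation of spot sodium with daily excretion.
#'
#' @param una_mmol_l Spot sodium concentration, mmol/l.
#' @param ucrea_mg_dl Spot creatinine concentration, mg/dl; strictly
#'   positive.
#' @return mmol sodium per g creatinine.
#' @examples
#' creatinine_adjust(100, 100) # 100 mmol/g
#' @export
creatinine_adjust <- function(una_mmol_l, ucrea_mg_dl) {
  check_positive(ucrea_mg_dl, "ucrea_mg_dl")
  una_mmol_l / (ucrea_mg_dl / 100)
}
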