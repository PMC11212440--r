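#' Run the full spot-urine validation analysis on a cohort
#'
#' Executes the complete workflow: screen the 24h collections, correct them
#' to 24 h, compute equation estimates for every eligible formula x timing
#' cell, then produce (i) Spearman correlations of spot sodium (AM, PM and
#' their average) with 24h excretion, 24h concentration and on the
#' creatinine-adjusted scale — overall and stratified by CKD stage
#' (G1-3a vs G3b-5) and diuretic use, with Fisher-Z comparisons between
#' strata and between timings; (ii) per-formula agreement statistics
#' (Bland-Altman bias and limits of agreement, Spearman rho, P30); and
#' (iii) threshold classification grids at the guideline sodium cutoffs.
#'
#' The Kawasaki-PM cell is structurally present in the agreement and
#' classification grids but carries `NA` statistics (the equation is not
#' applicable to evening samples). Any cell with fewer than `min_n`
#' complete pairs is reported as missing rather than failing, so small
#' cohorts still run. The analysis is deterministic given the input and
#' invariant to row order.
#'
#' @param cohort A cohort data frame (schema of [read_cohort()]) or a path
#'   to a cohort CSV file.
#' @param thresholds Sodium thresholds in g/d for the classification grid.
#' @param formulas Equations to evaluate.
#' @param strata Stratifications to run: any of `"ckd"` (G1-3a vs G3b-5,
#'   from `egfr_ml_min`) and `"diuretics"`.
#' @param min_n Minimum complete pairs for a cell (default 4).
#' @return An object of class `natriuria_report`: a list of tibbles
#'   `correlations`, `timing_comparisons`, `strata_comparisons`,
#'   `agreement`, `classification`, plus `bland_altman` (named list of
#'   [bland_altman()] objects) and `meta`. Supports [tidy()], [glance()]
#'   and `print()`; write to disk with [write_report()].
#' @examples
#' report <- simulate_cohort(n = 60, seed = 7) |> run_analysis()
#' report$agreement
#' @export
run_analysis <- function(cohort,
                         thresholds = c(2, 4),
                         formulas = c("kawasaki", "tanaka", "intersalt"),
                         strata = c("ckd", "diuretics"),
                         min_n = 4) {
  if (is.character(cohort) && length(cohort) == 1) {
    cohort <- read_cohort(cohort)
  }
  cohort <- tibble::as_tibble(cohort)
  if (!"id" %in% names(cohort)) cohort$id <- sprintf("S%04d", seq_len(nrow(cohort)))
  formulas <- match.arg(formulas, several.ok = TRUE)
  if (length(strata)) {
    strata <- match.arg(strata, c("ckd", "diuretics"), several.ok = TRUE)
  }

  screened <- screen_collections(cohort)
  n_rejected <- sum(!screened$collection_ok)
  data <- screened |>
    dplyr::filter(.data$collection_ok) |>
    normalize_collections() |>
    average_spot() |>
    dplyr::mutate(
      ckd_group = dplyr::case_when(
        is.na(.data$egfr_ml_min) ~ NA_character_,
        ckd_stage(.data$egfr_ml_min) %in% c("G1", "G2", "G3a") ~ "G1-3a",
        .default = "G3b-5"
      ),
      measured_g_d = .data$na24_mg_d / 1000
    )

  correlations <- correlation_table(data, strata, min_n)
  timing_comparisons <- timing_comparison_table(correlations)
  strata_comparisons <- strata_comparison_table(correlations, strata)

  estimates <- estimate_sodium(data, formulas = formulas)
  grid <- tidyr::expand_grid(
    formula = formulas,
    timing = c("am", "pm")
  )

  cells <- purrr::pmap(grid, function(formula, timing) {
    if (formula == "kawasaki" && timing == "pm") {
      return(list(agreement = empty_agreement_row(formula, timing),
                  classification = empty_classification_rows(formula, timing, thresholds),
                  ba = NULL))
    }
    est <- estimates |>
      dplyr::filter(.data$formula == !!formula, .data$timing == !!timing)
    est <- est[match(data$id, est$id), ]
    ok <- stats::complete.cases(data$na24_mg_d, est$na_mg_day)
    if (sum(ok) < max(min_n, 2)) {
      return(list(agreement = empty_agreement_row(formula, timing, n = sum(ok)),
                  classification = empty_classification_rows(formula, timing, thresholds, n = sum(ok)),
                  ba = NULL))
    }
    measured <- data$na24_mg_d[ok]
    estimated <- est$na_mg_day[ok]
    ba <- bland_altman(measured, estimated)
    sp <- spearman_rho(measured, estimated)
    agreement <- tibble::tibble(
      formula = formula, timing = timing, n = ba$n,
      rho = sp$rho, rho_p = sp$p,
      mean_bias = ba$mean_bias, sd_diff = ba$sd_diff,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      bias_p = ba$bias_p,
      p30 = p30_precision(measured, estimated)
    )
    classification <- purrr::map(thresholds, function(thr) {
      classification_metrics(measured / 1000, estimated / 1000, thr)
    }) |>
      purrr::list_rbind() |>
      dplyr::mutate(formula = formula, timing = timing, .before = 1)
    list(agreement = agreement, classification = classification, ba = ba)
  })

  ba_list <- purrr::map(cells, "ba")
  names(ba_list) <- paste(grid$formula, grid$timing, sep = "_")

  structure(
    list(
      correlations = correlations,
      timing_comparisons = timing_comparisons,
      strata_comparisons = strata_comparisons,
      agreement = purrr::list_rbind(purrr::map(cells, "agreement")),
      classification = purrr::list_rbind(purrr::map(cells, "classification")),
      bland_altman = ba_list[!purrr::map_lgl(ba_list, is.null)],
      meta = list(
        n_input = nrow(cohort),
        n_analyzed = nrow(data),
        n_rejected = n_rejected,
        thresholds = thresholds,
        formulas = formulas,
        strata = strata,
        min_n = min_n
      )
    ),
    class = "natriuria_report"
  )
}

# spot-vs-24h correlation grid: timing x comparator x stratum
correlation_table <- function(data, strata, min_n) {
  timings <- c(am = "am_una_mmol_l", pm = "pm_una_mmol_l", avg = "avg_una_mmol_l")
  comparators <- c("excretion", "concentration", "crea_adjusted")

  strata_defs <- list(list(stratum = "all", rows = rep(TRUE, nrow(data))))
  if ("ckd" %in% strata) {
    strata_defs <- c(strata_defs, list(
      list(stratum = "G1-3a", rows = data$ckd_group == "G1-3a"),
      list(stratum = "G3b-5", rows = data$ckd_group == "G3b-5")
    ))
  }
  if ("diuretics" %in% strata) {
    strata_defs <- c(strata_defs, list(
      list(stratum = "no_diuretics", rows = !data$diuretic),
      list(stratum = "diuretics", rows = data$diuretic)
    ))
  }

  tidyr::expand_grid(
    comparator = comparators,
    timing = names(timings),
    stratum = purrr::map_chr(strata_defs, "stratum")
  ) |>
    purrr::pmap(function(comparator, timing, stratum) {
      rows <- strata_defs[[match(stratum, purrr::map_chr(strata_defs, "stratum"))]]$rows
      d <- data[rows & !is.na(rows), ]
      x <- switch(comparator,
        excretion = d[[timings[[timing]]]],
        concentration = d[[timings[[timing]]]],
        crea_adjusted = {
          ucrea <- d[[sub("una_mmol_l", "ucrea_mg_dl", timings[[timing]])]]
          ifelse(!is.na(ucrea) & ucrea > 0,
                 d[[timings[[timing]]]] / (ucrea / 100), NA_real_)
        }
      )
      y <- switch(comparator,
        excretion = d$na24_mmol_d,
        concentration = d$u24_una_mmol_l,
        crea_adjusted = d$na24_mmol_d
      )
      n_ok <- sum(stats::complete.cases(x, y))
      res <- if (n_ok >= max(min_n, 3)) {
        suppressWarnings(spearman_rho(x, y))
      } else {
        tibble::tibble(rho = NA_real_, n = n_ok, p = NA_real_)
      }
      tibble::tibble(
        comparator = comparator, timing = timing, stratum = stratum,
        n = res$n, rho = res$rho, p = res$p
      )
    }) |>
    purrr::list_rbind()
}

# Fisher-Z between timings, overall stratum, per comparator.
timing_comparison_table <- function(correlations) {
  pairs <- list(c("am", "pm"), c("am", "avg"), c("avg", "pm"))
  purrr::map(unique(correlations$comparator), function(comp) {
    purrr::map(pairs, function(pr) {
      r <- dplyr::filter(correlations, .data$comparator == comp,
                         .data$stratum == "all", .data$timing %in% pr)
      r <- r[match(pr, r$timing), ]
      if (any(is.na(r$rho))) {
        return(tibble::tibble(comparator = comp, label1 = pr[[1]],
                              label2 = pr[[2]], z = NA_real_,
                              p_one_sided = NA_real_, p_two_sided = NA_real_))
      }
      fisher_z_compare(r$rho[[1]], r$n[[1]], r$rho[[2]], r$n[[2]], labels = pr) |>
        dplyr::mutate(comparator = comp, .before = 1) |>
        dplyr::select("comparator", "label1", "label2",
                      "z", "p_one_sided", "p_two_sided")
    }) |>
      purrr::list_rbind()
  }) |>
    purrr::list_rbind()
}

# Fisher-Z between strata (within timing and comparator).
strata_comparison_table <- function(correlations, strata) {
  defs <- list()
  if ("ckd" %in% strata) defs <- c(defs, list(c("G1-3a", "G3b-5")))
  if ("diuretics" %in% strata) defs <- c(defs, list(c("no_diuretics", "diuretics")))
  if (!length(defs)) {
    return(tibble::tibble(
      comparator = character(), timing = character(),
      label1 = character(), label2 = character(),
      z = double(), p_one_sided = double(), p_two_sided = double()
    ))
  }
  correlations |>
    dplyr::distinct(.data$comparator, .data$timing) |>
    purrr::pmap(function(comparator, timing) {
      purrr::map(defs, function(pr) {
        r <- dplyr::filter(correlations, .data$comparator == !!comparator,
                           .data$timing == !!timing, .data$stratum %in% pr)
        r <- r[match(pr, r$stratum), ]
        if (any(is.na(r$rho)) || any(r$n <= 3)) {
          return(tibble::tibble(comparator = comparator, timing = timing,
                                label1 = pr[[1]], label2 = pr[[2]],
                                z = NA_real_, p_one_sided = NA_real_,
                                p_two_sided = NA_real_))
        }
        fisher_z_compare(r$rho[[1]], r$n[[1]], r$rho[[2]], r$n[[2]], labels = pr) |>
          dplyr::mutate(comparator = comparator, timing = timing, .before = 1) |>
          dplyr::select("comparator", "timing", "label1", "label2",
                        "z", "p_one_sided", "p_two_sided")
      }) |>
        purrr::list_rbind()
    }) |>
    purrr::list_rbind()
}

empty_agreement_row <- function(formula, timing, n = NA_integer_) {
  tibble::tibble(
    formula = formula, timing = timing, n = as.integer(n),
    rho = NA_real_, rho_p = NA_real_, mean_bias = NA_real_,
    sd_diff = NA_real_, loa_lower = NA_real_, loa_upper = NA_real_,
    bias_p = NA_real_, p30 = NA_real_
  )
}

empty_classification_rows <- function(formula, timing, thresholds, n = NA_integer_) {
  tibble::tibble(
    formula = formula, timing = timing,
    threshold = thresholds, n = as.integer(n),
    tp = NA_integer_, fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
    sensitivity = NA_real_, specificity = NA_real_,
    ppv = NA_real_, npv = NA_real_
  )
}

#' @export
print.natriuria_report <- function(x, ...) {
  cat("Spot-urine sodium validation report\n")
  cat(sprintf("  participants analysed: %d of %d (%d excluded by collection screen)\n",
              x$meta$n_analyzed, x$meta$n_input, x$meta$n_rejected))
  cat("\nAgreement (measured - estimated, mg/d):\n")
  print(x$agreement, n = Inf)
  cat("\nClassification at", paste(x$meta$thresholds, collapse = ", "), "g/d sodium:\n")
  print(x$classification, n = Inf)
  invisible(x)
}

#' @rdname run_analysis
#' @param x,object A `natriuria_report`.
#' @param ... Unused.
#' @method tidy natriuria_report
#' @export
tidy.natriuria_report <- function(x, ...) x$agreement

#' @rdname run_analysis
#' @method glance natriuria_report
#' @export
glance.natriuria_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$meta$n_input,
    n_analyzed = x$meta$n_analyzed,
    n_rejected = x$meta$n_rejected,
    n_formulas = length(x$meta$formulas),
    best_formula = x$agreement$formula[[which.min(abs(x$agreement$mean_bias))]],
    min_abs_bias = min(abs(x$agreement$mean_bias), na.rm = TRUE)
  )
}

#' @rdname run_analysis
#' @method autoplot natriuria_report
#' @export
autoplot.natriuria_report <- function(object, ...) {
  plot_data <- purrr::imap(object$bland_altman, function(ba, nm) {
    dplyr::mutate(ba$data, cell = nm)
  }) |>
    purrr::list_rbind()
  lines <- dplyr::mutate(object$agreement, cell = paste(formula, timing, sep = "_")) |>
    dplyr::filter(!is.na(.data$mean_bias))
  ggplot2::ggplot(plot_data, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = mean_bias),
                        colour = "orange") +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = loa_lower),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::geom_hline(data = lines, ggplot2::aes(yintercept = loa_upper),
                        colour = "steelblue", linetype = "dashed") +
    ggplot2::facet_wrap(~cell, scales = "free") +
    ggplot2::labs(x = "Mean of measured and estimated (mg/d)",
                  y = "Measured - estimated (mg/d)") +
    ggplot2::theme_minimal()
}

#' Write an analysis report to disk
#'
#' Serialises a [run_analysis()] report as `report.json` plus TSV tables
#' (`tables/*.tsv`) and per-cell Bland-Altman plot data
#' (`blandaltman/<formula>_<timing>.csv`, columns `mean`, `difference`,
#' `mean_bias`, `loa_lower`, `loa_upper`). Output is deterministic: the
#' same report writes byte-identical files.
#'
#' @param report A `natriuria_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "natriuria_report"))
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "blandaltman"), recursive = TRUE, showWarnings = FALSE)

  writeLines(report_json(report), file.path(dir, "report.json"))
  for (nm in c("correlations", "timing_comparisons", "strata_comparisons",
               "agreement", "classification")) {
    readr::write_tsv(report[[nm]], file.path(dir, "tables", paste0(nm, ".tsv")),
                     progress = FALSE)
  }
  purrr::iwalk(report$bland_altman, function(ba, nm) {
    ba$data |>
      dplyr::mutate(mean_bias = ba$mean_bias, loa_lower = ba$loa_lower,
                    loa_upper = ba$loa_upper) |>
      readr::write_csv(file.path(dir, "blandaltman", paste0(nm, ".csv")),
                       progress = FALSE)
  })
  invisible(dir)
}

#' @rdname write_report
#' @return `report_json()`: the report serialised as a JSON string.
#' @export
report_json <- function(report) {
  jsonlite::toJSON(
    list(
      meta = report$meta,
      correlations = report$correlations,
      timing_comparisons = report$timing_comparisons,
      strata_comparisons = report$strata_comparisons,
      agreement = report$agreement,
      classification = report$classification
    ),
    dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE,
    na = "null"
  ) |>
    as.character()
}
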