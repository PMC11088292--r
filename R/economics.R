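# Incremental cost-effectiveness against standard care: pairwise ICERs
# with dominance handling and WTP verdicts, and the full country x sex x
# comparator grid with its run manifest.

#' Incremental cost-effectiveness comparison
#'
#' Compares a strategy's accruals against a baseline (standard care) on
#' discounted values: incremental cost, life-years and QALYs, cost per
#' life-year gained (C/LYG) and per QALY gained (C/QALYG), and the verdict
#' against a willingness-to-pay threshold. Ratios are computed from
#' unrounded increments and only when the effect increment is positive;
#' otherwise a dominance label is set instead of a signed ratio:
#' `"dominant"` (cheaper or equal cost, more effective), `"dominated"`
#' (costlier, no more effective), `"equivalent"` (identical cost and
#' effect).
#'
#' @param base `lb_accruals` of the baseline strategy.
#' @param comp `lb_accruals` of the comparator strategy.
#' @param wtp Willingness-to-pay threshold, EUR per QALY gained.
#' @return An object of class `lb_ce`: list with `baseline`, `comparator`,
#'   `incr_cost`, `incr_ly`, `incr_qaly`, `icer_clyg`, `icer_cqalyg`
#'   (numeric or `NA` when a dominance label applies), `dominance`
#'   (`"icer"`, `"dominant"`, `"dominated"` or `"equivalent"`) and
#'   `wtp_verdict` (`"below"`, `"above"` or `NA` without a ratio).
#' @export
compute_icer <- function(base, comp, wtp = 23500) {
  dc <- comp$discounted$total_cost - base$discounted$total_cost
  dl <- comp$discounted$life_years - base$discounted$life_years
  dq <- comp$discounted$qalys - base$discounted$qalys
  dominance <-
    if (dq == 0 && dc == 0) "equivalent"
    else if (dq > 0 && dc <= 0) "dominant"
    else if (dq <= 0 && dc > 0) "dominated"
    else if (dq > 0) "icer"
    else "dominated"  # less effective and cheaper-or-equal: not adopted
  icer_q <- if (dominance == "icer") dc / dq else NA_real_
  icer_l <- if (dominance == "icer" && dl > 0) dc / dl else NA_real_
  structure(
    list(baseline = base$label, comparator = comp$label,
         incr_cost = dc, incr_ly = dl, incr_qaly = dq,
         icer_clyg = icer_l, icer_cqalyg = icer_q,
         dominance = dominance,
         wtp = wtp,
         wtp_verdict = if (is.na(icer_q)) NA_character_
                       else if (icer_q <= wtp) "below" else "above"),
    class = "lb_ce"
  )
}

#' @export
print.lb_ce <- function(x, ...) {
  cat(sprintf("<CE> %s vs %s: dCost %.2f, dQALY %.4f", x$comparator,
              x$baseline, x$incr_cost, x$incr_qaly))
  if (x$dominance == "icer")
    cat(sprintf(", C/QALYG %.2f (%s WTP %.0f)", x$icer_cqalyg,
                x$wtp_verdict, x$wtp))
  else cat(", ", x$dominance)
  cat("\n")
  invisible(x)
}

#' Run the full comparator grid
#'
#' Evaluates every comparator in every country x sex cell with the cohort
#' engine and compares each non-baseline strategy pairwise against standard
#' care, mirroring the published results-table schema. The zero-effect
#' validation strategy is run in every cell (its comparisons must show
#' equivalent effects at strictly higher cost) but is flagged separately in
#' the manifest, which records both the 42 main runs (7 comparators x 6
#' cells) and the 6 validation runs.
#'
#' @param life_tables Named list of `lb_life_table`s with names like
#'   `"ESP_male"`, or a function `(country, sex) -> lb_life_table`.
#' @param comparators Named list of `lb_comparator`s including one named
#'   `standard_care`; default [default_comparators()].
#' @param config_fun Function `(country, sex) -> lb_config` defining the
#'   per-cell configuration; default [calibrated_study_config()].
#' @param countries,sexes Cells to run.
#' @return An object of class `lb_grid`: list with `results` (data frame in
#'   the published table's column layout: strategy, cost, incremental cost,
#'   effectiveness in life-years, incremental life-years, C/LYG, QALYs,
#'   incremental QALYs, C/QALYG), `comparisons` (list of `lb_ce`),
#'   `accruals`, and `manifest`.
#' @export
run_comparator_grid <- function(life_tables,
                                comparators = default_comparators(),
                                config_fun = calibrated_study_config,
                                countries = c("ESP", "FRA", "GER"),
                                sexes = c("male", "female")) {
  get_table <- if (is.function(life_tables)) {
    life_tables
  } else {
    function(country, sex) {
      nm <- paste(country, sex, sep = "_")
      tb <- life_tables[[nm]]
      if (is.null(tb))
        stop("no life table for cell ", country, "/", sex, call. = FALSE)
      tb
    }
  }
  if (!"standard_care" %in% names(comparators))
    stop("comparator set must contain 'standard_care'", call. = FALSE)

  rows <- list(); comparisons <- list(); accruals <- list()
  n_main <- 0L; n_validation <- 0L
  for (sex in sexes) for (country in countries) {
    cfg <- config_fun(country, sex)
    tb <- get_table(country, sex)
    params <- default_parameters(country, sex)
    cell_acc <- lapply(comparators, function(cm) {
      tr <- run_cohort(cfg, tb, params, cm)
      summarize_outcomes(tr, params)
    })
    base <- cell_acc$standard_care
    for (nm in names(comparators)) {
      acc <- cell_acc[[nm]]
      is_validation <- grepl("^validation", nm)
      if (is_validation) n_validation <- n_validation + 1L
      else n_main <- n_main + 1L
      ce <- if (nm == "standard_care") NULL
            else compute_icer(base, acc, cfg$wtp_threshold)
      key <- paste(country, sex, nm, sep = "_")
      accruals[[key]] <- acc
      if (!is.null(ce)) comparisons[[key]] <- ce
      rows[[key]] <- data.frame(
        country = country, sex = sex, comparator = nm,
        strategy = comparators[[nm]]$name,
        cost = acc$discounted$total_cost,
        incr_cost = if (is.null(ce)) NA_real_ else ce$incr_cost,
        eff_life_years = acc$discounted$life_years,
        incr_lyrs = if (is.null(ce)) NA_real_ else ce$incr_ly,
        icer_clyg = if (is.null(ce)) NA_real_ else ce$icer_clyg,
        qaly = acc$discounted$qalys,
        incr_qaly = if (is.null(ce)) NA_real_ else ce$incr_qaly,
        icer_cqalyg = if (is.null(ce)) NA_real_ else ce$icer_cqalyg,
        dominance = if (is.null(ce)) NA_character_ else ce$dominance,
        stringsAsFactors = FALSE
      )
    }
  }
  results <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  manifest <- list(
    cells = length(countries) * length(sexes),
    comparators = names(comparators),
    n_main_runs = n_main,
    n_validation_runs = n_validation,
    n_total_runs = n_main + n_validation,
    n_comparisons = length(comparisons),
    engine = "cohort"
  )
  structure(list(results = results, comparisons = comparisons,
                 accruals = accruals, manifest = manifest),
            class = "lb_grid")
}

#' @export
print.lb_grid <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<grid> %d runs (%d main + %d validation), %d comparisons\n",
              m$n_total_runs, m$n_main_runs, m$n_validation_runs,
              m$n_comparisons))
  invisible(x)
}

#' Format a grid's results in the published table style
#'
#' Renders the numeric results with thousands separators and two decimals
#' (reporting layer only; all internal arithmetic is full precision).
#'
#' @param grid An `lb_grid`.
#' @return Data frame of formatted strings.
#' @export
format_grid_results <- function(grid) {
  r <- grid$results
  eur <- function(x) ifelse(is.na(x), "",
                            paste0(formatC(x, format = "f", digits = 2,
                                           big.mark = ","), " €"))
  num <- function(x) ifelse(is.na(x), "",
                            formatC(x, format = "f", digits = 2))
  data.frame(
    Strategy = paste(r$sex, r$country, r$strategy, sep = " - "),
    Cost = eur(r$cost), `Incr Cost` = eur(r$incr_cost),
    `Eff Life-years` = num(r$eff_life_years), `Incr LYrs` = num(r$incr_lyrs),
    `ICER (C/LYG)` = eur(r$icer_clyg), QALY = num(r$qaly),
    `Incr QALY` = num(r$incr_qaly), `ICER (C/QALYG)` = eur(r$icer_cqalyg),
    check.names = FALSE, stringsAsFactors = FALSE
  )
}
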