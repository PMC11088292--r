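# Model parameters: stage-specific utilities, transition probabilities and
# three-tier direct treatment costs (reference year 2019, EUR), plus the
# comparator definitions (effect multipliers and liquid-biopsy usage).
#
# All defaults are stored exactly as printed in the source cost and
# parameter tables (cent precision); nothing is re-derived from the
# underlying cost literature.

# per-country stage cost tables, EUR 2019; rows ordered I, II, III, IV
.COSTS <- list(
  ESP = list(
    initial  = c(16795.80, 20043.33, 21451.55, 2161.49),
    followup = c(2308.54, 2041.31, 1478.37, 1478.37),
    advanced = c(6980.60, 25357.05, 40802.11, 40283.29)
  ),
  FRA = list(
    initial  = c(13584.48, 17488.52, 24553.72, 29300.69),
    followup = c(601.91, 601.91, 845.07, 1008.46),
    advanced = c(17488.52, 24553.72, 29300.69, 29300.69)
  ),
  GER = list(
    initial  = c(3819.31, 3819.31, 37552.13, 101655.77),
    followup = c(3084.29, 3084.29, 3084.29, 3084.29),
    advanced = c(80890.87, 80890.87, 80892.14, 80690.72)
  )
)

.UTILITIES <- c(0.74, 0.74, 0.67, 0.25)
# annual probability of NOT having a recurrence after therapy (annualized
# from 3-year cumulative incidences); stage IV is persistent
.STAY_PROB <- c(0.983, 0.944, 0.887, NA_real_)
# alternative parameterization: directly tabulated probability of recurrence
.ALT_RECURRENCE <- c(0.010, 0.025, 0.077, NA_real_)
.CRC_DEATH <- c(0.015, 0.039, 0.078, 0.330)

.LB_TEST_COST <- 441.45
# annual rates used to bring historical cost data to the 2019 reference year
.INFLATION <- c(ESP = 0.04, FRA = 0.04, GER = 0.03)

.COUNTRIES <- c("ESP", "FRA", "GER")
.SEXES <- c("male", "female")

#' Default stage-level model parameters for one country
#'
#' Returns the bundled stage-specific parameter set: utility weights,
#' annual recurrence and CRC-specific death probabilities, and the
#' three-tier direct treatment costs (initial first-year, annual follow-up,
#' advanced last-year; EUR, reference year 2019) for Spain (`ESP`),
#' France (`FRA`) or Germany (`GER`). Stage I/II values are bundled for
#' transparency; the reference analysis starts cohorts in stage III.
#'
#' @param country One of `"ESP"`, `"FRA"`, `"GER"`.
#' @param sex One of `"male"`, `"female"`. Stage parameters do not differ by
#'   sex (only general mortality does); the field is carried for bookkeeping.
#' @return An object of class `lb_params`: a list with elements `country`,
#'   `sex`, `stages` (data frame, one row per stage with columns `stage`,
#'   `utility`, `stay_prob`, `alt_recurrence_prob`, `crc_death_prob`,
#'   `cost_initial`, `cost_followup`, `cost_advanced`), `lb_test_cost`
#'   (EUR per NGS-LB test) and `inflation_rate` (annual cost-adjustment
#'   rate used for historical data).
#' @export
#' @examples
#' p <- default_parameters("GER", "male")
#' p$stages[p$stages$stage == "III", "cost_initial"]  # 37552.13
default_parameters <- function(country = c("ESP", "FRA", "GER"),
                               sex = c("male", "female")) {
  country <- match.arg(country)
  sex <- match.arg(sex)
  cc <- .COSTS[[country]]
  stages <- data.frame(
    stage = .STAGES,
    utility = .UTILITIES,
    stay_prob = .STAY_PROB,
    alt_recurrence_prob = .ALT_RECURRENCE,
    crc_death_prob = .CRC_DEATH,
    cost_initial = cc$initial,
    cost_followup = cc$followup,
    cost_advanced = cc$advanced,
    stringsAsFactors = FALSE
  )
  out <- structure(
    list(country = country, sex = sex, stages = stages,
         lb_test_cost = .LB_TEST_COST,
         inflation_rate = unname(.INFLATION[country])),
    class = "lb_params"
  )
  validate_parameters(out)
  out
}

#' Validate a stage-parameter bundle
#'
#' Checks the structural invariants of an `lb_params` object: probabilities
#' and utilities in \[0, 1\], non-negative costs, non-increasing utilities
#' from stage II through IV, and undefined recurrence for the persistent
#' stage IV.
#'
#' @param params An `lb_params` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_parameters <- function(params) {
  s <- params$stages
  chk01 <- function(x, nm) {
    bad <- !is.na(x) & (x < 0 | x > 1)
    if (any(bad))
      stop(sprintf("%s outside [0, 1]: %s", nm,
                   paste(x[bad], collapse = ", ")), call. = FALSE)
  }
  chk01(s$utility, "utility")
  chk01(s$stay_prob, "stay_prob")
  chk01(s$alt_recurrence_prob, "alt_recurrence_prob")
  chk01(s$crc_death_prob, "crc_death_prob")
  costs <- unlist(s[, c("cost_initial", "cost_followup", "cost_advanced")])
  if (any(costs < 0)) stop("costs must be >= 0", call. = FALSE)
  if (params$lb_test_cost < 0) stop("lb_test_cost must be >= 0", call. = FALSE)
  u <- s$utility
  if (!(u[4] <= u[3] && u[3] <= u[2]))
    stop("utilities must satisfy utility(IV) <= utility(III) <= utility(II)",
         call. = FALSE)
  if (!is.na(s$stay_prob[4]) || !is.na(s$alt_recurrence_prob[4]))
    stop("stage IV is persistent; its recurrence probabilities must be NA",
         call. = FALSE)
  invisible(params)
}

#' Comparator specification
#'
#' A comparator is a surveillance strategy defined by two effect multipliers
#' and a liquid-biopsy usage flag. The mortality multiplier scales the
#' CRC-specific death probability in every occupied stage I-IV; the
#' progression multiplier scales the recurrence (stage-progression)
#' probability. A multiplier of 1 means no effect; 0.99 and 0.97 encode the
#' assumed 1% and 3% improvements from NGS-LB surveillance. Standard care
#' has both multipliers at 1 and no liquid biopsy; the zero-effect
#' validation comparator has both multipliers at 1 *with* liquid biopsy
#' (identical medical outcomes, higher cost).
#'
#' @param name Strategy label.
#' @param mort_multiplier Factor applied to CRC-specific death probabilities.
#' @param prog_multiplier Factor applied to recurrence probabilities.
#' @param lb_enabled Logical; whether NGS-LB tests are performed (and paid).
#' @param lb_test_cost EUR per NGS-LB test (2019 reimbursement lump sum).
#' @return An object of class `lb_comparator`.
#' @export
#' @examples
#' comparator_spec("MortSuccess 3% + TxSuccess 3%", 0.97, 0.97, TRUE)
comparator_spec <- function(name, mort_multiplier = 1, prog_multiplier = 1,
                            lb_enabled = FALSE, lb_test_cost = .LB_TEST_COST) {
  stopifnot(mort_multiplier > 0, mort_multiplier <= 1,
            prog_multiplier > 0, prog_multiplier <= 1,
            lb_test_cost >= 0)
  structure(
    list(name = name, mort_multiplier = mort_multiplier,
         prog_multiplier = prog_multiplier, lb_enabled = lb_enabled,
         lb_test_cost = lb_test_cost),
    class = "lb_comparator"
  )
}

#' The study's comparator set
#'
#' Seven main comparators - standard care plus six NGS-LB strategies with
#' assumed survival improvements (MortSuccess) of 0/1/3% and stage
#' progression reductions (TxSuccess) of 0/1/3%, alone or combined - and
#' the zero-effect validation strategy (liquid biopsy with no medical
#' effect) used for internal model validation.
#'
#' @param lb_test_cost EUR per NGS-LB test used by all LB-enabled strategies.
#' @param include_validation Logical; include the zero-effect validation arm.
#' @return Named list of `lb_comparator` objects; the first element is
#'   always standard care.
#' @export
default_comparators <- function(lb_test_cost = .LB_TEST_COST,
                                include_validation = TRUE) {
  eff <- function(pct) 1 - pct / 100
  cmp <- list(
    standard_care = comparator_spec("standard care", 1, 1, FALSE),
    mort0_tx1 = comparator_spec("MortSuccess 0% - TxSuccess 1%",
                                eff(0), eff(1), TRUE, lb_test_cost),
    mort0_tx3 = comparator_spec("MortSuccess 0% - TxSuccess 3%",
                                eff(0), eff(3), TRUE, lb_test_cost),
    mort1_tx0 = comparator_spec("MortSuccess 1% - TxSuccess 0%",
                                eff(1), eff(0), TRUE, lb_test_cost),
    mort3_tx0 = comparator_spec("MortSuccess 3% - TxSuccess 0%",
                                eff(3), eff(0), TRUE, lb_test_cost),
    mort1_tx1 = comparator_spec("MortSuccess 1% - TxSuccess 1%",
                                eff(1), eff(1), TRUE, lb_test_cost),
    mort3_tx3 = comparator_spec("MortSuccess 3% - TxSuccess 3%",
                                eff(3), eff(3), TRUE, lb_test_cost)
  )
  if (include_validation)
    cmp$validation <- comparator_spec("validation (zero-effect LB)",
                                      1, 1, TRUE, lb_test_cost)
  cmp
}

#' Adjust a historical cost to a reference year
#'
#' Compounds an amount forward at a constant annual adjustment rate:
#' `amount * (1 + rate)^(to_year - from_year)`. The bundled cost tables use
#' 4% per year for Spain and France and 3% for Germany to express
#' historical cost data in 2019 euros.
#'
#' @param amount Cost in the currency of `from_year`.
#' @param from_year,to_year Calendar years; `to_year >= from_year`.
#' @param annual_rate Annual adjustment rate (e.g. 0.04), `>= 0`.
#' @return Adjusted amount.
#' @export
#' @examples
#' inflate_cost(100, 2017, 2019, 0.03)  # 106.09
inflate_cost <- function(amount, from_year, to_year, annual_rate) {
  if (to_year < from_year)
    stop("to_year must be >= from_year (no deflation)", call. = FALSE)
  if (annual_rate < 0) stop("annual_rate must be >= 0", call. = FALSE)
  amount * (1 + annual_rate)^(to_year - from_year)
}
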