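# Accrual of discounted costs, life-years and QALYs over a cohort trace.
#
# Reward timing conventions (tested in test-accounting.R):
#  * Cycle k covers the year [start_age + k, start_age + k + 1); rewards of
#    cycle k are discounted with (1 + r)^-k, so cycle 0 is undiscounted.
#  * Effects accrue on the cycle-start occupancy (a patient alive at the
#    start of a cycle is credited with that cycle); the optional half-cycle
#    correction replaces this by the trapezoid of consecutive occupancies.
#  * A stage-transition cycle charges the destination stage's initial cost
#    and no follow-up cost that cycle.
#  * Patients dying of CRC during a cycle receive the advanced (last-year)
#    cost for that cycle instead of the initial/follow-up cost; deaths from
#    general mortality receive the ordinary cycle cost unless
#    advanced_cost_on_general_death is set. Death is independent of how long
#    a patient has occupied the stage, so the dying fraction is split
#    proportionally between entrants and continuing occupants.
#  * One NGS-LB test at most per patient and cycle, charged to everyone
#    alive at cycle start in a tested stage (deaths during the cycle were
#    alive when the annual test was taken).

#' Discount factor for an annual cycle
#'
#' `(1 + rate)^-cycle`; cycle 0 is undiscounted, and a zero rate means no
#' discounting at any cycle.
#'
#' @param cycle Non-negative integer cycle index (vectorized).
#' @param rate Annual discount rate, `>= 0`.
#' @return Discount factor(s) in (0, 1\].
#' @export
#' @examples
#' discount_factor(1, 0.03)  # 0.9709...
discount_factor <- function(cycle, rate) {
  if (any(cycle < 0)) stop("cycle must be >= 0", call. = FALSE)
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  (1 + rate)^(-cycle)
}

#' Accrue (discounted) life-years and QALYs over a trace
#'
#' Life-years sum the discounted alive fraction per cycle; QALYs weight
#' each living stage's occupancy by its utility. With
#' `half_cycle = TRUE` the per-cycle reward is the trapezoid
#' `(x(k) + x(k+1)) / 2` of consecutive cycle occupancies.
#'
#' @param trace An `lb_trace` from [run_cohort()].
#' @param utilities Numeric length-4 vector of stage utilities.
#' @param rate Annual discount rate for effects.
#' @param half_cycle Logical; trapezoid (half-cycle corrected) accrual.
#' @return List with `life_years` and `qalys`.
#' @export
accrue_effects <- function(trace, utilities, rate,
                           half_cycle = trace$config$half_cycle_correction) {
  occ <- trace$occupancy
  Tn <- trace$n_cycles
  if (Tn == 0) return(list(life_years = 0, qalys = 0))
  alive <- rowSums(occ[, .LIVING, drop = FALSE])
  quality <- as.numeric(occ[, .LIVING, drop = FALSE] %*% utilities)
  df <- discount_factor(0:(Tn - 1), rate)
  agg <- function(x) {
    per_cycle <- if (half_cycle) (x[1:Tn] + x[2:(Tn + 1)]) / 2 else x[1:Tn]
    sum(df * per_cycle)
  }
  list(life_years = agg(alive), qalys = agg(quality))
}

#' Accrue the three-tier treatment costs and liquid-biopsy test costs
#'
#' Applies, per cycle and stage: the initial (first-year) cost to new
#' entrants, the annual follow-up cost to continuing occupants, the
#' advanced (last-year) cost to patients dying of CRC that cycle (replacing
#' their initial/follow-up charge), and - for LB-enabled comparators - one
#' NGS-LB test per alive patient and cycle (start test, stage III to IV
#' switch test and annual follow-up tests; never more than one per cycle).
#' See the conventions at the top of the accounting source file.
#'
#' @param trace An `lb_trace`.
#' @param params An `lb_params`.
#' @param comparator An `lb_comparator` (defaults to the trace's own).
#' @param rate Annual discount rate for costs.
#' @param config An `lb_config` (cost-timing switches; defaults to the
#'   trace's own).
#' @return List with tiers `initial`, `followup`, `advanced`, `lb_tests`
#'   and their sum `total` (EUR).
#' @export
accrue_costs <- function(trace, params, comparator = trace$comparator,
                         rate, config = trace$config) {
  Tn <- trace$n_cycles
  tiers <- c(initial = 0, followup = 0, advanced = 0, lb_tests = 0)
  if (Tn == 0)
    return(as.list(c(tiers, total = 0)))
  st <- params$stages
  lb_on <- isTRUE(comparator$lb_enabled)
  for (k in 0:(Tn - 1)) {
    i <- k + 1L
    df <- discount_factor(k, rate)
    occ <- trace$occupancy[i, ]
    entr <- trace$entrants[i, ]
    dieC <- trace$crc_deaths[i, ]
    dieG <- trace$gen_deaths[i, ]
    for (s in .LIVING) {
      m <- occ[s]
      if (m <= 0) next
      adv_payers <- dieC[s] +
        if (config$advanced_cost_on_general_death) dieG[s] else 0
      surv_frac <- 1 - adv_payers / m
      e <- entr[s]
      if (k == 0 && !config$initial_cost_at_start) e <- 0
      tiers["advanced"] <- tiers["advanced"] +
        df * st$cost_advanced[s] * adv_payers
      tiers["initial"] <- tiers["initial"] +
        df * st$cost_initial[s] * e * surv_frac
      tiers["followup"] <- tiers["followup"] +
        df * st$cost_followup[s] * (m - e) * surv_frac
    }
    if (lb_on) {
      tested <- sum(occ[1:3]) +
        if (config$lb_followup_in_stage_iv) occ[4] else entr[4]
      tiers["lb_tests"] <- tiers["lb_tests"] +
        df * comparator$lb_test_cost * tested
    }
  }
  out <- as.list(tiers)
  out$total <- sum(tiers)
  out
}

#' Summarize a cohort trace into outcome accruals
#'
#' Composes effect and cost accruals at the configured discount rates and
#' undiscounted, as an `lb_accruals` object.
#'
#' @param trace An `lb_trace`.
#' @param params An `lb_params`.
#' @param comparator,config Defaults taken from the trace.
#' @return An `lb_accruals` object: list with elements `discounted` and
#'   `undiscounted`, each holding `total_cost`, `life_years`, `qalys` and
#'   the cost `breakdown`; plus the strategy `label` and the rates.
#' @export
summarize_outcomes <- function(trace, params,
                               comparator = trace$comparator,
                               config = trace$config) {
  u <- params$stages$utility
  at <- function(rc, re) {
    eff <- accrue_effects(trace, u, re)
    cost <- accrue_costs(trace, params, comparator, rc, config)
    list(total_cost = cost$total, life_years = eff$life_years,
         qalys = eff$qalys,
         breakdown = cost[c("initial", "followup", "advanced", "lb_tests")])
  }
  structure(
    list(discounted = at(config$discount_rate_costs,
                         config$discount_rate_effects),
         undiscounted = at(0, 0),
         label = comparator$name,
         discount_rate_costs = config$discount_rate_costs,
         discount_rate_effects = config$discount_rate_effects),
    class = "lb_accruals"
  )
}

#' @export
print.lb_accruals <- function(x, ...) {
  d <- x$discounted
  cat(sprintf(
    "<accruals> %s: cost %.2f EUR, LE %.4f y, QALY %.4f (discounted)\n",
    x$label, d$total_cost, d$life_years, d$qalys))
  invisible(x)
}
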