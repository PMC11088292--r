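# Markov cohort engine: age-dependent six-state transition matrices and the
# deterministic cohort trace, plus survival summaries.

#' Annualize a multi-year cumulative incidence
#'
#' Converts a 3-year cumulative recurrence incidence to an annual
#' transition probability under a constant hazard:
#' `1 - (1 - cum)^(1/3)`.
#'
#' @param cum_incidence_3yr Cumulative 3-year incidence in \[0, 1).
#' @return Annual probability.
#' @export
#' @examples
#' annualize_recurrence(0.30)  # ~0.112, consistent with a 0.887 annual
#'                             # stay probability for stage III
annualize_recurrence <- function(cum_incidence_3yr) {
  if (any(cum_incidence_3yr < 0 | cum_incidence_3yr >= 1))
    stop("cumulative incidence must lie in [0, 1)", call. = FALSE)
  1 - (1 - cum_incidence_3yr)^(1 / 3)
}

# annual recurrence probabilities for stages I-IV under the configured
# parameterization (IV persistent -> 0)
.recurrence_probs <- function(params, config) {
  s <- params$stages
  p <- switch(config$recurrence_source,
              three_year_derived = 1 - s$stay_prob,
              alt_table_row = s$alt_recurrence_prob)
  p[4] <- 0
  p
}

#' Build the one-cycle transition matrix at a given age
#'
#' Constructs the 6x6 row-stochastic matrix over the states
#' `stage_I..stage_IV`, `death_general`, `death_crc` for one annual cycle.
#' For a living stage `s` with general-mortality probability `q` from the
#' life table, CRC-death probability `d = mort_multiplier * p_crcdeath(s)`
#' and progression probability `p = prog_multiplier * p_rec(s)` (0 for the
#' persistent stage IV), the default sequential competing-risk composition
#' is
#' \deqn{P(general) = q,\quad P(CRC) = (1-q)d,\quad
#'       P(next) = (1-q)(1-d)p,\quad P(stay) = (1-q)(1-d)(1-p),}
#' each risk conditional on escaping the previous one. This keeps every row
#' a valid distribution at all ages (including `q` near 1) and reduces to
#' the marginal probabilities when the competing risks vanish. The
#' `"additive"` composition uses the marginal probabilities directly and
#' rescales the exits proportionally if they exceed 1.
#'
#' @param age Age (years) at the start of the cycle.
#' @param table An `lb_life_table` for general mortality.
#' @param params An `lb_params` parameter bundle.
#' @param comparator An `lb_comparator`.
#' @param config An `lb_config` (recurrence source, composition).
#' @return 6x6 numeric matrix with state dimnames; rows sum to 1.
#' @export
build_transition_matrix <- function(age, table, params, comparator, config) {
  q <- death_prob(table, age)
  d <- pmin(1, comparator$mort_multiplier * params$stages$crc_death_prob)
  p <- pmin(1, comparator$prog_multiplier * .recurrence_probs(params, config))
  P <- matrix(0, 6, 6, dimnames = list(.STATES, .STATES))
  for (s in .LIVING) {
    if (config$composition == "sequential") {
      P[s, .GEN] <- q
      P[s, .CRC] <- (1 - q) * d[s]
      prog <- (1 - q) * (1 - d[s]) * p[s]
      stay <- (1 - q) * (1 - d[s]) * (1 - p[s])
    } else {
      exits <- q + d[s] + p[s]
      scale <- if (exits > 1) 1 / exits else 1
      P[s, .GEN] <- q * scale
      P[s, .CRC] <- d[s] * scale
      prog <- p[s] * scale
      stay <- 1 - (q + d[s] + p[s]) * scale
    }
    if (s < 4L) P[s, s + 1L] <- prog else stay <- stay + prog
    P[s, s] <- P[s, s] + stay
  }
  P[.GEN, .GEN] <- 1
  P[.CRC, .CRC] <- 1
  bad <- abs(rowSums(P) - 1) > 1e-12
  if (any(bad))
    stop("transition rows do not sum to 1: ",
         paste(.STATES[bad], collapse = ", "), call. = FALSE)
  P
}

#' Run the deterministic cohort trace
#'
#' Evolves the full occupancy distribution from the unit vector on the
#' start stage through `max_cycles` annual transitions with age-updated
#' matrices, stopping early once the living occupancy falls below
#' `occupancy_epsilon`. Besides occupancy the trace records, per cycle,
#' the fractions newly entering each stage and the cause- and
#' stage-specific death fractions, which the cost accrual needs to apply
#' the initial/follow-up/advanced tiers.
#'
#' @param config An `lb_config`.
#' @param table An `lb_life_table` matching the config's country/sex cell.
#' @param params An `lb_params`.
#' @param comparator An `lb_comparator`.
#' @return An object of class `lb_trace`: list with `occupancy`
#'   (`(T+1) x 6` matrix, row `t+1` = occupancy at the start of cycle `t`),
#'   `entrants` (`(T+1) x 4`, fraction newly arrived in each stage at each
#'   cycle start; cycle 0 holds the start cohort), `crc_deaths` and
#'   `gen_deaths` (`T x 4`, deaths *during* each cycle by stage of origin),
#'   `n_cycles`, and the inputs.
#' @export
run_cohort <- function(config, table, params, comparator) {
  Tmax <- config$max_cycles
  occ <- matrix(0, Tmax + 1L, 6L, dimnames = list(NULL, .STATES))
  entr <- matrix(0, Tmax + 1L, 4L, dimnames = list(NULL, .STATES[.LIVING]))
  crc_d <- matrix(0, Tmax, 4L, dimnames = list(NULL, .STATES[.LIVING]))
  gen_d <- matrix(0, Tmax, 4L, dimnames = list(NULL, .STATES[.LIVING]))
  s0 <- .stage_index(config$start_stage)
  occ[1L, s0] <- 1
  entr[1L, s0] <- 1
  t_used <- 0L
  for (t in seq_len(Tmax)) {
    cur <- occ[t, ]
    if (sum(cur[.LIVING]) < config$occupancy_epsilon) break
    P <- build_transition_matrix(config$start_age + t - 1L, table,
                                 params, comparator, config)
    nxt <- as.numeric(cur %*% P)
    if (abs(sum(nxt) - 1) > 1e-10)
      stop("mass conservation violated at cycle ", t, call. = FALSE)
    for (s in .LIVING) {
      crc_d[t, s] <- cur[s] * P[s, .CRC]
      gen_d[t, s] <- cur[s] * P[s, .GEN]
      if (s < 4L) entr[t + 1L, s + 1L] <- cur[s] * P[s, s + 1L]
    }
    occ[t + 1L, ] <- nxt
    t_used <- t
  }
  keep <- seq_len(t_used + 1L)
  structure(
    list(occupancy = occ[keep, , drop = FALSE],
         entrants = entr[keep, , drop = FALSE],
         crc_deaths = crc_d[seq_len(t_used), , drop = FALSE],
         gen_deaths = gen_d[seq_len(t_used), , drop = FALSE],
         n_cycles = t_used,
         config = config, comparator = comparator),
    class = "lb_trace"
  )
}

#' Survival curve and median survival of a cohort trace
#'
#' The alive fraction at each cycle is one minus the absorbing occupancy.
#' Median survival is the first cycle at which the alive fraction drops
#' below 0.5 (no within-cycle interpolation); if the cohort never does
#' within the horizon, `Inf` is returned (reported as beyond the horizon).
#'
#' @param trace An `lb_trace`.
#' @return `survival_curve()`: data frame with columns `cycle`, `age`,
#'   `alive`; `median_survival()`: years from simulation start (possibly
#'   `Inf`).
#' @export
survival_curve <- function(trace) {
  alive <- rowSums(trace$occupancy[, .LIVING, drop = FALSE])
  data.frame(cycle = seq_along(alive) - 1L,
             age = trace$config$start_age + seq_along(alive) - 1L,
             alive = alive)
}

#' @rdname survival_curve
#' @export
median_survival <- function(trace) {
  sc <- survival_curve(trace)
  i <- which(sc$alive < 0.5)
  if (!length(i)) return(Inf)
  sc$cycle[i[1]]
}
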