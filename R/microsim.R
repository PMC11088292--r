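# Patient-level Monte Carlo microsimulation: individual trajectories drawn
# from the same age-dependent transition matrices as the cohort engine,
# with per-individual accrual mirroring the cohort cost/effect timing.

#' Run the Monte Carlo microsimulation
#'
#' Simulates `n` independent patient trajectories under the same per-cycle
#' transition probabilities as [run_cohort()] and accrues discounted and
#' undiscounted life-years, QALYs and costs per individual with the same
#' timing rules as the cohort accrual. Results are reproducible for a fixed
#' seed. The cohort engine is the exact expectation of this process; the
#' two are cross-checked in the test suite via a three-standard-error
#' bound.
#'
#' @param config An `lb_config`.
#' @param table An `lb_life_table`.
#' @param params An `lb_params`.
#' @param comparator An `lb_comparator`.
#' @param n_individuals Number of simulated patients, `>= 1`.
#' @param seed Integer RNG seed (local to this call).
#' @return An object of class `lb_microsim`: list with `estimates`, a data
#'   frame with one row per outcome (`life_years`, `qalys`, `total_cost`,
#'   discounted and undiscounted) carrying `mean` and Monte Carlo standard
#'   error `se`; plus `n` and `seed`.
#' @export
run_microsim <- function(config, table, params, comparator,
                         n_individuals, seed) {
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  n <- as.integer(n_individuals)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  st <- params$stages
  u <- st$utility
  rc <- config$discount_rate_costs
  re <- config$discount_rate_effects
  lb_on <- isTRUE(comparator$lb_enabled)

  state <- rep(.stage_index(config$start_stage), n)
  entered <- rep(TRUE, n)   # entered current stage at this cycle start
  acc <- matrix(0, n, 6,
                dimnames = list(NULL,
                                c("le_d", "qaly_d", "cost_d",
                                  "le_u", "qaly_u", "cost_u")))
  for (k in 0:(config$max_cycles - 1L)) {
    alive <- state <= 4L
    if (!any(alive)) break
    P <- build_transition_matrix(config$start_age + k, table,
                                 params, comparator, config)
    dfc <- discount_factor(k, rc)
    dfe <- discount_factor(k, re)
    idx <- which(alive)
    s <- state[idx]
    # effects: credited to everyone alive at cycle start
    acc[idx, "le_d"] <- acc[idx, "le_d"] + dfe
    acc[idx, "le_u"] <- acc[idx, "le_u"] + 1
    acc[idx, "qaly_d"] <- acc[idx, "qaly_d"] + dfe * u[s]
    acc[idx, "qaly_u"] <- acc[idx, "qaly_u"] + u[s]
    # draw this cycle's transition
    r <- stats::runif(length(idx))
    nxt <- integer(length(idx))
    for (ss in sort(unique(s))) {
      sel <- s == ss
      cp <- cumsum(P[ss, ])
      nxt[sel] <- findInterval(r[sel], cp, left.open = TRUE) + 1L
    }
    # costs for cycle k
    dies_crc <- nxt == .CRC
    adv <- dies_crc |
      (config$advanced_cost_on_general_death & nxt == .GEN)
    ent <- entered
    if (k == 0 && !config$initial_cost_at_start) ent[] <- FALSE
    cyc_cost <- ifelse(adv, st$cost_advanced[s],
                       ifelse(ent[idx], st$cost_initial[s],
                              st$cost_followup[s]))
    if (lb_on) {
      tested <- s <= 3L | config$lb_followup_in_stage_iv |
        (s == 4L & entered[idx])
      cyc_cost <- cyc_cost + comparator$lb_test_cost * tested
    }
    acc[idx, "cost_d"] <- acc[idx, "cost_d"] + dfc * cyc_cost
    acc[idx, "cost_u"] <- acc[idx, "cost_u"] + cyc_cost
    entered[idx] <- nxt != s
    state[idx] <- nxt
  }
  est <- data.frame(
    outcome = c("life_years", "qalys", "total_cost"),
    discounted_mean = colMeans(acc[, c("le_d", "qaly_d", "cost_d"),
                                   drop = FALSE]),
    discounted_se = apply(acc[, c("le_d", "qaly_d", "cost_d"),
                              drop = FALSE], 2, stats::sd) / sqrt(n),
    undiscounted_mean = colMeans(acc[, c("le_u", "qaly_u", "cost_u"),
                                     drop = FALSE]),
    undiscounted_se = apply(acc[, c("le_u", "qaly_u", "cost_u"),
                                drop = FALSE], 2, stats::sd) / sqrt(n),
    row.names = NULL
  )
  structure(list(estimates = est, n = n, seed = as.integer(seed)),
            class = "lb_microsim")
}

#' @export
print.lb_microsim <- function(x, ...) {
  cat(sprintf("<microsim> n = %d, seed = %d\n", x$n, x$seed))
  print(x$estimates, digits = 5)
  invisible(x)
}
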