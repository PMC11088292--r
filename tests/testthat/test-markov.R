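# Transition-matrix construction, cohort evolution and survival summaries.

test_that("recurrence annualization follows the constant-hazard conversion", {
  expect_equal(annualize_recurrence(0), 0)
  expect_equal(annualize_recurrence(0.30), 1 - 0.7^(1 / 3))
  # round-trip: cubing the annual stay probability recovers the cumulative
  ann <- annualize_recurrence(0.056)
  expect_equal((1 - ann)^3, 1 - 0.056)
  expect_error(annualize_recurrence(1), "\\[0, 1\\)")
})

test_that("transition rows compose competing risks sequentially", {
  no_mort <- flat_life_table(0)
  cfg <- toy_config(recurrence_source = "three_year_derived")
  p <- default_parameters("GER", "female")
  cmp <- comparator_spec("std")
  P <- build_transition_matrix(60, no_mort, p, cmp, cfg)

  # persistent stage IV with no general mortality: stay 0.67, CRC death 0.33
  expect_equal(P["stage_IV", "stage_IV"], 0.67)
  expect_equal(P["stage_IV", "death_crc"], 0.33)

  # stage III row, hand-multiplied with q_gen = 0.01
  some_mort <- flat_life_table(0.01)
  P2 <- build_transition_matrix(60, some_mort, p, cmp, cfg)
  expect_equal(P2["stage_III", "death_general"], 0.01)
  expect_equal(P2["stage_III", "death_crc"], 0.99 * 0.078)
  expect_equal(P2["stage_III", "stage_IV"], 0.99 * (1 - 0.078) * 0.113)
  expect_equal(P2["stage_III", "stage_III"],
               1 - 0.01 - 0.99 * 0.078 - 0.99 * (1 - 0.078) * 0.113)

  # structural zeros: no regression, no stage jumps
  expect_equal(P2["stage_I", "stage_III"], 0)
  expect_equal(P2["stage_III", "stage_I"], 0)
  expect_equal(P2["stage_III", "stage_II"], 0)
  # absorbing rows are unit vectors
  expect_equal(unname(P2["death_general", ]), c(0, 0, 0, 0, 1, 0))
  expect_equal(unname(P2["death_crc", ]), c(0, 0, 0, 0, 0, 1))
})

test_that("rows are stochastic for randomized parameters, ages, multipliers", {
  set.seed(101)
  for (i in 1:50) {
    p <- toy_params(crc_death = runif(4),
                    stay = c(runif(3), NA),
                    alt_rec = c(runif(3), NA))
    cfg <- toy_config(recurrence_source =
                        sample(c("three_year_derived", "alt_table_row"), 1),
                      composition = sample(c("sequential", "additive"), 1))
    cmp <- comparator_spec("x", runif(1, 0.5, 1), runif(1, 0.5, 1), TRUE)
    lt <- flat_life_table(runif(1))
    P <- build_transition_matrix(sample(55:110, 1), lt, p, cmp, cfg)
    expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-12)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("cohort trace matches matrix-power oracle on a 3-cycle toy", {
  lt <- flat_life_table(0.02)
  cfg <- toy_config(max_cycles = 3, recurrence_source = "alt_table_row")
  p <- default_parameters("FRA", "male")
  cmp <- comparator_spec("lb", 0.97, 0.97, TRUE)
  tr <- run_cohort(cfg, lt, p, cmp)

  # independent oracle: explicit matrix powers (flat q so P is constant)
  P <- build_transition_matrix(60, lt, p, cmp, cfg)
  v0 <- c(0, 0, 1, 0, 0, 0)
  expect_equal(unname(tr$occupancy[1, ]), v0)
  expect_equal(unname(tr$occupancy[2, ]), as.numeric(v0 %*% P))
  expect_equal(unname(tr$occupancy[3, ]), as.numeric(v0 %*% P %*% P))
  expect_equal(unname(tr$occupancy[4, ]), as.numeric(v0 %*% P %*% P %*% P))

  # bookkeeping identities: entrants and deaths recompose the occupancy flow
  expect_equal(unname(tr$entrants[2, "stage_IV"]),
               unname(tr$occupancy[1, "stage_III"] * P["stage_III", "stage_IV"]))
  expect_equal(unname(tr$crc_deaths[1, "stage_III"]),
               unname(P["stage_III", "death_crc"]))
})

test_that("degenerate hazards drive the cohort to the expected absorptions", {
  # certain general death: everyone in death_general after one cycle
  lt <- flat_life_table(1)
  tr <- run_cohort(toy_config(), lt, default_parameters("ESP", "male"),
                   comparator_spec("std"))
  expect_equal(unname(tr$occupancy[2, "death_general"]), 1)
  expect_equal(tr$n_cycles, 1L)
  expect_equal(median_survival(tr), 1)

  # all-zero hazards from stage IV: occupancy parked there all 60 cycles
  # (table reaching past the horizon so no terminal absorption interferes)
  lt0 <- flat_life_table(0, 55, 125)
  p0 <- toy_params(crc_death = rep(0, 4))
  tr0 <- run_cohort(toy_config(start_stage = "IV"), lt0, p0,
                    comparator_spec("std"))
  expect_equal(tr0$n_cycles, 60L)
  expect_true(all(tr0$occupancy[, "stage_IV"] == 1))
  expect_equal(median_survival(tr0), Inf)
})

test_that("occupancy conserves mass and absorbing states grow monotonically", {
  set.seed(202)
  tabs <- synthetic_tables()
  for (i in 1:10) {
    p <- toy_params(crc_death = runif(4, 0, 0.5),
                    alt_rec = c(runif(3, 0, 0.3), NA))
    cfg <- calibrated_study_config(sample(c("ESP", "FRA", "GER"), 1),
                                   sample(c("male", "female"), 1))
    tb <- tabs[[paste(cfg$country, cfg$sex, sep = "_")]]
    tr <- run_cohort(cfg, tb, p, comparator_spec("x", 0.97, 0.97, TRUE))
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(1, nrow(tr$occupancy)), tolerance = 1e-10)
    expect_true(all(diff(tr$occupancy[, "death_general"]) >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "death_crc"]) >= -1e-15))
    alive <- survival_curve(tr)$alive
    expect_true(all(diff(alive) <= 1e-15))
  }
})

test_that("median survival reads the first cycle below one half", {
  # hand-built trace crossing 0.5 between cycles 4 and 5
  occ <- matrix(0, 6, 6, dimnames = list(NULL, health_states()))
  occ[, "stage_III"] <- c(1, 0.9, 0.7, 0.6, 0.55, 0.4)
  occ[, "death_crc"] <- 1 - occ[, "stage_III"]
  tr <- structure(list(occupancy = occ, n_cycles = 5L,
                       config = toy_config()), class = "lb_trace")
  expect_equal(median_survival(tr), 5)
})

test_that("microsimulation is seeded, degenerate-exact and matches cohort", {
  lt <- flat_life_table(0)
  p0 <- toy_params(crc_death = rep(0, 4))
  cfg <- toy_config(start_stage = "IV", max_cycles = 10,
                    discount_rate_effects = 0, discount_rate_costs = 0)
  ms <- run_microsim(cfg, lt, p0, comparator_spec("std"), 500, seed = 7)
  est <- ms$estimates
  # zero hazards: life expectancy equals the horizon with zero variance
  expect_equal(est$undiscounted_mean[est$outcome == "life_years"], 10)
  expect_equal(est$undiscounted_se[est$outcome == "life_years"], 0)

  ms2 <- run_microsim(cfg, lt, p0, comparator_spec("std"), 500, seed = 7)
  expect_identical(ms, ms2)
  # with live hazards, different seeds give different estimates
  lt2 <- flat_life_table(0.1)
  p <- default_parameters("ESP", "male")
  cfg2 <- toy_config(max_cycles = 10)
  msa <- run_microsim(cfg2, lt2, p, comparator_spec("std"), 500, seed = 7)
  msb <- run_microsim(cfg2, lt2, p, comparator_spec("std"), 500, seed = 8)
  expect_false(identical(msa$estimates, msb$estimates))
  expect_error(run_microsim(cfg, lt, p0, comparator_spec("std"), 0, 1),
               ">= 1")
})
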