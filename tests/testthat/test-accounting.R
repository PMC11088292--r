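# Discounting, effect accrual and the three-tier cost accrual.

test_that("discount factors follow the annual convention", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(0:10, 0), rep(1, 11))
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(5, 0.03), 1.03^-5)
  expect_error(discount_factor(-1, 0.03), ">= 0")
})

test_that("effect accrual weights occupancy by utility", {
  # two guaranteed undiscounted cycles in stage III (u = 0.67): QALY = 1.34
  lt <- flat_life_table(0)
  p <- toy_params(crc_death = rep(0, 4), alt_rec = c(0, 0, 0, NA))
  cfg <- toy_config(max_cycles = 2, recurrence_source = "alt_table_row")
  tr <- run_cohort(cfg, lt, p, comparator_spec("std"))
  eff <- accrue_effects(tr, p$stages$utility, rate = 0)
  expect_equal(eff$life_years, 2)
  expect_equal(eff$qalys, 2 * 0.67)

  # utilities of 1 make QALYs equal life-years on any trace
  tabs <- synthetic_tables()
  cfg2 <- calibrated_study_config("ESP", "female")
  p2 <- default_parameters("ESP", "female")
  tr2 <- run_cohort(cfg2, tabs$ESP_female, p2, comparator_spec("std"))
  eff2 <- accrue_effects(tr2, rep(1, 4), rate = 0.03)
  expect_equal(eff2$qalys, eff2$life_years)

  # a pure stage IV trace accrues QALYs at 0.25 per discounted alive-year
  tr4 <- run_cohort(calibrated_study_config("ESP", "female",
                                            start_stage = "IV"),
                    tabs$ESP_female, p2, comparator_spec("std"))
  e4 <- accrue_effects(tr4, p2$stages$utility, rate = 0.03)
  expect_equal(e4$qalys, 0.25 * e4$life_years)
})

test_that("undiscounted life-years equal the survival-curve area", {
  tabs <- synthetic_tables()
  p <- default_parameters("GER", "male")
  tr <- run_cohort(calibrated_study_config("GER", "male"), tabs$GER_male,
                   p, comparator_spec("std"))
  eff <- accrue_effects(tr, p$stages$utility, rate = 0)
  alive <- survival_curve(tr)$alive
  expect_equal(eff$life_years, sum(alive[seq_len(tr$n_cycles)]))
})

test_that("cost tiers attach to entrants, occupants and CRC deaths", {
  # whole cohort dies of CRC from stage III in cycle 0 (GER): only the
  # stage III advanced cost is charged, at full value
  lt <- flat_life_table(0)
  p <- toy_params("GER", crc_death = c(0, 0, 1, 0))
  cfg <- toy_config(recurrence_source = "alt_table_row")
  tr <- run_cohort(cfg, lt, p, comparator_spec("std"))
  cost <- accrue_costs(tr, p, rate = 0)
  expect_equal(cost$advanced, 80892.14)
  expect_equal(cost$initial, 0)
  expect_equal(cost$followup, 0)
  expect_equal(cost$lb_tests, 0)
  expect_equal(cost$total, 80892.14)

  # stage IV survivor for two undiscounted cycles (FRA): 2 x follow-up
  pf <- toy_params("FRA", crc_death = rep(0, 4))
  cfgf <- study_config("FRA", "female", start_stage = "IV", max_cycles = 2)
  trf <- run_cohort(cfgf, lt, pf, comparator_spec("std"))
  costf <- accrue_costs(trf, pf, rate = 0)
  expect_equal(costf$followup, 2 * 1008.46)
  expect_equal(costf$total, costf$followup)

  # initial_cost_at_start charges the start stage's first-year cost once
  cfgi <- study_config("FRA", "female", start_stage = "IV", max_cycles = 2,
                       initial_cost_at_start = TRUE)
  tri <- run_cohort(cfgi, lt, pf, comparator_spec("std"))
  costi <- accrue_costs(tri, pf, rate = 0)
  expect_equal(costi$initial, 29300.69)
  expect_equal(costi$followup, 1008.46)

  # a transition year charges the destination initial cost, not follow-up:
  # certain progression III -> IV in cycle 0, then certain CRC death
  pt <- toy_params("FRA", crc_death = c(0, 0, 0, 1),
                   alt_rec = c(0, 0, 1, NA))
  cfgt <- study_config("FRA", "female", max_cycles = 3,
                       recurrence_source = "alt_table_row")
  trt <- run_cohort(cfgt, lt, pt, comparator_spec("std"))
  costt <- accrue_costs(trt, pt, rate = 0)
  # cycle 0: stage III follow-up; cycle 1: stage IV advanced (dies of CRC,
  # replacing the initial charge of the transition year)
  expect_equal(costt$followup, 845.07)
  expect_equal(costt$advanced, 29300.69)
  expect_equal(costt$initial, 0)
})

test_that("liquid-biopsy tests charge once per alive patient-cycle", {
  lt <- flat_life_table(0)
  p <- toy_params("ESP", crc_death = rep(0, 4), alt_rec = c(0, 0, 0, NA))
  cfg <- toy_config(max_cycles = 4, recurrence_source = "alt_table_row")
  lb <- comparator_spec("lb", 1, 1, TRUE)
  tr <- run_cohort(cfg, lt, p, lb)
  cost <- accrue_costs(tr, p, rate = 0)
  expect_equal(cost$lb_tests, 4 * 441.45)

  # stage IV testing switch: only the III -> IV entry test remains
  pt <- toy_params("ESP", crc_death = rep(0, 4), alt_rec = c(0, 0, 1, NA))
  cfg_iv <- study_config("ESP", "male", max_cycles = 3,
                         recurrence_source = "alt_table_row",
                         lb_followup_in_stage_iv = FALSE)
  trt <- run_cohort(cfg_iv, lt, pt, lb)
  costt <- accrue_costs(trt, pt, rate = 0)
  # cycle 0 in III (tested) + entry test on reaching IV; no further IV tests
  expect_equal(costt$lb_tests, 2 * 441.45)
})

test_that("accrual summaries satisfy their structural invariants", {
  tabs <- synthetic_tables()
  cfg <- calibrated_study_config("GER", "female")
  p <- default_parameters("GER", "female")
  cmp <- default_comparators()
  for (nm in c("standard_care", "mort3_tx3", "validation")) {
    tr <- run_cohort(cfg, tabs$GER_female, p, cmp[[nm]])
    acc <- summarize_outcomes(tr, p)
    for (side in c("discounted", "undiscounted")) {
      a <- acc[[side]]
      expect_lte(a$qalys, a$life_years)
      expect_equal(sum(unlist(a$breakdown)), a$total_cost, tolerance = 1e-6)
    }
    expect_lte(acc$discounted$life_years, acc$undiscounted$life_years)
    expect_lte(acc$discounted$total_cost, acc$undiscounted$total_cost)
  }
})

test_that("cost accrual is monotone in liquid biopsy and in cost cells", {
  tabs <- synthetic_tables()
  cfg <- calibrated_study_config("FRA", "male")
  p <- default_parameters("FRA", "male")
  std <- summarize_outcomes(run_cohort(cfg, tabs$FRA_male, p,
                                       comparator_spec("std")), p)
  val <- summarize_outcomes(run_cohort(cfg, tabs$FRA_male, p,
                                       default_comparators()$validation), p)
  expect_gt(val$discounted$total_cost, std$discounted$total_cost)

  p_up <- p
  p_up$stages$cost_advanced[4] <- p$stages$cost_advanced[4] * 2
  up <- summarize_outcomes(run_cohort(cfg, tabs$FRA_male, p_up,
                                      comparator_spec("std")), p_up)
  expect_gte(up$discounted$total_cost, std$discounted$total_cost)

  # zero-cost parameter set accrues zero cost
  p0 <- p
  p0$stages[, c("cost_initial", "cost_followup", "cost_advanced")] <- 0
  z <- summarize_outcomes(run_cohort(cfg, tabs$FRA_male, p0,
                                     comparator_spec("std")), p0)
  expect_equal(z$discounted$total_cost, 0)
})

test_that("half-cycle corrected accrual equals the occupancy trapezoid", {
  tabs <- synthetic_tables()
  p <- default_parameters("ESP", "male")
  cfg <- calibrated_study_config("ESP", "male", half_cycle_correction = TRUE)
  tr <- run_cohort(cfg, tabs$ESP_male, p, comparator_spec("std"))
  eff <- accrue_effects(tr, p$stages$utility, rate = 0)
  alive <- survival_curve(tr)$alive
  Tn <- tr$n_cycles
  expect_equal(eff$life_years,
               sum((alive[1:Tn] + alive[2:(Tn + 1)]) / 2))
  # trapezoid accrual is below the cycle-start accrual (alive is decreasing)
  eff_plain <- accrue_effects(tr, p$stages$utility, rate = 0,
                              half_cycle = FALSE)
  expect_lt(eff$life_years, eff_plain$life_years)
})
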