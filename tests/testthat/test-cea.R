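control_scenario <- function() scenario("control", ref_matrix())

test_that("the no-intervention scenario matches direct accumulation", {
  res <- run_scenario(control_scenario(), ref_payoffs())
  traj <- simulate_trajectory(matrices = ref_matrix(), horizon = 4)
  direct <- accumulate_outcomes(traj, ref_payoffs())
  expect_equal(res$qalys, direct$qalys)
  expect_equal(res$costs, direct$costs)
  expect_equal(res$qalys, 2.355, tolerance = 0.01)
  expect_equal(res$costs, 24291, tolerance = 0.01)
})

test_that("an RR=1 zero-cost intervention is indistinguishable from control", {
  s <- scenario("null", ref_matrix(), effect = manual_effect(1))
  res <- run_scenario(s, ref_payoffs())
  ctrl <- run_scenario(control_scenario(), ref_payoffs())
  expect_equal(res$qalys, ctrl$qalys)
  expect_equal(res$costs, ctrl$costs)
  inc <- incremental_analysis(res, ctrl)
  expect_equal(inc$dominance, "zero_delta")
})

test_that("incremental analysis classifies quadrants and reports ICERs", {
  ctrl <- run_scenario(control_scenario(), ref_payoffs())
  expect_equal(incremental_analysis(ctrl, ctrl)$d_qalys, 0)

  arms <- ref_arms()
  sm <- scenario("SM", ref_matrix(),
                 effect = derive_effect(arms$SM, arms$control),
                 upfront_cost_pp = 160)
  inc <- incremental_analysis(run_scenario(sm, ref_payoffs()), ctrl)
  expect_equal(inc$dominance, "dominant")
  expect_true(is.na(inc$icer))

  # an effective but very expensive intervention sits in the trade-off
  # quadrant with ICER = d_costs / d_qalys
  dear <- scenario("dear", ref_matrix(),
                   effect = derive_effect(arms$SM, arms$control),
                   upfront_cost_pp = 50000)
  incd <- incremental_analysis(run_scenario(dear, ref_payoffs()), ctrl)
  expect_equal(incd$dominance, "tradeoff_ICER")
  expect_equal(incd$icer, incd$d_costs / incd$d_qalys)

  short <- scenario("short", ref_matrix(), horizon = 2)
  expect_error(incremental_analysis(run_scenario(short, ref_payoffs()), ctrl),
               "horizon")
})

test_that("scenario invariants are enforced", {
  expect_error(scenario("x", ref_matrix(), booster_cost_pp = 19),
               "booster_all_years")
  expect_error(scenario("x", ref_matrix(), upfront_cost_pp = -1),
               "negative")
  expect_error(scenario("x", ref_matrix(), horizon = 0), "horizon")
})

test_that("sensitivity: +20% cost shifts 4-year cost by the undiscounted fifth", {
  arms <- ref_arms()
  scns <- list(
    control = control_scenario(),
    SM = scenario("SM", ref_matrix(),
                  effect = derive_effect(arms$SM, arms$control),
                  upfront_cost_pp = 160),
    PV = scenario("PV", ref_matrix(),
                  effect = derive_effect(arms$PV, arms$control),
                  upfront_cost_pp = 71))
  tab <- sensitivity_suite(scns, ref_payoffs())
  pick <- function(a, s, col) tab[tab$analysis == a & tab$scenario == s, col]
  expect_equal(pick("increased_cost", "SM", "costs") -
                 pick("main", "SM", "costs"), 32)
  expect_equal(round_half_up(pick("increased_cost", "PV", "costs") -
                               pick("main", "PV", "costs")), 14)
  # effects untouched by the cost variant
  expect_equal(pick("increased_cost", "SM", "qalys"),
               pick("main", "SM", "qalys"))

  # attenuated effect never beats the main analysis
  expect_lt(pick("reduced_effect", "SM", "d_qalys"),
            pick("main", "SM", "d_qalys"))
  expect_lt(abs(pick("reduced_effect", "SM", "d_costs")),
            abs(pick("main", "SM", "d_costs")))

  # neutral multipliers reproduce the main analysis exactly
  neutral <- sensitivity_suite(scns, ref_payoffs(), cost_multiplier = 1,
                               effect_scale = 1)
  expect_equal(neutral[neutral$analysis == "increased_cost", "costs"],
               neutral[neutral$analysis == "main" &
                         neutral$scenario != "control", "costs"])
  expect_equal(neutral[neutral$analysis == "reduced_effect", "qalys"],
               neutral[neutral$analysis == "main" &
                         neutral$scenario != "control", "qalys"])
})

test_that("boosters extend the effect and charge mild-state occupants", {
  arms <- ref_arms()
  eff <- derive_effect(arms$SM, arms$control)
  boosted <- scenario("SM-booster", ref_matrix(), effect = eff,
                      schedule = "booster_all_years",
                      upfront_cost_pp = 160, booster_cost_pp = 19)
  res <- run_scenario(boosted, ref_payoffs())

  # the booster matrix differs from baseline only in the mild row, so
  # applying it to the whole cohort treats exactly the mild occupants
  m <- apply_effect(ref_matrix(), eff)
  diffs <- unclass(m) != unclass(ref_matrix())
  expect_true(all(!diffs[-1, ]))

  # independent cost bookkeeping: state costs + upfront + per-year boosters
  traj <- simulate_trajectory(matrices = m, horizon = 4)
  occ <- unclass(traj)
  state_costs <- sum((1.03)^-(1:4) * as.numeric(occ[-1, ] %*%
                                                  ref_payoffs()$annual_cost))
  boost_costs <- sum((1.03)^-(1:3) * 19 * occ[2:4, "mild"])
  expect_equal(res$costs, state_costs + 160 + boost_costs, tolerance = 1e-9)

  # booster gains exceed the one-time-effect gains
  ctrl <- run_scenario(control_scenario(), ref_payoffs())
  once <- run_scenario(scenario("SM", ref_matrix(), effect = eff,
                                upfront_cost_pp = 160), ref_payoffs())
  inc_once <- incremental_analysis(once, ctrl)
  inc_boost <- incremental_analysis(res, ctrl)
  expect_gt(inc_boost$d_qalys, inc_once$d_qalys)
  expect_gt(abs(inc_boost$d_costs), abs(inc_once$d_costs))
})

test_that("QALY differences convert to days of full health half-up", {
  expect_equal(qaly_to_days(0.054), 20)
  expect_equal(qaly_to_days(0), 0)
  expect_equal(qaly_to_days(0.123), 45)  # 44.895 rounds up
})

test_that("protective cheap interventions are always dominant", {
  ctrl <- run_scenario(control_scenario(), ref_payoffs())
  for (rr in c(0.3, 0.6, 0.9)) {
    s <- scenario("x", ref_matrix(), effect = manual_effect(rr),
                  upfront_cost_pp = 50)
    inc <- incremental_analysis(run_scenario(s, ref_payoffs()), ctrl)
    expect_equal(inc$dominance, "dominant")
  }
})
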