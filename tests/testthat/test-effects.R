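test_that("progression risks match the trial count arithmetic", {
  arms <- ref_arms()
  expect_equal(progression_risk(arms$control, "moderate"), 19 / 114)
  expect_equal(round_half_up(progression_risk(arms$control, "moderate"), 2),
               0.17)
  expect_equal(round_half_up(progression_risk(arms$SM, "moderate"), 2), 0.06)
  expect_equal(round_half_up(progression_risk(arms$PV, "moderate"), 2), 0.11)
  expect_equal(progression_risk(arms$control, "any"), 27 / 114)

  none <- trial_arm("none", c(50, 0, 0, 0, 0))
  expect_equal(progression_risk(none, "any"), 0)
  expect_error(trial_arm("bad", c(10, 1, 0, 0, 0), n = 12), "n = 12")
  expect_error(trial_arm("bad", c(-1, 1, 0, 0, 0)), "negative")
})

test_that("relative risks reproduce two-decimal and exact arithmetic", {
  arms <- ref_arms()
  expect_equal(relative_risk(arms$SM, arms$control, "moderate",
                             mode = "as_printed"), 0.35)
  expect_equal(relative_risk(arms$PV, arms$control, "moderate",
                             mode = "as_printed"), 0.65)
  expect_equal(relative_risk(arms$control, arms$control, "any"), 1)
  # exact fraction: (24/174)/(27/114) = (24*114)/(174*27)
  expect_equal(relative_risk(arms$PV, arms$control, "any"),
               (24 * 114) / (174 * 27), tolerance = 1e-15)
  # control count for total dependency is zero -> no information
  expect_true(is.na(relative_risk(arms$SM, arms$control, "total")))
})

test_that("the default convention reproduces the year-1 intervention cells", {
  arms <- ref_arms()
  p <- ref_matrix()
  sm_row <- unclass(apply_effect(p, derive_effect(arms$SM,
                                                  arms$control)))["mild", ]
  counts <- round_half_up(100 * sm_row)
  expect_equal(unname(counts[c("mild", "moderate")]), c(87, 7))
  expect_equal(unname(sm_row[["dead"]]), 0.03)  # death left at baseline

  pv_row <- unclass(apply_effect(p, derive_effect(arms$PV,
                                                  arms$control)))["mild", ]
  expect_equal(unname(round_half_up(100 * pv_row[["moderate"]])), 8)
})

test_that("apply_effect bookkeeping: saved mass moves to staying mild", {
  p <- ref_matrix()
  # full protection: all progression risk removed, death untouched
  eff0 <- manual_effect(0)
  expect_equal(unname(unclass(apply_effect(p, eff0))["mild", ]),
               c(0.97, 0, 0, 0, 0.03))
  # no effect: matrix unchanged
  eff1 <- manual_effect(1)
  expect_equal(unclass(apply_effect(p, eff1)), unclass(p))
  # effect_scale 0 reproduces baseline for any RR
  eff <- manual_effect(0.3, effect_scale = 0)
  expect_equal(unclass(apply_effect(p, eff)), unclass(p))
  # only the mild row ever changes
  effx <- manual_effect(0.5)
  changed <- unclass(apply_effect(p, effx)) != unclass(p)
  expect_true(all(!changed[-1, ]))
})

test_that("row-stochasticity survives every convention and RR in [0, 2]", {
  p <- ref_matrix()
  conventions <- c("overall_rr_nondeath", "per_destination_rr",
                   "direct_proportions", "moderate_only_rr")
  for (rr in seq(0, 2, by = 0.25)) {
    for (cv in conventions) {
      for (s in c(0.5, 1)) {
        eff <- manual_effect(rr, convention = cv, effect_scale = s)
        m <- apply_effect(p, eff)
        expect_s3_class(m, "transition_matrix")
        expect_true(all(abs(rowSums(unclass(m)) - 1) < 1e-9))
      }
    }
  }
})

test_that("smaller effective RR weakly increases staying-mild and QALYs", {
  p <- ref_matrix()
  payoffs <- ref_payoffs()
  rrs <- c(0.2, 0.5, 0.8, 1)
  stay <- numeric(length(rrs))
  qalys <- numeric(length(rrs))
  costs <- numeric(length(rrs))
  for (i in seq_along(rrs)) {
    m <- apply_effect(p, manual_effect(rrs[i]))
    stay[i] <- unclass(m)["mild", "mild"]
    traj <- simulate_trajectory(matrices = c(list(m), rep(list(p), 3)),
                                horizon = 4)
    out <- accumulate_outcomes(traj, payoffs)
    qalys[i] <- out$qalys
    costs[i] <- out$costs
  }
  expect_true(all(diff(stay) <= 0))
  expect_true(all(diff(qalys) <= 0))
  expect_true(all(diff(costs) >= 0))
})
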