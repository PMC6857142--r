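test_that("generated arms conserve mass and honour degenerate rows", {
  row <- unclass(ref_matrix())["mild", ]
  arm <- generate_arm(row, n = 114, seed = 1)
  expect_s3_class(arm, "trial_arm")
  expect_equal(sum(arm$counts), 114)

  sure <- generate_arm(c(1, 0, 0, 0, 0), n = 50, seed = 1)
  expect_equal(unname(sure$counts), c(50, 0, 0, 0, 0))

  expect_error(generate_arm(c(0.5, 0.5, 0.5, 0, 0), n = 10), "summing to 1")
  expect_error(generate_arm(row, n = 0), "positive")
})

test_that("generation is reproducible for a fixed seed", {
  row <- unclass(ref_matrix())["mild", ]
  a <- generate_arm(row, n = 1000, seed = 42)
  b <- generate_arm(row, n = 1000, seed = 42)
  expect_identical(a$counts, b$counts)

  m1 <- generate_random_matrix(seed = 99)
  m2 <- generate_random_matrix(seed = 99)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("random matrices always satisfy the structural invariants", {
  set.seed(11)
  for (i in 1:100) {
    m <- generate_random_matrix()
    expect_s3_class(m, "transition_matrix")  # validate_matrix already ran
    expect_equal(unclass(m)["total", "mild"], 0)
    expect_equal(unname(unclass(m)["dead", ]), c(0, 0, 0, 0, 1))
  }
})

test_that("estimated risks converge to the generating truth (LLN)", {
  # generating row = observed control-arm proportions
  ctrl_props <- ref_arms()$control$counts / 114
  arm <- generate_arm(ctrl_props, n = 100000, seed = 3)
  expect_lt(abs(progression_risk(arm, "any") - 27 / 114), 0.005)
})

test_that("pooled RR estimated from large synthetic arms is nearly unbiased", {
  base_row <- unclass(ref_matrix())["mild", ]
  true_rr <- 0.6
  # scale all progression mass by the target RR; pooled RR is then exact
  treated_row <- base_row
  treated_row[-1] <- base_row[-1] * true_rr
  treated_row[1] <- 1 - sum(treated_row[-1])

  set.seed(17)
  est <- replicate(50, {
    tr <- generate_arm(treated_row, n = 10000)
    ct <- generate_arm(base_row, n = 10000)
    relative_risk(tr, ct, "any")
  })
  expect_lt(abs(mean(est) - true_rr) / true_rr, 0.02)
})

test_that("synthetic arms flow through the whole pipeline cleanly", {
  set.seed(23)
  ctrl <- generate_arm(unclass(ref_matrix())["mild", ], n = 500,
                       label = "control")
  tr <- generate_arm(c(0.88, 0.06, 0.02, 0.01, 0.03), n = 500,
                     label = "treated")
  eff <- derive_effect(tr, ctrl)
  m <- apply_effect(ref_matrix(), eff)
  expect_true(all(abs(rowSums(unclass(m)) - 1) < 1e-9))
  s <- scenario("treated", ref_matrix(), effect = eff, upfront_cost_pp = 100)
  res <- run_scenario(s, ref_payoffs())
  inc <- incremental_analysis(res,
                              run_scenario(scenario("control", ref_matrix()),
                                           ref_payoffs()))
  expect_true(inc$dominance %in%
                c("dominant", "dominated", "tradeoff_ICER", "zero_delta"))
})
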