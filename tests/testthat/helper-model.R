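# Reference parameter objects built in code, independent of the shipped
# extdata files, so fixture-drift tests have something to compare against.

ref_matrix <- function() {
  transition_matrix(matrix(c(
    0.79, 0.13, 0.03, 0.02, 0.03,
    0.08, 0.82, 0.03, 0.01, 0.06,
    0.02, 0.12, 0.61, 0.11, 0.14,
    0.00, 0.03, 0.18, 0.63, 0.16,
    0.00, 0.00, 0.00, 0.00, 1.00), nrow = 5, byrow = TRUE,
    dimnames = list(dependency_states(), dependency_states())))
}

ref_payoffs <- function() {
  payoff_table(utility = c(0.77, 0.60, 0.47, 0.41, 0),
               annual_cost = c(2600, 7801, 20708, 62407, 0))
}

ref_arms <- function() {
  list(control = trial_arm("control", c(87, 19, 6, 0, 2)),
       SM = trial_arm("SM", c(149, 11, 3, 3, 5)),
       PV = trial_arm("PV", c(150, 19, 1, 0, 4)))
}

ref_sheets <- function() {
  list(SM = cost_sheet(c(education = 2143, salaries = 21071, travel = 234,
                         rooms = 3222, materials = 623),
                       participants = 171, booster_unit_cost = 19,
                       label = "SM"),
       PV = cost_sheet(c(education = 2143, salaries = 9322, travel = 238,
                         rooms = 0, materials = 634),
                       participants = 174, booster_unit_cost = 71,
                       label = "PV"))
}

# Independent oracle: occupancy after k cycles by brute-force enumeration of
# all length-k state paths (sum of products of step probabilities). Never
# uses step_cohort / simulate_trajectory.
enumerate_paths <- function(start, p, k) {
  states <- dependency_states()
  occ <- setNames(numeric(5), states)
  paths <- expand.grid(rep(list(states), k), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(paths))) {
    path <- as.character(paths[i, ])
    for (s0 in states) {
      pr <- start[[s0]]
      prev <- s0
      for (s in path) {
        pr <- pr * p[prev, s]
        prev <- s
      }
      occ[path[k]] <- occ[path[k]] + pr
    }
  }
  occ
}

# Independent oracle: k-fold matrix power applied to the start row vector.
matrix_power_occupancy <- function(start, p, k) {
  v <- matrix(start, nrow = 1)
  m <- unclass(p)
  for (i in seq_len(k)) v <- v %*% m
  setNames(as.numeric(v), dependency_states())
}

# Build an intervention_effect by hand with the given RRs (for property
# sweeps where no trial arm would yield the RR exactly).
manual_effect <- function(rr_overall, rr_each = rr_overall,
                          convention = "overall_rr_nondeath",
                          effect_scale = 1,
                          treated_props = c(0.9, 0.05, 0.02, 0.01, 0.02)) {
  structure(list(
    label = "manual",
    rr_by_destination = setNames(rep(rr_each, 4),
                                 setdiff(dependency_states(), "mild")),
    rr_overall_progression = rr_overall,
    treated_proportions = setNames(treated_props, dependency_states()),
    convention = convention,
    effect_scale = effect_scale
  ), class = "intervention_effect")
}
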