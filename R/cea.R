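#' Define a cost-effectiveness scenario
#'
#' A scenario bundles everything needed to run one arm of the analysis: the
#' baseline annual transition matrix, an optional intervention effect and
#' its schedule, the per-participant intervention costs, the horizon, the
#' discount rate and the starting cohort.
#'
#' Two schedules are supported. `year1_only` (the main analysis) applies the
#' effect-modified matrix in cycle 1 only; afterwards transitions revert to
#' baseline. `booster_all_years` extends the effect to every cycle by
#' delivering a booster session at the start of years 2..horizon to those
#' who remained in mild dependency; because the effect modifies only the
#' mild row, using the modified matrix in every cycle is exactly equivalent
#' to treating only mild-state occupants. The booster cost charged for year
#' `t` is `booster_cost_pp` times the mild-state occupancy at the end of
#' year `t - 1`.
#'
#' @param label Scenario label.
#' @param baseline A validated `transition_matrix`.
#' @param effect An `intervention_effect`, or `NULL` for no intervention.
#' @param schedule `"year1_only"` (default) or `"booster_all_years"`.
#' @param upfront_cost_pp Per-participant intervention cost in euros,
#'   charged undiscounted at cycle 0.
#' @param booster_cost_pp Per-participant booster session cost in euros;
#'   must be 0 unless `schedule = "booster_all_years"`.
#' @param horizon Years (default 4).
#' @param discount_rate Annual discount rate (default 0.03).
#' @param start Starting cohort distribution (default all mild).
#' @return Object of class `cea_scenario`.
#' @examples
#' p <- dependency_model_params()
#' scenario("control", p$transition_matrix)
#' @export
scenario <- function(label, baseline, effect = NULL,
                     schedule = c("year1_only", "booster_all_years"),
                     upfront_cost_pp = 0, booster_cost_pp = 0, horizon = 4,
                     discount_rate = 0.03, start = all_mild_cohort()) {
  schedule <- match.arg(schedule)
  if (!inherits(baseline, "transition_matrix")) {
    baseline <- validate_matrix(baseline)
  }
  if (!is.null(effect) && !inherits(effect, "intervention_effect")) {
    stop("effect must be an intervention_effect or NULL", call. = FALSE)
  }
  if (upfront_cost_pp < 0 || booster_cost_pp < 0) {
    stop("negative intervention cost", call. = FALSE)
  }
  if (booster_cost_pp > 0 && schedule != "booster_all_years") {
    stop("booster_cost_pp requires schedule = 'booster_all_years'",
         call. = FALSE)
  }
  if (horizon < 1) stop("horizon must be at least 1 year", call. = FALSE)
  structure(list(label = label, baseline = baseline, effect = effect,
                 schedule = schedule, upfront_cost_pp = upfront_cost_pp,
                 booster_cost_pp = booster_cost_pp, horizon = horizon,
                 discount_rate = discount_rate,
                 start = cohort_distribution(start)),
            class = "cea_scenario")
}

#' Run a scenario
#'
#' Builds the per-cycle matrix list from the effect and schedule, simulates
#' the occupancy trajectory, assembles the intervention cost stream
#' (upfront cost at cycle 0 undiscounted; booster costs proportional to the
#' mild occupancy entering each boosted year) and accumulates discounted
#' QALYs and societal costs.
#'
#' @param s A [scenario()].
#' @param payoffs A [payoff_table()].
#' @return Object of class `cea_result` with components `label`,
#'   `trajectory`, `qalys`, `costs` and the scenario itself.
#' @examples
#' p <- dependency_model_params()
#' run_scenario(scenario("control", p$transition_matrix), p$payoffs)
#' @export
run_scenario <- function(s, payoffs) {
  stopifnot(inherits(s, "cea_scenario"), inherits(payoffs, "payoff_table"))
  H <- s$horizon
  if (is.null(s$effect)) {
    mats <- rep(list(s$baseline), H)
  } else {
    modified <- apply_effect(s$baseline, s$effect)
    mats <- switch(s$schedule,
      year1_only = c(list(modified), rep(list(s$baseline), H - 1)),
      booster_all_years = rep(list(modified), H))
  }
  traj <- simulate_trajectory(s$start, mats, H)
  extra <- numeric(H)
  extra[1] <- s$upfront_cost_pp
  if (s$schedule == "booster_all_years" && H >= 2) {
    for (t in 2:H) {
      extra[t] <- s$booster_cost_pp * unclass(traj)[t, "mild"]
    }
  }
  out <- accumulate_outcomes(traj, payoffs, s$discount_rate, extra)
  structure(list(label = s$label, trajectory = traj, qalys = out$qalys,
                 costs = out$costs, scenario = s),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("Scenario '%s': %.3f QALYs, %.0f EUR (discounted, %d years)\n",
              x$label, x$qalys, x$costs, x$scenario$horizon))
  invisible(x)
}

#' Incremental analysis against a comparator
#'
#' Simple differences in accumulated QALYs and costs, with the
#' cost-effectiveness quadrant classified: `dominant` (more QALYs, lower
#' cost), `dominated` (fewer QALYs, higher cost), `zero_delta`, or
#' `tradeoff_ICER` with the incremental cost-effectiveness ratio
#' `d_costs / d_qalys`. ICERs are reported only for genuine trade-off
#' quadrants, where the ratio's sign is meaningful.
#'
#' @param result,comparator `cea_result` objects with matching horizon and
#'   discount rate.
#' @return List with `d_qalys`, `d_costs`, `dominance` and `icer` (`NA`
#'   unless `dominance == "tradeoff_ICER"`).
#' @examples
#' p <- dependency_model_params()
#' ctrl <- run_scenario(scenario("control", p$transition_matrix), p$payoffs)
#' incremental_analysis(ctrl, ctrl)
#' @export
incremental_analysis <- function(result, comparator) {
  stopifnot(inherits(result, "cea_result"), inherits(comparator, "cea_result"))
  if (result$scenario$horizon != comparator$scenario$horizon) {
    stop("mismatched horizons", call. = FALSE)
  }
  if (result$scenario$discount_rate != comparator$scenario$discount_rate) {
    stop("mismatched discount rates", call. = FALSE)
  }
  dq <- result$qalys - comparator$qalys
  dc <- result$costs - comparator$costs
  if (dq == 0 && dc == 0) {
    dominance <- "zero_delta"; icer <- NA_real_
  } else if (dq > 0 && dc < 0) {
    dominance <- "dominant"; icer <- NA_real_
  } else if (dq < 0 && dc > 0) {
    dominance <- "dominated"; icer <- NA_real_
  } else {
    dominance <- "tradeoff_ICER"
    icer <- if (dq != 0) dc / dq else Inf
  }
  list(d_qalys = dq, d_costs = dc, dominance = dominance, icer = icer)
}

# one row of a summary table for a result (+ optional comparator)
result_row <- function(analysis, res, comparator = NULL) {
  if (is.null(comparator) || identical(res$label, comparator$label)) {
    data.frame(analysis = analysis, scenario = res$label, qalys = res$qalys,
               costs = res$costs, d_qalys = NA_real_, d_costs = NA_real_,
               dominance = NA_character_, icer = NA_real_)
  } else {
    inc <- incremental_analysis(res, comparator)
    data.frame(analysis = analysis, scenario = res$label, qalys = res$qalys,
               costs = res$costs, d_qalys = inc$d_qalys,
               d_costs = inc$d_costs, dominance = inc$dominance,
               icer = inc$icer)
  }
}

#' Deterministic sensitivity suite
#'
#' Re-runs a set of scenarios under two independent one-way variations:
#' intervention (upfront and booster) costs multiplied by `cost_multiplier`
#' with effects unchanged, and the intervention effect attenuated by
#' `effect_scale` (each effective RR moved `1 - effect_scale` of the way
#' toward 1) with costs unchanged.
#'
#' @param scenarios Named list of [scenario()] objects; must include the
#'   comparator.
#' @param payoffs A [payoff_table()].
#' @param cost_multiplier Multiplier on intervention costs (default 1.2).
#' @param effect_scale Attenuation of the effect (default 0.8).
#' @param comparator Label of the no-intervention comparator scenario
#'   (default `"control"`).
#' @return Data frame with one row per scenario per analysis
#'   (`main`, `increased_cost`, `reduced_effect`), holding accumulated and
#'   incremental QALYs/costs and the dominance classification.
#' @export
sensitivity_suite <- function(scenarios, payoffs, cost_multiplier = 1.2,
                              effect_scale = 0.8, comparator = "control") {
  stopifnot(cost_multiplier > 0, effect_scale > 0)
  if (!comparator %in% names(scenarios)) {
    stop(sprintf("comparator scenario '%s' not found", comparator),
         call. = FALSE)
  }
  base_results <- lapply(scenarios, run_scenario, payoffs = payoffs)
  comp <- base_results[[comparator]]

  vary_cost <- function(s) {
    s$upfront_cost_pp <- s$upfront_cost_pp * cost_multiplier
    s$booster_cost_pp <- s$booster_cost_pp * cost_multiplier
    s
  }
  vary_effect <- function(s) {
    if (!is.null(s$effect)) s$effect$effect_scale <- effect_scale
    s
  }
  rows <- list()
  for (nm in names(scenarios)) {
    rows[[length(rows) + 1L]] <- result_row("main", base_results[[nm]], comp)
  }
  for (nm in setdiff(names(scenarios), comparator)) {
    res <- run_scenario(vary_cost(scenarios[[nm]]), payoffs)
    rows[[length(rows) + 1L]] <- result_row("increased_cost", res, comp)
  }
  for (nm in setdiff(names(scenarios), comparator)) {
    res <- run_scenario(vary_effect(scenarios[[nm]]), payoffs)
    rows[[length(rows) + 1L]] <- result_row("reduced_effect", res, comp)
  }
  do.call(rbind, rows)
}

#' Convert a QALY difference to days of full health
#'
#' `round_half_up(d_qaly * 365)`: one QALY equals one year in full health.
#'
#' @param d_qaly QALY difference.
#' @return Integer days.
#' @examples
#' qaly_to_days(0.054)  # 20
#' @export
qaly_to_days <- function(d_qaly) {
  as.integer(round_half_up(d_qaly * 365))
}
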