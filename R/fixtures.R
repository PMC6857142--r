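#' Built-in model parameters
#'
#' Loads the package's shipped parameter set for the dependency-state
#' cost-utility model of health promotion in community-dwelling older
#' people: the annual transition matrix, per-state HRQoL utilities and
#' annual societal costs, the one-year trial arm counts from which
#' intervention effects are derived (control, senior meetings SM,
#' preventive home visit PV), the itemised intervention cost sheets with
#' booster unit costs (19 EUR per extra senior meeting, 71 EUR per extra
#' home visit), a 3% annual discount rate and a 4-year horizon.
#'
#' @return List with components `transition_matrix`, `payoffs`, `arms`,
#'   `cost_sheets`, `discount_rate`, `horizon`, `cohort_size`.
#' @examples
#' p <- dependency_model_params()
#' p$transition_matrix
#' @export
dependency_model_params <- function() {
  cfg <- system.file("extdata", "main_analysis.yaml", package = "markovcea")
  load_config(cfg)$params
}

#' Run the full built-in analysis
#'
#' Executes the complete study design on the shipped parameter set: the
#' main analysis (one-time first-year effect for senior meetings and the
#' preventive home visit vs no intervention), the two one-way sensitivity
#' variants (intervention costs x1.2; effect attenuated to 80%), and the
#' yearly booster-session scenarios, plus the per-year occupancy count
#' tables for a hypothetical cohort.
#'
#' @param convention Effect application convention passed to
#'   [derive_effect()] (default `"overall_rr_nondeath"`).
#' @param cost_multiplier,effect_scale Sensitivity-variant settings
#'   (defaults 1.2 and 0.8).
#' @param cohort_size Cohort size for the occupancy report (default from
#'   the shipped config, 100).
#' @return List with `cea_table` (analysis, scenario, accumulated and
#'   incremental QALYs/costs, dominance), `occupancy` (long table of
#'   per-year person counts per scenario), and `params`.
#' @examples
#' ref <- reference_analysis()
#' subset(ref$cea_table, analysis == "main")
#' @export
reference_analysis <- function(convention = "overall_rr_nondeath",
                               cost_multiplier = 1.2, effect_scale = 0.8,
                               cohort_size = NULL) {
  params <- dependency_model_params()
  if (is.null(cohort_size)) cohort_size <- params$cohort_size
  eff <- function(arm_label, ...) {
    derive_effect(params$arms[[arm_label]], params$arms$control,
                  convention = convention, ...)
  }
  mk <- function(label, arm_label = NULL, schedule = "year1_only") {
    if (is.null(arm_label)) {
      return(scenario(label, params$transition_matrix,
                      horizon = params$horizon,
                      discount_rate = params$discount_rate))
    }
    sheet <- params$cost_sheets[[arm_label]]
    scenario(label, params$transition_matrix, effect = eff(arm_label),
             schedule = schedule,
             upfront_cost_pp = per_participant_cost(sheet),
             booster_cost_pp = if (schedule == "booster_all_years") {
               sheet$booster_unit_cost
             } else 0,
             horizon = params$horizon,
             discount_rate = params$discount_rate)
  }
  main <- list(control = mk("control"),
               senior_meetings = mk("senior_meetings", "SM"),
               preventive_home_visit = mk("preventive_home_visit", "PV"))
  tab <- sensitivity_suite(main, params$payoffs,
                           cost_multiplier = cost_multiplier,
                           effect_scale = effect_scale,
                           comparator = "control")
  comp <- run_scenario(main$control, params$payoffs)
  boosters <- list(
    mk("senior_meetings", "SM", schedule = "booster_all_years"),
    mk("preventive_home_visit", "PV", schedule = "booster_all_years"))
  for (b in boosters) {
    tab <- rbind(tab, result_row("booster", run_scenario(b, params$payoffs),
                                 comp))
  }
  occupancy <- do.call(rbind, lapply(names(main), function(nm) {
    res <- run_scenario(main[[nm]], params$payoffs)
    rep_df <- occupancy_report(res$trajectory, cohort_size)
    cbind(scenario = nm, rep_df)
  }))
  list(cea_table = tab, occupancy = occupancy, params = params)
}
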