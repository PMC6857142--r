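#' Advance a cohort distribution by one annual cycle
#'
#' Left-multiplies the cohort share vector by the transition matrix:
#' `share'[to] = sum_from share[from] * p[from, to]`. Mass is conserved.
#'
#' @param dist Cohort distribution (see [cohort_distribution()]).
#' @param matrix A `transition_matrix`.
#' @return The cohort distribution after one cycle.
#' @examples
#' p <- dependency_model_params()
#' step_cohort(all_mild_cohort(), p$transition_matrix)
#' @export
step_cohort <- function(dist, matrix) {
  dist <- cohort_distribution(dist)
  if (!inherits(matrix, "transition_matrix")) {
    matrix <- validate_matrix(matrix)
  }
  out <- as.numeric(dist %*% unclass(matrix))
  names(out) <- dependency_states()
  out
}

#' Propagate a cohort over annual cycles
#'
#' Computes the occupancy trajectory `occupancy[t, ]` for `t = 0..horizon`,
#' where row 0 is the starting distribution and each subsequent row is one
#' application of that cycle's transition matrix. Cycle-specific matrices
#' allow a first-year intervention effect or yearly booster sessions.
#'
#' @param start Starting cohort distribution (default: everyone in mild
#'   dependency).
#' @param matrices Either a single `transition_matrix` used for every cycle,
#'   or a list of length `horizon` with one matrix per cycle.
#' @param horizon Number of annual cycles (default 4; must be >= 1).
#' @return Numeric matrix with `horizon + 1` rows (named `"0"..horizon`) and
#'   one column per state, classed `cea_trajectory`.
#' @examples
#' p <- dependency_model_params()
#' simulate_trajectory(matrices = p$transition_matrix, horizon = 4)
#' @export
simulate_trajectory <- function(start = all_mild_cohort(), matrices,
                                horizon = 4) {
  if (horizon < 1) stop("horizon must be at least 1 year", call. = FALSE)
  start <- cohort_distribution(start)
  if (inherits(matrices, "transition_matrix") || is.matrix(matrices)) {
    matrices <- rep(list(matrices), horizon)
  }
  if (length(matrices) != horizon) {
    stop(sprintf("need one transition matrix per cycle: %d supplied for horizon %d",
                 length(matrices), horizon), call. = FALSE)
  }
  matrices <- lapply(matrices, function(m) {
    if (inherits(m, "transition_matrix")) m else validate_matrix(m)
  })
  states <- dependency_states()
  occ <- matrix(0, nrow = horizon + 1, ncol = length(states),
                dimnames = list(0:horizon, states))
  occ[1, ] <- start
  for (t in seq_len(horizon)) {
    occ[t + 1, ] <- step_cohort(occ[t, ], matrices[[t]])
  }
  structure(occ, class = c("cea_trajectory", "matrix", "array"),
            horizon = horizon)
}

#' Discount factors for end-of-cycle outcomes
#'
#' Outcomes realised during cycle `t` are valued at the end of the cycle and
#' discounted by `(1 + rate)^(-t)`, `t = 1..horizon`.
#'
#' @param rate Annual discount rate as a proportion (default 0.03).
#' @param horizon Number of cycles.
#' @return Numeric vector of length `horizon`.
#' @export
discount_factors <- function(rate = 0.03, horizon = 4) {
  if (rate < 0) stop("discount rate must be >= 0", call. = FALSE)
  (1 + rate)^(-seq_len(horizon))
}

#' Accumulate discounted QALYs and societal costs over a trajectory
#'
#' QALYs are the utility-weighted occupancy summed over cycles,
#' `sum_t (1+r)^(-t) sum_s occupancy[t, s] * utility[s]`, and state costs
#' analogously with the annual societal costs; both use end-of-cycle
#' discounting. `extra_costs[t]` carries per-person intervention spending
#' committed at the *start* of cycle `t` and is therefore discounted by
#' `(1+r)^(-(t-1))`: the upfront intervention cost (`t = 1`) is undiscounted
#' and a booster delivered at the start of year `t` is discounted one year
#' less than that year's state costs.
#'
#' @param traj A `cea_trajectory`.
#' @param payoffs A [payoff_table()].
#' @param discount_rate Annual discount rate (default 0.03).
#' @param extra_costs Optional numeric vector of per-cycle extra euro costs,
#'   length equal to the trajectory horizon; all entries must be >= 0.
#' @return List with numeric scalars `qalys` and `costs`.
#' @examples
#' p <- dependency_model_params()
#' traj <- simulate_trajectory(matrices = p$transition_matrix, horizon = 4)
#' accumulate_outcomes(traj, p$payoffs)
#' @export
accumulate_outcomes <- function(traj, payoffs, discount_rate = 0.03,
                                extra_costs = NULL) {
  stopifnot(inherits(traj, "cea_trajectory"), inherits(payoffs, "payoff_table"))
  horizon <- attr(traj, "horizon")
  if (is.null(extra_costs)) extra_costs <- numeric(horizon)
  if (length(extra_costs) != horizon) {
    stop(sprintf("extra_costs must have one entry per cycle (%d), got %d",
                 horizon, length(extra_costs)), call. = FALSE)
  }
  if (any(extra_costs < 0)) stop("negative extra cost", call. = FALSE)
  df <- discount_factors(discount_rate, horizon)
  occ <- unclass(traj)[-1, , drop = FALSE]  # rows t = 1..horizon
  qalys <- sum(df * as.numeric(occ %*% payoffs$utility))
  state_costs <- sum(df * as.numeric(occ %*% payoffs$annual_cost))
  upfront <- sum((1 + discount_rate)^(-(seq_len(horizon) - 1)) * extra_costs)
  list(qalys = qalys, costs = state_costs + upfront)
}

#' Person-count occupancy report
#'
#' Scales the occupancy trajectory to a hypothetical cohort and rounds each
#' cell half-up to a whole person count. Unrounded shares are propagated
#' internally; the rounding here is display-only.
#'
#' @param traj A `cea_trajectory`.
#' @param cohort_size Persons in the hypothetical cohort (default 100).
#' @return Data frame with a `year` column (0..horizon) and one integer
#'   column per state.
#' @examples
#' p <- dependency_model_params()
#' traj <- simulate_trajectory(matrices = p$transition_matrix, horizon = 4)
#' occupancy_report(traj, cohort_size = 100)
#' @export
occupancy_report <- function(traj, cohort_size = 100) {
  stopifnot(inherits(traj, "cea_trajectory"))
  if (cohort_size <= 0) stop("cohort_size must be positive", call. = FALSE)
  counts <- round_half_up(unclass(traj) * cohort_size)
  out <- data.frame(year = as.integer(rownames(unclass(traj))), counts,
                    row.names = NULL, check.names = FALSE)
  out
}

#' @export
print.cea_trajectory <- function(x, digits = 4, ...) {
  cat(sprintf("Cohort occupancy trajectory over %d annual cycles\n",
              attr(x, "horizon")))
  print(round(unclass(x), digits), ...)
  invisible(x)
}
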