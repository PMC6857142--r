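#' Per-state utilities and annual societal costs
#'
#' Each dependency state carries a health-related quality-of-life (HRQoL)
#' utility weight on the 0-1 scale and an annual societal cost in euros
#' (health care, home help, informal care and special accommodation). Death
#' carries zero utility and zero cost by construction.
#'
#' @param utility Numeric vector of length 5 in \[0, 1\], optionally named by
#'   state.
#' @param annual_cost Numeric vector of length 5, non-negative euros per
#'   person-year, optionally named by state.
#' @return A list with components `utility` and `annual_cost` (named numeric
#'   vectors in canonical order), classed `payoff_table`.
#' @examples
#' payoff_table(utility = c(0.77, 0.60, 0.47, 0.41, 0),
#'              annual_cost = c(2600, 7801, 20708, 62407, 0))
#' @export
payoff_table <- function(utility, annual_cost) {
  utility <- as_state_vector(as.numeric(utility), "utility")
  annual_cost <- as_state_vector(as.numeric(annual_cost), "annual_cost")
  if (any(utility < 0 | utility > 1)) {
    stop("utilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(annual_cost < 0)) {
    stop("annual costs must be non-negative", call. = FALSE)
  }
  if (utility[["dead"]] != 0 || annual_cost[["dead"]] != 0) {
    stop("dead state must have zero utility and zero cost", call. = FALSE)
  }
  structure(list(utility = utility, annual_cost = annual_cost),
            class = "payoff_table")
}

#' @export
print.payoff_table <- function(x, ...) {
  cat("Per-state payoffs (HRQoL utility, annual societal cost in EUR)\n")
  print(data.frame(state = dependency_states(),
                   utility = unname(x$utility),
                   annual_cost_eur = unname(x$annual_cost)),
        row.names = FALSE)
  invisible(x)
}
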