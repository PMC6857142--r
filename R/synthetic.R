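#' Generate a synthetic one-year trial arm
#'
#' Draws destination-state counts for an arm of `n` persons who all start
#' in mild dependency, multinomially from a true one-year transition row.
#' This emulates the statistical structure of a one-year trial follow-up
#' table, so that relative-risk estimation can be validated against a known
#' generating truth.
#'
#' @param true_row Probability vector over the five destination states
#'   (sums to 1), e.g. the mild row of a transition matrix.
#' @param n Arm size (> 0).
#' @param label Arm label (default `"synthetic"`).
#' @param seed Optional integer seed; when supplied the draw is
#'   reproducible via [set.seed()].
#' @return A [trial_arm()] whose counts sum to `n`.
#' @examples
#' p <- dependency_model_params()
#' generate_arm(unclass(p$transition_matrix)["mild", ], n = 114, seed = 1)
#' @export
generate_arm <- function(true_row, n, label = "synthetic", seed = NULL) {
  true_row <- as_state_vector(as.numeric(true_row), "true_row")
  if (any(true_row < 0) || abs(sum(true_row) - 1) > 1e-9) {
    stop("true_row must be a probability vector summing to 1", call. = FALSE)
  }
  if (n <= 0) stop("arm size must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  counts <- as.numeric(rmultinom(1, size = n, prob = true_row))
  trial_arm(label, setNames(counts, dependency_states()), n = n)
}

#' Generate a random valid transition matrix
#'
#' Samples each transient row from a flat Dirichlet distribution over its
#' allowed destinations, forces the dead row absorbing and honours the
#' model's structural zero (total -> mild). The result always passes
#' [validate_matrix()]. Used for property-style testing of cohort
#' propagation (mass conservation, absorption) on matrices far from the
#' shipped fixture.
#'
#' @param seed Optional integer seed for reproducibility.
#' @return A validated `transition_matrix`.
#' @examples
#' generate_random_matrix(seed = 42)
#' @export
generate_random_matrix <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- dependency_states()
  p <- matrix(0, 5, 5, dimnames = list(states, states))
  for (from in setdiff(states, "dead")) {
    allowed <- states
    if (from == "total") allowed <- setdiff(allowed, "mild")
    g <- rgamma(length(allowed), shape = 1)
    p[from, allowed] <- g / sum(g)
  }
  p["dead", "dead"] <- 1
  validate_matrix(p)
}
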