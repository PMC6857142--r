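#' Canonical dependency states
#'
#' The model describes community-dwelling older people by their level of
#' dependency in basic and instrumental activities of daily living, plus an
#' absorbing death state. The canonical order is mild < moderate < severe <
#' total < dead and is used for every matrix, vector and table in the
#' package.
#'
#' @return Character vector of the five state labels in canonical order.
#' @examples
#' dependency_states()
#' @export
dependency_states <- function() {
  c("mild", "moderate", "severe", "total", "dead")
}

#' Round half away from zero
#'
#' Base [round()] uses banker's rounding (round-half-to-even); person-count
#' reports and printed euro amounts in health-economic tables conventionally
#' round half up. Display-only: rounded values are never fed back into
#' cohort propagation.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return `x` rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.5, 63.51))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Coerce a 5-vector (optionally named) to canonical state order.
as_state_vector <- function(x, what = "vector") {
  states <- dependency_states()
  if (length(x) != length(states)) {
    stop(sprintf("%s must have length %d (one entry per state)",
                 what, length(states)), call. = FALSE)
  }
  if (!is.null(names(x))) {
    if (!setequal(names(x), states)) {
      stop(sprintf("%s names must be exactly: %s",
                   what, paste(states, collapse = ", ")), call. = FALSE)
    }
    x <- x[states]
  } else {
    names(x) <- states
  }
  x
}

#' Construct and validate a cohort distribution
#'
#' A cohort distribution is a named proportion vector over the five
#' dependency states. Shares must be non-negative and sum to one.
#'
#' @param shares Numeric vector of length 5, optionally named by state; in
#'   canonical order when unnamed.
#' @param tol Tolerance for the sum-to-one check.
#' @return Named numeric vector in canonical state order.
#' @examples
#' all_mild_cohort()
#' cohort_distribution(c(0.5, 0.3, 0.1, 0.05, 0.05))
#' @export
cohort_distribution <- function(shares, tol = 1e-9) {
  shares <- as_state_vector(as.numeric(shares), "cohort distribution")
  if (any(shares < -tol)) {
    stop("negative share in cohort distribution", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > tol) {
    stop(sprintf("cohort shares must sum to 1, got %.10g", sum(shares)),
         call. = FALSE)
  }
  shares
}

#' @rdname cohort_distribution
#' @details `all_mild_cohort()` is the study's starting condition: every
#'   participant begins in mild dependency.
#' @export
all_mild_cohort <- function() {
  cohort_distribution(c(1, 0, 0, 0, 0))
}
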