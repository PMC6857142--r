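#' Construct a validated annual transition matrix
#'
#' Row-stochastic matrix of one-year transition probabilities over the five
#' dependency states. Death is absorbing, and recovery from total to mild
#' dependency is structurally impossible in this model (the corresponding
#' cell must be exactly zero).
#'
#' @param p Numeric 5x5 matrix, rows = origin state, columns = destination
#'   state. Dimnames, when present, must use the canonical state labels.
#' @param structural_zeros List of `c(from, to)` pairs that must be exactly
#'   zero. The default encodes the model's single disallowed recovery,
#'   total -> mild. Pass `list()` to lift the restriction.
#' @param tol Row-sum tolerance.
#' @return The matrix with canonical dimnames and class `transition_matrix`.
#' @seealso [validate_matrix()], [step_cohort()]
#' @examples
#' transition_matrix(diag(5))
#' @export
transition_matrix <- function(p,
                              structural_zeros = list(c("total", "mild")),
                              tol = 1e-9) {
  states <- dependency_states()
  p <- as.matrix(p)
  if (nrow(p) != 5 || ncol(p) != 5) {
    stop("transition matrix must be 5x5 over the dependency states",
         call. = FALSE)
  }
  if (!is.null(rownames(p)) && !is.null(colnames(p))) {
    if (!setequal(rownames(p), states) || !setequal(colnames(p), states)) {
      stop(sprintf("transition matrix dimnames must be exactly: %s",
                   paste(states, collapse = ", ")), call. = FALSE)
    }
    p <- p[states, states]
  } else {
    dimnames(p) <- list(states, states)
  }
  validate_matrix(p, structural_zeros = structural_zeros, tol = tol)
}

#' Validate a transition matrix
#'
#' Checks every invariant a one-year dependency transition matrix must
#' satisfy: probabilities in \[0, 1\], each row summing to one within
#' tolerance, the dead row being the unit vector onto dead, and structurally
#' disallowed transitions being exactly zero.
#'
#' @inheritParams transition_matrix
#' @param p Numeric 5x5 matrix with canonical dimnames (as produced by
#'   [transition_matrix()]).
#' @return `p` invisibly unchanged, classed `transition_matrix`, iff all
#'   invariants hold; otherwise an error naming the violated invariant (e.g.
#'   `"non-stochastic row: mild, sum 1.01"`, `"death not absorbing"`,
#'   `"negative probability"`).
#' @examples
#' m <- diag(5)
#' dimnames(m) <- list(dependency_states(), dependency_states())
#' validate_matrix(m)
#' @export
validate_matrix <- function(p,
                            structural_zeros = list(c("total", "mild")),
                            tol = 1e-9) {
  states <- dependency_states()
  p <- as.matrix(unclass(p))
  if (nrow(p) != 5 || ncol(p) != 5) {
    stop("transition matrix must be 5x5 over the dependency states",
         call. = FALSE)
  }
  if (is.null(rownames(p)) || is.null(colnames(p))) {
    dimnames(p) <- list(states, states)
  } else {
    p <- p[states, states]
  }
  if (any(!is.finite(p))) stop("non-finite probability", call. = FALSE)
  if (any(p < 0)) {
    stop(sprintf("negative probability: %s -> %s",
                 states[which(p < 0, arr.ind = TRUE)[1, 1]],
                 states[which(p < 0, arr.ind = TRUE)[1, 2]]), call. = FALSE)
  }
  if (any(p > 1)) stop("probability above 1", call. = FALSE)
  sums <- rowSums(p)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad) > 0) {
    stop(sprintf("non-stochastic row: %s, sum %s",
                 states[bad[1]], format(sums[bad[1]], digits = 7)),
         call. = FALSE)
  }
  if (p["dead", "dead"] != 1 || any(p["dead", states != "dead"] != 0)) {
    stop("death not absorbing", call. = FALSE)
  }
  for (z in structural_zeros) {
    if (p[z[1], z[2]] != 0) {
      stop(sprintf("disallowed transition %s -> %s must be exactly 0",
                   z[1], z[2]), call. = FALSE)
    }
  }
  structure(p, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, digits = 4, ...) {
  cat("Annual dependency-state transition matrix (row-stochastic)\n")
  print(round(unclass(x), digits), ...)
  invisible(x)
}
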