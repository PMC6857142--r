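#' One-year trial arm counts
#'
#' Destination-state counts for a trial arm observed one year after
#' baseline. All participants start in mild dependency, so the counts are a
#' single multinomial row over the five states.
#'
#' @param label Arm label (e.g. `"control"`, `"SM"`, `"PV"`).
#' @param counts Integer vector of length 5 (persons per destination state),
#'   optionally named by state.
#' @param n Arm size; defaults to `sum(counts)` and must equal it.
#' @return List with `label`, `n` and named `counts`, classed `trial_arm`.
#' @examples
#' trial_arm("control", c(87, 19, 6, 0, 2))
#' @export
trial_arm <- function(label, counts, n = sum(counts)) {
  counts <- as_state_vector(as.numeric(counts), "trial arm counts")
  if (any(counts < 0)) stop("negative count", call. = FALSE)
  if (n <= 0) stop("arm size must be positive", call. = FALSE)
  if (sum(counts) != n) {
    stop(sprintf("counts sum to %d but n = %d", sum(counts), n),
         call. = FALSE)
  }
  structure(list(label = as.character(label), n = n, counts = counts),
            class = "trial_arm")
}

#' Risk of progressing out of mild dependency
#'
#' The one-year risk of ending in a given destination state (or in any
#' non-mild state, pooled) for an arm that started all-mild:
#' `count[destination] / n`.
#'
#' @param arm A [trial_arm()].
#' @param destination One of `"moderate"`, `"severe"`, `"total"`, `"dead"`,
#'   or `"any"` (default) to pool all non-mild destinations.
#' @return Probability in \[0, 1\].
#' @examples
#' ctrl <- trial_arm("control", c(87, 19, 6, 0, 2))
#' progression_risk(ctrl, "moderate")  # 19/114
#' progression_risk(ctrl, "any")       # 27/114
#' @export
progression_risk <- function(arm, destination = "any") {
  stopifnot(inherits(arm, "trial_arm"))
  destination <- match.arg(destination,
                           c("any", "moderate", "severe", "total", "dead"))
  if (destination == "any") {
    sum(arm$counts[setdiff(dependency_states(), "mild")]) / arm$n
  } else {
    arm$counts[[destination]] / arm$n
  }
}

#' Relative risk of progression between two trial arms
#'
#' Ratio of the treated to the control progression risk for a destination
#' (or pooled over all non-mild destinations). Computed on unrounded
#' fractions by default; `mode = "as_printed"` rounds each risk to two
#' decimals before dividing and rounds the ratio to two decimals, echoing
#' worked two-decimal arithmetic.
#'
#' A control risk of zero carries no information about the treatment effect:
#' the function then returns `NA` rather than an error, and downstream
#' effect application leaves such destinations unmodified.
#'
#' @param treated,control [trial_arm()] objects.
#' @param destination As in [progression_risk()].
#' @param mode `"unrounded"` (default) or `"as_printed"`.
#' @return Relative risk (unitless, >= 0), or `NA` when the control risk is
#'   zero.
#' @examples
#' ctrl <- trial_arm("control", c(87, 19, 6, 0, 2))
#' sm <- trial_arm("SM", c(149, 11, 3, 3, 5))
#' relative_risk(sm, ctrl, "moderate", mode = "as_printed")  # 0.35
#' @export
relative_risk <- function(treated, control, destination = "any",
                          mode = c("unrounded", "as_printed")) {
  mode <- match.arg(mode)
  rt <- progression_risk(treated, destination)
  rc <- progression_risk(control, destination)
  if (mode == "as_printed") {
    rt <- round_half_up(rt, 2)
    rc <- round_half_up(rc, 2)
  }
  if (rc == 0) return(NA_real_)
  rr <- rt / rc
  if (mode == "as_printed") rr <- round_half_up(rr, 2)
  rr
}

#' Derive an intervention effect from trial arms
#'
#' Packages the relative risks needed by [apply_effect()] under a chosen
#' application convention:
#'
#' * `overall_rr_nondeath` (default): a single pooled progression RR (all
#'   non-mild destinations, death included in the counts) multiplies the
#'   mild -> moderate/severe/total probabilities; mild -> dead is left at
#'   baseline.
#' * `per_destination_rr`: each destination's own RR multiplies its
#'   transition probability (undefined RRs leave the destination unchanged).
#' * `direct_proportions`: the mild row is replaced by the treated arm's
#'   observed one-year proportions.
#' * `moderate_only_rr`: only mild -> moderate is scaled, by the
#'   moderate-destination RR.
#'
#' `effect_scale` linearly attenuates the effect toward no effect: each
#' effective RR becomes `1 - effect_scale * (1 - RR)` (and under
#' `direct_proportions` the row is blended toward baseline). `effect_scale =
#' 0.8` is the "20% reduced effect" sensitivity variant; 0 reproduces the
#' baseline exactly.
#'
#' @param treated,control [trial_arm()] objects (all participants baseline
#'   mild).
#' @param convention Effect application convention; see Details.
#' @param effect_scale Multiplier on `(1 - RR)` in \[0, 1\], default 1.
#' @return Object of class `intervention_effect`.
#' @examples
#' ctrl <- trial_arm("control", c(87, 19, 6, 0, 2))
#' sm <- trial_arm("SM", c(149, 11, 3, 3, 5))
#' derive_effect(sm, ctrl)
#' @export
derive_effect <- function(treated, control,
                          convention = c("overall_rr_nondeath",
                                         "per_destination_rr",
                                         "direct_proportions",
                                         "moderate_only_rr"),
                          effect_scale = 1) {
  convention <- match.arg(convention)
  stopifnot(inherits(treated, "trial_arm"), inherits(control, "trial_arm"))
  if (effect_scale < 0 || effect_scale > 1) {
    stop("effect_scale must lie in [0, 1]", call. = FALSE)
  }
  dests <- setdiff(dependency_states(), "mild")
  rr_by_destination <- vapply(dests, function(d) {
    relative_risk(treated, control, d)
  }, numeric(1))
  structure(list(
    label = treated$label,
    rr_by_destination = rr_by_destination,
    rr_overall_progression = relative_risk(treated, control, "any"),
    treated_proportions = treated$counts / treated$n,
    convention = convention,
    effect_scale = effect_scale
  ), class = "intervention_effect")
}

#' @export
print.intervention_effect <- function(x, ...) {
  cat(sprintf("Intervention effect '%s' (convention: %s, effect scale %g)\n",
              x$label, x$convention, x$effect_scale))
  cat(sprintf("  pooled progression RR: %.5f\n", x$rr_overall_progression))
  cat("  per-destination RRs:",
      paste(sprintf("%s=%s", names(x$rr_by_destination),
                    ifelse(is.na(x$rr_by_destination), "no-info",
                           sprintf("%.3f", x$rr_by_destination))),
            collapse = ", "), "\n")
  invisible(x)
}

# effective RR after linear attenuation toward 1 (no effect)
effective_rr <- function(rr, effect_scale) {
  ifelse(is.na(rr), 1, 1 - effect_scale * (1 - rr))
}

#' Apply an intervention effect to the mild-dependency transition row
#'
#' Modifies only the mild row of the baseline matrix according to the
#' effect's convention (see [derive_effect()]); any probability mass removed
#' from progression destinations is added to mild -> mild (staying well is
#' the complement of progressing). The resulting row is re-validated, so an
#' effect that would push any probability outside \[0, 1\] errors out.
#'
#' @param baseline A validated `transition_matrix`.
#' @param effect An `intervention_effect`.
#' @return A new `transition_matrix` differing from `baseline` only in the
#'   mild row.
#' @examples
#' p <- dependency_model_params()
#' eff <- derive_effect(p$arms$SM, p$arms$control)
#' apply_effect(p$transition_matrix, eff)["mild", ]
#' @export
apply_effect <- function(baseline, effect) {
  stopifnot(inherits(effect, "intervention_effect"))
  if (!inherits(baseline, "transition_matrix")) {
    baseline <- validate_matrix(baseline)
  }
  row <- unclass(baseline)["mild", ]
  s <- effect$effect_scale
  new_row <- row
  if (effect$convention == "overall_rr_nondeath") {
    rr <- effective_rr(effect$rr_overall_progression, s)
    new_row[c("moderate", "severe", "total")] <-
      row[c("moderate", "severe", "total")] * rr
  } else if (effect$convention == "per_destination_rr") {
    rr <- effective_rr(effect$rr_by_destination, s)
    dests <- names(effect$rr_by_destination)
    new_row[dests] <- row[dests] * rr[dests]
  } else if (effect$convention == "direct_proportions") {
    new_row <- row + s * (effect$treated_proportions - row)
  } else if (effect$convention == "moderate_only_rr") {
    rr <- effective_rr(effect$rr_by_destination[["moderate"]], s)
    new_row[["moderate"]] <- row[["moderate"]] * rr
  }
  if (effect$convention != "direct_proportions") {
    new_row[["mild"]] <- row[["mild"]] + (sum(row) - sum(new_row))
  }
  if (any(new_row < -1e-12 | new_row > 1 + 1e-12)) {
    stop("effect pushes a mild-row probability outside [0, 1]",
         call. = FALSE)
  }
  out <- unclass(baseline)
  out["mild", ] <- pmin(pmax(new_row, 0), 1)
  validate_matrix(out)
}
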