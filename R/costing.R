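#' Itemised intervention cost sheet
#'
#' Holds the cost items for delivering an intervention to a trial-sized
#' group (education of interveners, salaries, travel, rented rooms,
#' materials), the number of participants, and the unit cost of one booster
#' session per participant.
#'
#' @param items Named numeric vector of item amounts in euros (>= 0).
#' @param participants Number of participants (> 0).
#' @param booster_unit_cost Euro cost of one booster session per participant
#'   (default 0).
#' @param label Optional sheet label.
#' @return Object of class `cost_sheet`.
#' @examples
#' cost_sheet(c(education = 2143, salaries = 21071, travel = 234,
#'              rooms = 3222, materials = 623),
#'            participants = 171, booster_unit_cost = 19, label = "SM")
#' @export
cost_sheet <- function(items, participants, booster_unit_cost = 0,
                       label = "") {
  items <- setNames(as.numeric(items), names(items))
  if (any(items < 0)) stop("negative item amount", call. = FALSE)
  if (participants <= 0) stop("participants must be positive", call. = FALSE)
  if (booster_unit_cost < 0) stop("negative booster cost", call. = FALSE)
  structure(list(label = label, items = items, participants = participants,
                 booster_unit_cost = booster_unit_cost),
            class = "cost_sheet")
}

#' Total intervention cost
#'
#' Arithmetic sum of the sheet's item amounts, in euros. Permutation
#' invariant in the items and additive under sheet concatenation.
#'
#' @param sheet A [cost_sheet()].
#' @return Total euros.
#' @export
total_cost <- function(sheet) {
  stopifnot(inherits(sheet, "cost_sheet"))
  sum(sheet$items)
}

#' Per-participant intervention cost
#'
#' Total cost divided by the number of participants, optionally rounded
#' half-up to whole euros (the form in which the scenario engine consumes
#' it).
#'
#' @param sheet A [cost_sheet()].
#' @param rounding `"nearest_int"` (default) or `"none"`.
#' @return Euros per participant.
#' @examples
#' sm <- cost_sheet(c(2143, 21071, 234, 3222, 623), participants = 171)
#' per_participant_cost(sm)  # 160
#' @export
per_participant_cost <- function(sheet,
                                 rounding = c("nearest_int", "none")) {
  rounding <- match.arg(rounding)
  pp <- total_cost(sheet) / sheet$participants
  if (rounding == "nearest_int") round_half_up(pp) else pp
}

#' @export
print.cost_sheet <- function(x, ...) {
  cat(sprintf("Intervention cost sheet '%s' (%d participants)\n",
              x$label, x$participants))
  print(data.frame(item = names(x$items), amount_eur = unname(x$items)),
        row.names = FALSE)
  cat(sprintf("  total %.0f EUR, per participant %.1f EUR, booster %.0f EUR\n",
              total_cost(x), total_cost(x) / x$participants,
              x$booster_unit_cost))
  invisible(x)
}
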