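# Delimited-text readers for the model's parameter tables, YAML scenario
# bundles, and report writers. All files are plain text with
# locale-independent decimal points.

#' Read an annual transition matrix from CSV
#'
#' Expected columns: `from` plus one column per destination state.
#'
#' @param path CSV file path.
#' @return A validated `transition_matrix`.
#' @export
read_transition_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  states <- dependency_states()
  if (!identical(colnames(df), c("from", states))) {
    stop("transition matrix file must have columns: from, ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, states])
  rownames(m) <- df$from
  transition_matrix(m)
}

#' Read per-state payoffs from CSV
#'
#' Expected columns: `state`, `utility`, `annual_cost_eur`.
#'
#' @param path CSV file path.
#' @return A [payoff_table()].
#' @export
read_payoff_table <- function(path) {
  df <- read.csv(path)
  if (!identical(colnames(df), c("state", "utility", "annual_cost_eur"))) {
    stop("payoff file must have columns: state, utility, annual_cost_eur",
         call. = FALSE)
  }
  payoff_table(setNames(df$utility, df$state),
               setNames(df$annual_cost_eur, df$state))
}

#' Read one-year trial arms from CSV
#'
#' Expected columns: `arm`, `n`, then one count column per state.
#'
#' @param path CSV file path.
#' @return Named list of [trial_arm()] objects.
#' @export
read_trial_arms <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  states <- dependency_states()
  if (!identical(colnames(df), c("arm", "n", states))) {
    stop("trial arm file must have columns: arm, n, ",
         paste(states, collapse = ", "), call. = FALSE)
  }
  arms <- lapply(seq_len(nrow(df)), function(i) {
    trial_arm(df$arm[i], setNames(as.numeric(df[i, states]), states),
              n = df$n[i])
  })
  setNames(arms, df$arm)
}

#' Read intervention cost sheets from CSV
#'
#' `items_path` holds columns `intervention`, `item`, `amount_eur`;
#' `meta_path` holds `intervention`, `participants`,
#' `booster_unit_cost_eur`.
#'
#' @param items_path,meta_path CSV file paths.
#' @return Named list of [cost_sheet()] objects.
#' @export
read_cost_sheets <- function(items_path, meta_path) {
  items <- read.csv(items_path)
  meta <- read.csv(meta_path)
  if (!identical(colnames(items), c("intervention", "item", "amount_eur"))) {
    stop("cost item file must have columns: intervention, item, amount_eur",
         call. = FALSE)
  }
  if (!identical(colnames(meta),
                 c("intervention", "participants", "booster_unit_cost_eur"))) {
    stop("intervention file must have columns: intervention, participants, ",
         "booster_unit_cost_eur", call. = FALSE)
  }
  sheets <- lapply(meta$intervention, function(iv) {
    sub <- items[items$intervention == iv, ]
    row <- meta[meta$intervention == iv, ]
    cost_sheet(setNames(sub$amount_eur, sub$item),
               participants = row$participants,
               booster_unit_cost = row$booster_unit_cost_eur, label = iv)
  })
  setNames(sheets, meta$intervention)
}

config_schema <- list(
  top = c("discount_rate", "horizon", "cohort_size", "files", "scenarios"),
  files = c("transition_matrix", "payoffs", "trial_arms", "cost_items",
            "interventions"),
  scenario = c("label", "arm", "convention", "effect_scale", "schedule",
               "upfront_cost", "booster_cost")
)

reject_unknown <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown config key under %s: %s", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

#' Load and validate a scenario bundle config
#'
#' Parses a YAML config naming the parameter files (paths relative to the
#' config file) and the scenarios to run. Every referenced matrix, payoff
#' table, arm and cost sheet is validated on load; unknown keys are
#' rejected with their key path. Scenarios with an `arm` derive their
#' intervention effect from that arm versus the `control` arm and take
#' their upfront cost from the matching cost sheet (rounded per-participant
#' cost) unless overridden; `schedule: booster_all_years` takes the
#' booster unit cost from the sheet likewise.
#'
#' @param path YAML config file path.
#' @return List with `params` (transition matrix, payoffs, arms, cost
#'   sheets, discount rate, horizon, cohort size) and `scenarios` (named
#'   list of [scenario()] objects).
#' @examples
#' cfg <- system.file("extdata", "main_analysis.yaml", package = "markovcea")
#' bundle <- load_config(cfg)
#' names(bundle$scenarios)
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || length(cfg) == 0) {
    stop("schema error: config is empty or not a mapping", call. = FALSE)
  }
  reject_unknown(cfg, config_schema$top, "top level")
  for (key in c("discount_rate", "horizon", "files", "scenarios")) {
    if (is.null(cfg[[key]])) {
      stop(sprintf("schema error: missing key '%s'", key), call. = FALSE)
    }
  }
  if (cfg$discount_rate < 0) stop("rate >= 0 required", call. = FALSE)
  if (cfg$horizon < 1) stop("horizon must be at least 1 year", call. = FALSE)
  reject_unknown(cfg$files, config_schema$files, "files")
  dir <- dirname(normalizePath(path))
  fp <- function(key) file.path(dir, cfg$files[[key]])

  params <- list(
    transition_matrix = read_transition_matrix(fp("transition_matrix")),
    payoffs = read_payoff_table(fp("payoffs")),
    arms = read_trial_arms(fp("trial_arms")),
    cost_sheets = read_cost_sheets(fp("cost_items"), fp("interventions")),
    discount_rate = cfg$discount_rate,
    horizon = cfg$horizon,
    cohort_size = if (is.null(cfg$cohort_size)) 100 else cfg$cohort_size
  )

  scenarios <- lapply(cfg$scenarios, function(sc) {
    reject_unknown(sc, config_schema$scenario,
                   paste0("scenarios/", sc$label %||% "?"))
    if (is.null(sc$label)) {
      stop("schema error: scenario without label", call. = FALSE)
    }
    if (is.null(sc$arm)) {
      return(scenario(sc$label, params$transition_matrix,
                      horizon = params$horizon,
                      discount_rate = params$discount_rate))
    }
    if (!sc$arm %in% names(params$arms)) {
      stop(sprintf("scenario '%s' references unknown arm '%s'",
                   sc$label, sc$arm), call. = FALSE)
    }
    if (!sc$arm %in% names(params$cost_sheets) && is.null(sc$upfront_cost)) {
      stop(sprintf("scenario '%s': no cost sheet for arm '%s'",
                   sc$label, sc$arm), call. = FALSE)
    }
    sheet <- params$cost_sheets[[sc$arm]]
    schedule <- sc$schedule %||% "year1_only"
    eff <- derive_effect(params$arms[[sc$arm]], params$arms$control,
                         convention = sc$convention %||% "overall_rr_nondeath",
                         effect_scale = sc$effect_scale %||% 1)
    scenario(sc$label, params$transition_matrix, effect = eff,
             schedule = schedule,
             upfront_cost_pp = sc$upfront_cost %||%
               per_participant_cost(sheet),
             booster_cost_pp = if (schedule == "booster_all_years") {
               sc$booster_cost %||% sheet$booster_unit_cost
             } else 0,
             horizon = params$horizon,
             discount_rate = params$discount_rate)
  })
  names(scenarios) <- vapply(cfg$scenarios, `[[`, "", "label")
  list(params = params, scenarios = scenarios)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize model parameters as a config bundle
#'
#' Writes the parameter tables as CSV files plus a YAML config referencing
#' them into `dir`, such that [load_config()] on the returned path
#' reconstructs the parameters exactly (round-trip property).
#'
#' @param params Parameter list as returned by [dependency_model_params()]
#'   or `load_config()$params`.
#' @param dir Output directory (created if missing).
#' @param scenarios Optional list of scenario config entries to embed; the
#'   default is a lone no-intervention scenario.
#' @return Path to the written YAML config, invisibly.
#' @export
write_params <- function(params, dir,
                         scenarios = list(list(label = "control"))) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  states <- dependency_states()
  m <- unclass(params$transition_matrix)
  write.csv(data.frame(from = rownames(m), m, check.names = FALSE),
            file.path(dir, "transition_probabilities.csv"),
            row.names = FALSE, quote = FALSE)
  write.csv(data.frame(state = states,
                       utility = unname(params$payoffs$utility),
                       annual_cost_eur = unname(params$payoffs$annual_cost)),
            file.path(dir, "state_payoffs.csv"),
            row.names = FALSE, quote = FALSE)
  arms <- params$arms
  arm_df <- do.call(rbind, lapply(arms, function(a) {
    data.frame(arm = a$label, n = a$n, t(a$counts), check.names = FALSE)
  }))
  write.csv(arm_df, file.path(dir, "trial_arms.csv"),
            row.names = FALSE, quote = FALSE)
  items <- do.call(rbind, lapply(params$cost_sheets, function(s) {
    data.frame(intervention = s$label, item = names(s$items),
               amount_eur = unname(s$items))
  }))
  write.csv(items, file.path(dir, "intervention_cost_items.csv"),
            row.names = FALSE, quote = FALSE)
  meta <- do.call(rbind, lapply(params$cost_sheets, function(s) {
    data.frame(intervention = s$label, participants = s$participants,
               booster_unit_cost_eur = s$booster_unit_cost)
  }))
  write.csv(meta, file.path(dir, "interventions.csv"),
            row.names = FALSE, quote = FALSE)
  cfg <- list(discount_rate = params$discount_rate,
              horizon = params$horizon,
              cohort_size = params$cohort_size,
              files = list(transition_matrix = "transition_probabilities.csv",
                           payoffs = "state_payoffs.csv",
                           trial_arms = "trial_arms.csv",
                           cost_items = "intervention_cost_items.csv",
                           interventions = "interventions.csv"),
              scenarios = scenarios)
  out <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, out)
  invisible(out)
}

#' Write analysis reports as delimited text
#'
#' Writes the cost-effectiveness summary (QALYs to 3 decimals, euros to
#' whole units) and the per-year occupancy count table as CSV files with a
#' run-metadata comment header. Output is deterministic: identical inputs
#' produce byte-identical files.
#'
#' @param results List with components `cea_table` (data frame as produced
#'   by [sensitivity_suite()] or [reference_analysis()]) and optionally
#'   `occupancy` (data frame of person counts).
#' @param out_dir Output directory (created if missing).
#' @param seed,convention Optional run metadata recorded in the header.
#' @return Character vector of written file paths, invisibly.
#' @export
write_reports <- function(results, out_dir, seed = NULL, convention = NULL) {
  if (is.null(results$cea_table) || nrow(results$cea_table) == 0) {
    stop("no results to write", call. = FALSE)
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  header <- c(
    sprintf("# markovcea %s", as.character(packageVersion("markovcea"))),
    sprintf("# seed: %s", if (is.null(seed)) "none" else seed),
    sprintf("# convention: %s",
            if (is.null(convention)) "default" else convention))
  fmt_num <- function(x, digits) {
    ifelse(is.na(x), "", sprintf(paste0("%.", digits, "f"), x))
  }
  tab <- results$cea_table
  tab$qalys <- fmt_num(tab$qalys, 3)
  tab$costs <- fmt_num(tab$costs, 0)
  if ("d_qalys" %in% names(tab)) tab$d_qalys <- fmt_num(tab$d_qalys, 3)
  if ("d_costs" %in% names(tab)) tab$d_costs <- fmt_num(tab$d_costs, 0)
  if ("icer" %in% names(tab)) tab$icer <- fmt_num(tab$icer, 0)
  if ("dominance" %in% names(tab)) {
    tab$dominance[is.na(tab$dominance)] <- ""
  }
  paths <- character(0)
  write_one <- function(df, file) {
    con <- file(file.path(out_dir, file), open = "wb")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       quote = FALSE, eol = "\n")
    file.path(out_dir, file)
  }
  paths <- c(paths, write_one(tab, "cea_summary.csv"))
  if (!is.null(results$occupancy)) {
    paths <- c(paths, write_one(results$occupancy, "occupancy_counts.csv"))
  }
  invisible(paths)
}
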