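#' Study configuration
#'
#' Configuration for a full utility study: conditions crossed with
#' chronic-load scenarios, each run for `n_replicates` seeded syntheses
#' of one input panel. The desk default of 50 replicates keeps a full
#' study quick on one CPU; a production run at 500 is one argument away.
#'
#' @param fixture A [fixture_config()] (the panel is generated), or a
#'   path to a panel CSV.
#' @param conditions Condition names, see [build_condition()].
#' @param cl_scenarios Chronic-load scenarios to cross with conditions.
#' @param n_replicates Replicate syntheses per cell (>= 1).
#' @param master_seed Seed from which all replicate seeds are derived.
#' @param output_dir Directory for per-replicate and summary artifacts
#'   (`NULL` to keep results in memory only).
#' @param timeout Per-replicate elapsed-time cap in seconds; replicates
#'   exceeding it are recorded as failures.
#' @return A `study_config` list.
#' @export
study_config <- function(fixture = fixture_config(),
                         conditions = c("base", "base_week", "time_lag_1wk",
                                        "time_lag_3wks"),
                         cl_scenarios = c("independent", "calculated"),
                         n_replicates = 50, master_seed = 1,
                         output_dir = NULL, timeout = 60) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (length(conditions) == 0L) stop("conditions must be non-empty")
  bad <- setdiff(conditions, CONDITION_NAMES)
  if (length(bad) > 0L) {
    stop("unknown condition(s): ", paste(bad, collapse = ", "))
  }
  structure(list(fixture = fixture, conditions = conditions,
                 cl_scenarios = cl_scenarios, n_replicates = n_replicates,
                 master_seed = master_seed, output_dir = output_dir,
                 timeout = timeout),
            class = "study_config")
}

study_panel <- function(config) {
  panel <- if (is.character(config$fixture)) {
    read_panel(config$fixture)
  } else {
    generate_fixture(config$fixture)
  }
  add_lag_features(panel)
}

#' Run one condition-scenario cell
#'
#' Synthesizes `n_replicates` panels under one condition and scenario,
#' computing for each the global utility metrics, the replicated injury
#' GEE, and the observation-level load MAEs against the original panel.
#' Replicate seeds are derived deterministically from `seed`; failures
#' (including per-replicate timeouts) are recorded and the run continues.
#'
#' @param panel The original panel (lag columns added automatically).
#' @param condition Condition name.
#' @param scenario Chronic-load scenario.
#' @param n_replicates Number of replicate syntheses.
#' @param seed Seed for replicate-seed derivation.
#' @param reference Optional precomputed `gee_result` for the panel.
#' @param control CART hyperparameters.
#' @param timeout Per-replicate elapsed cap, seconds.
#' @param keep_panels Also return the synthetic panels (for adjacent-pair
#'   analyses)?
#' @return List with `results` (one data-frame row per replicate),
#'   `reference`, `condition`, `scenario`, and optionally `panels`.
#' @export
run_condition <- function(panel, condition, scenario, n_replicates = 50,
                          seed = 1, reference = NULL,
                          control = tree_control(), timeout = 60,
                          keep_panels = FALSE) {
  if (!all(LAG_VARIABLES %in% names(panel))) panel <- add_lag_features(panel)
  plan <- build_condition(condition, scenario)
  if (is.null(reference)) reference <- fit_injury_gee(panel)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  rows <- vector("list", n_replicates)
  panels <- if (keep_panels) vector("list", n_replicates) else NULL
  for (r in seq_len(n_replicates)) {
    t0 <- proc.time()[["elapsed"]]
    rec <- tryCatch({
      setTimeLimit(elapsed = timeout, transient = TRUE)
      on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
      syn <- synthesize(panel, plan, seed = rep_seeds[r], control = control)
      gu <- global_utility(panel, syn)
      gee <- tryCatch(fit_injury_gee(syn), error = function(e) NULL)
      om <- observation_mae(panel, syn)
      if (keep_panels) panels[[r]] <- syn
      data.frame(
        replicate = r, seed = rep_seeds[r], status = "ok",
        pmse = gu$pmse, s_pmse = gu$s_pmse, po50 = gu$po50,
        c = gu$c, k = gu$k, n_stacked = gu$n_stacked,
        gee_estimate = if (is.null(gee)) NA_real_ else gee$estimate,
        gee_se = if (is.null(gee)) NA_real_ else gee$se,
        gee_p = if (is.null(gee)) NA_real_ else gee$p,
        gee_failed = is.null(gee),
        abs_err_estimate = if (is.null(gee)) NA_real_ else
          abs(gee$estimate - reference$estimate),
        abs_err_se = if (is.null(gee)) NA_real_ else abs(gee$se - reference$se),
        abs_err_p = if (is.null(gee)) NA_real_ else abs(gee$p - reference$p),
        obs_mae_acute = om[["AcuteLoad"]],
        obs_mae_chronic = om[["ChronicLoad"]],
        elapsed = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      data.frame(replicate = r, seed = rep_seeds[r],
                 status = paste("failed:", conditionMessage(e)),
                 pmse = NA_real_, s_pmse = NA_real_, po50 = NA_real_,
                 c = NA_real_, k = NA_integer_, n_stacked = NA_integer_,
                 gee_estimate = NA_real_, gee_se = NA_real_, gee_p = NA_real_,
                 gee_failed = TRUE, abs_err_estimate = NA_real_,
                 abs_err_se = NA_real_, abs_err_p = NA_real_,
                 obs_mae_acute = NA_real_, obs_mae_chronic = NA_real_,
                 elapsed = proc.time()[["elapsed"]] - t0)
    })
    setTimeLimit(elapsed = Inf)
    rows[[r]] <- rec
  }
  out <- list(results = do.call(rbind, rows), reference = reference,
              condition = condition, scenario = scenario)
  if (keep_panels) out$panels <- panels
  out
}

summarize_cell <- function(cell) {
  res <- cell$results
  ok <- res$status == "ok"
  msd <- function(x) {
    x <- x[ok & !is.na(x)]
    if (length(x) == 0L) return(c(NA_real_, NA_real_))
    c(mean(x), stats::sd(x))
  }
  pm <- msd(res$pmse); sp <- msd(res$s_pmse); po <- msd(res$po50)
  ee <- msd(res$abs_err_estimate); es <- msd(res$abs_err_se)
  ep <- msd(res$abs_err_p)
  oa <- msd(res$obs_mae_acute); oc <- msd(res$obs_mae_chronic)
  tt <- msd(res$elapsed)
  data.frame(condition = cell$condition, scenario = cell$scenario,
             n_replicates = nrow(res), n_ok = sum(ok),
             n_gee_failed = sum(res$gee_failed, na.rm = TRUE),
             pmse_mean = pm[1], pmse_sd = pm[2],
             s_pmse_mean = sp[1], s_pmse_sd = sp[2],
             po50_mean = po[1], po50_sd = po[2],
             mae_estimate = ee[1], mae_estimate_sd = ee[2],
             mae_se = es[1], mae_se_sd = es[2],
             mae_p = ep[1], mae_p_sd = ep[2],
             obs_mae_acute = oa[1], obs_mae_acute_sd = oa[2],
             obs_mae_chronic = oc[1], obs_mae_chronic_sd = oc[2],
             time_mean = tt[1], time_sd = tt[2])
}

#' Run the full study
#'
#' Iterates conditions crossed with chronic-load scenarios over the
#' configured panel, summarizing each cell as Mean (SD) rows of the
#' global and specific utility metrics, plus adjacent-pair consistency of
#' the GEE estimate when at least two replicates succeed. When
#' `output_dir` is set, per-replicate tables, the summary (CSV and JSON)
#' and a plain-text log are written there. The whole run is deterministic
#' under `master_seed`.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `summary` (data frame), `cells`
#'   (per-cell replicate tables) and `reference` (the original-panel GEE).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  panel <- study_panel(config)
  reference <- fit_injury_gee(panel)
  set.seed(config$master_seed)
  cell_seeds <- sample.int(.Machine$integer.max,
                           length(config$conditions) * length(config$cl_scenarios))
  log_lines <- character()
  cells <- list()
  summaries <- list()
  i <- 0L
  for (cond in config$conditions) {
    for (scen in config$cl_scenarios) {
      i <- i + 1L
      t0 <- proc.time()[["elapsed"]]
      cell <- run_condition(panel, cond, scen,
                            n_replicates = config$n_replicates,
                            seed = cell_seeds[i], reference = reference,
                            timeout = config$timeout,
                            keep_panels = config$n_replicates >= 2)
      smry <- summarize_cell(cell)
      ok_panels <- cell$panels[cell$results$status == "ok"]
      if (length(ok_panels) >= 2) {
        apc <- tryCatch(
          adjacent_pair_consistency(ok_panels, "gee_estimate"),
          error = function(e) NA_real_)
        smry$adjacent_gee_estimate_mean <- mean(apc, na.rm = TRUE)
      } else {
        smry$adjacent_gee_estimate_mean <- NA_real_
      }
      cell$panels <- NULL
      cells[[paste(cond, scen, sep = ".")]] <- cell
      summaries[[i]] <- smry
      log_lines <- c(log_lines, sprintf(
        "%s | %s/%s: %d/%d ok, %.1f s",
        format(Sys.time(), "%H:%M:%S"), cond, scen,
        smry$n_ok, config$n_replicates, proc.time()[["elapsed"]] - t0))
    }
  }
  summary <- do.call(rbind, summaries)
  out <- list(summary = summary, cells = cells, reference = reference)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(summary, file.path(config$output_dir, "study_summary.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(config$output_dir, "study_summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
    for (nm in names(cells)) {
      utils::write.csv(cells[[nm]]$results,
                       file.path(config$output_dir, paste0("replicates_", nm, ".csv")),
                       row.names = FALSE)
    }
    writeLines(log_lines, file.path(config$output_dir, "study_log.txt"))
  }
  invisible(out)
}

#' Serialize a synthesis plan to a plain list
#'
#' The list form is YAML/JSON friendly and round-trips through
#' [plan_from_list()].
#'
#' @param plan A `synthesis_plan`.
#' @return A plain list.
#' @export
plan_to_list <- function(plan) {
  list(
    cl_scenario = plan$cl_scenario,
    block_weeks = plan$block_weeks,
    condition = attr(plan, "condition"),
    visit_sequence = lapply(plan$visit_sequence, function(s) {
      out <- list(name = s$name, method = s$method)
      if (!is.null(s$predictors)) {
        out$predictors <- mapply(function(n, src) list(name = n, source = src),
                                 s$predictors$name, s$predictors$source,
                                 SIMPLIFY = FALSE, USE.NAMES = FALSE)
      }
      if (!is.null(s$derived_rule)) out$derived_rule <- s$derived_rule
      out
    }))
}

#' Rebuild a synthesis plan from its list form
#'
#' @param x A list as produced by [plan_to_list()].
#' @return A `synthesis_plan`.
#' @export
plan_from_list <- function(x) {
  specs <- lapply(x$visit_sequence, function(s) {
    preds <- NULL
    if (!is.null(s$predictors)) {
      preds <- data.frame(
        name = vapply(s$predictors, `[[`, character(1), "name"),
        source = vapply(s$predictors, `[[`, character(1), "source"))
    }
    variable_spec(s$name, s$method, predictors = preds,
                  derived_rule = s$derived_rule)
  })
  plan <- synthesis_plan(specs, x$cl_scenario, x$block_weeks)
  attr(plan, "condition") <- x$condition
  plan
}

#' Write the release sheet for a synthesis plan
#'
#' Produces the human-readable documentation that should accompany any
#' released synthetic panel: every variable with its method, predictors
#' and their original/synthetic source, the chronic-load scenario and
#' derivation rule, CART hyperparameters, the utility summary when
#' available, a limitations section stating what analyses the synthetic
#' panels do and do not support, and a machine-readable YAML block from
#' which the plan can be rebuilt exactly.
#'
#' @param plan A `synthesis_plan`.
#' @param summary Optional study summary data frame ([run_study()]).
#' @param notes Optional character vector of free-text notes.
#' @param control The [tree_control()] used for generation.
#' @param path Optional output file; the text is returned either way.
#' @return The sheet as a character vector of lines, invisibly if `path`
#'   is given.
#' @export
make_release_sheet <- function(plan, summary = NULL, notes = NULL,
                               control = tree_control(), path = NULL) {
  cond <- attr(plan, "condition")
  lines <- c(
    "# Synthetic panel release sheet",
    "",
    sprintf("Condition: %s", if (is.null(cond)) "(custom plan)" else cond),
    sprintf("Chronic-load scenario: %s", plan$cl_scenario),
    if (plan$cl_scenario == "calculated") sprintf(
      "Chronic-load derivation: uncoupled trailing mean of synthetic acute load over the %d weeks preceding each week (%d-week block excluding the acute week)",
      plan$block_weeks - 1L, plan$block_weeks),
    "",
    "## Variables and generation methods",
    "")
  for (s in plan$visit_sequence) {
    desc <- switch(s$method,
      fixed = "fixed (copied from the original data, never synthesized)",
      random_sample = "random sample with replacement from the observed marginal",
      derived = sprintf("derived by rule '%s'", s$derived_rule),
      cart = sprintf("CART leaf-donor sampling on {%s}",
                     paste(sprintf("%s(%s)", s$predictors$name,
                                   s$predictors$source), collapse = ", ")))
    lines <- c(lines, sprintf("- %s: %s", s$name, desc))
  }
  lines <- c(lines, "",
    "## CART hyperparameters",
    "",
    sprintf("- min_leaf: %d; min_split: %d; complexity: %g; max_depth: %s",
            control$min_leaf, control$min_split, control$complexity,
            if (is.finite(control$max_depth))
              as.character(control$max_depth) else "none"))
  if (!is.null(summary)) {
    lines <- c(lines, "", "## Utility summary (Mean (SD) across replicates)", "")
    for (i in seq_len(nrow(summary))) {
      s <- summary[i, ]
      lines <- c(lines, sprintf(
        "- %s / %s: pMSE %.4g (%.2g), s-pMSE %.3g (%.2g), PO50 %.3g (%.2g), GEE-estimate MAE %.3g (%.2g)",
        s$condition, s$scenario, s$pmse_mean, s$pmse_sd, s$s_pmse_mean,
        s$s_pmse_sd, s$po50_mean, s$po50_sd, s$mae_estimate, s$mae_estimate_sd))
    }
  }
  synthesized <- vapply(plan$visit_sequence, function(s) s$method != "fixed",
                        logical(1))
  syn_names <- vapply(plan$visit_sequence[synthesized], `[[`, character(1), "name")
  fix_names <- vapply(plan$visit_sequence[!synthesized], `[[`, character(1), "name")
  lines <- c(lines, "",
    "## Limitations",
    "",
    sprintf("- Synthesized variables: %s. Analyses conditioning only on these and on the fixed variables (%s) through the listed predictors are the intended use.",
            paste(syn_names, collapse = ", "),
            if (length(fix_names)) paste(fix_names, collapse = ", ") else "none"),
    "- Relationships not encoded in the conditioning sets (e.g. temporal structure absent from the predictors) are not preserved and must not be analysed from these panels.",
    "- Synthetic panels support hypothesis framing only; findings must be verified on the original data.")
  if (!is.null(notes)) lines <- c(lines, "", "## Notes", "", paste("-", notes))
  lines <- c(lines, "",
    "## Machine-readable plan",
    "",
    "```yaml",
    strsplit(yaml::as.yaml(plan_to_list(plan)), "\n")[[1]],
    "```")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Parse the machine-readable block of a release sheet
#'
#' @param lines Release-sheet text (character vector) or a file path.
#' @return The embedded `synthesis_plan`.
#' @export
read_release_sheet_plan <- function(lines) {
  if (length(lines) == 1L && file.exists(lines)) lines <- readLines(lines)
  open <- which(lines == "```yaml")
  close <- which(lines == "```")
  close <- close[close > open[1]][1]
  if (length(open) == 0L || is.na(close)) stop("no machine-readable block found")
  plan_from_list(yaml::yaml.load(paste(lines[(open[1] + 1L):(close - 1L)],
                                       collapse = "\n")))
}
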