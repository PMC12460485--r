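LAG_VARIABLES <- c("AL_Lag1", "AL_Lag2", "AL_Lag3",
                   "CL_Lag1", "CL_Lag2", "CL_Lag3")

CONDITION_NAMES <- c("base", "base_week", "time_lag_1wk", "time_lag_3wks",
                     "time_lag_injury", "injury_time_lag", "no_playerid")

#' Specification of one variable in a synthesis plan
#'
#' Each variable in the visit sequence is handled by one method:
#' `"fixed"` (copied from the original data, usable as a predictor but
#' never synthesized), `"cart"` (synthesized by tree fitting and leaf
#' donor sampling, conditional on the listed predictors), `"random_sample"`
#' (i.i.d. draws with replacement from the observed marginal) or
#' `"derived"` (recomputed by a named deterministic rule, currently
#' `"chronic_from_acute"`). Each CART predictor carries a source:
#' `"original"` predictors feed observed values at generation time (the
#' starred, not-synthesized variables), `"synthetic"` predictors feed the
#' values synthesized earlier in the sequence.
#'
#' @param name Variable (column) name.
#' @param method One of `"fixed"`, `"cart"`, `"random_sample"`, `"derived"`.
#' @param predictors For `"cart"`: data frame with columns `name` and
#'   `source`, or a character vector of names (sources defaulting to
#'   `"original"`).
#' @param derived_rule For `"derived"`: the rule name.
#' @return A `variable_spec` list.
#' @export
variable_spec <- function(name,
                          method = c("fixed", "cart", "random_sample", "derived"),
                          predictors = NULL, derived_rule = NULL) {
  method <- match.arg(method)
  if (method == "cart") {
    if (is.character(predictors)) {
      predictors <- data.frame(name = predictors, source = "original")
    }
    if (is.null(predictors) || nrow(predictors) < 1L) {
      stop("cart variables need at least one predictor")
    }
    if (!all(predictors$source %in% c("original", "synthetic"))) {
      stop("predictor source must be 'original' or 'synthetic'")
    }
  } else if (method %in% c("fixed", "random_sample")) {
    if (!is.null(predictors) && nrow(as.data.frame(predictors)) > 0L) {
      stop(method, " variables take no predictors")
    }
    predictors <- NULL
  } else if (method == "derived") {
    if (is.null(derived_rule)) stop("derived variables must name a rule")
    predictors <- NULL
  }
  structure(list(name = name, method = method, predictors = predictors,
                 derived_rule = derived_rule),
            class = "variable_spec")
}

#' Assemble a synthesis plan
#'
#' A plan is an ordered visit sequence of [variable_spec()]s plus the
#' chronic-load scenario: `"independent"` synthesizes chronic load as its
#' own variable; `"calculated"` recomputes it deterministically from the
#' synthetic acute load.
#'
#' @param visit_sequence List of [variable_spec()]s, in synthesis order.
#' @param cl_scenario `"independent"` or `"calculated"`.
#' @param block_weeks Chronic-load block used by the derivation rule.
#' @return A `synthesis_plan` object.
#' @export
synthesis_plan <- function(visit_sequence,
                           cl_scenario = c("independent", "calculated"),
                           block_weeks = 4) {
  cl_scenario <- match.arg(cl_scenario)
  stopifnot(all(vapply(visit_sequence, inherits, logical(1), "variable_spec")))
  nm <- vapply(visit_sequence, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("exactly one spec per variable is allowed")
  structure(list(visit_sequence = visit_sequence, cl_scenario = cl_scenario,
                 block_weeks = block_weeks),
            class = "synthesis_plan")
}

#' Build one of the named simulation conditions
#'
#' Encodes the seven predictor-specification conditions of the study
#' design. In every condition the starred variables are fixed (copied,
#' original-source predictors) and acute load is synthesized by CART;
#' chronic load is either CART-synthesized conditional on the synthetic
#' acute load (`cl_scenario = "independent"`) or recomputed from it
#' (`"calculated"`):
#'
#' * `base`: acute load from \{Injury*, PlayerID*\}; chronic load adds the
#'   synthetic acute load.
#' * `base_week`: `base` with WeekID* added to both conditioning sets.
#' * `time_lag_1wk`: WeekID replaced by the original-source 1-step lags of
#'   acute and chronic load.
#' * `time_lag_3wks`: as above with 1-, 2- and 3-step lag pairs.
#' * `time_lag_injury`: the `time_lag_3wks` predictors without Injury;
#'   Injury is synthesized last by CART on \{PlayerID*, lags*, synthetic
#'   acute and chronic load\}.
#' * `injury_time_lag`: Injury synthesized first as a random sample; loads
#'   as in `time_lag_injury`.
#' * `no_playerid`: `time_lag_injury` with PlayerID removed everywhere.
#'
#' @param name Condition name (see above).
#' @param cl_scenario Chronic-load scenario.
#' @param block_weeks Chronic block for the `"calculated"` derivation.
#' @return A `synthesis_plan`.
#' @export
build_condition <- function(name, cl_scenario = c("independent", "calculated"),
                            block_weeks = 4) {
  cl_scenario <- match.arg(cl_scenario)
  if (!name %in% CONDITION_NAMES) {
    stop("unknown condition '", name, "'; valid conditions: ",
         paste(CONDITION_NAMES, collapse = ", "))
  }
  orig <- function(nms) data.frame(name = nms, source = "original")
  syn <- function(nms) data.frame(name = nms, source = "synthetic")
  cl_spec <- function(al_preds) {
    if (cl_scenario == "calculated") {
      variable_spec("ChronicLoad", "derived", derived_rule = "chronic_from_acute")
    } else {
      variable_spec("ChronicLoad", "cart",
                    predictors = rbind(al_preds, syn("AcuteLoad")))
    }
  }
  fixed <- function(nms) lapply(nms, variable_spec, method = "fixed")

  seqs <- switch(name,
    base = {
      al_preds <- orig(c("Injury", "PlayerID"))
      c(fixed(c("Injury", "PlayerID")),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds)))
    },
    base_week = {
      al_preds <- orig(c("Injury", "PlayerID", "WeekID"))
      c(fixed(c("Injury", "PlayerID", "WeekID")),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds)))
    },
    time_lag_1wk = {
      lags <- c("AL_Lag1", "CL_Lag1")
      al_preds <- orig(c("Injury", "PlayerID", lags))
      c(fixed(c("Injury", "PlayerID", lags)),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds)))
    },
    time_lag_3wks = {
      al_preds <- orig(c("Injury", "PlayerID", LAG_VARIABLES))
      c(fixed(c("Injury", "PlayerID", LAG_VARIABLES)),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds)))
    },
    time_lag_injury = {
      al_preds <- orig(c("PlayerID", LAG_VARIABLES))
      c(fixed(c("PlayerID", LAG_VARIABLES)),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds),
             variable_spec("Injury", "cart",
                           predictors = rbind(al_preds,
                                              syn(c("AcuteLoad", "ChronicLoad"))))))
    },
    injury_time_lag = {
      al_preds <- orig(c("PlayerID", LAG_VARIABLES))
      c(list(variable_spec("Injury", "random_sample")),
        fixed(c("PlayerID", LAG_VARIABLES)),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds)))
    },
    no_playerid = {
      al_preds <- orig(LAG_VARIABLES)
      c(fixed(LAG_VARIABLES),
        list(variable_spec("AcuteLoad", "cart", predictors = al_preds),
             cl_spec(al_preds),
             variable_spec("Injury", "cart",
                           predictors = rbind(al_preds,
                                              syn(c("AcuteLoad", "ChronicLoad"))))))
    })
  plan <- synthesis_plan(seqs, cl_scenario, block_weeks)
  attr(plan, "condition") <- name
  plan
}

#' Validate a plan against a panel
#'
#' Checks the plan invariants without throwing: every synthetic-source
#' predictor must be synthesized earlier in the visit sequence; every
#' original-source predictor must exist as a panel column; variables are
#' unique. Returns all problems at once.
#'
#' @param plan A `synthesis_plan`.
#' @param panel A monitoring panel.
#' @return List with `valid` (logical) and `problems` (character vector).
#' @export
validate_plan <- function(plan, panel) {
  problems <- character()
  synthesized_so_far <- character()
  for (spec in plan$visit_sequence) {
    if (spec$method == "cart") {
      for (i in seq_len(nrow(spec$predictors))) {
        pname <- spec$predictors$name[i]
        psource <- spec$predictors$source[i]
        if (psource == "synthetic") {
          if (!pname %in% synthesized_so_far) {
            problems <- c(problems, paste0(
              "ordering violation: '", spec$name, "' conditions on synthetic '",
              pname, "' which is not synthesized earlier in the sequence"))
          }
        } else if (!pname %in% names(panel)) {
          problems <- c(problems, paste0(
            "missing-column violation: predictor '", pname,
            "' for '", spec$name, "' is not a panel column"))
        }
      }
    }
    if (!spec$name %in% names(panel) && spec$method != "fixed") {
      problems <- c(problems, paste0("missing-column violation: variable '",
                                     spec$name, "' is not a panel column"))
    }
    if (spec$method %in% c("cart", "random_sample", "derived")) {
      synthesized_so_far <- c(synthesized_so_far, spec$name)
    }
  }
  list(valid = length(problems) == 0L, problems = problems)
}

#' Sequentially synthesize a panel
#'
#' Iterates the plan's visit sequence over a copy of the panel. Fixed
#' variables are left untouched; `random_sample` variables are redrawn
#' i.i.d. from the observed marginal; `cart` variables are synthesized by
#' fitting a tree of the observed response on the observed predictor
#' values (rows with any missing value excluded from fitting) and then
#' donor-sampling with original-source columns taken from the input panel
#' and synthetic-source columns from the values generated earlier in the
#' sequence; `derived` variables are recomputed from the synthetic values
#' by their rule. Rows whose generation-time predictors are missing (the
#' first weeks of each player, for lag predictors) receive draws from the
#' observed marginal of the response over those same row positions; rows
#' whose observed response is missing stay missing, so original and
#' synthetic panels drop identical rows downstream. The output has the
#' same shape, ordering and fixed columns as the input and is reproducible
#' from `seed`.
#'
#' @param panel A monitoring panel (with lag columns when the plan needs
#'   them).
#' @param plan A `synthesis_plan`.
#' @param seed Optional integer seed applied before generation.
#' @param control [tree_control()] hyperparameters for CART fitting.
#' @param proper Use proper (bootstrap-donor) synthesis in CART draws?
#' @return The synthetic panel.
#' @export
synthesize <- function(panel, plan, seed = NULL, control = tree_control(),
                       proper = FALSE) {
  validate_panel(panel)
  chk <- validate_plan(plan, panel)
  if (!chk$valid) {
    stop("invalid plan:\n  ", paste(chk$problems, collapse = "\n  "))
  }
  if (!is.null(seed)) set.seed(seed)
  out <- panel
  for (spec in plan$visit_sequence) {
    switch(spec$method,
      fixed = NULL,
      random_sample = {
        obs <- panel[[spec$name]]
        pool <- obs[!is.na(obs)]
        vals <- pool[sample.int(length(pool), nrow(panel), replace = TRUE)]
        vals[is.na(obs)] <- obs[is.na(obs)]
        out[[spec$name]] <- vals
      },
      derived = {
        if (spec$derived_rule != "chronic_from_acute") {
          stop("unknown derived rule '", spec$derived_rule,
               "' for variable '", spec$name, "'")
        }
        out <- derive_chronic_load(out, block_weeks = plan$block_weeks,
                                   uncoupled = TRUE)
      },
      cart = {
        res <- tryCatch(
          synthesize_cart_variable(panel, out, spec, control, proper),
          error = function(e) {
            stop("synthesis of '", spec$name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
          })
        out[[spec$name]] <- res
      })
  }
  out
}

synthesize_cart_variable <- function(panel, out, spec, control, proper) {
  y_obs <- panel[[spec$name]]
  kind <- if (spec$name == "Injury" || is.factor(y_obs)) "categorical"
          else "continuous"
  fit_X <- panel[, spec$predictors$name, drop = FALSE]
  fit_rows <- !is.na(y_obs) & stats::complete.cases(fit_X)
  if (sum(fit_rows) < control$min_leaf) {
    stop("too few complete rows to fit a tree")
  }
  tree <- fit_tree(fit_X[fit_rows, , drop = FALSE], y_obs[fit_rows],
                   kind = kind, control = control)
  gen_X <- fit_X
  from_syn <- spec$predictors$name[spec$predictors$source == "synthetic"]
  for (v in from_syn) gen_X[[v]] <- out[[v]]
  gen_ok <- stats::complete.cases(gen_X) & !is.na(y_obs)
  vals <- y_obs
  if (any(gen_ok)) {
    vals[gen_ok] <- synthesize_variable(tree, gen_X[gen_ok, , drop = FALSE],
                                        proper = proper)
  }
  # incomplete-predictor rows with an observed response: marginal draw
  # from the observed response over the same row positions
  partial <- !gen_ok & !is.na(y_obs)
  if (any(partial)) {
    pool <- y_obs[partial]
    vals[partial] <- pool[sample.int(length(pool), sum(partial), replace = TRUE)]
  }
  vals
}
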