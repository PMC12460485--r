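#' Specific utility: MAE of replicated GEE results
#'
#' Mean absolute error of the ACWR log-odds estimate, its standard error
#' and its p-value across replicate synthetic-data GEE fits, relative to
#' the reference fit on the original panel. Failed replicates (e.g. GEE
#' fits on degenerate synthetic panels) may be passed as `NULL` entries;
#' they are excluded and counted, never imputed.
#'
#' @param reference A `gee_result` from [fit_injury_gee()] on the
#'   original panel.
#' @param replicates List of `gee_result`s (or `NULL` for failures).
#' @return A `specific_utility_report` list with `mae_estimate`,
#'   `mae_se`, `mae_p` (each with an `sd_*` companion across replicates),
#'   `n_replicates` (successful) and `n_failed`.
#' @export
specific_utility_mae <- function(reference, replicates) {
  stopifnot(inherits(reference, "gee_result"))
  ok <- vapply(replicates, inherits, logical(1), "gee_result")
  if (!any(ok)) stop("no successful replicates")
  succ <- replicates[ok]
  abs_err <- function(field) {
    vapply(succ, function(r) abs(r[[field]] - reference[[field]]), numeric(1))
  }
  e <- abs_err("estimate"); s <- abs_err("se"); p <- abs_err("p")
  structure(list(mae_estimate = mean(e), sd_estimate = stats::sd(e),
                 mae_se = mean(s), sd_se = stats::sd(s),
                 mae_p = mean(p), sd_p = stats::sd(p),
                 n_replicates = length(succ),
                 n_failed = sum(!ok)),
            class = "specific_utility_report")
}

#' Observation-level MAE between aligned panels
#'
#' Mean absolute difference per variable over rows aligned by
#' (player, week), restricted to rows where both values are present.
#' Detects how well a synthetic panel retains individual player-week
#' values (e.g. temporal training-load trends), complementing the
#' analysis-level specific utility.
#'
#' @param original,synthetic Panels with identical (player, week) keys.
#' @param variables Columns to compare.
#' @return Named numeric vector of MAEs (load units).
#' @export
observation_mae <- function(original, synthetic,
                            variables = c("AcuteLoad", "ChronicLoad")) {
  key_o <- paste(original$PlayerID, original$WeekID)
  key_s <- paste(synthetic$PlayerID, synthetic$WeekID)
  if (!identical(key_o, key_s)) {
    bad <- union(setdiff(key_o, key_s), setdiff(key_s, key_o))
    if (length(bad) == 0L) bad <- "(same keys, different order)"
    stop("player-week index mismatch: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  vapply(variables, function(v) {
    d <- abs(synthetic[[v]] - original[[v]])
    mean(d, na.rm = TRUE)
  }, numeric(1))
}

#' Consistency of adjacent synthetic replicates
#'
#' Applies a two-panel metric to consecutive pairs of an ordered list of
#' synthetic panels — (1,2), (2,3), ..., (R-1,R) — to gauge the
#' variability of the generation process itself, independent of the
#' original data. For reference-based metrics the first panel of each
#' pair plays the reference role.
#'
#' @param panels Ordered list of at least two panels.
#' @param metric Function of two panels returning a numeric scalar, or a
#'   built-in name: `"gee_estimate"`, `"gee_se"`, `"gee_p"` (absolute
#'   difference of [fit_injury_gee()] fields) or `"obs_mae_acute"`,
#'   `"obs_mae_chronic"` (observation-level MAE of the load columns).
#' @return Numeric vector of length `length(panels) - 1`.
#' @export
adjacent_pair_consistency <- function(panels, metric = "gee_estimate") {
  if (length(panels) < 2L) stop("need at least 2 panels")
  if (is.character(metric)) {
    metric <- switch(metric,
      gee_estimate = function(a, b) {
        abs(fit_injury_gee(b)$estimate - fit_injury_gee(a)$estimate)
      },
      gee_se = function(a, b) abs(fit_injury_gee(b)$se - fit_injury_gee(a)$se),
      gee_p = function(a, b) abs(fit_injury_gee(b)$p - fit_injury_gee(a)$p),
      obs_mae_acute = function(a, b) {
        unname(observation_mae(a, b, "AcuteLoad"))
      },
      obs_mae_chronic = function(a, b) {
        unname(observation_mae(a, b, "ChronicLoad"))
      },
      stop("unknown metric name"))
  }
  vapply(seq_len(length(panels) - 1L), function(i) {
    metric(panels[[i]], panels[[i + 1L]])
  }, numeric(1))
}
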