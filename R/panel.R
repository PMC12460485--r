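#' Monitoring panels
#'
#' A monitoring panel is a long-format data frame with one row per
#' player-week and the five core columns `PlayerID` (factor), `WeekID`
#' (positive integer), `AcuteLoad` (non-negative weekly load), `ChronicLoad`
#' (multi-week average of acute load, possibly missing in early weeks) and
#' `Injury` (0/1). Derived columns (`AL_Lag1` ... `CL_Lag3`, `ACWR`) are
#' appended after the core five. Rows are kept sorted by (player, week) and
#' (player, week) pairs are unique.
#'
#' @name monitoring-panel
#' @keywords internal
NULL

PANEL_CORE_COLUMNS <- c("PlayerID", "WeekID", "AcuteLoad", "ChronicLoad", "Injury")

#' Validate a monitoring panel
#'
#' Checks the panel invariants: core columns present, unique
#' (player, week) keys, 1-based positive integer weeks, non-negative acute
#' load and strictly binary injury indicator. Missing values are allowed in
#' `ChronicLoad` (incomplete early windows) but not in the other core
#' columns.
#'
#' @param panel A data frame with the core columns.
#' @param require_sorted Require rows sorted by (player, week)?
#' @return The panel, invisibly, if valid. Otherwise an error is thrown
#'   describing the first violated invariant.
#' @export
validate_panel <- function(panel, require_sorted = TRUE) {
  if (!is.data.frame(panel)) stop("panel must be a data frame")
  missing_cols <- setdiff(PANEL_CORE_COLUMNS, names(panel))
  if (length(missing_cols) > 0L) {
    stop("panel is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(panel$PlayerID) || anyNA(panel$WeekID)) {
    stop("PlayerID and WeekID must not be missing")
  }
  if (any(panel$WeekID < 1) || any(panel$WeekID != round(panel$WeekID))) {
    stop("WeekID must be a positive integer (1-based weeks)")
  }
  key <- paste(panel$PlayerID, panel$WeekID)
  if (anyDuplicated(key)) {
    stop("duplicated (PlayerID, WeekID) pair at row ", which(duplicated(key))[1L])
  }
  bad_injury <- which(!(panel$Injury %in% c(0, 1)))
  if (length(bad_injury) > 0L) {
    stop("Injury must be 0 or 1; invalid value at row ", bad_injury[1L])
  }
  if (anyNA(panel$AcuteLoad)) stop("AcuteLoad must not be missing")
  if (any(panel$AcuteLoad < 0)) stop("AcuteLoad must be non-negative")
  if (require_sorted) {
    ord <- order(panel$PlayerID, panel$WeekID)
    if (!identical(ord, seq_len(nrow(panel)))) {
      stop("panel rows must be sorted by (PlayerID, WeekID)")
    }
  }
  invisible(panel)
}

#' Read a monitoring panel from CSV
#'
#' Expects a comma-separated file with a header row naming at least the
#' five core columns. Extra columns are preserved. Empty fields are read as
#' missing. Rows are sorted by (player, week) and the panel invariants are
#' checked.
#'
#' @param path Path to a CSV file.
#' @return A validated monitoring panel data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(PANEL_CORE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ", paste(missing_cols, collapse = ", "),
         " in ", path)
  }
  raw$PlayerID <- factor(raw$PlayerID)
  raw$WeekID <- as.integer(raw$WeekID)
  raw <- raw[order(raw$PlayerID, raw$WeekID), , drop = FALSE]
  rownames(raw) <- NULL
  extra <- setdiff(names(raw), PANEL_CORE_COLUMNS)
  raw <- raw[, c(PANEL_CORE_COLUMNS, extra), drop = FALSE]
  validate_panel(raw)
  raw
}

#' Write a monitoring panel to CSV
#'
#' Core columns come first, derived columns after; missing cells are
#' written as empty fields so `read_panel(write_panel(p))` round-trips the
#' panel up to floating-point formatting.
#'
#' @param panel A monitoring panel.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  extra <- setdiff(names(panel), PANEL_CORE_COLUMNS)
  out <- panel[, c(PANEL_CORE_COLUMNS, extra), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Derive chronic load from acute load
#'
#' Recomputes `ChronicLoad` per player, in week order, as a trailing mean
#' of `AcuteLoad` over a `block_weeks`-week block. With `uncoupled = TRUE`
#' (the default) the current week is excluded, so the default 4-week block
#' averages the 3 weeks strictly before week t. With `uncoupled = FALSE`
#' the block includes the current week (t down to t - block_weeks + 1).
#' Weeks without a full window get a missing chronic load. Windows never
#' cross player boundaries and are taken over the player's consecutive
#' sorted weeks.
#'
#' @param panel A monitoring panel.
#' @param block_weeks Length of the chronic block in weeks (>= 2).
#' @param uncoupled Exclude the acute week from the averaging window?
#' @return The panel with `ChronicLoad` replaced by the derived values.
#' @export
derive_chronic_load <- function(panel, block_weeks = 4, uncoupled = TRUE) {
  validate_panel(panel)
  if (block_weeks < 2) stop("block_weeks must be >= 2")
  window <- if (uncoupled) block_weeks - 1L else block_weeks
  offset <- if (uncoupled) 1L else 0L
  cl <- rep(NA_real_, nrow(panel))
  for (idx in split(seq_len(nrow(panel)), panel$PlayerID, drop = TRUE)) {
    al <- panel$AcuteLoad[idx]
    n <- length(al)
    cs <- cumsum(al)
    # mean of al[(t - offset - window + 1) : (t - offset)] when fully inside
    for (t in seq_len(n)) {
      hi <- t - offset
      lo <- hi - window + 1L
      if (lo >= 1L) {
        cl[idx[t]] <- (cs[hi] - if (lo > 1L) cs[lo - 1L] else 0) / window
      }
    }
  }
  panel$ChronicLoad <- cl
  panel
}

#' Add lagged predictor columns
#'
#' For each named variable, adds columns holding the value k weeks earlier
#' within the same player, for k = 1..`max_lag`. The first k weeks of each
#' player are missing. Column names follow the panel convention:
#' `AcuteLoad` lags become `AL_Lag1` ... and `ChronicLoad` lags `CL_Lag1`
#' ...; any other variable `x` becomes `x_Lag1` ....
#'
#' @param panel A monitoring panel.
#' @param variables Names of columns to lag.
#' @param max_lag Largest lag, in weeks (>= 1).
#' @return The panel with lag columns appended.
#' @export
add_lag_features <- function(panel,
                             variables = c("AcuteLoad", "ChronicLoad"),
                             max_lag = 3) {
  validate_panel(panel)
  if (max_lag < 1) stop("max_lag must be >= 1")
  unknown <- setdiff(variables, names(panel))
  if (length(unknown) > 0L) {
    stop("unknown variable(s): ", paste(unknown, collapse = ", "))
  }
  prefix <- function(v) switch(v, AcuteLoad = "AL_Lag", ChronicLoad = "CL_Lag",
                               paste0(v, "_Lag"))
  groups <- split(seq_len(nrow(panel)), panel$PlayerID, drop = TRUE)
  for (v in variables) {
    x <- panel[[v]]
    for (k in seq_len(max_lag)) {
      lagged <- rep(NA_real_, nrow(panel))
      for (idx in groups) {
        n <- length(idx)
        if (n > k) lagged[idx[(k + 1L):n]] <- x[idx[1L:(n - k)]]
      }
      panel[[paste0(prefix(v), k)]] <- lagged
    }
  }
  panel
}

#' Compute the acute:chronic workload ratio
#'
#' Adds (or replaces) an `ACWR` column equal to `AcuteLoad / ChronicLoad`
#' where the chronic load is present and strictly positive, and missing
#' otherwise, so downstream regression design matrices stay finite.
#'
#' @param panel A monitoring panel with `AcuteLoad` and `ChronicLoad`.
#' @return The panel with an `ACWR` column.
#' @export
compute_acwr <- function(panel) {
  validate_panel(panel)
  ok <- !is.na(panel$ChronicLoad) & panel$ChronicLoad > 0
  acwr <- rep(NA_real_, nrow(panel))
  acwr[ok] <- panel$AcuteLoad[ok] / panel$ChronicLoad[ok]
  panel$ACWR <- acwr
  panel
}
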