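DEFAULT_PROPENSITY_PREDICTORS <- c("WeekID", "AcuteLoad", "ChronicLoad", "Injury")

#' Fit the propensity model on a stacked original/synthetic table
#'
#' Stacks the two panels with an indicator (1 = synthetic), keeps rows
#' complete on the listed predictors, drops zero-variance predictors, and
#' fits a main-effects logistic regression of the indicator on the
#' predictors. By default the propensity design uses the numeric core
#' variables; set `include_player = TRUE` to add `PlayerID` (one dummy
#' per level, enlarging `k`). If the fit separates (fitted probabilities
#' numerically 0/1 or non-convergence) a weakly ridge-penalized logistic
#' fit is used instead and the result is flagged.
#'
#' @param original,synthetic Monitoring panels sharing a schema.
#' @param predictors Character vector of predictor column names.
#' @param include_player Add `PlayerID` to the predictors?
#' @return List with `probabilities`, `labels`, `c` (synthetic fraction),
#'   `k` (fitted parameters incl. intercept), `n_stacked`, `separation`
#'   flag and `dropped` predictors.
#' @export
fit_propensity <- function(original, synthetic,
                           predictors = DEFAULT_PROPENSITY_PREDICTORS,
                           include_player = FALSE) {
  if (include_player) predictors <- union(predictors, "PlayerID")
  for (p in predictors) {
    if (!p %in% names(original) || !p %in% names(synthetic)) {
      stop("predictor '", p, "' missing from a panel")
    }
  }
  stack <- rbind(
    cbind(original[, predictors, drop = FALSE], .synthetic = 0L),
    cbind(synthetic[, predictors, drop = FALSE], .synthetic = 1L))
  stack <- stack[stats::complete.cases(stack[, predictors, drop = FALSE]), ,
                 drop = FALSE]
  dropped <- character()
  for (p in predictors) {
    x <- stack[[p]]
    degenerate <- if (is.factor(x) || is.character(x)) {
      length(unique(as.character(x))) < 2L
    } else {
      stats::var(as.numeric(x)) == 0
    }
    if (degenerate) dropped <- c(dropped, p)
  }
  use <- setdiff(predictors, dropped)
  labels <- stack$.synthetic
  n <- nrow(stack)
  c_frac <- mean(labels)
  if (length(use) == 0L) {
    return(list(probabilities = rep(c_frac, n), labels = labels, c = c_frac,
                k = 1L, n_stacked = n, separation = FALSE, dropped = dropped))
  }
  X <- stats::model.matrix(~ ., data = stack[, use, drop = FALSE])
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, labels, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
      }
      invokeRestart("muffleWarning")
    })
  if (!fit$converged) separated <- TRUE
  if (separated) {
    beta <- ridge_logit(X, labels, lambda = 1e-2)
    prob <- stats::plogis(drop(X %*% beta))
    k <- ncol(X)
  } else {
    prob <- fit$fitted.values
    k <- sum(!is.na(fit$coefficients))
  }
  list(probabilities = prob, labels = labels, c = c_frac, k = k,
       n_stacked = n, separation = separated, dropped = dropped,
       design = X)
}

# ridge-penalized logistic regression by IRLS (intercept unpenalized);
# bounded-coefficient fallback for separated propensity fits
ridge_logit <- function(X, y, lambda = 1e-2, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  pen <- diag(rep(lambda, p)); pen[1, 1] <- 0
  beta <- rep(0, p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * w, X) + pen
    delta <- solve(H, z)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) break
  }
  beta
}

#' Propensity-score global utility metrics
#'
#' From fitted propensity scores on the stacked table: `pmse` is the mean
#' squared deviation of the scores from the synthetic fraction `c`;
#' `s_pmse` standardizes it by its expectation under the null of
#' indistinguishability, `(k - 1) (1 - c)^2 c / N`, so a well-fitting
#' synthesis gives values near 1; `po50` is the percentage of stacked
#' rows correctly classified at the 0.5 threshold, minus 50 (ties count
#' half-correct), so 0 is ideal.
#'
#' @param probabilities Fitted propensity scores in \[0, 1\].
#' @param labels 0/1 indicator (1 = synthetic).
#' @param c Synthetic fraction of the stack.
#' @param k Number of propensity-model parameters including intercept.
#' @return A `global_utility_report` list with `pmse`, `s_pmse`, `po50`,
#'   `c`, `k`, `n_stacked`.
#' @export
compute_global_utility <- function(probabilities, labels, c, k) {
  stopifnot(all(probabilities >= 0 & probabilities <= 1),
            all(labels %in% c(0, 1)))
  n <- length(probabilities)
  pmse <- mean((probabilities - c)^2)
  s_pmse <- if (k <= 1L) NA_real_ else pmse / ((k - 1) * (1 - c)^2 * c / n)
  correct <- sum(probabilities > 0.5 & labels == 1) +
    sum(probabilities < 0.5 & labels == 0) + 0.5 * sum(probabilities == 0.5)
  structure(list(pmse = pmse, s_pmse = s_pmse,
                 po50 = 100 * correct / n - 50,
                 c = c, k = k, n_stacked = n),
            class = "global_utility_report")
}

#' Global utility of a synthetic panel
#'
#' Convenience wrapper: fits the propensity model on the stacked panels
#' and computes pMSE, s-pMSE and PO50. `standardization = "expected_null"`
#' (the default, recorded in the report) divides pMSE by its closed-form
#' null expectation; `"permutation"` instead reports a z-score of pMSE
#' against a label-permutation null with `n_perm` refits.
#'
#' @param original,synthetic Monitoring panels.
#' @param predictors Propensity predictors.
#' @param include_player Add `PlayerID` dummies to the propensity design?
#' @param standardization `"expected_null"` or `"permutation"`.
#' @param n_perm Permutation count for the permutation null.
#' @return A `global_utility_report` with additional fields `separation`,
#'   `dropped` and `standardization`.
#' @export
global_utility <- function(original, synthetic,
                           predictors = DEFAULT_PROPENSITY_PREDICTORS,
                           include_player = FALSE,
                           standardization = c("expected_null", "permutation"),
                           n_perm = 50) {
  standardization <- match.arg(standardization)
  prop <- fit_propensity(original, synthetic, predictors, include_player)
  rep <- compute_global_utility(prop$probabilities, prop$labels, prop$c, prop$k)
  if (standardization == "permutation") {
    if (is.null(prop$design)) stop("permutation null needs a fitted design")
    null_pmse <- replicate(n_perm, {
      perm <- sample(prop$labels)
      pf <- suppressWarnings(
        stats::glm.fit(prop$design, perm, family = stats::binomial()))
      mean((pf$fitted.values - prop$c)^2)
    })
    rep$s_pmse <- (rep$pmse - mean(null_pmse)) / stats::sd(null_pmse)
  }
  rep$separation <- prop$separation
  rep$dropped <- prop$dropped
  rep$standardization <- standardization
  rep
}
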