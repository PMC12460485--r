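#' Tree hyperparameters
#'
#' Stopping and complexity controls for [fit_tree()]. Defaults follow the
#' conventional CART defaults for synthesis engines: at least 5 records
#' per leaf, at least 10 to attempt a split, a near-zero relative
#' complexity threshold, and no depth cap.
#'
#' @param min_leaf Minimum records per leaf (>= 1).
#' @param min_split Minimum records in a node to attempt a split
#'   (>= 2 * min_leaf).
#' @param complexity Minimum impurity decrease to accept a split, as a
#'   fraction of the root impurity.
#' @param max_depth Optional depth cap (root has depth 0); `Inf` for none.
#' @return A `tree_control` list.
#' @export
tree_control <- function(min_leaf = 5, min_split = 10,
                         complexity = 1e-8, max_depth = Inf) {
  if (min_leaf < 1) stop("min_leaf must be >= 1")
  if (min_split < 2 * min_leaf) stop("min_split must be >= 2 * min_leaf")
  if (complexity < 0) stop("complexity must be >= 0")
  structure(list(min_leaf = min_leaf, min_split = min_split,
                 complexity = complexity, max_depth = max_depth),
            class = "tree_control")
}

node_impurity <- function(y, kind) {
  m <- length(y)
  if (kind == "continuous") {
    sum(y^2) - sum(y)^2 / m
  } else {
    counts <- tabulate(y, attr(y, "n_class"))
    m - sum(counts^2) / m
  }
}

# Best split of a node on one numeric vector x. Returns NULL or
# list(dec, i, threshold). Tie among thresholds -> smallest threshold.
best_numeric_split <- function(x, y, kind, min_leaf) {
  m <- length(x)
  ord <- order(x, method = "radix")
  xs <- x[ord]
  i_max <- m - min_leaf
  if (i_max < min_leaf) return(NULL)
  valid <- seq_len(m - 1L) >= min_leaf & seq_len(m - 1L) <= i_max &
    xs[-m] < xs[-1L]
  if (!any(valid)) return(NULL)
  idx <- seq_len(m - 1L)
  if (kind == "continuous") {
    ys <- y[ord]
    s1 <- cumsum(ys)
    tot <- s1[m]
    # impurity decrease = between-group sum of squares of the 2-way split
    dec <- s1[idx]^2 / idx + (tot - s1[idx])^2 / (m - idx) - tot^2 / m
  } else {
    K <- attr(y, "n_class")
    ys <- unclass(y)[ord]
    M <- vapply(seq_len(K), function(k) cumsum(ys == k), numeric(m))
    if (m == 1L) M <- matrix(M, nrow = 1L)
    totc <- M[m, ]
    left <- idx - rowSums(M[idx, , drop = FALSE]^2) / idx
    Rm <- matrix(totc, nrow = m - 1L, ncol = K, byrow = TRUE) -
      M[idx, , drop = FALSE]
    right <- (m - idx) - rowSums(Rm^2) / (m - idx)
    dec <- (m - sum(totc^2) / m) - left - right
  }
  dec[!valid] <- -Inf
  i <- which.max(dec)  # first maximum = smallest threshold
  if (!is.finite(dec[i]) || dec[i] <= 0) return(NULL)
  list(dec = dec[i], threshold = (xs[i] + xs[i + 1L]) / 2)
}

# Categorical predictor: order observed levels by mean response
# (continuous) or event rate (binary), then scan as an ordered variable.
best_categorical_split <- function(x, y, kind, min_leaf) {
  lv <- levels(droplevels(x))
  if (length(lv) < 2L) return(NULL)
  x <- droplevels(x)
  score <- if (kind == "continuous") {
    vapply(split(y, x), mean, numeric(1))
  } else {
    if (attr(y, "n_class") > 2L) {
      stop("categorical predictors require a continuous or binary response")
    }
    vapply(split(unclass(y) == 2L, x), mean, numeric(1))
  }
  ord_lv <- lv[order(score, seq_along(lv))]  # ties keep level order
  rank_x <- match(as.character(x), ord_lv)
  sp <- best_numeric_split(rank_x, y, kind, min_leaf)
  if (is.null(sp)) return(NULL)
  sp$left_levels <- ord_lv[seq_len(floor(sp$threshold))]
  sp
}

#' Fit a classification or regression tree
#'
#' Greedy binary recursive partitioning by exhaustive split search:
#' impurity is the within-node sum of squared deviations for continuous
#' responses and the Gini index for categorical ones; numeric predictors
#' are scanned over every distinct threshold, categorical predictors over
#' mean-ordered (or event-rate-ordered) level groupings — the classical
#' exact shortcut for continuous and binary responses. Splitting stops
#' when `min_split`, `min_leaf`, `complexity` (relative to the root
#' impurity) or `max_depth` binds. Ties among equally good splits are
#' broken by predictor order, then by the smaller threshold. Each leaf
#' stores the multiset of observed response values (its donors).
#'
#' @param predictors Data frame of predictor columns (numeric or factor);
#'   no missing values.
#' @param response Response vector (numeric, or factor/binary for
#'   categorical trees); no missing values.
#' @param kind `"continuous"` or `"categorical"`.
#' @param control A [tree_control()].
#' @return A `cart_tree` object.
#' @export
fit_tree <- function(predictors, response,
                     kind = c("continuous", "categorical"),
                     control = tree_control()) {
  kind <- match.arg(kind)
  if (!is.data.frame(predictors) || ncol(predictors) < 1L) {
    stop("predictors must be a data frame with at least one column")
  }
  n <- nrow(predictors)
  if (n == 0L || length(response) == 0L) stop("empty input")
  if (length(response) != n) stop("response length must match predictor rows")
  if (anyNA(response) || any(vapply(predictors, anyNA, logical(1)))) {
    stop("missing values are not allowed in tree fitting")
  }
  predictors <- as.data.frame(predictors)
  for (j in seq_along(predictors)) {
    if (is.character(predictors[[j]]) || is.logical(predictors[[j]])) {
      predictors[[j]] <- factor(predictors[[j]])
    }
  }
  raw_response <- response
  if (kind == "categorical") {
    fy <- factor(response)
    y <- structure(as.integer(fy), n_class = nlevels(fy), class_levels = levels(fy))
  } else {
    if (!is.numeric(response)) stop("continuous response must be numeric")
    y <- response
  }

  root_imp <- node_impurity(y, kind)
  min_dec <- control$complexity * max(root_imp, .Machine$double.eps)
  leaves <- list()
  next_id <- 0L

  build <- function(rows, depth) {
    m <- length(rows)
    imp <- node_impurity(if (kind == "categorical") {
      structure(unclass(y)[rows], n_class = attr(y, "n_class"))
    } else y[rows], kind)
    make_leaf <- function() {
      next_id <<- next_id + 1L
      leaves[[next_id]] <<- raw_response[rows]
      list(leaf = TRUE, id = next_id, n = m)
    }
    if (m < control$min_split || depth >= control$max_depth || imp <= 0) {
      return(make_leaf())
    }
    yy <- if (kind == "categorical") {
      structure(unclass(y)[rows], n_class = attr(y, "n_class"))
    } else y[rows]
    best <- NULL; best_var <- NA_integer_
    for (j in seq_along(predictors)) {
      xj <- predictors[[j]][rows]
      sp <- if (is.factor(xj)) {
        best_categorical_split(xj, yy, kind, control$min_leaf)
      } else {
        best_numeric_split(xj, yy, kind, control$min_leaf)
      }
      if (is.null(sp)) next
      # smallest-threshold ties are resolved inside the per-predictor scan;
      # requiring a strictly better decrease here keeps the lowest-index
      # predictor on cross-predictor ties
      if (is.null(best) || sp$dec > best$dec + 1e-12) { best <- sp; best_var <- j }
    }
    if (is.null(best) || best$dec < min_dec) return(make_leaf())
    xj <- predictors[[best_var]][rows]
    if (is.factor(xj)) {
      go_left <- as.character(xj) %in% best$left_levels
      right_levels <- setdiff(levels(droplevels(xj)), best$left_levels)
      node <- list(leaf = FALSE, var = names(predictors)[best_var],
                   type = "categorical", threshold = best$threshold,
                   left_levels = best$left_levels, right_levels = right_levels,
                   n = m)
    } else {
      go_left <- xj <= best$threshold
      node <- list(leaf = FALSE, var = names(predictors)[best_var],
                   type = "numeric", threshold = best$threshold, n = m)
    }
    node$majority <- if (sum(go_left) >= sum(!go_left)) "left" else "right"
    node$left <- build(rows[go_left], depth + 1L)
    node$right <- build(rows[!go_left], depth + 1L)
    node
  }

  root <- build(seq_len(n), 0L)
  structure(list(root = root, leaves = leaves, response_kind = kind,
                 predictor_names = names(predictors),
                 n_train = n, root_impurity = root_imp, control = control),
            class = "cart_tree")
}

#' Route rows to tree leaves
#'
#' Deterministically traverses the fitted tree for each row of
#' `new_predictors` and returns the leaf identifier. A category never seen
#' at a split routes to the side that held the majority of that node's
#' training records; a missing predictor value is an error.
#'
#' @param tree A `cart_tree` from [fit_tree()].
#' @param new_predictors Data frame supplying every predictor the tree
#'   splits on.
#' @return Integer vector of leaf ids, one per row.
#' @export
assign_leaf <- function(tree, new_predictors) {
  stopifnot(inherits(tree, "cart_tree"))
  n <- nrow(new_predictors)
  out <- integer(n)
  walk <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (isTRUE(node$leaf)) {
      out[idx] <<- node$id
      return(invisible())
    }
    x <- new_predictors[[node$var]]
    if (is.null(x)) stop("predictor '", node$var, "' absent from new data")
    x <- x[idx]
    if (anyNA(x)) stop("missing value in predictor '", node$var, "'")
    if (node$type == "numeric") {
      go_left <- x <= node$threshold
    } else {
      ch <- as.character(x)
      go_left <- ch %in% node$left_levels
      unseen <- !(ch %in% node$left_levels) & !(ch %in% node$right_levels)
      if (any(unseen)) go_left[unseen] <- node$majority == "left"
    }
    walk(node$left, idx[go_left])
    walk(node$right, idx[!go_left])
  }
  walk(tree$root, seq_len(n))
  out
}

#' Generate synthetic values from a fitted tree
#'
#' Routes each new row to its leaf and draws one donor value uniformly
#' with replacement from that leaf's stored multiset of observed response
#' values (no smoothing; every synthetic value is an observed value).
#' With `proper = TRUE` each leaf's donor pool is bootstrap-resampled
#' before drawing, giving proper synthesis; the default is the improper
#' direct draw. Draws consume the current RNG stream, so results are
#' reproducible after `set.seed()`.
#'
#' @param tree A `cart_tree`.
#' @param new_predictors Data frame of predictor values.
#' @param proper Bootstrap each leaf's donor pool before drawing?
#' @return Vector of synthetic values, one per row, typed like the
#'   training response.
#' @export
synthesize_variable <- function(tree, new_predictors, proper = FALSE) {
  leaf <- assign_leaf(tree, new_predictors)
  template <- tree$leaves[[1L]]
  out <- rep(template[1L], length(leaf))
  for (id in sort(unique(leaf))) {
    idx <- which(leaf == id)
    pool <- tree$leaves[[id]]
    if (length(pool) == 0L) stop("internal error: empty leaf ", id)
    if (proper) pool <- pool[sample.int(length(pool), length(pool), replace = TRUE)]
    out[idx] <- pool[sample.int(length(pool), length(idx), replace = TRUE)]
  }
  out
}
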