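# independent brute-force oracle for the first CART split: enumerates every
# numeric threshold and every categorical level subset, computes the exact
# impurity decrease, and returns the best with the lowest-predictor-index /
# smallest-threshold tie rule

sse_of <- function(y) sum((y - mean(y))^2)
gini_of <- function(y) { p <- table(y) / length(y); length(y) * (1 - sum(p^2)) }

brute_force_first_split <- function(X, y, kind, min_leaf = 5) {
  imp <- if (kind == "continuous") sse_of else gini_of
  total <- imp(y)
  best <- NULL
  consider <- function(mask, j, thr) {
    nl <- sum(mask); nr <- sum(!mask)
    if (nl < min_leaf || nr < min_leaf) return()
    dec <- total - imp(y[mask]) - imp(y[!mask])
    if (is.null(best) || dec > best$dec + 1e-12) {
      best <<- list(dec = dec, var = j, threshold = thr, mask = mask)
    }
  }
  for (j in seq_along(X)) {
    x <- X[[j]]
    if (is.numeric(x)) {
      ux <- sort(unique(x))
      if (length(ux) < 2) next
      for (i in seq_len(length(ux) - 1)) {
        thr <- (ux[i] + ux[i + 1]) / 2
        consider(x <= thr, j, thr)
      }
    } else {
      lv <- levels(droplevels(factor(x)))
      L <- length(lv)
      if (L < 2) next
      # all subsets containing the first level (canonical halves)
      for (code in 0:(2^(L - 1) - 1)) {
        left <- lv[c(TRUE, as.logical(bitwAnd(code, 2^(0:(L - 2))) > 0))[seq_len(L)]]
        if (length(left) == 0 || length(left) == L) next
        consider(as.character(x) %in% left, j, NA_real_)
      }
    }
  }
  best
}

# partition (left mask) induced by a fitted tree's root split
root_split_mask <- function(tree, X) {
  node <- tree$root
  if (isTRUE(node$leaf)) return(NULL)
  x <- X[[node$var]]
  if (node$type == "numeric") x <= node$threshold
  else as.character(x) %in% node$left_levels
}
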