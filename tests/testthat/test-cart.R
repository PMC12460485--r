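test_that("degenerate fits behave: constant response, too-small nodes, errors", {
  X <- data.frame(x = 1:20)
  tr <- fit_tree(X, rep(5, 20), "continuous")
  expect_true(tr$root$leaf)
  expect_equal(tr$leaves[[1]], rep(5, 20))
  # a perfect 4/4 split is refused when min_leaf = 5 binds
  X8 <- data.frame(x = 1:8)
  y8 <- c(rep(0, 4), rep(100, 4))
  tr8 <- fit_tree(X8, y8, "continuous")
  expect_true(tr8$root$leaf)
  expect_error(fit_tree(data.frame(x = numeric(0)), numeric(0), "continuous"),
               "empty")
  expect_error(fit_tree(data.frame(x = c(1, NA)), c(1, 2), "continuous",
                        tree_control(min_leaf = 1, min_split = 2)), "missing")
})

test_that("step data: the single split matches the exhaustive threshold scan", {
  X <- data.frame(x = 1:10)
  y <- c(rep(0, 5), rep(100, 5))
  tr <- fit_tree(X, y, "continuous")
  expect_false(tr$root$leaf)
  expect_equal(tr$root$threshold, 5.5)
  oracle <- brute_force_first_split(X, y, "continuous", min_leaf = 5)
  expect_equal(tr$root$threshold, oracle$threshold)
  expect_true(tr$root$left$leaf && tr$root$right$leaf)
  expect_setequal(tr$leaves[[assign_leaf(tr, data.frame(x = 2))]], rep(0, 5))
  expect_setequal(tr$leaves[[assign_leaf(tr, data.frame(x = 9))]], rep(100, 5))
})

test_that("first split equals the global brute-force optimum on small instances", {
  set.seed(101)
  ctrl <- tree_control(min_leaf = 2, min_split = 4)
  for (rep in 1:25) {
    n <- sample(8:12, 1)
    kind <- sample(c("continuous", "categorical"), 1)
    X <- data.frame(a = round(stats::rnorm(n), 3),
                    b = factor(sample(letters[1:3], n, replace = TRUE)))
    y <- if (kind == "continuous") round(stats::rnorm(n), 3)
         else sample(0:1, n, replace = TRUE)
    tr <- fit_tree(X, y, kind, ctrl)
    oracle <- brute_force_first_split(X, y, kind, min_leaf = 2)
    if (is.null(oracle) || oracle$dec <= 1e-12) {
      expect_true(tr$root$leaf)
    } else {
      expect_false(tr$root$leaf)
      mask <- root_split_mask(tr, X)
      imp <- if (kind == "continuous") sse_of else gini_of
      achieved <- imp(y) - imp(y[mask]) - imp(y[!mask])
      expect_equal(achieved, oracle$dec, tolerance = 1e-10)
    }
  }
})

test_that("leaves partition the training data and donors equal the response multiset", {
  set.seed(55)
  n <- 300
  X <- data.frame(x = stats::rnorm(n), g = factor(sample(1:6, n, TRUE)))
  y <- as.numeric(X$g) * 10 + stats::rnorm(n)
  tr <- fit_tree(X, y, "continuous")
  expect_equal(sort(unlist(tr$leaves)), sort(y))
  # every training row routes to a leaf holding >= min_leaf donors
  ids <- assign_leaf(tr, X)
  sizes <- vapply(tr$leaves, length, integer(1))
  expect_true(all(sizes >= 5))
  expect_equal(sort(unique(ids)), seq_along(tr$leaves))
  # training rows land in the leaf whose donors include their own response
  expect_true(all(vapply(seq_len(n), function(i) y[i] %in% tr$leaves[[ids[i]]],
                         logical(1))))
})

test_that("every accepted split strictly decreases impurity", {
  set.seed(66)
  X <- data.frame(x = stats::rnorm(120), z = stats::rnorm(120))
  y <- X$x * 3 + stats::rnorm(120)
  tr <- fit_tree(X, y, "continuous")
  check <- function(node, rows) {
    if (isTRUE(node$leaf)) return(invisible())
    x <- X[[node$var]][rows]
    mask <- if (node$type == "numeric") x <= node$threshold
            else as.character(x) %in% node$left_levels
    dec <- sse_of(y[rows]) - sse_of(y[rows][mask]) - sse_of(y[rows][!mask])
    expect_gt(dec, 0)
    check(node$left, rows[mask])
    check(node$right, rows[!mask])
  }
  check(tr$root, seq_len(120))
})

test_that("leaf assignment is deterministic and unseen levels take the majority side", {
  set.seed(77)
  X <- data.frame(g = factor(rep(c("a", "b", "c"), times = c(12, 8, 10))))
  # right-hand side is constant so it stays a single leaf
  y <- c(rnorm(12, 0), rep(50, 18))
  tr <- fit_tree(X, y, "continuous")
  expect_false(tr$root$leaf)
  row <- data.frame(g = factor("b", levels = c("a", "b", "c")))
  expect_identical(assign_leaf(tr, row), assign_leaf(tr, row))
  # unseen level: routed with the larger child ("b","c" side holds 18 > 12)
  unseen <- data.frame(g = "zz")
  expect_equal(assign_leaf(tr, unseen),
               assign_leaf(tr, data.frame(g = "b")))
  expect_error(assign_leaf(tr, data.frame(g = NA_character_)), "missing")
})

test_that("synthetic values are always observed donor values from the assigned leaf", {
  # two well-separated leaves: draws never cross over
  X <- data.frame(x = 1:10)
  y <- c(1, 2, 1, 2, 1, 9, 10, 9, 10, 9)
  tr <- fit_tree(X, y, "continuous")
  set.seed(1)
  lows <- replicate(100, synthesize_variable(tr, data.frame(x = 3)))
  expect_true(all(lows %in% c(1, 2)))
  # membership over a larger random panel
  set.seed(2)
  n <- 200
  Xr <- data.frame(x = rnorm(n))
  yr <- round(rnorm(n), 4)
  trr <- fit_tree(Xr, yr, "continuous")
  draws <- replicate(5, synthesize_variable(trr, Xr))
  expect_true(all(draws %in% yr))
  # single-leaf tree on a constant response returns the constant
  trc <- fit_tree(data.frame(x = 1:20), rep(7, 20), "continuous")
  expect_equal(synthesize_variable(trc, data.frame(x = c(0, 100))), c(7, 7))
})

test_that("self-synthesis preserves the response distribution as well as a bootstrap", {
  set.seed(303)
  n <- 400
  X <- data.frame(x = rnorm(n))
  y <- X$x * 2 + rnorm(n)
  tr <- fit_tree(X, y, "continuous")
  ks <- function(a, b) suppressWarnings(stats::ks.test(a, b)$statistic)
  d_syn <- replicate(30, ks(synthesize_variable(tr, X), y))
  d_boot <- replicate(30, ks(sample(y, n, replace = TRUE), y))
  expect_lte(mean(d_syn), mean(d_boot) * 1.05)
})

test_that("first split agrees with rpart on a shared configuration", {
  skip_if_not_installed("rpart")
  set.seed(404)
  n <- 150
  X <- data.frame(u = rnorm(n), v = rnorm(n))
  y <- ifelse(X$u > 0.3, 10, 0) + rnorm(n, sd = 0.5)
  tr <- fit_tree(X, y, "continuous")
  rp <- rpart::rpart(y ~ u + v, data = cbind(X, y), method = "anova",
                     control = rpart::rpart.control(minbucket = 5,
                                                    minsplit = 10, cp = 1e-8,
                                                    xval = 0))
  expect_equal(tr$root$var, as.character(rp$frame$var[1]))
  expect_equal(tr$root$threshold, rp$splits[1, "index"], tolerance = 1e-8)
})
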