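test_that("named conditions encode the documented conditioning sets", {
  b <- build_condition("base", "independent")
  al <- b$visit_sequence[[3]]
  expect_equal(al$name, "AcuteLoad")
  expect_equal(al$predictors$name, c("Injury", "PlayerID"))
  expect_true(all(al$predictors$source == "original"))
  cl <- b$visit_sequence[[4]]
  expect_equal(cl$name, "ChronicLoad")
  expect_equal(cl$predictors$name, c("Injury", "PlayerID", "AcuteLoad"))
  expect_equal(cl$predictors$source, c("original", "original", "synthetic"))

  bw <- build_condition("base_week", "independent")
  expect_true("WeekID" %in% bw$visit_sequence[[4]]$predictors$name)

  np <- build_condition("no_playerid", "independent")
  al7 <- Find(function(s) s$name == "AcuteLoad", np$visit_sequence)
  expect_equal(al7$predictors$name,
               c("AL_Lag1", "AL_Lag2", "AL_Lag3", "CL_Lag1", "CL_Lag2", "CL_Lag3"))
  expect_true(all(al7$predictors$source == "original"))
  inj7 <- Find(function(s) s$name == "Injury", np$visit_sequence)
  expect_equal(inj7$method, "cart")
  expect_equal(tail(inj7$predictors$name, 2), c("AcuteLoad", "ChronicLoad"))
  expect_equal(tail(inj7$predictors$source, 2), c("synthetic", "synthetic"))

  itl <- build_condition("injury_time_lag", "independent")
  expect_equal(itl$visit_sequence[[1]]$name, "Injury")
  expect_equal(itl$visit_sequence[[1]]$method, "random_sample")

  calc <- build_condition("base", "calculated")
  cl_calc <- Find(function(s) s$name == "ChronicLoad", calc$visit_sequence)
  expect_equal(cl_calc$method, "derived")
  expect_equal(cl_calc$derived_rule, "chronic_from_acute")

  expect_error(build_condition("bogus", "independent"), "valid conditions")
  expect_error(build_condition("base", "sideways"))
})

test_that("validate_plan reports ordering and missing-column violations", {
  p <- default_fixture()
  good <- build_condition("base", "independent")
  res <- validate_plan(good, p)
  expect_true(res$valid)
  # CL conditions on synthetic AL but AL comes later
  bad <- synthesis_plan(list(
    variable_spec("ChronicLoad", "cart",
                  predictors = data.frame(name = "AcuteLoad", source = "synthetic")),
    variable_spec("AcuteLoad", "cart",
                  predictors = data.frame(name = "Injury", source = "original"))),
    "independent")
  res2 <- validate_plan(bad, p)
  expect_false(res2$valid)
  expect_match(res2$problems, "ordering violation", all = FALSE)
  # lag predictor absent from the panel
  res3 <- validate_plan(build_condition("time_lag_3wks", "independent"),
                        p[, setdiff(names(p), "AL_Lag2")])
  expect_false(res3$valid)
  expect_match(res3$problems, "AL_Lag2", all = FALSE)
})

test_that("an all-fixed plan is the identity and fixed columns never change", {
  p <- default_fixture()
  ident <- synthesis_plan(lapply(c("Injury", "PlayerID", "AcuteLoad",
                                   "ChronicLoad"), variable_spec,
                                 method = "fixed"), "independent")
  expect_identical(synthesize(p, ident, seed = 4), p)
  for (cond in c("base", "time_lag_3wks", "injury_time_lag", "no_playerid")) {
    plan <- build_condition(cond, "independent")
    fixed_vars <- vapply(Filter(function(s) s$method == "fixed",
                                plan$visit_sequence), `[[`, character(1), "name")
    syn <- synthesize(p, plan, seed = 5)
    for (v in c(fixed_vars, "WeekID")) expect_identical(syn[[v]], p[[v]])
    expect_equal(dim(syn), dim(p))
  }
})

test_that("synthesis is seed-reproducible and varies across seeds", {
  p <- default_fixture()
  plan <- build_condition("base", "independent")
  s1 <- synthesize(p, plan, seed = 99)
  expect_identical(s1, synthesize(p, plan, seed = 99))
  s2 <- synthesize(p, plan, seed = 100)
  expect_gt(sum(s1$AcuteLoad != s2$AcuteLoad), 0)
})

test_that("the calculated scenario enforces the load-coupling identity", {
  p <- default_fixture()
  syn <- synthesize(p, build_condition("base", "calculated"), seed = 6)
  expect_equal(syn$ChronicLoad, derive_chronic_load(syn)$ChronicLoad)
  # and the independent scenario draws chronic load from observed donors
  syn_i <- synthesize(p, build_condition("base", "independent"), seed = 6)
  got <- syn_i$ChronicLoad[!is.na(syn_i$ChronicLoad)]
  expect_true(all(got %in% p$ChronicLoad))
  # missing-window rows stay missing in both scenarios
  expect_identical(is.na(syn$ChronicLoad), is.na(p$ChronicLoad))
  expect_identical(is.na(syn_i$ChronicLoad), is.na(p$ChronicLoad))
})

test_that("synthetic acute load values are members of the observed donor set", {
  p <- default_fixture()
  for (cond in c("base", "time_lag_1wk")) {
    syn <- synthesize(p, build_condition(cond, "independent"), seed = 8)
    expect_true(all(syn$AcuteLoad %in% p$AcuteLoad))
  }
})

test_that("random-sample injury counts follow the binomial law of the observed rate", {
  set.seed(14)
  n <- 600
  p <- make_panel(players = 4, weeks = 150,
                  al = round(runif(600, 1000, 3000)),
                  injury = rbinom(n, 1, 0.06))
  plan <- synthesis_plan(list(variable_spec("Injury", "random_sample")),
                         "independent")
  rate <- mean(p$Injury)
  lim <- qbinom(c(0.005, 0.995), n, rate)
  hits <- replicate(200, {
    cnt <- sum(synthesize(p, plan)$Injury)
    cnt >= lim[1] && cnt <= lim[2]
  })
  expect_gte(mean(hits), 0.97)
})

test_that("synthesized marginals stay close to the originals (KS over seeds)", {
  p <- default_fixture()
  plan <- build_condition("base", "independent")
  ks <- function(a, b) suppressWarnings(stats::ks.test(a, b)$statistic)
  set.seed(15)
  d <- replicate(20, {
    syn <- synthesize(p, plan, seed = sample.int(1e8, 1))
    c(ks(syn$AcuteLoad, p$AcuteLoad),
      ks(syn$ChronicLoad[!is.na(syn$ChronicLoad)],
         p$ChronicLoad[!is.na(p$ChronicLoad)]))
  })
  expect_lt(mean(d[1, ]), 0.1)
  expect_lt(mean(d[2, ]), 0.1)
})
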