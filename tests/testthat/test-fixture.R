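test_that("default fixture has the study dimensions and is seed-reproducible", {
  p <- default_fixture()
  expect_equal(nrow(p), 34 * 120)
  expect_equal(nlevels(p$PlayerID), 34)
  expect_equal(range(p$WeekID), c(1, 120))
  expect_true(all(p$AcuteLoad >= 0))
  expect_silent(validate_panel(p))
  # byte-identical regeneration from the same seed
  q <- generate_fixture(fixture_config())
  expect_identical(q, generate_fixture(fixture_config()))
  # chronic load is exactly the uncoupled trailing mean of acute load
  expect_equal(q$ChronicLoad, derive_chronic_load(q)$ChronicLoad)
})

test_that("injury generation follows the logistic model", {
  # essentially impossible injuries at beta0 = -20
  p <- generate_fixture(fixture_config(beta0 = -20, beta1 = 0, seed = 3))
  expect_equal(sum(p$Injury), 0)
  # weeks without a full chronic window never carry an injury
  p <- default_fixture()
  expect_true(all(p$Injury[is.na(p$ChronicLoad)] == 0))
  # Monte-Carlo check of the marginal rate with a flat model
  target <- 0.05
  cfg <- fixture_config(beta0 = qlogis(target), beta1 = 0, sd_frailty = 0,
                        seed = 11)
  p <- generate_fixture(cfg)
  ok <- !is.na(p$ChronicLoad) & p$ChronicLoad > 0
  n <- sum(ok)
  se <- sqrt(target * (1 - target) / n)
  expect_lt(abs(mean(p$Injury[ok]) - target), 3 * se)
})

test_that("post-injury load reduction feeds back into the series", {
  cfg <- fixture_config(beta0 = 5, beta1 = 0, sd_frailty = 0,
                        post_injury_multiplier = 0.5, seed = 2)
  # beta0 = 5 makes injury near-certain on every eligible week
  p <- generate_fixture(cfg)
  base <- generate_fixture(fixture_config(beta0 = 5, beta1 = 0, sd_frailty = 0,
                                          post_injury_multiplier = 1, seed = 2))
  inj_weeks <- which(base$Injury == 1 & base$WeekID < 120)
  expect_gt(length(inj_weeks), 100)
  expect_true(all(p$AcuteLoad[inj_weeks + 1] <= base$AcuteLoad[inj_weeks + 1]))
  expect_lt(mean(p$AcuteLoad), mean(base$AcuteLoad))
})

test_that("baseline-risk calibration is exact, monotone and verified by simulation", {
  cfg0 <- fixture_config(beta1 = 0, sd_frailty = 0)
  expect_equal(as.numeric(calibrate_baseline_risk(cfg0, 0.07)), qlogis(0.07))
  cfg <- fixture_config(n_players = 12, n_weeks = 60, seed = 5)
  b8 <- calibrate_baseline_risk(cfg, 0.08, tol = 0.004, n_rep = 8)
  b4 <- calibrate_baseline_risk(cfg, 0.04, tol = 0.004, n_rep = 8)
  expect_gt(as.numeric(b8), as.numeric(b4))
  # fresh-simulation check of the calibrated value
  cfg$beta0 <- as.numeric(b4)
  cfg$seed <- 909
  rates <- vapply(1:8, function(i) {
    cfg$seed <- 909 + i
    p <- generate_fixture(cfg)
    ok <- !is.na(p$ChronicLoad) & p$ChronicLoad > 0
    mean(p$Injury[ok])
  }, numeric(1))
  expect_lt(abs(mean(rates) - 0.04), 0.01)
})

test_that("fixture summary recovers the configured AR(1) autocorrelation", {
  s <- summarize_fixture(default_fixture())
  expect_lt(abs(s$al_lag1_autocor - 0.5), 0.1)
  expect_equal(s$n_players, 34)
  # degenerate constant-load panel: SD 0, autocorrelation reported missing
  p <- make_panel(players = 2, weeks = 8)
  s0 <- summarize_fixture(p)
  expect_equal(s0$al_sd, 0)
  expect_true(is.na(s0$al_lag1_autocor))
  expect_equal(s0$injury_rate, 0)
})

test_that("player frailty induces within-player injury clustering", {
  # overdispersion of per-player injury counts, relative to binomial,
  # should be larger with frailty than without (averaged over seeds)
  overdisp <- function(sd_frailty, seed) {
    p <- generate_fixture(fixture_config(sd_frailty = sd_frailty, seed = seed))
    ok <- !is.na(p$ChronicLoad) & p$ChronicLoad > 0
    d <- p[ok, ]
    counts <- tapply(d$Injury, droplevels(d$PlayerID), sum)
    m <- tapply(rep(1, nrow(d)), droplevels(d$PlayerID), sum)
    rate <- sum(counts) / sum(m)
    sum((counts - m * rate)^2 / (m * rate * (1 - rate))) / (length(counts) - 1)
  }
  set.seed(13)
  seeds <- sample.int(1e6, 8)
  with_fr <- vapply(seeds, function(s) overdisp(0.8, s), numeric(1))
  without <- vapply(seeds, function(s) overdisp(0, s), numeric(1))
  expect_gt(mean(with_fr), mean(without))
  expect_gt(mean(with_fr), 1.5)
})
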