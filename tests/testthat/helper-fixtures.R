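# small panels built in code for unit tests

make_panel <- function(players = 2, weeks = 6, al = NULL, injury = NULL) {
  n <- players * weeks
  if (is.null(al)) al <- rep(100, n)
  if (is.null(injury)) injury <- rep(0L, n)
  data.frame(
    PlayerID = factor(rep(seq_len(players), each = weeks)),
    WeekID = rep(seq_len(weeks), players),
    AcuteLoad = al,
    ChronicLoad = NA_real_,
    Injury = injury)
}

# default study fixture with lags, shared across test files
default_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- add_lag_features(generate_fixture(fixture_config()))
    }
    cache
  }
})

# brute-force per-player trailing-mean oracle for chronic load
oracle_chronic <- function(panel, block_weeks = 4, uncoupled = TRUE) {
  k <- if (uncoupled) block_weeks - 1 else block_weeks
  off <- if (uncoupled) 1 else 0
  out <- rep(NA_real_, nrow(panel))
  for (pl in levels(panel$PlayerID)) {
    idx <- which(panel$PlayerID == pl)
    for (t in seq_along(idx)) {
      lo <- t - off - k + 1; hi <- t - off
      if (lo >= 1) out[idx[t]] <- mean(panel$AcuteLoad[idx[lo:hi]])
    }
  }
  out
}

# brute-force shift oracle for lags
oracle_lag <- function(panel, var, k) {
  out <- rep(NA_real_, nrow(panel))
  for (pl in levels(panel$PlayerID)) {
    idx <- which(panel$PlayerID == pl)
    if (length(idx) > k) out[idx[(k + 1):length(idx)]] <- panel[[var]][idx[1:(length(idx) - k)]]
  }
  out
}
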